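#' Count the methionine pool of a proteome subset
#'
#' Counts M residues across the given records. With
#' `exclude_initiator = TRUE`, the methionine at the first position of each
#' record (the translation-initiator reading) is not counted; no
#' signal-peptide prediction is attempted.
#'
#' @param proteome A `proteome` data frame.
#' @param exclude_initiator Drop the position-1 M of each record.
#' @return Integer count.
#' @examples
#' count_methionine_pool(proteome("p", "MKM"))          # 1
#' count_methionine_pool(proteome("p", "MKM"), FALSE)   # 2
#' @export
count_methionine_pool <- function(proteome, exclude_initiator = TRUE) {
  if (nrow(proteome) == 0) return(0L)
  total <- sum(nchar(proteome$sequence) -
                 nchar(gsub("M", "", proteome$sequence, fixed = TRUE)))
  if (exclude_initiator) {
    total <- total - sum(substring(proteome$sequence, 1, 1) == "M")
  }
  as.integer(total)
}

#' Method-of-Exclusion filter for M-anchored candidate windows
#'
#' Filters 11-residue candidate windows of the form M followed by ten
#' residues, removing any window whose residues 2-11 contain a residue
#' outside the allowed set minus M (the leading M is "used up" as the first
#' residue, so a second M is excluding). Survivors are scored by
#' `distinct_allowed_count`: the number of distinct residues of the full
#' 11-mer that belong to the allowed set, repeats counted once.
#'
#' @param windows A character vector of 11-mers, or a data frame with
#'   columns `protein_id`, `start`, `window`.
#' @param allowed_residues The allowed residue set (default `"MKPLTGVEF"`,
#'   the unique residues of the reference peptide less its NNI suffix).
#' @param excluded_extra Residues excluding beyond the complement of the
#'   allowed set; defaults to `"M"` (the consumed anchor).
#' @return A data frame of survivors with columns `protein_id`, `start`,
#'   `window`, `distinct_allowed_count`, sorted by descending
#'   `distinct_allowed_count` then by (`protein_id`, `start`).
#' @examples
#' method_of_exclusion(c("MLKTGEKPVEP", "MLKTGEKPVEW"))
#' @export
method_of_exclusion <- function(windows,
                                allowed_residues = "MKPLTGVEF",
                                excluded_extra = "M") {
  if (is.character(windows)) {
    windows <- data.frame(protein_id = paste0("w", seq_along(windows)),
                          start = seq_along(windows), window = windows,
                          stringsAsFactors = FALSE)
  }
  allowed <- unique(strsplit(toupper(allowed_residues), "")[[1]])
  stopifnot(all(allowed %in% AA_CANONICAL))
  extra <- unique(strsplit(toupper(excluded_extra), "")[[1]])
  if (nrow(windows) == 0) {
    return(data.frame(protein_id = character(0), start = integer(0),
                      window = character(0),
                      distinct_allowed_count = integer(0),
                      stringsAsFactors = FALSE))
  }
  w <- toupper(windows$window)
  if (any(nchar(w) != 11L) || any(substring(w, 1, 1) != "M")) {
    bad <- which(nchar(w) != 11L | substring(w, 1, 1) != "M")
    stop("window(s) not an M-initial 11-mer at index: ",
         paste(bad, collapse = ", "))
  }
  tail_ok <- vapply(strsplit(substring(w, 2), ""), function(ch) {
    all(ch %in% setdiff(allowed, extra))
  }, logical(1))
  out <- windows[tail_ok, , drop = FALSE]
  out$window <- w[tail_ok]
  out$distinct_allowed_count <- vapply(strsplit(out$window, ""), function(ch) {
    length(intersect(unique(ch), allowed))
  }, integer(1))
  out <- out[order(-out$distinct_allowed_count, out$protein_id, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("protein_id", "start", "window", "distinct_allowed_count")]
}

#' Run the full motif census ("sift") over a proteome
#'
#' Computes, for a proteome and a core motif (e.g. NNI): the motif-ome (the
#' proteins carrying at least one motif occurrence), total and C-terminal
#' occurrence counts, occurrence counts of extended sub-patterns (e.g. FNNI,
#' EFNNI) within the motif-ome, the count of short motif-ome proteins, the
#' non-initiator methionine pool of the motif-ome, the anchored-window hits
#' (e.g. `M..........NNI`), and the Method-of-Exclusion survivors among the
#' windows' M-anchored 11-mers.
#'
#' @param proteome A `proteome` data frame.
#' @param motif Core motif (string or `motif_pattern`), default `"NNI"`.
#' @param sub_patterns Character vector of sub-patterns to tally within the
#'   motif-ome (default `c("FNNI", "EFNNI")`).
#' @param short_threshold Residue-count threshold below which a motif-ome
#'   protein counts as short (default 100).
#' @param window_pattern Anchored window pattern (default
#'   `"M..........NNI"`).
#' @param allowed_residues Allowed set for the Method of Exclusion.
#' @param overlap Count overlapping occurrences (default `TRUE`).
#' @return An object of class `sift_report`: a list with elements
#'   `proteome_size`, `motif_ome_size`, `total_hits`, `terminal_hits`,
#'   `sub_pattern_counts` (named integer vector), `short_protein_count`,
#'   `methionine_pool`, `anchored_windows` (data frame),
#'   `exclusion_survivors` (data frame), `motif_ome_ids`, and the
#'   parameters used.
#' @export
build_sift_report <- function(proteome,
                              motif = "NNI",
                              sub_patterns = c("FNNI", "EFNNI"),
                              short_threshold = 100L,
                              window_pattern = "M..........NNI",
                              allowed_residues = "MKPLTGVEF",
                              overlap = TRUE) {
  motif <- as_motif_pattern(motif)
  hits <- scan_motif(proteome, motif, overlap = overlap)
  ome_ids <- unique(hits$protein_id)
  ome <- proteome[proteome$id %in% ome_ids, , drop = FALSE]

  sub_counts <- vapply(sub_patterns, function(p) {
    nrow(scan_motif(ome, p, overlap = overlap))
  }, integer(1))
  names(sub_counts) <- vapply(lapply(sub_patterns, as_motif_pattern),
                              format, character(1))

  windows <- anchored_window_search(ome, window_pattern, overlap = overlap)
  wp <- as_motif_pattern(window_pattern)
  candidates <- windows
  if (nrow(candidates) > 0) {
    # the M-anchored 11-mer candidate is the window less its fixed suffix
    suffix_len <- sum(!is.na(rev(wp$slots)) &
                        cumsum(is.na(rev(wp$slots))) == 0)
    candidates$window <- substring(candidates$window, 1,
                                   wp$length - suffix_len)
  }
  survivors <- method_of_exclusion(candidates[, c("protein_id", "start", "window")],
                                   allowed_residues = allowed_residues)

  structure(list(
    proteome_size = nrow(proteome),
    motif_ome_size = length(ome_ids),
    total_hits = nrow(hits),
    terminal_hits = sum(hits$c_terminal),
    sub_pattern_counts = sub_counts,
    short_protein_count = sum(ome$length < short_threshold),
    methionine_pool = count_methionine_pool(ome, exclude_initiator = TRUE),
    anchored_window_count = nrow(windows),
    anchored_windows = windows,
    exclusion_survivors = survivors,
    motif_ome_ids = ome_ids,
    hits = hits,
    params = list(motif = format(motif),
                  sub_patterns = names(sub_counts),
                  short_threshold = short_threshold,
                  window_pattern = format(wp),
                  allowed_residues = allowed_residues,
                  overlap = overlap)
  ), class = "sift_report")
}

#' @export
print.sift_report <- function(x, ...) {
  cat("Motif census (", x$params$motif, ")\n", sep = "")
  cat(sprintf("  proteome size        : %d\n", x$proteome_size))
  cat(sprintf("  motif-ome size       : %d\n", x$motif_ome_size))
  cat(sprintf("  total occurrences    : %d\n", x$total_hits))
  cat(sprintf("  C-terminal           : %d\n", x$terminal_hits))
  for (p in names(x$sub_pattern_counts)) {
    cat(sprintf("  %-21s: %d\n", p, x$sub_pattern_counts[[p]]))
  }
  cat(sprintf("  short (<%d aa)       : %d\n",
              x$params$short_threshold, x$short_protein_count))
  cat(sprintf("  methionine pool      : %d\n", x$methionine_pool))
  cat(sprintf("  anchored windows (%s): %d\n",
              x$params$window_pattern, x$anchored_window_count))
  cat(sprintf("  exclusion survivors  : %d\n", nrow(x$exclusion_survivors)))
  invisible(x)
}

#' Write a sift report to CSV
#'
#' Writes two files: `<stem>_census.csv` (one row per census statistic) and
#' `<stem>_survivors.csv` (protein_id, start, window,
#' distinct_allowed_count).
#'
#' @param report A `sift_report`.
#' @param stem Output path stem (no extension).
#' @return The two file paths, invisibly.
#' @export
write_sift_report <- function(report, stem) {
  census <- data.frame(
    statistic = c("proteome_size", "motif_ome_size", "total_hits",
                  "terminal_hits",
                  paste0("count_", names(report$sub_pattern_counts)),
                  "short_protein_count", "methionine_pool",
                  "anchored_window_count", "exclusion_survivors"),
    value = c(report$proteome_size, report$motif_ome_size,
              report$total_hits, report$terminal_hits,
              unname(report$sub_pattern_counts),
              report$short_protein_count, report$methionine_pool,
              report$anchored_window_count, nrow(report$exclusion_survivors)),
    stringsAsFactors = FALSE
  )
  f1 <- paste0(stem, "_census.csv")
  f2 <- paste0(stem, "_survivors.csv")
  write.csv(census, f1, row.names = FALSE)
  write.csv(report$exclusion_survivors, f2, row.names = FALSE)
  invisible(c(f1, f2))
}
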