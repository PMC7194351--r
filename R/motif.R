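#' Define a fixed-plus-wildcard residue motif
#'
#' A motif is an ordered run of slots, each either a fixed canonical residue
#' or a wildcard. Wildcards (written `x` or `.`) match any of the 20
#' canonical residues but never ambiguity codes (X, B, Z, U, O); fixed slots
#' match only their exact residue. A pattern may be anchored to the
#' N terminus or to the C terminus, in which case only matches starting at
#' the first residue or ending at the final residue are reported.
#'
#' @param pattern A string such as `"NNI"`, `"FNNI"` or `"MxxxxxxxxxxNNI"`.
#'   Lower-case `x` and `.` are wildcard slots; every other character must
#'   be a canonical residue letter.
#' @param anchor One of `"none"`, `"N-terminal"`, `"C-terminal"`.
#' @return An object of class `motif_pattern` with elements `slots`
#'   (character vector, `NA` for wildcards), `length`, `n_fixed`, `anchor`.
#' @examples
#' motif_pattern("NNI")
#' motif_pattern("M..........NNI")
#' @export
motif_pattern <- function(pattern, anchor = c("none", "N-terminal", "C-terminal")) {
  anchor <- match.arg(anchor)
  stopifnot(is.character(pattern), length(pattern) == 1, nchar(pattern) >= 1)
  chars <- strsplit(pattern, "")[[1]]
  slots <- ifelse(chars %in% c("x", "."), NA_character_, toupper(chars))
  bad <- !is.na(slots) & !(slots %in% AA_CANONICAL)
  if (any(bad)) {
    stop("non-canonical residue in motif pattern: ",
         paste(unique(slots[bad]), collapse = ", "))
  }
  structure(
    list(slots = slots, length = length(slots),
         n_fixed = sum(!is.na(slots)), anchor = anchor),
    class = "motif_pattern"
  )
}

#' @export
format.motif_pattern <- function(x, ...) {
  paste(ifelse(is.na(x$slots), "x", x$slots), collapse = "")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s (length %d, %d fixed, anchor %s)\n",
              format(x), x$length, x$n_fixed, x$anchor))
  invisible(x)
}

as_motif_pattern <- function(x, anchor = "none") {
  if (inherits(x, "motif_pattern")) x else motif_pattern(x, anchor)
}

# Logical match vector over all window starts of one sequence.
# Wildcards require a canonical residue; fixed slots require equality.
match_starts <- function(chars, pattern) {
  k <- pattern$length
  L <- length(chars)
  n <- L - k + 1L
  if (n < 1L) return(logical(0))
  ok <- rep(TRUE, n)
  for (j in seq_len(k)) {
    cj <- chars[seq_len(n) + (j - 1L)]
    slot <- pattern$slots[j]
    ok <- ok & if (is.na(slot)) cj %in% AA_CANONICAL else cj == slot
  }
  ok
}

#' Locate all occurrences of a motif in one protein
#'
#' Returns every occurrence (overlapping occurrences included) in ascending
#' start order, using 1-based inclusive coordinates. A hit is C-terminal
#' when it ends at the protein's final residue.
#'
#' @param protein Either a single sequence string or a one-or-more-row
#'   `proteome` data frame; with several rows, all proteins are scanned.
#' @param pattern A `motif_pattern` or a pattern string.
#' @param overlap Count overlapping occurrences (default `TRUE`); when
#'   `FALSE`, occurrences are taken greedily left to right without overlap.
#' @return A data frame with columns `protein_id`, `start`, `end`,
#'   `matched_text`, `c_terminal`; zero rows when there is no match.
#' @examples
#' scan_motif("AANNINNIA", "NNI")
#' scan_motif("QQNNI", "NNI")$c_terminal
#' @export
scan_motif <- function(protein, pattern, overlap = TRUE) {
  pattern <- as_motif_pattern(pattern)
  if (is.character(protein)) {
    protein <- proteome(paste0("seq", seq_along(protein)), protein)
  }
  hits <- lapply(seq_len(nrow(protein)), function(i) {
    seqstr <- protein$sequence[i]
    chars <- strsplit(seqstr, "")[[1]]
    ok <- match_starts(chars, pattern)
    starts <- which(ok)
    if (!overlap && length(starts) > 1) {
      keep <- starts[1]
      for (s in starts[-1]) {
        if (s >= keep[length(keep)] + pattern$length) keep <- c(keep, s)
      }
      starts <- keep
    }
    L <- nchar(seqstr)
    ends <- starts + pattern$length - 1L
    if (pattern$anchor == "N-terminal") {
      ends <- ends[starts == 1L]; starts <- starts[starts == 1L]
    } else if (pattern$anchor == "C-terminal") {
      starts <- starts[ends == L]; ends <- ends[ends == L]
    }
    if (length(starts) == 0) return(NULL)
    data.frame(
      protein_id = protein$id[i],
      start = starts,
      end = ends,
      matched_text = substring(seqstr, starts, ends),
      c_terminal = ends == L,
      stringsAsFactors = FALSE
    )
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) {
    hits <- data.frame(protein_id = character(0), start = integer(0),
                       end = integer(0), matched_text = character(0),
                       c_terminal = logical(0), stringsAsFactors = FALSE)
  }
  hits
}

#' Search for anchored motif windows (e.g. M, ten wildcards, then NNI)
#'
#' Finds every occurrence of a window pattern with a fixed first slot and a
#' fixed suffix, such as `M..........NNI` (a 14-mer: methionine, ten
#' arbitrary canonical residues, then NNI), and reports the matched window
#' text.
#'
#' @param proteome A `proteome` data frame.
#' @param window_pattern A `motif_pattern` or string; the first slot and at
#'   least the final slot must be fixed.
#' @param overlap Count overlapping windows (default `TRUE`).
#' @return A data frame with columns `protein_id`, `start`, `end`,
#'   `window` (matched text), `c_terminal`.
#' @examples
#' p <- proteome("demo", "MAAAAAAAAAANNI")
#' anchored_window_search(p, "M..........NNI")
#' @export
anchored_window_search <- function(proteome, window_pattern = "M..........NNI",
                                   overlap = TRUE) {
  window_pattern <- as_motif_pattern(window_pattern)
  if (is.na(window_pattern$slots[1]) ||
      is.na(window_pattern$slots[window_pattern$length])) {
    stop("window pattern must have fixed first and last slots")
  }
  hits <- scan_motif(proteome, window_pattern, overlap = overlap)
  names(hits)[names(hits) == "matched_text"] <- "window"
  hits
}
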