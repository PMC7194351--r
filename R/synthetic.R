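#' Generate a synthetic proteome with planted motif occurrences
#'
#' Emits a proteome of random background residues (drawn from a stated
#' composition) carrying planted occurrences of a core motif at recorded
#' coordinates: internal occurrences, C-terminal occurrences, and anchored
#' windows (M, a run of wildcard fill, then the motif; e.g. the 14-mer
#' `M..........NNI`). Backgrounds are rejection-sampled so that no
#' unplanned occurrence of the motif or of an anchored window exists,
#' making the manifest's planted counts exact; derived census fields
#' (sub-pattern counts, methionine pool, short proteins, exclusion
#' survivors) are recomputed directly on the emitted sequences with plain
#' string operations, independent of the scan machinery.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Min/max protein length (uniform).
#' @param motif Core motif string (fixed residues only; default `"NNI"`).
#' @param n_internal,n_c_terminal,n_anchored Planted occurrence counts by
#'   placement.
#' @param window_wildcards Wildcard-fill length of the anchored window
#'   (default 10: a 14-mer with a 3-residue motif).
#' @param composition A [residue_composition()] for background residues.
#' @param sub_patterns Sub-patterns tallied in the manifest.
#' @param short_threshold Short-protein threshold for the manifest.
#' @param allowed_residues Allowed set for the manifest's exclusion filter.
#' @param seed Integer seed; the same seed reproduces the proteome exactly.
#' @param max_retries Rejection-sampling cap per protein.
#' @return A list with `proteome` (a `proteome` data frame), `manifest`
#'   (list of expected census values plus a `planted` coordinate data
#'   frame), and `params`.
#' @export
make_proteome <- function(n_proteins = 50,
                          length_range = c(60, 300),
                          motif = "NNI",
                          n_internal = 12,
                          n_c_terminal = 2,
                          n_anchored = 3,
                          window_wildcards = 10,
                          composition = residue_composition(),
                          sub_patterns = c("FNNI", "EFNNI"),
                          short_threshold = 100L,
                          allowed_residues = "MKPLTGVEF",
                          seed = 1,
                          max_retries = 200L) {
  stopifnot(n_proteins >= 0, n_internal >= 0, n_c_terminal >= 0,
            n_anchored >= 0)
  set.seed(seed)
  comp <- unclass(composition)
  motif_len <- nchar(motif)
  win_len <- motif_len + 1L + window_wildcards

  plant_kind <- c(rep("internal", n_internal),
                  rep("c_terminal", n_c_terminal),
                  rep("anchored", n_anchored))
  if (length(plant_kind) > 0 && n_proteins == 0) stop("infeasible plan")
  if (n_c_terminal > n_proteins) stop("infeasible plan: more C-terminal plants than proteins")
  # a protein has one C terminus, so C-terminal plants get distinct owners
  owner <- integer(length(plant_kind))
  owner[plant_kind == "c_terminal"] <-
    sample(seq_len(n_proteins), n_c_terminal, replace = FALSE)
  owner[plant_kind != "c_terminal"] <-
    sample(seq_len(n_proteins), sum(plant_kind != "c_terminal"),
           replace = TRUE)

  draw_bg <- function(n) {
    paste(sample(names(comp), n, replace = TRUE, prob = comp), collapse = "")
  }
  count_fixed <- function(seqstr, pat) {
    # overlapping fixed-string count via lookahead-free scan
    n <- nchar(seqstr) - nchar(pat) + 1L
    if (n < 1L) return(list(n = 0L, starts = integer(0)))
    starts <- which(vapply(seq_len(n), function(s) {
      substring(seqstr, s, s + nchar(pat) - 1L) == pat
    }, logical(1)))
    list(n = length(starts), starts = starts)
  }

  records <- vector("list", n_proteins)
  planted <- vector("list", n_proteins)
  for (i in seq_len(n_proteins)) {
    kinds <- plant_kind[owner == i]
    seg_len <- ifelse(kinds == "anchored", win_len, motif_len)
    L <- sample(seq(length_range[1], length_range[2]), 1)
    L <- max(L, sum(seg_len) + length(kinds) + win_len)  # room to place
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      # choose non-overlapping, non-terminal starts (C-terminal plant at end)
      starts <- integer(0)
      ok <- TRUE
      occupied <- rep(FALSE, L)
      n_ct <- sum(kinds == "c_terminal")
      if (n_ct > 1) stop("at most one C-terminal plant per protein; replant")
      order_idx <- order(kinds != "c_terminal")  # place C-terminal first
      starts <- rep(NA_integer_, length(kinds))
      for (jj in order_idx) {
        len_j <- seg_len[jj]
        if (kinds[jj] == "c_terminal") {
          s <- L - len_j + 1L
        } else {
          # keep strictly internal so planted ends never touch the C terminus
          cand_s <- seq_len(L - len_j)
          cand_s <- cand_s[vapply(cand_s, function(s) {
            !any(occupied[s:(s + len_j - 1L)])
          }, logical(1))]
          if (length(cand_s) == 0) { ok <- FALSE; break }
          s <- if (length(cand_s) == 1) cand_s else sample(cand_s, 1)
        }
        if (any(occupied[s:(s + len_j - 1L)])) { ok <- FALSE; break }
        occupied[s:(s + len_j - 1L)] <- TRUE
        starts[jj] <- s
      }
      if (!ok) next
      chars <- strsplit(draw_bg(L), "")[[1]]
      for (jj in seq_along(kinds)) {
        s <- starts[jj]
        text <- if (kinds[jj] == "anchored") {
          paste0("M", draw_bg(window_wildcards), motif)
        } else {
          motif
        }
        chars[s:(s + nchar(text) - 1L)] <- strsplit(text, "")[[1]]
      }
      seqstr <- paste(chars, collapse = "")
      # verify: motif occurrences exactly at planted motif positions
      motif_starts <- sort(c(
        starts[kinds != "anchored"],
        starts[kinds == "anchored"] + 1L + window_wildcards
      ))
      got <- count_fixed(seqstr, motif)
      if (!identical(got$starts, as.integer(motif_starts))) next
      # verify: anchored windows exactly at planted anchored positions
      win_pat <- paste0("M", strrep(".", window_wildcards), motif)
      wn <- nchar(seqstr) - win_len + 1L
      win_starts <- if (wn < 1L) integer(0) else {
        which(vapply(seq_len(wn), function(s) {
          substring(seqstr, s, s) == "M" &&
            substring(seqstr, s + 1L + window_wildcards,
                      s + win_len - 1L) == motif
        }, logical(1)))
      }
      if (!identical(win_starts, sort(as.integer(starts[kinds == "anchored"])))) next
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("rejection sampling failed for protein ", i,
           " after ", max_retries, " retries")
    }
    records[[i]] <- seqstr
    planted[[i]] <- if (length(kinds) > 0) {
      data.frame(protein_id = sprintf("SYN%04d", i), start = starts,
                 end = starts + seg_len - 1L, kind = kinds,
                 stringsAsFactors = FALSE)
    } else NULL
  }

  prot <- proteome(sprintf("SYN%04d", seq_len(n_proteins)),
                   unlist(records, use.names = FALSE) %||% character(0),
                   description = "synthetic")
  planted <- do.call(rbind, planted)
  if (is.null(planted)) {
    planted <- data.frame(protein_id = character(0), start = integer(0),
                          end = integer(0), kind = character(0),
                          stringsAsFactors = FALSE)
  }

  # manifest: planted counts by construction; derived fields by direct
  # string recount on the emitted sequences
  ome_ids <- unique(planted$protein_id)
  ome <- prot[prot$id %in% ome_ids, , drop = FALSE]
  count_all <- function(seqs, pat) {
    sum(vapply(seqs, function(s) count_fixed(s, pat)$n, integer(1)))
  }
  sub_counts <- vapply(sub_patterns, function(p) count_all(ome$sequence, p),
                       integer(1))
  m_total <- sum(vapply(strsplit(ome$sequence, ""),
                        function(ch) sum(ch == "M"), integer(1)))
  m_init <- sum(substring(ome$sequence, 1, 1) == "M")
  anchored <- planted[planted$kind == "anchored", , drop = FALSE]
  windows11 <- if (nrow(anchored) > 0) {
    substring(prot$sequence[match(anchored$protein_id, prot$id)],
              anchored$start, anchored$start + window_wildcards)
  } else character(0)
  allowed <- strsplit(allowed_residues, "")[[1]]
  surv <- vapply(strsplit(windows11, ""), function(ch) {
    all(ch[-1] %in% setdiff(allowed, "M"))
  }, logical(1))

  manifest <- list(
    proteome_size = n_proteins,
    motif_ome_size = length(ome_ids),
    total_hits = nrow(planted),
    terminal_hits = sum(planted$kind == "c_terminal"),
    sub_pattern_counts = sub_counts,
    short_protein_count = sum(ome$length < short_threshold),
    methionine_pool = as.integer(m_total - m_init),
    anchored_window_count = nrow(anchored),
    exclusion_survivor_count = sum(surv),
    planted = planted
  )
  list(proteome = prot, manifest = manifest,
       params = list(motif = motif, window_wildcards = window_wildcards,
                     sub_patterns = sub_patterns,
                     short_threshold = short_threshold,
                     allowed_residues = allowed_residues, seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Jittered copies of a base distance table
#'
#' Each output table equals the base table plus independent Gaussian noise
#' of the stated SD per entry; entries are redrawn while non-positive so
#' all distances stay > 0.
#'
#' @param base A `distance_table`.
#' @param jitter_sd Noise SD in angstroms (>= 0).
#' @param n_tables Number of tables.
#' @param seed Integer seed.
#' @return A list of `distance_table` objects.
#' @export
make_distance_tables <- function(base, jitter_sd, n_tables, seed = 1) {
  stopifnot(inherits(base, "distance_table"), jitter_sd >= 0, n_tables >= 0)
  set.seed(seed)
  lapply(seq_len(n_tables), function(i) {
    e <- base$entries + rnorm(base$n_pairs, 0, jitter_sd)
    while (any(e <= 0)) {
      bad <- e <= 0
      e[bad] <- base$entries[bad] + rnorm(sum(bad), 0, jitter_sd)
    }
    distance_table(setNames(e, names(base$entries)),
                   peptide_name = sprintf("%s_jit%g_%d",
                                          base$peptide_name, jitter_sd, i))
  })
}

#' Synthetic preabsorption dose-response measurements
#'
#' Peptides matching the planted suffix rule are blockers and follow the
#' inhibition curve `percent = 100 / (1 + (c / IC50)^slope)` (a logistic in
#' log-dose with floor 0 and ceiling 100) plus Gaussian replicate noise,
#' floored at 0; non-blockers follow 100 plus noise.
#'
#' @param peptides Data frame with `peptide_code`, `sequence`.
#' @param rule Planted suffix-pattern string (e.g. `"NNI"`).
#' @param ic50 IC50 in ng/ml: a single value or a named vector per blocker.
#' @param slope Hill slope (> 0).
#' @param noise_sd Replicate noise SD in percent points.
#' @param n_rep Replicates per dose.
#' @param concentrations Tested doses in ng/ml.
#' @param seed Integer seed.
#' @return A list with `measurements` (data frame: `peptide_code`,
#'   `concentration`, `replicate`, `percent`), and `truth` (rule, blocker
#'   flags, IC50s).
#' @export
make_panel_measurements <- function(peptides,
                                    rule = "NNI",
                                    ic50 = 10,
                                    slope = 1,
                                    noise_sd = 5,
                                    n_rep = 4,
                                    concentrations = c(0.1, 1, 10, 100, 1000),
                                    seed = 1) {
  stopifnot(all(concentrations > 0), all(ic50 > 0), noise_sd >= 0, n_rep >= 1)
  set.seed(seed)
  blocker <- suffix_matches(rule, peptides$sequence)
  ic <- if (is.null(names(ic50))) {
    setNames(rep_len(ic50, sum(blocker)), peptides$peptide_code[blocker])
  } else ic50
  rows <- list()
  for (i in seq_len(nrow(peptides))) {
    code <- peptides$peptide_code[i]
    for (c0 in concentrations) {
      mu <- if (blocker[i]) 100 / (1 + (c0 / ic[[code]])^slope) else 100
      y <- pmax(0, mu + rnorm(n_rep, 0, noise_sd))
      rows[[length(rows) + 1]] <- data.frame(
        peptide_code = code, concentration = c0,
        replicate = seq_len(n_rep), percent = y,
        stringsAsFactors = FALSE)
    }
  }
  list(measurements = do.call(rbind, rows),
       truth = list(rule = rule,
                    blocker = setNames(blocker, peptides$peptide_code),
                    ic50 = ic, slope = slope, noise_sd = noise_sd))
}

#' Synthetic blockade panel from a planted suffix rule
#'
#' Random peptides over the canonical alphabet; roughly half are forced to
#' end with the rule's fixed suffix. `blocks` labels follow the planted
#' rule exactly (no label noise), so recovery failures isolate the
#' inference, not the generator. A panel with no blocker or no non-blocker
#' is flagged unidentifiable.
#'
#' @param n_peptides Panel size.
#' @param length_range Peptide length range.
#' @param rule Planted suffix-pattern string.
#' @param seed Integer seed.
#' @return A list with `panel` (data frame) and `identifiable` flag.
#' @export
make_panel <- function(n_peptides = 16, length_range = c(4, 12),
                       rule = "NNI", seed = 1) {
  set.seed(seed)
  suffix <- gsub("[x.]", "", rule)
  lens <- sample(seq(length_range[1], length_range[2]), n_peptides,
                 replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(AA_CANONICAL, L, replace = TRUE), collapse = "")
  }, character(1))
  force_block <- runif(n_peptides) < 0.5
  seqs[force_block] <- paste0(
    substring(seqs[force_block], 1,
              pmax(0, lens[force_block] - nchar(suffix))), suffix)
  blocks <- ifelse(suffix_matches(rule, seqs), "yes", "no")
  panel <- data.frame(peptide_code = sprintf("PEP%02d", seq_len(n_peptides)),
                      sequence = seqs, blocks = blocks,
                      stringsAsFactors = FALSE)
  list(panel = panel,
       identifiable = any(blocks == "yes") && any(blocks == "no"))
}

#' Synthetic grayscale image with a known labelled fraction
#'
#' At zero noise, exactly `round(fraction * npixels)` pixels lie strictly
#' above the threshold, so [area_fraction()] recovers the target exactly.
#'
#' @param fraction Target above-threshold fraction in \[0, 1\].
#' @param dims Image dimensions (rows, cols).
#' @param threshold Intensity threshold (default 0.5).
#' @param noise_sd Intensity noise SD (default 0).
#' @param seed Integer seed.
#' @param path Optional PNG output path.
#' @return A list with `image` (matrix), `truth` (target fraction and
#'   realized above-threshold count), and `path` when written.
#' @export
make_image <- function(fraction, dims = c(64, 64), threshold = 0.5,
                       noise_sd = 0, seed = 1, path = NULL) {
  stopifnot(fraction >= 0, fraction <= 1, threshold > 0, threshold < 1)
  set.seed(seed)
  npix <- prod(dims)
  n_above <- round(fraction * npix)
  img <- matrix(runif(npix, 0, threshold * 0.98), dims[1], dims[2])
  if (n_above > 0) {
    idx <- sample(npix, n_above)
    img[idx] <- runif(n_above, threshold + (1 - threshold) * 0.02, 1)
  }
  if (noise_sd > 0) {
    img <- pmin(1, pmax(0, img + rnorm(npix, 0, noise_sd)))
  }
  if (!is.null(path)) png::writePNG(img, path)
  list(image = img,
       truth = list(fraction = fraction, n_above = n_above,
                    threshold = threshold),
       path = path)
}
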