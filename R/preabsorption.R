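#' Read a preabsorption panel CSV
#'
#' Expects columns `peptide_code`, `sequence`, `blocks` with `blocks` one
#' of `yes`, `no`, `partial`, `highest-conc-only`.
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_panel <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("peptide_code", "sequence", "blocks") %in% names(df)))
  df$sequence <- toupper(df$sequence)
  stopifnot(all(nchar(df$sequence) > 0))
  bad <- !df$blocks %in% c("yes", "no", "partial", "highest-conc-only")
  if (any(bad)) {
    stop("invalid blockade category: ",
         paste(unique(df$blocks[bad]), collapse = ", "))
  }
  df
}

#' Fraction of image pixels above a fixed intensity threshold
#'
#' The "area labelled" readout of staining quantification: the fraction of
#' pixels strictly above the threshold.
#'
#' @param image A numeric matrix of intensities, or a path to a grayscale
#'   PNG (read with the png package; multi-channel images are averaged).
#' @param threshold Intensity threshold.
#' @return A fraction in \[0, 1\].
#' @export
area_fraction <- function(image, threshold) {
  if (is.character(image)) {
    arr <- png::readPNG(image)
    image <- if (length(dim(arr)) == 3) apply(arr, c(1, 2), mean) else arr
  }
  stopifnot(is.numeric(image))
  if (length(image) == 0) stop("empty image")
  mean(image > threshold)
}

#' Express staining areas as a percentage of the no-peptide control
#'
#' Annotates each measurement with
#' `percent_of_control = 100 * area / mean(control areas)`, where the
#' control rows are those whose `peptide_code` equals `control_key`.
#'
#' @param measurements Data frame with columns `peptide_code` and
#'   `area_labelled` (other columns are carried through).
#' @param control_key Peptide code of the no-peptide condition
#'   (default `"NONE"`).
#' @return The data frame with a `percent_of_control` column added.
#' @export
percent_of_control <- function(measurements, control_key = "NONE") {
  stopifnot(all(c("peptide_code", "area_labelled") %in% names(measurements)))
  ctrl <- measurements$area_labelled[measurements$peptide_code == control_key]
  if (length(ctrl) == 0) stop("control group '", control_key, "' is empty")
  m <- mean(ctrl)
  if (m == 0) stop("control mean area is zero")
  measurements$percent_of_control <- 100 * measurements$area_labelled / m
  measurements
}

#' Summarize a group of replicate values as mean and SEM
#'
#' @param x Numeric replicate values (n >= 1).
#' @return A list with `n`, `mean`, `sem` (sample SD / sqrt(n); 0 when
#'   n = 1).
#' @examples
#' group_summary(c(0, 2))  # mean 1, sem 1
#' @export
group_summary <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1)
  n <- length(x)
  list(n = n, mean = mean(x), sem = if (n == 1) 0 else sd(x) / sqrt(n))
}

#' Summarize grouped percent-of-control values
#'
#' @param df Data frame of measurements.
#' @param value_col Column of values to summarize.
#' @param by Character vector of grouping columns.
#' @return One row per group with `n`, `mean`, `sem`.
#' @export
summarize_groups <- function(df, value_col = "percent_of_control",
                             by = "peptide_code") {
  parts <- split(df, df[by], drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(d) {
    s <- group_summary(d[[value_col]])
    cbind(d[1, by, drop = FALSE],
          data.frame(n = s$n, mean = s$mean, sem = s$sem))
  }))
  rownames(out) <- NULL
  out
}

as_group_summary <- function(g) {
  if (is.numeric(g)) {
    if (length(g) < 2) stop("need >= 2 replicates for a variance estimate")
    return(group_summary(g))
  }
  stopifnot(is.list(g), all(c("n", "mean", "sem") %in% names(g)))
  g
}

#' Unpaired two-sample t-test from raw values or (n, mean, sem) summaries
#'
#' Pooled-variance Student test by default, with a Welch (unequal-variance)
#' variant. Either group may be a numeric vector of replicates or a list
#' `list(n =, mean =, sem =)`; summary input gives results identical to raw
#' input when the summaries are computed from the raw values.
#'
#' @param group_a,group_b Raw replicate vectors or summary lists.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return A list of class `t_test_result` with `t`, `dof`, `p`, `variant`,
#'   `zero_variance` flag. Both groups constant and equal gives t = 0,
#'   p = 1; constant but unequal groups are flagged with an infinite
#'   statistic.
#' @examples
#' unpaired_t(c(1, 2, 3), c(4, 5, 6))
#' unpaired_t(list(n = 8, mean = 29.53, sem = 9.69),
#'            list(n = 8, mean = 0.09, sem = 0.05))
#' @export
unpaired_t <- function(group_a, group_b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  a <- as_group_summary(group_a)
  b <- as_group_summary(group_b)
  stopifnot(a$n >= 2, b$n >= 2)
  va <- a$sem^2 * a$n   # sample variance
  vb <- b$sem^2 * b$n
  delta <- a$mean - b$mean
  if (va == 0 && vb == 0) {
    if (delta == 0) {
      return(structure(list(t = 0, dof = a$n + b$n - 2, p = 1,
                            variant = variant, zero_variance = TRUE),
                       class = "t_test_result"))
    }
    warning("zero variance in both groups with unequal means")
    return(structure(list(t = sign(delta) * Inf, dof = a$n + b$n - 2, p = 0,
                          variant = variant, zero_variance = TRUE),
                     class = "t_test_result"))
  }
  if (variant == "pooled") {
    dof <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * va + (b$n - 1) * vb) / dof
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    se2a <- va / a$n
    se2b <- vb / b$n
    se <- sqrt(se2a + se2b)
    dof <- (se2a + se2b)^2 / (se2a^2 / (a$n - 1) + se2b^2 / (b$n - 1))
  }
  t <- delta / se
  structure(list(t = t, dof = dof, p = 2 * pt(-abs(t), df = dof),
                 variant = variant, zero_variance = FALSE),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("unpaired t (%s): t = %.4g, dof = %.4g, p = %.4g\n",
              x$variant, x$t, x$dof, x$p))
  invisible(x)
}

#' IC50 bound from a tested dose series
#'
#' Reports the smallest tested concentration at which the mean
#' percent-of-control staining is at or below 50%, as a bound over tested
#' doses (not a fitted midpoint): `"<= c"` in general, `"< cmin"` when
#' staining is already at or below 50% at the lowest tested dose, and
#' `"not reached"` when no tested dose halves the staining.
#'
#' @param dose_response Data frame with columns `concentration` and
#'   `mean_percent` (one row per tested dose).
#' @return A list with `bound` (concentration, `Inf` when not reached),
#'   `comparator` (`"<"`, `"<="` or `"not reached"`), `label`.
#' @examples
#' ic50_bound(data.frame(concentration = c(0.1, 10, 1000),
#'                       mean_percent = c(80, 40, 5)))  # <= 10
#' @export
ic50_bound <- function(dose_response) {
  stopifnot(all(c("concentration", "mean_percent") %in% names(dose_response)),
            nrow(dose_response) >= 2)
  d <- dose_response[order(dose_response$concentration), ]
  hit <- which(d$mean_percent <= 50)
  if (length(hit) == 0) {
    return(list(bound = Inf, comparator = "not reached",
                label = "not reached"))
  }
  c0 <- d$concentration[min(hit)]
  if (min(hit) == 1L) {
    list(bound = c0, comparator = "<", label = paste("<", format(c0)))
  } else {
    list(bound = c0, comparator = "<=", label = paste("<=", format(c0)))
  }
}

# --- suffix patterns ---------------------------------------------------

#' Does a C-terminal suffix pattern match a peptide?
#'
#' A suffix pattern is written N-to-C with `x`/`.` wildcards, e.g. `"xNNI"`
#' (any canonical residue, then NNI, ending the peptide). A peptide matches
#' iff it is at least as long as the pattern and every pattern slot matches
#' the corresponding C-terminal residue.
#'
#' @param pattern Suffix-pattern string.
#' @param sequences Character vector of peptide sequences.
#' @return Logical vector.
#' @export
suffix_matches <- function(pattern, sequences) {
  slots <- rev(strsplit(pattern, "")[[1]])  # index 1 = C-terminal slot
  slots <- ifelse(slots %in% c("x", "."), NA_character_, toupper(slots))
  L <- length(slots)
  n <- nchar(sequences)
  ok <- n >= L
  for (j in seq_len(L)) {
    cj <- substring(sequences, n - j + 1, n - j + 1)
    ok <- ok & if (is.na(slots[j])) cj %in% AA_CANONICAL else cj == slots[j]
  }
  ok
}

#' Infer the epitope suffix pattern from a blockade panel
#'
#' Enumerates C-terminal suffix patterns up to `max_len` slots (fixed
#' residue or wildcard per slot, at least one fixed slot) and scores each
#' by the separation accuracy of the rule "the peptide blocks the antibody
#' iff the pattern matches its C terminus". Patterns are ranked by accuracy
#' (descending), fixed-slot count (descending), length (ascending), then
#' pattern string; enumeration at each C-terminal offset is restricted to
#' residues actually observed there in the panel (a fixed residue
#' unobserved at its offset matches no panel peptide, so such patterns are
#' score-equivalent to an enumerated no-match pattern and never uniquely
#' optimal).
#'
#' `blocks` handling: `yes` and (by default) `partial` entries count as
#' blockers; `highest-conc-only` entries are excluded from the core
#' inference unless `include_highest_conc_only` is set, in which case they
#' count as blockers (sensitivity mode). Alanine-substitution variants of a
#' base peptide are better analysed separately with
#' [substitution_scan()] and passed here via `variants` for the per-residue
#' classification.
#'
#' @param panel Data frame with `peptide_code`, `sequence`, `blocks`.
#' @param max_len Maximum suffix-pattern length (default 6).
#' @param partial_policy `"blocker"` (default) or `"non-blocker"`: how
#'   `partial` entries are counted.
#' @param include_highest_conc_only Include `highest-conc-only` entries as
#'   blockers (default `FALSE`: excluded).
#' @param variants Optional data frame of single-residue substitution
#'   variants (see [substitution_scan()]) used for the per-residue
#'   classification.
#' @param variant_base The unsubstituted base peptide for `variants`.
#' @return An object of class `epitope_inference` with `patterns` (ranked
#'   data frame: `pattern`, `length`, `n_fixed`, `accuracy`, `sensitivity`,
#'   `specificity`), `best` (top row), `degenerate` flag, and
#'   `classification` (per-residue data frame when `variants` given).
#' @export
infer_epitope <- function(panel, max_len = 6,
                          partial_policy = c("blocker", "non-blocker"),
                          include_highest_conc_only = FALSE,
                          variants = NULL, variant_base = NULL) {
  partial_policy <- match.arg(partial_policy)
  keep <- panel$blocks %in% c("yes", "no", "partial") |
    (include_highest_conc_only & panel$blocks == "highest-conc-only")
  panel <- panel[keep, , drop = FALSE]
  blocker <- panel$blocks == "yes" |
    (partial_policy == "blocker" & panel$blocks == "partial") |
    panel$blocks == "highest-conc-only"
  seqs <- toupper(panel$sequence)
  n <- length(seqs)

  if (!any(blocker) || all(blocker)) {
    pat <- data.frame(pattern = "x", length = 1L, n_fixed = 0L,
                      accuracy = max(mean(blocker), mean(!blocker)),
                      sensitivity = NA_real_, specificity = NA_real_,
                      stringsAsFactors = FALSE)
    return(structure(list(patterns = pat, best = pat[1, ],
                          degenerate = TRUE, classification = NULL,
                          n_blockers = sum(blocker),
                          n_non_blockers = sum(!blocker)),
                     class = "epitope_inference"))
  }

  len <- nchar(seqs)
  # residue observed at C-terminal offset j (1 = last residue), per peptide
  obs_at <- function(j) {
    r <- rep(NA_character_, n)
    has <- len >= j
    r[has] <- substring(seqs[has], len[has] - j + 1, len[has] - j + 1)
    r
  }
  offsets <- lapply(seq_len(max_len), obs_at)
  # candidate slots per offset: observed residues + wildcard (NA)
  cand <- lapply(offsets, function(r) c(sort(unique(r[!is.na(r)])), NA))
  # peptide-match mask for slot value v at offset j
  mask <- function(j, v) {
    r <- offsets[[j]]
    if (is.na(v)) !is.na(r) & r %in% AA_CANONICAL else !is.na(r) & r == v
  }

  rows <- vector("list", 0)
  for (L in seq_len(max_len)) {
    grid <- expand.grid(cand[seq_len(L)], KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    if (nrow(grid) == 0) next
    nf <- rowSums(!is.na(grid))
    grid <- grid[nf >= 1, , drop = FALSE]
    if (nrow(grid) == 0) next
    masks <- lapply(seq_len(L), function(j) {
      vals <- cand[[j]]
      m <- vapply(vals, function(v) mask(j, v), logical(n))
      colnames(m) <- ifelse(is.na(vals), "x", vals)
      m
    })
    matched <- matrix(TRUE, nrow(grid), n)
    for (j in seq_len(L)) {
      key <- ifelse(is.na(grid[[j]]), "x", grid[[j]])
      matched <- matched & t(masks[[j]][, key, drop = FALSE])
    }
    tp <- matched %*% blocker
    tn <- (!matched) %*% (!blocker)
    # pattern string rendered N-to-C: slot for offset j sits at position L-j+1
    pat_str <- apply(grid, 1, function(s) {
      paste(rev(ifelse(is.na(s), "x", s)), collapse = "")
    })
    rows[[L]] <- data.frame(
      pattern = pat_str,
      length = L,
      n_fixed = rowSums(!is.na(grid)),
      accuracy = as.numeric(tp + tn) / n,
      sensitivity = as.numeric(tp) / sum(blocker),
      specificity = as.numeric(tn) / sum(!blocker),
      stringsAsFactors = FALSE
    )
  }
  pats <- do.call(rbind, rows)
  pats <- pats[order(-pats$accuracy, -pats$n_fixed, pats$length,
                     pats$pattern), , drop = FALSE]
  rownames(pats) <- NULL

  classification <- NULL
  if (!is.null(variants)) {
    scan <- substitution_scan(variants, variant_base)
    core <- strsplit(gsub("x", "", pats$pattern[1]), "")[[1]]
    req <- scan$residue[!scan$tolerated & !scan$residue %in% core]
    disp <- scan$residue[scan$tolerated & !scan$residue %in% core]
    classification <- data.frame(
      residue = c(unique(core), req, disp),
      class = c(rep("contiguous-core", length(unique(core))),
                rep("required-non-contiguous", length(req)),
                rep("dispensable", length(disp))),
      stringsAsFactors = FALSE)
  }

  structure(list(patterns = pats, best = pats[1, ], degenerate = FALSE,
                 classification = classification,
                 n_blockers = sum(blocker), n_non_blockers = sum(!blocker)),
            class = "epitope_inference")
}

#' @export
print.epitope_inference <- function(x, ...) {
  if (x$degenerate) {
    cat("degenerate panel (no blocker/non-blocker contrast); wildcard pattern\n")
    return(invisible(x))
  }
  cat(sprintf("best C-terminal pattern: %s (accuracy %.3f, sens %.3f, spec %.3f; %d blockers vs %d non-blockers)\n",
              x$best$pattern, x$best$accuracy, x$best$sensitivity,
              x$best$specificity, x$n_blockers, x$n_non_blockers))
  print(head(x$patterns, 5))
  invisible(x)
}

#' Second-pass analysis of single-residue substitution variants
#'
#' Given a base peptide (e.g. `FNNI`) and panel rows for its
#' single-substitution variants (e.g. `FNNA`, `FNAI`, `FANI`, `ANNI`),
#' reports, per substituted position of the base, whether blockade was
#' retained (`yes`/`partial` -> substitution tolerated) or effectively lost
#' (`no`/`highest-conc-only` -> the original residue is required). Residues
#' required here but outside the contiguous core are candidates for
#' non-contiguous epitope elements.
#'
#' @param variants Data frame with `peptide_code`, `sequence`, `blocks`.
#' @param base The unsubstituted base peptide string.
#' @return A data frame with `position`, `residue` (base residue),
#'   `variant`, `blocks`, `tolerated`.
#' @export
substitution_scan <- function(variants, base) {
  stopifnot(!is.null(base), nchar(base) >= 1)
  base_ch <- strsplit(toupper(base), "")[[1]]
  out <- lapply(seq_len(nrow(variants)), function(i) {
    v <- toupper(variants$sequence[i])
    vch <- strsplit(v, "")[[1]]
    if (length(vch) != length(base_ch)) {
      stop("variant ", v, " is not a length-preserving substitution of ", base)
    }
    diff <- which(vch != base_ch)
    if (length(diff) != 1) {
      stop("variant ", v, " differs from ", base, " at ",
           length(diff), " positions; expected exactly 1")
    }
    data.frame(position = diff, residue = base_ch[diff], variant = v,
               blocks = variants$blocks[i],
               tolerated = variants$blocks[i] %in% c("yes", "partial"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$position), ]
}
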