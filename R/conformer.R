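#' Labelled interatomic-distance table
#'
#' A peptide conformer is summarized by the pairwise distances (in
#' angstroms) between a set of labelled atoms (labels are single letters,
#' e.g. a-k). Pair labels are unordered: `"b-a"` is canonicalized to
#' `"a-b"`.
#'
#' @param entries Named numeric vector: names are pair labels like
#'   `"a-b"`, values are distances in angstroms (all > 0).
#' @param peptide_name Peptide identifier.
#' @return An object of class `distance_table` with elements
#'   `peptide_name`, `entries`, `n_pairs`.
#' @examples
#' distance_table(c("a-b" = 3, "a-c" = 4), "toy")
#' @export
distance_table <- function(entries, peptide_name = "peptide") {
  stopifnot(is.numeric(entries), !is.null(names(entries)))
  names(entries) <- canonical_pair(names(entries))
  if (anyDuplicated(names(entries))) {
    stop("duplicate pair label(s): ",
         paste(unique(names(entries)[duplicated(names(entries))]),
               collapse = ", "))
  }
  if (any(entries <= 0)) stop("all distances must be > 0")
  structure(list(peptide_name = peptide_name,
                 entries = entries[order(names(entries))],
                 n_pairs = length(entries)),
            class = "distance_table")
}

canonical_pair <- function(pair) {
  parts <- strsplit(pair, "-", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2) stop("malformed pair label: ", paste(p, collapse = "-"))
    paste(sort(p), collapse = "-")
  }, character(1))
}

#' @export
print.distance_table <- function(x, ...) {
  cat(sprintf("<distance_table> %s: %d pairs, %.2f-%.2f A\n",
              x$peptide_name, x$n_pairs, min(x$entries), max(x$entries)))
  invisible(x)
}

#' Read labelled distance tables from CSV
#'
#' Expects columns `peptide`, plus either `pair` (e.g. `"a-b"`) or
#' `atom_from`/`atom_to`, and `distance_angstrom`. One file may hold
#' several peptides; one `distance_table` is returned per peptide.
#'
#' @param path CSV file path.
#' @return A named list of `distance_table` objects.
#' @export
read_distance_tables <- function(path) {
  if (!file.exists(path)) stop("distance table file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"pair" %in% names(df)) {
    stopifnot(all(c("atom_from", "atom_to") %in% names(df)))
    df$pair <- paste(df$atom_from, df$atom_to, sep = "-")
  }
  stopifnot(all(c("peptide", "distance_angstrom") %in% names(df)))
  out <- lapply(split(df, df$peptide), function(d) {
    distance_table(setNames(d$distance_angstrom, d$pair),
                   peptide_name = d$peptide[1])
  })
  out
}

#' Write distance tables to CSV
#'
#' @param tables A `distance_table` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_distance_tables <- function(tables, path) {
  if (inherits(tables, "distance_table")) tables <- list(tables)
  rows <- do.call(rbind, lapply(tables, function(t) {
    parts <- strsplit(names(t$entries), "-", fixed = TRUE)
    data.frame(peptide = t$peptide_name,
               pair = names(t$entries),
               atom_from = vapply(parts, `[`, character(1), 1),
               atom_to = vapply(parts, `[`, character(1), 2),
               distance_angstrom = unname(t$entries),
               stringsAsFactors = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

align_tables <- function(observed, expected) {
  ol <- names(observed$entries)
  el <- names(expected$entries)
  if (!setequal(ol, el)) {
    stop("pair-label sets differ; symmetric difference: ",
         paste(union(setdiff(ol, el), setdiff(el, ol)), collapse = ", "))
  }
  if (length(ol) < 2) stop("need at least 2 shared pairs")
  list(o = observed$entries[sort(ol)], e = expected$entries[sort(ol)])
}

#' Chi-squared comparison of two conformer distance tables
#'
#' Compares observed (O) against expected (E) interatomic distances over an
#' identical set of pair labels using the statistic sum((O - E)^2 / E) with
#' n_pairs - 1 degrees of freedom. Note this is a descriptive index on
#' distances in angstroms, evaluated against the chi-squared distribution
#' for the similarity verdict; it is not a count-based goodness-of-fit
#' test. Also reports the fraction of pairs whose squared difference
#' (O - E)^2 exceeds the big-difference threshold.
#'
#' @param observed,expected `distance_table` objects sharing one pair-label
#'   set.
#' @param threshold Big-difference threshold on (O - E)^2, in squared
#'   angstroms (default 10, strict inequality).
#' @param confidence Confidence level for the similarity verdict
#'   (default 0.995).
#' @return An object of class `conformer_comparison` with `chi_squared`,
#'   `dof`, `proportion_big_diff` (fraction), `threshold`, `verdict`,
#'   `quantile`, `confidence`.
#' @examples
#' o <- distance_table(c("a-b" = 3, "a-c" = 4))
#' e <- distance_table(c("a-b" = 2, "a-c" = 5))
#' chi_squared_compare(o, e)  # chi2 = 1/2 + 1/5 = 0.7
#' @export
chi_squared_compare <- function(observed, expected, threshold = 10,
                                confidence = 0.995) {
  al <- align_tables(observed, expected)
  chi2 <- sum((al$o - al$e)^2 / al$e)
  dof <- length(al$o) - 1L
  v <- significance_verdict(chi2, dof, confidence)
  structure(list(
    chi_squared = chi2,
    dof = dof,
    proportion_big_diff = mean((al$o - al$e)^2 > threshold),
    threshold = threshold,
    verdict = v$verdict,
    quantile = v$quantile,
    confidence = confidence,
    observed_name = observed$peptide_name,
    expected_name = expected$peptide_name
  ), class = "conformer_comparison")
}

#' @export
print.conformer_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s (expected): Chi2 = %.4g, dof = %d -> %s at %g%% confidence (quantile %.2f)\n",
              x$observed_name, x$expected_name, x$chi_squared, x$dof,
              x$verdict, 100 * x$confidence, x$quantile))
  cat(sprintf("  (O-E)^2 > %g A^2 for %.0f%% of pairs\n",
              x$threshold, 100 * x$proportion_big_diff))
  invisible(x)
}

#' Similarity verdict from a chi-squared statistic
#'
#' The conformers are called `"indistinguishable"` when the statistic is
#' below the chi-squared quantile at the stated confidence level for the
#' given degrees of freedom, `"distinct"` otherwise.
#'
#' @param chi_squared The statistic.
#' @param dof Degrees of freedom (>= 1).
#' @param confidence Confidence level in (0, 1).
#' @return A list with `verdict`, `quantile`, `confidence`, `p_value`
#'   (upper-tail probability of the statistic).
#' @examples
#' significance_verdict(4.54, 19, 0.995)
#' @export
significance_verdict <- function(chi_squared, dof, confidence = 0.995) {
  stopifnot(dof >= 1, confidence > 0, confidence < 1, chi_squared >= 0)
  q <- qchisq(confidence, df = dof)
  list(verdict = if (chi_squared < q) "indistinguishable" else "distinct",
       quantile = q,
       confidence = confidence,
       p_value = pchisq(chi_squared, df = dof, lower.tail = FALSE))
}

#' Proportion of atom pairs with a big squared difference
#'
#' The percentage of shared pairs whose squared distance difference
#' (O - E)^2 is strictly above the threshold.
#'
#' @inheritParams chi_squared_compare
#' @return A percentage (0-100).
#' @export
big_diff_proportion <- function(observed, expected, threshold = 10) {
  al <- align_tables(observed, expected)
  100 * mean((al$o - al$e)^2 > threshold)
}

#' Distance table from labelled 3-D coordinates
#'
#' Computes Euclidean distances for every unordered pair of labelled atoms
#' (or a caller-specified pair subset).
#'
#' @param coordinates Numeric matrix with 3 columns (x, y, z) and row names
#'   giving the atom labels.
#' @param pairs Optional character vector of pair labels (e.g. `"a-c"`)
#'   restricting the output; default all pairs.
#' @param peptide_name Name for the resulting table.
#' @return A `distance_table`.
#' @examples
#' xyz <- rbind(a = c(0, 0, 0), b = c(3, 4, 0))
#' distances_from_coordinates(xyz)  # a-b = 5
#' @export
distances_from_coordinates <- function(coordinates, pairs = NULL,
                                       peptide_name = "model") {
  stopifnot(is.matrix(coordinates), ncol(coordinates) == 3,
            !is.null(rownames(coordinates)))
  labels <- rownames(coordinates)
  d <- as.matrix(stats::dist(coordinates))
  cmb <- utils::combn(labels, 2)
  all_pairs <- canonical_pair(paste(cmb[1, ], cmb[2, ], sep = "-"))
  entries <- setNames(d[cbind(cmb[1, ], cmb[2, ])], all_pairs)
  if (!is.null(pairs)) {
    pairs <- canonical_pair(pairs)
    missing <- setdiff(pairs, all_pairs)
    if (length(missing) > 0) {
      stop("pair label(s) without coordinates: ",
           paste(missing, collapse = ", "))
    }
    entries <- entries[pairs]
  }
  distance_table(entries, peptide_name = peptide_name)
}
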