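#' Residue composition model
#'
#' A probability distribution over the 20 canonical residues, used by the
#' chance-match calculus. The default is uniform (1/20 per residue), under
#' which the printed partial-anagram and initial-residue odds are exact.
#'
#' @param frequencies Named numeric vector of residue probabilities; names
#'   must be canonical residue letters and values must sum to 1 (within
#'   1e-9). `NULL` (default) gives the uniform composition.
#' @return A named numeric vector of class `residue_composition` covering
#'   all 20 canonical residues (absent residues get probability 0).
#' @export
residue_composition <- function(frequencies = NULL) {
  if (is.null(frequencies)) {
    frequencies <- setNames(rep(1 / 20, 20), AA_CANONICAL)
  }
  stopifnot(is.numeric(frequencies), !is.null(names(frequencies)))
  names(frequencies) <- toupper(names(frequencies))
  stopifnot(all(names(frequencies) %in% AA_CANONICAL),
            all(frequencies >= 0))
  if (abs(sum(frequencies) - 1) > 1e-9) {
    stop("residue frequencies must sum to 1 (got ", sum(frequencies), ")")
  }
  out <- setNames(rep(0, 20), AA_CANONICAL)
  out[names(frequencies)] <- frequencies
  class(out) <- "residue_composition"
  out
}

#' Per-window probability of a motif match
#'
#' The probability that a single random window matches the motif: the
#' product over fixed slots of each slot residue's frequency; wildcard
#' slots contribute a factor of 1.
#'
#' @param pattern A `motif_pattern` or pattern string.
#' @param composition A [residue_composition()].
#' @return A probability.
#' @examples
#' per_window_prob("NNI")          # (1/20)^3
#' per_window_prob("IILExxR")      # (1/20)^5
#' @export
per_window_prob <- function(pattern, composition = residue_composition()) {
  pattern <- as_motif_pattern(pattern)
  fixed <- pattern$slots[!is.na(pattern$slots)]
  prod(unclass(composition)[fixed])
}

#' Chance of a motif match anywhere in a protein of given length
#'
#' Slides the motif over all `L - k + 1` windows of a random protein of
#' length `L` and reports the expected occurrence count and, under an
#' independence approximation across windows, the probability of at least
#' one occurrence, together with its "1 in N" rendering.
#'
#' @param pattern A `motif_pattern` or string.
#' @param protein_length Protein length in residues.
#' @param composition A [residue_composition()].
#' @return A list of class `chance_match` with `per_window_prob`,
#'   `n_windows`, `expected_occurrences`, `prob_at_least_one`,
#'   `reciprocal_odds` (see [render_odds()]).
#' @examples
#' protein_match_prob("NNI", 619)
#' @export
protein_match_prob <- function(pattern, protein_length,
                               composition = residue_composition()) {
  pattern <- as_motif_pattern(pattern)
  stopifnot(protein_length >= 0)
  p <- per_window_prob(pattern, composition)
  n <- max(0L, as.integer(protein_length) - pattern$length + 1L)
  p_any <- 1 - (1 - p)^n
  structure(list(
    per_window_prob = p,
    n_windows = n,
    expected_occurrences = n * p,
    prob_at_least_one = p_any,
    reciprocal_odds = render_odds(p_any)
  ), class = "chance_match")
}

#' @export
print.chance_match <- function(x, ...) {
  cat(sprintf("per-window p = %.3g over %d windows; expected %.4g; P(>=1) = %.3g (%s)\n",
              x$per_window_prob, x$n_windows, x$expected_occurrences,
              x$prob_at_least_one, x$reciprocal_odds$rendering))
  invisible(x)
}

#' Combine two independent chance-match probabilities
#'
#' The probability that two independent events co-occur, `p1 * p2`, with
#' its "1 in N" rendering. Passing reciprocals is supported via
#' `odds_prob()`, e.g. `combined_independent_odds(1/5247, 1/2636)`.
#'
#' @param p1,p2 Probabilities in (0, 1].
#' @return A list with `probability` and `reciprocal_odds`.
#' @examples
#' combined_independent_odds(1 / 5247, 1 / 2636)$reciprocal_odds$rendering
#' @export
combined_independent_odds <- function(p1, p2) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  p <- p1 * p2
  list(probability = p, reciprocal_odds = render_odds(p))
}

#' Residue multiset from a peptide string
#'
#' @param peptide A residue string, e.g. `"MKPLTGKVKEF"`.
#' @return Named integer vector of residue multiplicities.
#' @export
residue_multiset <- function(peptide) {
  ch <- strsplit(toupper(peptide), "")[[1]]
  stopifnot(all(ch %in% AA_CANONICAL))
  tab <- table(ch)
  setNames(as.integer(tab), names(tab))
}

# All residue-count vectors c with 0 <= c_i <= m_i and sum(c) = k,
# one row per sub-multiset of size k.
submultiset_grid <- function(multiset, k) {
  grid <- expand.grid(lapply(multiset, function(m) 0:m),
                      KEEP.OUT.ATTRS = FALSE)
  grid[rowSums(grid) == k, , drop = FALSE]
}

#' Probability that a random k-mer is a partial anagram of a multiset
#'
#' Computes, by exact sub-multiset enumeration, the probability that a
#' window of `k` residues drawn independently from the composition is an
#' ordered arrangement of `k` residues taken (with multiplicity) from the
#' given multiset. For each size-`k` sub-multiset the number of distinct
#' orderings is the multinomial coefficient `k! / prod(c_i!)`; distinct
#' sub-multisets contribute disjoint ordered strings, so the probability is
#' the sum over sub-multisets of (orderings x product of residue
#' probabilities).
#'
#' @param multiset Named integer multiplicities (see [residue_multiset()])
#'   or a peptide string.
#' @param k Window length; must not exceed the multiset's total size.
#' @param composition A [residue_composition()].
#' @param alphabet_size Alphabet size used for the ordered-string count
#'   report (default 20).
#' @return A list with `probability`, `n_ordered_kmers` (count of distinct
#'   ordered k-mers that are partial anagrams), `reciprocal_odds`.
#' @examples
#' # nine-residue partial anagrams of MKPLTGKVKEF (11 residues, K x3)
#' anagram_window_prob("MKPLTGKVKEF", 9)
#' @export
anagram_window_prob <- function(multiset, k,
                                composition = residue_composition(),
                                alphabet_size = 20) {
  if (is.character(multiset)) multiset <- residue_multiset(multiset)
  stopifnot(all(multiset >= 1), k >= 0, k <= sum(multiset))
  if (k == 0) {
    return(list(probability = 1, n_ordered_kmers = 1L,
                reciprocal_odds = render_odds(1)))
  }
  grid <- submultiset_grid(multiset, k)
  comp <- unclass(composition)[names(multiset)]
  logfact <- lgamma(k + 1)
  orderings <- apply(grid, 1, function(cnt) exp(logfact - sum(lgamma(cnt + 1))))
  per_sub_prob <- apply(grid, 1, function(cnt) prod(comp^cnt))
  prob <- sum(round(orderings) * per_sub_prob)
  list(probability = prob,
       n_ordered_kmers = sum(round(orderings)),
       reciprocal_odds = render_odds(prob))
}

#' Probability that a random ordered k-permutation starts with a residue
#'
#' For a uniformly random ordered `k`-permutation of the multiset (all
#' distinct orderings of all size-`k` sub-multisets equally likely when
#' items are regarded as distinguishable), the probability that the first
#' element is the given residue equals `multiplicity / multiset size` by
#' symmetry, independent of `k`.
#'
#' @param multiset Named multiplicities or a peptide string.
#' @param residue A single residue letter.
#' @param k Permutation length (recorded; the probability does not depend
#'   on it).
#' @return A list with `probability` and `reciprocal_odds`; probability 0
#'   when the residue is absent from the multiset.
#' @examples
#' initial_residue_conditional_prob("MKPLTGKVKEF", "M", 9)  # 1/11
#' @export
initial_residue_conditional_prob <- function(multiset, residue, k = NULL) {
  if (is.character(multiset) && length(multiset) == 1 && is.null(names(multiset))) {
    multiset <- residue_multiset(multiset)
  }
  residue <- toupper(residue)
  m <- if (residue %in% names(multiset)) multiset[[residue]] else 0L
  p <- m / sum(multiset)
  list(probability = p, reciprocal_odds = render_odds(p))
}

#' Empirical fraction of database proteins containing a motif
#'
#' A census (not a sample): the fraction of proteins in the given proteome
#' carrying at least one motif occurrence, with its reciprocal rendering.
#'
#' @param proteome A `proteome` data frame.
#' @param pattern A `motif_pattern` or string.
#' @return A list with `fraction`, `n_with_match`, `n_proteins`,
#'   `reciprocal_odds`.
#' @export
empirical_database_prob <- function(proteome, pattern) {
  if (nrow(proteome) == 0) stop("empty proteome")
  hits <- scan_motif(proteome, pattern)
  nm <- length(unique(hits$protein_id))
  f <- nm / nrow(proteome)
  list(fraction = f, n_with_match = nm, n_proteins = nrow(proteome),
       reciprocal_odds = render_odds(f))
}

#' Render a probability as "1 in N" odds
#'
#' The reciprocal is rounded at a magnitude-dependent granularity: nearest
#' million above 1e7 (rendered e.g. "1 in 14m"), nearest hundred-thousand
#' above 1e6 ("1 in 1.6m"), nearest thousand above 1e5 ("1 in 146,000"),
#' otherwise nearest integer. A zero probability is flagged as never
#' occurring under the model.
#'
#' @param p A probability in \[0, 1\].
#' @return A list with `reciprocal` (rounded numeric, `Inf` for p = 0) and
#'   `rendering` (string).
#' @examples
#' render_odds(1 / 13831092)$rendering  # "1 in 14m"
#' @export
render_odds <- function(p) {
  stopifnot(p >= 0, p <= 1)
  if (p == 0) {
    return(list(reciprocal = Inf, rendering = "never by this model"))
  }
  n <- 1 / p
  if (n > 1e7) {
    r <- round(n / 1e6) * 1e6
    s <- sprintf("1 in %sm", format(r / 1e6, trim = TRUE))
  } else if (n > 1e6) {
    r <- round(n / 1e5) * 1e5
    s <- sprintf("1 in %sm", format(r / 1e6, trim = TRUE))
  } else if (n > 1e5) {
    r <- round(n / 1e3) * 1e3
    s <- sprintf("1 in %s", format(r, big.mark = ",", scientific = FALSE,
                                   trim = TRUE))
  } else {
    r <- round(n)
    s <- sprintf("1 in %s", format(r, big.mark = ",", scientific = FALSE,
                                   trim = TRUE))
  }
  list(reciprocal = r, rendering = s)
}

#' Parse a "1 in N" rendering back to a probability
#'
#' @param rendering A string such as `"1 in 14m"` or `"1 in 146,000"`.
#' @return The probability 1/N, or 0 for the never-flag.
#' @export
parse_odds <- function(rendering) {
  if (rendering == "never by this model") return(0)
  body <- sub("^~?1 in ", "", rendering)
  mult <- 1
  if (grepl("m$", body)) {
    mult <- 1e6
    body <- sub("m$", "", body)
  }
  n <- as.numeric(gsub(",", "", body)) * mult
  1 / n
}
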