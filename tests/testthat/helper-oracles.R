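# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# naive exhaustive-window motif scan; pattern string with x/. wildcards
oracle_scan_starts <- function(seqstr, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  k <- length(pat)
  ch <- strsplit(seqstr, "")[[1]]
  starts <- integer(0)
  for (s in seq_len(max(0, length(ch) - k + 1))) {
    ok <- TRUE
    for (j in seq_len(k)) {
      c0 <- ch[s + j - 1]
      if (pat[j] %in% c("x", ".")) {
        if (!(c0 %in% AA20)) { ok <- FALSE; break }
      } else if (c0 != pat[j]) { ok <- FALSE; break }
    }
    if (ok) starts <- c(starts, s)
  }
  starts
}

# brute-force Method-of-Exclusion filter over 11-mers
oracle_exclusion <- function(windows, allowed = "MKPLTGVEF") {
  allow <- strsplit(allowed, "")[[1]]
  tail_allow <- setdiff(allow, "M")
  keep <- vapply(windows, function(w) {
    ch <- strsplit(w, "")[[1]]
    all(ch[-1] %in% tail_allow)
  }, logical(1))
  score <- vapply(windows, function(w) {
    length(intersect(unique(strsplit(w, "")[[1]]), allow))
  }, integer(1))
  list(keep = unname(keep), score = unname(score))
}

# exhaustive enumeration of all |alphabet|^k strings: fraction that are
# ordered partial anagrams of the multiset (uniform letter model)
oracle_anagram_prob <- function(multiset, k, alphabet) {
  if (k == 0) return(1)
  grid <- expand.grid(rep(list(alphabet), k), stringsAsFactors = FALSE)
  is_sub <- apply(grid, 1, function(s) {
    tab <- table(factor(s, levels = names(multiset)))
    all(tab <= multiset) && sum(tab) == k && all(s %in% names(multiset))
  })
  mean(is_sub)
}

# random proteome over the full canonical alphabet (no planting)
random_proteome <- function(n, max_len, seed) {
  set.seed(seed)
  lens <- sample(5:max_len, n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(AA20, L, replace = TRUE), collapse = "")
  }, character(1))
  proteome(sprintf("RP%03d", seq_len(n)), seqs)
}

table1_core_panel <- function() {
  pan <- read_panel(system.file("extdata", "table1_panel.csv",
                                package = "nniomics"))
  pan[!pan$peptide_code %in% c("FNNA", "FNAI", "FANI", "ANNI"), ]
}
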