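test_that("read_fasta parses, canonicalizes and round-trips", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">p1 first entry", "MKPLTGKVK", ">p2", "aaNNIaaQQ", "WWWWW"), f)
  p <- read_fasta(f)
  expect_equal(nrow(p), 2)
  expect_equal(p$length, c(9, 14))
  expect_equal(p$sequence[2], "AANNIAAQQWWWWW")
  expect_equal(p$id, c("p1", "p2"))
  expect_equal(p$description[1], "first entry")

  # round-trip through the generator's writer
  sp <- make_proteome(n_proteins = 10, seed = 7)
  f2 <- tempfile(fileext = ".fasta")
  write_fasta(sp$proteome, f2)
  back <- read_fasta(f2)
  expect_equal(back$id, sp$proteome$id)
  expect_equal(back$sequence, sp$proteome$sequence)

  expect_error(read_fasta(tempfile()), "not found")
  f3 <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "MK", ">b", "", ">c", "MK"), f3)
  expect_error(read_fasta(f3), "empty sequence.*2")
})

test_that("scan_motif finds all overlapping occurrences with C-terminal flags", {
  h <- scan_motif("AANNINNIA", "NNI")
  expect_equal(h$start, c(3, 6))
  expect_equal(h$end, c(5, 8))
  expect_false(any(h$c_terminal))

  h2 <- scan_motif("QQNNI", "NNI")
  expect_equal(nrow(h2), 1)
  expect_true(h2$c_terminal)
  expect_equal(h2$end, 5)

  # overlap convention: NNI has no self-overlap, so NNNNI holds exactly one
  expect_equal(scan_motif("NNNNI", "NNI")$start, 3)
  # a genuinely self-overlapping pattern distinguishes the two modes
  expect_equal(scan_motif("ANNNNA", "NN")$start, c(2, 3, 4))
  expect_equal(scan_motif("ANNNNA", "NN", overlap = FALSE)$start, c(2, 4))

  # degenerate inputs
  expect_equal(nrow(scan_motif("QQ", "NNI")), 0)
  expect_error(motif_pattern(""))

  # wildcards match canonical residues only; fixed slots never match X
  expect_equal(nrow(scan_motif("AXNNI", "x.NNI")), 0)
  expect_equal(nrow(scan_motif("AGNNI", "x.NNI")), 1)
  expect_equal(nrow(scan_motif("NNX", "NNI")), 0)

  # anchors
  expect_equal(nrow(scan_motif("NNIANNI", motif_pattern("NNI", "C-terminal"))), 1)
  expect_equal(scan_motif("NNIANNI", motif_pattern("NNI", "N-terminal"))$start, 1)
})

test_that("scan_motif and anchored_window_search agree with the naive oracle", {
  patterns <- c("NNI", "FNNI", "M..........NNI", "IILExxR", "Kx")
  for (seed in 1:20) {
    pr <- random_proteome(10, 200, seed = seed)
    for (pat in patterns) {
      for (i in seq_len(nrow(pr))) {
        got <- scan_motif(pr[i, , drop = FALSE], pat)
        expect_equal(got$start, oracle_scan_starts(pr$sequence[i], pat),
                     info = sprintf("seed %d pattern %s protein %d", seed, pat, i))
      }
    }
    win <- anchored_window_search(pr, "M..........NNI")
    want <- unlist(lapply(seq_len(nrow(pr)), function(i) {
      oracle_scan_starts(pr$sequence[i], "M..........NNI")
    }))
    expect_equal(nrow(win), length(want))
  }
})

test_that("anchored_window_search enforces the exact wildcard gap", {
  p <- proteome("demo", "MAAAAAAAAAANNI")
  h <- anchored_window_search(p, "M..........NNI")
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 1)
  expect_equal(h$window, "MAAAAAAAAAANNI")
  # nine wildcards between M and NNI: no 14-mer match
  p2 <- proteome("demo", "MAAAAAAAAANNI")
  expect_equal(nrow(anchored_window_search(p2, "M..........NNI")), 0)
  expect_error(anchored_window_search(p, "x.........NNIx"), "fixed first")
})

test_that("methionine pool counts non-initiator Ms", {
  expect_equal(count_methionine_pool(proteome("p", "MKM")), 1)
  expect_equal(count_methionine_pool(proteome("p", "MKM"),
                                     exclude_initiator = FALSE), 2)
  expect_equal(count_methionine_pool(proteome(c("a", "b"), c("KKK", "MMMM"))), 3)
  expect_equal(count_methionine_pool(empty_proteome <- proteome(character(0), character(0))), 0)
})

test_that("Method of Exclusion filters and scores as the rule states", {
  # reference survivor: 8 distinct allowed residues (M,L,K,T,G,E,P,V)
  s <- method_of_exclusion("MLKTGEKPVEP")
  expect_equal(nrow(s), 1)
  expect_equal(s$distinct_allowed_count, 8)

  # forbidden residue W and a second M are both excluding
  expect_equal(nrow(method_of_exclusion("MLKTGEKPVEW")), 0)
  expect_equal(nrow(method_of_exclusion("MLKTGEKPVEM")), 0)

  expect_error(method_of_exclusion("ALKTGEKPVEP"), "M-initial")
  expect_error(method_of_exclusion("MLKTG"), "M-initial")

  # 200 random windows against the brute-force oracle
  set.seed(42)
  wins <- vapply(1:200, function(i) {
    paste0("M", paste(sample(AA20, 10, replace = TRUE), collapse = ""))
  }, character(1))
  # bias half towards the allowed alphabet so some survive
  wins[1:100] <- vapply(1:100, function(i) {
    paste0("M", paste(sample(strsplit("KPLTGVEF", "")[[1]], 10,
                             replace = TRUE), collapse = ""))
  }, character(1))
  got <- method_of_exclusion(wins)
  want <- oracle_exclusion(wins)
  expect_equal(nrow(got), sum(want$keep))
  expect_setequal(got$window, wins[want$keep])
  expect_equal(got$distinct_allowed_count[match(wins[want$keep], got$window)],
               want$score[want$keep])
  # ranking: descending score, ties by (protein_id, start)
  expect_true(all(diff(got$distinct_allowed_count) <= 0))
})

test_that("sift report matches generator manifests across seeds", {
  for (seed in 1:20) {
    sp <- make_proteome(n_proteins = 40, n_internal = 8, n_c_terminal = 2,
                        n_anchored = 2, seed = seed)
    rep <- build_sift_report(sp$proteome)
    m <- sp$manifest
    expect_equal(rep$proteome_size, m$proteome_size)
    expect_equal(rep$motif_ome_size, m$motif_ome_size)
    expect_equal(rep$total_hits, m$total_hits)
    expect_equal(rep$terminal_hits, m$terminal_hits)
    expect_equal(rep$sub_pattern_counts, m$sub_pattern_counts)
    expect_equal(rep$short_protein_count, m$short_protein_count)
    expect_equal(rep$methionine_pool, m$methionine_pool)
    expect_equal(rep$anchored_window_count, m$anchored_window_count)
    expect_equal(nrow(rep$exclusion_survivors), m$exclusion_survivor_count)
    # planted coordinates re-found exactly
    hits <- rep$hits
    key_got <- paste(hits$protein_id, hits$start)
    motif_plants <- with(m$planted,
      paste(protein_id, ifelse(kind == "anchored", start + 11L, start)))
    expect_setequal(key_got, motif_plants)
  }
})

test_that("sift report honours conservation and monotonicity invariants", {
  sp <- make_proteome(n_proteins = 30, seed = 11)
  rep <- build_sift_report(sp$proteome)
  no_motif <- rep$proteome_size - rep$motif_ome_size
  expect_equal(rep$motif_ome_size + no_motif, rep$proteome_size)
  expect_true(rep$terminal_hits <= rep$total_hits)
  expect_true(all(rep$sub_pattern_counts <= rep$total_hits))
  expect_true(all(rep$exclusion_survivors$protein_id %in% rep$motif_ome_ids))

  # adding a motif-bearing protein never decreases census counts
  bigger <- rbind(sp$proteome,
                  proteome("EXTRA1", "AAAANNIAAA"))
  class(bigger) <- class(sp$proteome)
  rep2 <- build_sift_report(bigger)
  expect_gte(rep2$motif_ome_size, rep$motif_ome_size)
  expect_gte(rep2$total_hits, rep$total_hits)

  # empty proteome: all zeros
  rep0 <- build_sift_report(proteome(character(0), character(0)))
  expect_equal(rep0$proteome_size, 0)
  expect_equal(rep0$motif_ome_size, 0)
  expect_equal(rep0$total_hits, 0)
  expect_equal(rep0$methionine_pool, 0)
})

test_that("sift report writes census and survivor CSVs", {
  sp <- make_proteome(n_proteins = 15, seed = 5)
  rep <- build_sift_report(sp$proteome)
  stem <- tempfile()
  write_sift_report(rep, stem)
  census <- read.csv(paste0(stem, "_census.csv"))
  expect_equal(census$value[census$statistic == "total_hits"], rep$total_hits)
  surv <- read.csv(paste0(stem, "_survivors.csv"))
  expect_equal(nrow(surv), nrow(rep$exclusion_survivors))
})
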