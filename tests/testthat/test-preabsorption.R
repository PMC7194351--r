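test_that("area fraction counts pixels strictly above the threshold", {
  expect_equal(area_fraction(matrix(0, 4, 4), 0), 0)
  half <- matrix(c(rep(0.2, 8), rep(0.8, 8)), 4, 4)
  expect_equal(area_fraction(half, 0.5), 0.5)
  expect_error(area_fraction(matrix(numeric(0), 0, 0), 0.5), "empty")

  img <- make_image(0.25, dims = c(20, 20), seed = 2)
  expect_equal(area_fraction(img$image, img$truth$threshold), 0.25)
  # PNG round-trip
  f <- tempfile(fileext = ".png")
  make_image(0.3, dims = c(16, 16), seed = 3, path = f)
  expect_equal(area_fraction(f, 0.5), 0.3, tolerance = 1 / 256)
})

test_that("percent of control normalizes to the control mean", {
  m <- data.frame(
    peptide_code = c("NONE", "NONE", "PEP", "PEP", "BLOCKED"),
    area_labelled = c(0.03, 0.05, 0.04, 0.02, 0))
  out <- percent_of_control(m)
  expect_equal(out$percent_of_control[1:2], c(75, 125))
  expect_equal(mean(out$percent_of_control[out$peptide_code == "NONE"]), 100)
  expect_equal(out$percent_of_control[3:4], c(100, 50))
  expect_equal(out$percent_of_control[5], 0)

  # scale invariance
  m2 <- m
  m2$area_labelled <- m$area_labelled * 7.3
  expect_equal(percent_of_control(m2)$percent_of_control,
               out$percent_of_control)
  expect_error(percent_of_control(data.frame(peptide_code = "NONE",
                                             area_labelled = 0)), "zero")
  expect_error(percent_of_control(m, control_key = "missing"), "empty")
})

test_that("group summaries give mean and SEM", {
  s <- group_summary(c(10, 10, 10))
  expect_equal(s$mean, 10)
  expect_equal(s$sem, 0)
  s2 <- group_summary(c(0, 2))
  expect_equal(s2$mean, 1)
  expect_equal(s2$sem, 1)
  expect_equal(group_summary(5)$sem, 0)

  df <- data.frame(peptide_code = rep(c("A", "B"), each = 3),
                   percent_of_control = c(1, 2, 3, 10, 10, 10))
  out <- summarize_groups(df)
  expect_equal(out$mean, c(2, 10))
  expect_equal(out$n, c(3, 3))

  # planted mean recovery over seeds
  set.seed(55)
  devs <- replicate(100, {
    x <- rnorm(8, mean = 40, sd = 6)
    s <- group_summary(x)
    (s$mean - 40) / (6 / sqrt(8))
  })
  expect_lt(abs(mean(devs)), 3 / sqrt(100) + 0.5)
})

test_that("unpaired t from summaries equals t from raw values", {
  set.seed(77)
  for (i in 1:10) {
    a <- rnorm(6, 10, 2)
    b <- rnorm(9, 12, 3)
    raw <- unpaired_t(a, b)
    smry <- unpaired_t(group_summary(a), group_summary(b))
    expect_equal(raw$t, smry$t, tolerance = 1e-9)
    expect_equal(raw$p, smry$p, tolerance = 1e-9)

    # oracle: stats::t.test
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(raw$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(raw$p, ref$p.value, tolerance = 1e-9)

    w <- unpaired_t(a, b, variant = "welch")
    refw <- t.test(a, b)
    expect_equal(w$t, unname(refw$statistic), tolerance = 1e-9)
    expect_equal(w$dof, unname(refw$parameter), tolerance = 1e-9)
    expect_equal(w$p, refw$p.value, tolerance = 1e-9)
  }

  same <- unpaired_t(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_warning(unpaired_t(c(5, 5, 5), c(7, 7, 7)), "zero variance")
  expect_error(unpaired_t(3, c(1, 2)), ">= 2")
})

test_that("pooled t-test maintains its type-I error and detects separation", {
  set.seed(123)
  n_sim <- 500
  rej_null <- mean(replicate(n_sim, {
    unpaired_t(rnorm(8), rnorm(8))$p < 0.05
  }))
  se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(rej_null - 0.05), 3 * se)

  # planted separation delta/sigma = 3, n = 8: power near 1
  rej_alt <- mean(replicate(200, {
    unpaired_t(rnorm(8, 3), rnorm(8, 0))$p < 0.05
  }))
  expect_gt(rej_alt, 0.95)
})

test_that("IC50 bound applies the tested-dose rule", {
  flat <- data.frame(concentration = c(0.1, 10, 1000),
                     mean_percent = c(100, 98, 101))
  expect_equal(ic50_bound(flat)$comparator, "not reached")

  mid <- data.frame(concentration = c(0.1, 10, 1000),
                    mean_percent = c(80, 40, 5))
  b <- ic50_bound(mid)
  expect_equal(b$bound, 10)
  expect_equal(b$comparator, "<=")

  low <- data.frame(concentration = c(0.1, 10, 1000),
                    mean_percent = c(30, 10, 2))
  b2 <- ic50_bound(low)
  expect_equal(b2$bound, 0.1)
  expect_equal(b2$comparator, "<")
})

test_that("suffix matching honours wildcards and lengths", {
  expect_equal(suffix_matches("NNI", c("MKPLTGKVKEFNNI", "NNI", "ANN", "FNN")),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(suffix_matches("xNNI", c("FNNI", "NNI")), c(TRUE, FALSE))
  expect_equal(suffix_matches("FxNI", c("FANI", "FNNI", "AANI")),
               c(TRUE, TRUE, FALSE))
})

test_that("the printed panel is separated perfectly by a C-terminal NNI", {
  core <- table1_core_panel()
  inf <- infer_epitope(core, max_len = 6)
  expect_false(inf$degenerate)
  expect_equal(inf$best$pattern, "NNI")
  expect_equal(inf$best$accuracy, 1.0)
  expect_equal(inf$best$sensitivity, 1.0)
  expect_equal(inf$best$specificity, 1.0)
  expect_equal(inf$n_blockers, 8)
  expect_equal(inf$n_non_blockers, 12)

  # permutation invariance
  set.seed(31)
  shuf <- core[sample(nrow(core)), ]
  expect_equal(infer_epitope(shuf, max_len = 6)$best$pattern, "NNI")

  # adding a non-blocker already rejected by the best pattern changes nothing
  extra <- rbind(core, data.frame(peptide_code = "XTRA", sequence = "GGGG",
                                  blocks = "no"))
  expect_equal(infer_epitope(extra, max_len = 6)$best$pattern, "NNI")

  # degenerate panel: all blockers
  allb <- core[core$blocks == "yes", ]
  degen <- infer_epitope(allb)
  expect_true(degen$degenerate)
  expect_equal(degen$patterns$pattern[1], "x")
})

test_that("substitution scan classifies tolerant and required positions", {
  pan <- read_panel(system.file("extdata", "table1_panel.csv",
                                package = "nniomics"))
  vars <- pan[pan$peptide_code %in% c("FNNA", "FNAI", "FANI", "ANNI"), ]
  scan <- substitution_scan(vars, base = "FNNI")
  expect_equal(scan$position, 1:4)
  expect_equal(scan$tolerated, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(scan$residue, c("F", "N", "N", "I"))

  core <- table1_core_panel()
  inf <- infer_epitope(core, max_len = 6, variants = vars,
                       variant_base = "FNNI")
  cls <- inf$classification
  expect_true(all(c("N", "I") %in% cls$residue[cls$class == "contiguous-core"]))
  expect_equal(cls$residue[cls$class == "required-non-contiguous"], "F")

  expect_error(substitution_scan(data.frame(peptide_code = "x",
                                            sequence = "FAAI",
                                            blocks = "no"), "FNNI"),
               "2 positions")
})

test_that("planted suffix rules are recovered from synthetic panels", {
  recovered <- vapply(1:50, function(seed) {
    g <- make_panel(n_peptides = 14, rule = "NNI", seed = seed)
    if (!g$identifiable) return(NA)
    inf <- infer_epitope(g$panel, max_len = 4)
    inf$best$accuracy == 1 &&
      identical(unname(suffix_matches(inf$best$pattern, g$panel$sequence)),
                g$panel$blocks == "yes")
  }, logical(1))
  expect_true(all(recovered[!is.na(recovered)]))
})

test_that("dose-response generator hits the curve midpoint and ordering", {
  peps <- data.frame(peptide_code = c("B1", "NB1"),
                     sequence = c("KEFNNI", "KEFAAA"))
  g <- make_panel_measurements(peps, rule = "NNI", ic50 = 10, slope = 1,
                               noise_sd = 0, n_rep = 2,
                               concentrations = c(10), seed = 1)
  b <- g$measurements[g$measurements$peptide_code == "B1", ]
  expect_equal(b$percent, c(50, 50))
  nb <- g$measurements[g$measurements$peptide_code == "NB1", ]
  expect_equal(nb$percent, c(100, 100))

  # planted IC50s in 1:10:100 ratio recover their bound ordering
  peps3 <- data.frame(peptide_code = c("P1", "P2", "P3"),
                      sequence = c("AKNNI", "GGNNI", "TTNNI"))
  ok <- vapply(1:50, function(seed) {
    g <- make_panel_measurements(
      peps3, rule = "NNI", ic50 = c(P1 = 0.05, P2 = 5, P3 = 50),
      slope = 1, noise_sd = 5, n_rep = 4,
      concentrations = c(0.1, 1, 10, 100, 1000), seed = seed)
    ms <- aggregate(percent ~ peptide_code + concentration, g$measurements,
                    mean)
    bounds <- vapply(c("P1", "P2", "P3"), function(p) {
      d <- ms[ms$peptide_code == p, ]
      ic50_bound(data.frame(concentration = d$concentration,
                            mean_percent = d$percent))$bound
    }, numeric(1))
    bounds[["P1"]] <= bounds[["P2"]] && bounds[["P2"]] <= bounds[["P3"]]
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
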