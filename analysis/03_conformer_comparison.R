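#!/usr/bin/env Rscript
# Chi-squared comparison of peptide conformer interatomic-distance tables.
# Uses the deposited distance tables when present under
# inst/extdata/deposited/ (see README); otherwise demonstrates the
# machinery on a synthetic 20-pair geometry, including the monotone
# response of the statistic to coordinate jitter. Writes results/conformer/.

suppressPackageStartupMessages(library(nniomics))
out_dir <- "results/conformer"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

deposited <- system.file("extdata", "deposited", "interatomic_distances.csv",
                         package = "nniomics")
if (nzchar(deposited) && file.exists(deposited)) {
  tabs <- read_distance_tables(deposited)
  message("Comparing deposited tables against the embedded reference ",
          "conformer (expected distances).")
  for (pep in setdiff(names(tabs), "EPL001")) {
    print(chi_squared_compare(tabs[[pep]], tabs$EPL001))
  }
} else {
  message("Deposited distance tables not present; running on a synthetic ",
          "11-atom geometry (20-pair subset) instead.")
  set.seed(1)
  xyz <- matrix(rnorm(33, sd = 4), 11, 3,
                dimnames = list(letters[1:11], NULL))
  base <- distances_from_coordinates(xyz, peptide_name = "reference")
  pairs20 <- names(base$entries)[1:20]
  base <- distance_table(base$entries[pairs20], "reference")

  near <- make_distance_tables(base, 0.5, 1, seed = 2)[[1]]
  far <- make_distance_tables(base, 3.0, 1, seed = 3)[[1]]
  message("A lightly jittered conformer (SD 0.5 A) vs a heavily jittered ",
          "one (SD 3 A):")
  print(chi_squared_compare(near, base))
  print(chi_squared_compare(far, base))
}

message("Jitter response: mean chi-squared over 200 seeded tables per SD.")
set.seed(10)
base20 <- distance_table(setNames(runif(20, 3, 14),
                                  paste0(letters[1:20], "-z")), "base")
sigmas <- c(0.1, 0.5, 1.0, 2.0)
means <- vapply(sigmas, function(s) {
  mean(vapply(make_distance_tables(base20, s, 200, seed = 100 + s * 10),
              function(t) chi_squared_compare(t, base20)$chi_squared,
              numeric(1)))
}, numeric(1))
jit <- data.frame(jitter_sd_angstrom = sigmas, mean_chi_squared = means)
print(jit)
stopifnot(all(diff(means) > 0))
message("Mean statistic increases strictly with jitter SD, as it must.")
write.csv(jit, file.path(out_dir, "jitter_response.csv"), row.names = FALSE)
message("Wrote ", out_dir, "/jitter_response.csv")
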