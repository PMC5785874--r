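# Regenerates the shipped fixture datasets (inst/extdata/trial_*.csv).
# Run from the repository root:  Rscript scripts/make_fixtures.R
library(fenofood)

write_fixture <- function(n, seed, path) {
  trial <- generate_trial(trial_design(n_subjects = n), mbpk_params(),
                          seed = seed)
  d <- trial$dataset
  d$DV <- signif(d$DV, 7)
  tmp <- tempfile()
  utils::write.csv(d, tmp, row.names = FALSE, quote = FALSE)
  header <- sprintf(
    "# synthetic crossover trial: generate_trial(trial_design(n_subjects = %d), mbpk_params(), seed = %d)",
    n, seed)
  writeLines(c(header, readLines(tmp)), path)
  unlink(tmp)
}

write_fixture(6, 101, "inst/extdata/trial_small.csv")
write_fixture(24, 202, "inst/extdata/trial_full.csv")
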