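#!/usr/bin/env Rscript

# Step 5 -- scenario simulation.
#
# Arm-level location parameters (covariate-adjusted typical value times the
# study's empirical Bayes multiplier) are pooled per scenario by
# DerSimonian-Laird random-effects meta-analysis; 10,000 Monte-Carlo draws
# from each pooled distribution give the median PFS and its 90% band, in
# the shape of a per-scenario summary table.

suppressMessages(library(survmbma))

seed <- 1L
corpus <- read_corpus("results/corpus.csv")
model <- mbma_model("lognormal", list(
  covariate_effect("therapy_type", target = "mu", kind = "categorical",
                   reference = "combination")))
fit <- if (file.exists("scratch/fit.rds")) readRDS("scratch/fit.rds") else
  fit_mbma(corpus, model, seed = seed)

scenarios <- list(
  monotherapy            = list(therapy_type = "monotherapy"),
  combination            = list(therapy_type = "combination"),
  mono_olaparib          = list(therapy_type = "monotherapy",
                                drug = "olaparib"),
  mono_niraparib         = list(therapy_type = "monotherapy",
                                drug = "niraparib"),
  mono_rucaparib         = list(therapy_type = "monotherapy",
                                drug = "rucaparib"),
  mono_BRCAm             = list(therapy_type = "monotherapy",
                                biomarker = "BRCAm"),
  mono_HRD_positive      = list(therapy_type = "monotherapy",
                                biomarker = "HRD_positive"),
  platinum_sensitive     = list(platinum = "sensitive"),
  partially_resistant    = list(platinum = "partially_resistant"))

out <- simulate_scenarios(fit, corpus, scenarios, n_rep = 10000,
                          seed = seed, level = 90)
print(out$table, digits = 4)
write.csv(out$table, "results/scenario_summaries.csv", row.names = FALSE)

cat("\nWrote results/scenario_summaries.csv\n")
cat("Note: medians here summarize the synthetic corpus, not the original",
    "trial data; the generating typical medians are exp(2.3236) = 10.2",
    "months (monotherapy) and exp(2.96) = 19.3 months (combination).\n")
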