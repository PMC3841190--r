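#!/usr/bin/env Rscript
# Regenerates the two fixtures shipped under inst/extdata/:
#   sa_model_toy27.json     27-letter model fitted on a synthetic bank
#   mjs_thresholds_toy.json per-size MJS thresholds calibrated on the
#                           synthetic calibration set
# Run from the package root: Rscript tools/make_fixtures.R
suppressMessages(devtools::load_all(".", quiet = TRUE))

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

## 1. toy 27-letter model ---------------------------------------------
train_spec <- bank_spec(
  n_proteins = 40L, len_range = c(50L, 90L),
  weights = c(helix = 0.35, strand = 0.25, hairpin = 0.2, coil = 0.2),
  noise_sd = 0.15, seed = 42L
)
train_traces <- withr::with_seed(train_spec$seed, {
  lens <- sample(train_spec$len_range[1]:train_spec$len_range[2],
                 train_spec$n_proteins, replace = TRUE)
  lapply(seq_len(train_spec$n_proteins), function(i) {
    sapick:::assemble_chain(lens[i], train_spec$weights, train_spec$noise_sd,
                            chain_id = sprintf("train%03d", i))
  })
})
message("fitting 27-state model ...")
model <- fit_baum_welch(train_traces, n_states = 27L, seed = 7L,
                        max_iter = 150L, tol = 1e-3)
fit <- attr(model, "fit")
message(sprintf("  %d iterations, loglik %.1f -> %.1f, converged: %s",
                fit$iterations, fit$loglik[1], tail(fit$loglik, 1),
                fit$converged))
write_sa_model(model, "inst/extdata/sa_model_toy27.json", digits = 7)
model <- read_sa_model("inst/extdata/sa_model_toy27.json")

## 2. per-size MJS thresholds ------------------------------------------
# study conditions: bank and query profiles both carry predictor-grade
# Dirichlet noise (concentration 50)
calib_bank <- build_bank(
  bank_spec(n_proteins = 12L, len_range = c(40L, 70L),
            noise_sd = 0.15, seed = 101L),
  model, concentration = 50
)
query_spec <- bank_spec(n_proteins = 4L, len_range = c(40L, 60L),
                        noise_sd = 0.15, seed = 202L)
queries <- build_bank(query_spec, model)       # exact posteriors + structures
query_profiles <- lapply(seq_len(nrow(queries)), function(i) {
  pseudo_predict(queries$profile[[i]], concentration = 50,
                 seed = 202L + i)
})

bg <- background_stats(calib_bank, sizes = 6:27, n_samples = 300L, seed = 11L)
rule <- tp_rule(bg, k = 2, floor = 0.5)

message("collecting scored pairs ...")
pairs <- calibration_pairs(queries$trace, query_profiles, calib_bank,
                           sizes = 6:27, max_per_size = 1500L,
                           mjs_cap = 0.9, seed = 13L)
th <- calibrate_mjs_thresholds(pairs, rule, precision_target = 0.95,
                               sizes = 6:27)
print(as.data.frame(th))
jsonlite::write_json(th[, c("size", "threshold")],
                     "inst/extdata/mjs_thresholds_toy.json", digits = NA)
message("done.")
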