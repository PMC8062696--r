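test_that("simulation is bit-identical under a fixed seed", {
  a <- simulate_dataset(sim_params(n_proteins = 150, seed = 77))
  b <- simulate_dataset(sim_params(n_proteins = 150, seed = 77))
  expect_identical(a$table$ratios, b$table$ratios)
  expect_identical(a$lists$pc, b$lists$pc)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$truth, b$truth)
  c <- simulate_dataset(sim_params(n_proteins = 150, seed = 78))
  expect_false(identical(a$table$ratios, c$table$ratios))
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(sim_params(frac_labeled = 1.2), "\\[0, 1\\]")
  expect_error(sim_params(sigma_labeled = 0), "positive")
  expect_error(sim_params(missing_rate = 1), "< 1")
  expect_error(sim_params(n_proteins = 0), "positive")
})

test_that("the zero-labeled limit yields a pure background table", {
  sim <- simulate_dataset(sim_params(n_proteins = 300, frac_labeled = 0,
                                     nc_coverage = 0.5, seed = 12))
  expect_false(any(sim$truth$is_labeled))
  # ratios are centred background noise; any positive threshold catches
  # only false positives
  thr <- setNames(rep(1.5, 4), comparison_ids(sim$table$design))
  sc <- score_table(sim$table, thr)
  hits <- call_hits(sc, 1)
  ev <- evaluate_calls(hits, sim$truth)
  expect_equal(ev$sensitivity, NA_real_)
  expect_true(ev$empirical_fdr %in% c(0, 1) || ev$empirical_fdr == 1)
  expect_lt(length(hits) / 300, 0.05)
})

test_that("labeled-protein ratios converge on mu_labeled", {
  p <- sim_params(n_proteins = 4000, seed = 5)
  sim <- simulate_dataset(p)
  lab <- sim$truth$is_labeled
  vals <- sim$table$ratios[lab, ]
  n_obs <- sum(!is.na(vals))
  expect_gt(n_obs, 1000)
  expect_lt(abs(mean(vals, na.rm = TRUE) - p$mu_labeled),
            3 * p$sigma_labeled / sqrt(n_obs) + 0.05)
  bg <- sim$table$ratios[!lab, ]
  expect_lt(abs(mean(bg, na.rm = TRUE)), 0.05)
  # marginal spread close to the declared sigma
  expect_lt(abs(sd(vals, na.rm = TRUE) - p$sigma_labeled), 0.05)
})

test_that("the shared bait-replicate effect induces within-replicate correlation", {
  sim <- simulate_dataset(sim_params(n_proteins = 5000, missing_rate = 0,
                                     seed = 42))
  lab <- sim$truth$is_labeled
  r <- sim$table$ratios[lab, ]
  same_bait <- cor(r[, "bait1/ctrl1"], r[, "bait1/ctrl2"])
  diff_bait <- cor(r[, "bait1/ctrl1"], r[, "bait2/ctrl2"])
  expect_gt(same_bait, diff_bait + 0.2)
  expect_gt(same_bait, 0.3)
})

test_that("annotation flags are coupled to the true labeling state", {
  sim <- simulate_dataset(sim_params(n_proteins = 3000, seed = 2))
  sp <- sim$annotations$signal_peptide
  lab <- sim$truth$is_labeled
  expect_gt(mean(sp[lab]), 0.8)    # sp_sens 0.9
  expect_lt(mean(sp[!lab]), 0.1)   # 1 - sp_spec = 0.05
  ab <- sim$annotations$abundance_ppm
  expect_lt(median(ab[lab]), median(ab[!lab]))
})

test_that("signal-peptide prevalence increases across score strata under perfect flags", {
  sim <- simulate_dataset(sim_params(n_proteins = 8000,
                                     pc_contamination = 0,
                                     sp_sens = 1, sp_spec = 1, seed = 30))
  tab <- suppressMessages(median_normalize(filter_quant_table(sim$table)))
  cal <- calibrate_comparisons(tab, sim$lists, rule = "purity",
                               parameter = 0.9)
  sc <- score_table(tab, calibration_thresholds(cal))
  sp <- setNames(sim$annotations$signal_peptide, sim$annotations$protein_id)
  frac_sp <- vapply(0:4, function(k) {
    ids <- sc$protein_id[sc$score == k]
    mean(sp[ids])
  }, numeric(1))
  # top strata saturate at 1 when the flag is perfect, so the rise is
  # monotone with a strict overall increase
  expect_true(all(diff(frac_sp) >= 0))
  expect_gt(frac_sp[5], frac_sp[1])
  expect_gt(frac_sp[3], frac_sp[2])
})

test_that("evaluate_calls computes sensitivity, FDR and precision", {
  truth <- data.frame(protein_id = sprintf("P%02d", 1:20),
                      is_labeled = c(rep(TRUE, 10), rep(FALSE, 10)))
  lab <- truth$protein_id[1:10]
  bg <- truth$protein_id[11:20]
  perfect <- evaluate_calls(lab, truth)
  expect_equal(perfect, list(sensitivity = 1, empirical_fdr = 0,
                             precision = 1))
  none <- evaluate_calls(character(0), truth)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$empirical_fdr, 0)
  mixed <- evaluate_calls(c(lab[1:8], bg[1:2]), truth)
  expect_equal(mixed$sensitivity, 0.8)
  expect_equal(mixed$empirical_fdr, 0.2)
  expect_error(evaluate_calls("GHOST", truth), "absent from truth")
})

test_that("pipeline sensitivity is monotone in the labeled-ratio mean", {
  sens_at_mu <- function(mu, seed) {
    sim <- simulate_dataset(sim_params(n_proteins = 800, mu_labeled = mu,
                                       seed = seed))
    tab <- suppressMessages(median_normalize(filter_quant_table(sim$table)))
    cal <- suppressWarnings(
      calibrate_comparisons(tab, sim$lists, rule = "purity",
                            parameter = 0.9))
    thr <- calibration_thresholds(cal)
    if (anyNA(thr)) return(NA_real_)
    hits <- call_hits(score_table(tab, thr), 1)
    evaluate_calls(hits, sim$truth)$sensitivity
  }
  seeds <- 1:10
  mean_sens <- vapply(c(1, 2, 3), function(mu) {
    mean(vapply(seeds, function(s) sens_at_mu(mu, s), numeric(1)),
         na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_sens) >= 0))
})
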