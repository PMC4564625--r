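test_that("generator configuration is validated", {
  expect_gbm_error(simulation_config(n_patients = 1), "gbm_config_error")
  expect_gbm_error(simulation_config(class_separation = -1), "gbm_config_error")
  expect_gbm_error(simulation_config(missingness = c(perfusion = 1.2,
                                                     diffusion = 0.4,
                                                     spectroscopy = 0.6)),
                   "gbm_config_error")
  expect_gbm_error(simulation_config(zero_volume_missing_coupling = 2),
                   "gbm_config_error")
  expect_gbm_error(
    simulation_config(sessions_before_decision = rep(0.5, 12)),
    "gbm_config_error")
  # config round-trips through YAML
  cfg <- simulation_config(seed = 9, class_separation = 2)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_simulation_config(cfg, path)
  expect_equal(read_simulation_config(path), cfg)
})

test_that("generation is deterministic in the seed and schema-conformant", {
  cfg <- simulation_config(seed = 21)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data,
                         generate_cohort(simulation_config(seed = 22))$data))
  # re-validation passes, labels propagated, fully observed
  expect_silent(as_cohort(a$data, a$schema))
  expect_false(anyNA(a$data[, schema27$names]))
  expect_true(all(a$data$label[a$data$offset < 0] == "unlabeled"))
  expect_true(all(a$data$label[a$data$offset >= 0] == a$data$decision_class[a$data$offset >= 0]))
})

test_that("session counts bracket the emulated study size", {
  totals <- vapply(1:20, function(s) {
    n_sessions(generate_cohort(simulation_config(seed = s,
                                                 class_separation = 0)))
  }, numeric(1))
  expect_true(all(totals >= 100 & totals <= 260))
  # centred near the 178 sessions of the emulated cohort
  expect_gt(mean(totals), 150)
  expect_lt(mean(totals), 205)
})

test_that("separation parameter controls class-conditional means", {
  cfg0 <- simulation_config(n_patients = 60, class_separation = 0, seed = 31)
  co0 <- generate_cohort(cfg0)
  d <- co0$data
  gap <- abs(mean(d$rrCBV_CE[d$decision_class == "progressive"]) -
             mean(d$rrCBV_CE[d$decision_class == "responsive"]))
  expect_lt(gap, 0.1)   # sampling noise only (sd 0.25, n ~ 180/class)
  cfg3 <- simulation_config(n_patients = 60, class_separation = 3, seed = 31)
  co3 <- generate_cohort(cfg3)
  d3 <- co3$data
  gap3 <- mean(d3$rrCBV_CE[d3$decision_class == "progressive"]) -
    mean(d3$rrCBV_CE[d3$decision_class == "responsive"])
  expect_gt(gap3, 0.5)
})

test_that("missingness masks whole modality blocks at the configured rates", {
  cfg <- simulation_config(seed = 41)
  co <- generate_cohort(cfg)
  # rates 0: identity
  none <- simulation_config(seed = 41, missingness = c(perfusion = 0,
                                                       diffusion = 0,
                                                       spectroscopy = 0))
  expect_identical(inject_missingness(co, none)$data, co$data)
  # rates 1: everything but the 5 always-present features is masked
  all_cfg <- simulation_config(seed = 41, missingness = c(perfusion = 1,
                                                          diffusion = 1,
                                                          spectroscopy = 1))
  gone <- inject_missingness(co, all_cfg)
  expect_true(all(is.na(gone$data[, c(perf_feats, diff_feats, spec_feats)])))
  expect_false(anyNA(gone$data[, schema27$always_present]))
  # block structure: a session loses a modality entirely or not at all
  masked <- inject_missingness(co, cfg)
  for (block in list(perf_feats, diff_feats, spec_feats)) {
    nna <- rowSums(is.na(masked$data[, block]))
    expect_true(all(nna %in% c(0L, length(block))))
  }
  # masking a masked cohort is refused
  expect_gbm_error(inject_missingness(masked, cfg), "gbm_missing_error")
})

test_that("most sessions carry at least one missing feature at default rates", {
  fracs <- vapply(1:20, function(s) {
    cfg <- simulation_config(seed = s)
    m <- inject_missingness(generate_cohort(cfg), cfg)
    mean(!stats::complete.cases(m$data[, schema27$names]))
  }, numeric(1))
  expect_gt(mean(fracs), 0.5)
})

test_that("mask-then-impute preserves means at zero-volume-coupled entries", {
  # entries masked on sessions whose CE region is absent are filled with
  # healthy-tissue surrogates (perfusion 1, responsive means); those fills
  # must sit within sampling error of the values they replaced
  cfg <- simulation_config(n_patients = 40, class_separation = 2, seed = 51)
  co <- generate_cohort(cfg)
  masked <- inject_missingness(co, cfg)
  filled <- impute_cohort(masked, fit_imputer(masked))
  for (f in c(perf_feats[1], diff_feats[1], spec_feats[1])) {
    hit <- is.na(masked$data[[f]]) & masked$data$vol_CE == 0
    expect_gt(sum(hit), 5)   # the coupling must produce such entries
    truth <- co$data[[f]][hit]
    se <- stats::sd(truth) / sqrt(length(truth))
    expect_lt(abs(mean(filled$data[[f]][hit]) - mean(truth)), 2 * se)
  }
})
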