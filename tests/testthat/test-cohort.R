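test_that("label propagation aligns offsets on the decision session", {
  co <- toy_cohort(toy_patient("A", "progressive", dsess = 5, n_sessions = 8))
  d <- co$data
  expect_equal(d$offset, -4:3)
  expect_equal(d$label, c(rep("unlabeled", 4), rep("progressive", 4)))

  # decision at the first session: everything labeled
  co2 <- toy_cohort(toy_patient("B", "responsive", dsess = 1, n_sessions = 3))
  expect_true(all(co2$data$label == "responsive"))
  expect_equal(co2$data$offset, 0:2)

  # single-session patient
  co3 <- toy_cohort(toy_patient("C", "progressive", dsess = 1, n_sessions = 1))
  expect_equal(co3$data$offset, 0L)
  expect_equal(co3$data$label, "progressive")

  # idempotence
  expect_identical(propagate_labels(co)$data, co$data)
})

test_that("cohort validation rejects malformed tables", {
  good <- toy_patient("A", "progressive", 1, 2)
  expect_gbm_error(as_cohort(good[, setdiff(names(good), "vol_CE")]),
                   "gbm_column_error")
  bad <- good; bad$resection[1] <- NA
  expect_gbm_error(as_cohort(bad), "gbm_always_present_error")
  dup <- rbind(good, good[1, ])
  expect_gbm_error(as_cohort(dup), "gbm_duplicate_error")
  off_grid <- good; off_grid$decision_session <- 9L
  expect_gbm_error(as_cohort(off_grid), "gbm_decision_error")
  neg <- good; neg$vol_ED[1] <- -2
  expect_gbm_error(as_cohort(neg), "gbm_volume_error")
  twoclass <- good; twoclass$decision_class[2] <- "responsive"
  expect_gbm_error(as_cohort(twoclass), "gbm_class_error")
})

test_that("CSV loading reflects empty cells as missing and validates columns", {
  df <- rbind(toy_patient("A", "progressive", 1, 2),
              toy_patient("B", "responsive", 1, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  df$MD_CE[2] <- NA  # one empty diffusion cell
  readr::write_csv(df, path, na = "")
  co <- load_cohort(path)
  expect_equal(n_sessions(co), 3L)
  expect_true(is.na(co$data$MD_CE[co$data$patient_id == "A"][2]))
  expect_equal(sum(is.na(co$data[, schema27$names])), 1L)

  # blank resection flag: always-present violation
  df2 <- df; df2$MD_CE[2] <- 0.5; df2$resection[1] <- NA
  readr::write_csv(df2, path, na = "")
  expect_gbm_error(load_cohort(path), "gbm_always_present_error")

  # dropped volume column: schema violation
  readr::write_csv(df[, setdiff(names(df), "vol_CE")], path, na = "")
  expect_gbm_error(load_cohort(path), "gbm_column_error")
})

test_that("write/load round-trip preserves features, masks and labels exactly", {
  cfg <- simulation_config(n_patients = 6, seed = 42)
  co <- inject_missingness(generate_cohort(cfg), cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- load_cohort(path)
  expect_identical(back$data, co$data)
  # rerun is byte-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("select_complete keeps fully observed sessions and drops empty patients", {
  df <- rbind(toy_patient("A", "progressive", 1, 2),
              toy_patient("B", "responsive", 1, 1))
  df$NAA_tCho[3] <- NA
  co <- toy_cohort(df)
  kept <- select_complete(co)
  expect_equal(n_sessions(kept), 2L)
  expect_equal(unique(kept$data$patient_id), "A")  # B had only the masked row
  # identity on a complete cohort, idempotence in general
  expect_identical(select_complete(kept)$data, kept$data)
  full <- toy_cohort(toy_patient("C", "responsive", 1, 3))
  expect_identical(select_complete(full)$data, full$data)
})

test_that("modality subsets restrict feature columns as configured", {
  co <- toy_cohort(toy_patient("A", "progressive", 1, 2))
  perf <- modality_subset(co, "perfusion")
  expect_setequal(perf$schema$names, c(perf_feats, "resection", "group"))
  expect_false(any(c("vol_CE", "MD_CE") %in% names(perf$data)))
  bare <- modality_subset(co, "perfusion", keep_clinical = FALSE)
  expect_equal(length(bare$schema$names), 6L)
  spect <- modality_subset(co, "spectroscopy")
  expect_equal(sum(spect$schema$modality == "spectroscopy"), 10L)
  expect_identical(modality_subset(co, "all"), co)
  expect_error(modality_subset(co, "anatomy"))
})

test_that("per-offset patient counts sum to the number of sessions", {
  co <- toy_cohort(toy_patient("A", "progressive", 2, 3),
                   toy_patient("B", "responsive", 2, 2))
  counts <- counts_per_offset(co)
  expect_equal(counts$n[counts$offset == -1], 2L)
  expect_equal(counts$n[counts$offset == 0], 2L)
  expect_equal(counts$n[counts$offset == 1], 1L)
  expect_equal(sum(counts$n), n_sessions(co))

  empty <- co; empty$data <- co$data[0, ]
  expect_equal(nrow(counts_per_offset(empty)), 0L)

  # property: holds for generated cohorts
  for (seed in 1:5) {
    g <- generate_cohort(simulation_config(n_patients = 10, seed = seed))
    expect_equal(sum(counts_per_offset(g)$n), n_sessions(g))
  }
})

test_that("schema serialisation round-trips", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_schema(schema27, path)
  back <- read_schema(path)
  expect_identical(back$names, schema27$names)
  expect_identical(back$modality, schema27$modality)
  expect_identical(back$region, schema27$region)
})
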