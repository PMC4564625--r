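# In-code fixtures: tiny hand-built cohorts with fully controlled values.

schema27 <- gbm_schema()
perf_feats <- modality_features(schema27, "perfusion", keep_clinical = FALSE)
diff_feats <- modality_features(schema27, "diffusion", keep_clinical = FALSE)
spec_feats <- modality_features(schema27, "spectroscopy", keep_clinical = FALSE)

# one complete, physiologically sane feature vector
default_features <- function() {
  v <- stats::setNames(rep(0.5, length(schema27$names)), schema27$names)
  v[c("vol_CE", "vol_ED", "vol_N")] <- c(2, 3, 1)
  v[perf_feats] <- 1
  v["resection"] <- 0
  v["group"] <- 1
  v
}

# n_sessions rows for one patient; feature overrides apply to every session
toy_patient <- function(pid, dclass, dsess, n_sessions,
                        overrides = list()) {
  f <- default_features()
  f[names(overrides)] <- unlist(overrides)
  do.call(rbind, lapply(seq_len(n_sessions), function(s) {
    as.data.frame(c(list(patient_id = pid, session_index = s,
                         decision_class = dclass, decision_session = dsess),
                    as.list(f)))
  }))
}

toy_cohort <- function(...) {
  propagate_labels(as_cohort(do.call(rbind, list(...)), schema27))
}

# small noisy-but-separable synthetic cohort for evaluation tests
separable_cohort <- function(seed = 1, n_patients = 8, delta = 4) {
  cfg <- simulation_config(n_patients = n_patients, class_separation = delta,
                           missingness = c(perfusion = 0, diffusion = 0,
                                           spectroscopy = 0),
                           seed = seed)
  generate_cohort(cfg)
}

expect_gbm_error <- function(expr, class) {
  expect_error(expr, class = class)
}
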