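# Synthetic longitudinal cohort generator.
#
# Emulates the sampling structure of a 29-patient GBM follow-up study: per
# patient a decision class, a timeline of sessions aligned on the clinical
# decision, class-conditional feature distributions (perfusion centred at 1
# for responsive patients, reflecting NAWM normalisation), a volume model in
# which responsive tumour regions shrink to exactly zero after the decision
# while progressive regions grow, and per-modality block missingness at the
# observed study rates (spectroscopy 66%, diffusion 44%, perfusion 30%).

# Default session-count distributions: derived from the per-offset patient
# counts of the emulated study (29 patients, 178 sessions). Element k+1 is
# the probability of k sessions before (resp. after) the decision session.
.DEFAULT_BEFORE_PMF <- c(0, 5, 8, 3, 1, 4, 2, 1, 1, 1, 1, 2) / 29  # 0..11
.DEFAULT_AFTER_PMF  <- c(17, 4, 5, 1, 0, 2) / 29                   # 0..5

# Class-conditional feature distributions: baseline mean (responsive class),
# within-class SD, and the sign with which the progressive mean is shifted
# by class_separation * SD. Perfusion baselines are 1 (NAWM ratio of healthy
# tissue); other baselines are plausible native-unit constants — only the
# direction of separation is meaningful.
.FEATURE_PARAMS <- data.frame(
  feature = c(.PERFUSION_FEATURES, .DIFFUSION_FEATURES, .SPECTRO_FEATURES),
  mean = c(rep(1, 6),
           0.90, 0.70, 1.10, 1.30, 0.25, 0.35,
           1.20, 0.30, 0.25, 1.50, 0.40, 0.80, 0.10, 0.20, 0.50, 0.15),
  sd = c(rep(0.25, 6),
         rep(0.15, 6),
         rep(0.20, 10)),
  sign = c(rep(1, 6),                       # hypervascular tumour: ratios rise
           1, 1, -1, -1, -1, -1,            # MK up, MD and FA down
           -1, -1, 1, -1, 1, 1, 1, -1, 1, 1),  # NAA down, tCho/Lips up
  stringsAsFactors = FALSE
)

#' Configure the synthetic cohort generator
#'
#' Defaults reproduce the structure of the emulated study: 29 patients,
#' session-count distributions whose expected total is 178 sessions, block
#' missingness rates of 0.66 (spectroscopy), 0.30 (perfusion) and 0.44
#' (diffusion), and protocol-group frequencies 16/29, 7/29, 6/29. The class
#' split is not reported by the study; it defaults to one half.
#'
#' @param n_patients number of patients (>= 2).
#' @param fraction_progressive expected fraction of progressive patients.
#' @param sessions_before_decision probability vector over 0..11 pre-decision
#'   session counts.
#' @param sessions_after_decision probability vector over 0..5 post-decision
#'   session counts.
#' @param class_separation delta >= 0: shift of the progressive feature means,
#'   in within-class standard deviations.
#' @param missingness named rates in `[0,1]` for `perfusion`, `diffusion`,
#'   `spectroscopy` block masking.
#' @param zero_volume_missing_coupling probability that a masked modality
#'   block falls on a session whose contrast-enhancing volume is zero
#'   (honoured as far as the cohort contains such sessions; the marginal
#'   masking rate is preserved).
#' @param volume_model list with `p_zero_after` (per-session probability that
#'   a responsive region collapses to exactly 0 after the decision),
#'   `shrink` and `growth` (per-session volume factors for responsive /
#'   progressive patients).
#' @param seed integer RNG seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 29L,
                              fraction_progressive = 0.5,
                              sessions_before_decision = .DEFAULT_BEFORE_PMF,
                              sessions_after_decision = .DEFAULT_AFTER_PMF,
                              class_separation = 1.5,
                              missingness = c(perfusion = 0.30,
                                              diffusion = 0.44,
                                              spectroscopy = 0.66),
                              zero_volume_missing_coupling = 0.25,
                              volume_model = list(p_zero_after = 0.5,
                                                  shrink = 0.6,
                                                  growth = 1.25),
                              seed = 1L) {
  cfg <- structure(list(n_patients = as.integer(n_patients),
                        fraction_progressive = fraction_progressive,
                        sessions_before_decision = sessions_before_decision,
                        sessions_after_decision = sessions_after_decision,
                        class_separation = class_separation,
                        missingness = missingness,
                        zero_volume_missing_coupling = zero_volume_missing_coupling,
                        volume_model = volume_model,
                        seed = as.integer(seed)),
                   class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_patients < 2L)
    gbm_abort("n_patients must be >= 2", "gbm_config_error")
  if (cfg$fraction_progressive < 0 || cfg$fraction_progressive > 1)
    gbm_abort("fraction_progressive must lie in [0, 1]", "gbm_config_error")
  if (cfg$class_separation < 0)
    gbm_abort("class_separation must be >= 0", "gbm_config_error")
  m <- cfg$missingness
  if (!all(c("perfusion", "diffusion", "spectroscopy") %in% names(m)))
    gbm_abort("missingness must name perfusion, diffusion and spectroscopy rates",
              "gbm_config_error")
  if (any(m < 0 | m > 1))
    gbm_abort("missingness rates must lie in [0, 1]", "gbm_config_error")
  c0 <- cfg$zero_volume_missing_coupling
  if (c0 < 0 || c0 > 1)
    gbm_abort("zero_volume_missing_coupling must lie in [0, 1]",
              "gbm_config_error")
  for (p in list(cfg$sessions_before_decision, cfg$sessions_after_decision)) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      gbm_abort("session-count distributions must be probability vectors",
                "gbm_config_error")
  }
  invisible(cfg)
}

#' Write / read a simulation configuration
#' @param config a [simulation_config()].
#' @param path YAML file path.
#' @return `write_simulation_config` returns `path` invisibly;
#'   `read_simulation_config` returns a `simulation_config`.
#' @export
write_simulation_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  x <- unclass(config)
  x$missingness <- as.list(x$missingness)  # keep the rate names in the YAML map
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$missingness <- unlist(x$missingness)
  do.call(simulation_config, x)
}

#' Generate a complete synthetic cohort
#'
#' Draws a schema-conformant, fully observed cohort: each patient gets a
#' decision class, a timeline with the configured pre-/post-decision session
#' counts, class-conditional Gaussian modality features separated by
#' `class_separation` within-class SDs (perfusion centred at 1 for the
#' responsive class), volumes following the configured trajectory model
#' (responsive regions collapse to exactly 0 after the decision with the
#' configured per-session probability), a per-patient resection flag and
#' protocol-group code. Labels are propagated before return. Deterministic
#' given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return A labeled, fully observed `gbm_cohort`.
#' @export
generate_cohort <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  schema <- gbm_schema()
  vm <- config$volume_model
  # deterministic class split (round(n * fraction), shuffled): a drawn split
  # could leave a class empty, which no two-class study design permits
  n_prog <- round(config$n_patients * config$fraction_progressive)
  if (config$fraction_progressive > 0) n_prog <- max(1L, n_prog)
  if (config$fraction_progressive < 1) n_prog <- min(config$n_patients - 1L, n_prog)
  classes <- sample(c(rep("progressive", n_prog),
                      rep("responsive", config$n_patients - n_prog)))
  rows <- vector("list", config$n_patients)
  for (p in seq_len(config$n_patients)) {
    cls <- classes[p]
    n_before <- sample(0:11, 1, prob = config$sessions_before_decision)
    n_after <- sample(0:5, 1, prob = config$sessions_after_decision)
    n_sess <- n_before + 1L + n_after
    offs <- seq_len(n_sess) - (n_before + 1L)

    df <- data.frame(patient_id = sprintf("P%02d", p),
                     session_index = seq_len(n_sess),
                     decision_class = cls,
                     decision_session = n_before + 1L,
                     stringsAsFactors = FALSE)

    # volumes: lognormal baselines; progressive regions grow along the whole
    # timeline, responsive regions shrink and collapse to exactly 0 after the
    # decision (absorbing). The trajectory divergence is part of the class
    # signal, so at class_separation = 0 (identical class distributions by
    # definition) both classes follow the responsive trajectory.
    vol_cls <- if (config$class_separation > 0) cls else "responsive"
    base <- c(vol_CE = stats::rlnorm(1, log(10), 0.6),
              vol_ED = stats::rlnorm(1, log(20), 0.6),
              vol_N = stats::rlnorm(1, log(4), 0.8))
    for (v in names(base)) {
      trend <- if (vol_cls == "progressive") vm$growth else vm$shrink
      vol <- base[[v]] * trend^(offs - min(offs)) * stats::rlnorm(n_sess, 0, 0.1)
      if (vol_cls == "responsive") {
        post <- which(offs > 0)
        if (length(post)) {
          gone <- stats::runif(length(post)) < vm$p_zero_after
          if (any(gone)) {
            first <- post[min(which(gone))]
            vol[first:n_sess] <- 0   # region resolved: stays absent
          }
        }
      }
      df[[v]] <- vol
    }

    # modality features: class-conditional Gaussians, constant separation
    # along the timeline (pre-decision sessions are as informative as the
    # class itself — the quantity the evaluation protocol probes)
    for (i in seq_len(nrow(.FEATURE_PARAMS))) {
      fp <- .FEATURE_PARAMS[i, ]
      mu <- fp$mean +
        (cls == "progressive") * fp$sign * config$class_separation * fp$sd
      df[[fp$feature]] <- pmax(0, stats::rnorm(n_sess, mu, fp$sd))
    }

    df$resection <- as.numeric(stats::runif(1) < 0.5)
    df$group <- sample(0:2, 1, prob = c(16, 7, 6) / 29)
    rows[[p]] <- df[, c(.COHORT_ID_COLS, schema$names)]
  }
  propagate_labels(as_cohort(do.call(rbind, rows), schema))
}

#' Mask modality blocks of a complete cohort
#'
#' Applies per-session, per-modality Bernoulli block masking at the
#' configured rates: when a session loses a modality it loses the whole
#' block (all 6 perfusion, all 6 diffusion or all 10 spectroscopy values),
#' mirroring per-acquisition quality rejection. Always-present features are
#' never masked. The zero-volume coupling tilts masking towards sessions
#' whose contrast-enhancing volume is zero while preserving the marginal
#' rate. Deterministic given `config$seed`.
#'
#' @param cohort a complete `gbm_cohort`.
#' @param config a [simulation_config()].
#' @return The masked `gbm_cohort`.
#' @export
inject_missingness <- function(cohort, config) {
  stopifnot(inherits(cohort, "gbm_cohort"))
  validate_simulation_config(config)
  if (anyNA(cohort$data[, cohort$schema$names]))
    gbm_abort("inject_missingness expects a complete cohort", "gbm_missing_error")
  set.seed(config$seed + 1003L)
  d <- cohort$data
  n <- nrow(d)
  zero_ce <- d$vol_CE == 0
  f_zero <- mean(zero_ce)
  cpl <- config$zero_volume_missing_coupling
  for (m in c("perfusion", "diffusion", "spectroscopy")) {
    rate <- config$missingness[[m]]
    if (rate == 0 || n == 0) next
    # per-session masking probability, tilted so that
    # P(zero CE volume | masked) ~= coupling while the marginal stays `rate`
    p <- rep(rate, n)
    if (f_zero > 0 && f_zero < 1 && cpl > 0) {
      p_zero <- min(1, cpl * rate / f_zero)
      p_pos <- min(1, max(0, (rate - p_zero * f_zero) / (1 - f_zero)))
      p <- ifelse(zero_ce, p_zero, p_pos)
    }
    mask <- stats::runif(n) < p
    cols <- cohort$schema$names[cohort$schema$modality == m]
    d[mask, cols] <- NA_real_
  }
  cohort$data <- d
  cohort
}
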