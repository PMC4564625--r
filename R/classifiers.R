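# Classifier bank: thin adapters over established implementations, plus
# hand-written correlation-distance kNN, pseudoinverse linear discriminant
# scoring, and stump-based AdaBoost / LogitBoost (no installed package
# provides these as specified). Every adapter takes numeric matrices with no
# missing values and a two-level factor response.

.CLASSIFIER_FAMILIES <- c("knn", "dlda", "svm", "classification_tree",
                          "neural_net", "random_forest", "boosting")
# families whose decision rule is scale-sensitive: features are z-scored on
# the training fold before fitting
.SCALED_FAMILIES <- c("knn", "dlda", "svm", "neural_net")

#' Specify a classifier
#'
#' Builds a classifier specification with the bank's default hyperparameters:
#' kNN uses 3 neighbours under the correlation distance; random forests and
#' boosting use 100 trees; the neural net uses 10 hidden units. SVM variants
#' name the kernel (`"lin"`, `"poly"`, `"rbf"`, `"mlp"` — the multilayer
#' perceptron kernel, i.e. the sigmoid kernel); boosting variants are
#' `"adaboost"` (discrete AdaBoost over decision stumps), `"logitboost"`
#' (LogitBoost: Newton boosting of the logistic likelihood over regression
#' stumps) and `"robustboost"` (mapped to subsampled LogitBoost, the nearest
#' available robust variant; the substitution is recorded in evaluation
#' reports).
#'
#' @param family one of `"knn"`, `"dlda"`, `"svm"`, `"classification_tree"`,
#'   `"neural_net"`, `"random_forest"`, `"boosting"`.
#' @param variant kernel / boosting subtype where the family has one.
#' @param ... hyperparameter overrides (`k`, `ntree`, `nrounds`, `size`, ...).
#' @return An object of class `classifier_spec`.
#' @export
#' @examples
#' classifier_spec("random_forest")
#' classifier_spec("svm", "lin")
classifier_spec <- function(family, variant = NULL, ...) {
  family <- match.arg(family, .CLASSIFIER_FAMILIES)
  hp <- list(...)
  defaults <- switch(family,
    knn = list(k = 3L, distance = "correlation"),
    dlda = list(),
    svm = list(),
    classification_tree = list(),
    neural_net = list(size = 10L, maxit = 200L),
    random_forest = list(ntree = 100L),
    boosting = list(nrounds = 100L)
  )
  hp <- utils::modifyList(defaults, hp)
  if (family == "svm") {
    variant <- match.arg(variant, c("lin", "poly", "rbf", "mlp"))
  } else if (family == "boosting") {
    variant <- match.arg(variant, c("adaboost", "logitboost", "robustboost"))
  } else if (!is.null(variant)) {
    gbm_abort(paste0("family '", family, "' takes no variant"),
              "gbm_classifier_error")
  }
  label <- if (is.null(variant)) family else paste(family, variant, sep = "_")
  structure(list(family = family, variant = variant,
                 hyperparameters = hp, label = label,
                 substitution = if (identical(variant, "robustboost"))
                   "robustboost mapped to subsampled LogitBoost"
                 else NULL),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- paste(sprintf("%s=%s", names(x$hyperparameters),
                      vapply(x$hyperparameters, format, "")), collapse = ", ")
  cat(sprintf("<classifier_spec> %s%s\n", x$label,
              if (nzchar(hp)) paste0(" (", hp, ")") else ""))
  invisible(x)
}

#' Default classifier bank
#'
#' The ten supervised classifiers evaluated by default: correlation-distance
#' 3-NN, pseudoinverse linear discriminant scoring, linear and sigmoid-kernel
#' SVMs, a classification tree, a 10-hidden-unit neural net, a 100-tree
#' random forest, and three boosting variants over stumps.
#'
#' @return List of [classifier_spec()] objects.
#' @export
default_classifier_bank <- function() {
  list(
    classifier_spec("knn"),
    classifier_spec("dlda"),
    classifier_spec("svm", "lin"),
    classifier_spec("svm", "mlp"),
    classifier_spec("classification_tree"),
    classifier_spec("neural_net"),
    classifier_spec("random_forest"),
    classifier_spec("boosting", "adaboost"),
    classifier_spec("boosting", "logitboost"),
    classifier_spec("boosting", "robustboost")
  )
}

# ---- internal fitting ------------------------------------------------------

# z-score parameters from the training matrix; zero-variance columns are
# centred but left unscaled
.scale_params <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd)
}
.apply_scale <- function(X, p) sweep(sweep(X, 2, p$mu), 2, p$sd, "/")

# correlation-distance k-nearest-neighbour vote
.knn_correlation <- function(X_train, y, X_test, k) {
  k <- min(k, nrow(X_train))
  pred <- character(nrow(X_test))
  # 1 - Pearson correlation between feature vectors; rows with zero variance
  # get the maximal distance 2
  suppressWarnings(C <- stats::cor(t(X_test), t(X_train)))
  D <- 1 - C
  D[!is.finite(D)] <- 2
  for (j in seq_len(nrow(X_test))) {
    nb <- order(D[j, ], decreasing = FALSE)[seq_len(k)]
    votes <- table(y[nb])
    top <- names(votes)[votes == max(votes)]
    pred[j] <- if (length(top) == 1L) top else y[nb[1]]  # tie: nearest wins
  }
  pred
}

# linear discriminant scores with the Moore-Penrose pseudoinverse of the
# pooled within-class covariance (handles singular covariance from small
# folds without regularisation)
.dlda_predict <- function(X_train, y, X_test) {
  classes <- levels(y)
  n <- nrow(X_train)
  mus <- lapply(classes, function(cl) colMeans(X_train[y == cl, , drop = FALSE]))
  S <- matrix(0, ncol(X_train), ncol(X_train))
  for (i in seq_along(classes)) {
    Xi <- X_train[y == classes[i], , drop = FALSE]
    if (nrow(Xi) > 1) S <- S + stats::cov(Xi) * (nrow(Xi) - 1)
  }
  S <- S / max(1, n - length(classes))
  Sinv <- MASS::ginv(as.matrix(S))
  priors <- as.numeric(table(y)[classes]) / n
  scores <- vapply(seq_along(classes), function(i) {
    a <- Sinv %*% mus[[i]]
    drop(X_test %*% a) - 0.5 * drop(crossprod(mus[[i]], a)) + log(priors[i])
  }, numeric(nrow(X_test)))
  scores <- matrix(scores, nrow = nrow(X_test))
  classes[max.col(scores, ties.method = "first")]
}

# Weighted decision stump: for every feature, scan the split thresholds by
# cumulative weight sums and keep the (feature, threshold, polarity) with the
# lowest weighted error. `orders` holds precomputed per-feature sort orders.
.stump_fit <- function(X, yy, w, orders) {
  n <- length(yy)
  best <- list(err = Inf, j = 1L, thr = -Inf, pol = 1)
  for (j in seq_len(ncol(X))) {
    ord <- orders[[j]]
    x <- X[ord, j]
    wp <- cumsum(w[ord] * (yy[ord] > 0))
    wn <- cumsum(w[ord] * (yy[ord] < 0))
    tp <- wp[n]; tn <- wn[n]
    # split after position i: left = x <= threshold; skip tied positions
    valid <- c(x[-n] < x[-1], FALSE)
    # polarity +1: left -> -1, right -> +1
    err_a <- c(tn, wp + tn - wn)        # i = 0..n
    err_b <- c(tp, wn + tp - wp)        # polarity -1
    ok <- c(TRUE, valid)
    err_a[!ok] <- Inf; err_b[!ok] <- Inf
    ia <- which.min(err_a); ib <- which.min(err_b)
    if (err_a[ia] < best$err) {
      best <- list(err = err_a[ia], j = j,
                   thr = if (ia == 1L) -Inf else (x[ia - 1] + x[ia]) / 2,
                   pol = 1)
    }
    if (err_b[ib] < best$err) {
      best <- list(err = err_b[ib], j = j,
                   thr = if (ib == 1L) -Inf else (x[ib - 1] + x[ib]) / 2,
                   pol = -1)
    }
  }
  best
}

.stump_predict <- function(stump, X) {
  h <- ifelse(X[, stump$j] <= stump$thr, -1, 1)
  h * stump$pol
}

# discrete AdaBoost over decision stumps
.adaboost_predict <- function(X_train, y, X_test, nrounds) {
  yy <- ifelse(y == levels(y)[1], -1, 1)
  n <- length(yy)
  w <- rep(1 / n, n)
  orders <- lapply(seq_len(ncol(X_train)), function(j) order(X_train[, j]))
  score <- rep(0, nrow(X_test))
  for (m in seq_len(nrounds)) {
    stump <- .stump_fit(X_train, yy, w, orders)
    h_train <- .stump_predict(stump, X_train)
    err <- sum(w * (h_train != yy))
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    score <- score + alpha * .stump_predict(stump, X_test)
    w <- w * exp(-alpha * yy * h_train)
    w <- w / sum(w)
    if (err <= 1e-10) break  # perfect weak learner: ensemble is decided
  }
  ifelse(score >= 0, levels(y)[2], levels(y)[1])
}

# Weighted least-squares regression stump for LogitBoost working responses:
# maximises the split gain sum(wz_left)^2/sum(w_left) +
# sum(wz_right)^2/sum(w_right) by cumulative scans over sorted features.
.reg_stump_fit <- function(X, z, w, orders) {
  n <- length(z)
  W <- sum(w); WZ <- sum(w * z)
  best <- list(gain = WZ^2 / W, j = 1L, thr = -Inf,
               left = WZ / W, right = WZ / W)   # constant stump fallback
  for (j in seq_len(ncol(X))) {
    ord <- orders[[j]]
    x <- X[ord, j]
    cw <- cumsum(w[ord])
    cwz <- cumsum((w * z)[ord])
    i <- which(x[-n] < x[-1])         # valid split positions
    if (!length(i)) next
    gain <- cwz[i]^2 / cw[i] + (WZ - cwz[i])^2 / (W - cw[i])
    k <- which.max(gain)
    if (gain[k] > best$gain + 1e-12) {
      s <- i[k]
      best <- list(gain = gain[k], j = j, thr = (x[s] + x[s + 1]) / 2,
                   left = cwz[s] / cw[s], right = (WZ - cwz[s]) / (W - cw[s]))
    }
  }
  best
}

.reg_stump_value <- function(stump, X) {
  ifelse(X[, stump$j] <= stump$thr, stump$left, stump$right)
}

# two-class LogitBoost over regression stumps (Newton steps on the logistic
# log-likelihood with capped working responses); subsample < 1 refits each
# round on a random row subset, giving the subsampled robust variant
.logitboost_predict <- function(X_train, y, X_test, nrounds, subsample = 1) {
  y01 <- as.numeric(y == levels(y)[2])
  n <- length(y01)
  F_tr <- numeric(n)
  F_te <- numeric(nrow(X_test))
  orders_full <- lapply(seq_len(ncol(X_train)), function(j) order(X_train[, j]))
  for (m in seq_len(nrounds)) {
    p <- 1 / (1 + exp(-2 * F_tr))
    w <- pmax(p * (1 - p), 1e-8)
    z <- pmin(pmax((y01 - p) / w, -4), 4)
    if (subsample < 1) {
      idx <- sort(sample.int(n, max(2L, round(subsample * n))))
      Xs <- X_train[idx, , drop = FALSE]
      orders <- lapply(seq_len(ncol(Xs)), function(j) order(Xs[, j]))
      stump <- .reg_stump_fit(Xs, z[idx], w[idx], orders)
    } else {
      stump <- .reg_stump_fit(X_train, z, w, orders_full)
    }
    F_tr <- F_tr + 0.5 * .reg_stump_value(stump, X_train)
    F_te <- F_te + 0.5 * .reg_stump_value(stump, X_test)
  }
  ifelse(F_te >= 0, levels(y)[2], levels(y)[1])
}

# Fit on (X_train, y) and predict classes for X_test. Deterministic given the
# caller's RNG state (stochastic learners consume the R RNG).
classifier_predict <- function(spec, X_train, y, X_test) {
  stopifnot(inherits(spec, "classifier_spec"))
  y <- factor(as.character(y), levels = .CLASS_LEVELS)
  if (nlevels(droplevels(y)) < 2L)
    gbm_abort("training set contains only one class", "gbm_one_class_error")
  if (nrow(X_test) == 0L) return(character(0))
  if (spec$family %in% .SCALED_FAMILIES) {
    p <- .scale_params(X_train)
    X_train <- .apply_scale(X_train, p)
    X_test <- .apply_scale(X_test, p)
  }
  hp <- spec$hyperparameters
  pred <- switch(spec$family,
    knn = .knn_correlation(X_train, as.character(y), X_test, hp$k),
    dlda = .dlda_predict(X_train, y, X_test),
    svm = {
      kernel <- switch(spec$variant, lin = "linear", poly = "polynomial",
                       rbf = "radial", mlp = "sigmoid")
      fit <- e1071::svm(X_train, y, kernel = kernel, scale = FALSE)
      as.character(predict(fit, X_test))
    },
    classification_tree = {
      df <- as.data.frame(X_train); df$.y <- y
      fit <- rpart::rpart(.y ~ ., data = df, method = "class")
      as.character(predict(fit, as.data.frame(X_test), type = "class"))
    },
    neural_net = {
      fit <- nnet::nnet(X_train, stats::model.matrix(~ y - 1)[, 2],
                        size = hp$size, maxit = hp$maxit,
                        entropy = TRUE, trace = FALSE)
      ifelse(drop(predict(fit, X_test)) >= 0.5, levels(y)[2], levels(y)[1])
    },
    random_forest = {
      fit <- randomForest::randomForest(X_train, y, ntree = hp$ntree)
      as.character(predict(fit, X_test))
    },
    boosting = switch(spec$variant,
      adaboost = .adaboost_predict(X_train, y, X_test, hp$nrounds),
      logitboost = .logitboost_predict(X_train, y, X_test, hp$nrounds),
      robustboost = .logitboost_predict(X_train, y, X_test, hp$nrounds,
                                        subsample = 0.7))
  )
  pred
}
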