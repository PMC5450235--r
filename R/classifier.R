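TA_MODEL_VERSION <- "1.0"

# Canonical class order used for argmax tie-breaking and output columns.
ta_classes <- function() c("PO", "MITO", "ER")

# Rolling hash of a feature table, used to notice
# evaluation on a different dataset than the model was trained on.
ta_fingerprint <- function(tail_charge, tmd_gravy, label) {
  s <- paste(sprintf("%.6f", tail_charge), sprintf("%.6f", tmd_gravy),
             label, collapse = "|")
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  h
}

ta_prepare_training <- function(data, include_shared = FALSE) {
  data <- as_tibble(data)
  if (!all(c("tail_charge", "tmd_gravy") %in% names(data))) {
    abort("training data needs 'tail_charge' and 'tmd_gravy' columns")
  }
  lab_col <- intersect(c("label", "location"), names(data))[1]
  if (is.na(lab_col)) abort("training data needs a 'label' or 'location' column")
  if (!"id" %in% names(data)) data$id <- sprintf("ex%03d", seq_len(nrow(data)))
  raw <- as.character(data[[lab_col]])
  if (include_shared) {
    parts <- strsplit(raw, "_", fixed = TRUE)
    data <- data[rep(seq_len(nrow(data)), lengths(parts)), ]
    raw <- unlist(parts)
  }
  keep <- raw %in% ta_classes()
  out <- data[keep, c("id", "tail_charge", "tmd_gravy")]
  out$label <- raw[keep]
  if (any(!is.finite(out$tail_charge)) || any(!is.finite(out$tmd_gravy))) {
    abort("non-finite feature values in training data")
  }
  out
}

#' Train the 3-class probabilistic SVM for TA-protein targeting
#'
#' Fits one-vs-one radial-basis-function support vector machines on
#' (tail charge, TMD GRAVY) with Platt-sigmoid probability calibration and
#' pairwise coupling, via the LIBSVM implementation in \pkg{e1071}. The
#' defaults are that implementation's defaults for two features:
#' `cost = 1`, `gamma = 1/2`, standardised features. Dual-location entries
#' (e.g. `PO_MITO`) are excluded from training by default, leaving the
#' three unique classes PO, MITO, ER; set `include_shared = TRUE` to
#' duplicate shared entries into their component classes instead.
#' Probability calibration involves internal cross-validation, so the fit
#' is seeded and deterministic: identical calls give identical models.
#'
#' @param data Data frame with columns `tail_charge`, `tmd_gravy` and
#'   `label` (or `location`); an `id` column is kept if present.
#' @param cost SVM cost parameter C.
#' @param gamma RBF kernel width.
#' @param standardize Standardise the two features to zero mean / unit
#'   variance (fitted on the training set)?
#' @param seed Integer seed for the probability-calibration shuffling.
#' @param include_shared Duplicate shared-location entries into their
#'   component classes?
#' @return Object of class `ta_svm` holding the standardisation
#'   parameters, support vectors, dual coefficients, sigmoid calibration
#'   constants, class order, training fingerprint and seed. Supports
#'   `predict()`, [generics::tidy()], [generics::glance()],
#'   [ggplot2::autoplot()], [save_model()].
#' @export
ta_train <- function(data, cost = 1, gamma = 0.5, standardize = TRUE,
                     seed = 0, include_shared = FALSE) {
  train <- ta_prepare_training(data, include_shared = include_shared)
  counts <- table(train$label)
  if (length(counts) < 2) {
    abort("training data must contain at least 2 classes")
  }
  if (any(counts < 2)) {
    abort(paste0("class '", names(counts)[counts < 2][1],
                 "' has fewer than 2 examples"))
  }
  X <- as.matrix(train[, c("tail_charge", "tmd_gravy")])
  if (standardize) {
    center <- colMeans(X)
    scl <- apply(X, 2, sd)
    if (any(scl == 0)) abort("zero-variance feature in training data")
  } else {
    center <- c(tail_charge = 0, tmd_gravy = 0)
    scl <- c(tail_charge = 1, tmd_gravy = 1)
  }
  Xs <- sweep(sweep(X, 2, center), 2, scl, "/")
  y <- factor(train$label, levels = intersect(ta_classes(), names(counts)))
  fit <- with_seed(seed, e1071::svm(Xs, y, kernel = "radial", cost = cost,
                                    gamma = gamma, probability = TRUE,
                                    scale = FALSE))
  structure(
    list(
      version = TA_MODEL_VERSION,
      feature_names = c("tail_charge", "tmd_gravy"),
      classes = fit$levels[fit$labels],  # LIBSVM internal class order
      center = center, scale = scl,
      cost = cost, gamma = gamma, seed = seed,
      nSV = fit$nSV, SV = unname(fit$SV), coefs = unname(fit$coefs),
      rho = fit$rho, probA = fit$probA, probB = fit$probB,
      coupling = "platt-sigmoid/pairwise-coupling",
      n_train = nrow(train),
      fingerprint = ta_fingerprint(train$tail_charge, train$tmd_gravy,
                                   train$label),
      training = train
    ),
    class = "ta_svm"
  )
}

# RBF decision values for one standardized point, one value per class
# pair (i, j), i < j in the model's internal class order; positive favours
# class i.
ta_decision_values <- function(model, xs) {
  k <- length(model$classes)
  nSV <- model$nSV
  start <- cumsum(c(1, nSV))
  Kv <- exp(-model$gamma * colSums((t(model$SV) - xs)^2))
  dec <- numeric(k * (k - 1) / 2)
  pidx <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      pidx <- pidx + 1
      si <- start[i]:(start[i] + nSV[i] - 1)
      sj <- start[j]:(start[j] + nSV[j] - 1)
      dec[pidx] <- sum(model$coefs[si, j - 1] * Kv[si]) +
        sum(model$coefs[sj, i] * Kv[sj]) - model$rho[pidx]
    }
  }
  dec
}

# Numerically stable Platt sigmoid.
ta_sigmoid <- function(dec, A, B) {
  f <- dec * A + B
  if (f >= 0) exp(-f) / (1 + exp(-f)) else 1 / (1 + exp(f))
}

# Pairwise coupling of binary class probabilities (the iterative
# second-approach algorithm of Wu, Lin & Weng used by LIBSVM); returns the
# multiclass probability vector, which sums to 1 by construction.
ta_couple <- function(rmat) {
  k <- nrow(rmat)
  Q <- matrix(0, k, k)
  for (t in seq_len(k)) {
    Q[t, t] <- sum(rmat[-t, t]^2)
    for (j in seq_len(k)) if (j != t) Q[t, j] <- -rmat[j, t] * rmat[t, j]
  }
  p <- rep(1 / k, k)
  eps <- 0.005 / k
  for (it in seq_len(max(100, k))) {
    Qp <- as.numeric(Q %*% p)
    pQp <- sum(p * Qp)
    if (max(abs(Qp - pQp)) < eps) break
    for (t in seq_len(k)) {
      diff <- (-Qp[t] + pQp) / Q[t, t]
      p[t] <- p[t] + diff
      pQp <- (pQp + diff * (diff * Q[t, t] + 2 * Qp[t])) / (1 + diff)^2
      Qp <- (Qp + diff * Q[t, ]) / (1 + diff)
      p <- p / (1 + diff)
    }
  }
  p
}

# Probability matrix (rows = observations, columns = model$classes).
ta_predict_matrix <- function(model, X) {
  k <- length(model$classes)
  Xs <- sweep(sweep(as.matrix(X), 2, model$center), 2, model$scale, "/")
  out <- matrix(NA_real_, nrow(Xs), k, dimnames = list(NULL, model$classes))
  for (r in seq_len(nrow(Xs))) {
    dec <- ta_decision_values(model, Xs[r, ])
    rmat <- matrix(0, k, k)
    pidx <- 0
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        pidx <- pidx + 1
        rij <- ta_sigmoid(dec[pidx], model$probA[pidx], model$probB[pidx])
        rij <- min(max(rij, 1e-7), 1 - 1e-7)
        rmat[i, j] <- rij
        rmat[j, i] <- 1 - rij
      }
    }
    out[r, ] <- ta_couple(rmat)
  }
  out
}

#' Predict organelle-targeting probabilities
#'
#' Applies the trained model's standardisation internally and returns one
#' calibrated probability per class, the highest-probability class
#' (`predicted`; exact ties broken by the fixed order PO > MITO > ER) and
#' a low-margin note when the top two probabilities differ by less than
#' 0.1.
#'
#' @param object A [ta_train()] model.
#' @param newdata Data frame with `tail_charge` and `tmd_gravy` columns
#'   (an `id` column is carried through).
#' @param ... Unused.
#' @return Tibble with `id` (if present), the two features, `p_PO`,
#'   `p_MITO`, `p_ER`, `predicted`, `margin` and `note` (`"low_margin"`
#'   or `NA`).
#' @export
predict.ta_svm <- function(object, newdata, ...) {
  newdata <- as_tibble(newdata)
  if (!all(c("tail_charge", "tmd_gravy") %in% names(newdata))) {
    abort("newdata needs 'tail_charge' and 'tmd_gravy' columns")
  }
  X <- as.matrix(newdata[, c("tail_charge", "tmd_gravy")])
  if (any(!is.finite(X))) abort("non-finite feature values in newdata")
  prob <- ta_predict_matrix(object, X)
  classes <- intersect(ta_classes(), object$classes)
  prob <- prob[, classes, drop = FALSE]  # canonical column order
  pred <- classes[apply(prob, 1, which.max)]
  sorted <- t(apply(prob, 1, sort, decreasing = TRUE))
  margin <- if (ncol(prob) >= 2) sorted[, 1] - sorted[, 2] else rep(1, nrow(prob))
  out <- tibble(
    tail_charge = newdata$tail_charge,
    tmd_gravy = newdata$tmd_gravy
  )
  if ("id" %in% names(newdata)) out <- dplyr::bind_cols(
    tibble(id = newdata$id), out)
  for (cl in ta_classes()) {
    out[[paste0("p_", cl)]] <- if (cl %in% classes) unname(prob[, cl]) else 0
  }
  out$predicted <- pred
  out$margin <- unname(margin)
  out$note <- ifelse(margin < 0.1, "low_margin", NA_character_)
  out
}

#' Count in-sample misclassifications
#'
#' Number of labelled examples whose highest-probability class differs
#' from their label. Warns when the examples are not the table the model
#' was trained on (fingerprint mismatch).
#'
#' @param model A [ta_train()] model.
#' @param data Labelled feature table (same shape as for [ta_train()]).
#' @param include_shared Passed to the label preparation, see
#'   [ta_train()].
#' @return Integer count, with the per-example report attached as
#'   attribute `"details"` (a tibble with probabilities, `predicted` and
#'   `correct`).
#' @export
in_sample_misclassifications <- function(model, data,
                                         include_shared = FALSE) {
  ex <- ta_prepare_training(data, include_shared = include_shared)
  fp <- ta_fingerprint(ex$tail_charge, ex$tmd_gravy, ex$label)
  if (!identical(fp, model$fingerprint)) {
    warn("evaluating on a different dataset than the model was trained on")
  }
  pr <- predict(model, ex)
  pr$label <- ex$label
  pr$correct <- pr$predicted == pr$label
  structure(sum(!pr$correct), details = pr)
}

#' Leave-one-out cross-validated misclassification count
#'
#' For each labelled example, trains on the remaining n - 1 examples
#' (standardisation refitted per fold) and classifies the held-out point
#' by highest probability. If holding a point out leaves its class with
#' fewer than 2 members, that class is dropped from the fold's training
#' set; a held-out point whose label is absent from its fold is counted
#' misclassified and the condition is reported via a message.
#'
#' @param data Labelled feature table (same shape as for [ta_train()]).
#' @param cost,gamma,standardize,seed,include_shared As in [ta_train()];
#'   the same seed is used for every fold.
#' @return Integer count of misclassified examples, with a per-example
#'   tibble attached as attribute `"details"`.
#' @export
loocv_misclassifications <- function(data, cost = 1, gamma = 0.5,
                                     standardize = TRUE, seed = 0,
                                     include_shared = FALSE) {
  ex <- ta_prepare_training(data, include_shared = include_shared)
  n <- nrow(ex)
  if (n < 3) abort("need at least 3 examples for leave-one-out")
  pred <- character(n)
  dropped <- 0L
  for (i in seq_len(n)) {
    fold <- ex[-i, ]
    counts <- table(fold$label)
    ok_classes <- names(counts)[counts >= 2]
    if (length(ok_classes) < 2) {
      abort("a leave-one-out fold has fewer than 2 trainable classes")
    }
    fold <- fold[fold$label %in% ok_classes, ]
    if (!ex$label[i] %in% ok_classes) {
      pred[i] <- NA_character_
      dropped <- dropped + 1L
      next
    }
    m <- ta_train(fold, cost = cost, gamma = gamma,
                  standardize = standardize, seed = seed)
    pred[i] <- predict(m, ex[i, ])$predicted
  }
  if (dropped > 0) {
    inform(paste0(dropped, " held-out point(s) had no trainable class in ",
                  "their fold and were counted misclassified"))
  }
  correct <- !is.na(pred) & pred == ex$label
  details <- tibble(id = ex$id, label = ex$label, predicted = pred,
                    correct = correct)
  structure(sum(!correct), details = details)
}

#' Class-probability grid for contour plots
#'
#' Evaluates the model on a rectangular lattice of (tail charge, TMD
#' GRAVY) values, as used for probability-contour classifier plots.
#'
#' @param model A [ta_train()] model.
#' @param charge_range,gravy_range Length-2 numeric ranges.
#' @param step Lattice step (same units on both axes), > 0.
#' @return Tibble with `tail_charge`, `tmd_gravy`, `p_PO`, `p_MITO`,
#'   `p_ER`, `predicted`.
#' @export
probability_grid <- function(model, charge_range = c(-2, 10),
                             gravy_range = c(0, 4), step = 0.25) {
  if (!is.numeric(step) || step <= 0) abort("step must be > 0")
  if (length(charge_range) != 2 || length(gravy_range) != 2 ||
      diff(charge_range) < 0 || diff(gravy_range) < 0) {
    abort("ranges must be length-2 increasing numeric vectors")
  }
  grid <- tidyr::expand_grid(
    tail_charge = seq(charge_range[1], charge_range[2], by = step),
    tmd_gravy = seq(gravy_range[1], gravy_range[2], by = step)
  )
  pr <- predict(model, grid)
  pr[, c("tail_charge", "tmd_gravy", "p_PO", "p_MITO", "p_ER", "predicted")]
}

#' Save / load a trained model as versioned JSON
#'
#' The JSON file stores everything needed to reproduce predictions:
#' standardisation parameters, support vectors, dual coefficients, sigmoid
#' calibration constants, class order, training fingerprint, seed and the
#' training features. Loading a file with a different format version, or
#' one missing required fields, is an error. Reloaded models reproduce
#' predictions to better than 1e-12.
#'
#' @param model A [ta_train()] model.
#' @param path File path.
#' @return `save_model()` returns `path` invisibly; `load_model()`
#'   returns the `ta_svm` object.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "ta_svm")) abort("not a ta_svm model")
  payload <- unclass(model)
  payload$SV <- as.data.frame(payload$SV)
  payload$coefs <- as.data.frame(payload$coefs)
  # I(17) = 17 significant digits, enough for a lossless double round-trip
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) abort(paste0("model file not found: ", path))
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) abort(paste0("corrupt model file: ",
                                                       conditionMessage(e))))
  required <- c("version", "classes", "center", "scale", "gamma", "cost",
                "nSV", "SV", "coefs", "rho", "probA", "probB", "fingerprint")
  if (!is.list(payload) || !all(required %in% names(payload))) {
    abort("corrupt model file: missing required fields")
  }
  if (!identical(payload$version, TA_MODEL_VERSION)) {
    abort(paste0("model file version '", payload$version,
                 "' does not match supported version '",
                 TA_MODEL_VERSION, "'"))
  }
  payload$SV <- as.matrix(payload$SV)
  dimnames(payload$SV) <- NULL
  payload$coefs <- as.matrix(payload$coefs)
  dimnames(payload$coefs) <- NULL
  payload$center <- unlist(payload$center)
  payload$scale <- unlist(payload$scale)
  payload$training <- as_tibble(payload$training)
  structure(payload, class = "ta_svm")
}

#' @export
print.ta_svm <- function(x, ...) {
  cat("TA-protein targeting SVM (RBF, probability-calibrated)\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  n =", x$n_train, " cost =", x$cost, " gamma =", x$gamma,
      " seed =", x$seed, "\n")
  cat("  support vectors:", sum(x$nSV), "\n")
  invisible(x)
}

#' Broom-style tidiers for `ta_svm` models
#'
#' `tidy()` returns one row per support vector (class, dual coefficients
#' and the features on the original scale); `glance()` returns a one-row
#' model summary including the in-sample misclassification count on the
#' stored training set.
#'
#' @param x A `ta_svm` model.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ta_svm <- function(x, ...) {
  sv_class <- rep(x$classes, x$nSV)
  orig <- sweep(sweep(x$SV, 2, x$scale, "*"), 2, -x$center)
  out <- tibble(
    class = sv_class,
    tail_charge = orig[, 1],
    tmd_gravy = orig[, 2]
  )
  for (k in seq_len(ncol(x$coefs))) out[[paste0("coef", k)]] <- x$coefs[, k]
  out
}

#' @rdname tidy.ta_svm
#' @export
glance.ta_svm <- function(x, ...) {
  err <- suppressWarnings(in_sample_misclassifications(x, x$training))
  tibble(
    n = x$n_train,
    n_classes = length(x$classes),
    n_sv = sum(x$nSV),
    cost = x$cost,
    gamma = x$gamma,
    in_sample_errors = as.integer(err),
    error_rate = as.integer(err) / x$n_train
  )
}
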