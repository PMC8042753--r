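## The DFD model: a binomial GLM on KA/KS and Re/KS whose fitted probability
## is the degree of functional divergence (DFD) of a duplicate pair, with
## decision thresholds calibrated at a fixed false-positive rate.

#' Construct a DFD model from coefficients
#'
#' Builds a model object directly, e.g. from previously published or stored
#' coefficients. `coef` is `c(intercept, one per variable)`.
#'
#' @param coef numeric vector of length `length(variables) + 1`.
#' @param variables feature names, default `c("ka_ks", "re_ks")`.
#' @param thr_low,thr_high calibrated decision thresholds (optional).
#' @return an object of class `dfd_model`.
#' @export
dfd_model <- function(coef, variables = c("ka_ks", "re_ks"),
                      thr_low = NA_real_, thr_high = NA_real_) {
  stopifnot(length(coef) == length(variables) + 1L)
  structure(
    list(
      coef = stats::setNames(as.numeric(coef), c("(Intercept)", variables)),
      variables = variables,
      thr_low = thr_low, thr_high = thr_high,
      n = NA_integer_, converged = NA, loglik = NA_real_,
      ridge = FALSE, non_separating = FALSE
    ),
    class = "dfd_model"
  )
}

#' Fit the DFD logistic model
#'
#' Maximum-likelihood binomial GLM (logit link) of the high/low class on the
#' feature columns. The positive class is `"high"`, so the fitted probability
#' is DFD = P(high diversification): DFD near 1 means strongly diverged
#' functions, near 0 largely redundant ones. On (quasi-)separation the fit
#' falls back to a lightly ridge-penalised IRLS (`lambda`), flagged in the
#' returned object.
#'
#' @param features data.frame containing `variables` and a label column.
#' @param variables feature columns to use.
#' @param label_col column with values `"high"` / `"low"`.
#' @param ridge_lambda penalty used only by the separation fallback.
#' @return a `dfd_model` (thresholds uncalibrated; see
#'   [calibrate_thresholds()]).
#' @export
fit_dfd <- function(features, variables = c("ka_ks", "re_ks"),
                    label_col = "label", ridge_lambda = 1e-6) {
  y <- features[[label_col]]
  if (!all(y %in% c("high", "low"))) {
    stop("labels must be 'high' or 'low' for model fitting")
  }
  if (length(unique(y)) < 2L || min(table(y)) < 2L) {
    stop("need at least 2 pairs of each class to fit the model")
  }
  X <- as.matrix(features[, variables, drop = FALSE])
  if (!all(is.finite(X))) stop("non-finite feature values")
  yy <- as.integer(y == "high")
  dat <- data.frame(.y = yy, X)
  fml <- stats::as.formula(paste(".y ~", paste(variables, collapse = " + ")))

  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separated || !fit$converged) {
    beta <- ridge_logistic(cbind(1, X), yy, lambda = ridge_lambda)
    model <- dfd_model(beta, variables)
    model$ridge <- TRUE
    model$converged <- TRUE
    eta <- cbind(1, X) %*% beta
    model$loglik <- sum(yy * eta - log1p(exp(eta)))
  } else {
    model <- dfd_model(stats::coef(fit), variables)
    model$converged <- fit$converged
    model$loglik <- as.numeric(stats::logLik(fit))
    model$vcov <- stats::vcov(fit)
    model$se <- sqrt(diag(model$vcov))
  }
  model$n <- nrow(features)
  model
}

## Ridge-penalised IRLS for logistic regression (intercept unpenalised);
## used only as the separation fallback of fit_dfd.
ridge_logistic <- function(X, y, lambda = 1e-6, max_iter = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  pen <- diag(lambda, ncol(X))
  pen[1, 1] <- 0
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    new_beta <- solve(crossprod(X, w * X) + pen, crossprod(X, w * z))
    if (max(abs(new_beta - beta)) < tol) {
      beta <- drop(new_beta)
      break
    }
    beta <- drop(new_beta)
  }
  beta
}

#' DFD score of duplicate pairs
#'
#' `logistic(beta0 + beta_kaks * ka_ks + beta_reks * re_ks)` — the modelled
#' probability that a pair is highly diversified.
#'
#' @param model a `dfd_model`.
#' @param ka_ks either a numeric vector, or a data.frame containing the
#'   model's feature columns (in which case `re_ks` is ignored).
#' @param re_ks numeric vector (when `ka_ks` is numeric).
#' @return numeric vector of scores in (0, 1).
#' @export
dfd_score <- function(model, ka_ks, re_ks = NULL) {
  if (is.data.frame(ka_ks)) {
    X <- as.matrix(ka_ks[, model$variables, drop = FALSE])
  } else {
    X <- cbind(ka_ks, re_ks)
    if (ncol(X) != length(model$variables)) {
      stop("supply one numeric vector per model variable or a data.frame")
    }
  }
  stats::plogis(drop(model$coef[1] + X %*% model$coef[-1]))
}

#' Calibrate high/low decision thresholds at a fixed false-positive rate
#'
#' `thr_low` is the `fpr` quantile of the DFD scores of the truly high
#' training pairs (calling "low" below it mislabels at most `fpr` of the
#' highs); `thr_high` is the `1 - fpr` quantile of the scores of the truly
#' low pairs. Quantiles use linear interpolation. If the classes overlap so
#' badly that `thr_low > thr_high`, both are still returned and the model is
#' flagged `non_separating`.
#'
#' @param model fitted `dfd_model`.
#' @param features training features with labels.
#' @param label_col label column name.
#' @param fpr nominal false-positive rate (default 0.05).
#' @return the model with `thr_low`, `thr_high` (and possibly
#'   `non_separating`) set.
#' @export
calibrate_thresholds <- function(model, features, label_col = "label", fpr = 0.05) {
  y <- features[[label_col]]
  if (!all(c("high", "low") %in% y)) stop("both classes required for calibration")
  dfd <- dfd_score(model, features)
  model$thr_low <- stats::quantile(dfd[y == "high"], fpr, type = 7, names = FALSE)
  model$thr_high <- stats::quantile(dfd[y == "low"], 1 - fpr, type = 7, names = FALSE)
  model$fpr <- fpr
  if (model$thr_low > model$thr_high) {
    model$non_separating <- TRUE
    warning("calibrated thresholds do not separate: thr_low > thr_high",
            call. = FALSE)
  }
  model
}

#' Three-way classification of duplicate pairs
#'
#' A pair is called `"high"` when its DFD exceeds `thr_high`, `"low"` when it
#' falls below `thr_low`, and `"unclassified"` otherwise (scores exactly at a
#' threshold are unclassified).
#'
#' @param model calibrated `dfd_model`.
#' @param features data.frame with the model's feature columns and,
#'   optionally, a `pair` id column.
#' @return data.frame `pair`, `dfd`, `call`, with a `counts` attribute
#'   (named vector over high/low/unclassified).
#' @export
classify_pairs <- function(model, features) {
  if (is.na(model$thr_low) || is.na(model$thr_high)) {
    stop("model thresholds are not calibrated")
  }
  dfd <- dfd_score(model, features)
  call <- rep("unclassified", length(dfd))
  call[dfd > model$thr_high] <- "high"
  call[dfd < model$thr_low] <- "low"
  out <- data.frame(
    pair = if ("pair" %in% names(features)) features$pair else seq_along(dfd),
    dfd = dfd, call = call, stringsAsFactors = FALSE
  )
  attr(out, "counts") <- c(
    high = sum(call == "high"), low = sum(call == "low"),
    unclassified = sum(call == "unclassified")
  )
  out
}

#' Area under the ROC curve
#'
#' Computed through the Mann-Whitney U identity with midrank tie correction:
#' the probability that a random positive scores above a random negative
#' (ties counting one half).
#'
#' @param scores numeric scores, higher meaning more positive.
#' @param labels vector; `positive` marks the positive class.
#' @param positive positive-class value (default `"high"`).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive = "high") {
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise interpolation over descending score thresholds: the curve takes
#' one step per distinct score, and the area accumulates precision times the
#' recall increment.
#'
#' @inheritParams roc_auc
#' @return AUC in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels, positive = "high") {
  pos <- labels == positive
  n1 <- sum(pos)
  if (n1 == 0L || all(pos)) stop("both classes required for AUC")
  ord <- order(scores, decreasing = TRUE)
  pos <- pos[ord]
  s <- scores[ord]
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  ## evaluate only at the last index of each tied score block
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[keep]
  fp <- fp[keep]
  precision <- tp / (tp + fp)
  recall <- tp / n1
  sum(diff(c(0, recall)) * precision)
}

#' Cross-validated threshold stability and held-out error
#'
#' Repeats `n_rounds` stratified random train/test splits; each round fits the
#' model and calibrates thresholds on the training part, then measures on the
#' held-out part the false-positive rate of each call (fraction of true highs
#' called low, fraction of true lows called high) and the AUCs.
#'
#' @param features labelled feature table.
#' @param n_rounds number of random splits (default 100).
#' @param train_frac fraction of each class used for training.
#' @param fpr nominal false-positive rate for calibration.
#' @param label_col label column name.
#' @param variables feature columns.
#' @param seed RNG seed.
#' @return list with `rounds` (one row per split: thresholds, held-out FPRs,
#'   AUCs) and `summary` (column means).
#' @export
cross_validate <- function(features, n_rounds = 100, train_frac = 0.8,
                           fpr = 0.05, label_col = "label",
                           variables = c("ka_ks", "re_ks"), seed = 1L) {
  if (n_rounds == 0L) {
    return(list(rounds = data.frame(), summary = numeric(0)))
  }
  set.seed(seed)
  y <- features[[label_col]]
  idx_high <- which(y == "high")
  idx_low <- which(y == "low")
  rounds <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    tr <- c(
      sample(idx_high, floor(train_frac * length(idx_high))),
      sample(idx_low, floor(train_frac * length(idx_low)))
    )
    train <- features[tr, , drop = FALSE]
    test <- features[-tr, , drop = FALSE]
    model <- fit_dfd(train, variables = variables, label_col = label_col)
    model <- suppressWarnings(
      calibrate_thresholds(model, train, label_col = label_col, fpr = fpr)
    )
    dfd <- dfd_score(model, test)
    yt <- test[[label_col]]
    rounds[[r]] <- data.frame(
      round = r,
      thr_low = model$thr_low, thr_high = model$thr_high,
      fpr_low_call = mean(dfd[yt == "high"] < model$thr_low),
      fpr_high_call = mean(dfd[yt == "low"] > model$thr_high),
      roc_auc = roc_auc(dfd, yt), pr_auc = pr_auc(dfd, yt)
    )
  }
  rounds <- do.call(rbind, rounds)
  list(rounds = rounds, summary = colMeans(rounds[, -1, drop = FALSE]))
}

#' Relative importance of model variables
#'
#' Importance of a variable is the increase in residual deviance when it is
#' dropped from the full logistic model (a deviance-decomposition proxy).
#' Ties are broken deterministically by variable name.
#'
#' @param features labelled feature table.
#' @param variables variables to rank.
#' @param label_col label column name.
#' @return data.frame `variable`, `importance`, sorted decreasing.
#' @export
relative_importance <- function(features, variables, label_col = "label") {
  if (length(variables) < 2L) stop("need at least 2 variables to rank")
  full <- fit_dfd(features, variables = variables, label_col = label_col)
  dev_full <- -2 * full$loglik
  imp <- vapply(variables, function(v) {
    red <- fit_dfd(features, variables = setdiff(variables, v),
                   label_col = label_col)
    (-2 * red$loglik) - dev_full
  }, numeric(1))
  out <- data.frame(variable = variables, importance = unname(imp),
                    stringsAsFactors = FALSE)
  out[order(-out$importance, out$variable), , drop = FALSE]
}

#' Single-variable model comparison
#'
#' Fits one univariate logistic model per variable and reports its ROC and PR
#' AUCs, mirroring the comparison of candidate explanatory variables.
#'
#' @inheritParams relative_importance
#' @return data.frame `variable`, `roc_auc`, `pr_auc`.
#' @export
single_variable_models <- function(features, variables, label_col = "label") {
  y <- features[[label_col]]
  res <- lapply(variables, function(v) {
    m <- fit_dfd(features, variables = v, label_col = label_col)
    s <- dfd_score(m, features[, v, drop = FALSE])
    data.frame(variable = v, roc_auc = roc_auc(s, y), pr_auc = pr_auc(s, y),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' @export
print.dfd_model <- function(x, ...) {
  cat("DFD logistic model\n")
  cat("  logit(DFD) =", format(x$coef[1], digits = 5))
  for (v in x$variables) {
    b <- x$coef[v]
    cat(sprintf(" %s %s*%s", ifelse(b >= 0, "+", "-"),
                format(abs(b), digits = 5), v))
  }
  cat("\n")
  if (!is.na(x$thr_low)) {
    cat(sprintf("  thresholds: low < %.4f, high > %.4f (FPR %.2f)\n",
                x$thr_low, x$thr_high, if (is.null(x$fpr)) NA else x$fpr))
  }
  if (isTRUE(x$ridge)) cat("  (ridge fallback used: data were separated)\n")
  invisible(x)
}

#' Write / read a DFD model as plain-text key-value pairs
#'
#' @param model a `dfd_model`.
#' @param path file path.
#' @return `read_dfd_model` returns a `dfd_model`.
#' @export
write_dfd_model <- function(model, path) {
  lines <- c(
    paste0("beta0=", format(model$coef[1], digits = 17)),
    vapply(model$variables, function(v) {
      paste0("beta_", v, "=", format(model$coef[v], digits = 17))
    }, character(1)),
    paste0("variables=", paste(model$variables, collapse = ",")),
    paste0("thr_low=", format(model$thr_low, digits = 17)),
    paste0("thr_high=", format(model$thr_high, digits = 17)),
    paste0("n=", model$n),
    "method=logistic"
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_dfd_model
#' @export
read_dfd_model <- function(path) {
  kv <- read_key_values(path)
  variables <- strsplit(kv[["variables"]], ",")[[1]]
  coef <- c(as.numeric(kv[["beta0"]]),
            vapply(variables, function(v) as.numeric(kv[[paste0("beta_", v)]]),
                   numeric(1)))
  m <- dfd_model(coef, variables,
                 thr_low = as.numeric(kv[["thr_low"]]),
                 thr_high = as.numeric(kv[["thr_high"]]))
  m$n <- as.integer(kv[["n"]])
  m
}
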