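# Stepwise parameter selection and leave-one-out cross-validated combined
# classification. Selection follows the classic recipe: bidirectional
# add/remove moves on an initial all-main-effects *linear* fit, scored by
# AIC; the selected terms are then refit by maximum-likelihood logistic
# regression. Inputs are z-scored for selection and fitting; coefficients
# are reported on the original scale.

lm_aic <- function(X, y) {
  fit <- stats::.lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  n * log(rss / n) + 2 * ncol(X)
}

# Bidirectional AIC stepwise on a linear model; matches
# step(lm(...), direction = "both") move for move.
stepwise_select <- function(Xz, y) {
  p <- ncol(Xz)
  n <- nrow(Xz)
  ones <- rep(1, n)
  aic_for <- function(set) {
    lm_aic(cbind(ones, Xz[, set, drop = FALSE]), y)
  }
  current <- seq_len(p)
  cur_aic <- aic_for(current)
  repeat {
    best_aic <- cur_aic
    best_set <- NULL
    for (j in current) {
      a <- aic_for(setdiff(current, j))
      if (a < best_aic - 1e-10) { best_aic <- a; best_set <- setdiff(current, j) }
    }
    for (j in setdiff(seq_len(p), current)) {
      a <- aic_for(sort(c(current, j)))
      if (a < best_aic - 1e-10) { best_aic <- a; best_set <- sort(c(current, j)) }
    }
    if (is.null(best_set)) break
    current <- best_set
    cur_aic <- best_aic
  }
  colnames(Xz)[current]
}

# Ridge-penalised logistic log-likelihood fit, used as the fallback when the
# selected terms separate the classes perfectly.
ridge_logistic <- function(X, y, lambda = 1e-2) {
  p <- ncol(X)
  nll <- function(beta) {
    eta <- beta[1] + X %*% beta[-1]
    -sum(y * eta - log1p(exp(eta))) + lambda * sum(beta[-1]^2)
  }
  fit <- optim(rep(0, p + 1), nll, method = "BFGS",
               control = list(maxit = 500))
  fit$par
}

fit_logistic <- function(Xz, y) {
  separated <- FALSE
  if (ncol(Xz) == 0) {
    co <- c(stats::qlogis(max(1e-6, min(1 - 1e-6, mean(y)))))
    return(list(coef = co, separated = FALSE))
  }
  df <- data.frame(y = y, Xz)
  fit <- withCallingHandlers(
    glm(y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        separated <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  co <- coef(fit)
  if (separated || any(!is.finite(co)) || max(abs(co[-1])) > 50) {
    separated <- TRUE
    co <- ridge_logistic(as.matrix(Xz), y)
    names(co) <- c("(Intercept)", colnames(Xz))
  }
  list(coef = co, separated = separated)
}

#' Stepwise logistic combination of cohort parameters
#'
#' Selects a parameter subset by bidirectional AIC stepwise moves on an
#' initial linear fit of all candidate main effects, then refits the
#' selected terms by maximum-likelihood logistic regression of
#' SSc vs pooled HC/PRP. Candidates are z-scored internally; reported
#' coefficients are on the original scale. Perfect separation triggers a
#' ridge-penalised fallback fit, flagged in the output.
#'
#' @param table cohort data.frame (see [cohort_table()]).
#' @param candidates candidate parameter columns.
#' @param labels optional logical labels (default: `group == "SSc"`).
#' @return a `model_fit`: `selected_terms`, `coefficients` (original scale,
#'   including `(Intercept)`), `separated`, plus the standardisation used.
#' @export
stepwise_logistic <- function(table, candidates = NF_PARAMS, labels = NULL) {
  if (length(candidates) < 2) {
    nf_error("nailfold_invalid_input", "need >= 2 candidate parameters")
  }
  missing_cols <- setdiff(candidates, names(table))
  if (length(missing_cols)) {
    nf_error("nailfold_schema_error",
             paste("missing parameter columns:",
                   paste(missing_cols, collapse = ", ")))
  }
  X <- as.matrix(table[candidates])
  if (any(!is.finite(X))) {
    nf_error("nailfold_invalid_input", "candidate columns must be finite")
  }
  sdv <- apply(X, 2, sd)
  if (any(sdv == 0)) {
    nf_error("nailfold_invalid_input", "constant candidate column")
  }
  y <- as.numeric(as_positive_label(labels %||% table$group))
  mu <- colMeans(X)
  Xz <- scale(X, center = mu, scale = sdv)
  sel <- stepwise_select(Xz, y)
  fit <- fit_logistic(Xz[, sel, drop = FALSE], y)
  coz <- fit$coef
  beta <- if (length(sel)) coz[-1] / sdv[sel] else numeric(0)
  intercept <- coz[1] - if (length(sel)) sum(coz[-1] * mu[sel] / sdv[sel]) else 0
  structure(list(
    selected_terms = sel,
    coefficients = c("(Intercept)" = unname(intercept), beta),
    separated = fit$separated,
    center = mu, scale = sdv, coef_z = coz
  ), class = "model_fit")
}

predict_model_fit <- function(fit, table) {
  eta <- rep(fit$coefficients[["(Intercept)"]], nrow(table))
  for (term in fit$selected_terms) {
    eta <- eta + fit$coefficients[[term]] * table[[term]]
  }
  plogis(eta)
}

#' Leave-one-out cross-validated combined classifier
#'
#' For each subject the *entire* selection-plus-fit procedure of
#' [stepwise_logistic()] is rerun on the remaining subjects and the held-out
#' subject's class probability predicted, giving unbiased out-of-fold
#' scores; the combined ROC is computed on those scores with fixed
#' orientation (higher probability = SSc). A fold whose training set holds a
#' single class is skipped and flagged.
#'
#' @inheritParams stepwise_logistic
#' @return a `model_fit` (fit on the full table) extended with
#'   `loocv_scores` (named by subject id), `combined_roc` (a `roc_result`)
#'   and `skipped_folds`.
#' @export
loocv_roc <- function(table, candidates = NF_PARAMS, labels = NULL) {
  n <- nrow(table)
  if (n < 4) {
    nf_error("nailfold_invalid_input", "LOOCV needs at least 4 subjects")
  }
  y <- as_positive_label(labels %||% table$group)
  scores <- rep(NA_real_, n)
  skipped <- integer(0)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2) {
      skipped <- c(skipped, i)
      next
    }
    f <- stepwise_logistic(table[-i, , drop = FALSE], candidates,
                           labels = ytr)
    # an intercept-only fold ranks every subject equally: score it as a tie.
    # (Its leave-one-out prevalence is perfectly anti-correlated with the
    # held-out label, which would bias the cross-validated AUC to 0.)
    scores[i] <- if (length(f$selected_terms) == 0) 0.5 else
      predict_model_fit(f, table[i, , drop = FALSE])
  }
  full <- stepwise_logistic(table, candidates, labels = y)
  ok <- !is.na(scores)
  full$loocv_scores <- setNames(scores, table$subject_id %||% seq_len(n))
  full$combined_roc <- roc_auc(scores[ok], y[ok], direction = ">")
  full$skipped_folds <- skipped
  full
}
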