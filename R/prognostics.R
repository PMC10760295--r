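# Risk classification and signature construction.
#
# The classifier is a ridge-penalized logistic regression fitted by
# iteratively reweighted least squares on standardized features with an
# unpenalized intercept, evaluated by 10x10 nested ("double-loop")
# cross-validation: outer folds estimate out-of-sample AUC, inner folds
# select the penalty, and no inner computation (including
# standardization) ever sees outer-test rows.

#' Fit a ridge-penalized logistic regression
#'
#' Minimizes the negative Bernoulli log-likelihood plus
#' `(lambda/2) * ||beta||^2` over features standardized to zero mean
#' and unit SD (standardization parameters are stored in the model, so
#' predictions are invariant to affine rescaling of the raw features).
#' The intercept is unpenalized. Newton/IRLS with step halving,
#' converged when the max penalized-gradient component is <= `tol`.
#'
#' @param X numeric matrix (slides x features), no missing values.
#' @param y binary outcome (0/1 or logical), both classes present.
#' @param lambda ridge penalty >= 0.
#' @param tol gradient convergence tolerance.
#' @param max_iter Newton iteration cap.
#' @return object of class `ridge_model`.
#' @export
fit_ridge_logistic <- function(X, y, lambda = 1, tol = 1e-8,
                               max_iter = 200L) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X contains non-finite values")
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  stopifnot(all(y %in% c(0, 1)), lambda >= 0)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1  # constant columns carry no signal; leave centered
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  p <- ncol(Z)
  beta <- rep(0, p)
  b0 <- stats::qlogis(mean(y))
  pen <- c(0, rep(lambda, p))  # intercept unpenalized
  Za <- cbind(1, Z)
  theta <- ridge_irls(Za, y, pen, c(b0, beta), tol, max_iter)
  eta <- drop(Za %*% theta)
  g <- -drop(crossprod(Za, y - stats::plogis(eta))) + pen * theta
  structure(list(intercept = theta[1], coefficients = theta[-1],
                 lambda = lambda, feature_means = mu, feature_sds = sdv,
                 converged = max(abs(g)) <= tol * 10,
                 grad_norm = max(abs(g)),
                 feature_names = colnames(X)),
            class = "ridge_model")
}

# Newton/IRLS with step halving on a fixed design (first column is the
# intercept); `pen` is the per-coefficient ridge penalty vector.
ridge_irls <- function(Za, y, pen, theta, tol = 1e-8, max_iter = 200L) {
  obj <- function(th) {
    eta <- drop(Za %*% th)
    # stable -loglik: log(1 + e^eta) = max(eta, 0) + log1p(e^-|eta|)
    -sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))) +
      sum(pen * th^2) / 2
  }
  pp <- length(theta)
  for (it in seq_len(max_iter)) {
    eta <- drop(Za %*% theta)
    prob <- stats::plogis(eta)
    g <- -drop(crossprod(Za, y - prob)) + pen * theta
    if (max(abs(g)) <= tol) break
    w <- pmax(prob * (1 - prob), 1e-10)
    H <- crossprod(Za, Za * w) + diag(pen, pp)
    step <- solve(H, g)
    f0 <- obj(theta)
    s <- 1
    repeat {
      cand <- theta - s * step
      if (obj(cand) <= f0 || s < 1e-10) break
      s <- s / 2
    }
    theta <- cand
  }
  theta
}

# Warm-started lambda path: AUC on (Xte, yte) for each lambda, with
# standardization fitted on the training rows only. Used by the inner
# CV loop; equivalent to fit_ridge_logistic + predict per lambda.
ridge_path_auc <- function(Xtr, ytr, Xte, yte, lambdas, tol = 1e-6) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Za <- cbind(1, sweep(sweep(Xtr, 2, mu), 2, sdv, "/"))
  Ze <- cbind(1, sweep(sweep(Xte, 2, mu), 2, sdv, "/"))
  p <- ncol(Xtr)
  theta <- c(stats::qlogis(mean(ytr)), rep(0, p))
  out <- numeric(length(lambdas))
  ord <- order(lambdas, decreasing = TRUE)  # heavy shrinkage first
  for (li in ord) {
    pen <- c(0, rep(lambdas[li], p))
    theta <- ridge_irls(Za, ytr, pen, theta, tol)
    out[li] <- auc(drop(Ze %*% theta), yte)
  }
  out
}

#' Predict event probabilities from a ridge model
#' @param object a `ridge_model`.
#' @param newdata feature matrix on the raw scale.
#' @param ... unused.
#' @return vector of probabilities.
#' @export
predict.ridge_model <- function(object, newdata, ...) {
  Z <- sweep(sweep(as.matrix(newdata), 2, object$feature_means),
             2, object$feature_sds, "/")
  stats::plogis(object$intercept + drop(Z %*% object$coefficients))
}

#' Area under the ROC curve
#'
#' Probability that a random positive outranks a random negative, ties
#' counted one half (equals the Mann-Whitney U statistic divided by
#' `n1 * n0`). Computed from midranks.
#'
#' @param scores numeric risk scores.
#' @param labels binary labels (0/1/logical), both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Derive the binary horizon outcome from a cohort table
#'
#' Positive class: iIBC event by `horizon_years`. Patients censored
#' before the horizon without an event have unknown status at the
#' horizon; the default policy excludes them (the documented
#' alternative treats them as negatives).
#'
#' @param cohort validated cohort table ([read_cohort_table()]).
#' @param horizon_years classification horizon (5, 10 or 15).
#' @param censored_policy `"exclude"` (default) or `"negative"`.
#' @return data.frame with `slide_id` and binary `y` for the usable
#'   patients.
#' @export
horizon_outcome <- function(cohort, horizon_years = 5,
                            censored_policy = c("exclude", "negative")) {
  censored_policy <- match.arg(censored_policy)
  event_by <- !is.na(cohort$event_years) &
    cohort$event_years <= horizon_years
  known_neg <- cohort$followup_years >= horizon_years & !event_by
  usable <- event_by | known_neg |
    (censored_policy == "negative" & !event_by)
  data.frame(slide_id = cohort$slide_id[usable],
             y = as.integer(event_by[usable]),
             stringsAsFactors = FALSE)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Nested (double-loop) cross-validated AUC of the ridge classifier
#'
#' Outer stratified k-fold; for each outer training set, an inner
#' stratified k-fold selects the penalty maximizing mean inner-fold AUC
#' over `lambda_grid` (largest lambda on ties); the model refits on the
#' full outer-training set and scores the held-out fold. Reports
#' per-fold AUCs, their median, pooled out-of-fold predictions, and a
#' percentile bootstrap 95% CI on the pooled AUC. The seed fixes every
#' random choice, so identical calls are identical.
#'
#' @param X feature matrix with rownames = slide_id (or rows aligned to
#'   `cohort`).
#' @param cohort validated cohort table.
#' @param horizon_years classification horizon in years.
#' @param k_outer,k_inner fold counts (default 10 and 10).
#' @param lambda_grid penalty grid; default 50 log-spaced values in
#'   `[1e-4, 1e4]`.
#' @param n_boot bootstrap resamples for the CI (default 2000).
#' @param seed integer seed.
#' @param censored_policy see [horizon_outcome()].
#' @return object of class `nested_cv`: per-fold AUC, median AUC,
#'   bootstrap CI, chosen lambda per fold, fold assignments, pooled
#'   out-of-fold predictions.
#' @export
nested_cv_auc <- function(X, cohort, horizon_years = 5, k_outer = 10L,
                          k_inner = 10L,
                          lambda_grid = 10^seq(-4, 4, length.out = 50),
                          n_boot = 2000L, seed = 1L,
                          censored_policy = "exclude") {
  out <- horizon_outcome(cohort, horizon_years, censored_policy)
  X <- as.matrix(X)
  if (!is.null(rownames(X))) {
    miss <- setdiff(out$slide_id, rownames(X))
    if (length(miss)) stop("features missing for slide(s): ",
                           paste(utils::head(miss, 5), collapse = ", "))
    X <- X[out$slide_id, , drop = FALSE]
  } else if (nrow(X) != nrow(cohort)) {
    stop("X has no rownames and does not align with the cohort")
  } else {
    X <- X[match(out$slide_id, cohort$slide_id), , drop = FALSE]
  }
  y <- out$y
  n <- length(y)
  if (n < 30L) stop("need at least 30 usable patients, got ", n)
  if (min(table(y)) < k_outer)
    stop("minority class too small for ", k_outer, "-fold stratification")
  set.seed(seed)
  lambda_grid <- sort(lambda_grid)
  ofold <- stratified_folds(y, k_outer)
  oof <- rep(NA_real_, n)
  fold_auc <- numeric(k_outer)
  fold_lambda <- numeric(k_outer)
  for (f in seq_len(k_outer)) {
    tr <- which(ofold != f); te <- which(ofold == f)
    ifold <- stratified_folds(y[tr], k_inner)
    inner_auc <- matrix(NA_real_, k_inner, length(lambda_grid))
    for (g in seq_len(k_inner)) {
      itr <- tr[ifold != g]; ite <- tr[ifold == g]
      if (length(unique(y[ite])) < 2L || length(unique(y[itr])) < 2L) next
      inner_auc[g, ] <- ridge_path_auc(X[itr, , drop = FALSE], y[itr],
                                       X[ite, , drop = FALSE], y[ite],
                                       lambda_grid)
    }
    mean_auc <- colMeans(inner_auc, na.rm = TRUE)
    best <- max(which(mean_auc >= max(mean_auc) - 1e-12))
    fold_lambda[f] <- lambda_grid[best]
    fit <- fit_ridge_logistic(X[tr, , drop = FALSE], y[tr],
                              fold_lambda[f])
    oof[te] <- predict(fit, X[te, , drop = FALSE])
    fold_auc[f] <- auc(oof[te], y[te])
  }
  pooled <- auc(oof, y)
  boot <- replicate(n_boot, {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(y[idx])) < 2L) NA_real_ else auc(oof[idx], y[idx])
  })
  ci <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(fold_auc = fold_auc, median_auc = stats::median(fold_auc),
                 pooled_auc = pooled, ci95 = ci,
                 fold_lambda = fold_lambda, folds = ofold,
                 oof_predictions = oof, y = y, slide_id = out$slide_id,
                 horizon_years = horizon_years, seed = seed),
            class = "nested_cv")
}

#' @export
print.nested_cv <- function(x, ...) {
  cat(sprintf(
    "<nested_cv> horizon %g y: median AUC %.3f (pooled %.3f, 95%% CI %.3f-%.3f)\n",
    x$horizon_years, x$median_auc, x$pooled_auc, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Univariate association of slide variables with 5-level iIBC status
#'
#' Per standardized variable, fits a proportional-odds (ordinal
#' logistic) regression of the 5-level status ordered from earliest
#' event to no event, and reports the odds ratio per SD with a Wald
#' p-value. Under this ordering OR > 1 means higher values shift
#' patients toward later-or-no events (protective). A linear model on
#' the ordinal status code is available as a fallback effect model.
#' Zero-variance variables are skipped with a warning. Significance is
#' flagged at `alpha`, uncorrected by default; set `adjust = "BH"` for
#' Benjamini-Hochberg.
#'
#' @param features feature table (rows matched to `cohort` by
#'   `slide_id`).
#' @param cohort validated cohort table with `iibc_status5`.
#' @param variables variables to test (default: all feature columns).
#' @param alpha significance level (default 0.05).
#' @param adjust p-value adjustment method (default "none").
#' @param model `"ordinal"` (proportional odds, default) or `"linear"`.
#' @return data.frame of class `association_result`: variable, OR per
#'   SD, p, adjusted p, direction, significance flag.
#' @export
univariate_association <- function(features, cohort,
                                   variables = NULL, alpha = 0.05,
                                   adjust = "none",
                                   model = c("ordinal", "linear")) {
  model <- match.arg(model)
  X <- feature_matrix(features)
  idx <- match(features$slide_id, cohort$slide_id)
  if (any(is.na(idx))) stop("features contain slides absent from cohort")
  status <- cohort$iibc_status5[idx]
  if (any(is.na(status))) stop("iibc_status5 must be populated")
  if (is.null(variables)) variables <- colnames(X)
  res <- lapply(variables, function(v) {
    x <- X[, v]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      warning("zero-variance variable skipped: ", v)
      return(data.frame(variable = v, or_per_sd = NA_real_, p = NA_real_,
                        skipped = TRUE, stringsAsFactors = FALSE))
    }
    z <- (x - mean(x)) / s
    if (model == "ordinal") {
      fit <- tryCatch(
        MASS::polr(status ~ z, Hess = TRUE,
                   data = data.frame(status = status, z = z)),
        error = function(e) NULL)
      if (is.null(fit))
        return(data.frame(variable = v, or_per_sd = NA_real_,
                          p = NA_real_, skipped = TRUE,
                          stringsAsFactors = FALSE))
      est <- fit$coefficients[["z"]]
      se <- sqrt(diag(stats::vcov(fit)))[["z"]]
    } else {
      fit <- stats::lm(as.numeric(status) ~ z)
      est <- stats::coef(fit)[["z"]]
      se <- sqrt(diag(stats::vcov(fit)))[["z"]]
    }
    p <- 2 * stats::pnorm(-abs(est / se))
    data.frame(variable = v, or_per_sd = exp(est), p = p, skipped = FALSE,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adjusted <- stats::p.adjust(res$p, method = adjust)
  res$direction <- ifelse(res$or_per_sd > 1, "protective", "risk")
  res$significant <- !res$skipped & res$p_adjusted < alpha
  class(res) <- c("association_result", "data.frame")
  res
}

#' Hierarchical morphometric signatures
#'
#' Agglomerative clustering of slides on z-scored variables (Euclidean
#' distance, Ward linkage via `hclust(method = "ward.D2")`) cut into K
#' clusters. Deterministic given input order; `stats::hclust` breaks
#' distance ties by merge index, which is documented and stable.
#'
#' @param features feature table.
#' @param variables variables to cluster on (e.g. the significant set
#'   from [univariate_association()]); default all.
#' @param k number of signatures (default 4).
#' @return object of class `signature_assignment`: per-slide `cluster`
#'   (integer 1..k), the `hclust` tree, z-scoring parameters, the
#'   variables used, and per-cluster per-variable mean summaries.
#' @export
hierarchical_signatures <- function(features, variables = NULL, k = 4L) {
  X <- feature_matrix(features)
  if (is.null(variables)) variables <- colnames(X)
  X <- X[, variables, drop = FALSE]
  if (k < 1L || k > nrow(X))
    stop("k must be between 1 and the number of slides")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  hc <- stats::hclust(stats::dist(Z), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  summaries <- stats::aggregate(X, by = list(cluster = cl), FUN = mean)
  structure(list(slide_id = features$slide_id, cluster = unname(cl),
                 k = k, tree = hc, variables = variables,
                 z_means = mu, z_sds = sdv,
                 cluster_summaries = summaries),
            class = "signature_assignment")
}

#' @export
print.signature_assignment <- function(x, ...) {
  cat(sprintf("<signature_assignment> %d slides in %d signatures: %s\n",
              length(x$cluster), x$k,
              paste(sprintf("%d (n=%d)", seq_len(x$k),
                            tabulate(x$cluster, x$k)), collapse = ", ")))
  invisible(x)
}
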