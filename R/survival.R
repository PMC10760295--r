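# Survival evaluation of morphometric signatures: Kaplan-Meier
# cumulative incidence by signature group, the log-rank test, and
# multivariate Cox proportional-hazards regression of iIBC risk on the
# signature plus clinicopathological covariates. The time origin is the
# primary DCIS diagnosis; the event is iIBC; other endings of follow-up
# are treated as censoring (no competing-risks decomposition). All
# estimators are the standard ones from the survival package.

# Surv outcome from a validated cohort table.
cohort_surv <- function(cohort) {
  survival::Surv(cohort$followup_years, !is.na(cohort$event_years))
}

align_groups <- function(cohort, groups) {
  if (inherits(groups, "signature_assignment")) {
    idx <- match(cohort$slide_id, groups$slide_id)
    if (any(is.na(idx)))
      stop("signature assignment missing for slide(s): ",
           paste(utils::head(cohort$slide_id[is.na(idx)], 5),
                 collapse = ", "))
    groups$cluster[idx]
  } else {
    stopifnot(length(groups) == nrow(cohort))
    groups
  }
}

#' Kaplan-Meier cumulative incidence by signature group
#'
#' Product-limit estimate per group; cumulative incidence is
#' `1 - S(t)`, truncated at `max_years`. Empty groups are omitted with
#' a warning.
#'
#' @param cohort validated cohort table.
#' @param groups a [hierarchical_signatures()] assignment, or a vector
#'   of group labels aligned with the cohort rows.
#' @param max_years truncation horizon (default 15).
#' @return object of class `km_incidence`: data.frame `curves` with
#'   group, time, cumulative incidence, at-risk counts and Greenwood
#'   standard errors, plus the underlying `survfit`.
#' @export
km_cumulative_incidence <- function(cohort, groups, max_years = 15) {
  g <- factor(align_groups(cohort, groups))
  empty <- levels(g)[tabulate(g, nlevels(g)) == 0L]
  if (length(empty)) {
    warning("empty group(s) omitted: ", paste(empty, collapse = ", "))
    g <- droplevels(g)
  }
  fit <- survival::survfit(cohort_surv(cohort) ~ g)
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(levels(g)[1], length(s$time))
         else sub("^g=", "", as.character(s$strata))
  curves <- data.frame(group = grp, time = s$time,
                       cum_incidence = 1 - s$surv,
                       n_risk = s$n.risk, n_event = s$n.event,
                       std_err = s$std.err, stringsAsFactors = FALSE)
  curves <- curves[curves$time <= max_years, , drop = FALSE]
  structure(list(curves = curves, survfit = fit, max_years = max_years),
            class = "km_incidence")
}

#' Log-rank test across signature groups
#'
#' @inheritParams km_cumulative_incidence
#' @return list: `chisq`, `df` (groups - 1), `p`.
#' @export
logrank_test <- function(cohort, groups) {
  g <- factor(align_groups(cohort, groups))
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("log-rank test needs at least 2 groups")
  sd <- survival::survdiff(cohort_surv(cohort) ~ g)
  df <- nlevels(g) - 1L
  list(chisq = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Multivariate Cox regression of iIBC risk
#'
#' Cox proportional-hazards model (Efron ties) of the iIBC event on the
#' morphometric signature plus grade, ER, HER2 and COX-2. By default
#' the signature enters as a binary indicator of `reference_signature`
#' versus the rest (matching a single reported hazard ratio for the
#' low-risk group); set `signature_coding = "dummy"` for K-1 dummy
#' coding against `reference_signature`.
#'
#' @param cohort validated cohort table.
#' @param groups signature assignment (see [km_cumulative_incidence()]).
#' @param reference_signature the signature of interest (default 1).
#' @param signature_coding `"indicator"` (default) or `"dummy"`.
#' @param covariates cohort columns to adjust for.
#' @return object of class `cox_result`: data.frame `table` (term, HR,
#'   95% CI, p), `loglik`, `converged`, `n`, `n_dropped` (missing
#'   covariate rows), and the `coxph` fit.
#' @export
cox_fit <- function(cohort, groups, reference_signature = 1L,
                    signature_coding = c("indicator", "dummy"),
                    covariates = c("grade", "er", "her2", "cox2")) {
  signature_coding <- match.arg(signature_coding)
  g <- align_groups(cohort, groups)
  dat <- cohort[, c("followup_years", covariates), drop = FALSE]
  dat$event <- !is.na(cohort$event_years)
  if (signature_coding == "indicator") {
    dat$signature <- as.integer(g == reference_signature)
  } else {
    dat$signature <- stats::relevel(factor(g),
                                    ref = as.character(reference_signature))
  }
  complete <- stats::complete.cases(dat)
  n_dropped <- sum(!complete)
  if (n_dropped) message(n_dropped,
                         " row(s) dropped for missing covariates")
  dat <- dat[complete, , drop = FALSE]
  rhs <- paste(c("signature", covariates), collapse = " + ")
  fml <- stats::as.formula(
    paste("survival::Surv(followup_years, event) ~", rhs))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  s <- summary(fit)
  conv <- is.null(fit$info) && all(is.finite(stats::coef(fit)))
  if (any(abs(stats::coef(fit)) > 15))
    stop("Cox fit suggests complete separation (|beta| > 15); ",
         "check group/covariate coding")
  tab <- data.frame(term = rownames(s$coefficients),
                    hr = s$conf.int[, "exp(coef)"],
                    lower95 = s$conf.int[, "lower .95"],
                    upper95 = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, loglik = fit$loglik[2], converged = conv,
                 n = nrow(dat), n_dropped = n_dropped, fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> n=%d (%d dropped), converged=%s\n",
              x$n, x$n_dropped, x$converged))
  print(transform(x$table, hr = round(hr, 3), lower95 = round(lower95, 3),
                  upper95 = round(upper95, 3), p = signif(p, 3)),
        row.names = FALSE)
  invisible(x)
}
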