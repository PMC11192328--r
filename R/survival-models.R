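#' @importFrom survival Surv coxph survfit survdiff coxph.control
NULL

.checkCohort <- function(cohort) {
  need <- c("time", "event")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(cohort$time) || anyNA(cohort$event))
    stop("time/event must not be missing")
  if (any(cohort$time <= 0)) stop("times must be positive")
  invisible(cohort)
}

#' Kaplan-Meier estimate
#'
#' Product-limit survival estimate with median and quartile survival
#' times. Censored subjects (\code{event = 0}) leave the risk set after
#' their time; S is nonincreasing with S(0) = 1.
#'
#' @param time positive follow-up times (days).
#' @param event event indicator (1 = death, 0 = censored).
#' @return A list with \code{curve} (data frame \code{time},
#'   \code{n_risk}, \code{n_event}, \code{surv}), \code{median} and
#'   \code{quartiles} (times at which S crosses 0.75/0.50/0.25; \code{NA}
#'   where never reached).
#' @export
kmEstimate <- function(time, event) {
  .checkCohort(data.frame(time = time, event = event))
  fit <- survfit(Surv(time, event) ~ 1)
  q <- stats::quantile(fit, probs = c(0.25, 0.5, 0.75))$quantile
  list(curve = data.frame(time = fit$time, n_risk = fit$n.risk,
                          n_event = fit$n.event, surv = fit$surv),
       median = unname(q[2L]),
       quartiles = stats::setNames(unname(q), c("q25", "q50", "q75")))
}

#' Log-rank test
#'
#' Standard observed-minus-expected log-rank statistic across event times,
#' with \code{df = nlevels(group) - 1}.
#'
#' @param group group labels (>= 2 nonempty groups).
#' @inheritParams kmEstimate
#' @return A list: \code{chi2}, \code{df}, \code{p}.
#' @export
logrankTest <- function(group, time, event) {
  .checkCohort(data.frame(time = time, event = event))
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need >= 2 nonempty groups")
  if (any(table(group) == 0L)) stop("a group has zero subjects")
  sd <- survdiff(Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(chi2 = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Two-segment linear spline basis
#'
#' Decomposes an expression vector about a knot into
#' \code{below = min(x, knot)} and \code{above = max(x - knot, 0)}, so
#' that \code{below + above == x} exactly and a Cox model on the two
#' columns has one log-hazard slope below the knot and another above it.
#'
#' @param x numeric expression vector (CPM).
#' @param knot knot location on the same scale.
#' @return A two-column matrix \code{below}, \code{above}.
#' @export
splineBasis <- function(x, knot) {
  cbind(below = pmin(x, knot), above = pmax(x - knot, 0))
}

#' Cox model with a linear-spline expression covariate
#'
#' Fits a proportional-hazards model whose log-hazard is piecewise linear
#' in \code{cohort$expression} with a single knot, via partial-likelihood
#' maximization (Efron tie handling by default; Breslow available).
#' Optional categorical adjustment covariates (e.g. IDH status, MGMT
#' methylation, 1p/19q codeletion) enter as main effects with listwise
#' deletion of missing values. AIC is \code{-2 loglik + 2 k} with k the
#' number of regression coefficients (the baseline hazard is
#' nonparametric).
#'
#' @param cohort data frame with \code{time} (days), \code{event}
#'   (1 = death), \code{expression} (CPM), plus any adjustment columns.
#' @param knot knot location (CPM); must lie within the observed
#'   expression range.
#' @param covariates optional character vector of adjustment column names.
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @return A \linkS4class{SplineCoxFit}.
#' @export
coxSplineFit <- function(cohort, knot = 2.5, covariates = NULL,
                         ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  .checkCohort(cohort)
  if (sum(cohort$event) < 1L) stop("need >= 1 event")
  x <- cohort$expression
  if (knot < min(x) || knot > max(x))
    stop("knot ", knot, " outside the observed expression range")
  basis <- splineBasis(x, knot)
  dat <- data.frame(time = cohort$time, event = cohort$event,
                    below = basis[, "below"], above = basis[, "above"])
  form <- "Surv(time, event) ~ below + above"
  if (!is.null(covariates)) {
    for (cv in covariates) dat[[cv]] <- factor(cohort[[cv]])
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    form <- paste(form, "+", paste(covariates, collapse = " + "))
  }
  .newSplineCoxFit(stats::as.formula(form), dat, knot, ties)
}

.newSplineCoxFit <- function(form, dat, knot, ties) {
  fit <- tryCatch(
    coxph(form, data = dat, ties = ties,
          control = coxph.control(eps = 1e-10, iter.max = 100)),
    warning = function(w) stop("Cox fit did not converge cleanly: ",
                               conditionMessage(w)),
    error = function(e) stop("Cox fit failed: ", conditionMessage(e)))
  b <- stats::coef(fit)
  if (anyNA(b)) stop("singular information: ",
                     paste(names(b)[is.na(b)], collapse = ", "))
  se <- sqrt(diag(fit$var))
  ll <- fit$loglik[2L]
  k <- length(b)
  out <- new("SplineCoxFit", knot = knot, beta = b,
             se = stats::setNames(se, names(b)), loglik = ll,
             aic = -2 * ll + 2 * k, n = as.integer(fit$n),
             nEvents = as.integer(fit$nevent), ties = ties,
             converged = TRUE, coxph = fit)
  validObject(out)
  out
}

#' AIC knot search over a grid
#'
#' Refits the spline Cox model at every candidate knot on a grid and
#' returns the knot with the lowest AIC (ties to the smaller knot).
#' Candidates at which the fit fails are skipped with a warning; all
#' candidates failing is an error.
#'
#' @inheritParams coxSplineFit
#' @param gridLo,gridHi,step knot grid (defaults 2.0 to 3.0 by 0.1).
#' @return A list: \code{best_knot}, \code{best_fit} (the
#'   \linkS4class{SplineCoxFit} at the best knot), and \code{profile}
#'   (data frame \code{knot}, \code{aic} over converged candidates).
#' @export
knotSearch <- function(cohort, gridLo = 2.0, gridHi = 3.0, step = 0.1,
                       covariates = NULL, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (gridHi < gridLo || step <= 0) stop("invalid knot grid")
  grid <- seq(gridLo, gridHi, by = step)
  fits <- lapply(grid, function(k)
    tryCatch(coxSplineFit(cohort, knot = k, covariates = covariates,
                          ties = ties),
             error = function(e) NULL))
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) stop("no knot on the grid yielded a converged fit")
  if (!all(ok))
    warning("skipped non-converging knot(s): ",
            paste(format(grid[!ok]), collapse = ", "))
  aic <- vapply(fits[ok], function(f) f@aic, 0)
  best <- which.min(aic)  # which.min takes the first, i.e. smallest knot
  list(best_knot = grid[ok][best], best_fit = fits[ok][[best]],
       profile = data.frame(knot = grid[ok], aic = aic))
}

#' Martingale residuals of a spline Cox fit
#'
#' Per-subject residual \code{event - estimated cumulative hazard at
#' exit}; these sum to (numerically) zero at the fitted coefficients and
#' are the standard diagnostic for the linearity of a continuous
#' covariate's log-hazard contribution.
#'
#' @param fit a converged \linkS4class{SplineCoxFit}.
#' @return Numeric vector of residuals, one per subject used in the fit.
#' @export
martingaleResiduals <- function(fit) {
  stopifnot(is(fit, "SplineCoxFit"))
  unname(stats::residuals(fit@coxph, type = "martingale"))
}

#' Dichotomize expression into risk groups at a cutoff
#'
#' High risk is strictly above the cutoff; values at or below it
#' (including exactly the cutoff) are low risk.
#'
#' @param expression numeric vector (CPM).
#' @param cutoff threshold (default 2.5 CPM).
#' @return Factor with levels \code{low}, \code{high}.
#' @export
riskGroupSplit <- function(expression, cutoff = 2.5) {
  factor(ifelse(expression > cutoff, "high", "low"),
         levels = c("low", "high"))
}
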