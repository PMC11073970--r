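#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function, computed with
#' [survival::survfit] and returned in a plain vector form used throughout the
#' package: `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct observed
#' times with `d_i` events among `n_i` at risk.
#'
#' @param times nonnegative follow-up times (months).
#' @param events event indicators, 1 = death/relapse observed, 0 = censored.
#' @return object of class `kmCurve`: list with `time`, `surv`, `n_risk`,
#'   `n_event`, `n`.
#' @seealso [medianSurvival()], [survivalAt()]
#' @export
kmFit <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input")
  stopifnot(length(times) == length(events))
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and nonnegative")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- list(time = as.numeric(sf$time), surv = as.numeric(sf$surv),
              n_risk = as.numeric(sf$n.risk), n_event = as.numeric(sf$n.event),
              n = length(times))
  class(out) <- "kmCurve"
  out
}

#' @export
print.kmCurve <- function(x, ...) {
  med <- medianSurvival(x)
  cat("Kaplan-Meier curve: n =", x$n, ", events =", sum(x$n_event),
      ", median =", if (is.finite(med)) format(med) else "not reached", "\n")
  invisible(x)
}

#' Median survival of a Kaplan-Meier curve
#'
#' The smallest observed time at which `S(t) <= 0.5` (right-continuous
#' convention). When the curve never drops to 0.5 within follow-up the median
#' is not reached and `Inf` is returned, so that "not reached beats any finite
#' median" holds under ordinary comparison; test with [is.finite()].
#'
#' @param curve a `kmCurve` from [kmFit()].
#' @return numeric; `Inf` means not reached.
#' @export
medianSurvival <- function(curve) {
  stopifnot(inherits(curve, "kmCurve"))
  hit <- which(curve$surv <= 0.5 + 1e-12)
  if (length(hit) == 0L) Inf else curve$time[hit[1L]]
}

#' Survival probability at a time point
#'
#' Right-continuous step-function value `S(t)`; before the first observed
#' time it is 1, beyond the last it is the last estimate. The five-year rates
#' used by the triage projection are `survivalAt(curve, 60)`.
#'
#' @param curve a `kmCurve`.
#' @param t nonnegative time (months); vectorised.
#' @return survival probabilities in `[0, 1]`.
#' @export
survivalAt <- function(curve, t) {
  stopifnot(inherits(curve, "kmCurve"))
  if (any(t < 0)) stop("negative time")
  idx <- findInterval(t, curve$time)
  c(1, curve$surv)[idx + 1L]
}

#' Multi-group log-rank test
#'
#' Standard G-group log-rank chi-square (observed minus expected event counts
#' with the hypergeometric risk-set variance, via [survival::survdiff]) on
#' G - 1 degrees of freedom. Degenerate inputs with no events at all return
#' statistic 0, p = 1.
#'
#' @param times,events as in [kmFit()].
#' @param groups group labels (>= 2 nonempty groups).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
logrankTest <- function(times, events, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2L) stop("log-rank test needs at least two groups")
  if (length(unique(c(length(times), length(events), length(groups)))) != 1L)
    stop("input lengths differ")
  df <- nlevels(groups) - 1L
  if (sum(events) == 0)
    return(list(statistic = 0, df = df, p_value = 1))
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  stat <- as.numeric(sd$chisq)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (via [stats::p.adjust]), clipped to 1 and monotone
#' in the ranks. `NA` entries are passed through.
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bhAdjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Breslow tie handling via [survival::coxph].
#' Non-convergence or separation is reported through `converged = FALSE` with
#' a warning rather than an error.
#'
#' @param times,events as in [kmFit()].
#' @param covariates numeric matrix or data.frame of covariates (no constant
#'   column; `n` must exceed the number of covariates).
#' @return object of class `coxFit`: per-covariate `coefficients`,
#'   `hazard_ratio`, `ci_lower`, `ci_upper` (Wald 95%), `p_value`, and a
#'   `converged` flag.
#' @export
coxphFit <- function(times, events, covariates) {
  x <- as.matrix(covariates)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (nrow(x) <= ncol(x)) stop("need more observations than covariates")
  if (any(apply(x, 2L, function(v) stats::sd(v) == 0)))
    stop("constant covariate")
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ x, ties = "breslow"),
    warning = function(w) {
      if (grepl("converge|infinite|loglik", conditionMessage(w))) {
        converged <<- FALSE
        warning("Cox fit did not converge cleanly: ", conditionMessage(w),
                call. = FALSE)
        invokeRestart("muffleWarning")
      }
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(!is.finite(beta)) || any(!is.finite(se))) converged <- FALSE
  out <- list(coefficients = stats::setNames(beta, colnames(x)),
              hazard_ratio = exp(beta),
              ci_lower = exp(beta - 1.96 * se),
              ci_upper = exp(beta + 1.96 * se),
              p_value = 2 * stats::pnorm(-abs(beta / se)),
              converged = converged)
  class(out) <- "coxFit"
  out
}

#' @export
print.coxFit <- function(x, ...) {
  cat("Cox PH fit (Breslow ties), converged:", x$converged, "\n")
  print(data.frame(coef = x$coefficients, HR = x$hazard_ratio,
                   lower95 = x$ci_lower, upper95 = x$ci_upper,
                   p = x$p_value))
  invisible(x)
}
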