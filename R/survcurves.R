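#' Right-continuous step curve
#'
#' Minimal container for survival and cumulative-incidence estimates: jump
#' times, the value immediately after each jump, the value at time 0, and
#' the at-risk count entering each time.
#'
#' @param times increasing jump times.
#' @param values curve value just after each time.
#' @param value0 value on [0, first jump).
#' @param n_risk at-risk count at each time (optional).
#' @param std_err pointwise standard errors (optional).
#' @param type \code{"survival"} (non-increasing) or \code{"cif"}
#'   (non-decreasing).
#' @param cause event cause for CIF curves (optional).
#' @return object of class \code{step_curve}.
#' @export
step_curve <- function(times, values, value0, n_risk = NULL, std_err = NULL,
                       type = c("survival", "cif"), cause = NA_integer_) {
  type <- match.arg(type)
  o <- order(times)
  structure(list(times = as.numeric(times)[o], values = as.numeric(values)[o],
                 value0 = as.numeric(value0),
                 n_risk = if (is.null(n_risk)) NULL else n_risk[o],
                 std_err = if (is.null(std_err)) NULL else std_err[o],
                 type = type, cause = cause),
            class = "step_curve")
}

#' Evaluate a step curve (right-continuously) at arbitrary times
#'
#' @param curve a \code{\link{step_curve}}.
#' @param t numeric vector of evaluation times.
#' @return numeric vector of curve values.
#' @export
eval_step <- function(curve, t) {
  stopifnot(inherits(curve, "step_curve"))
  idx <- findInterval(t, curve$times)
  c(curve$value0, curve$values)[idx + 1L]
}

#' @export
print.step_curve <- function(x, ...) {
  cat(sprintf("step_curve (%s%s): %d jump times on [%.3g, %.3g], final value %.4f\n",
              x$type, if (!is.na(x$cause)) paste0(", cause ", x$cause) else "",
              length(x$times), min(x$times), max(x$times),
              utils::tail(x$values, 1)))
  invisible(x)
}

#' @export
as.data.frame.step_curve <- function(x, ...) {
  data.frame(time = x$times, estimate = x$values,
             n_at_risk = x$n_risk %||% NA_real_,
             std_err = x$std_err %||% NA_real_,
             type = x$type, cause = x$cause)
}

#' Kaplan-Meier product-limit estimator (optionally weighted)
#'
#' \eqn{S(t) = \prod_{t_j \le t} (1 - d_j / n_j)} with event and at-risk
#' counts replaced by weighted sums when weights are supplied; delegates to
#' \code{survival::survfit}. Events precede censorings at tied times.
#'
#' @param time non-negative follow-up times.
#' @param event_flag 1 = event, 0 = censored.
#' @param weights optional positive case weights (default 1).
#' @return a \code{\link{step_curve}} of type \code{"survival"}.
#' @export
km_curve <- function(time, event_flag, weights = NULL) {
  stopifnot(all(time >= 0), all(event_flag %in% 0:1))
  if (!is.null(weights) && any(weights <= 0)) stop2("weights must be > 0")
  if (sum(event_flag) == 0) {
    warn2("no events; survival curve is identically 1")
    return(step_curve(max(time), 1, 1, n_risk = length(time),
                      type = "survival"))
  }
  df <- data.frame(time = time, event = event_flag,
                   w = weights %||% rep(1, length(time)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = df,
                           weights = w)
  step_curve(fit$time, fit$surv, 1, n_risk = fit$n.risk,
             std_err = fit$std.err * fit$surv, type = "survival")
}

#' Aalen-Johansen estimator of cause-specific cumulative incidence
#'
#' Multi-state estimate of \eqn{F_k(t) = \sum_{t_j \le t} S(t_j-) d_{kj}/n_j}
#' with \eqn{S} the all-cause Kaplan-Meier; the reference nonparametric CIF
#' estimator under competing risks. Delegates to the multi-state machinery
#' of \code{survival::survfit}, which guarantees
#' \eqn{S(t) + F_1(t) + F_2(t) = 1} at every time.
#'
#' @param time follow-up times.
#' @param event 0 = censored, 1 = cause-1 (cancer) death, 2 = cause-2
#'   (other-cause) death.
#' @return object of class \code{cif_set}: list with step curves
#'   \code{cif1}, \code{cif2} and all-cause \code{surv}.
#' @export
aalen_johansen <- function(time, event) {
  stopifnot(all(event %in% 0:2))
  df <- data.frame(time = time,
                   ev = factor(event, levels = 0:2,
                               labels = c("censor", "cause1", "cause2")))
  fit <- survival::survfit(survival::Surv(time, ev) ~ 1, data = df)
  states <- fit$states
  i1 <- which(states == "cause1"); i2 <- which(states == "cause2")
  i0 <- which(states == "(s0)")
  se <- fit$std.err
  structure(list(
    cif1 = step_curve(fit$time, fit$pstate[, i1], 0,
                      n_risk = fit$n.risk[, i0],
                      std_err = if (!is.null(se)) se[, i1] else NULL,
                      type = "cif", cause = 1L),
    cif2 = step_curve(fit$time, fit$pstate[, i2], 0,
                      n_risk = fit$n.risk[, i0],
                      std_err = if (!is.null(se)) se[, i2] else NULL,
                      type = "cif", cause = 2L),
    surv = step_curve(fit$time, fit$pstate[, i0], 1,
                      n_risk = fit$n.risk[, i0], type = "survival")
  ), class = "cif_set")
}

#' @export
print.cif_set <- function(x, ...) {
  cat("Aalen-Johansen cumulative incidence set\n")
  print(x$cif1); print(x$cif2); print(x$surv)
  invisible(x)
}

#' Naive one-minus-Kaplan-Meier estimate of cause-specific incidence
#'
#' Treats deaths from the competing cause as censorings and returns
#' \eqn{1 - KM}. In the presence of competing risks this estimator
#' overstates the cumulative incidence — it is the biased comparator that
#' the class-mixture and Aalen-Johansen estimators are measured against.
#'
#' @param time follow-up times.
#' @param event 0/1/2 event codes.
#' @param cause target cause (1 or 2).
#' @param weights optional positive case weights.
#' @return a \code{\link{step_curve}} of type \code{"cif"}.
#' @export
naive_cif <- function(time, event, cause, weights = NULL) {
  stopifnot(cause %in% 1:2, all(event %in% 0:2))
  flag <- as.integer(event == cause)
  km <- suppressWarnings(km_curve(time, flag, weights))
  step_curve(km$times, 1 - km$values, 0, n_risk = km$n_risk,
             std_err = km$std_err, type = "cif", cause = as.integer(cause))
}

#' Cause-specific proportional hazards fit (multi-state component)
#'
#' Fits the Cox partial likelihood for transitions into the target cause,
#' censoring deaths from the competing cause, with Efron handling of tied
#' event times. With case weights the robust (working-independence
#' sandwich) standard errors are reported, as appropriate for rescaled
#' weights. The multi-state model of cancer-specific survival is the pair
#' of such fits, one per cause.
#'
#' @param time follow-up times.
#' @param event 0/1/2 event codes.
#' @param cause target cause (1 or 2).
#' @param covariate categorical covariate (factor); the first level is the
#'   reference.
#' @param weights optional positive case weights.
#' @return data.frame of class \code{hr_table} with one row per covariate
#'   level: \code{cause}, \code{level}, \code{reference}, \code{loghr},
#'   \code{hr}, \code{se}, \code{ci_low}, \code{ci_high}, \code{p},
#'   \code{n_events}, \code{estimable}; the underlying \code{coxph} fit is
#'   attached as attribute \code{"fit"}.
#' @export
cause_specific_cox <- function(time, event, cause, covariate,
                               weights = NULL) {
  stopifnot(cause %in% 1:2, all(event %in% 0:2))
  covariate <- as.factor(covariate)
  covariate <- droplevels(covariate)
  if (nlevels(covariate) < 2L) stop2("covariate needs >= 2 observed levels")
  status <- as.integer(event == cause)
  ev_by_level <- tapply(status, covariate, sum)
  df <- data.frame(time = time, status = status, x = covariate,
                   w = weights %||% rep(1, length(time)))
  fit <- survival::coxph(survival::Surv(time, status) ~ x, data = df,
                         weights = w, ties = "efron",
                         robust = !is.null(weights),
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 50))
  sm <- summary(fit)
  levs <- levels(covariate)
  co <- sm$coefficients
  se_col <- if ("robust se" %in% colnames(co)) "robust se" else "se(coef)"
  rows <- lapply(seq_along(levs), function(i) {
    if (i == 1L) {
      data.frame(cause = cause, level = levs[1], reference = TRUE,
                 loghr = 0, hr = 1, se = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, p = NA_real_,
                 n_events = as.integer(ev_by_level[1]), estimable = TRUE)
    } else {
      nm <- paste0("x", levs[i])
      b <- co[nm, "coef"]; s <- co[nm, se_col]
      est <- is.finite(b) && is.finite(s) && ev_by_level[i] > 0 &&
        abs(b) < 15
      data.frame(cause = cause, level = levs[i], reference = FALSE,
                 loghr = b, hr = exp(b), se = s,
                 ci_low = exp(b - 1.96 * s), ci_high = exp(b + 1.96 * s),
                 p = co[nm, ncol(co)],
                 n_events = as.integer(ev_by_level[i]), estimable = est)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("hr_table", "data.frame")
  attr(out, "fit") <- fit
  attr(out, "ties") <- "efron"
  out
}

#' Cause-specific Cox fits for both competing causes
#'
#' @inheritParams cause_specific_cox
#' @return \code{hr_table} stacking the cause-1 and cause-2 fits.
#' @export
multi_state_model <- function(time, event, covariate, weights = NULL) {
  t1 <- cause_specific_cox(time, event, 1L, covariate, weights)
  t2 <- cause_specific_cox(time, event, 2L, covariate, weights)
  out <- rbind(as.data.frame(t1), as.data.frame(t2))
  class(out) <- c("hr_table", "data.frame")
  attr(out, "fits") <- list(cause1 = attr(t1, "fit"), cause2 = attr(t2, "fit"))
  out
}

#' Export a set of step curves as a tidy table
#'
#' @param curves named list of \code{\link{step_curve}} objects.
#' @return data.frame with columns \code{name}, \code{time},
#'   \code{estimate}, \code{n_at_risk}, \code{std_err}, \code{type},
#'   \code{cause}.
#' @export
curves_to_table <- function(curves) {
  do.call(rbind, lapply(names(curves), function(nm) {
    d <- as.data.frame(curves[[nm]])
    cbind(name = nm, d)
  }))
}
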