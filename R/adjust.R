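#' Rescaled balancing weights (marginal survival-curve adjustment)
#'
#' Computes, for a patient in group \eqn{g} with balancing class \eqn{z},
#' the base weight \eqn{w = \hat P(Z=z) / \hat P(Z=z \mid G=g)}, which makes
#' the weighted class distribution inside every group equal to the pooled
#' (marginal) class distribution, then rescales the weights within each
#' group to sum to the group size. Groups are typically molecular subtypes
#' and the balancing variable the latent-class label.
#'
#' @param group factor of comparison groups (e.g. subtype).
#' @param balance factor of the balancing variable (e.g. assigned class).
#' @return object of class \code{weight_set}: list with \code{weights}
#'   (per patient), \code{base_weights}, \code{group}, \code{balance},
#'   \code{report} (per-group weight sums and sizes), and \code{empty_cells}.
#' @export
rescaled_weights <- function(group, balance) {
  group <- as.factor(group); balance <- as.factor(balance)
  stopifnot(length(group) == length(balance))
  if (anyNA(group) || anyNA(balance))
    stop2("group/balance must not contain missing values")
  N <- length(group)
  tab <- table(group, balance)
  n_g <- rowSums(tab); n_z <- colSums(tab)
  if (any(tab == 0 & outer(n_g, n_z, function(a, b) a > 0 & b > 0)))
    warn2("some group/class cells are empty; those classes contribute ",
          "weight only through occupied cells")
  marg <- n_z / N
  cond <- tab / n_g                       # P(z | g)
  w_base <- numeric(N)
  gi <- as.integer(group); zi <- as.integer(balance)
  w_base <- marg[zi] / cond[cbind(gi, zi)]
  # rescale within group so weights sum to the group size
  sums <- tapply(w_base, group, sum)
  w <- w_base * (n_g / sums)[gi]
  report <- data.frame(group = names(n_g), n = as.integer(n_g),
                       weight_sum = as.numeric(tapply(w, group, sum)))
  structure(list(weights = as.numeric(w), base_weights = as.numeric(w_base),
                 group = group, balance = balance, report = report,
                 empty_cells = sum(tab == 0)),
            class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat("Rescaled weight set:", length(x$weights), "patients,",
      nlevels(x$group), "groups balanced over", nlevels(x$balance),
      "classes\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Adjusted (and unadjusted) per-group Kaplan-Meier curves
#'
#' Weighted product-limit curves per comparison group using rescaled
#' balancing weights; with unit weights the adjusted curves coincide with
#' the classical per-group Kaplan-Meier.
#'
#' @param time follow-up times.
#' @param event_flag 1 = event, 0 = censored.
#' @param group comparison-group factor.
#' @param weights a \code{\link{weight_set}} from
#'   \code{\link{rescaled_weights}} on the same patients, or a numeric
#'   vector, or NULL for unit weights.
#' @return list with named step-curve lists \code{adjusted} and
#'   \code{unadjusted}.
#' @export
adjusted_km_curves <- function(time, event_flag, group, weights = NULL) {
  group <- as.factor(group)
  w <- if (inherits(weights, "weight_set")) weights$weights else
    weights %||% rep(1, length(time))
  stopifnot(length(w) == length(time))
  one_set <- function(wt) {
    out <- lapply(levels(group), function(g) {
      i <- group == g
      suppressWarnings(km_curve(time[i], event_flag[i], wt[i]))
    })
    names(out) <- levels(group)
    out
  }
  list(adjusted = one_set(w), unadjusted = one_set(rep(1, length(time))))
}

#' Class-mixture estimate of a cause-specific cumulative incidence
#'
#' Stratifies on the class label, estimates the naive (1 - KM) incidence of
#' the target cause within each stratum — where the competing cause acts as
#' approximately uninformative censoring if the class captures the
#' competing-risk heterogeneity — and mixes the stratum curves with the
#' stratum shares: \eqn{\hat F(t) = \sum_z \hat p_z \hat F_z(t)}. Strata
#' smaller than \code{min_stratum} are pooled into the stratum with the
#' nearest share before estimation.
#'
#' @param time follow-up times.
#' @param event 0/1/2 event codes.
#' @param cause target cause.
#' @param class_labels stratification labels (e.g. assigned latent class).
#' @param subgroup optional logical filter defining the subpopulation.
#' @param min_stratum minimum stratum size before pooling (default 50).
#' @return a \code{\link{step_curve}} of type \code{"cif"} with attribute
#'   \code{"pooling"} describing any pooled strata.
#' @export
class_mixture_cif <- function(time, event, cause, class_labels,
                              subgroup = NULL, min_stratum = 50L) {
  stopifnot(cause %in% 1:2)
  if (!is.null(subgroup)) {
    time <- time[subgroup]; event <- event[subgroup]
    class_labels <- class_labels[subgroup]
  }
  cls <- droplevels(as.factor(class_labels))
  sizes <- table(cls)
  if (all(sizes < min_stratum)) {
    warn2("all class strata below min_stratum; falling back to the naive ",
          "1-KM estimator")
    out <- naive_cif(time, event, cause)
    attr(out, "pooling") <- "all strata pooled (naive fallback)"
    return(out)
  }
  # pool undersized strata into the stratum with the nearest share
  pool_map <- stats::setNames(levels(cls), levels(cls))
  pooling <- character(0)
  repeat {
    sizes <- table(factor(pool_map[as.character(cls)],
                          levels = unique(pool_map)))
    small <- names(sizes)[sizes < min_stratum & sizes > 0]
    if (length(small) == 0L) break
    s <- small[which.min(sizes[small])]
    others <- setdiff(names(sizes)[sizes > 0], s)
    tgt <- others[which.min(abs(sizes[others] - sizes[s]))]
    pool_map[pool_map == s] <- tgt
    pooling <- c(pooling, paste0(s, " -> ", tgt))
  }
  strata <- factor(pool_map[as.character(cls)])
  shares <- table(strata) / length(strata)
  grid <- sort(unique(time[event == cause]))
  if (length(grid) == 0L) grid <- max(time)
  mix <- rep(0, length(grid))
  for (s in levels(strata)) {
    i <- strata == s
    curve <- naive_cif(time[i], event[i], cause)
    mix <- mix + as.numeric(shares[s]) * eval_step(curve, grid)
  }
  out <- step_curve(grid, mix, 0, type = "cif", cause = as.integer(cause))
  attr(out, "pooling") <- if (length(pooling)) pooling else "none"
  out
}

#' Robust score test for a group effect in a (weighted) hazards model
#'
#' Score test at \eqn{\beta = 0} of a proportional-hazards model with group
#' indicators. With unit weights this is the classical log-rank test; with
#' rescaled weights the robust (working-independence sandwich) variance of
#' the weighted score is used, i.e. a log-rank test corrected for
#' weighting.
#'
#' @param time follow-up times.
#' @param event_flag 1 = event, 0 = censored.
#' @param group comparison-group factor (>= 2 levels).
#' @param weights optional \code{\link{weight_set}} or numeric weights.
#' @return object of class \code{score_test}: \code{statistic}, \code{df},
#'   \code{p_value}, \code{weighted}.
#' @export
robust_score_test <- function(time, event_flag, group, weights = NULL) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) stop2("need >= 2 groups")
  w <- if (inherits(weights, "weight_set")) weights$weights else weights
  weighted <- !is.null(w)
  df <- data.frame(time = time, status = event_flag, g = group,
                   w = w %||% rep(1, length(time)))
  fit <- survival::coxph(survival::Surv(time, status) ~ g, data = df,
                         weights = w, ties = "efron", robust = weighted)
  sm <- summary(fit)
  res <- if (weighted) sm$robscore else sm$sctest
  structure(list(statistic = unname(res["test"]), df = unname(res["df"]),
                 p_value = unname(res["pvalue"]), weighted = weighted),
            class = "score_test")
}

#' @export
print.score_test <- function(x, ...) {
  cat(sprintf("%s score test: chi-square %.4f on %d df, p = %.4g\n",
              if (x$weighted) "Robust (weighted)" else "Classical",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Harrell's concordance index for censored data (optionally weighted)
#'
#' Counts usable pairs (the earlier time is an observed event; pairs tied
#' on time with both events are not comparable), scoring a pair concordant
#' when the earlier event carries the higher risk score and 0.5 for tied
#' scores. With weights, a pair (i, j) contributes \eqn{w_i w_j}.
#'
#' @param time follow-up times.
#' @param event_flag 1 = event, 0 = censored.
#' @param risk_score numeric risk score (higher = earlier event expected),
#'   e.g. the linear predictor of a hazards model.
#' @param weights optional \code{\link{weight_set}} or numeric weights.
#' @return object of class \code{concordance_result}: \code{c_index},
#'   \code{comparable}, \code{concordant}, \code{tied}, \code{weighted}.
#' @export
concordance_index <- function(time, event_flag, risk_score, weights = NULL) {
  n <- length(time)
  stopifnot(length(event_flag) == n, length(risk_score) == n)
  w <- if (inherits(weights, "weight_set")) weights$weights else
    weights %||% rep(1, n)
  comp <- conc <- tied <- 0
  chunk <- 1024L
  for (start in seq(1L, n, by = chunk)) {
    i <- start:min(start + chunk - 1L, n)
    # usable with i as the earlier event
    usable <- outer(time[i], time, "<") |
      (outer(time[i], time, "==") & outer(rep(TRUE, length(i)), event_flag == 0))
    usable <- usable & (event_flag[i] == 1)
    diag_idx <- cbind(seq_along(i), i)
    usable[diag_idx] <- FALSE
    pw <- outer(w[i], w)
    sgn <- outer(risk_score[i], risk_score, "-")
    comp <- comp + sum(pw * usable)
    conc <- conc + sum(pw * (usable & sgn > 0))
    tied <- tied + sum(pw * (usable & sgn == 0))
  }
  if (comp == 0) {
    warn2("no comparable pairs; concordance undefined")
    return(structure(list(c_index = NA_real_, comparable = 0, concordant = 0,
                          tied = 0, weighted = !is.null(weights)),
                     class = "concordance_result"))
  }
  structure(list(c_index = (conc + 0.5 * tied) / comp, comparable = comp,
                 concordant = conc, tied = tied,
                 weighted = !is.null(weights)),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("C-index %.4f (%s; %.0f comparable, %.0f concordant, %.0f tied)\n",
              x$c_index, if (x$weighted) "weighted" else "unweighted",
              x$comparable, x$concordant, x$tied))
  invisible(x)
}

#' Before/after adjustment comparison of subtype survival stratification
#'
#' For all subtypes jointly and for each subtype pair, fits the subtype
#' proportional-hazards model without and with rescaled class-balancing
#' weights and reports the (robust) score statistic and Harrell C-index of
#' the fitted subtype risk score under each weighting scheme. Weights are
#' recomputed within each pairwise subset so the class distribution is
#' balanced across exactly the groups being compared.
#'
#' @param time follow-up times.
#' @param event 0/1/2 event codes.
#' @param class_labels balancing classification (e.g. assigned latent class).
#' @param subtype molecular-subtype factor.
#' @param endpoint \code{"os"} (all-cause death) or \code{"css"}
#'   (cancer-specific: cause-2 deaths censored), or both.
#' @return data.frame of class \code{adjustment_report}: one row per
#'   endpoint x comparison x metric with \code{unadjusted} and
#'   \code{adjusted} values.
#' @export
adjustment_report <- function(time, event, class_labels, subtype,
                              endpoint = c("os", "css")) {
  endpoint <- match.arg(endpoint, several.ok = TRUE)
  subtype <- droplevels(as.factor(subtype))
  cls <- as.factor(class_labels)
  levs <- levels(subtype)
  comparisons <- c(list(all = levs),
                   stats::setNames(utils::combn(levs, 2, simplify = FALSE),
                                   utils::combn(levs, 2, paste, collapse = " vs ")))
  rows <- list()
  for (ep in endpoint) {
    flag <- if (ep == "os") as.integer(event > 0) else as.integer(event == 1)
    for (nm in names(comparisons)) {
      sel <- subtype %in% comparisons[[nm]]
      g <- droplevels(subtype[sel])
      if (nlevels(g) < 2L || sum(flag[sel]) == 0) next
      t_s <- time[sel]; f_s <- flag[sel]; z_s <- droplevels(cls[sel])
      ws <- rescaled_weights(g, z_s)
      m <- function(weights) {
        dfit <- data.frame(time = t_s, status = f_s, g = g,
                           w = weights %||% rep(1, length(t_s)))
        fit <- survival::coxph(survival::Surv(time, status) ~ g, data = dfit,
                               weights = w, ties = "efron",
                               robust = !is.null(weights))
        lp <- as.numeric(stats::predict(fit, type = "lp"))
        list(score = robust_score_test(t_s, f_s, g, weights),
             cidx = concordance_index(t_s, f_s, lp,
                                      if (is.null(weights)) NULL else ws))
      }
      un <- m(NULL); ad <- m(ws$weights)
      rows[[length(rows) + 1L]] <- data.frame(
        endpoint = ep, comparison = nm, metric = "score_statistic",
        unadjusted = un$score$statistic, adjusted = ad$score$statistic)
      rows[[length(rows) + 1L]] <- data.frame(
        endpoint = ep, comparison = nm, metric = "c_index",
        unadjusted = un$cidx$c_index, adjusted = ad$cidx$c_index)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("adjustment_report", "data.frame")
  out
}
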