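#' Fit diagnostics for a latent class model
#'
#' Information criteria and classification-quality summaries used for model
#' selection: \code{aic = -2LL + 2p}, \code{bic = -2LL + p log n},
#' \code{sabic = -2LL + p log((n+2)/24)}; raw classification entropy
#' \eqn{\sum_{i,c} -\theta_{ic}\log\theta_{ic}} and its normalization
#' \eqn{E = 1 - \mathrm{raw}/(n \log K)} (defined as 1 for K = 1, and 1 for
#' a perfectly crisp posterior); the smallest modal-class share and the mean
#' posterior probability among patients assigned to each class, both at
#' assignment cutoff 0.5.
#'
#' @param object fitted \code{\link{lca}} model.
#' @param posterior optional posterior matrix overriding the stored one.
#' @return a list of class \code{lca_diagnostics} with fields \code{aic},
#'   \code{bic}, \code{sabic}, \code{entropy_raw}, \code{entropy_normalized},
#'   \code{min_class_share}, \code{mean_posterior_per_class},
#'   \code{unassigned_fraction}, \code{K}, \code{n}.
#' @export
lca_diagnostics <- function(object, posterior = NULL) {
  stopifnot(inherits(object, "lca"))
  theta <- posterior %||% object$posterior
  n <- nrow(theta); K <- object$K
  ll <- object$loglik; p <- object$n_params
  tl <- theta * log(theta)
  tl[theta == 0] <- 0
  raw <- -sum(tl)
  E <- if (K == 1L) 1 else 1 - raw / (n * log(K))
  a <- suppressMessages(assign_classes(theta, cutoff = 0.5))
  shares <- tabulate(a$class, nbins = K) / n
  meanpost <- vapply(seq_len(K), function(c)
    if (any(a$class == c, na.rm = TRUE))
      mean(theta[which(a$class == c), c]) else NA_real_, 1)
  structure(list(
    aic = -2 * ll + 2 * p,
    bic = -2 * ll + p * log(n),
    sabic = -2 * ll + p * log((n + 2) / 24),
    entropy_raw = raw,
    entropy_normalized = E,
    min_class_share = min(shares),
    mean_posterior_per_class = meanpost,
    unassigned_fraction = attr(a, "unassigned_fraction"),
    K = K, n = n
  ), class = "lca_diagnostics")
}

#' @export
print.lca_diagnostics <- function(x, ...) {
  cat(sprintf("K = %d: AIC %.2f  BIC %.2f  SABIC %.2f  entropy %.4f\n",
              x$K, x$aic, x$bic, x$sabic, x$entropy_normalized))
  invisible(x)
}

#' Parametric bootstrap likelihood-ratio test for K vs K-1 classes
#'
#' Tests whether a K-class model fits better than a (K-1)-class model. The
#' observed statistic is \eqn{2(LL_K - LL_{K-1})}. B datasets are simulated
#' from the fitted (K-1)-class model (the null), both models are refit on
#' each, and the p-value is \eqn{(1 + \#\{T_b \ge T_{obs}\})/(B + 1)}.
#' This replaces analytic mixture LRT reference distributions, whose
#' regularity conditions fail at the boundary.
#'
#' @param formula,data as in \code{\link{lca}}.
#' @param K number of classes under the alternative (\eqn{\ge 2}).
#' @param B number of bootstrap replicates (\eqn{\ge 19}).
#' @param nrep EM restarts per fit (bootstrap refits use
#'   \code{max(3, nrep %/% 3)} restarts to keep the test affordable).
#' @param seed integer seed; replicate b simulates with seed
#'   \code{seed + 1000 + b}.
#' @param ... passed to \code{\link{lca}} (e.g. \code{tol}, \code{max_iter}).
#' @return list of class \code{lca_blrt}: \code{statistic}, \code{p_value},
#'   \code{B_used}, \code{boot_stats}, plus both fitted models.
#' @export
lca_bootstrap_lrt <- function(formula, data, K, B = 99L, nrep = 10L,
                              seed = 1L, ...) {
  K <- as.integer(K); B <- as.integer(B)
  if (K < 2L) stop2("K must be >= 2")
  if (B < 19L) stop2("B must be >= 19")
  fit0 <- lca(formula, data, K = K - 1L, nrep = nrep, seed = seed, ...)
  fit1 <- lca(formula, data, K = K, nrep = nrep, seed = seed, ...)
  obs <- 2 * (fit1$loglik - fit0$loglik)
  nrep_b <- max(3L, nrep %/% 3L)
  boot <- rep(NA_real_, B)
  f_ind <- stats::reformulate(fit0$indicators)
  for (b in seq_len(B)) {
    sim <- simulate(fit0, seed = seed + 1000L + b)
    bs <- tryCatch({
      b0 <- lca(f_ind, sim, K = K - 1L, nrep = nrep_b, seed = seed + b, ...)
      b1 <- lca(f_ind, sim, K = K, nrep = nrep_b, seed = seed + b, ...)
      # non-converged runs are kept: on flat mixture ridges EM may exhaust
      # max_iter while the attained log-likelihood is already stable
      2 * (b1$loglik - b0$loglik)
    }, error = function(e) NA_real_)
    boot[b] <- bs
  }
  used <- sum(!is.na(boot))
  if (used < 0.9 * B)
    warn2("only ", used, " of ", B, " bootstrap replicates could be fitted")
  p <- (1 + sum(boot >= obs, na.rm = TRUE)) / (used + 1)
  structure(list(statistic = obs, p_value = p, B = B, B_used = used,
                 boot_stats = boot, fit_null = fit0, fit_alt = fit1),
            class = "lca_blrt")
}

#' @export
print.lca_blrt <- function(x, ...) {
  cat(sprintf("Bootstrap LRT (K = %d vs %d): 2*dLL = %.3f, p = %.4f (B = %d)\n",
              x$fit_alt$K, x$fit_null$K, x$statistic, x$p_value, x$B_used))
  invisible(x)
}

#' Scan candidate numbers of latent classes and select a model
#'
#' Fits every K in \code{K_range}, computes \code{\link{lca_diagnostics}}
#' and applies the selection rules: among the candidates that pass the hard
#' criteria — normalized entropy \eqn{\ge 0.8}, mean posterior probability
#' \eqn{\ge 0.5} in every class, smallest modal class share \eqn{> 5\%} —
#' the model minimizing BIC is selected (AIC replaces BIC when n < 500;
#' SABIC is reported alongside). Optionally the bootstrap likelihood-ratio
#' test against K-1 is added as a criterion.
#'
#' @param formula,data as in \code{\link{lca}}.
#' @param K_range integer vector of candidate class counts.
#' @param nrep,max_iter,tol,seed EM settings per fit.
#' @param entropy_min,mean_posterior_min,min_share hard-criterion thresholds.
#' @param use_blrt add a bootstrap LRT significance requirement.
#' @param blrt_B,blrt_alpha bootstrap replicates and level.
#' @param verbose print progress.
#' @return object of class \code{lca_scan}: list with \code{fits},
#'   \code{table} (per-K diagnostics and criterion pass/fail),
#'   \code{selected_K} (NA when no candidate is admissible) and
#'   \code{selected} (the chosen fit, reordered by descending prevalence).
#' @export
lca_scan <- function(formula = ~ ., data, K_range = 1:6, nrep = 10L,
                     max_iter = 1000L, tol = 1e-8, seed = 1L,
                     entropy_min = 0.8, mean_posterior_min = 0.5,
                     min_share = 0.05, use_blrt = FALSE, blrt_B = 99L,
                     blrt_alpha = 0.05, verbose = FALSE) {
  K_range <- sort(unique(as.integer(K_range)))
  if (length(K_range) == 0L) stop2("K_range must be non-empty")
  fits <- list(); rows <- list()
  for (K in K_range) {
    fit <- lca(formula, data, K = K, nrep = nrep, max_iter = max_iter,
               tol = tol, seed = seed)
    d <- lca_diagnostics(fit)
    blrt_p <- NA_real_
    if (use_blrt && K >= 2L) {
      blrt_p <- lca_bootstrap_lrt(formula, data, K = K, B = blrt_B,
                                  nrep = nrep, seed = seed,
                                  max_iter = max_iter, tol = tol)$p_value
    }
    pass_entropy <- d$entropy_normalized >= entropy_min
    pass_post <- all(d$mean_posterior_per_class >= mean_posterior_min,
                     na.rm = TRUE)
    pass_share <- d$min_class_share > min_share
    pass_blrt <- if (use_blrt && K >= 2L) blrt_p < blrt_alpha else TRUE
    rows[[as.character(K)]] <- data.frame(
      K = K, loglik = fit$loglik, n_params = fit$n_params,
      aic = d$aic, bic = d$bic, sabic = d$sabic,
      entropy = d$entropy_normalized, min_class_share = d$min_class_share,
      min_mean_posterior = min(d$mean_posterior_per_class, na.rm = TRUE),
      blrt_p = blrt_p,
      pass_entropy = pass_entropy, pass_posterior = pass_post,
      pass_share = pass_share, pass_blrt = pass_blrt,
      admissible = pass_entropy && pass_post && pass_share && pass_blrt)
    fits[[as.character(K)]] <- fit
    if (verbose)
      cat(sprintf("K=%d BIC=%.1f entropy=%.3f admissible=%s\n", K, d$bic,
                  d$entropy_normalized, rows[[as.character(K)]]$admissible))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  crit <- if (nrow(data) < 500) "aic" else "bic"
  adm <- tab[tab$admissible, , drop = FALSE]
  selected_K <- if (nrow(adm)) adm$K[which.min(adm[[crit]])] else NA_integer_
  selected <- if (!is.na(selected_K))
    reorder_classes(fits[[as.character(selected_K)]]) else NULL
  structure(list(fits = fits, table = tab, selected_K = selected_K,
                 selected = selected, criterion = crit),
            class = "lca_scan")
}

#' @export
print.lca_scan <- function(x, ...) {
  cat("Latent class model scan (selection criterion: ",
      toupper(x$criterion), ")\n", sep = "")
  print(x$table[, c("K", "loglik", "aic", "bic", "sabic", "entropy",
                    "min_class_share", "admissible")], digits = 6)
  if (is.na(x$selected_K)) cat("No admissible model.\n")
  else cat("Selected K =", x$selected_K, "\n")
  invisible(x)
}

#' @export
plot.lca_scan <- function(x, ...) {
  tab <- x$table
  graphics::matplot(tab$K, cbind(tab$bic, tab$sabic, tab$aic), type = "b",
                    pch = 1:3, lty = 1, xlab = "number of classes",
                    ylab = "information criterion", ...)
  graphics::legend("topright", c("BIC", "SABIC", "AIC"), pch = 1:3, lty = 1,
                   col = 1:3)
  if (!is.na(x$selected_K)) graphics::abline(v = x$selected_K, lty = 3)
  invisible(x)
}
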