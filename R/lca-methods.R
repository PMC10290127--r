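#' @export
print.lca <- function(x, digits = 4, ...) {
  cat("Latent class model (", x$K, " classes, ", x$n_obs, " observations)\n",
      sep = "")
  cat("  logLik ", format(x$loglik, nsmall = 2), "  free parameters ",
      x$n_params, if (!x$converged) "  [NOT converged]", "\n", sep = "")
  cat("  class prevalences:",
      paste(format(round(x$pi, digits)), collapse = " "), "\n")
  cat("  indicators:", paste(x$indicators, collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.lca <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' Extract latent class parameters
#'
#' @param object fitted \code{\link{lca}} model.
#' @param ... unused.
#' @return named list with \code{pi} (class prevalences) and \code{rho}
#'   (item-response probability matrices).
#' @export
coef.lca <- function(object, ...) {
  list(pi = object$pi, rho = object$rho)
}

#' @export
summary.lca <- function(object, cutoff = 0.5, ...) {
  d <- lca_diagnostics(object)
  a <- assign_classes(object$posterior, cutoff = cutoff)
  structure(list(fit = object, diagnostics = d, assignment_summary = table(
    factor(a$class, levels = seq_len(object$K)), useNA = "ifany"),
    unassigned_fraction = attr(a, "unassigned_fraction")),
    class = "summary.lca")
}

#' @export
print.summary.lca <- function(x, ...) {
  print(x$fit)
  d <- x$diagnostics
  cat(sprintf("  AIC %.2f  BIC %.2f  SABIC %.2f\n", d$aic, d$bic, d$sabic))
  cat(sprintf("  entropy (normalized) %.4f  raw %.2f\n",
              d$entropy_normalized, d$entropy_raw))
  cat(sprintf("  smallest modal class share %.4f; unassigned fraction %.4f\n",
              d$min_class_share, x$unassigned_fraction))
  cat("  mean posterior per assigned class:",
      paste(sprintf("%.3f", d$mean_posterior_per_class), collapse = " "), "\n")
  invisible(x)
}

#' Posterior class membership and class prediction
#'
#' \code{type = "posterior"} returns the n x K matrix of membership
#' probabilities \eqn{\theta_{ic} \propto \pi_c \prod_j \rho_{j,c,y_{ij}}};
#' \code{type = "class"} additionally applies modal assignment under
#' \code{cutoff} (see \code{\link{assign_classes}}).
#'
#' @param object fitted \code{\link{lca}} model.
#' @param newdata optional data.frame with the model's indicator columns;
#'   defaults to the training data posterior.
#' @param type \code{"posterior"} or \code{"class"}.
#' @param cutoff minimum posterior for assignment when \code{type="class"}.
#' @param ... unused.
#' @export
predict.lca <- function(object, newdata = NULL,
                        type = c("posterior", "class"), cutoff = 0.5, ...) {
  type <- match.arg(type)
  theta <- if (is.null(newdata)) object$posterior else
    .lca_eval(object, newdata)$theta
  if (type == "posterior") return(theta)
  assign_classes(theta, cutoff = cutoff)
}

#' Evaluate the mixture log-likelihood of a fitted model on a cohort
#'
#' Computes \eqn{\sum_i \log \sum_c \pi_c \prod_j \rho_{j,c,y_{ij}}} in log
#' space. Unseen indicator levels raise an error naming the indicator and
#' level.
#'
#' @param object fitted \code{\link{lca}} model.
#' @param data data.frame with the model's indicator columns.
#' @return scalar log-likelihood.
#' @export
lca_loglik <- function(object, data) {
  sum(.lca_eval(object, data)$logdens)
}

#' Modal class assignment under a posterior cutoff
#'
#' Each patient receives the class with the largest posterior probability,
#' provided that maximum reaches \code{cutoff}; otherwise the patient is
#' unassigned (\code{NA}). Exact ties are broken toward the lowest class
#' index (a message reports the count).
#'
#' @param posterior n x K matrix of membership probabilities (or an
#'   \code{\link{lca}} fit, whose training posterior is used).
#' @param cutoff assignment threshold in (0, 1]; 0.5 is the conventional
#'   training-cohort choice, while projection onto an external cohort uses
#'   the highest probability with no threshold (see
#'   \code{\link{project_classes}}).
#' @return data.frame with columns \code{class} (integer or NA) and
#'   \code{max_posterior}; attributes \code{cutoff} and
#'   \code{unassigned_fraction}.
#' @export
assign_classes <- function(posterior, cutoff = 0.5) {
  if (inherits(posterior, "lca")) posterior <- posterior$posterior
  if (!is.matrix(posterior)) posterior <- as.matrix(posterior)
  if (!(cutoff > 0 && cutoff <= 1)) stop2("cutoff must be in (0, 1]")
  mx <- apply(posterior, 1L, max)
  lab <- apply(posterior, 1L, which.max)   # ties -> lowest index
  nt <- sum(rowSums(posterior == mx) > 1L)
  if (nt > 0) message(nt, " tied modal assignment(s) broken toward the ",
                      "lowest class index")
  lab[mx < cutoff] <- NA_integer_
  out <- data.frame(class = as.integer(lab), max_posterior = mx)
  attr(out, "cutoff") <- cutoff
  attr(out, "unassigned_fraction") <- mean(is.na(lab))
  out
}

#' Reorder latent classes canonically or to match a reference model
#'
#' With no reference, classes are sorted by descending prevalence (the
#' canonical ordering used for reporting). With a reference model of the
#' same structure, classes are matched to the reference classes by
#' minimizing the total L1 distance between item-response vectors over all
#' K! permutations, which reproduces cross-cohort correspondences (e.g. a
#' right-colon-dominant class in a new cohort maps onto the reference
#' right-colon class). Prevalences, item-response rows and the stored
#' posterior columns are permuted consistently; the log-likelihood is
#' unchanged.
#'
#' @param object fitted \code{\link{lca}} model.
#' @param reference optional \code{\link{lca}} model with the same K and
#'   indicator structure.
#' @return the reordered \code{lca} object, with attribute
#'   \code{"permutation"} giving the map (new position -> old class index).
#' @export
reorder_classes <- function(object, reference = NULL) {
  stopifnot(inherits(object, "lca"))
  K <- object$K
  if (is.null(reference)) {
    perm <- order(object$pi, decreasing = TRUE)
  } else {
    stopifnot(inherits(reference, "lca"))
    if (reference$K != K ||
        !identical(reference$indicators, object$indicators) ||
        !identical(reference$levels, object$levels))
      stop2("reference model has a different class/indicator structure")
    # cost[c_new, c_ref] = L1 distance between rho vectors
    cost <- matrix(0, K, K)
    for (j in object$indicators)
      for (a in seq_len(K)) for (b in seq_len(K))
        cost[a, b] <- cost[a, b] +
          sum(abs(object$rho[[j]][a, ] - reference$rho[[j]][b, ]))
    best <- NULL; best_cost <- Inf
    for (p in permutations(K)) {
      # position b gets object's class p[b]
      cc <- sum(cost[cbind(unlist(p), seq_len(K))])
      if (cc < best_cost) { best_cost <- cc; best <- unlist(p) }
    }
    perm <- best
  }
  object$pi <- object$pi[perm]
  names(object$pi) <- paste0("class", seq_len(K))
  for (j in object$indicators) {
    object$rho[[j]] <- object$rho[[j]][perm, , drop = FALSE]
    rownames(object$rho[[j]]) <- paste0("class", seq_len(K))
  }
  object$posterior <- object$posterior[, perm, drop = FALSE]
  colnames(object$posterior) <- paste0("class", seq_len(K))
  attr(object, "permutation") <- perm
  object
}

#' Project a fitted latent class model onto a new cohort
#'
#' Computes posterior membership probabilities for patients in a new cohort
#' under the training-cohort parameters and assigns each patient the class
#' with the highest probability. Projection uses no posterior threshold by
#' default (\code{cutoff = 0}, i.e. every patient is assigned), in contrast
#' to the 0.5 cutoff conventional for the training cohort.
#'
#' @param object fitted \code{\link{lca}} model.
#' @param newdata data.frame using the same indicator level sets.
#' @param cutoff assignment threshold; \code{0} (assign everyone) by default.
#' @return list with \code{posterior} (matrix) and \code{assignment}
#'   (data.frame from \code{\link{assign_classes}}).
#' @export
project_classes <- function(object, newdata, cutoff = 0) {
  theta <- .lca_eval(object, newdata)$theta
  eff <- if (cutoff <= 0) .Machine$double.xmin else cutoff
  list(posterior = theta, assignment = assign_classes(theta, cutoff = eff))
}

#' Simulate indicator data from a fitted latent class model
#'
#' Draws \code{n} patients: class from the fitted prevalences, then each
#' indicator from its class-conditional distribution. Used by the
#' parametric bootstrap likelihood-ratio test.
#'
#' @param object fitted \code{\link{lca}} model.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param n patients per dataset (default: the training size).
#' @param ... unused.
#' @return a data.frame when \code{nsim = 1}, else a list of data.frames.
#' @export
simulate.lca <- function(object, nsim = 1, seed = NULL, n = NULL, ...) {
  n <- as.integer(n %||% object$n_obs)
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  if (!is.null(seed)) set.seed(seed)
  one <- function() {
    z <- sample.int(object$K, n, replace = TRUE, prob = object$pi)
    cols <- lapply(object$indicators, function(j) {
      rho <- object$rho[[j]]
      u <- stats::runif(n)
      cum <- t(apply(rho, 1L, cumsum))
      k <- rowSums(u > cum[z, , drop = FALSE]) + 1L
      factor(object$levels[[j]][k], levels = object$levels[[j]])
    })
    names(cols) <- object$indicators
    out <- as.data.frame(cols, stringsAsFactors = FALSE)
    out$true_class <- z
    out
  }
  if (nsim == 1L) one() else replicate(nsim, one(), simplify = FALSE)
}

#' Class profile plot
#'
#' Barplot of item-response probabilities per indicator, one panel per
#' indicator with class-coloured bars — the standard way to read a latent
#' class solution.
#'
#' @param x fitted \code{\link{lca}} model.
#' @param ... passed to \code{barplot}.
#' @export
plot.lca <- function(x, ...) {
  J <- length(x$indicators)
  op <- graphics::par(mfrow = c(1, J), mar = c(6, 3, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  for (j in x$indicators) {
    graphics::barplot(x$rho[[j]], beside = TRUE, las = 2, main = j,
                      ylim = c(0, 1),
                      legend.text = if (j == x$indicators[1])
                        rownames(x$rho[[j]]) else FALSE, ...)
  }
  invisible(x)
}
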