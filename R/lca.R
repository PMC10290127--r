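#' Fit a latent class model to categorical indicators
#'
#' Maximum-likelihood estimation of the finite mixture of products of
#' multinomials
#' \deqn{P(Y_i) = \sum_{c=1}^{K} \pi_c \prod_{j=1}^{J} \rho_{j,c,y_{ij}}}
#' by expectation-maximization. Observations are collapsed to unique
#' response patterns with counts before iterating, so each EM step costs
#' O(patterns x K x J) regardless of cohort size. Multiple random restarts
#' (class-membership probabilities and item-response rows drawn from flat
#' Dirichlet distributions) guard against local maxima; the restart with the
#' highest log-likelihood is returned.
#'
#' @param formula one-sided formula naming the indicator columns, e.g.
#'   \code{~ age_group + sex + race + site + stage}. With \code{~ .} (the
#'   default) all factor/character columns except
#'   \code{patient_id}, \code{time_months}, \code{event}, \code{subtype},
#'   \code{true_class} are used.
#' @param data a data.frame; indicator columns are coerced to factors (their
#'   existing level sets are kept).
#' @param K number of latent classes (\eqn{\ge 1}).
#' @param nrep number of random EM restarts.
#' @param max_iter maximum EM iterations per restart.
#' @param tol convergence tolerance on the log-likelihood increase.
#' @param seed integer; restart r uses seed \code{seed + r - 1}.
#' @param verbose print per-restart log-likelihoods.
#' @return an object of class \code{"lca"}: a list with components
#'   \code{pi} (class prevalences, length K), \code{rho} (named list of
#'   \code{K x m_j} item-response matrices), \code{loglik}, \code{n_params}
#'   (\eqn{(K-1) + K\sum_j (m_j-1)}), \code{n_obs}, \code{posterior}
#'   (n x K membership probabilities for the training rows), \code{converged},
#'   \code{n_iterations}, \code{restart_loglik}, \code{ll_trace} (per-iteration
#'   log-likelihoods of the best restart), \code{levels}, \code{indicators},
#'   \code{n_dropped_rows}, \code{settings} and \code{call}.
#' @details Rows with a missing value in any indicator are excluded before
#'   fitting (the count is messaged and stored). An indicator with a single
#'   observed level carries no information and is dropped from the
#'   likelihood with a warning. Item-response probabilities are floored at
#'   1e-12 inside log computations only; reported estimates are unfloored,
#'   so boundary cells can be exactly 0 or 1.
#' @examples
#' cohort <- simulate_cohort(default_config(n_patients = 600))
#' fit <- lca(~ age_group + sex + race + site + stage, cohort, K = 2,
#'            nrep = 3, seed = 1)
#' fit
#' @seealso \code{\link{lca_scan}}, \code{\link{project_classes}},
#'   \code{\link{assign_classes}}, \code{\link{reorder_classes}}
#' @export
lca <- function(formula = ~ ., data, K, nrep = 30L, max_iter = 1000L,
                tol = 1e-10, seed = 1L, verbose = FALSE) {
  cl <- match.call()
  ind_names <- .lca_indicators(formula, data)
  K <- as.integer(K)
  if (K < 1L) stop2("K must be >= 1")

  Y <- data[, ind_names, drop = FALSE]
  for (j in ind_names) if (!is.factor(Y[[j]])) Y[[j]] <- factor(Y[[j]])
  complete <- stats::complete.cases(Y)
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    message(n_dropped, " row(s) with missing indicator values excluded")
  Y <- Y[complete, , drop = FALSE]
  n <- nrow(Y)
  if (n < K) stop2("need at least K complete observations (n = ", n, ")")

  # drop uninformative indicators (single observed level)
  single <- vapply(Y, function(f) length(unique(f[!is.na(f)])) < 2L, TRUE)
  if (any(single)) {
    warn2("indicator(s) with a single observed level dropped from the ",
          "likelihood: ", paste(ind_names[single], collapse = ", "))
    ind_names <- ind_names[!single]
    Y <- Y[, ind_names, drop = FALSE]
    if (length(ind_names) == 0L) stop2("no informative indicators left")
  }
  levs <- lapply(Y, levels)
  m <- vapply(levs, length, 1L)

  ymat <- vapply(Y, as.integer, integer(n))
  if (n == 1L) ymat <- matrix(ymat, nrow = 1L)

  # collapse to unique response patterns
  key <- do.call(paste, c(as.data.frame(ymat), sep = "\r"))
  uk <- !duplicated(key)
  Yp <- ymat[uk, , drop = FALSE]
  pat_index <- match(key, key[uk])
  w <- as.numeric(tabulate(pat_index, nbins = nrow(Yp)))
  if (K > nrow(Yp))
    stop2("K = ", K, " exceeds the number of distinct response patterns (",
          nrow(Yp), ")")

  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)

  best <- NULL
  restart_ll <- numeric(nrep)
  for (r in seq_len(nrep)) {
    set.seed(seed + r - 1L)
    init <- .lca_random_init(K, m)
    run <- .lca_em(Yp, w, m, K, init, max_iter = max_iter, tol = tol)
    restart_ll[r] <- run$loglik
    if (verbose)
      cat(sprintf("restart %d: logLik %.6f (%d iterations)\n",
                  r, run$loglik, run$n_iterations))
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }

  names(best$pi) <- paste0("class", seq_len(K))
  for (j in seq_along(best$rho)) {
    dimnames(best$rho[[j]]) <- list(paste0("class", seq_len(K)), levs[[j]])
  }
  names(best$rho) <- ind_names

  theta_full <- best$theta[pat_index, , drop = FALSE]
  colnames(theta_full) <- paste0("class", seq_len(K))

  structure(list(
    call = cl,
    K = K,
    pi = best$pi,
    rho = best$rho,
    loglik = best$loglik,
    n_params = (K - 1L) + K * sum(m - 1L),
    n_obs = n,
    posterior = theta_full,
    converged = best$converged,
    n_iterations = best$n_iterations,
    restart_loglik = restart_ll,
    ll_trace = best$ll_trace,
    levels = levs,
    indicators = ind_names,
    n_dropped_rows = n_dropped,
    patient_id = if (!is.null(data$patient_id)) data$patient_id[complete] else NULL,
    settings = list(nrep = nrep, max_iter = max_iter, tol = tol, seed = seed)
  ), class = "lca")
}

# resolve indicator column names from a one-sided formula
.lca_indicators <- function(formula, data) {
  stopifnot(inherits(formula, "formula"))
  if (length(formula) != 2L)
    stop2("formula must be one-sided, e.g. ~ age_group + sex")
  vars <- all.vars(formula)
  if (identical(vars, character(0)) || identical(deparse(formula[[2]]), ".")) {
    reserved <- c("patient_id", "time_months", "event", "subtype", "true_class")
    cand <- setdiff(names(data), reserved)
    vars <- cand[vapply(data[cand], function(x)
      is.factor(x) || is.character(x), TRUE)]
    if (length(vars) == 0L) stop2("no categorical indicator columns found")
  }
  missing <- setdiff(vars, names(data))
  if (length(missing))
    stop2("indicator column(s) not in data: ", paste(missing, collapse = ", "))
  vars
}

.lca_random_init <- function(K, m) {
  rdirich <- function(k) { g <- stats::rgamma(k, 1); g / sum(g) }
  list(pi = rdirich(K),
       rho = lapply(m, function(mj)
         t(vapply(seq_len(K), function(c) rdirich(mj), numeric(mj)))))
}

# EM on collapsed patterns. Yp: P x J integer matrix, w: pattern counts.
.lca_em <- function(Yp, w, m, K, init, max_iter, tol, floor = 1e-12) {
  P <- nrow(Yp); J <- ncol(Yp); n <- sum(w)
  pi <- init$pi
  rho <- init$rho
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  theta <- NULL
  estep <- function() {
    logA <- matrix(log(pi), P, K, byrow = TRUE)
    for (j in seq_len(J)) {
      lr <- log(pmax(rho[[j]], floor))      # K x m_j
      logA <- logA + t(lr)[Yp[, j], , drop = FALSE]
    }
    ls <- logsumexp_rows(logA)
    list(ll = sum(w * ls), theta = exp(logA - ls))
  }
  for (it in seq_len(max_iter)) {
    e <- estep()
    ll <- e$ll; theta <- e$theta
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    # M-step
    wt <- theta * w
    cs <- colSums(wt)
    pi <- cs / n
    for (j in seq_len(J)) {
      acc <- rowsum(wt, group = Yp[, j])    # observed levels x K
      full <- matrix(0, m[j], K)
      full[as.integer(rownames(acc)), ] <- acc
      rho[[j]] <- t(full) / cs
    }
  }
  if (!converged) {
    # max_iter ended on an M-step: refresh ll/theta so the returned
    # parameters, likelihood and posterior are mutually consistent
    e <- estep()
    ll <- e$ll; theta <- e$theta
    ll_trace <- c(ll_trace, ll)
  }
  list(pi = pi, rho = rho, loglik = ll, theta = theta,
       converged = converged, n_iterations = length(ll_trace),
       ll_trace = ll_trace)
}

# posterior/likelihood evaluation for arbitrary data under fitted parameters;
# returns list(logdens_rows, theta)
.lca_eval <- function(object, data, floor = 1e-12) {
  K <- object$K
  for (j in object$indicators) {
    if (!j %in% names(data)) stop2("missing indicator column '", j, "'")
    v <- as.character(data[[j]])
    bad <- !is.na(v) & !(v %in% object$levels[[j]])
    if (any(bad))
      stop2("unseen level '", v[which(bad)[1]], "' in indicator '", j, "'")
  }
  keep <- rep(TRUE, nrow(data))
  for (j in object$indicators) keep <- keep & !is.na(data[[j]])
  if (!all(keep)) stop2("missing indicator values; validate the cohort first")
  n <- nrow(data)
  logA <- matrix(log(object$pi), n, K, byrow = TRUE)
  for (j in object$indicators) {
    k <- match(as.character(data[[j]]), object$levels[[j]])
    lr <- log(pmax(object$rho[[j]], floor))
    logA <- logA + t(lr)[k, , drop = FALSE]
  }
  ls <- logsumexp_rows(logA)
  theta <- exp(logA - ls)
  colnames(theta) <- paste0("class", seq_len(K))
  list(logdens = ls, theta = theta)
}
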