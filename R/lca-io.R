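#' Serialize a fitted latent class model as YAML
#'
#' Writes the parameters and metadata needed to reuse a fit — level sets,
#' prevalences, item-response probabilities, log-likelihood, parameter
#' count, sample size and EM settings — in a human-readable form.
#' \code{read_lca_model} reconstructs an \code{\link{lca}} object suitable
#' for \code{\link{project_classes}}, \code{predict} and
#' \code{\link{reorder_classes}} (the training posterior is not stored).
#'
#' @param object fitted \code{\link{lca}} model.
#' @param path YAML file path.
#' @return \code{read_lca_model} returns an object of class \code{lca};
#'   \code{write_lca_model} returns \code{path} invisibly.
#' @export
write_lca_model <- function(object, path) {
  stopifnot(inherits(object, "lca"))
  obj <- list(
    K = object$K,
    indicators = object$indicators,
    levels = object$levels,
    pi = as.numeric(object$pi),
    rho = lapply(object$rho, function(m)
      lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))),
    loglik = object$loglik,
    n_params = object$n_params,
    n_obs = object$n_obs,
    converged = object$converged,
    n_iterations = object$n_iterations,
    settings = object$settings
  )
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_lca_model
#' @export
read_lca_model <- function(path) {
  obj <- yaml::read_yaml(path)
  K <- as.integer(obj$K)
  rho <- lapply(obj$indicators, function(j) {
    m <- do.call(rbind, lapply(obj$rho[[j]], as.numeric))
    dimnames(m) <- list(paste0("class", seq_len(K)), obj$levels[[j]])
    m
  })
  names(rho) <- obj$indicators
  pi <- as.numeric(obj$pi)
  names(pi) <- paste0("class", seq_len(K))
  if (abs(sum(pi) - 1) > 1e-8 ||
      any(vapply(rho, function(m) max(abs(rowSums(m) - 1)), 1) > 1e-8))
    stop2("stored parameters are not valid probability vectors")
  structure(list(
    call = NULL, K = K, pi = pi, rho = rho,
    loglik = obj$loglik, n_params = obj$n_params, n_obs = obj$n_obs,
    posterior = NULL, converged = obj$converged,
    n_iterations = obj$n_iterations, restart_loglik = NULL, ll_trace = NULL,
    levels = obj$levels[obj$indicators], indicators = obj$indicators,
    n_dropped_rows = 0L, patient_id = NULL, settings = obj$settings
  ), class = "lca")
}
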