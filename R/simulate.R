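#' Simulate a cohort with latent-class and competing-risks structure
#'
#' For each patient a latent class \eqn{z} is drawn from the prevalence
#' vector \eqn{\pi}; each categorical indicator is drawn independently from
#' its class-conditional distribution \eqn{\rho_{j,z,\cdot}} (local
#' independence); latent death times for the two competing causes are
#' exponential with rates \eqn{\lambda_c \times \mathrm{HR}_{c,z}} (cause 1
#' further multiplied by the subtype hazard ratio when a subtype is
#' configured); censoring is the minimum of exponential dropout and the
#' administrative horizon. The observed time is the minimum of all latent
#' times and the event code records which cause won (0 = censored).
#'
#' @param config a \code{\link{generator_config}}.
#' @param n override for \code{config$n_patients}.
#' @param seed override for \code{config$seed}; the draw is deterministic
#'   given the seed.
#' @return a \code{data.frame} with columns \code{patient_id}, one factor per
#'   indicator, \code{time_months}, \code{event} (0 censored, 1 cancer
#'   death, 2 other-cause death), optional \code{subtype}, and
#'   \code{true_class}.
#' @examples
#' cohort <- simulate_cohort(default_config(n_patients = 500))
#' table(cohort$event)
#' @export
simulate_cohort <- function(config, n = NULL, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  n <- as.integer(n %||% config$n_patients)
  seed <- as.integer(seed %||% config$seed)
  if (n < 1L) stop2("n must be positive")

  K <- length(config$class_prevalence)
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  z <- sample.int(K, n, replace = TRUE, prob = config$class_prevalence)

  ind <- lapply(config$item_response, function(rho) {
    lev <- colnames(rho)
    u <- stats::runif(n)
    # inverse-CDF draw from the class-specific rows
    cum <- t(apply(rho, 1L, cumsum))
    k <- rowSums(u > cum[z, , drop = FALSE]) + 1L
    factor(lev[k], levels = lev)
  })

  subtype <- NULL
  sub_mult <- rep(1, n)
  if (!is.null(config$subtype_given_class)) {
    sm <- config$subtype_given_class
    lev <- colnames(sm)
    u <- stats::runif(n)
    cum <- t(apply(sm, 1L, cumsum))
    s <- rowSums(u > cum[z, , drop = FALSE]) + 1L
    subtype <- factor(lev[s], levels = lev)
    sub_mult <- config$subtype_cause1_hr[s]
  }

  rate1 <- config$baseline_hazards[1] * config$cause_hr[z, 1] * sub_mult
  rate2 <- config$baseline_hazards[2] * config$cause_hr[z, 2]
  t1 <- stats::rexp(n, rate1)
  t2 <- stats::rexp(n, rate2)
  gamma <- if (length(config$dropout_hazard) == 1L)
    rep(config$dropout_hazard, n) else config$dropout_hazard[z]
  tdrop <- ifelse(gamma > 0, stats::rexp(n, pmax(gamma, 1e-300)), Inf)
  tcens <- pmin(tdrop, config$censor_admin_months)

  time <- pmin(t1, t2, tcens)
  # at exact ties an observed death takes precedence over censoring
  event <- ifelse(tcens < pmin(t1, t2), 0L, ifelse(t1 <= t2, 1L, 2L))

  out <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    ind,
    time_months = time,
    event = event,
    stringsAsFactors = FALSE
  )
  if (!is.null(subtype)) out$subtype <- subtype
  out$true_class <- z
  out
}

# save/restore the global RNG state so simulation does not disturb callers
.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
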