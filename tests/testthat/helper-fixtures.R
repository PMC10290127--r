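# shared fixtures and independent oracles

std_formula <- ~ age_group + sex + race + site + stage

# tiny two-indicator, two-level toy used for the grid-search oracle
toy6 <- function() {
  data.frame(
    a = factor(c("x", "x", "x", "y", "y", "x"), levels = c("x", "y")),
    b = factor(c("u", "u", "v", "v", "v", "u"), levels = c("u", "v"))
  )
}

# brute-force maximizer of the 2-class LCA likelihood on a 2x2-indicator toy:
# coarse grid over (pi, rho) followed by long EM polishing from the best
# grid points; independent of the package EM defaults (tol 1e-12, many
# iterations, deterministic starts).
toy_grid_oracle <- function(data, grid_n = 6) {
  ymat <- cbind(as.integer(data$a), as.integer(data$b))
  g <- seq(0.05, 0.95, length.out = grid_n)
  best <- -Inf; best_par <- NULL
  ll_fun <- function(pi1, r) {
    ll <- 0
    for (i in seq_len(nrow(ymat))) {
      d1 <- pi1; d2 <- 1 - pi1
      for (j in 1:2) {
        pj1 <- if (ymat[i, j] == 1L) r[j, 1] else 1 - r[j, 1]
        pj2 <- if (ymat[i, j] == 1L) r[j, 2] else 1 - r[j, 2]
        d1 <- d1 * pj1; d2 <- d2 * pj2
      }
      ll <- ll + log(d1 + d2)
    }
    ll
  }
  for (pi1 in g) for (ra1 in g) for (ra2 in g) for (rb1 in g) for (rb2 in g) {
    r <- rbind(c(ra1, ra2), c(rb1, rb2))
    ll <- ll_fun(pi1, r)
    if (ll > best) { best <- ll; best_par <- list(pi1 = pi1, r = r) }
  }
  # polish with a plain (re-derived) EM at fine tolerance
  pi <- c(best_par$pi1, 1 - best_par$pi1)
  rho <- list(rbind(c(best_par$r[1, 1], 1 - best_par$r[1, 1]),
                    c(best_par$r[1, 2], 1 - best_par$r[1, 2])),
              rbind(c(best_par$r[2, 1], 1 - best_par$r[2, 1]),
                    c(best_par$r[2, 2], 1 - best_par$r[2, 2])))
  rho <- lapply(1:2, function(j) t(rho[[j]]))  # K x m
  ll_old <- -Inf
  for (it in 1:100000) {
    A <- matrix(rep(pi, each = nrow(ymat)), ncol = 2)
    for (j in 1:2) A <- A * t(pmax(rho[[j]], 1e-12))[ymat[, j], ]
    ll <- sum(log(rowSums(A)))
    if (ll - ll_old < 1e-13) break
    ll_old <- ll
    th <- A / rowSums(A)
    pi <- colMeans(th)
    for (j in 1:2) {
      acc <- rbind(colSums(th[ymat[, j] == 1L, , drop = FALSE]),
                   colSums(th[ymat[, j] == 2L, , drop = FALSE]))
      rho[[j]] <- t(acc) / colSums(th)
    }
  }
  ll
}

# hand multi-state recursion for the Aalen-Johansen CIF (independent of
# survival::survfit): returns F_k evaluated at each unique event time
aj_hand <- function(time, event) {
  ts <- sort(unique(time[event > 0]))
  n <- length(time)
  S <- 1; F1 <- 0; F2 <- 0
  out <- data.frame(time = ts, F1 = NA_real_, F2 = NA_real_, S = NA_real_)
  for (i in seq_along(ts)) {
    t <- ts[i]
    at_risk <- sum(time >= t)
    d1 <- sum(time == t & event == 1)
    d2 <- sum(time == t & event == 2)
    F1 <- F1 + S * d1 / at_risk
    F2 <- F2 + S * d2 / at_risk
    S <- S * (1 - (d1 + d2) / at_risk)
    out[i, 2:4] <- c(F1, F2, S)
  }
  out
}

# hand two-group log-rank chi-square (no ties assumed handled exactly)
logrank_hand <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  ts <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    n <- sum(time >= t); n1 <- sum(time >= t & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / max(n - 1, 1)
  }
  (O - E)^2 / V
}

# dense grid + golden-section refinement of the two-group Efron partial
# likelihood, as an oracle for the Cox log-HR
cox_grid_oracle <- function(time, status, x01) {
  plik <- function(b) {
    eta <- b * x01
    ll <- 0
    for (t in sort(unique(time[status == 1]))) {
      dead <- which(time == t & status == 1)
      risk <- which(time >= t)
      d <- length(dead)
      sum_risk <- sum(exp(eta[risk]))
      sum_dead <- sum(exp(eta[dead]))
      ll <- ll + sum(eta[dead])
      for (l in seq_len(d) - 1L)
        ll <- ll - log(sum_risk - (l / d) * sum_dead)
    }
    ll
  }
  bs <- seq(-5, 5, by = 0.001)
  lls <- vapply(bs, plik, 1)
  b0 <- bs[which.max(lls)]
  # refine around the coarse maximum
  bs2 <- seq(b0 - 0.002, b0 + 0.002, by = 1e-6)
  bs2[which.max(vapply(bs2, plik, 1))]
}

# match fitted classes to generating classes by total L1 distance on rho
match_classes <- function(fit, cfg) {
  K <- fit$K
  cost <- matrix(0, K, K)
  for (j in names(cfg$item_response))
    for (a in seq_len(K)) for (b in seq_len(K))
      cost[a, b] <- cost[a, b] +
        sum(abs(fit$rho[[j]][a, ] - cfg$item_response[[j]][b, ]))
  perms <- lcarisk:::permutations(K)
  costs <- vapply(perms, function(p) sum(cost[cbind(p, seq_len(K))]), 1)
  perms[[which.min(costs)]]  # position b of truth gets fit class perm[b]
}
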