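make_fit <- function(n = 2000, K = 2, seed = 3, nrep = 3) {
  cfg <- default_config(n_patients = n, seed = seed)
  lca(std_formula, simulate_cohort(cfg), K = K, nrep = nrep, seed = 1)
}

test_that("diagnostics follow their defining formulas", {
  fit <- make_fit()
  d <- lca_diagnostics(fit)
  expect_equal(d$aic, -2 * fit$loglik + 2 * fit$n_params)
  expect_equal(d$bic, -2 * fit$loglik + fit$n_params * log(fit$n_obs))
  expect_equal(d$sabic,
               -2 * fit$loglik + fit$n_params * log((fit$n_obs + 2) / 24))

  # hand entropy cases via a posterior override
  one_hot <- matrix(c(1, 0, 0, 1, 1, 0), ncol = 2, byrow = TRUE)
  d1 <- lca_diagnostics(fit, posterior = one_hot)
  expect_equal(d1$entropy_raw, 0)
  expect_equal(d1$entropy_normalized, 1)
  unif <- matrix(0.5, 4, 2)
  expect_equal(lca_diagnostics(fit, posterior = unif)$entropy_normalized, 0)
  mixed <- matrix(c(1, 0, 0.5, 0.5, 1, 0), ncol = 2, byrow = TRUE)
  d3 <- lca_diagnostics(fit, posterior = mixed)
  expect_equal(d3$entropy_raw, log(2), tolerance = 1e-12)
  expect_equal(d3$entropy_normalized, 2 / 3, tolerance = 1e-12)
})

test_that("K = 1 entropy is defined as 1 and BIC matches count arithmetic", {
  set.seed(4)
  d <- data.frame(a = factor(sample(c("x", "y", "z"), 400, TRUE)),
                  b = factor(sample(c("u", "v"), 400, TRUE)))
  fit <- lca(~ a + b, d, K = 1, nrep = 1, seed = 1)
  di <- lca_diagnostics(fit)
  expect_equal(di$entropy_normalized, 1)
  ll <- sum(table(d$a) * log(table(d$a) / 400)) +
    sum(table(d$b) * log(table(d$b) / 400))
  expect_equal(di$bic, -2 * ll + 3 * log(400), tolerance = 1e-8)
})

test_that("modal assignment honours the cutoff and breaks ties low", {
  th <- rbind(c(0.8181, 0.1819), c(0.49, 0.51), c(0.5, 0.5))
  a <- suppressMessages(assign_classes(th, cutoff = 0.5))
  expect_equal(a$class, c(1L, 2L, 1L))
  th3 <- rbind(c(0.45, 0.30, 0.25))
  a3 <- assign_classes(th3, cutoff = 0.5)
  expect_true(is.na(a3$class[1]))
  expect_equal(attr(a3, "unassigned_fraction"), 1)
  expect_error(assign_classes(th, cutoff = 0), "cutoff")
  expect_error(assign_classes(th, cutoff = 1.2), "cutoff")
})

test_that("bootstrap LRT is well behaved under null and alternative", {
  # null: data truly 1-class; p should not be systematically small
  set.seed(6)
  ps <- vapply(1:5, function(s) {
    d <- data.frame(a = factor(sample(c("x", "y"), 150, TRUE)),
                    b = factor(sample(c("u", "v"), 150, TRUE)),
                    c = factor(sample(c("p", "q"), 150, TRUE)))
    lca_bootstrap_lrt(~ a + b + c, d, K = 2, B = 19, nrep = 3,
                      seed = 50 + s, tol = 1e-8)$p_value
  }, 1)
  expect_gt(mean(ps > 0.05), 0.5)

  # alternative: strongly separated 2-class data, K = 2 vs 1
  rho <- rbind(c(0.95, 0.05), c(0.05, 0.95)); colnames(rho) <- c("l1", "l2")
  cfg <- generator_config(500, c(0.5, 0.5),
                          list(a = rho, b = rho, c = rho),
                          c(0.01, 0.01), cbind(c(1, 1), c(1, 1)), 100,
                          seed = 2)
  ch <- simulate_cohort(cfg)
  r <- lca_bootstrap_lrt(~ a + b + c, ch, K = 2, B = 19, nrep = 3, seed = 1,
                         tol = 1e-8)
  expect_lte(r$p_value, 0.05)  # 1/(B+1) is the smallest attainable p
  expect_error(lca_bootstrap_lrt(~ a + b + c, ch, K = 2, B = 0), "B must")
  expect_error(lca_bootstrap_lrt(~ a + b + c, ch, K = 1, B = 19), "K must")
})

test_that("model scan recovers the generating class count", {
  rho1 <- rbind(c(0.92, 0.08), c(0.10, 0.90)); colnames(rho1) <- c("l1", "l2")
  rho2 <- rbind(c(0.88, 0.12), c(0.15, 0.85)); colnames(rho2) <- c("m1", "m2")
  rho3 <- rbind(c(0.90, 0.10), c(0.08, 0.92)); colnames(rho3) <- c("n1", "n2")
  rho4 <- rbind(c(0.85, 0.15), c(0.12, 0.88)); colnames(rho4) <- c("o1", "o2")
  cfg <- generator_config(2500, c(0.6, 0.4),
                          list(a = rho1, b = rho2, c = rho3, d = rho4),
                          c(0.01, 0.01), cbind(c(1, 1), c(1, 1)), 100,
                          seed = 21)
  ch <- simulate_cohort(cfg)
  scan <- lca_scan(~ a + b + c + d, ch, K_range = 1:3, nrep = 5, tol = 1e-8,
                   seed = 1)
  expect_equal(scan$selected_K, 2L)
  expect_true(all(c("bic", "entropy", "admissible") %in% names(scan$table)))

  # vacuous single-K scan
  scan1 <- lca_scan(~ a + b + c + d, ch, K_range = 1, nrep = 2, seed = 1)
  expect_equal(scan1$selected_K, 1L)
})

test_that("AIC replaces BIC for small samples in the scan", {
  rho <- rbind(c(0.95, 0.05), c(0.05, 0.95)); colnames(rho) <- c("l1", "l2")
  cfg <- generator_config(300, c(0.5, 0.5), list(a = rho, b = rho, c = rho),
                          c(0.01, 0.01), cbind(c(1, 1), c(1, 1)), 100,
                          seed = 3)
  ch <- simulate_cohort(cfg)
  scan <- lca_scan(~ a + b + c, ch, K_range = 1:2, nrep = 4, seed = 1)
  expect_identical(scan$criterion, "aic")
  expect_equal(scan$selected_K, 2L)
})

test_that("canonical reorder sorts by prevalence; reference matching inverts a permutation", {
  cfg <- default_config(n_patients = 4000, seed = 17)
  ch <- simulate_cohort(cfg)
  fit <- lca(std_formula, ch, K = 4, nrep = 6, tol = 1e-9, seed = 2)
  can <- reorder_classes(fit)
  expect_true(all(diff(can$pi) <= 0))
  expect_identical(reorder_classes(can)$pi, can$pi)  # idempotent

  # a second cohort from a config with permuted classes must map back
  perm_true <- c(3L, 1L, 4L, 2L)
  cfg2 <- generator_config(
    4000, cfg$class_prevalence[perm_true],
    lapply(cfg$item_response, function(m) m[perm_true, , drop = FALSE]),
    cfg$baseline_hazards, cfg$cause_hr[perm_true, ],
    cfg$censor_admin_months, cfg$dropout_hazard, seed = 18)
  ch2 <- simulate_cohort(cfg2)
  fit2 <- lca(std_formula, ch2, K = 4, nrep = 6, tol = 1e-9, seed = 2)
  matched <- reorder_classes(fit2, reference = fit)
  # after matching to the reference, class c of `matched` should carry the
  # same profile as class c of `fit` (e.g. the all-70+ class lines up)
  i70 <- which.max(fit$rho$age_group[, "70+"])
  expect_equal(which.max(matched$rho$age_group[, "70+"]), i70)
  d <- mean(abs(matched$rho$age_group - fit$rho$age_group))
  expect_lt(d, 0.1)
  expect_error(reorder_classes(fit, reference = lca(std_formula, ch, K = 2,
                                                    nrep = 2, seed = 1)),
               "structure")
})

test_that("projection reproduces the training posterior and recovers classes", {
  cfg <- default_config(n_patients = 3000, seed = 19)
  ch <- simulate_cohort(cfg)
  fit <- lca(std_formula, ch, K = 4, nrep = 6, tol = 1e-9, seed = 2)
  pr <- project_classes(fit, ch)
  expect_equal(unname(pr$posterior), unname(fit$posterior), tolerance = 1e-9)
  # projection assigns everyone (cutoff 0), unlike the 0.5 training cutoff
  expect_true(all(!is.na(pr$assignment$class)))

  # single-row projection equals the hand posterior
  fit2 <- lca(~ a, data.frame(a = factor(rep(c("l1", "l2"), 10))), K = 2,
              nrep = 2, seed = 1)
  fit2$pi[] <- c(0.5, 0.5)
  fit2$rho$a[1, ] <- c(0.9, 0.1); fit2$rho$a[2, ] <- c(0.2, 0.8)
  one <- project_classes(fit2, data.frame(a = factor("l1",
                                                     levels = c("l1", "l2"))))
  expect_equal(as.numeric(one$posterior), c(0.45, 0.10) / 0.55,
               tolerance = 1e-12)

  # modal labels agree with the generating classes when separation is strong
  ch_new <- simulate_cohort(cfg, seed = 99)
  prn <- project_classes(fit, ch_new)
  perm <- match_classes(fit, cfg)
  agree <- mean(match(prn$assignment$class, perm) == ch_new$true_class)
  expect_gt(agree, 0.9)
  # unseen levels error
  bad <- ch_new[1:5, ]
  levels(bad$race) <- c(levels(bad$race), "??")
  bad$race[1] <- "??"
  expect_error(project_classes(fit, bad), "unseen level")
})

test_that("fitted model YAML round-trip preserves projection behaviour", {
  cfg <- default_config(n_patients = 800, seed = 23)
  ch <- simulate_cohort(cfg)
  fit <- reorder_classes(lca(std_formula, ch, K = 2, nrep = 3, seed = 1))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_lca_model(fit, path)
  back <- read_lca_model(path)
  expect_equal(back$pi, fit$pi, tolerance = 1e-12)
  expect_equal(back$rho, fit$rho, tolerance = 1e-12)
  expect_equal(project_classes(back, ch)$posterior,
               project_classes(fit, ch)$posterior, tolerance = 1e-10)
  expect_equal(lca_loglik(back, ch), fit$loglik, tolerance = 1e-6)
})
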