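test_that("rescaled weights match hand arithmetic on the 2x2 table", {
  g <- rep(c("g1", "g2"), times = c(40, 40))
  z <- c(rep("z1", 30), rep("z2", 10), rep("z1", 10), rep("z2", 30))
  w <- rescaled_weights(g, z)
  expect_equal(unique(w$weights[g == "g1" & z == "z1"]), 2/3,
               tolerance = 1e-12)
  expect_equal(unique(w$weights[g == "g1" & z == "z2"]), 2,
               tolerance = 1e-12)
  expect_equal(w$report$weight_sum, c(40, 40), tolerance = 1e-9)
  # weighted class distribution in each group equals the marginal (0.5, 0.5)
  for (gg in c("g1", "g2")) {
    share <- sum(w$weights[g == gg & z == "z1"]) / sum(w$weights[g == gg])
    expect_equal(share, 0.5, tolerance = 1e-12)
  }
})

test_that("identical class composition yields unit weights", {
  g <- rep(c("a", "b"), each = 30)
  z <- rep(rep(c("z1", "z2", "z3"), times = c(10, 10, 10)), 2)
  w <- rescaled_weights(g, z)
  expect_equal(w$weights, rep(1, 60), tolerance = 1e-12)
})

test_that("weight balance and rescaling invariants hold on random inputs", {
  set.seed(60)
  for (rep in 1:30) {
    n <- sample(40:200, 1)
    g <- factor(sample(letters[1:sample(2:4, 1)], n, TRUE))
    z <- factor(sample(paste0("z", 1:sample(2:4, 1)), n, TRUE))
    # ensure no empty group x class cell for the exact-balance property
    tab <- table(g, z)
    if (any(tab == 0)) next
    w <- rescaled_weights(g, z)
    expect_true(all(w$weights > 0))
    for (gg in levels(g)) {
      expect_equal(sum(w$weights[g == gg]), sum(g == gg), tolerance = 1e-9)
      for (zz in levels(z)) {
        share <- sum(w$weights[g == gg & z == zz]) / sum(w$weights[g == gg])
        expect_equal(share, mean(z == zz), tolerance = 1e-9)
      }
    }
  }
})

test_that("empty cells trigger a warning and per-group sums still rescale", {
  g <- rep(c("a", "b"), each = 20)
  z <- c(rep(c("z1", "z2"), each = 10), rep("z1", 20))
  expect_warning(w <- rescaled_weights(g, z), "empty")
  expect_equal(sum(w$weights[g == "a"]), 20, tolerance = 1e-9)
  expect_equal(sum(w$weights[g == "b"]), 20, tolerance = 1e-9)
})

test_that("adjusted KM with unit weights reproduces the plain KM exactly", {
  cfg <- confounded_subtype_config(n_patients = 600, seed = 61)
  ch <- simulate_cohort(cfg)
  flag <- as.integer(ch$event > 0)
  res <- adjusted_km_curves(ch$time_months, flag, ch$subtype, weights = NULL)
  for (g in levels(ch$subtype)) {
    i <- ch$subtype == g
    km <- km_curve(ch$time_months[i], flag[i])
    expect_identical(res$adjusted[[g]]$times, km$times)
    expect_identical(res$adjusted[[g]]$values, km$values)
    expect_identical(res$unadjusted[[g]]$values, km$values)
  }
})

test_that("null subtype effect: weighting shrinks the spurious gap", {
  # class drives cause-2 mortality; subtype depends on class but has no
  # effect of its own, so adjusted curves should be closer together
  gaps <- vapply(1:6, function(s) {
    cfg0 <- confounded_subtype_config(n_patients = 3000, seed = 700 + s)
    cfg <- generator_config(
      cfg0$n_patients, cfg0$class_prevalence, cfg0$item_response,
      cfg0$baseline_hazards, cfg0$cause_hr, cfg0$censor_admin_months,
      cfg0$dropout_hazard, cfg0$subtype_given_class,
      subtype_cause1_hr = c(1, 1, 1, 1), seed = cfg0$seed)
    ch <- simulate_cohort(cfg)
    sub <- ch$subtype %in% c("CMS1", "CMS4")
    ch <- ch[sub, ]; ch$subtype <- droplevels(ch$subtype)
    flag <- as.integer(ch$event > 0)
    w <- rescaled_weights(ch$subtype, factor(ch$true_class))
    res <- adjusted_km_curves(ch$time_months, flag, ch$subtype, w)
    grid <- seq(12, 240, by = 12)
    gap <- function(set) max(abs(eval_step(set[[1]], grid) -
                                   eval_step(set[[2]], grid)))
    gap(res$unadjusted) - gap(res$adjusted)
  }, 1)
  expect_gt(mean(gaps > 0), 0.5)
})

test_that("class-mixture CIF is a convex combination and collapses correctly", {
  cfg <- competing_hazard_config(n_patients = 2000, seed = 62)
  ch <- simulate_cohort(cfg)
  mix <- class_mixture_cif(ch$time_months, ch$event, 1,
                           factor(ch$true_class), min_stratum = 50)
  strata <- lapply(1:2, function(z) {
    i <- ch$true_class == z
    naive_cif(ch$time_months[i], ch$event[i], 1)
  })
  grid <- mix$times
  lo <- pmin(eval_step(strata[[1]], grid), eval_step(strata[[2]], grid))
  hi <- pmax(eval_step(strata[[1]], grid), eval_step(strata[[2]], grid))
  v <- eval_step(mix, grid)
  expect_true(all(v >= lo - 1e-10 & v <= hi + 1e-10))

  # single class stratum equals the naive estimator
  i <- ch$true_class == 1
  one <- class_mixture_cif(ch$time_months[i], ch$event[i], 1,
                           rep(1, sum(i)), min_stratum = 50)
  nv <- naive_cif(ch$time_months[i], ch$event[i], 1)
  expect_equal(eval_step(one, one$times), eval_step(nv, one$times),
               tolerance = 1e-12)

  # all-small strata fall back to naive with a warning
  expect_warning(
    fb <- class_mixture_cif(ch$time_months[1:40], ch$event[1:40], 1,
                            rep(1:2, 20), min_stratum = 50),
    "falling back")
  nv40 <- naive_cif(ch$time_months[1:40], ch$event[1:40], 1)
  expect_equal(eval_step(fb, fb$times), eval_step(nv40, fb$times),
               tolerance = 1e-12)
})

test_that("small strata are pooled into the nearest-share stratum", {
  cfg <- competing_hazard_config(n_patients = 1000, seed = 63)
  ch <- simulate_cohort(cfg)
  lab <- as.character(ch$true_class)
  lab[1:10] <- "3"   # a 10-patient stratum must be pooled
  mix <- class_mixture_cif(ch$time_months, ch$event, 1, lab,
                           min_stratum = 50)
  expect_match(paste(attr(mix, "pooling"), collapse = " "), "3 ->")
})

test_that("mixture CIF tracks Aalen-Johansen better than naive KM under
          class-driven competing hazards", {
  cfg <- competing_hazard_config(n_patients = 5000, seed = 64)
  ch <- simulate_cohort(cfg)
  aj <- aalen_johansen(ch$time_months, ch$event)
  grid <- sort(unique(ch$time_months[ch$event == 1]))
  f_aj <- eval_step(aj$cif1, grid)
  mix <- class_mixture_cif(ch$time_months, ch$event, 1, factor(ch$true_class))
  nv <- naive_cif(ch$time_months, ch$event, 1)
  d_mix <- max(abs(eval_step(mix, grid) - f_aj))
  d_nv <- max(abs(eval_step(nv, grid) - f_aj))
  expect_lt(d_mix, d_nv)
})

test_that("robust score test matches the hand log-rank with unit weights", {
  time <- c(1, 3, 5, 7, 9, 11)
  event <- c(1, 1, 0, 1, 1, 0)
  g <- factor(c("A", "B", "A", "B", "A", "B"))
  st <- robust_score_test(time, event, g)
  expect_equal(st$statistic, logrank_hand(time, event, g), tolerance = 1e-6)
  expect_equal(st$df, 1)
  expect_false(st$weighted)
  expect_error(robust_score_test(time, event, factor(rep("A", 6))),
               ">= 2 groups")
})

test_that("robust score statistic is invariant to rescaling all weights", {
  cfg <- confounded_subtype_config(n_patients = 800, seed = 65)
  ch <- simulate_cohort(cfg)
  flag <- as.integer(ch$event > 0)
  w <- rescaled_weights(ch$subtype, factor(ch$true_class))$weights
  s1 <- robust_score_test(ch$time_months, flag, ch$subtype, w)
  s2 <- robust_score_test(ch$time_months, flag, ch$subtype, w * 7.3)
  expect_equal(s1$statistic, s2$statistic, tolerance = 1e-8)
  expect_true(s1$weighted)
})

test_that("score test has null uniform behaviour and detects separation", {
  set.seed(66)
  ps <- vapply(1:20, function(i) {
    n <- 120
    time <- rexp(n, 0.05); event <- rbinom(n, 1, 0.8)
    g <- factor(sample(c("A", "B"), n, TRUE))
    robust_score_test(time, event, g)$p_value
  }, 1)
  expect_gt(mean(ps), 0.25)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  n <- 400
  time <- c(rexp(n, 0.02), rexp(n, 0.08))
  g <- factor(rep(c("A", "B"), each = n))
  st <- robust_score_test(time, rep(1, 2 * n), g)
  expect_lt(st$p_value, 1e-6)
})

test_that("concordance index matches hand enumeration", {
  # 4-patient toy: times 1..4 all events, scores 4,3,1,2 -> C = 5/6
  ci <- concordance_index(1:4, rep(1, 4), c(4, 3, 1, 2))
  expect_equal(ci$comparable, 6)
  expect_equal(ci$concordant, 5)
  expect_equal(ci$c_index, 5/6)

  # perfect ordering -> 1; constant score -> 0.5
  expect_equal(concordance_index(1:5, rep(1, 5), 5:1)$c_index, 1)
  expect_equal(concordance_index(1:5, rep(1, 5), rep(2, 5))$c_index, 0.5)

  # no comparable pairs -> undefined with warning
  expect_warning(und <- concordance_index(c(1, 2), c(0, 0), c(1, 2)),
                 "no comparable")
  expect_true(is.na(und$c_index))
})

test_that("concordance agrees with survival::concordance under censoring", {
  set.seed(67)
  n <- 300
  time <- rexp(n, 0.05)
  event <- rbinom(n, 1, 0.6)
  score <- rnorm(n) + 0.8 * log(1 / time)
  ours <- concordance_index(time, event, score)
  ref <- survival::concordance(survival::Surv(time, event) ~ score,
                               reverse = TRUE)
  expect_equal(ours$c_index, unname(ref$concordance), tolerance = 1e-10)
})

test_that("adjustment report: no confounding means weighted ~ unweighted", {
  cfg0 <- confounded_subtype_config(n_patients = 2500, seed = 68)
  sub_ind <- matrix(0.25, 4, 4); colnames(sub_ind) <- paste0("CMS", 1:4)
  cfg <- generator_config(
    cfg0$n_patients, cfg0$class_prevalence, cfg0$item_response,
    cfg0$baseline_hazards, cfg0$cause_hr, cfg0$censor_admin_months,
    cfg0$dropout_hazard, subtype_given_class = sub_ind,
    subtype_cause1_hr = cfg0$subtype_cause1_hr, seed = 68)
  ch <- simulate_cohort(cfg)
  rep_tab <- adjustment_report(ch$time_months, ch$event,
                               factor(ch$true_class), ch$subtype,
                               endpoint = "os")
  ci <- rep_tab[rep_tab$metric == "c_index" & rep_tab$comparison == "all", ]
  expect_lt(abs(ci$adjusted - ci$unadjusted), 0.02)

  # identical groups give C near 0.5 both ways
  ch2 <- ch[ch$subtype %in% c("CMS1", "CMS2"), ]
  ch2$subtype <- factor(sample(c("X", "Y"), nrow(ch2), TRUE))
  r2 <- adjustment_report(ch2$time_months, ch2$event,
                          factor(ch2$true_class), ch2$subtype,
                          endpoint = "os")
  c2 <- r2[r2$metric == "c_index" & r2$comparison == "all", ]
  expect_lt(abs(c2$unadjusted - 0.5), 0.03)
  expect_lt(abs(c2$adjusted - 0.5), 0.03)
})

test_that("confounded subtypes: weighting raises the C-index (directional)", {
  wins <- vapply(1:10, function(s) {
    ch <- simulate_cohort(confounded_subtype_config(n_patients = 2000,
                                                    seed = 800 + s))
    rep_tab <- adjustment_report(ch$time_months, ch$event,
                                 factor(ch$true_class), ch$subtype,
                                 endpoint = "os")
    ci <- rep_tab[rep_tab$metric == "c_index" & rep_tab$comparison == "all", ]
    ci$adjusted > ci$unadjusted
  }, TRUE)
  expect_gt(mean(wins), 0.5)
})
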