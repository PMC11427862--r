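test_that("the fitted odds ratio on a 2x2 table equals ad/bc", {
  fit <- fit_model(two_by_two, model_spec("y", "x"))
  or <- fit$terms$odds_ratio[fit$terms$term == "x"]
  expect_equal(or, (20 * 20) / (10 * 10), tolerance = 1e-6)
  expect_true(all(fit$terms$ci_low < fit$terms$odds_ratio &
                    fit$terms$odds_ratio < fit$terms$ci_high))
})

test_that("the LR test vs null matches an explicit log-likelihood oracle", {
  fit <- fit_model(two_by_two, model_spec("y", "x"))
  # saturated-by-group likelihoods computed directly from the counts
  ll <- function(p, k, n) k * log(p) + (n - k) * log(1 - p)
  ll1 <- ll(20 / 30, 20, 30) + ll(10 / 30, 10, 30)
  ll0 <- ll(30 / 60, 30, 60)
  expect_equal(fit$lr$chi2, 2 * (ll1 - ll0), tolerance = 1e-8)
  expect_equal(fit$lr$df, 1)

  null_only <- glm(y ~ 1, family = binomial(), data = two_by_two)
  lr0 <- lr_test_vs_null(null_only)
  expect_equal(lr0$chi2, 0)
  expect_equal(lr0$df, 0)
})

test_that("Tjur's R2 is the fitted-probability group-mean difference", {
  expect_equal(tjur_r2(list(y = c(1, 1, 0, 0),
                            fitted.values = c(1, 1, 0, 0))), 1)
  expect_equal(tjur_r2(list(y = c(1, 0), fitted.values = c(0.4, 0.4))), 0)
  expect_error(tjur_r2(list(y = c(1, 1), fitted.values = c(0.5, 0.6))),
               "single class")

  fit <- fit_model(two_by_two, model_spec("y", "x"))
  fv <- fit$model$fitted.values
  y <- two_by_two$y
  expect_equal(fit$tjur_r2, mean(fv[y == 1]) - mean(fv[y == 0]))
})

test_that("Benjamini-Hochberg flags match a hand step-up walk", {
  expect_true(bh_adjust(0.01))
  expect_equal(bh_adjust(rep(0.04, 5)), rep(TRUE, 5))
  # hand walk at m = 4, alpha = 0.05: sorted p vs (k/m) * alpha =
  # 0.0125, 0.025, 0.0375, 0.05 -> largest k with p_(k) <= k*alpha/m is 2
  p <- c(0.001, 0.013, 0.04, 0.3)
  expect_equal(bh_adjust(p), c(TRUE, TRUE, FALSE, FALSE))
  # monotone: any rejected p implies rejection of all smaller p
  set.seed(8)
  for (i in 1:20) {
    pv <- runif(sample(2:12, 1))
    fl <- bh_adjust(pv)
    if (any(fl)) expect_true(all(fl[pv <= max(pv[fl])]))
  }
  expect_error(bh_adjust(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("variance inflation factors match their closed forms", {
  X <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_equal(unname(vif_design(X)), c(1, 1))

  expect_warning(v <- vif_design(cbind(a = rnorm(20), b = 1:20, c = 1:20)),
                 "collinear")
  expect_true(is.infinite(v[["b"]]) && is.infinite(v[["c"]]))

  set.seed(3)
  n <- 40000
  z <- rnorm(n)
  x1 <- 0.6 * z + sqrt(1 - 0.36) * rnorm(n)
  v2 <- vif_design(cbind(x1 = x1, z = z))
  expect_equal(unname(v2), rep(1 / (1 - 0.36), 2), tolerance = 0.02)

  # agrees with car's VIF on a numeric linear model
  df <- data.frame(y = rnorm(50), a = rnorm(50), b = rnorm(50), c = rnorm(50))
  m <- stats::lm(y ~ a + b + c, data = df)
  expect_equal(vif_design(model.matrix(m)[, -1]), car::vif(m),
               tolerance = 1e-8)
})

test_that("type II analysis of deviance respects term degrees of freedom", {
  fit <- fit_model(two_by_two, model_spec("y", "x"))
  expect_equal(fit$type2$chi2, fit$lr$chi2, tolerance = 1e-8)
  expect_equal(fit$type2$df, 1)

  set.seed(4)
  df <- data.frame(
    g = sample(c("18-35", "36-45", ">46"), 600, replace = TRUE),
    z = rnorm(600))
  df$age_group <- df$g
  df$y <- rbinom(600, 1, plogis(0.3 * df$z))
  fit3 <- fit_model(df, model_spec("y", c("age_group", "z")))
  expect_equal(fit3$type2$df[fit3$type2$term == "age_group"], 2)
})

test_that("Tukey contrasts cover all level pairs with adjusted p-values", {
  set.seed(5)
  n <- 900
  df <- data.frame(
    category = sample(c("distract", "calm", "address"), n, replace = TRUE),
    z = rnorm(n))
  # calm and address share the same true effect; distract differs
  lp <- -0.2 + 0.8 * (df$category == "distract") + 0.3 * df$z
  df$y <- rbinom(n, 1, plogis(lp))
  fit <- fit_model(df, model_spec("y", c("category", "z")))
  tk <- fit$tukey$category
  expect_equal(nrow(tk), 3)  # k(k-1)/2 for k = 3
  expect_true(all(tk$p_adjusted >= tk$p_unadjusted - 1e-12))
  null_contrast <- tk[grepl("address", tk$contrast) &
                        grepl("calm", tk$contrast), ]
  expect_lt(abs(null_contrast$estimate), 0.5)

  expect_error(tukey_pairwise(fit_model(two_by_two, model_spec("y", "x")),
                              "x"), "not a factor")
  df$gender <- sample(c("man", "woman"), n, replace = TRUE)
  fit2 <- fit_model(df, model_spec("y", c("gender", "z")))
  expect_error(tukey_pairwise(fit2, "gender"), "Wald")
})

test_that("model specifications reproduce the published designs' df", {
  truth <- default_truth_models()
  rec <- simulate_nudge_records(3000, truth, seed = 41)
  fit <- fit_model(rec, default_model_specs()$engaged)
  expect_equal(fit$lr$df, 21)
  expect_equal(nrow(fit$terms), 22)  # intercept + 21 parameters

  comp <- simulate_completed_records(3000, truth, seed = 42)
  fit6 <- fit_model(comp, default_model_specs()$improved)
  expect_equal(fit6$lr$df, 29)

  set.seed(43)
  comp$engaged <- rbinom(nrow(comp), 1, 0.6) == 1
  expect_equal(fit_model(comp,
                         default_model_specs()$engaged_after_chosen)$lr$df,
               27)
  comp$liked <- rbinom(nrow(comp), 1, 0.5) == 1
  comp$stress_reduction <- sample(-1:3, nrow(comp), replace = TRUE)
  expect_equal(fit_model(comp, default_model_specs()$liked)$lr$df, 28)
})

test_that("degenerate designs fail loudly", {
  set.seed(6)
  sep <- data.frame(x = c(rnorm(30, -3), rnorm(30, 3)),
                    y = rep(c(0, 1), each = 30))
  expect_error(fit_model(sep, model_spec("y", "x")), "separation")

  dup <- two_by_two
  dup$x2 <- dup$x
  expect_error(fit_model(dup, model_spec("y", c("x", "x2"))),
               "aliased|rank")

  nas <- two_by_two
  nas$x[1] <- NA
  expect_error(fit_model(nas, model_spec("y", "x")), "missing values")

  notbin <- data.frame(y = c(0, 1, 2), x = 1:3)
  expect_error(fit_model(notbin, model_spec("y", "x")), "binary")
})

test_that("ORs and coefficients are exp/log consistent and fits deterministic", {
  truth <- default_truth_models()
  rec <- simulate_nudge_records(2000, truth, seed = 51)
  f1 <- fit_model(rec, default_model_specs()$engaged)
  f2 <- fit_model(rec, default_model_specs()$engaged)
  expect_identical(f1$terms, f2$terms)
  expect_equal(f1$terms$odds_ratio, exp(f1$terms$estimate))
  expect_true(all(f1$terms$odds_ratio > 0))
  expect_true(f1$tjur_r2 >= -1 && f1$tjur_r2 <= 1)
})

test_that("Wald intervals achieve near-nominal coverage under the model", {
  set.seed(60)
  beta <- 0.5
  hits <- 0L
  reps <- 300
  for (r in seq_len(reps)) {
    x <- rnorm(1500)
    y <- rbinom(1500, 1, plogis(-0.4 + beta * x))
    m <- glm(y ~ x, family = binomial())
    ci <- coef(m)["x"] + c(-1, 1) * qnorm(0.975) *
      sqrt(vcov(m)["x", "x"])
    if (ci[1] <= beta && beta <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.91)
  expect_lte(hits / reps, 0.99)
})
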