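test_that("regression recovers an exact linear construction", {
  set.seed(30)
  age <- sample(1:10, 100, replace = TRUE)
  res <- rnorm(100)
  y <- 2 * age + res
  fit <- fit_regression(y, data.frame(age = age, residual = res))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$coefficients$estimate, c(2, 1), tolerance = 1e-10)
})

test_that("standardized slopes equal raw slopes on z-scored inputs", {
  set.seed(31)
  x1 <- rnorm(150); x2 <- rnorm(150)
  y <- x1 + 0.5 * x2 + rnorm(150)
  zfit <- fit_regression(
    as.vector(scale(y)),
    data.frame(a = as.vector(scale(x1)), b = as.vector(scale(x2)))
  )
  expect_equal(zfit$coefficients$estimate, zfit$coefficients$std_estimate,
    tolerance = 1e-12
  )
  # and standardized coefficients are invariant to predictor rescaling
  f1 <- fit_regression(y, data.frame(a = x1, b = x2))
  f2 <- fit_regression(y, data.frame(a = 100 * x1 + 3, b = x2 / 7))
  expect_equal(f1$coefficients$std_estimate, f2$coefficients$std_estimate,
    tolerance = 1e-10
  )
})

test_that("a response independent of the predictors yields a null fit", {
  set.seed(32)
  fit <- fit_regression(rnorm(200), data.frame(a = rnorm(200), b = rnorm(200)))
  expect_lt(fit$r_squared, 0.05)
  expect_gt(fit$p_overall, 0.05)
  expect_error(fit_regression(rnorm(10), data.frame(a = rep(1, 10))), "constant")
})

test_that("relative weights sum to R-squared and percentages to 100", {
  set.seed(34)
  for (rep in 1:10) {
    n <- 120
    x1 <- rnorm(n)
    x2 <- 0.5 * x1 + sqrt(1 - 0.25) * rnorm(n)
    y <- x1 + x2 + rnorm(n, 0, 2)
    rw <- relative_weights(y, data.frame(x1 = x1, x2 = x2))
    r2 <- summary(lm(y ~ x1 + x2))$r.squared
    expect_equal(sum(rw$weights$raw_weight), r2, tolerance = 1e-10)
    expect_equal(rw$r_squared, r2, tolerance = 1e-10)
    expect_equal(sum(rw$weights$pct), 100, tolerance = 1e-9)
    expect_true(all(rw$weights$raw_weight >= 0))
  }
})

test_that("orthogonal predictors get their squared correlations as weights", {
  n <- 64
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, -1, 1, 1), n / 4) # exactly orthogonal to x1
  set.seed(35)
  y <- 1.5 * x1 + 0.7 * x2 + rnorm(n)
  rw <- relative_weights(y, data.frame(x1 = x1, x2 = x2))
  expect_equal(
    rw$weights$raw_weight,
    c(cor(y, x1)^2, cor(y, x2)^2),
    tolerance = 1e-10
  )
})

test_that("weights agree with the brute-force LMG decomposition within 2 points", {
  set.seed(36)
  for (rho in c(-0.9, -0.5, 0, 0.3, 0.6, 0.9)) {
    n <- 400
    x1 <- rnorm(n)
    x2 <- rho * x1 + sqrt(1 - rho^2) * rnorm(n)
    y <- 0.8 * x1 + 0.4 * x2 + rnorm(n)
    rw <- relative_weights(y, data.frame(x1 = x1, x2 = x2))
    lmg <- lmg_two_predictors(y, x1, x2)
    expect_lt(max(abs(rw$weights$pct - lmg)), 2)
  }
})

test_that("weights are invariant to affine rescaling of inputs", {
  set.seed(37)
  x1 <- rnorm(100); x2 <- 0.4 * x1 + rnorm(100)
  y <- x1 - x2 + rnorm(100)
  w1 <- relative_weights(y, data.frame(a = x1, b = x2))
  w2 <- relative_weights(5 * y - 2, data.frame(a = -3 * x1 + 1, b = x2 / 10))
  expect_equal(w1$weights$pct, w2$weights$pct, tolerance = 1e-9)
  expect_equal(w1$r_squared, w2$r_squared, tolerance = 1e-12)
})

test_that("rank-deficient predictors are rejected", {
  x <- rnorm(50)
  expect_error(
    relative_weights(rnorm(50), data.frame(a = x, b = 2 * x)),
    "rank-deficient"
  )
})

test_that("VIFs follow the closed form and agree with car", {
  n <- 1000
  rho <- 0.6
  set.seed(38)
  x1 <- rnorm(n)
  x2 <- rho * x1 + sqrt(1 - rho^2) * rnorm(n)
  v <- compute_vif(data.frame(x1 = x1, x2 = x2))
  r <- cor(x1, x2)
  expect_equal(unname(v), rep(1 / (1 - r^2), 2), tolerance = 1e-10)
  y <- x1 + x2 + rnorm(n)
  ref <- car::vif(lm(y ~ x1 + x2))
  expect_equal(unname(v), unname(ref), tolerance = 1e-8)
  # orthogonal limit
  a <- rep(c(-1, 1), 10); b <- rep(c(-1, -1, 1, 1), 5)
  expect_equal(unname(compute_vif(data.frame(a = a, b = b))), c(1, 1), tolerance = 1e-12)
  # collinear limit
  expect_warning(vc <- compute_vif(data.frame(a = x1, b = 3 * x1)), "collinearity")
  expect_true(all(is.infinite(vc)))
})

test_that("per-site partition attributes pure scenarios to the right factor", {
  p <- growth_params(20, 0.3, 0)
  set.seed(39)
  n_layer <- 30
  # site A: constant growing conditions, age-at-harvest varies by layer
  ages_a <- unlist(lapply(c(2, 4, 6, 8), function(m) pmax(1, round(rnorm(n_layer, m, 1)))))
  rec_a <- tibble::tibble(
    shell_id = sprintf("A-%03d", seq_along(ages_a)), site = "A",
    period = "Mesolithic",
    layer_label = sprintf("L%d", rep(1:4, each = n_layer)),
    layer_order = rep(1:4, each = n_layer),
    hinge_mm = round(predict_hinge(p, ages_a) + rnorm(length(ages_a), 0, 0.3), 1),
    age_years = as.integer(ages_a)
  )
  # site B: near-constant age-at-harvest, growing conditions vary by layer
  mult_b <- rep(c(0.6, 0.9, 1.1, 1.4), each = n_layer)
  ages_b <- as.integer(pmax(1, round(rnorm(4 * n_layer, 3, 0.5))))
  rec_b <- tibble::tibble(
    shell_id = sprintf("B-%03d", seq_along(ages_b)), site = "B",
    period = "Mesolithic",
    layer_label = sprintf("L%d", rep(1:4, each = n_layer)),
    layer_order = rep(1:4, each = n_layer),
    hinge_mm = round(mult_b * predict_hinge(p, ages_b) + rnorm(length(ages_b), 0, 0.3), 1),
    age_years = ages_b
  )
  asm <- assemblage(rbind(rec_a, rec_b))
  fit <- fit_growth_curve(asm)
  res <- compute_residuals(fit, asm)
  part <- partition_by_site(asm, res)
  expect_gt(part$weight_age_pct[part$site == "A"], 80)
  expect_gt(part$weight_growth_pct[part$site == "B"], 80)
  expect_true(all(part$reliable))
  expect_equal(part$weight_age_pct + part$weight_growth_pct, rep(100, 2), tolerance = 1e-9)
})

test_that("short or shallow sequences are flagged unreliable", {
  p <- growth_params(20, 0.3, 0)
  set.seed(40)
  age <- sample(1:8, 12, replace = TRUE)
  rec <- tibble::tibble(
    shell_id = sprintf("short-%d", 1:12), site = "short", period = "Mesolithic",
    layer_label = sprintf("L%d", rep(1:2, 6)), layer_order = rep(1:2, 6),
    hinge_mm = round(predict_hinge(p, age) + rnorm(12, 0, 1), 1),
    age_years = as.integer(age)
  )
  asm <- assemblage(rec)
  res <- compute_residuals(p, asm)
  part <- partition_by_site(asm, res, min_n = 30, min_levels = 4)
  expect_false(part$reliable[1])
  part2 <- partition_by_site(asm, res, min_n = 10, min_levels = 2)
  expect_true(part2$reliable[1])
})
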