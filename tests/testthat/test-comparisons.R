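test_that("Mann-Whitney handles the canonical small cases", {
  same <- mann_whitney(1:5, 1:5)
  expect_equal(same$statistic, 12.5) # n^2/2 with mid-ranks
  expect_equal(same$p_raw, 1)
  sep <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$statistic, 0)
  expect_equal(sep$p_raw, 0.1) # 2 of the 20 assignments are as extreme
})

test_that("exact small-sample p-values match full enumeration", {
  set.seed(101)
  for (rep in 1:20) {
    n_a <- sample(2:6, 1)
    n_b <- sample(2:6, 1)
    # integer-valued samples: ties guaranteed to occur across replicates
    a <- sample(1:6, n_a, replace = TRUE)
    b <- sample(1:6, n_b, replace = TRUE)
    got <- mann_whitney(a, b)
    expect_equal(got$p_raw, mw_enumerate_oracle(a, b))
    expect_match(got$test, "exact")
  }
})

test_that("tie-free exact p-values agree with wilcox.test", {
  set.seed(33)
  for (rep in 1:10) {
    a <- rnorm(sample(3:7, 1))
    b <- rnorm(sample(3:7, 1))
    got <- mann_whitney(a, b)
    ref <- suppressWarnings(wilcox.test(a, b, exact = TRUE))
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_raw, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large-sample approximation matches the uncorrected normal test", {
  set.seed(71)
  a <- sample(1:12, 60, replace = TRUE) # heavy ties
  b <- sample(2:13, 45, replace = TRUE)
  got <- mann_whitney(a, b)
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
  expect_equal(got$p_raw, ref$p.value, tolerance = 1e-12)
  expect_equal(got$statistic, unname(ref$statistic))
})

test_that("two-sided p-values are exchangeable under group swap", {
  set.seed(5)
  a <- rnorm(12); b <- rnorm(9, 0.8)
  expect_equal(mann_whitney(a, b)$p_raw, mann_whitney(b, a)$p_raw)
  expect_equal(variance_f_test(a, b)$p_raw, variance_f_test(b, a)$p_raw)
  expect_equal(levene_test(a, b)$p_raw, levene_test(b, a)$p_raw)
  a4 <- rnorm(4); b4 <- rnorm(5)
  expect_equal(mann_whitney(a4, b4)$p_raw, mann_whitney(b4, a4)$p_raw)
})

test_that("variance F test detects spread differences and matches var.test", {
  x <- c(1, 2, 3, 4, 5)
  eq <- variance_f_test(x, x + 10)
  expect_equal(eq$statistic, 1)
  expect_equal(eq$p_raw, 1)
  set.seed(14)
  a <- rnorm(100, sd = 1); b <- rnorm(100, sd = 3)
  wide <- variance_f_test(a, b)
  expect_lt(wide$p_raw, 0.001)
  expect_equal(wide$p_raw, var.test(a, b)$p.value, tolerance = 1e-12)
  expect_error(variance_f_test(c(1, 1), c(2, 2)), "zero")
})

test_that("Levene's test flags spread differences; both centerings computed", {
  set.seed(15)
  a <- rnorm(100, sd = 1); b <- rnorm(100, sd = 3)
  expect_lt(levene_test(a, b)$p_raw, 0.001)
  expect_equal(levene_test(a, a + 5)$p_raw, 1)
  skewed <- rexp(40); other <- rexp(40) * 1.3
  p_mean <- levene_test(skewed, other, center = "mean")$p_raw
  p_median <- levene_test(skewed, other, center = "median")$p_raw
  expect_true(p_mean >= 0 && p_mean <= 1)
  expect_true(p_median >= 0 && p_median <= 1)
  expect_false(isTRUE(all.equal(p_mean, p_median)))
})

test_that("classical Levene equals a one-way ANOVA on absolute deviations", {
  set.seed(16)
  a <- rnorm(30, sd = 1); b <- rnorm(25, sd = 2)
  got <- levene_test(a, b, center = "mean")
  dev <- c(abs(a - mean(a)), abs(b - mean(b)))
  grp <- factor(rep(1:2, c(30, 25)))
  ref <- anova(lm(dev ~ grp))
  expect_equal(got$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(got$p_raw, ref$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("Bonferroni adjustment is exact arithmetic, capped, and monotone", {
  expect_equal(bonferroni_adjust(0.01, family_size = 1), 0.01)
  expect_equal(bonferroni_adjust(c(0.01, 0.04, 0.2)), c(0.03, 0.12, 0.6))
  expect_equal(bonferroni_adjust(c(0.5, 0.9), family_size = 6), c(1, 1))
  p <- sort(runif(20))
  adj <- bonferroni_adjust(p, family_size = 7)
  expect_true(all(diff(adj) >= 0))
  expect_true(all(adj >= p))
  expect_error(bonferroni_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("stars follow the three-threshold convention", {
  expect_equal(
    significance_stars(c(0.2, 0.049, 0.009, 0.0009, 0.05)),
    c(0L, 1L, 2L, 3L, 0L)
  )
})

test_that("period comparison finds a true age shift and stays null otherwise", {
  build <- function(shift) {
    set.seed(20)
    n <- 500
    meso_age <- sample(2:10, n, replace = TRUE)
    neo_age <- pmax(meso_age - shift, 1L)
    p <- growth_params(20, 0.3, 0)
    mk <- function(age, period, tag) {
      tibble::tibble(
        shell_id = sprintf("%s-%d", tag, seq_along(age)),
        site = rep(sprintf("S%d", 1:5), length.out = length(age)),
        period = period,
        hinge_mm = round(predict_hinge(p, age) + rnorm(length(age), 0, 1), 1),
        age_years = as.integer(age)
      )
    }
    assemblage(rbind(mk(meso_age, "Mesolithic", "m"), mk(neo_age, "Neolithic", "n")))
  }
  shifted <- build(1L)
  cmp <- compare_by_period(shifted, variables = "age")
  pooled <- cmp[cmp$level == "pooled", ]
  expect_lt(pooled$p_raw, 0.01)

  null_asm <- build(0L)
  cmp0 <- compare_by_period(null_asm, variables = "age")
  expect_gt(cmp0$p_raw[cmp0$level == "pooled"], 0.05)
  expect_true(all(cmp0$stars[cmp0$level == "site"] == 0))
})

test_that("site-level tests form one Bonferroni family per variable", {
  set.seed(21)
  mk_site <- function(s, periods) {
    do.call(rbind, lapply(periods, function(per) {
      tibble::tibble(
        shell_id = sprintf("%s-%s-%d", s, per, 1:8),
        site = s, period = per,
        hinge_mm = round(runif(8, 3, 12), 1),
        age_years = sample(1:6, 8, replace = TRUE)
      )
    }))
  }
  asm <- assemblage(rbind(
    mk_site("both1", c("Mesolithic", "Neolithic")),
    mk_site("both2", c("Mesolithic", "Neolithic")),
    mk_site("meso_only", "Mesolithic")
  ))
  cmp <- compare_by_period(asm, variables = "hinge")
  site_rows <- cmp[cmp$level == "site", ]
  expect_equal(sort(site_rows$site), c("both1", "both2")) # one-period site excluded
  expect_equal(site_rows$p_adjusted, bonferroni_adjust(site_rows$p_raw, 2))
  expect_message(
    compare_by_period(asm, variables = "hinge", sites = "meso_only"),
    "skipped"
  )
})
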