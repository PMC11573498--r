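# Shared fixture builders. All synthetic; nothing is read from disk except
# files the tests themselves write to tempdir().

make_records <- function(n = 10, site = "S1", period = "Mesolithic",
                         hinge = round(seq(2, 12, length.out = n), 1),
                         age = rep(1:5, length.out = n),
                         layer_label = NULL, layer_order = NULL) {
  tibble::tibble(
    shell_id = sprintf("%s-%03d", site, seq_len(n)),
    site = site,
    period = period,
    layer_label = if (is.null(layer_label)) NA_character_ else layer_label,
    layer_order = if (is.null(layer_order)) NA_integer_ else layer_order,
    hinge_mm = hinge,
    age_years = as.integer(age)
  )
}

# Noise-free records generated exactly from a growth curve (full-precision
# hinges; wrap with assemblage(..., enforce_decimals = FALSE)).
vbgf_records <- function(params = growth_params(20, 0.3, 0),
                         ages = 1:10, reps = 3, site = "VB") {
  age <- rep(ages, each = reps)
  tibble::tibble(
    shell_id = sprintf("%s-%03d", site, seq_along(age)),
    site = site,
    period = "Mesolithic",
    layer_label = NA_character_, layer_order = NA_integer_,
    hinge_mm = predict_hinge(params, age), age_years = as.integer(age)
  )
}

vbgf_assemblage <- function(...) {
  assemblage(vbgf_records(...), enforce_decimals = FALSE)
}

write_temp_csv <- function(df, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = env)
  readr::write_csv(df, path, na = "")
  path
}

# Independent brute-force oracles ------------------------------------------

# Full-enumeration two-sided Mann-Whitney p-value (distance from null mean).
mw_enumerate_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); n_a <- length(a)
  r <- rank(pooled)
  splits <- utils::combn(n, n_a)
  u <- colSums(matrix(r[splits], nrow = n_a)) - n_a * (n_a + 1) / 2
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * (n - n_a) / 2
  mean(abs(u - mu) >= abs(u_obs - mu) - 1e-9)
}

# LMG / averaging-over-orderings decomposition for two predictors, via lm.
lmg_two_predictors <- function(y, x1, x2) {
  r2 <- function(fml, d) summary(lm(fml, data = d))$r.squared
  d <- data.frame(y = y, x1 = x1, x2 = x2)
  r2_full <- r2(y ~ x1 + x2, d)
  r2_1 <- r2(y ~ x1, d)
  r2_2 <- r2(y ~ x2, d)
  w1 <- 0.5 * (r2_1 + (r2_full - r2_2))
  w2 <- 0.5 * (r2_2 + (r2_full - r2_1))
  100 * c(w1, w2) / (w1 + w2)
}
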