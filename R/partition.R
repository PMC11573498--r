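#' Multiple regression of hinge size on age and growth rate
#'
#' Ordinary least squares with intercept, plus standardized coefficients
#' (slopes after z-scoring response and predictors), the model R-squared
#' and the overall F-test p-value. Used to evaluate the joint influence of
#' age-at-harvest and growth rate on shell size before partitioning the
#' explained variance.
#'
#' @param response Numeric response vector (hinge sizes).
#' @param predictors A named data frame or list of numeric predictor
#'   vectors (typically `age` and `residual`).
#' @return An object of class `regression_summary`: a list with
#'   `coefficients` (tibble of `term`, `estimate`, `std_estimate`),
#'   `r_squared`, `n`, `p_overall`.
#' @export
fit_regression <- function(response, predictors) {
  X <- as.data.frame(predictors)
  if (nrow(X) != length(response)) stop("response and predictors must have equal length", call. = FALSE)
  cc <- complete.cases(X) & !is.na(response)
  X <- X[cc, , drop = FALSE]
  y <- response[cc]
  if (length(y) <= ncol(X) + 1) stop("too few observations for regression", call. = FALSE)
  if (any(vapply(X, sd, numeric(1)) == 0)) stop("constant predictor", call. = FALSE)
  fit <- lm(y ~ ., data = X)
  sm <- suppressWarnings(summary(fit)) # "perfect fit" warning on exact data
  est <- coef(fit)[-1]
  std <- est * vapply(X, sd, numeric(1)) / sd(y)
  fstat <- sm$fstatistic
  p_overall <- unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  structure(
    list(
      coefficients = tibble::tibble(
        term = names(est), estimate = unname(est), std_estimate = unname(std)
      ),
      intercept = unname(coef(fit)[1]),
      r_squared = sm$r.squared,
      n = length(y),
      p_overall = p_overall
    ),
    class = "regression_summary"
  )
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf(
    "Multiple regression: n = %d, R^2 = %.4f, overall p = %.3g\n",
    x$n, x$r_squared, x$p_overall
  ))
  print.data.frame(as.data.frame(x$coefficients), row.names = FALSE)
  invisible(x)
}

#' Relative weights of correlated predictors (Johnson's epsilon)
#'
#' Partitions a regression's explained variance among correlated
#' predictors. The standardized predictor matrix is approximated by its
#' closest set of orthogonal variables through the singular value
#' decomposition; the response is regressed on those orthogonal variables
#' and the squared loadings are mapped back to the original predictors.
#' Each predictor receives a nonnegative share; the unnormalized weights
#' sum to the model R-squared, and are also reported as percentages of
#' R-squared summing to 100. With exactly orthogonal predictors each
#' weight equals that predictor's squared correlation with the response.
#'
#' @param response Numeric response vector.
#' @param predictors A named data frame or list of two or more numeric
#'   predictor vectors.
#' @return An object of class `relative_weights`: a list with `weights`
#'   (tibble of `predictor`, `raw_weight`, `pct`), `r_squared`, `n`.
#' @export
relative_weights <- function(response, predictors) {
  X <- as.data.frame(predictors)
  if (ncol(X) < 2) stop("need at least two predictors", call. = FALSE)
  cc <- complete.cases(X) & !is.na(response)
  X <- X[cc, , drop = FALSE]
  y <- response[cc]
  n <- length(y)
  if (n <= ncol(X) + 1) stop("too few observations", call. = FALSE)
  if (any(vapply(X, sd, numeric(1)) == 0)) stop("constant predictor", call. = FALSE)

  # Standardize so that crossprod(Xs) is the predictor correlation matrix.
  Xs <- scale(as.matrix(X)) / sqrt(n - 1)
  ys <- as.vector(scale(y)) / sqrt(n - 1)
  s <- svd(Xs)
  if (min(s$d) < 1e-10 * max(s$d)) stop("rank-deficient predictor matrix", call. = FALSE)
  Z <- s$u %*% t(s$v)                      # orthogonal approximation of Xs
  Lambda <- s$v %*% diag(s$d, length(s$d)) %*% t(s$v) # Xs = Z %*% Lambda
  beta <- drop(crossprod(Z, ys))           # Z has orthonormal columns
  raw <- drop(Lambda^2 %*% beta^2)
  r2 <- sum(beta^2)
  structure(
    list(
      weights = tibble::tibble(
        predictor = colnames(X), raw_weight = raw, pct = 100 * raw / sum(raw)
      ),
      r_squared = r2,
      n = n
    ),
    class = "relative_weights"
  )
}

#' @export
print.relative_weights <- function(x, ...) {
  cat(sprintf("Relative weights (n = %d, R^2 = %.4f):\n", x$n, x$r_squared))
  y <- as.data.frame(x$weights)
  y$pct <- round(y$pct)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing predictor
#' `j` on the remaining predictors; computed as the diagonal of the inverse
#' predictor correlation matrix. A VIF of 1 indicates orthogonal
#' predictors; perfectly collinear predictors yield infinite VIFs, reported
#' as `Inf` with a warning.
#'
#' @param predictors A named data frame or list of two or more non-constant
#'   numeric predictor vectors.
#' @return Named numeric vector of VIFs, each >= 1.
#' @export
compute_vif <- function(predictors) {
  X <- as.data.frame(predictors)
  if (ncol(X) < 2) stop("need at least two predictors", call. = FALSE)
  X <- X[complete.cases(X), , drop = FALSE]
  if (any(vapply(X, sd, numeric(1)) == 0)) stop("constant predictor", call. = FALSE)
  R <- stats::cor(as.matrix(X))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-12) {
    warning("perfect collinearity among predictors; VIFs are unbounded", call. = FALSE)
    return(setNames(rep(Inf, ncol(X)), colnames(X)))
  }
  setNames(diag(solve(R)), colnames(X))
}

#' Partition shell-size control between age and growth rate, per site
#'
#' For every site with enough data, regresses hinge size on age-at-harvest
#' and the growth residual (the per-shell deviation from the global
#' standardized growth curve) and partitions the explained variance with
#' [relative_weights()]. The age share measures how much of the site's size
#' variation is demographic (harvest pressure selecting younger or older
#' oysters); the growth share measures how much is environmental (growing
#' conditions varying across the deposit).
#'
#' Sites with short or weak sequences give unstable partitions, so a result
#' is flagged `reliable` only when it rests on at least `min_n` complete
#' records spread over at least `min_levels` distinct stratigraphic levels;
#' unreliable rows are retained but excluded from headline reporting.
#'
#' @param x An [assemblage()].
#' @param residuals Residual table from [compute_residuals()] under the
#'   global growth curve.
#' @param min_n Minimum complete records for a reliable result (default 30).
#' @param min_levels Minimum distinct stratigraphic levels (default 4).
#' @return A tibble with one row per site: `site`, `n`, `n_levels`,
#'   `r_squared`, `weight_age_pct`, `weight_growth_pct`, `reliable`.
#'   Percentages are full precision; round for Table-style reports.
#' @export
partition_by_site <- function(x, residuals, min_n = 30, min_levels = 4) {
  rec <- as_assemblage(x)$records
  d <- dplyr::inner_join(
    rec[c("shell_id", "site", "layer_order", "hinge_mm", "age_years")],
    residuals[c("shell_id", "residual_mm")],
    by = "shell_id"
  )
  d <- d[!is.na(d$hinge_mm) & !is.na(d$age_years) & !is.na(d$residual_mm), , drop = FALSE]
  out <- list()
  for (s in sort(unique(d$site))) {
    ds <- d[d$site == s, , drop = FALSE]
    n <- nrow(ds)
    n_levels <- length(unique(ds$layer_order[!is.na(ds$layer_order)]))
    if (n < 5) next
    rw <- tryCatch(
      relative_weights(
        ds$hinge_mm,
        data.frame(age = as.numeric(ds$age_years), growth = ds$residual_mm)
      ),
      error = function(e) NULL
    )
    if (is.null(rw)) next
    w <- setNames(rw$weights$pct, rw$weights$predictor)
    out[[length(out) + 1]] <- tibble::tibble(
      site = s, n = n, n_levels = n_levels,
      r_squared = rw$r_squared,
      weight_age_pct = unname(w["age"]),
      weight_growth_pct = unname(w["growth"]),
      reliable = n >= min_n && n_levels >= min_levels
    )
  }
  if (length(out) == 0) {
    message("no site had enough complete records for a partition")
    return(tibble::tibble(
      site = character(0), n = integer(0), n_levels = integer(0),
      r_squared = numeric(0), weight_age_pct = numeric(0),
      weight_growth_pct = numeric(0), reliable = logical(0)
    ))
  }
  dplyr::bind_rows(out)
}

#' Assemblage-level attribution summary of a site partition
#'
#' Aggregates a [partition_by_site()] table to a single attribution: the
#' record-count-weighted mean of the per-site age and growth shares, and
#' which factor holds the majority. Used to read off which causal channel
#' dominates a (real or simulated) assemblage.
#'
#' @param partition A tibble from [partition_by_site()].
#' @param reliable_only Use only rows flagged reliable when any exist
#'   (default `TRUE`).
#' @return A list with `weight_age_pct`, `weight_growth_pct`, `majority`
#'   (`"age"` or `"growth"`), and `n_sites`.
#' @export
attribution_summary <- function(partition, reliable_only = TRUE) {
  if (nrow(partition) == 0) stop("empty partition table", call. = FALSE)
  if (reliable_only && any(partition$reliable)) {
    partition <- partition[partition$reliable, , drop = FALSE]
  }
  wa <- sum(partition$weight_age_pct * partition$n) / sum(partition$n)
  list(
    weight_age_pct = wa,
    weight_growth_pct = 100 - wa,
    majority = if (wa > 50) "age" else "growth",
    n_sites = nrow(partition)
  )
}
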