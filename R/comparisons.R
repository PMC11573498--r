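#' Significance stars for a p-value
#'
#' Maps p-values to the conventional star count: `p < 0.05` one star,
#' `p < 0.01` two, `p < 0.001` three, otherwise zero.
#'
#' @param p Numeric vector of p-values.
#' @return Integer vector of star counts (0-3).
#' @export
significance_stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  ifelse(p < 0.001, 3L, ifelse(p < 0.01, 2L, ifelse(p < 0.05, 1L, 0L)))
}

comparison_row <- function(variable, group_a, n_a, group_b, n_b, test,
                           statistic, p_raw, level = "pooled", site = NA_character_) {
  tibble::tibble(
    variable = variable, level = level, site = site,
    group_a = group_a, n_a = n_a, group_b = group_b, n_b = n_b,
    test = test, statistic = statistic, p_raw = p_raw,
    p_adjusted = p_raw, stars = significance_stars(p_raw)
  )
}

#' Mann-Whitney U test (rank-sum) for two independent samples
#'
#' Two-sided test of distributional shift between two samples. For small
#' samples (both groups below `exact_max`) the p-value is computed by exact
#' enumeration of all assignments of the pooled values to the two groups,
#' which remains valid in the presence of ties; otherwise the tie-corrected
#' normal approximation to the U statistic is used (mid-ranks, variance
#' reduced by the standard tie term, no continuity correction). Ties are
#' pervasive in assemblage data because ages are small integers.
#'
#' The reported statistic is the U count for the first sample
#' (`U = rank sum of a - n_a(n_a+1)/2` with mid-ranks), and the two-sided
#' exact p-value is the permutation probability of a U at least as far from
#' its null mean `n_a n_b / 2` as observed.
#'
#' @param a,b Numeric samples, non-empty.
#' @param exact_max Use exact enumeration when both samples have fewer than
#'   this many observations (default 8).
#' @return A one-row comparison tibble with columns `variable`, `level`,
#'   `site`, `group_a`, `n_a`, `group_b`, `n_b`, `test`, `statistic`,
#'   `p_raw`, `p_adjusted` (equal to `p_raw` here), `stars`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(10, 11, 12)) # U = 0, exact p = 0.1
mann_whitney <- function(a, b, exact_max = 8) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty", call. = FALSE)
  n_a <- length(a); n_b <- length(b)
  u_obs <- u_statistic(a, b)
  if (n_a < exact_max && n_b < exact_max) {
    p <- mw_exact_p(a, b, u_obs)
    test <- "mann_whitney_u_exact"
  } else {
    p <- mw_normal_p(a, b, u_obs)
    test <- "mann_whitney_u"
  }
  comparison_row("value", "a", n_a, "b", n_b, test, u_obs, p)
}

u_statistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

# Exact permutation p-value: enumerate all C(n, n_a) splits of the pooled
# sample. Valid with ties; two-sided via distance from the null mean.
mw_exact_p <- function(a, b, u_obs) {
  pooled <- c(a, b)
  n <- length(pooled); n_a <- length(a)
  r <- rank(pooled)
  splits <- utils::combn(n, n_a)
  offset <- n_a * (n_a + 1) / 2
  u_all <- colSums(matrix(r[splits], nrow = n_a)) - offset
  mu <- n_a * (n - n_a) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Tie-corrected normal approximation (mid-ranks), no continuity correction.
mw_normal_p <- function(a, b, u_obs) {
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (u_obs - n_a * n_b / 2) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Variance-ratio F test for equality of spread
#'
#' Two-sided F test of equal variances with the larger sample variance in
#' the numerator, used to compare the range of sizes between periods.
#'
#' @param a,b Numeric samples with at least 2 observations each.
#' @return A one-row comparison tibble (see [mann_whitney()]).
#' @export
variance_f_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2", call. = FALSE)
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) stop("both sample variances are zero", call. = FALSE)
  if (va >= vb) {
    f <- va / vb; df1 <- length(a) - 1; df2 <- length(b) - 1
  } else {
    f <- vb / va; df1 <- length(b) - 1; df2 <- length(a) - 1
  }
  p <- min(1, 2 * pf(f, df1, df2, lower.tail = FALSE))
  comparison_row("value", "a", length(a), "b", length(b), "variance_f", f, p)
}

#' Levene's test for equality of spread
#'
#' One-way ANOVA on absolute deviations from each group's center. The
#' classical test centers on the mean (the default); centering on the
#' median gives the Brown-Forsythe variant, more robust under skew.
#' Delegates to [car::leveneTest()].
#'
#' @param a,b Numeric samples with at least 2 observations each.
#' @param center `"mean"` (classical Levene, default) or `"median"`
#'   (Brown-Forsythe).
#' @return A one-row comparison tibble (see [mann_whitney()]).
#' @export
levene_test <- function(a, b, center = c("mean", "median")) {
  center <- match.arg(center)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2", call. = FALSE)
  if (var(a) == 0 && var(b) == 0) stop("both sample variances are zero", call. = FALSE)
  grp <- factor(rep(c("a", "b"), c(length(a), length(b))))
  centre_fun <- if (center == "mean") mean else median
  res <- car::leveneTest(c(a, b), grp, center = centre_fun)
  comparison_row(
    "value", "a", length(a), "b", length(b),
    paste0("levene_", center), res[1, "F value"], res[1, "Pr(>F)"]
  )
}

#' Bonferroni adjustment of p-values
#'
#' `p_adjusted = min(1, m * p)` with family size `m` defaulting to the
#' number of p-values supplied. Monotone and never decreasing.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param family_size Family size `m`; defaults to `length(p)`.
#' @return Adjusted p-values.
#' @export
#' @examples
#' bonferroni_adjust(c(0.01, 0.04, 0.2)) # 0.03 0.12 0.60
bonferroni_adjust <- function(p, family_size = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]", call. = FALSE)
  pmin(1, family_size * p)
}

#' Period comparisons of sizes, ages, and growth residuals
#'
#' Reproduces the comparison structure of a two-period assemblage analysis:
#' for each requested variable, a pooled Mesolithic-vs-Neolithic
#' Mann-Whitney test over all shells, plus one test per site at which both
#' periods are sufficiently represented. Within one variable the site-level
#' tests form a single Bonferroni family (`m` = number of qualifying
#' sites); pooled tests are single comparisons and are reported unadjusted
#' (`p_adjusted = p_raw`).
#'
#' `"length"` is the monotone hinge-to-length transform, so its rank tests
#' coincide with the hinge tests; it is offered for reporting symmetry.
#' Unassigned-period shells are excluded.
#'
#' @param x An [assemblage()].
#' @param residuals Optional residual table from [compute_residuals()];
#'   required when `"residual"` is among `variables`.
#' @param variables Any of `"hinge"`, `"length"`, `"age"`, `"residual"`.
#' @param sites Optional character vector restricting the site-level tests.
#'   Requested sites lacking one period are skipped with a message.
#' @param min_n Minimum observations per period for a site-level test
#'   (default 5).
#' @param coefficient Hinge-to-length coefficient for `"length"`.
#' @return A tibble of comparison rows (one per test) with columns
#'   `variable`, `level` (`"pooled"` or `"site"`), `site`, `group_a`,
#'   `n_a`, `group_b`, `n_b`, `test`, `statistic`, `p_raw`, `p_adjusted`,
#'   `stars`.
#' @export
compare_by_period <- function(x, residuals = NULL,
                              variables = c("hinge", "age", "residual"),
                              sites = NULL, min_n = 5, coefficient = 35.4) {
  variables <- match.arg(variables, c("hinge", "length", "age", "residual"), several.ok = TRUE)
  rec <- as_assemblage(x)$records
  rec <- rec[rec$period %in% c("Mesolithic", "Neolithic"), , drop = FALSE]
  if (nrow(rec) == 0) stop("no records with an assigned period", call. = FALSE)
  if ("residual" %in% variables) {
    if (is.null(residuals)) {
      message("no residuals supplied; dropping variable 'residual'")
      variables <- setdiff(variables, "residual")
    } else {
      rec <- dplyr::left_join(rec, residuals[c("shell_id", "residual_mm")], by = "shell_id")
    }
  }

  value_of <- function(d, variable) {
    switch(variable,
      hinge = d$hinge_mm,
      length = {
        v <- rep(NA_real_, nrow(d))
        ok <- !is.na(d$hinge_mm) & d$hinge_mm > 0
        v[ok] <- suppressWarnings(hinge_to_length(d$hinge_mm[ok], coefficient))
        v
      },
      age = as.numeric(d$age_years),
      residual = if ("residual_mm" %in% names(d)) d$residual_mm else rep(NA_real_, nrow(d))
    )
  }

  out <- list()
  for (variable in variables) {
    v <- value_of(rec, variable)
    meso <- v[rec$period == "Mesolithic" & !is.na(v)]
    neo <- v[rec$period == "Neolithic" & !is.na(v)]
    if (length(meso) > 0 && length(neo) > 0) {
      row <- mann_whitney(meso, neo)
      row$variable <- variable
      row$group_a <- "Mesolithic"; row$group_b <- "Neolithic"
      out[[length(out) + 1]] <- row
    }
    site_rows <- list()
    candidate_sites <- if (is.null(sites)) sort(unique(rec$site)) else sites
    for (s in candidate_sites) {
      d <- rec[rec$site == s, , drop = FALSE]
      vs <- value_of(d, variable)
      sm <- vs[d$period == "Mesolithic" & !is.na(vs)]
      sn <- vs[d$period == "Neolithic" & !is.na(vs)]
      if (length(sm) < min_n || length(sn) < min_n) {
        if (!is.null(sites)) {
          message("site '", s, "' skipped for '", variable, "': needs >= ", min_n, " per period")
        }
        next
      }
      row <- mann_whitney(sm, sn)
      row$variable <- variable
      row$level <- "site"; row$site <- s
      row$group_a <- "Mesolithic"; row$group_b <- "Neolithic"
      site_rows[[length(site_rows) + 1]] <- row
    }
    if (length(site_rows) > 0) {
      site_tab <- dplyr::bind_rows(site_rows)
      site_tab$p_adjusted <- bonferroni_adjust(site_tab$p_raw, family_size = nrow(site_tab))
      site_tab$stars <- significance_stars(site_tab$p_adjusted)
      out[[length(out) + 1]] <- site_tab
    }
  }
  if (length(out) == 0) stop("no comparison had both periods represented", call. = FALSE)
  dplyr::bind_rows(out)
}
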