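#' Layer-by-layer summaries for one site
#'
#' Builds the stratigraphic sequence of a site: one row per layer in
#' stratigraphic order (larger `layer_order` = later), with counts, means
#' and standard deviations of hinge size, age and growth residual, plus the
#' layer's period (the period of the majority of its shells). Spit- and
#' context-excavated sites are treated identically once `layer_order` is
#' assigned.
#'
#' @param x An [assemblage()].
#' @param site Site label.
#' @param residuals Optional residual table from [compute_residuals()].
#' @return A tibble sorted by `layer_order` with columns `site`,
#'   `layer_label`, `layer_order`, `period`, `n_hinge`, `n_age`,
#'   `n_residual`, `mean_hinge`, `sd_hinge`, `mean_age`, `sd_age`,
#'   `mean_residual`, `sd_residual`. Means are `NA` where a layer has no
#'   observation of the variable.
#' @export
layer_sequence <- function(x, site, residuals = NULL) {
  rec <- as_assemblage(x)$records
  rec <- rec[rec$site == site, , drop = FALSE]
  if (nrow(rec) == 0) stop("no records for site '", site, "'", call. = FALSE)
  rec <- rec[!is.na(rec$layer_order), , drop = FALSE]
  if (length(unique(rec$layer_order)) < 2) {
    stop("site '", site, "' needs at least 2 stratigraphically ordered layers", call. = FALSE)
  }
  if (!is.null(residuals)) {
    rec <- dplyr::left_join(rec, residuals[c("shell_id", "residual_mm")], by = "shell_id")
  } else {
    rec$residual_mm <- NA_real_
  }
  mean_or_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  sd_or_na <- function(v) if (sum(!is.na(v)) < 2) NA_real_ else sd(v, na.rm = TRUE)
  majority_period <- function(p) {
    tab <- sort(table(p), decreasing = TRUE)
    names(tab)[1]
  }
  out <- rec |>
    dplyr::group_by(layer_order = .data$layer_order) |>
    dplyr::summarise(
      layer_label = .data$layer_label[1],
      period = majority_period(.data$period),
      n_hinge = sum(!is.na(.data$hinge_mm)),
      n_age = sum(!is.na(.data$age_years)),
      n_residual = sum(!is.na(.data$residual_mm)),
      mean_hinge = mean_or_na(.data$hinge_mm),
      sd_hinge = sd_or_na(.data$hinge_mm),
      mean_age = mean_or_na(as.numeric(.data$age_years)),
      sd_age = sd_or_na(as.numeric(.data$age_years)),
      mean_residual = mean_or_na(.data$residual_mm),
      sd_residual = sd_or_na(.data$residual_mm),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$layer_order)
  tibble::add_column(out, site = site, .before = 1)
}

#' Trend descriptors of a stratigraphic sequence
#'
#' Describes the layer-to-layer movement of hinge size, age and growth
#' residual along a site's sequence: maximal runs of consecutive same-sign
#' changes, and the concordance between age and hinge movements (the
#' fraction of adjacent-layer steps in which both move in the same
#' direction). Because measurements carry one-decimal precision, steps
#' smaller than a dead-band (0.05 mm for hinge and residual, 0.1 y for age,
#' by default) count as ties; ties break runs and count as non-concordant.
#'
#' @param sequence A layer table from [layer_sequence()] with at least 3
#'   layers.
#' @param deadband Named numeric vector of tie thresholds for `hinge`,
#'   `age`, `residual`.
#' @return An object of class `trend_descriptors`: a list with `runs` (a
#'   named list of tibbles `span`, `sign` per variable — spans partition
#'   the step sequence) and `concordance_age_size` (in `[0, 1]`, or `NA`
#'   when no steps have both variables).
#' @export
trend_descriptors <- function(sequence,
                              deadband = c(hinge = 0.05, age = 0.1, residual = 0.05)) {
  if (nrow(sequence) < 3) stop("need at least 3 layers", call. = FALSE)
  sequence <- sequence[order(sequence$layer_order), , drop = FALSE]
  step_signs <- function(means, band) {
    d <- diff(means)
    s <- sign(d)
    s[!is.na(d) & abs(d) < band] <- 0
    s
  }
  runs_of <- function(s) {
    s_clean <- s[!is.na(s)]
    if (length(s_clean) == 0) {
      return(tibble::tibble(span = integer(0), sign = integer(0)))
    }
    r <- rle(s_clean)
    tibble::tibble(span = r$lengths, sign = as.integer(r$values))
  }
  cols <- c(hinge = "mean_hinge", age = "mean_age", residual = "mean_residual")
  signs <- lapply(names(cols), function(v) step_signs(sequence[[cols[[v]]]], deadband[[v]]))
  names(signs) <- names(cols)
  runs <- lapply(signs, runs_of)

  both <- !is.na(signs$hinge) & !is.na(signs$age)
  concordance <- if (!any(both)) {
    NA_real_
  } else {
    mean(signs$hinge[both] != 0 & signs$age[both] != 0 &
      signs$hinge[both] == signs$age[both])
  }
  structure(
    list(runs = runs, concordance_age_size = concordance),
    class = "trend_descriptors"
  )
}

#' @export
print.trend_descriptors <- function(x, ...) {
  for (v in names(x$runs)) {
    r <- x$runs[[v]]
    lab <- if (nrow(r) == 0) {
      "(no steps)"
    } else {
      paste(sprintf("%s%d", c("-", "=", "+")[r$sign + 2], r$span), collapse = " ")
    }
    cat(sprintf("  %-8s runs: %s\n", v, lab))
  }
  cat(sprintf("  age-size concordance: %s\n", format(x$concordance_age_size, digits = 3)))
  invisible(x)
}
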