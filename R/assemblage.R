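#' Construct an assemblage of shell records
#'
#' An assemblage is the central data container of the package: one row per
#' measured oyster shell, carrying its identifiers, stratigraphic position,
#' hinge size and sclerochronological age. Records must satisfy the shell
#' record invariants (see [validate_shell_records()]): a positive hinge
#' recorded to one decimal of a millimetre, an integer age of at least one
#' year, at least one of the two present, and stratigraphic label and rank
#' present together or not at all.
#'
#' @param records A data frame with columns `shell_id`, `site`, `period`,
#'   `layer_label`, `layer_order`, `hinge_mm`, `age_years`. Missing optional
#'   columns are added as `NA`.
#' @param provenance Free-text description of where the records came from.
#' @param reject Handling of invalid rows: `"error"` (default) stops with a
#'   row-indexed message, `"drop"` removes them and attaches the diagnostics
#'   as the `"diagnostics"` attribute with a warning.
#' @param enforce_decimals Enforce the one-decimal caliper convention on
#'   `hinge_mm` (default `TRUE`). Set to `FALSE` for exact model-generated
#'   sizes that have not passed through a measurement step.
#'
#' @return An object of class `assemblage`: a list with elements `records`
#'   (a tibble) and `provenance`.
#' @seealso [read_assemblage()], [summarize_metrics()]
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   shell_id = c("a", "b"), site = "S1", period = "Mesolithic",
#'   hinge_mm = c(6.0, 7.5), age_years = c(3L, 5L)
#' )
#' assemblage(rec, provenance = "example")
assemblage <- function(records, provenance = "unknown", reject = c("error", "drop"),
                       enforce_decimals = TRUE) {
  reject <- match.arg(reject)
  records <- tibble::as_tibble(records)
  for (col in setdiff(ASSEMBLAGE_COLUMNS, names(records))) {
    records[[col]] <- if (col == "layer_order") NA_integer_ else if (col %in% c("hinge_mm")) NA_real_ else if (col == "age_years") NA_integer_ else NA_character_
  }
  records <- records[ASSEMBLAGE_COLUMNS]
  records$shell_id <- as.character(records$shell_id)
  records$site <- as.character(records$site)
  records$period <- normalize_period(records$period)
  records$layer_label <- as.character(records$layer_label)
  records$layer_order <- as.integer(records$layer_order)
  records$hinge_mm <- as.numeric(records$hinge_mm)
  records$age_years <- as.integer(records$age_years)

  diag <- validate_shell_records(records, enforce_decimals = enforce_decimals)
  if (nrow(diag) > 0) {
    if (reject == "error") {
      stop(
        "invalid shell records:\n",
        paste0("  row ", diag$row, " (", diag$shell_id, "): ", diag$reason, collapse = "\n"),
        call. = FALSE
      )
    }
    warning(nrow(diag), " invalid record(s) dropped; see attr(, \"diagnostics\")", call. = FALSE)
    records <- records[-diag$row, , drop = FALSE]
  }
  if (anyDuplicated(records$shell_id)) {
    dup <- unique(records$shell_id[duplicated(records$shell_id)])
    stop("duplicate shell_id value(s): ", paste(head(dup, 5), collapse = ", "), call. = FALSE)
  }
  out <- structure(
    list(records = records, provenance = provenance),
    class = "assemblage"
  )
  if (nrow(diag) > 0) attr(out, "diagnostics") <- diag
  out
}

normalize_period <- function(x) {
  x <- trimws(as.character(x))
  low <- tolower(x)
  out <- rep("unassigned", length(x))
  out[low == "mesolithic"] <- "Mesolithic"
  out[low == "neolithic"] <- "Neolithic"
  out
}

#' Validate shell records against the data-model invariants
#'
#' Checks every row of a record table and reports violations without
#' modifying the data. The invariants are: `hinge_mm`, if present, positive
#' and recorded to one decimal place (the caliper convention); `age_years`,
#' if present, an integer of at least 1 (ages are annual-line counts, and
#' the youngest harvested oyster is one winter old); at least one of hinge
#' and age present; `layer_order` present exactly when `layer_label` is.
#'
#' @param records A data frame with the canonical columns.
#' @param enforce_decimals Check the one-decimal convention on `hinge_mm`
#'   (default `TRUE`).
#' @return A tibble of diagnostics with columns `row`, `shell_id`, `reason`;
#'   zero rows when everything is valid.
#' @export
validate_shell_records <- function(records, enforce_decimals = TRUE) {
  rows <- integer(0); ids <- character(0); reasons <- character(0)
  note <- function(i, reason) {
    rows <<- c(rows, i)
    ids <<- c(ids, ifelse(is.na(records$shell_id[i]), "<NA>", records$shell_id[i]))
    reasons <<- c(reasons, reason)
  }
  for (i in seq_len(nrow(records))) {
    h <- records$hinge_mm[i]; a <- records$age_years[i]
    if (is.na(h) && is.na(a)) note(i, "both hinge_mm and age_years missing")
    if (!is.na(h)) {
      if (h <= 0) note(i, "hinge_mm must be > 0")
      else if (enforce_decimals && abs(h * 10 - round(h * 10)) > 1e-6) {
        note(i, "hinge_mm not recorded to one decimal place")
      }
    }
    if (!is.na(a) && a < 1) note(i, "age_years must be >= 1")
    if (is.na(records$layer_label[i]) != is.na(records$layer_order[i])) {
      note(i, "layer_label and layer_order must be present together")
    }
  }
  tibble::tibble(row = rows, shell_id = ids, reason = reasons)
}

#' Read an assemblage from a delimited text file
#'
#' Reads a comma-separated, UTF-8 file with a header row into an
#' [assemblage()]. Arbitrary source headers are supported through a column
#' mapping; empty cells and the literal `NA` both parse as missing, matching
#' data exported from R. Period labels are normalized case-insensitively and
#' unrecognized labels map to `"unassigned"` (kept for site-level work,
#' excluded from period comparisons). Rows that violate the record
#' invariants — including non-numeric hinge or age cells — are rejected with
#' row-indexed diagnostics.
#'
#' @param path Path to the CSV file.
#' @param format_spec Optional column mapping: a named character vector (or
#'   list) from canonical names (`shell_id`, `site`, `period`, `layer_label`,
#'   `layer_order`, `hinge_mm`, `age_years`) to the file's headers, or the
#'   path of a YAML file holding such a mapping under the key `columns`.
#'   Canonical names absent from the mapping are looked up verbatim.
#' @param provenance Provenance string; defaults to the file path.
#' @return An [assemblage()]. Rejected rows (if any) are attached as the
#'   `"diagnostics"` attribute and reported in a warning.
#' @export
read_assemblage <- function(path, format_spec = NULL, provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  mapping <- resolve_format_spec(format_spec)
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), comment = "#", progress = FALSE
  )
  required <- c("shell_id", "site")
  for (canon in names(mapping)) {
    if (canon %in% required && !(mapping[[canon]] %in% names(raw))) {
      stop("required column '", mapping[[canon]], "' (", canon, ") not found in ", path, call. = FALSE)
    }
  }
  out <- tibble::tibble(.rows = nrow(raw))
  for (canon in ASSEMBLAGE_COLUMNS) {
    src <- mapping[[canon]]
    out[[canon]] <- if (!is.null(src) && src %in% names(raw)) blank_to_na(raw[[src]]) else NA_character_
  }

  # Numeric conversion with row-indexed diagnostics; offending rows are
  # rejected, not silently coerced.
  bad <- tibble::tibble(row = integer(0), shell_id = character(0), reason = character(0))
  num <- suppressWarnings(as.numeric(out$hinge_mm))
  bad_h <- which(!is.na(out$hinge_mm) & is.na(num))
  agei <- suppressWarnings(as.numeric(out$age_years))
  bad_a <- which(!is.na(out$age_years) & is.na(agei))
  bad_frac <- which(!is.na(agei) & abs(agei - round(agei)) > 1e-8)
  if (length(c(bad_h, bad_a, bad_frac)) > 0) {
    bad <- tibble::tibble(
      row = c(bad_h, bad_a, bad_frac),
      shell_id = out$shell_id[c(bad_h, bad_a, bad_frac)],
      reason = c(
        rep("non-numeric hinge_mm cell", length(bad_h)),
        rep("non-numeric age_years cell", length(bad_a)),
        rep("non-integer age_years cell", length(bad_frac))
      )
    )
  }
  out$hinge_mm <- num
  agei[c(bad_a, bad_frac)] <- NA
  out$age_years <- as.integer(round(agei))
  ord <- suppressWarnings(as.integer(out$layer_order))
  out$layer_order <- ord

  keep <- !(seq_len(nrow(out)) %in% bad$row)
  asm <- suppressWarnings(
    assemblage(out[keep, , drop = FALSE], provenance = provenance, reject = "drop")
  )
  inv_diag <- attr(asm, "diagnostics")
  if (!is.null(inv_diag)) inv_diag$row <- which(keep)[inv_diag$row] # back to file rows
  diag <- rbind(bad, inv_diag)
  if (nrow(diag) > 0) {
    diag <- diag[order(diag$row), , drop = FALSE]
    attr(asm, "diagnostics") <- diag
    warning(nrow(diag), " row(s) rejected while reading ", path,
      "; see attr(, \"diagnostics\")",
      call. = FALSE
    )
  }
  asm
}

blank_to_na <- function(x) {
  x <- trimws(x)
  x[x == "" | x == "NA"] <- NA_character_
  x
}

resolve_format_spec <- function(format_spec) {
  identity_map <- as.list(setNames(ASSEMBLAGE_COLUMNS, ASSEMBLAGE_COLUMNS))
  if (is.null(format_spec)) return(identity_map)
  if (is.character(format_spec) && length(format_spec) == 1 && file.exists(format_spec)) {
    cfg <- yaml::read_yaml(format_spec)
    format_spec <- if (!is.null(cfg$columns)) cfg$columns else cfg
  }
  format_spec <- as.list(format_spec)
  unknown <- setdiff(names(format_spec), ASSEMBLAGE_COLUMNS)
  if (length(unknown) > 0) {
    stop("unknown canonical column(s) in format_spec: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  utils::modifyList(identity_map, format_spec)
}

#' Write an assemblage to the canonical CSV format
#'
#' Writes the canonical columns with hinge sizes formatted to one decimal
#' and ages as integers, so that a write/read round trip reproduces every
#' present value exactly.
#'
#' @param x An [assemblage()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_assemblage <- function(x, path) {
  x <- as_assemblage(x)
  rec <- x$records
  rec$hinge_mm <- ifelse(is.na(rec$hinge_mm), NA_character_, sprintf("%.1f", rec$hinge_mm))
  rec$age_years <- ifelse(is.na(rec$age_years), NA_character_, sprintf("%d", rec$age_years))
  readr::write_csv(rec, path, na = "")
  invisible(path)
}

#' Coerce to an assemblage
#'
#' @param x An `assemblage`, or a data frame of shell records.
#' @param ... Passed to [assemblage()] for data-frame input.
#' @return An `assemblage`.
#' @export
as_assemblage <- function(x, ...) {
  if (inherits(x, "assemblage")) return(x)
  if (is.data.frame(x)) return(assemblage(x, ...))
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"), " to assemblage", call. = FALSE)
}

#' @export
print.assemblage <- function(x, ...) {
  n <- count_shells(x)
  cat("<assemblage> ", n$n_total, " shells from ",
    length(unique(x$records$site)), " site(s)\n",
    sep = ""
  )
  cat("  hinge+age: ", n$n_both, "  hinge only: ", n$n_hinge_only,
    "  age only: ", n$n_age_only, "\n",
    sep = ""
  )
  cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Count shells by measurement availability
#'
#' @param x An [assemblage()] or record data frame.
#' @return A list with `n_total`, `n_both`, `n_hinge_only`, `n_age_only`,
#'   `n_hinge`, `n_age`. The first four always satisfy
#'   `n_total == n_both + n_hinge_only + n_age_only`.
#' @export
count_shells <- function(x) {
  rec <- as_assemblage(x)$records
  has_h <- !is.na(rec$hinge_mm)
  has_a <- !is.na(rec$age_years)
  list(
    n_total = nrow(rec),
    n_both = sum(has_h & has_a),
    n_hinge_only = sum(has_h & !has_a),
    n_age_only = sum(!has_h & has_a),
    n_hinge = sum(has_h),
    n_age = sum(has_a)
  )
}

#' Six-number summaries of hinge, derived length, and age
#'
#' Computes minimum, first quartile, median, mean, third quartile and
#' maximum for hinge size, for total shell length derived from each present
#' hinge via [hinge_to_length()], and for age — each over present values
#' only. Quantiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7), fixed so summary tables are reproducible.
#'
#' @param x An [assemblage()].
#' @param coefficient Hinge-to-length coefficient, passed to
#'   [hinge_to_length()].
#' @return A tibble with one row per variable (`hinge_mm`, `length_mm`,
#'   `age_years`) and columns `n`, `min`, `q1`, `median`, `mean`, `q3`,
#'   `max`, at full precision. The print method applies the reporting
#'   convention (one decimal).
#' @export
summarize_metrics <- function(x, coefficient = 35.4) {
  rec <- as_assemblage(x)$records
  if (nrow(rec) == 0) stop("empty assemblage", call. = FALSE)
  hinge <- rec$hinge_mm[!is.na(rec$hinge_mm)]
  length_mm <- if (length(hinge) > 0) hinge_to_length(hinge, coefficient) else numeric(0)
  age <- as.numeric(rec$age_years[!is.na(rec$age_years)])
  six <- function(v) {
    if (length(v) == 0) {
      return(c(n = 0, min = NA, q1 = NA, median = NA, mean = NA, q3 = NA, max = NA))
    }
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    c(
      n = length(v), min = min(v), q1 = q[1], median = q[2],
      mean = mean(v), q3 = q[3], max = max(v)
    )
  }
  out <- rbind(six(hinge), six(length_mm), six(age))
  out <- tibble::as_tibble(out)
  out <- tibble::add_column(out,
    variable = c("hinge_mm", "length_mm", "age_years"), .before = 1
  )
  class(out) <- c("oyster_metrics", class(out))
  out
}

#' @export
print.oyster_metrics <- function(x, digits = 1, ...) {
  y <- as.data.frame(x)
  num <- c("min", "q1", "median", "mean", "q3", "max")
  y[num] <- lapply(y[num], function(v) round(v, digits))
  cat("Summary metrics (present values only):\n")
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
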