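#' Multi-source table of small-area prevalence estimates
#'
#' An `estimate_table` holds one prevalence point estimate per (area, source)
#' cell together with its sampling standard error, on the percent scale
#' (0--100).  Sampling standard errors are treated as known throughout the
#' package; when a survey publishes only a 95% confidence interval the
#' standard error is recovered with [se_from_interval()].  Cells a source did
#' not cover are recorded in the `present` mask and contribute no likelihood
#' term to any model.
#'
#' @param areas character vector of unique area labels (length A).
#' @param sources character vector of unique source labels (length S).
#' @param y A x S numeric matrix of prevalence point estimates in percent.
#' @param se A x S numeric matrix of sampling standard errors, in
#'   percentage points.
#' @param present optional A x S logical matrix marking available cells;
#'   defaults to `!is.na(y)`.
#' @param year optional length-S integer vector of mid-survey calendar years
#'   (required only by the time-trend model).
#' @param adjusted logical flag marking a table of bias-adjusted estimates
#'   produced by [bias_adjusted_estimates()].
#'
#' @return An object of class `estimate_table`: a list with elements
#'   `areas`, `sources`, `year`, `y`, `se`, `present`, `adjusted`.
#' @seealso [read_estimates()], [validate_table()], [simulate_dataset()]
#' @export
#' @examples
#' tab <- estimate_table(
#'   areas = c("A1", "A2"), sources = c("S1", "S2"),
#'   y = matrix(c(22, 25, 20, 24), 2, 2),
#'   se = matrix(1, 2, 2)
#' )
#' tab
estimate_table <- function(areas, sources, y, se, present = NULL,
                           year = NULL, adjusted = FALSE) {
  areas <- as.character(areas)
  sources <- as.character(sources)
  y <- as.matrix(y)
  se <- as.matrix(se)
  A <- length(areas)
  S <- length(sources)
  if (!all(dim(y) == c(A, S)) || !all(dim(se) == c(A, S)))
    stop("y and se must be A x S matrices matching the label vectors")
  if (is.null(present)) present <- !is.na(y)
  present <- as.matrix(present)
  if (!all(dim(present) == c(A, S)))
    stop("present mask must be A x S")
  storage.mode(present) <- "logical"
  if (!is.null(year)) {
    if (length(year) != S) stop("year must have one entry per source")
    year <- as.integer(year)
  }
  dimnames(y) <- dimnames(se) <- dimnames(present) <- list(areas, sources)
  structure(
    list(areas = areas, sources = sources, year = year,
         y = y, se = se, present = present, adjusted = isTRUE(adjusted)),
    class = "estimate_table"
  )
}

#' @export
print.estimate_table <- function(x, ...) {
  cat(sprintf("<estimate_table%s> %d areas x %d sources, %d/%d cells present\n",
              if (x$adjusted) " (bias-adjusted)" else "",
              length(x$areas), length(x$sources),
              sum(x$present), length(x$present)))
  if (!is.null(x$year))
    cat("  source years:", paste(x$year, collapse = ", "), "\n")
  rng <- range(x$y[x$present])
  cat(sprintf("  estimates %.1f-%.1f%%, se %.2f-%.2f pp\n",
              rng[1], rng[2],
              min(x$se[x$present]), max(x$se[x$present])))
  invisible(x)
}

#' @export
dim.estimate_table <- function(x) c(length(x$areas), length(x$sources))

#' Recover a standard error from a 95% confidence interval
#'
#' Converts a symmetric 95% Wald interval to a standard error by dividing its
#' width by 3.92 (twice the 1.96 normal quantile).  This is how sampling
#' standard errors are obtained for sources that publish only confidence
#' limits.
#'
#' @param lower,upper numeric vectors of interval limits in percent.
#' @return numeric vector of standard errors in percentage points.
#' @export
#' @examples
#' se_from_interval(20, 24) # 4 / 3.92
se_from_interval <- function(lower, upper) {
  if (any(upper <= lower))
    stop("degenerate interval: upper must exceed lower")
  (upper - lower) / 3.92
}

#' Validate an estimate table
#'
#' Checks every structural requirement a table must meet before model
#' fitting: estimates strictly inside (0, 100), positive standard errors, no
#' duplicate labels, at least two areas and two sources, at least one present
#' cell per area, and at least two present cells per source (with a single
#' cell a source's bias variance is unidentifiable).
#'
#' @param table an [estimate_table()].
#' @return A `validation_report`: a data frame with columns `severity`
#'   (`"error"` or `"warning"`), `where` (cell or global locator) and
#'   `message`.  An empty report means the table is valid.
#' @export
validate_table <- function(table) {
  stopifnot(inherits(table, "estimate_table"))
  issues <- list()
  add <- function(severity, where, message)
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, where = where, message = message,
      stringsAsFactors = FALSE)

  A <- length(table$areas); S <- length(table$sources)
  if (anyDuplicated(table$areas))
    add("error", "areas", "duplicate area labels")
  if (anyDuplicated(table$sources))
    add("error", "sources", "duplicate source labels")
  if (A < 2) add("error", "areas", "at least 2 areas required")
  if (S < 2) add("error", "sources", "at least 2 sources required")

  for (i in seq_len(A)) {
    if (!any(table$present[i, ]))
      add("error", table$areas[i], "area has no present cells")
  }
  for (j in seq_len(S)) {
    np <- sum(table$present[, j])
    if (np < 2)
      add("error", table$sources[j],
          "source has < 2 present cells: bias variance unidentifiable")
  }
  idx <- which(table$present, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    loc <- paste0(table$areas[i], "/", table$sources[j])
    yv <- table$y[i, j]; sv <- table$se[i, j]
    if (!is.finite(yv) || yv <= 0 || yv >= 100)
      add("error", loc, sprintf("estimate %g not strictly inside (0, 100)", yv))
    if (!is.finite(sv) || sv <= 0)
      add("error", loc, sprintf("standard error %g not strictly positive", sv))
  }

  rep <- if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(), where = character(),
               message = character(), stringsAsFactors = FALSE)
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("<validation_report> no issues\n")
  } else {
    cat(sprintf("<validation_report> %d issue(s):\n", nrow(x)))
    print.data.frame(x)
  }
  invisible(x)
}

# stop unless the table passes validation with no errors
assert_valid_table <- function(table) {
  rep <- validate_table(table)
  errs <- rep[rep$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0)
    stop("invalid estimate table: ",
         paste(sprintf("[%s] %s", errs$where, errs$message), collapse = "; "))
  invisible(table)
}

#' Read an estimate table from CSV
#'
#' Long-form CSV with header `area,source,year,estimate,se,ci_lower,ci_upper`
#' (the `year`, `se` and `ci_*` columns are optional).  Each row is one
#' (area, source) cell; rows absent from the file become non-present cells.
#' Every row must supply either `se` or both confidence limits; when both are
#' given `se` wins, and a disagreement beyond 1e-6 is reported as a warning
#' in the attached validation report.  An asymmetric interval (midpoint more
#' than 0.1 percentage points away from the estimate) also draws a warning,
#' since the width/3.92 conversion assumes a symmetric Wald interval.
#'
#' @param path CSV file path.
#' @return An [estimate_table()].  Reader warnings are attached as the
#'   `"io_report"` attribute (a `validation_report`).
#' @export
read_estimates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("area", "source", "estimate")
  if (!all(need %in% names(df)))
    stop("missing mandatory column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  has_se <- "se" %in% names(df)
  has_ci <- all(c("ci_lower", "ci_upper") %in% names(df))

  if (anyDuplicated(df[c("area", "source")]))
    stop("duplicate (area, source) rows in ", path)

  issues <- list()
  note <- function(severity, where, message)
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, where = where, message = message,
      stringsAsFactors = FALSE)

  se_row <- function(r) {
    loc <- paste0(df$area[r], "/", df$source[r])
    se_given <- has_se && !is.na(df$se[r])
    ci_given <- has_ci && !is.na(df$ci_lower[r]) && !is.na(df$ci_upper[r])
    if (!se_given && !ci_given)
      stop("row ", r, " (", loc, "): neither se nor a confidence interval given")
    if (ci_given) {
      se_ci <- se_from_interval(df$ci_lower[r], df$ci_upper[r])
      mid <- (df$ci_lower[r] + df$ci_upper[r]) / 2
      if (abs(mid - df$estimate[r]) > 0.1)
        note("warning", loc,
             "asymmetric interval: width/3.92 conversion assumes symmetry")
      if (se_given && abs(se_ci - df$se[r]) > 1e-6)
        note("warning", loc, sprintf(
          "se column (%.6g) disagrees with interval-derived se (%.6g); se column used",
          df$se[r], se_ci))
    }
    if (se_given) df$se[r] else se_ci
  }
  se_vals <- vapply(seq_len(nrow(df)), se_row, numeric(1))

  areas <- unique(df$area)
  sources <- unique(df$source)
  A <- length(areas); S <- length(sources)
  y <- se <- matrix(NA_real_, A, S)
  present <- matrix(FALSE, A, S)
  ai <- match(df$area, areas); sj <- match(df$source, sources)
  for (r in seq_len(nrow(df))) {
    y[ai[r], sj[r]] <- df$estimate[r]
    se[ai[r], sj[r]] <- se_vals[r]
    present[ai[r], sj[r]] <- TRUE
  }

  year <- NULL
  if ("year" %in% names(df) && any(!is.na(df$year))) {
    year <- vapply(seq_len(S), function(j) {
      yr <- unique(df$year[sj == j & !is.na(df$year)])
      if (length(yr) > 1)
        stop("source ", sources[j], " has conflicting years")
      if (length(yr) == 0) NA_integer_ else as.integer(yr)
    }, integer(1))
  }

  tab <- estimate_table(areas, sources, y, se, present, year)
  io_rep <- if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(), where = character(),
               message = character(), stringsAsFactors = FALSE)
  class(io_rep) <- c("validation_report", "data.frame")
  attr(tab, "io_report") <- io_rep
  tab
}

#' Write an estimate table to CSV
#'
#' Inverse of [read_estimates()]: writes one row per present cell in the
#' long-form dialect, so `read_estimates(write_estimates(tab, f))`
#' round-trips up to floating-point formatting.
#'
#' @param table an [estimate_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(table, path) {
  stopifnot(inherits(table, "estimate_table"))
  if (length(table$areas) == 0 || length(table$sources) == 0)
    stop("cannot write an empty table")
  idx <- which(table$present, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(
    area = table$areas[idx[, 1]],
    source = table$sources[idx[, 2]],
    year = if (is.null(table$year)) NA_integer_ else table$year[idx[, 2]],
    estimate = table$y[idx],
    se = table$se[idx]
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
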