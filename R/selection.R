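#' Spearman rank correlation with tie correction
#'
#' For tie-free data returns the classical rank-difference form
#' `Rs = 1 - 6 * sum(d_i^2) / (n^3 - n)`; with ties (grade levels always
#' tie) it returns the product-moment correlation of average ranks, the
#' standard tie-corrected estimator, to which the classical form reduces
#' when there are no ties. A constant `x` yields 0 with a warning.
#'
#' @param x,y numeric vectors of equal length `n >= 3`; `y` must not be
#'   constant.
#' @return Correlation in `[-1, 1]`.
#' @examples
#' spearmanRho(1:5, c(1, 3, 2, 5, 4))  # 1 - 24/120 = 0.8
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(y) == 0) stop("y is constant")
  if (stats::sd(x) == 0) {
    warning("x is constant; returning rho = 0")
    return(0)
  }
  rx <- rank(x); ry <- rank(y)
  if (!anyDuplicated(x) && !anyDuplicated(y)) {
    1 - 6 * sum((rx - ry)^2) / (n^3 - n)
  } else {
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
}

#' Correlation strength bins
#'
#' Bins `|rho|` into the strength groups used for feature screening:
#' `[0, 0.3)` weak, `[0.3, 0.5)` moderate, `[0.5, 0.8)` strong,
#' `[0.8, 1]` very strong. The bins partition `[0, 1]` (half-open, closed
#' on the left).
#'
#' @param rho numeric vector with `|rho| <= 1`.
#' @return Factor with levels `weak`, `moderate`, `strong`, `very_strong`.
#' @export
classifyStrength <- function(rho) {
  if (any(abs(rho) > 1)) stop("|rho| must not exceed 1")
  lev <- c("weak", "moderate", "strong", "very_strong")
  idx <- findInterval(abs(rho), c(0, 0.3, 0.5, 0.8))
  factor(lev[idx], levels = lev)
}

#' Screen features by Spearman correlation with the grade
#'
#' Correlates every feature column with the numeric grade level (A = 1 ...
#' D = 4) using [spearmanRho()], bins each `|rho|` with
#' [classifyStrength()], and selects the `very_strong` group, preserving
#' [featureNames()] order. An empty selection is returned with a warning,
#' not an error.
#'
#' @param feature_table data.frame containing numeric feature columns
#'   (extra columns such as `id`/`grade` are ignored).
#' @param grades grade labels (`A`-`D`, character or factor) or numeric
#'   levels, one per row; at least 8 rows spanning at least 2 grades.
#' @return List with `selected` (character vector of feature names) and
#'   `report` (data.frame: `feature`, `rho`, `abs_rho`, `strength`,
#'   `selected`).
#' @export
selectFeatures <- function(feature_table, grades) {
  if (is.numeric(grades)) {
    level <- as.numeric(grades)
  } else {
    g <- as.character(grades)
    if (!all(g %in% gradeLabels())) stop("unknown grade label")
    level <- match(g, gradeLabels())
  }
  if (nrow(feature_table) != length(level)) stop("row/label length mismatch")
  if (nrow(feature_table) < 8) stop("need at least 8 rows")
  if (length(unique(level)) < 2) stop("need at least 2 distinct grades")
  cols <- names(feature_table)[vapply(feature_table, is.numeric, logical(1))]
  cols <- setdiff(cols, c("level"))
  known <- featureNames()
  cols <- c(intersect(known, cols), setdiff(cols, known))
  rho <- vapply(cols, function(cn) {
    x <- feature_table[[cn]]
    if (stats::sd(x) == 0) {
      warning(sprintf("feature '%s' is constant; rho = 0", cn))
      0
    } else spearmanRho(x, level)
  }, numeric(1))
  strength <- classifyStrength(rho)
  report <- data.frame(feature = cols, rho = unname(rho),
                       abs_rho = abs(unname(rho)),
                       strength = strength,
                       selected = strength == "very_strong",
                       row.names = NULL)
  sel <- report$feature[report$selected]
  if (length(sel) == 0)
    warning("no feature reaches the very_strong band; empty selection")
  list(selected = sel, report = report)
}

#' Write the Spearman screening report and selection
#'
#' @param selection result of [selectFeatures()].
#' @param csv_path path for the full per-feature report CSV.
#' @param json_path optional path for the selected-name list as JSON.
#' @return `csv_path`, invisibly.
#' @export
writeSelectionReport <- function(selection, csv_path, json_path = NULL) {
  utils::write.csv(selection$report, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(selection$selected, json_path)
  invisible(csv_path)
}
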