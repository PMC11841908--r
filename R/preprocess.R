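#' Mean imputation of missing survey cells
#'
#' Replaces each missing cell by the mean of its column's observed values.
#' Appropriate when missingness is low and completely at random; applied at
#' the section level so the trust count stays constant across sections.
#'
#' @param dataset data frame of numeric columns, possibly with `NA`s.
#' @return The same data frame with no missing cells; observed values and all
#'   attributes are untouched.
#' @examples
#' impute_mean(data.frame(x = c(1, 2, NA, 3)))
#' @export
impute_mean <- function(dataset) {
  for (j in seq_along(dataset)) {
    x <- dataset[[j]]
    miss <- is.na(x)
    if (all(miss)) stop("column ", names(dataset)[j], " is fully missing")
    if (any(miss)) dataset[[j]][miss] <- mean(x[!miss])
  }
  dataset
}

#' Cronbach's alpha for a block of items
#'
#' Internal-consistency reliability: `alpha = m/(m-1) * (1 - sum(var_i) / var_total)`
#' where `var_i` are the item sample variances and `var_total` the variance of
#' the row sums (n-1 denominator throughout).
#'
#' @param items numeric matrix or data frame, one column per item (`m >= 2`),
#'   no missing values.
#' @return Cronbach's alpha (a single number, at most 1).
#' @examples
#' cronbach_alpha(cbind(1:10, 1:10))  # 1
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  m <- ncol(items)
  if (m < 2) stop("need at least 2 items")
  if (anyNA(items)) stop("items must not contain missing values")
  vt <- stats::var(rowSums(items))
  if (vt == 0) stop("zero total variance")
  m / (m - 1) * (1 - sum(apply(items, 2, stats::var)) / vt)
}

#' Per-section reliability report
#'
#' Computes Cronbach's alpha for each section's item block and flags values
#' inside the conventionally adequate band `[0.50, 0.95]`.
#'
#' @param items item-level data frame with a `section_of` attribute (or see
#'   `section_of`).
#' @param section_of optional named character vector mapping item columns to
#'   section ids; defaults to the data frame's attribute.
#' @param band numeric length-2 acceptability band for alpha.
#' @return A data frame with columns `section`, `n_items`, `alpha`,
#'   `acceptable`.
#' @export
reliability_report <- function(items, section_of = attr(items, "section_of"),
                               band = c(0.50, 0.95)) {
  if (is.null(section_of)) stop("no section mapping available")
  sections <- unique(section_of)
  rows <- lapply(sections, function(s) {
    block <- items[, names(section_of)[section_of == s], drop = FALSE]
    a <- cronbach_alpha(block)
    data.frame(section = s, n_items = ncol(block), alpha = a,
               acceptable = a >= band[1] & a <= band[2])
  })
  do.call(rbind, rows)
}

#' Descriptive summary of survey columns
#'
#' Mean, median, SD, min, max and n per column, in the layout of a standard
#' survey descriptives table.
#'
#' @param dataset data frame of numeric columns with no missing cells.
#' @return A data frame with one row per column.
#' @export
describe_sections <- function(dataset) {
  if (ncol(dataset) == 0 || nrow(dataset) == 0) stop("empty dataset")
  if (anyNA(dataset)) stop("impute missing values first")
  out <- data.frame(
    section = names(dataset),
    mean = vapply(dataset, mean, 0),
    median = vapply(dataset, stats::median, 0),
    sd = vapply(dataset, stats::sd, 0),
    min = vapply(dataset, min, 0),
    max = vapply(dataset, max, 0),
    n = nrow(dataset))
  rownames(out) <- NULL
  out
}

#' Pearson correlation matrix of survey sections
#'
#' @param dataset data frame of numeric columns, no missing cells, >= 2 rows.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
section_correlations <- function(dataset) {
  if (anyNA(dataset)) stop("impute missing values first")
  if (nrow(dataset) < 2) stop("need at least 2 rows")
  sds <- vapply(dataset, stats::sd, 0)
  if (any(sds == 0)) stop("zero-variance column: ",
                          paste(names(dataset)[sds == 0], collapse = ", "))
  stats::cor(as.matrix(dataset))
}

#' Optional z-score outlier filter
#'
#' Drops rows containing any cell more than `z_max` column SDs from its column
#' mean. Off by default in the pipeline; a cleanup convenience only.
#'
#' @param dataset numeric data frame without missing cells.
#' @param z_max absolute z-score threshold.
#' @return The filtered data frame.
#' @export
remove_outliers <- function(dataset, z_max = 4) {
  z <- scale(as.matrix(dataset))
  keep <- rowSums(abs(z) > z_max, na.rm = TRUE) == 0
  dataset[keep, , drop = FALSE]
}
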