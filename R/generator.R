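#' Default configuration for the maternity-survey generator
#'
#' Returns a generator configuration calibrated to the published trust-level
#' summaries of the 2021 NHS maternity patient-experience survey: 122 trusts,
#' eight section scores S1..S8 on a 0-10 scale with the printed means, standard
#' deviations and inter-section Pearson correlations, per-section Cronbach
#' alphas for the 50 underlying questions, and a 7% missing-cell rate.
#'
#' @param n_rows number of trusts (rows) to generate.
#' @param missing_rate fraction of cells set missing, completely at random.
#' @param seed integer seed controlling all randomness downstream.
#' @return A list of class `"survey_config"` with components `n_rows`,
#'   `section_means`, `section_sds`, `correlation`, `items_per_section`,
#'   `target_alphas`, `missing_rate`, `scale_bounds` and `seed`.
#' @examples
#' cfg <- maternity_survey_config(seed = 1)
#' cfg$section_means[["S5"]]
#' @export
maternity_survey_config <- function(n_rows = 122L, missing_rate = 0.07, seed = 1L) {
  sections <- paste0("S", 1:8)
  means <- c(5.10, 7.95, 8.26, 8.13, 8.35, 7.03, 8.28, 7.51)
  sds   <- c(0.51, 0.36, 0.35, 0.36, 0.31, 0.53, 0.32, 0.36)
  low <- c(
    0.63,
    0.61, 0.80,
    0.49, 0.50, 0.63,
    0.41, 0.43, 0.61, 0.77,
    0.33, 0.34, 0.43, 0.50, 0.57,
    0.32, 0.43, 0.60, 0.50, 0.61, 0.65,
    0.42, 0.66, 0.67, 0.50, 0.57, 0.50, 0.61)
  R <- diag(8)
  R[upper.tri(R)] <- low   # row-wise lower triangle == column-wise upper
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  dimnames(R) <- list(sections, sections)
  alphas <- c(0.83, 0.75, 0.79, 0.74, 0.92, 0.53, 0.70, 0.92)
  # 50 questions over 8 sections; exact split is not published, use a near-even one
  items <- c(6L, 6L, 6L, 6L, 6L, 7L, 6L, 7L)
  names(means) <- names(sds) <- names(alphas) <- names(items) <- sections
  survey_config(n_rows = n_rows, section_means = means, section_sds = sds,
                correlation = R, items_per_section = items,
                target_alphas = alphas, missing_rate = missing_rate,
                seed = seed)
}

#' Construct and validate a survey generator configuration
#'
#' @param n_rows row (trust) count.
#' @param section_means,section_sds numeric vectors, one value per section.
#' @param correlation symmetric correlation matrix with unit diagonal; it is
#'   repaired to the nearest positive-semidefinite correlation matrix at
#'   generation time if needed.
#' @param items_per_section integer item counts per section (>= 2 wherever a
#'   nonzero reliability target is set).
#' @param target_alphas per-section Cronbach alpha targets in `[0, 1)`.
#' @param missing_rate fraction of cells to blank, in `[0, 1)`.
#' @param scale_bounds length-2 numeric; scores are clipped to this range.
#' @param seed integer seed.
#' @return A validated list of class `"survey_config"`.
#' @export
survey_config <- function(n_rows, section_means, section_sds, correlation,
                          items_per_section = NULL, target_alphas = NULL,
                          missing_rate = 0, scale_bounds = c(0, 10),
                          seed = 1L) {
  p <- length(section_means)
  stopifnot(n_rows >= 1, length(section_sds) == p,
            nrow(correlation) == p, ncol(correlation) == p)
  if (!isSymmetric(unname(correlation), tol = 1e-8))
    stop("correlation matrix must be symmetric")
  if (any(abs(diag(correlation) - 1) > 1e-8))
    stop("correlation matrix must have unit diagonal")
  if (any(correlation < -1 - 1e-8 | correlation > 1 + 1e-8))
    stop("correlation entries must lie in [-1, 1]")
  if (any(section_sds <= 0)) stop("section_sds must be positive")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (!is.null(target_alphas)) {
    if (any(target_alphas < 0 | target_alphas >= 1))
      stop("target_alphas must be in [0, 1)")
    if (is.null(items_per_section)) stop("items_per_section required with target_alphas")
    if (any(items_per_section < 2 & target_alphas > 0))
      stop("items_per_section must be >= 2 wherever a nonzero alpha target is set")
  }
  sections <- names(section_means)
  if (is.null(sections)) sections <- paste0("S", seq_len(p))
  names(section_means) <- names(section_sds) <- sections
  dimnames(correlation) <- list(sections, sections)
  structure(list(n_rows = as.integer(n_rows), section_means = section_means,
                 section_sds = section_sds, correlation = correlation,
                 items_per_section = items_per_section,
                 target_alphas = target_alphas, missing_rate = missing_rate,
                 scale_bounds = scale_bounds, seed = as.integer(seed)),
            class = "survey_config")
}

#' Repair a correlation matrix to the nearest positive-semidefinite one
#'
#' Printed correlation matrices are rounded and occasionally fail positive
#' semidefiniteness. This projects onto the nearest (Frobenius) correlation
#' matrix by Higham's alternating-projections method; an already-PSD input is
#' returned unchanged.
#'
#' @param mat symmetric matrix with unit diagonal.
#' @param tol eigenvalue tolerance below which repair is triggered.
#' @return A positive-semidefinite correlation matrix of the same dimension.
#' @examples
#' repair_correlation(diag(3))
#' @export
repair_correlation <- function(mat, tol = 1e-10) {
  mat <- as.matrix(mat)
  if (!isSymmetric(unname(mat), tol = 1e-8)) stop("matrix must be symmetric")
  ev <- eigen(mat, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= -tol) return(mat)
  out <- as.matrix(Matrix::nearPD(mat, corr = TRUE, do2eigen = TRUE)$mat)
  dimnames(out) <- dimnames(mat)
  out
}

#' Invert the Spearman-Brown relation for equicorrelated items
#'
#' For `m` equicorrelated items with common inter-item correlation `rho`,
#' Cronbach's alpha is `m * rho / (1 + (m - 1) * rho)`. This returns the
#' `rho` at which the population alpha equals a requested target, used to
#' calibrate the compound-symmetry item generator.
#'
#' @param alpha target Cronbach alpha in `[0, 1)`.
#' @param m item count, at least 2.
#' @return The inter-item correlation `rho` in `[0, 1)`.
#' @examples
#' invert_spearman_brown(0.92, 6)
#' @export
invert_spearman_brown <- function(alpha, m) {
  stopifnot(m >= 2)
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)")
  alpha / (m - alpha * (m - 1))
}

#' Generate section-level survey scores
#'
#' Draws rows from a multivariate Gaussian with the configured means, SDs and
#' (PSD-repaired) correlation matrix, then clips to the score scale. At the
#' published parameters the bounds sit more than five SDs from every mean, so
#' clipping is numerically negligible.
#'
#' @param config a [survey_config()].
#' @param n_rows optional override of `config$n_rows`.
#' @param seed optional override of `config$seed`.
#' @return A data frame with one numeric column per section; attributes
#'   `section_of` (column-to-section map) and `level = "section"`.
#' @examples
#' d <- generate_sections(maternity_survey_config(seed = 7))
#' dim(d)
#' @export
generate_sections <- function(config, n_rows = config$n_rows, seed = config$seed) {
  R <- repair_correlation(config$correlation)
  S <- diag(config$section_sds) %*% R %*% diag(config$section_sds)
  set.seed(seed)
  x <- MASS::mvrnorm(n_rows, mu = config$section_means, Sigma = S)
  x <- pmin(pmax(x, config$scale_bounds[1]), config$scale_bounds[2])
  d <- as.data.frame(x)
  names(d) <- names(config$section_means)
  attr(d, "section_of") <- stats::setNames(names(d), names(d))
  attr(d, "level") <- "section"
  d
}

#' Generate question-level item blocks around section scores
#'
#' For each section with score column y and target alpha, builds `m`
#' equicorrelated items `y + (g_j - mean(g))` with `g_j` iid Gaussian noise
#' whose variance is chosen so the item block has exact compound symmetry at
#' the inverted Spearman-Brown correlation; the population Cronbach alpha then
#' equals the target and each row's item mean equals its section score exactly.
#'
#' @param config a [survey_config()] with `items_per_section` and
#'   `target_alphas` set.
#' @param sections section-level data frame from [generate_sections()].
#' @param seed seed for the item noise (distinct from the section seed).
#' @return A data frame of item columns named `<section>_Q<j>`, with a
#'   `section_of` attribute mapping items to sections and `level = "item"`.
#' @export
generate_items <- function(config, sections, seed = config$seed + 1L) {
  stopifnot(!is.null(config$items_per_section), !is.null(config$target_alphas))
  set.seed(seed)
  n <- nrow(sections)
  cols <- list(); section_of <- character(0)
  for (s in names(config$items_per_section)) {
    m <- config$items_per_section[[s]]
    alpha <- config$target_alphas[[s]]
    if (m < 2 && alpha > 0) stop("need >= 2 items for a nonzero alpha target: ", s)
    rho <- invert_spearman_brown(alpha, m)
    sd_y <- config$section_sds[[s]]
    # noise variance giving compound symmetry at rho after row-centering
    sigma2 <- m * sd_y^2 * (1 - rho) / (1 + rho * (m - 1))
    g <- matrix(stats::rnorm(n * m, sd = sqrt(sigma2)), n, m)
    e <- g - rowMeans(g)
    block <- sections[[s]] + e
    colnames(block) <- paste0(s, "_Q", seq_len(m))
    cols[[s]] <- block
    section_of <- c(section_of, stats::setNames(rep(s, m), colnames(block)))
  }
  d <- as.data.frame(do.call(cbind, cols))
  names(d) <- names(section_of)
  attr(d, "section_of") <- section_of
  attr(d, "level") <- "item"
  d
}

#' Blank a fixed number of cells completely at random
#'
#' Sets exactly `round(rate * n_cells)` cells to `NA`, chosen uniformly
#' without replacement, never leaving a column fully missing.
#'
#' @param dataset a data frame of numeric columns.
#' @param rate missing fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return The data frame with `NA`s injected; all attributes preserved.
#' @examples
#' d <- inject_missing(as.data.frame(matrix(1, 122, 8)), 0.07, seed = 1)
#' sum(is.na(d))  # 68
#' @export
inject_missing <- function(dataset, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  n_cells <- nrow(dataset) * ncol(dataset)
  n_miss <- round(rate * n_cells)
  if (n_miss == 0) return(dataset)
  set.seed(seed)
  repeat {
    idx <- sample.int(n_cells, n_miss)
    cols <- (idx - 1L) %/% nrow(dataset) + 1L
    if (all(tabulate(cols, ncol(dataset)) < nrow(dataset))) break
  }
  out <- dataset
  for (j in seq_len(ncol(out))) {
    rows <- (idx[cols == j] - 1L) %% nrow(out) + 1L
    out[rows, j] <- NA_real_
  }
  out
}

#' Generate a complete synthetic survey dataset
#'
#' Convenience wrapper running [generate_sections()], optionally
#' [generate_items()], and [inject_missing()] on the section scores.
#'
#' @param config a [survey_config()]; defaults to the published maternity
#'   survey calibration.
#' @param items logical; also generate question-level item blocks?
#' @return A list with `sections` (with missing cells if configured), `items`
#'   (or `NULL`), and the `config`.
#' @export
generate_survey <- function(config = maternity_survey_config(), items = FALSE) {
  sections <- generate_sections(config)
  item_df <- if (items) generate_items(config, sections) else NULL
  if (config$missing_rate > 0)
    sections <- inject_missing(sections, config$missing_rate,
                               seed = config$seed + 2L)
  list(sections = sections, items = item_df, config = config)
}

#' Write / read a survey matrix as a delimited text table
#'
#' Comma-separated with a header row and `NA` as the missing marker.
#'
#' @param dataset data frame of survey scores.
#' @param path file path.
#' @return `read_survey` returns the data frame with a `section_of` attribute
#'   mapping each column to its section (the part of the name before `_`).
#' @export
write_survey <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_survey
#' @export
read_survey <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  attr(d, "section_of") <- stats::setNames(sub("_.*$", "", names(d)), names(d))
  attr(d, "level") <- if (any(grepl("_Q", names(d)))) "item" else "section"
  d
}
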