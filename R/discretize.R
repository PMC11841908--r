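# Discretization of continuous section scores into ordered states C0..C(k-1).
# Bins are half-open [lo, hi) with the last bin closed; values falling exactly
# on an interior edge belong to the upper bin, and out-of-range values at
# apply time clamp to the nearest bin.

#' Interior cut points for equal-width bins
#'
#' @param values numeric vector with `max > min`.
#' @param k number of bins (2 or 3).
#' @return `k - 1` strictly increasing interior edges.
#' @examples
#' equal_width_edges(c(0, 10), 2)  # 5
#' @export
equal_width_edges <- function(values, k) {
  check_k(k)
  lo <- min(values); hi <- max(values)
  if (hi <= lo) stop("constant column cannot be binned")
  lo + seq_len(k - 1) * (hi - lo) / k
}

#' Interior cut points for equal-frequency bins
#'
#' Edges at the `j/k` sample quantiles (linear interpolation). With distinct
#' values the bin counts differ by at most one; heavy ties can break that
#' balance, in which case tied values stay together in one bin.
#'
#' @inheritParams equal_width_edges
#' @return `k - 1` interior edges.
#' @export
equal_frequency_edges <- function(values, k) {
  check_k(k)
  if (length(unique(values)) < k) stop("need at least k distinct values")
  e <- stats::quantile(values, probs = seq_len(k - 1) / k, names = FALSE, type = 7)
  if (any(duplicated(e))) stop("quantile edges collide; too many ties for k = ", k)
  e
}

#' Interior cut points from one-dimensional k-means
#'
#' Lloyd's algorithm on the raw values, initialized at the
#' `(2j - 1) / (2k)` quantiles so the fit is deterministic; edges are the
#' midpoints between sorted cluster centers.
#'
#' @inheritParams equal_width_edges
#' @return `k - 1` interior edges.
#' @export
kmeans_edges <- function(values, k) {
  check_k(k)
  centers <- sort(kmeans_1d(values, k)$centers)
  (centers[-1] + centers[-k]) / 2
}

check_k <- function(k) {
  if (!(k %in% c(2L, 3L))) stop("state count k must be 2 or 3")
}

# Deterministic 1-D k-means. At survey scale (n <= 2000) the optimal
# partition is found exactly by dynamic programming over the sorted values
# (1-D clusters are contiguous); longer vectors fall back to a
# quantile-initialized Lloyd iteration.
kmeans_1d <- function(values, k, max_iter = 100L) {
  if (length(unique(values)) < k) stop("fewer distinct values than clusters")
  if (length(values) <= 2000) kmeans_1d_dp(values, k)
  else kmeans_1d_lloyd(values, k, max_iter)
}

kmeans_1d_dp <- function(values, k) {
  ord <- order(values)
  x <- values[ord]
  n <- length(x)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  seg <- function(i, j)  # within-SS of x[i..j], vectorized over i
    (cs2[j + 1] - cs2[i]) - (cs[j + 1] - cs[i])^2 / (j - i + 1)
  dp <- matrix(Inf, k, n)
  choice <- matrix(0L, k, n)
  dp[1, ] <- seg(1, seq_len(n))
  if (k > 1) for (m in 2:k) for (j in m:n) {
    t <- (m - 1):(j - 1)
    cand <- dp[m - 1, t] + seg(t + 1, j)
    best <- which.min(cand)
    dp[m, j] <- cand[best]
    choice[m, j] <- t[best]
  }
  bounds <- integer(k + 1); bounds[k + 1] <- n
  for (m in k:2) bounds[m] <- choice[m, bounds[m + 1]]
  cl_sorted <- rep(seq_len(k), diff(bounds))
  cluster <- integer(n); cluster[ord] <- cl_sorted
  centers <- vapply(seq_len(k), function(m) mean(x[(bounds[m] + 1):bounds[m + 1]]), 0)
  list(centers = centers, cluster = cluster, withinss = dp[k, n])
}

kmeans_1d_lloyd <- function(values, k, max_iter = 100L) {
  ux <- unique(values)
  centers <- stats::quantile(values, probs = (2 * seq_len(k) - 1) / (2 * k),
                             names = FALSE, type = 7)
  if (any(duplicated(centers))) centers <- sort(ux)[round(seq(1, length(ux), length.out = k))]
  for (iter in seq_len(max_iter)) {
    d <- abs(outer(values, centers, "-"))
    assign <- max.col(-d, ties.method = "first")
    for (j in which(tabulate(assign, k) == 0)) {   # revive empty clusters
      far <- which.max(d[cbind(seq_along(values), assign)])
      centers[j] <- values[far]
      d <- abs(outer(values, centers, "-"))
      assign <- max.col(-d, ties.method = "first")
    }
    new_centers <- vapply(seq_len(k), function(j) mean(values[assign == j]), 0)
    if (max(abs(new_centers - centers)) < 1e-12) break
    centers <- new_centers
  }
  list(centers = centers, cluster = assign,
       withinss = sum((values - centers[assign])^2))
}

# Mean silhouette width of a 1-D clustering (Euclidean distance).
mean_silhouette <- function(values, cluster) {
  n <- length(values)
  d <- abs(outer(values, values, "-"))
  sizes <- tabulate(cluster, max(cluster))
  s <- vapply(seq_len(n), function(i) {
    own <- cluster == cluster[i]
    if (sizes[cluster[i]] == 1) return(0)
    a <- sum(d[i, own]) / (sizes[cluster[i]] - 1)
    b <- min(vapply(setdiff(unique(cluster), cluster[i]),
                    function(cl) mean(d[i, cluster == cl]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

#' Choose 2 versus 3 states for one variable
#'
#' Clusters the values by one-dimensional k-means at each candidate count and
#' picks the count maximizing mean silhouette width; ties go to the smaller
#' count. The within-cluster sum of squares per candidate (the elbow curve) is
#' attached as a diagnostic attribute.
#'
#' @param values numeric vector with at least 4 distinct values.
#' @param candidates candidate state counts.
#' @return The selected k, with attributes `silhouette` and `elbow`.
#' @export
select_state_count <- function(values, candidates = c(2L, 3L)) {
  if (length(unique(values)) < 4) stop("need at least 4 distinct values")
  fits <- lapply(candidates, function(k) kmeans_1d(values, k))
  sil <- vapply(seq_along(candidates),
                function(i) mean_silhouette(values, fits[[i]]$cluster), 0)
  elbow <- vapply(fits, function(f) f$withinss, 0)
  k <- candidates[which.max(sil)]   # which.max takes the first (smaller k) on ties
  structure(k, silhouette = stats::setNames(sil, candidates),
            elbow = stats::setNames(elbow, candidates))
}

#' Build a binning specification for a dataset
#'
#' Applies one of the three binning methods column-wise under a state-count
#' scheme: `"two_state"` forces k = 2 everywhere, `"three_state"` forces
#' k = 3, and `"mixed"` selects k per variable by silhouette.
#'
#' @param dataset clean numeric data frame.
#' @param method `"equal_width"`, `"equal_frequency"` or `"kmeans"`.
#' @param scheme `"two_state"`, `"three_state"` or `"mixed"`.
#' @return An object of class `"binning_spec"`: per-variable state count,
#'   interior edges, state labels, and the fitted range.
#' @examples
#' spec <- binning_spec(data.frame(x = c(0, 2, 5, 7, 10)), "equal_width", "two_state")
#' spec$vars$x$edges  # 5
#' @export
binning_spec <- function(dataset,
                         method = c("equal_width", "equal_frequency", "kmeans"),
                         scheme = c("mixed", "two_state", "three_state")) {
  method <- match.arg(method)
  scheme <- match.arg(scheme)
  if (anyNA(dataset)) stop("impute missing values first")
  edge_fun <- switch(method, equal_width = equal_width_edges,
                     equal_frequency = equal_frequency_edges,
                     kmeans = kmeans_edges)
  vars <- lapply(dataset, function(x) {
    k <- switch(scheme, two_state = 2L, three_state = 3L,
                mixed = as.integer(select_state_count(x)))
    list(k = k, edges = as.numeric(edge_fun(x, k)),
         labels = paste0("C", seq_len(k) - 1L),
         range = range(x))
  })
  structure(list(method = method, scheme = scheme, vars = vars),
            class = "binning_spec")
}

#' @export
print.binning_spec <- function(x, ...) {
  cat("Binning spec:", x$method, "/", x$scheme, "\n")
  for (v in names(x$vars))
    cat(sprintf("  %-4s k=%d  edges: %s\n", v, x$vars[[v]]$k,
                paste(signif(x$vars[[v]]$edges, 4), collapse = ", ")))
  invisible(x)
}

#' Discretize a dataset under a binning specification
#'
#' Each value maps to the state whose half-open interval contains it; values
#' on an interior edge go to the upper bin and out-of-range values clamp to
#' the boundary bins.
#'
#' @param dataset numeric data frame with the spec's columns.
#' @param spec a [binning_spec()].
#' @return A data frame of ordered factors labelled `C0..C(k-1)`, with the
#'   spec attached as attribute `"binning_spec"`.
#' @export
apply_binning <- function(dataset, spec) {
  stopifnot(inherits(spec, "binning_spec"),
            all(names(spec$vars) %in% names(dataset)))
  out <- dataset[names(spec$vars)]
  for (v in names(spec$vars)) {
    vs <- spec$vars[[v]]
    state <- findInterval(out[[v]], vs$edges) + 1L  # edge value -> upper bin
    out[[v]] <- factor(vs$labels[state], levels = vs$labels, ordered = TRUE)
  }
  attr(out, "binning_spec") <- spec
  out
}

#' One-call discretization
#'
#' Convenience wrapper: fit a [binning_spec()] and apply it.
#'
#' @inheritParams binning_spec
#' @return Discrete data frame of ordered factors (see [apply_binning()]).
#' @export
discretize <- function(dataset, method = "equal_width", scheme = "mixed") {
  apply_binning(dataset, binning_spec(dataset, method, scheme))
}

#' Write / read a binning specification as plain text
#'
#' A human-readable, replayable record of the discretization: method, scheme,
#' and per-variable state counts and edges.
#'
#' @param spec a [binning_spec()].
#' @param path file path.
#' @export
write_binning_spec <- function(spec, path) {
  lines <- c(paste("method", spec$method), paste("scheme", spec$scheme))
  for (v in names(spec$vars)) {
    vs <- spec$vars[[v]]
    lines <- c(lines, sprintf("var %s k=%d range=%s edges=%s", v, vs$k,
                              paste(format(vs$range, digits = 17), collapse = ","),
                              paste(format(vs$edges, digits = 17), collapse = ",")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_binning_spec
#' @export
read_binning_spec <- function(path) {
  lines <- readLines(path)
  method <- sub("^method ", "", lines[1])
  scheme <- sub("^scheme ", "", lines[2])
  vars <- list()
  for (ln in lines[-(1:2)]) {
    parts <- strsplit(ln, " ")[[1]]
    v <- parts[2]
    kv <- function(key) sub(paste0("^", key, "="), "", parts[grepl(paste0("^", key, "="), parts)])
    k <- as.integer(kv("k"))
    vars[[v]] <- list(k = k,
                      edges = as.numeric(strsplit(kv("edges"), ",")[[1]]),
                      labels = paste0("C", seq_len(k) - 1L),
                      range = as.numeric(strsplit(kv("range"), ",")[[1]]))
  }
  structure(list(method = method, scheme = scheme, vars = vars),
            class = "binning_spec")
}
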