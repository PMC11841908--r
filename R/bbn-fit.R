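#' Fit a discrete Bayesian belief network to survey data
#'
#' The package's central modelling function. Continuous section scores are
#' discretized into ordered states (see [binning_spec()]), a structure is
#' learned by the requested algorithm, and conditional probability tables are
#' fitted with Laplace smoothing. Already-discrete data (a data frame of
#' factors) skips the discretization step.
#'
#' @param data numeric data frame of section scores, or a data frame of
#'   factors already discretized.
#' @param algorithm structure learner: `"gtt"` (Greedy Thick Thinning,
#'   default), `"bs"` (score-based search with restarts) or `"pc"`
#'   (constraint-based).
#' @param scheme state-count scheme for discretization: `"mixed"` (silhouette
#'   choice of 2 vs 3 states per variable, default), `"two_state"` or
#'   `"three_state"`.
#' @param method binning method: `"equal_width"` (default),
#'   `"equal_frequency"` or `"kmeans"`.
#' @param max_parents parent limit during learning.
#' @param restarts random restarts for `"bs"`.
#' @param ci_alpha significance level of the PC independence tests.
#' @param ess BDeu equivalent sample size.
#' @param pseudocount CPT smoothing count.
#' @param seed integer seed (used by `"bs"`).
#' @return An object of class `"bbn"`; see [fit_cpts()] for the core fields.
#'   Adds `call`, `algorithm`, `scheme`, `method`, `spec` (the binning spec,
#'   if fitted here), `score` (total BDeu) and `data` (the discrete training
#'   data).
#' @seealso [predict.bbn()], [simulate.bbn()], [infer()], [influence_scan()]
#' @examples
#' d <- generate_sections(maternity_survey_config(seed = 3))
#' fit <- bbn(d, algorithm = "gtt", scheme = "two_state")
#' fit
#' @export
bbn <- function(data, algorithm = c("gtt", "bs", "pc"),
                scheme = c("mixed", "two_state", "three_state"),
                method = c("equal_width", "equal_frequency", "kmeans"),
                max_parents = 4, restarts = 20, ci_alpha = 0.05,
                ess = 1, pseudocount = 1, seed = 1L) {
  algorithm <- match.arg(algorithm)
  cl <- match.call()
  spec <- NULL
  if (all(vapply(data, is.numeric, TRUE))) {
    scheme <- match.arg(scheme)
    method <- match.arg(method)
    spec <- binning_spec(data, method, scheme)
    ddata <- apply_binning(data, spec)
  } else if (all(vapply(data, is.factor, TRUE))) {
    ddata <- data
    spec <- attr(data, "binning_spec")
    scheme <- if (inherits(spec, "binning_spec")) spec$scheme else NA_character_
    method <- if (inherits(spec, "binning_spec")) spec$method else NA_character_
  } else stop("data must be all-numeric or all-factor")
  structure_ <- learn_structure(ddata, algorithm, max_parents = max_parents,
                                restarts = restarts, seed = seed, ess = ess,
                                ci_alpha = ci_alpha)
  net <- fit_cpts(structure_, ddata, pseudocount)
  net$call <- cl
  net$algorithm <- algorithm
  net$scheme <- scheme
  net$method <- method
  net$spec <- spec
  net$score <- total_score(structure_, ddata, ess)
  net$data <- ddata
  net$seed <- seed
  net
}

#' @export
print.bbn <- function(x, ...) {
  a <- arcs(x)
  cat("Discrete Bayesian belief network\n")
  if (!is.null(x$algorithm))
    cat("  learner:", toupper(x$algorithm),
        if (!is.na(x$scheme)) paste0("(", x$scheme, ", ", x$method, ")"), "\n")
  cat("  nodes:  ", length(x$nodes), " (",
      paste(vapply(x$states, length, 0L), collapse = "/"), " states)\n", sep = "")
  cat("  arcs:   ", nrow(a), "\n", sep = "")
  if (nrow(a)) cat(paste0("    ", a[, 1], " -> ", a[, 2], collapse = "\n"), "\n")
  if (!is.null(x$score)) cat("  BDeu score:", format(x$score, digits = 8), "\n")
  invisible(x)
}

#' @export
summary.bbn <- function(object, ...) {
  marg <- infer(object)
  out <- list(arcs = arcs(object), score = object$score,
              algorithm = object$algorithm, scheme = object$scheme,
              marginals = marg)
  class(out) <- "summary.bbn"
  out
}

#' @export
print.summary.bbn <- function(x, ...) {
  cat("Network:", nrow(x$arcs), "arcs")
  if (!is.null(x$algorithm)) cat(" (", toupper(x$algorithm), ")", sep = "")
  cat("\n\nPrior marginals (%):\n")
  for (v in names(x$marginals)) {
    p <- round(100 * x$marginals[[v]])
    cat(sprintf("  %-4s %s\n", v,
                paste(sprintf("%s=%d", names(p), p), collapse = "  ")))
  }
  invisible(x)
}

#' @export
coef.bbn <- function(object, ...) object$cpt

#' @export
logLik.bbn <- function(object, data = object$data, ...) {
  if (is.null(data)) stop("no training data stored")
  ll <- sum(vapply(seq_len(nrow(data)), function(i)
    log(joint_probability(object,
                          vapply(data[i, , drop = FALSE], as.character, ""))), 0))
  structure(ll, df = NA_integer_, nobs = nrow(data), class = "logLik")
}

#' Predict a node's state from the other variables
#'
#' For each row of `newdata`, computes the target node's exact posterior
#' given every other column as hard evidence, and predicts the
#' maximum-posterior state.
#'
#' @param object a fitted `"bbn"`.
#' @param newdata data frame; numeric columns are discretized with the
#'   fitted binning spec, factor columns are used as-is.
#' @param node target node id.
#' @param type `"state"` for the argmax label, `"prob"` for the full
#'   posterior matrix (rows = observations, columns = states).
#' @param ... unused.
#' @return Factor of predicted states, or a probability matrix.
#' @export
predict.bbn <- function(object, newdata, node,
                        type = c("state", "prob"), ...) {
  type <- match.arg(type)
  stopifnot(node %in% object$nodes)
  if (all(vapply(newdata, is.numeric, TRUE))) {
    if (is.null(object$spec)) stop("numeric newdata but no binning spec stored")
    newdata <- apply_binning(newdata, object$spec)
  }
  others <- setdiff(object$nodes, node)
  probs <- t(vapply(seq_len(nrow(newdata)), function(i) {
    ev <- evidence(hard = vapply(newdata[i, others, drop = FALSE],
                                 as.character, ""))
    infer(object, ev, node)[[node]]
  }, numeric(length(object$states[[node]]))))
  colnames(probs) <- object$states[[node]]
  if (type == "prob") return(probs)
  factor(object$states[[node]][max.col(probs, ties.method = "first")],
         levels = object$states[[node]], ordered = TRUE)
}

#' Plot the network structure
#'
#' Renders the DAG with igraph; isolated nodes are kept so disconnected
#' sections remain visible.
#'
#' @param x a fitted `"bbn"` or a `"bbn_dag"`.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.bbn <- function(x, ...) {
  g <- igraph::graph_from_data_frame(as.data.frame(arcs(x)), directed = TRUE,
                                     vertices = data.frame(name = x$nodes))
  igraph::plot.igraph(g, vertex.size = 30, vertex.color = "lightsteelblue",
                      edge.arrow.size = 0.6, ...)
  invisible(x)
}

#' @export
plot.bbn_dag <- plot.bbn
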