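# Probabilistic sensitivity analysis: a state-doubling intervention at each
# source node, propagated by virtual (Jeffrey-style) evidence, and tabulated
# as net effects on every other node; plus a one-at-a-time CPT-perturbation
# scan in the style of GUI sensitivity tools.

#' Baseline marginal distributions of every node
#'
#' No-evidence posterior marginals, reported as percentages per state.
#'
#' @param net a fitted `"bbn"`.
#' @return Named list of percentage vectors (each sums to 100).
#' @export
baseline_marginals <- function(net) {
  lapply(infer(net), function(p) 100 * p)
}

#' Double one state of a marginal, preserving the other states' ratios
#'
#' The chosen state's probability is multiplied (default doubled) and capped
#' at `1 - eps`; the remaining states are rescaled by a common factor so the
#' vector sums to one with their mutual ratios unchanged.
#'
#' @param marginal probability vector.
#' @param state index or name of the state to boost.
#' @param multiplier boost factor, greater than 1.
#' @param eps cap margin keeping the boosted probability below 1.
#' @return The adjusted probability vector.
#' @examples
#' double_state(c(0.25, 0.75), 1)  # c(0.5, 0.5)
#' @export
double_state <- function(marginal, state, multiplier = 2, eps = 1e-6) {
  if (multiplier <= 1) stop("multiplier must exceed 1")
  if (eps <= 0 || eps >= 0.01) stop("eps must be in (0, 0.01)")
  if (abs(sum(marginal) - 1) > 1e-6) stop("marginal must sum to 1")
  i <- if (is.character(state)) match(state, names(marginal)) else state
  p <- marginal[i]
  if (p >= 1) stop("state already has probability 1; nothing to rescale")
  p_new <- min(multiplier * p, 1 - eps)
  out <- marginal * (1 - p_new) / (1 - p)
  out[i] <- p_new
  out
}

#' Impose a doubled marginal on one node and propagate
#'
#' The boosted marginal `q` is imposed on the source node by virtual evidence
#' with likelihood `q(x) / p(x)` (a Jeffrey-style update, matching what
#' adjusting a node's probability does in evidence-propagation software, not
#' an arc-cutting `do` intervention); exact inference then yields every
#' node's posterior. With `do = TRUE` the source's CPT is replaced by `q` and
#' its incoming arcs severed instead.
#'
#' @param net a fitted `"bbn"`.
#' @param source source node id.
#' @param state state to boost; defaults to the node's highest-valued state.
#' @param multiplier,eps see [double_state()].
#' @param do logical: graph-surgery semantics instead of virtual evidence.
#' @return Named list of posterior probability vectors for all nodes; the
#'   source's equals the boosted marginal.
#' @export
intervene <- function(net, source, state = NULL, multiplier = 2, eps = 1e-6,
                      do = FALSE) {
  stopifnot(source %in% net$nodes)
  states <- net$states[[source]]
  if (is.null(state)) state <- states[length(states)]
  p <- infer(net, query = source)[[source]]
  if (p[state] <= 0) stop("baseline probability of the boosted state is zero")
  q <- double_state(p, state, multiplier, eps)
  if (do) {
    net2 <- net
    net2$parents[[source]] <- character(0)
    net2$cpt[[source]] <- array(as.numeric(q), dim = length(states),
                                dimnames = list(states))
    return(infer(net2))
  }
  lik <- q / p
  infer(net, evidence(virtual = stats::setNames(list(lik), source)))
}

#' Net effect of an intervention on a target node
#'
#' Relative percent change of the target's highest-valued state:
#' `100 * (P'(top) - P(top)) / P(top)`.
#'
#' @param baseline,intervened named lists of marginals over the same states.
#' @param target target node id.
#' @return Signed percentage.
#' @export
net_effect <- function(baseline, intervened, target) {
  p <- baseline[[target]]; q <- intervened[[target]]
  top <- length(p)
  if (p[top] <= 0) stop("zero baseline probability on the top state")
  unname(100 * (q[top] - p[top]) / p[top])
}

#' Net-effect matrix over all source-target pairs
#'
#' Applies the doubling intervention at every node in turn and tabulates the
#' net effect on every other node; sources are ranked by summed absolute
#' effect, the criterion for the most influential care factor.
#'
#' @param net a fitted `"bbn"`.
#' @param multiplier,eps see [double_state()].
#' @return Object of class `"bbn_sensitivity"`: `effects` (source x target
#'   matrix, `NA` diagonal), `baseline` marginals (percent), and `ranking`.
#' @export
influence_scan <- function(net, multiplier = 2, eps = 1e-6) {
  nodes <- net$nodes
  base <- infer(net)
  # marginal d-connection: two nodes can influence each other iff they share
  # an ancestor (counting a node as its own ancestor); d-separated pairs get
  # an exact zero without touching the inference engine
  anc <- lapply(stats::setNames(nodes, nodes), function(v) {
    seen <- v
    frontier <- v
    while (length(frontier)) {
      frontier <- setdiff(unique(unlist(net$parents[frontier])), seen)
      seen <- c(seen, frontier)
    }
    seen
  })
  eff <- matrix(NA_real_, length(nodes), length(nodes),
                dimnames = list(source = nodes, target = nodes))
  for (s in nodes) {
    post <- intervene(net, s, multiplier = multiplier, eps = eps)
    for (t in setdiff(nodes, s))
      eff[s, t] <- if (length(intersect(anc[[s]], anc[[t]])) == 0) 0
                   else net_effect(base, post, t)
  }
  tot <- rowSums(abs(eff), na.rm = TRUE)
  structure(list(effects = eff, baseline = lapply(base, function(p) 100 * p),
                 ranking = names(sort(tot, decreasing = TRUE)),
                 multiplier = multiplier),
            class = "bbn_sensitivity")
}

#' @export
print.bbn_sensitivity <- function(x, digits = 1, ...) {
  cat("State-doubling sensitivity (net effect on each target's top state, %)\n")
  print(round(x$effects, digits), na.print = ".")
  cat("most influential first:", paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}

#' Write a sensitivity table as a delimited text file
#'
#' Long format: changed factor, affected factor, signed percent effect.
#'
#' @param x a `"bbn_sensitivity"`.
#' @param path file path.
#' @export
write_sensitivity <- function(x, path) {
  eff <- x$effects
  long <- do.call(rbind, lapply(rownames(eff), function(s) {
    t <- setdiff(colnames(eff), s)
    data.frame(changed = s, affected = t, net_effect_pct = eff[s, t])
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' One-at-a-time CPT perturbation scan
#'
#' Perturbs each conditional probability entry of each node by plus/minus a
#' relative fraction (renormalizing its row), recomputes the focus node's
#' marginal, and records the largest absolute change per node. Nodes are
#' labelled `high`, `mild` or `none` by thresholds on that change, mirroring
#' the colour-coding of GUI sensitivity tools.
#'
#' @param net a fitted `"bbn"`.
#' @param focus focus node id.
#' @param delta relative perturbation size (default 0.10).
#' @param thresholds two increasing cutoffs separating none/mild/high, on the
#'   max absolute marginal change.
#' @return Data frame ranked by impact: `node`, `max_change`, `level`.
#' @export
cpt_sensitivity <- function(net, focus, delta = 0.10,
                            thresholds = c(1e-4, 0.01)) {
  stopifnot(focus %in% net$nodes)
  base <- infer(net, query = focus)[[focus]]
  impact <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  for (v in net$nodes) {
    a <- net$cpt[[v]]
    k <- length(net$states[[v]])
    m <- matrix(as.numeric(a), nrow = k)
    for (col in seq_len(ncol(m))) for (row in seq_len(k)) for (sgn in c(1, -1)) {
      m2 <- m
      m2[row, col] <- max(m[row, col] * (1 + sgn * delta), 0)
      m2[, col] <- m2[, col] / sum(m2[, col])
      net2 <- net
      net2$cpt[[v]] <- array(m2, dim = dim(a), dimnames = dimnames(a))
      p <- infer(net2, query = focus)[[focus]]
      impact[v] <- max(impact[v], max(abs(p - base)))
    }
  }
  level <- cut(impact, c(-Inf, thresholds, Inf),
               labels = c("none", "mild", "high"))
  out <- data.frame(node = names(impact), max_change = as.numeric(impact),
                    level = level)
  out[order(-out$max_change), ]
}
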