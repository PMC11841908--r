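# Discrete Bayesian-network core: DAG structure, CPT fitting, BDeu scoring,
# and exact inference by variable elimination. The joint distribution is the
# usual product of per-node conditionals, P(x1..xn) = prod_i P(xi | Pa(xi)).

#' Construct a DAG structure over named nodes
#'
#' @param nodes character vector of node ids.
#' @param arcs two-column matrix or data frame of directed arcs (from, to);
#'   `NULL` for the empty graph.
#' @return An object of class `"bbn_dag"` with a per-node parent list.
#' @examples
#' g <- bbn_dag(c("A", "B"), rbind(c("A", "B")))
#' parents(g, "B")
#' @export
bbn_dag <- function(nodes, arcs = NULL) {
  stopifnot(is.character(nodes), !anyDuplicated(nodes))
  par <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
  if (!is.null(arcs) && NROW(arcs) > 0) {
    arcs <- matrix(as.character(as.matrix(arcs)), ncol = 2)
    if (!all(arcs %in% nodes)) stop("arc endpoint not among nodes")
    if (any(arcs[, 1] == arcs[, 2])) stop("self-arcs not allowed")
    key <- paste(arcs[, 1], arcs[, 2])
    if (anyDuplicated(key)) stop("duplicate arcs not allowed")
    for (i in seq_len(nrow(arcs)))
      par[[arcs[i, 2]]] <- c(par[[arcs[i, 2]]], arcs[i, 1])
  }
  g <- structure(list(nodes = nodes, parents = par), class = "bbn_dag")
  if (!check_acyclic(g)) stop("arc set contains a directed cycle")
  g
}

#' @export
print.bbn_dag <- function(x, ...) {
  a <- arcs(x)
  cat("DAG with", length(x$nodes), "nodes,", nrow(a), "arcs\n")
  if (nrow(a)) cat(paste0("  ", a[, 1], " -> ", a[, 2], collapse = "\n"), "\n")
  invisible(x)
}

#' Arc list of a DAG
#' @param dag a `"bbn_dag"` (or fitted `"bbn"`).
#' @return Two-column character matrix `(from, to)`, sorted lexicographically.
#' @export
arcs <- function(dag) {
  out <- do.call(rbind, lapply(dag$nodes, function(v) {
    p <- dag$parents[[v]]
    if (length(p)) cbind(from = p, to = v) else NULL
  }))
  if (is.null(out)) out <- matrix(character(0), 0, 2,
                                  dimnames = list(NULL, c("from", "to")))
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' @rdname arcs
#' @param node node id.
#' @export
parents <- function(dag, node) dag$parents[[node]]

#' Test acyclicity of a parent structure
#'
#' Kahn's algorithm: true iff a topological order exists.
#' @param dag a `"bbn_dag"` or a bare named parent list.
#' @return `TRUE` or `FALSE`.
#' @export
check_acyclic <- function(dag) {
  par <- if (inherits(dag, "bbn_dag") || inherits(dag, "bbn")) dag$parents else dag
  !is.null(topo_order_or_null(par))
}

topo_order_or_null <- function(par) {
  nodes <- names(par)
  indeg <- vapply(par, length, 0L)
  order <- character(0)
  avail <- nodes[indeg == 0]
  while (length(avail)) {
    v <- sort(avail)[1]               # deterministic order
    order <- c(order, v)
    avail <- setdiff(avail, v)
    for (w in nodes)
      if (v %in% par[[w]]) {
        indeg[[w]] <- indeg[[w]] - 1L
        if (indeg[[w]] == 0L) avail <- c(avail, w)
      }
  }
  if (length(order) == length(nodes)) order else NULL
}

topo_order <- function(net) {
  out <- topo_order_or_null(net$parents)
  if (is.null(out)) stop("structure is cyclic")
  out
}

state_spaces <- function(data) lapply(data, levels)

#' Fit conditional probability tables on a fixed structure
#'
#' Maximum a-posteriori CPTs with a Laplace-style pseudocount:
#' `P(x | pa) = (N(x, pa) + c) / (N(pa) + c * |states(x)|)`. With
#' `pseudocount = 0`, parent configurations never observed get uniform rows.
#' State spaces are taken from the factor levels (i.e. the binning spec), not
#' from the observed values, so states absent in a subsample still exist.
#'
#' @param structure a [bbn_dag()] whose nodes match the data columns.
#' @param data data frame of factors.
#' @param pseudocount nonnegative smoothing count (default 1).
#' @return A fitted network of class `"bbn"`: structure, state spaces and one
#'   CPT array per node (first dimension the node, then its parents).
#' @export
fit_cpts <- function(structure, data, pseudocount = 1) {
  if (nrow(data) == 0) stop("empty data")
  stopifnot(all(structure$nodes %in% names(data)))
  data <- data[structure$nodes]
  if (!all(vapply(data, is.factor, TRUE))) stop("data columns must be factors")
  states <- state_spaces(data)
  cpt <- lapply(structure$nodes, function(v) {
    fam <- c(v, structure$parents[[v]])
    counts <- table(data[fam])
    k <- length(states[[v]])
    m <- matrix(as.numeric(counts), nrow = k) + pseudocount
    tot <- rep(colSums(m), each = k)
    m <- ifelse(tot > 0, m / tot, 1 / k)   # unseen configs -> uniform
    array(m, dim = dim(counts), dimnames = dimnames(counts))
  })
  names(cpt) <- structure$nodes
  structure(list(nodes = structure$nodes, parents = structure$parents,
                 states = states, cpt = cpt, pseudocount = pseudocount),
            class = "bbn")
}

#' Joint probability of one full assignment
#'
#' Product of the per-node CPT entries, the defining factorization of the
#' network's joint distribution.
#'
#' @param net a fitted `"bbn"`.
#' @param assignment named character vector or list giving a state label for
#'   every node.
#' @return A single probability.
#' @export
joint_probability <- function(net, assignment) {
  assignment <- unlist(assignment)
  if (!all(net$nodes %in% names(assignment))) stop("assignment must cover all nodes")
  prod(vapply(net$nodes, function(v) {
    idx <- assignment[c(v, net$parents[[v]])]
    if (!all(mapply(function(s, vv) s %in% net$states[[vv]],
                    idx, c(v, net$parents[[v]]))))
      stop("unknown state label for node ", v)
    do.call(`[`, c(list(net$cpt[[v]]), as.list(idx)))
  }, 0))
}

# ---- factor algebra for variable elimination ------------------------------

new_factor <- function(vars, tab) list(vars = vars, tab = tab)

cpt_factor <- function(net, v) {
  fam <- c(v, net$parents[[v]])
  tab <- net$cpt[[v]]
  if (is.null(dim(tab))) tab <- array(tab, dim = length(tab),
                                      dimnames = list(net$states[[v]]))
  new_factor(fam, tab)
}

expand_factor <- function(f, vars, states) {
  if (!length(vars)) return(f$tab)
  if (!length(f$vars)) {      # scalar factor -> constant array over vars
    dims <- vapply(vars, function(v) length(states[[v]]), 0L)
    return(array(f$tab, dim = dims, dimnames = lapply(vars, function(v) states[[v]])))
  }
  tab <- f$tab
  have <- f$vars
  for (m in setdiff(vars, have)) {
    tab <- outer(tab, rep(1, length(states[[m]])))
    have <- c(have, m)
  }
  dimnames(tab) <- lapply(have, function(v) states[[v]])
  aperm(tab, match(vars, have))
}

factor_product <- function(f1, f2, states) {
  vars <- union(f1$vars, f2$vars)
  new_factor(vars, expand_factor(f1, vars, states) * expand_factor(f2, vars, states))
}

factor_marginalize <- function(f, var) {
  i <- match(var, f$vars)
  if (length(f$vars) == 1) return(new_factor(character(0), sum(f$tab)))
  t2 <- aperm(f$tab, c(i, seq_along(f$vars)[-i]))
  s <- colSums(t2, dims = 1)
  if (is.null(dim(s))) s <- array(s, dim = length(s), dimnames = list(names(s)))
  new_factor(f$vars[-i], s)
}

factor_reduce <- function(f, var, state) {
  i <- match(var, f$vars)
  d <- dim(f$tab)
  if (is.null(d)) d <- length(f$tab)
  si <- match(state, dimnames(f$tab)[[i]])
  if (is.na(si)) stop("unknown state ", state, " for ", var)
  t2 <- aperm(f$tab, c(i, seq_along(f$vars)[-i]))
  m <- matrix(t2, nrow = d[i])
  rest <- f$vars[-i]
  if (!length(rest)) return(new_factor(character(0), m[si, 1]))
  new_factor(rest, array(m[si, ], dim = d[-i][match(rest, f$vars[-i])],
                         dimnames = dimnames(f$tab)[-i]))
}

# ---- evidence --------------------------------------------------------------

#' Specify hard and virtual evidence
#'
#' Hard evidence fixes a node to one observed state. Virtual (soft) evidence
#' attaches a nonnegative likelihood vector to a node, multiplying its factor
#' before normalization (a Jeffrey-style update when the vector is a ratio of
#' target to current marginals).
#'
#' @param hard named character vector, node -> state label.
#' @param virtual named list, node -> nonnegative per-state weight vector
#'   (named by state, or in state order).
#' @return An object of class `"bbn_evidence"`.
#' @examples
#' evidence(hard = c(S1 = "C0"))
#' @export
evidence <- function(hard = NULL, virtual = NULL) {
  if (!is.null(hard) && !is.null(virtual) &&
      length(intersect(names(hard), names(virtual))))
    stop("a node cannot carry both hard and virtual evidence")
  for (v in names(virtual)) {
    w <- virtual[[v]]
    if (any(w < 0) || all(w <= 0))
      stop("virtual likelihood for ", v, " must be nonnegative with a positive entry")
  }
  structure(list(hard = hard, virtual = virtual), class = "bbn_evidence")
}

# ---- inference -------------------------------------------------------------

variable_elimination <- function(net, ev, query) {
  states <- net$states
  factors <- lapply(net$nodes, function(v) cpt_factor(net, v))
  for (v in names(ev$virtual)) {
    w <- ev$virtual[[v]]
    if (is.null(names(w))) names(w) <- states[[v]]
    tab <- array(as.numeric(w[states[[v]]]), dim = length(states[[v]]),
                 dimnames = list(states[[v]]))
    factors <- c(factors, list(new_factor(v, tab)))
  }
  for (v in names(ev$hard))
    factors <- lapply(factors, function(f)
      if (v %in% f$vars) factor_reduce(f, v, ev$hard[[v]]) else f)
  elim <- setdiff(net$nodes, c(query, names(ev$hard)))
  while (length(elim)) {
    # min-degree: eliminate the variable appearing with fewest distinct others
    deg <- vapply(elim, function(v) {
      nb <- unique(unlist(lapply(factors, function(f)
        if (v %in% f$vars) f$vars else NULL)))
      length(setdiff(nb, v))
    }, 0L)
    v <- sort(elim[deg == min(deg)])[1]
    touch <- vapply(factors, function(f) v %in% f$vars, TRUE)
    prod_f <- Reduce(function(a, b) factor_product(a, b, states), factors[touch])
    factors <- c(factors[!touch], list(factor_marginalize(prod_f, v)))
    elim <- setdiff(elim, v)
  }
  out <- Reduce(function(a, b) factor_product(a, b, states), factors)
  if (length(out$vars)) out$tab <- aperm(out$tab, match(query, out$vars))
  z <- sum(out$tab)
  if (z <= 0) stop("evidence has zero probability")
  out$tab / z
}

#' Exact posterior marginals by variable elimination
#'
#' Computes the posterior distribution of each query node given the evidence,
#' by exact variable elimination with a min-degree elimination order.
#'
#' @param net a fitted `"bbn"`.
#' @param ev a [evidence()] object (default: none).
#' @param query character vector of nodes (default: all).
#' @return Named list of posterior probability vectors, one per query node; a
#'   hard-evidenced query node returns its point mass.
#' @export
infer <- function(net, ev = evidence(), query = net$nodes) {
  stopifnot(inherits(net, "bbn"))
  if (!inherits(ev, "bbn_evidence")) stop("ev must be built with evidence()")
  out <- lapply(query, function(v) {
    if (v %in% names(ev$hard)) {
      p <- stats::setNames(as.numeric(net$states[[v]] == ev$hard[[v]]),
                           net$states[[v]])
      return(p)
    }
    p <- variable_elimination(net, ev, v)
    stats::setNames(as.numeric(p), net$states[[v]])
  })
  stats::setNames(out, query)
}

# ---- scoring ---------------------------------------------------------------

#' BDeu family score and total network score
#'
#' Log marginal likelihood of one node's family under a Bayesian-Dirichlet
#' equivalent uniform prior with equivalent sample size `ess`: Dirichlet
#' hyperparameters `ess / (r * q)` per cell, `r` child states and `q` parent
#' configurations. Decomposable: the total score is the sum over families.
#'
#' @param node node id.
#' @param parents character vector of parent ids.
#' @param data data frame of factors.
#' @param ess equivalent sample size, strictly positive.
#' @return Log score (a single number).
#' @export
family_score <- function(node, parents, data, ess = 1) {
  if (ess <= 0) stop("ess must be positive")
  if (!all(vapply(data[c(node, parents)], is.factor, TRUE)))
    stop("data columns must be factors")
  r <- nlevels(data[[node]])
  q <- prod(vapply(parents, function(p) nlevels(data[[p]]), 0L), 1L)
  counts <- matrix(as.numeric(table(data[c(node, parents)])), nrow = r)
  a_cell <- ess / (r * q)
  a_cfg <- ess / q
  nj <- colSums(counts)
  sum(lgamma(a_cfg) - lgamma(a_cfg + nj)) +
    sum(lgamma(a_cell + counts) - lgamma(a_cell))
}

#' @rdname family_score
#' @param structure a [bbn_dag()].
#' @export
total_score <- function(structure, data, ess = 1) {
  sum(vapply(structure$nodes,
             function(v) family_score(v, structure$parents[[v]], data, ess), 0))
}

# ---- simulation ------------------------------------------------------------

#' Sample observations from a fitted network
#'
#' Ancestral sampling in topological order.
#'
#' @param object a fitted `"bbn"`.
#' @param nsim number of rows to draw.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return Data frame of factors with the network's state spaces.
#' @export
simulate.bbn <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ord <- topo_order(object)
  out <- stats::setNames(vector("list", length(object$nodes)), object$nodes)
  for (v in ord) {
    pa <- object$parents[[v]]
    k <- length(object$states[[v]])
    if (!length(pa)) {
      p <- as.numeric(object$cpt[[v]])
      out[[v]] <- sample(object$states[[v]], nsim, replace = TRUE, prob = p)
    } else {
      cfg <- do.call(paste, c(lapply(pa, function(p) out[[p]]), sep = "\r"))
      draws <- character(nsim)
      for (cf in unique(cfg)) {
        rows <- which(cfg == cf)
        idx <- strsplit(cf, "\r", fixed = TRUE)[[1]]
        p <- do.call(`[`, c(list(object$cpt[[v]]), list(seq_len(k)), as.list(idx)))
        draws[rows] <- sample(object$states[[v]], length(rows),
                              replace = TRUE, prob = as.numeric(p))
      }
      out[[v]] <- draws
    }
  }
  d <- as.data.frame(stats::setNames(
    lapply(object$nodes, function(v)
      factor(out[[v]], levels = object$states[[v]], ordered = TRUE)),
    object$nodes))
  d
}
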