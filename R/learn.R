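# Structure learning: score-based hill climbing ("Bayesian search"), Greedy
# Thick Thinning, and the constraint-based PC algorithm. All learners are
# deterministic given the data and seed; ties break lexicographically by
# node id so runs are reproducible.

score_cache <- function(data, ess) {
  env <- new.env(parent = emptyenv())
  function(node, pa) {
    key <- paste(node, paste(sort(pa), collapse = ","), sep = "|")
    if (is.null(env[[key]])) env[[key]] <- family_score(node, pa, data, ess)
    env[[key]]
  }
}

creates_cycle <- function(par, from, to) {
  # would adding from -> to close a directed path to -> ... -> from?
  seen <- from
  frontier <- from
  while (length(frontier)) {
    frontier <- unique(unlist(par[frontier]))
    frontier <- setdiff(frontier, seen)
    if (to %in% frontier) return(TRUE)
    seen <- c(seen, frontier)
  }
  FALSE
}

# One greedy hill climb over add/delete/reverse moves from a starting parent
# list; returns the local optimum.
hill_climb <- function(par, nodes, fam, max_parents) {
  score_of <- function(p) sum(vapply(nodes, function(v) fam(v, p[[v]]), 0))
  repeat {
    best_gain <- 1e-9; best <- NULL
    for (from in nodes) for (to in nodes) {
      if (from == to) next
      if (from %in% par[[to]]) {
        # delete from -> to
        gain <- fam(to, setdiff(par[[to]], from)) - fam(to, par[[to]])
        if (gain > best_gain) { best_gain <- gain; best <- list("del", from, to) }
        # reverse to: to -> from
        if (!(to %in% par[[from]]) && length(par[[from]]) < max_parents) {
          par2 <- par; par2[[to]] <- setdiff(par2[[to]], from)
          if (!creates_cycle(par2, to, from)) {
            gain <- (fam(to, par2[[to]]) - fam(to, par[[to]])) +
                    (fam(from, c(par[[from]], to)) - fam(from, par[[from]]))
            if (gain > best_gain) { best_gain <- gain; best <- list("rev", from, to) }
          }
        }
      } else if (length(par[[to]]) < max_parents && !creates_cycle(par, from, to)) {
        gain <- fam(to, c(par[[to]], from)) - fam(to, par[[to]])
        if (gain > best_gain) { best_gain <- gain; best <- list("add", from, to) }
      }
    }
    if (is.null(best)) break
    op <- best[[1]]; from <- best[[2]]; to <- best[[3]]
    if (op == "add") par[[to]] <- sort(c(par[[to]], from))
    if (op == "del") par[[to]] <- setdiff(par[[to]], from)
    if (op == "rev") { par[[to]] <- setdiff(par[[to]], from)
                       par[[from]] <- sort(c(par[[from]], to)) }
  }
  list(parents = par, score = score_of(par))
}

random_dag <- function(nodes, max_parents, arc_prob = 0.25) {
  ord <- sample(nodes)
  par <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
  for (j in seq_along(ord)[-1]) {
    cand <- ord[seq_len(j - 1)]
    pick <- cand[stats::runif(length(cand)) < arc_prob]
    if (length(pick) > max_parents) pick <- pick[seq_len(max_parents)]
    par[[ord[j]]] <- sort(pick)
  }
  par
}

#' Score-based structure search with random restarts
#'
#' Greedy hill climbing over arc additions, deletions and reversals
#' maximizing the total BDeu score, restarted from seeded random DAGs; the
#' best-scoring local optimum is returned.
#'
#' @param data data frame of factors.
#' @param max_parents parent limit per node.
#' @param restarts number of random restarts beyond the empty start.
#' @param seed integer seed making the search deterministic.
#' @param ess BDeu equivalent sample size.
#' @return A [bbn_dag()] with attribute `"score"`.
#' @export
bayesian_search <- function(data, max_parents = 4, restarts = 20, seed = 1L,
                            ess = 1) {
  nodes <- names(data)
  if (length(nodes) < 2) stop("need at least 2 variables")
  fam <- score_cache(data, ess)
  empty <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
  set.seed(seed)
  starts <- c(list(empty), replicate(restarts, random_dag(nodes, max_parents),
                                     simplify = FALSE))
  best <- NULL
  for (st in starts) {
    fit <- hill_climb(st, nodes, fam, max_parents)
    if (is.null(best) || fit$score > best$score + 1e-9) best <- fit
  }
  out <- bbn_dag(nodes, parents_to_arcs(best$parents))
  attr(out, "score") <- best$score
  out
}

parents_to_arcs <- function(par) {
  do.call(rbind, lapply(names(par), function(v)
    if (length(par[[v]])) cbind(par[[v]], v) else NULL))
}

#' Greedy Thick Thinning
#'
#' Two-phase score-based learner: thickening adds, from the empty graph, the
#' acyclicity-preserving arc with the largest positive BDeu gain until none
#' improves; thinning then repeatedly deletes the arc whose removal most
#' increases the score. Fully deterministic (lexicographic tie-break).
#'
#' @inheritParams bayesian_search
#' @return A [bbn_dag()] with attribute `"score"`.
#' @export
greedy_thick_thinning <- function(data, max_parents = 4, ess = 1) {
  nodes <- names(data)
  if (length(nodes) < 2) stop("need at least 2 variables")
  fam <- score_cache(data, ess)
  par <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
  repeat {  # thickening
    best_gain <- 1e-9; best <- NULL
    for (from in nodes) for (to in nodes) {
      if (from == to || from %in% par[[to]] ||
          length(par[[to]]) >= max_parents || creates_cycle(par, from, to)) next
      gain <- fam(to, c(par[[to]], from)) - fam(to, par[[to]])
      if (gain > best_gain) { best_gain <- gain; best <- c(from, to) }
    }
    if (is.null(best)) break
    par[[best[2]]] <- sort(c(par[[best[2]]], best[1]))
  }
  repeat {  # thinning
    best_gain <- 1e-9; best <- NULL
    for (to in nodes) for (from in par[[to]]) {
      gain <- fam(to, setdiff(par[[to]], from)) - fam(to, par[[to]])
      if (gain > best_gain) { best_gain <- gain; best <- c(from, to) }
    }
    if (is.null(best)) break
    par[[best[2]]] <- setdiff(par[[best[2]]], best[1])
  }
  out <- bbn_dag(nodes, parents_to_arcs(par))
  attr(out, "score") <- sum(vapply(nodes, function(v) fam(v, par[[v]]), 0))
  out
}

#' G-squared conditional-independence test
#'
#' Likelihood-ratio test of independence between two discrete variables,
#' stratified over the configurations of a conditioning set. Degrees of
#' freedom are `(|x|-1)(|y|-1)` per nonempty stratum, so empty strata reduce
#' the reference distribution rather than inflating it.
#'
#' @param data data frame of factors.
#' @param x,y column names to test.
#' @param z character vector of conditioning columns (possibly empty).
#' @return List with `statistic`, `df` and `p.value`.
#' @export
ci_test_g2 <- function(data, x, y, z = character(0)) {
  f <- data[c(x, y, z)]
  if (!all(vapply(f, is.factor, TRUE))) stop("columns must be factors")
  tab <- table(f)
  rx <- nlevels(f[[x]]); ry <- nlevels(f[[y]])
  m <- array(tab, dim = c(rx, ry, length(tab) / (rx * ry)))
  g2 <- 0; df <- 0L
  for (s in seq_len(dim(m)[3])) {
    slab <- m[, , s]
    n_s <- sum(slab)
    if (n_s == 0) next
    e <- outer(rowSums(slab), colSums(slab)) / n_s
    obs <- slab > 0
    g2 <- g2 + 2 * sum(slab[obs] * log(slab[obs] / e[obs]))
    df <- df + (rx - 1L) * (ry - 1L)
  }
  list(statistic = g2, df = df,
       p.value = stats::pchisq(g2, df, lower.tail = FALSE))
}

# deterministic list of size-l subsets of a character vector
subsets_of <- function(x, l) {
  if (l == 0) return(list(character(0)))
  if (length(x) < l) return(list())
  cmb <- utils::combn(sort(x), l)
  lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
}

#' The PC algorithm
#'
#' Constraint-based structure learning: starts from the complete undirected
#' graph, deletes edges whose endpoints test conditionally independent
#' (G-squared test) given subsets of current adjacencies of increasing size,
#' orients v-structures from the recorded separating sets, and closes under
#' Meek's orientation rules.
#'
#' @param data data frame of factors.
#' @param ci_alpha significance level of the independence tests.
#' @param max_cond largest conditioning-set size considered.
#' @return An object of class `"bbn_cpdag"`: directed arcs, undirected edges
#'   and the separating sets.
#' @export
pc_algorithm <- function(data, ci_alpha = 0.05, max_cond = 4) {
  nodes <- sort(names(data))
  if (length(nodes) < 2) stop("need at least 2 variables")
  if (ci_alpha <= 0 || ci_alpha >= 1) stop("ci_alpha must be in (0,1)")
  adj <- matrix(TRUE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  diag(adj) <- FALSE
  sepset <- list()
  for (l in 0:max_cond) {
    changed_possible <- FALSE
    for (x in nodes) for (y in nodes) {
      if (x >= y || !adj[x, y]) next
      cands <- union(setdiff(nodes[adj[x, ]], y), setdiff(nodes[adj[y, ]], x))
      if (length(cands) >= l) changed_possible <- TRUE
      for (S in subsets_of(setdiff(nodes[adj[x, ]], y), l)) {
        if (ci_test_g2(data, x, y, S)$p.value > ci_alpha) {
          adj[x, y] <- adj[y, x] <- FALSE
          sepset[[paste(x, y)]] <- S
          break
        }
      }
      if (adj[x, y]) for (S in subsets_of(setdiff(nodes[adj[y, ]], x), l)) {
        if (ci_test_g2(data, x, y, S)$p.value > ci_alpha) {
          adj[x, y] <- adj[y, x] <- FALSE
          sepset[[paste(x, y)]] <- S
          break
        }
      }
    }
    if (!changed_possible) break
  }
  # orient v-structures x -> z <- y when z is outside sepset(x, y)
  dir <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  und <- adj
  point_at <- function(a, z) {
    if (!dir[z, a]) {          # keep the first orientation on a conflict
      dir[a, z] <<- TRUE
      und[a, z] <<- und[z, a] <<- FALSE
    }
  }
  for (z in nodes) {
    nb <- nodes[adj[z, ]]
    for (x in nb) for (y in nb) {
      if (x >= y || adj[x, y]) next
      S <- sepset[[paste(x, y)]]
      if (!is.null(S) && !(z %in% S)) { point_at(x, z); point_at(y, z) }
    }
  }
  res <- meek_closure(dir, und)
  structure(list(nodes = nodes, directed = res$dir, undirected = res$und,
                 sepset = sepset), class = "bbn_cpdag")
}

# Meek rules 1-3 to orientation closure.
meek_closure <- function(dir, und) {
  nodes <- rownames(dir)
  adj <- function(a, b) und[a, b] || dir[a, b] || dir[b, a]
  repeat {
    changed <- FALSE
    for (a in nodes) for (b in nodes) {
      if (!und[a, b] || a == b) next
      orient <- FALSE
      # R1: c -> a, a - b, c and b nonadjacent  =>  a -> b
      for (c in nodes[dir[, a]]) if (!adj(c, b) && c != b) orient <- TRUE
      # R2: a -> c -> b with a - b  =>  a -> b
      if (!orient) for (c in nodes[dir[a, ]]) if (dir[c, b]) orient <- TRUE
      # R3: a - c, a - d, c -> b, d -> b, c and d nonadjacent  =>  a -> b
      if (!orient) {
        cs <- nodes[und[a, ] & dir[, b]]
        if (length(cs) >= 2)
          for (i in seq_along(cs)) for (j in seq_along(cs))
            if (i < j && !adj(cs[i], cs[j])) orient <- TRUE
      }
      if (orient) {
        dir[a, b] <- TRUE
        und[a, b] <- und[b, a] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(dir = dir, und = und)
}

#' @export
print.bbn_cpdag <- function(x, ...) {
  d <- which(x$directed, arr.ind = TRUE)
  u <- which(x$undirected & upper.tri(x$undirected), arr.ind = TRUE)
  cat("CPDAG:", nrow(d), "directed,", nrow(u), "undirected\n")
  for (i in seq_len(nrow(d)))
    cat(" ", x$nodes[d[i, 1]], "->", x$nodes[d[i, 2]], "\n")
  for (i in seq_len(nrow(u)))
    cat(" ", x$nodes[u[i, 1]], "--", x$nodes[u[i, 2]], "\n")
  invisible(x)
}

#' Extend a CPDAG to a DAG
#'
#' Orients each remaining undirected edge from the earlier to the later node
#' in id order unless that creates a directed cycle or a new v-structure, in
#' which case the reverse orientation is tried.
#'
#' @param cpdag a `"bbn_cpdag"` from [pc_algorithm()].
#' @return A [bbn_dag()] containing every directed arc of the input.
#' @export
extend_to_dag <- function(cpdag) {
  nodes <- cpdag$nodes
  dir <- cpdag$directed
  und <- cpdag$undirected
  par_of <- function() {
    p <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
    idx <- which(dir, arr.ind = TRUE)
    for (i in seq_len(nrow(idx)))
      p[[nodes[idx[i, 2]]]] <- c(p[[nodes[idx[i, 2]]]], nodes[idx[i, 1]])
    p
  }
  new_vstruct <- function(from, to) {
    # would from -> to collide with an existing parent of `to` nonadjacent to `from`?
    for (q in nodes[dir[, to]])
      if (q != from && !(und[q, from] || dir[q, from] || dir[from, q]))
        return(TRUE)
    FALSE
  }
  pairs <- which(und & upper.tri(und), arr.ind = TRUE)
  ord <- order(nodes[pairs[, 1]], nodes[pairs[, 2]])
  for (i in seq_len(nrow(pairs))[ord]) {
    u <- nodes[pairs[i, 1]]; v <- nodes[pairs[i, 2]]
    first <- min(u, v); second <- max(u, v)
    try_orient <- function(from, to, allow_vstruct = FALSE) {
      if (!allow_vstruct && new_vstruct(from, to)) return(FALSE)
      if (creates_cycle(par_of(), from, to)) return(FALSE)
      dir[from, to] <<- TRUE
      und[from, to] <<- und[to, from] <<- FALSE
      TRUE
    }
    # finite-sample CPDAGs can be inconsistent: tolerate a new v-structure
    # rather than fail, but never a cycle
    if (!try_orient(first, second) && !try_orient(second, first) &&
        !try_orient(first, second, TRUE) && !try_orient(second, first, TRUE))
      stop("CPDAG is not extensible to a DAG")
  }
  idx <- which(dir, arr.ind = TRUE)
  bbn_dag(nodes, cbind(nodes[idx[, 1]], nodes[idx[, 2]]))
}

#' Learn one structure by a named algorithm
#'
#' @param data data frame of factors.
#' @param algorithm `"bs"` (score search with restarts), `"gtt"` (Greedy
#'   Thick Thinning) or `"pc"` (constraint-based, extended to a DAG).
#' @param max_parents parent / conditioning-set limit.
#' @param restarts,seed,ess,ci_alpha algorithm-specific settings.
#' @return A [bbn_dag()].
#' @export
learn_structure <- function(data, algorithm = c("gtt", "bs", "pc"),
                            max_parents = 4, restarts = 20, seed = 1L,
                            ess = 1, ci_alpha = 0.05) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
         bs  = bayesian_search(data, max_parents, restarts, seed, ess),
         gtt = greedy_thick_thinning(data, max_parents, ess),
         pc  = extend_to_dag(pc_algorithm(data, ci_alpha, max_parents)))
}

#' Learn the full scheme-by-algorithm model grid
#'
#' Discretizes the clean survey data under each state-count scheme and learns
#' a structure with each algorithm, fitting CPTs for all nine combinations.
#'
#' @param dataset clean numeric data frame of section scores.
#' @param method binning method shared across the grid.
#' @param schemes,algorithms grid axes.
#' @param seed master seed; each model gets a derived seed.
#' @param pseudocount CPT smoothing count.
#' @param ... passed to [learn_structure()].
#' @return A list of class `"bbn_grid"`; each element has `scheme`,
#'   `algorithm`, `seed`, the discrete `data`, the binning `spec`, the learned
#'   `structure` and the fitted `network`.
#' @export
learn_grid <- function(dataset, method = "equal_width",
                       schemes = c("two_state", "three_state", "mixed"),
                       algorithms = c("bs", "pc", "gtt"),
                       seed = 1L, pseudocount = 1, ...) {
  models <- list()
  i <- 0L
  for (scheme in schemes) {
    spec <- binning_spec(dataset, method, scheme)
    ddata <- apply_binning(dataset, spec)
    for (alg in algorithms) {
      i <- i + 1L
      mseed <- seed + 1000L * i
      structure_ <- learn_structure(ddata, alg, seed = mseed, ...)
      net <- fit_cpts(structure_, ddata, pseudocount)
      models[[paste(scheme, alg, sep = "_")]] <-
        list(scheme = scheme, algorithm = alg, seed = mseed, data = ddata,
             spec = spec, structure = structure_, network = net)
    }
  }
  structure(models, class = "bbn_grid")
}
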