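# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: marginals by brute-force enumeration of the full
# joint, optimal 1-D partitions by dynamic programming, exhaustive DAG
# scoring by enumeration.

# All full assignments of a network's nodes.
all_assignments <- function(net) {
  expand.grid(net$states, stringsAsFactors = FALSE)
}

# Posterior marginals by summing joint_probability over every assignment.
enum_marginals <- function(net, hard = NULL, weight = NULL) {
  asn <- all_assignments(net)
  w <- vapply(seq_len(nrow(asn)), function(i)
    joint_probability(net, unlist(asn[i, , drop = FALSE])), 0)
  if (!is.null(hard))
    for (v in names(hard)) w[asn[[v]] != hard[[v]]] <- 0
  if (!is.null(weight))
    for (v in names(weight)) w <- w * weight[[v]][asn[[v]]]
  w <- w / sum(w)
  lapply(stats::setNames(names(asn), names(asn)), function(v)
    vapply(stats::setNames(net$states[[v]], net$states[[v]]),
           function(s) sum(w[asn[[v]] == s]), 0))
}

# Random CPTs on a random DAG (nodes added in order, arcs only backwards).
random_network <- function(n_nodes, max_states = 3, arc_prob = 0.4) {
  nodes <- paste0("N", seq_len(n_nodes))
  arcs <- NULL
  for (j in seq_len(n_nodes)[-1]) for (i in seq_len(j - 1))
    if (stats::runif(1) < arc_prob) arcs <- rbind(arcs, c(nodes[i], nodes[j]))
  g <- bbn_dag(nodes, arcs)
  states <- lapply(stats::setNames(nodes, nodes), function(v) {
    ks <- seq(2, max_states)
    paste0("C", seq_len(ks[sample.int(length(ks), 1)]) - 1)
  })
  cpt <- lapply(nodes, function(v) {
    pa <- parents(g, v)
    k <- length(states[[v]])
    q <- prod(vapply(pa, function(p) length(states[[p]]), 0L), 1L)
    m <- matrix(stats::rgamma(k * q, 1), k)
    m <- sweep(m, 2, colSums(m), "/")
    array(m, dim = c(k, vapply(pa, function(p) length(states[[p]]), 0L)),
          dimnames = c(list(states[[v]]), lapply(pa, function(p) states[[p]])))
  })
  names(cpt) <- nodes
  structure(list(nodes = nodes, parents = g$parents, states = states,
                 cpt = cpt, pseudocount = NA_real_), class = "bbn")
}

# Optimal 1-D k-partition by dynamic programming over sorted values
# (minimum within-cluster sum of squares).
optimal_partition_ss <- function(values, k) {
  x <- sort(values); n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  seg <- function(i, j) {  # ss of x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  dp <- matrix(Inf, k, n)
  for (j in 1:n) dp[1, j] <- seg(1, j)
  if (k > 1) for (m in 2:k) for (j in m:n)
    dp[m, j] <- min(vapply((m - 1):(j - 1), function(t)
      dp[m - 1, t] + seg(t + 1, j), 0))
  dp[k, n]
}

# Every DAG over 3 labelled nodes (25 of them), as parent lists.
all_3node_dags <- function(nodes) {
  pairs <- t(utils::combn(nodes, 2))
  out <- list()
  for (s1 in 0:2) for (s2 in 0:2) for (s3 in 0:2) {
    arcs <- NULL
    st <- c(s1, s2, s3)
    for (e in 1:3) {
      if (st[e] == 1) arcs <- rbind(arcs, pairs[e, ])
      if (st[e] == 2) arcs <- rbind(arcs, rev(pairs[e, ]))
    }
    g <- tryCatch(bbn_dag(nodes, arcs), error = function(e) NULL)
    if (!is.null(g)) out <- c(out, list(g))
  }
  out
}

# Simulate a strong 3-node chain X -> Y -> Z of binary factors.
simulate_chain <- function(n, flip = 0.1) {
  x <- sample(c("C0", "C1"), n, replace = TRUE)
  y <- ifelse(stats::runif(n) < flip, sample(c("C0", "C1"), n, TRUE), x)
  z <- ifelse(stats::runif(n) < flip, sample(c("C0", "C1"), n, TRUE), y)
  data.frame(X = factor(x, c("C0", "C1")), Y = factor(y, c("C0", "C1")),
             Z = factor(z, c("C0", "C1")))
}

# The published 5-arc structure used as a topology fixture in sensitivity
# tests: S5 parents S4, S6, S8; S4 -> S3 -> S2; S1 and S7 isolated.
star_chain_dag <- function() {
  bbn_dag(paste0("S", 1:8),
          rbind(c("S5", "S4"), c("S5", "S6"), c("S5", "S8"),
                c("S4", "S3"), c("S3", "S2")))
}

# Fit a network over the star_chain_dag from data simulated on it.
star_chain_net <- function(seed = 42, n = 400) {
  set.seed(seed)
  g <- star_chain_dag()
  d <- data.frame(lapply(stats::setNames(g$nodes, g$nodes), function(v)
    factor(sample(c("C0", "C1"), n, TRUE), c("C0", "C1"))))
  # overwrite children to induce real dependence on parents
  d$S4 <- factor(ifelse(stats::runif(n) < 0.2, as.character(d$S4),
                        as.character(d$S5)), c("C0", "C1"))
  d$S6 <- factor(ifelse(stats::runif(n) < 0.3, as.character(d$S6),
                        as.character(d$S5)), c("C0", "C1"))
  d$S8 <- factor(ifelse(stats::runif(n) < 0.3, as.character(d$S8),
                        as.character(d$S5)), c("C0", "C1"))
  d$S3 <- factor(ifelse(stats::runif(n) < 0.25, as.character(d$S3),
                        as.character(d$S4)), c("C0", "C1"))
  d$S2 <- factor(ifelse(stats::runif(n) < 0.25, as.character(d$S2),
                        as.character(d$S3)), c("C0", "C1"))
  fit_cpts(g, d)
}
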