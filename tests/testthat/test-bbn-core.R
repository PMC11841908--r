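test_that("DAG construction enforces acyclicity and rejects malformed arcs", {
  expect_true(check_acyclic(bbn_dag(c("A", "B", "C"))))
  expect_error(bbn_dag(c("A", "B", "C"),
                       rbind(c("A", "B"), c("B", "C"), c("C", "A"))), "cycle")
  expect_error(bbn_dag(c("A", "B"), rbind(c("A", "A"))), "self")
  expect_error(bbn_dag(c("A", "B"), rbind(c("A", "B"), c("A", "B"))), "duplicate")
  # the published 5-arc maternity structure is a valid DAG
  expect_true(check_acyclic(star_chain_dag()))
})

test_that("CPT fitting follows the smoothing formula with full state spaces", {
  x <- factor(rep(c("C0", "C1"), c(30, 70)), c("C0", "C1"))
  d <- data.frame(X = x)
  g <- bbn_dag("X")
  expect_equal(as.numeric(fit_cpts(g, d, pseudocount = 0)$cpt$X), c(0.3, 0.7))
  x2 <- factor(rep(c("C0", "C1"), c(34, 88)), c("C0", "C1"))
  expect_equal(as.numeric(fit_cpts(g, data.frame(X = x2), 1)$cpt$X),
               c(35 / 124, 89 / 124))
  # unseen parent configuration gives a uniform row
  d2 <- data.frame(
    P = factor(rep("C0", 10), c("C0", "C1")),
    X = factor(rep(c("C0", "C1", "C2"), length.out = 10), c("C0", "C1", "C2")))
  net <- fit_cpts(bbn_dag(c("P", "X"), rbind(c("P", "X"))), d2, pseudocount = 0)
  expect_equal(as.numeric(net$cpt$X[, "C1"]), rep(1 / 3, 3))
  # rows always sum to 1 and positive pseudocount leaves no zeros
  net1 <- fit_cpts(bbn_dag(c("P", "X"), rbind(c("P", "X"))), d2, pseudocount = 1)
  for (v in net1$nodes) {
    m <- matrix(as.numeric(net1$cpt[[v]]), nrow = length(net1$states[[v]]))
    expect_equal(colSums(m), rep(1, ncol(m)), tolerance = 1e-9)
    expect_true(all(m > 0))
  }
  expect_error(fit_cpts(g, d[0, , drop = FALSE]), "empty")
})

test_that("the joint factorizes as the product of CPT entries", {
  set.seed(1)
  net1 <- random_network(1, max_states = 2)
  net1$cpt$N1[] <- c(0.5, 0.5)
  expect_equal(joint_probability(net1, c(N1 = "C0")), 0.5)
  # empty-arc network: joint is the product of marginals
  set.seed(2)
  net <- random_network(4, arc_prob = 0)
  asn <- lapply(net$states, function(s) s[1])
  expect_equal(joint_probability(net, unlist(asn)),
               prod(vapply(net$nodes, function(v) net$cpt[[v]][1], 0)))
  # fitted 3-node chain joint equals the enumerated empirical-smoothed joint
  set.seed(3)
  d <- simulate_chain(500)
  g <- bbn_dag(c("X", "Y", "Z"), rbind(c("X", "Y"), c("Y", "Z")))
  net3 <- fit_cpts(g, d)
  tot <- 0
  for (x in c("C0", "C1")) for (y in c("C0", "C1")) for (z in c("C0", "C1")) {
    p <- joint_probability(net3, c(X = x, Y = y, Z = z))
    px <- net3$cpt$X[x]; pyx <- net3$cpt$Y[y, x]; pzy <- net3$cpt$Z[z, y]
    expect_equal(p, as.numeric(px * pyx * pzy))
    tot <- tot + p
  }
  expect_equal(tot, 1, tolerance = 1e-12)
  expect_error(joint_probability(net3, c(X = "C9", Y = "C0", Z = "C0")), "state")
})

test_that("variable elimination equals brute-force enumeration on random networks", {
  set.seed(10)
  for (rep in 1:25) {
    net <- random_network(sample(3:8, 1))
    # no evidence
    got <- infer(net)
    want <- enum_marginals(net)
    for (v in net$nodes) expect_equal(got[[v]], want[[v]], tolerance = 1e-9)
    # one hard + one virtual evidence node
    ev_nodes <- sample(net$nodes, 2)
    hard <- stats::setNames(net$states[[ev_nodes[1]]][1], ev_nodes[1])
    lik <- stats::setNames(
      list(stats::setNames(runif(length(net$states[[ev_nodes[2]]]), 0.1, 1),
                           net$states[[ev_nodes[2]]])), ev_nodes[2])
    got2 <- infer(net, evidence(hard = hard, virtual = lik))
    want2 <- enum_marginals(net, hard = as.list(hard), weight = lik)
    for (v in setdiff(net$nodes, ev_nodes[1]))
      expect_equal(got2[[v]], want2[[v]], tolerance = 1e-9)
  }
})

test_that("evidence handling covers point masses, no-ops and degeneracies", {
  net <- star_chain_net()
  # no evidence on a parentless node returns its prior row
  expect_equal(infer(net, query = "S5")$S5,
               stats::setNames(as.numeric(net$cpt$S5), net$states$S5))
  # hard evidence on the query node is a point mass
  p <- infer(net, evidence(hard = c(S4 = "C1")), "S4")$S4
  expect_equal(as.numeric(p), c(0, 1))
  # all-ones virtual likelihood changes nothing
  base <- infer(net)
  same <- infer(net, evidence(virtual = list(S4 = c(C0 = 1, C1 = 1))))
  for (v in net$nodes) expect_equal(same[[v]], base[[v]], tolerance = 1e-12)
  expect_error(evidence(hard = c(S4 = "C0"), virtual = list(S4 = c(1, 1))),
               "both")
  expect_error(evidence(virtual = list(S4 = c(0, 0))), "positive")
  net0 <- net
  net0$cpt$S5[] <- c(1, 0)
  expect_error(infer(net0, evidence(hard = c(S5 = "C1")), "S4"), "zero probability")
})

test_that("BDeu scoring is decomposable and prefers real dependence", {
  set.seed(6)
  d <- simulate_chain(1000)
  # decomposability: score difference between structures differing in Z's
  # family depends only on that family
  g1 <- bbn_dag(c("X", "Y", "Z"), rbind(c("X", "Y")))
  g2 <- bbn_dag(c("X", "Y", "Z"), rbind(c("X", "Y"), c("Y", "Z")))
  delta_total <- total_score(g2, d) - total_score(g1, d)
  delta_family <- family_score("Z", "Y", d) - family_score("Z", character(0), d)
  expect_equal(delta_total, delta_family, tolerance = 1e-9)
  # a deterministic copy strongly favors the arc
  y <- factor(sample(c("C0", "C1"), 1000, TRUE), c("C0", "C1"))
  dd <- data.frame(X = y, Y = y)
  expect_gt(family_score("Y", "X", dd), family_score("Y", character(0), dd))
  expect_error(family_score("Y", "X", dd, ess = 0), "positive")
  expect_error(family_score("a", NULL, data.frame(a = 1:5)), "factor")
})

test_that("ancestral simulation reproduces the network distribution", {
  net <- star_chain_net()
  d1 <- simulate(net, 2000, seed = 99)
  d2 <- simulate(net, 2000, seed = 99)
  expect_identical(d1, d2)
  marg <- infer(net)
  for (v in c("S5", "S2"))
    expect_equal(as.numeric(prop.table(table(d1[[v]]))), as.numeric(marg[[v]]),
                 tolerance = 0.05)
  # refitting CPTs on a large simulated sample recovers them
  big <- simulate(net, 20000, seed = 7)
  refit <- fit_cpts(bbn_dag(net$nodes, arcs(net)), big, pseudocount = 0)
  expect_equal(as.numeric(refit$cpt$S4), as.numeric(net$cpt$S4), tolerance = 0.05)
})

test_that("networks round-trip through the native text format and BIF", {
  net <- star_chain_net()
  for (writer in list(list(w = write_bbn, r = read_bbn, ext = ".txt"),
                      list(w = write_bif, r = read_bif, ext = ".bif"))) {
    path <- withr::local_tempfile(fileext = writer$ext)
    writer$w(net, path)
    back <- writer$r(path)
    expect_identical(sort(back$nodes), sort(net$nodes))
    expect_identical(arcs(back), arcs(net))
    for (v in net$nodes)
      expect_equal(as.numeric(back$cpt[[v]]), as.numeric(net$cpt[[v]]),
                   tolerance = 1e-12)
    bm <- infer(back); nm <- infer(net)
    for (v in net$nodes) expect_equal(bm[[v]], nm[[v]], tolerance = 1e-9)
  }
})
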