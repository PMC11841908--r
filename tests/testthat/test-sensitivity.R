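test_that("state doubling rescales exactly, preserving off-state ratios", {
  expect_equal(double_state(c(0.25, 0.75), 1), c(0.50, 0.50))
  # three-state worked example from the published S2 marginal (18/67/15)
  out <- double_state(c(0.18, 0.67, 0.15), 3)
  expect_equal(out[3], 0.30)
  expect_equal(out[1], 0.18 * 0.70 / 0.85, tolerance = 1e-12)
  expect_equal(out[2], 0.67 * 0.70 / 0.85, tolerance = 1e-12)
  # the cap engages when doubling would exceed 1
  eps <- 1e-6
  capped <- double_state(c(0.36, 0.64), 2, eps = eps)
  expect_equal(capped[2], 1 - eps)
  expect_equal(capped[1], eps, tolerance = 1e-4)
  expect_equal(sum(capped), 1, tolerance = 1e-12)
  expect_error(double_state(c(0, 1), 2), "probability 1")
  expect_error(double_state(c(0.5, 0.5), 1, multiplier = 1), "multiplier")
})

test_that("doubling keeps distributions normalized with unboosted ratios intact", {
  set.seed(14)
  for (rep in 1:50) {
    k <- sample(2:3, 1)
    p <- rgamma(k, 1); p <- p / sum(p)
    i <- sample(k, 1)
    if (p[i] >= 1 - 1e-9) next
    q <- double_state(p, i)
    expect_equal(sum(q), 1, tolerance = 1e-12)
    others <- setdiff(seq_len(k), i)
    if (length(others) == 2 && all(p[others] > 0))
      expect_equal(q[others[1]] / q[others[2]], p[others[1]] / p[others[2]],
                   tolerance = 1e-12)
  }
})

test_that("interventions propagate exactly and vanish under d-separation", {
  net <- star_chain_net()
  # source posterior equals the boosted marginal
  base <- infer(net)
  post <- intervene(net, "S4")
  expect_equal(post$S4, double_state(base$S4, 2), tolerance = 1e-9)
  # S1 and S7 are isolated: boosting them moves nothing else,
  # and boosting anything else never moves them
  for (iso in c("S1", "S7")) {
    p_iso <- intervene(net, iso)
    for (v in setdiff(net$nodes, iso))
      expect_equal(p_iso[[v]], base[[v]], tolerance = 1e-9)
  }
  p5 <- intervene(net, "S5")
  expect_equal(p5$S1, base$S1, tolerance = 1e-9)
  expect_equal(p5$S7, base$S7, tolerance = 1e-9)
})

test_that("root-node interventions match the prior-replacement oracle", {
  net <- star_chain_net()
  q <- double_state(infer(net, query = "S5")$S5, 2)
  via_evidence <- intervene(net, "S5")
  # oracle: replace the root prior and re-enumerate the whole joint
  net2 <- net
  net2$cpt$S5[] <- as.numeric(q)
  oracle <- enum_marginals(net2)
  for (v in net$nodes)
    expect_equal(via_evidence[[v]], oracle[[v]], tolerance = 1e-9)
  # the do-mode agrees on root nodes
  via_do <- intervene(net, "S5", do = TRUE)
  for (v in net$nodes)
    expect_equal(via_do[[v]], oracle[[v]], tolerance = 1e-9)
})

test_that("net effects measure relative change of the top state", {
  net <- star_chain_net()
  base <- infer(net)
  expect_equal(net_effect(base, base, "S3"), 0)
  fake <- base
  fake$S3 <- stats::setNames(c(0.60, 0.40), names(base$S3))
  base2 <- base
  base2$S3 <- stats::setNames(c(0.75, 0.25), names(base$S3))
  expect_equal(net_effect(base2, fake, "S3"), 60)
  # enumeration oracle on a fitted chain
  post <- intervene(net, "S5")
  lik <- double_state(base$S5, 2) / base$S5
  oracle <- enum_marginals(net, weight = list(S5 = lik))
  expect_equal(net_effect(base, post, "S2"),
               unname(100 * (oracle$S2[2] - base$S2[2]) / base$S2[2]),
               tolerance = 1e-6)
})

test_that("the influence scan reflects the graph's connectivity pattern", {
  net <- star_chain_net()
  scan <- influence_scan(net)
  eff <- scan$effects
  # isolated sources affect nothing; isolated targets are never affected
  expect_true(all(abs(eff[c("S1", "S7"), -c(1, 7)]) < 1e-9))
  expect_true(all(abs(eff[-c(1, 7), c("S1", "S7")]) < 1e-9))
  # the hub's direct children and its descendants through the chain respond
  expect_true(all(abs(eff["S5", c("S4", "S6", "S8", "S3", "S2")]) > 1e-6))
  expect_true(is.na(eff["S5", "S5"]))
  # fully disconnected network: all-zero table
  iso <- fit_cpts(bbn_dag(net$nodes), simulate(net, 200, seed = 3))
  scan0 <- influence_scan(iso)
  expect_true(all(abs(scan0$effects) < 1e-9, na.rm = TRUE))
  # deterministic under a fixed network
  expect_identical(influence_scan(net)$effects, scan$effects)
  # baseline marginals are percentages matching enumeration
  oracle <- enum_marginals(net)
  for (v in net$nodes)
    expect_equal(scan$baseline[[v]], 100 * oracle[[v]], tolerance = 1e-9)
})

test_that("CPT perturbation scans rank by verified marginal impact", {
  net <- star_chain_net()
  sens <- cpt_sensitivity(net, "S3", delta = 0.1)
  imp <- stats::setNames(sens$max_change, sens$node)
  expect_true(all(imp[c("S1", "S7")] < 1e-12))      # d-separated from the focus
  expect_gt(imp["S3"], 0)
  expect_identical(as.character(sens$level[sens$node %in% c("S1", "S7")]),
                   c("none", "none"))
  # brute-force verification of one reported impact
  v <- "S4"
  base <- infer(net, query = "S3")$S3
  a <- net$cpt[[v]]
  m <- matrix(as.numeric(a), nrow = 2)
  best <- 0
  for (col in seq_len(ncol(m))) for (row in 1:2) for (sgn in c(1, -1)) {
    m2 <- m
    m2[row, col] <- max(m[row, col] * (1 + sgn * 0.1), 0)
    m2[, col] <- m2[, col] / sum(m2[, col])
    net2 <- net
    net2$cpt[[v]] <- array(m2, dim = dim(a), dimnames = dimnames(a))
    best <- max(best, max(abs(enum_marginals(net2)$S3 - base)))
  }
  expect_equal(imp[[v]], best, tolerance = 1e-9)
})
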