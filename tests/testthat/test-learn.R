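make_binary <- function(x) factor(x, c("C0", "C1"))

test_that("score search leaves independent variables unconnected", {
  set.seed(21)
  d <- data.frame(X = make_binary(sample(c("C0", "C1"), 2000, TRUE)),
                  Y = make_binary(sample(c("C0", "C1"), 2000, TRUE)))
  expect_identical(nrow(arcs(bayesian_search(d, seed = 1))), 0L)
  expect_identical(nrow(arcs(greedy_thick_thinning(d))), 0L)
  # score-comparison oracle: the empty graph beats every single-arc structure
  s_empty <- total_score(bbn_dag(c("X", "Y")), d)
  s_xy <- total_score(bbn_dag(c("X", "Y"), rbind(c("X", "Y"))), d)
  s_yx <- total_score(bbn_dag(c("X", "Y"), rbind(c("Y", "X"))), d)
  expect_gt(s_empty, max(s_xy, s_yx))
})

test_that("a deterministic copy yields exactly one arc between the pair", {
  set.seed(22)
  x <- sample(c("C0", "C1"), 2000, TRUE)
  d <- data.frame(X = make_binary(x), Y = make_binary(x))
  for (g in list(bayesian_search(d, seed = 3), greedy_thick_thinning(d))) {
    a <- arcs(g)
    expect_identical(nrow(a), 1L)
    expect_setequal(as.vector(a), c("X", "Y"))
  }
})

test_that("learners are deterministic given data and seed", {
  set.seed(23)
  d <- as.data.frame(lapply(1:4, function(i)
    make_binary(sample(c("C0", "C1"), 300, TRUE))))
  names(d) <- paste0("V", 1:4)
  expect_identical(arcs(bayesian_search(d, seed = 11)),
                   arcs(bayesian_search(d, seed = 11)))
  expect_identical(arcs(greedy_thick_thinning(d)), arcs(greedy_thick_thinning(d)))
  expect_identical(arcs(extend_to_dag(pc_algorithm(d))),
                   arcs(extend_to_dag(pc_algorithm(d))))
})

test_that("BS and GTT attain the exhaustive-search optimum on 3-node problems", {
  set.seed(24)
  for (rep in 1:5) {
    d <- simulate_chain(400, flip = runif(1, 0.05, 0.4))
    dags <- all_3node_dags(names(d))
    expect_length(dags, 25)
    best <- max(vapply(dags, function(g) total_score(g, d), 0))
    expect_equal(attr(bayesian_search(d, seed = rep), "score"), best,
                 tolerance = 1e-9)
    expect_equal(attr(greedy_thick_thinning(d), "score"), best, tolerance = 1e-9)
  }
})

test_that("GTT recovers the chain skeleton without a shortcut arc", {
  set.seed(25)
  d <- simulate_chain(5000, flip = 0.05)
  g <- greedy_thick_thinning(d)
  skel <- apply(arcs(g), 1, function(r) paste(sort(r), collapse = "-"))
  # enumeration oracle: the best-scoring of all 25 DAGs has the chain skeleton
  dags <- all_3node_dags(names(d))
  scores <- vapply(dags, function(h) total_score(h, d), 0)
  oracle_skel <- apply(arcs(dags[[which.max(scores)]]), 1,
                       function(r) paste(sort(r), collapse = "-"))
  expect_setequal(oracle_skel, c("X-Y", "Y-Z"))
  expect_setequal(skel, oracle_skel)
  expect_gte(attr(g, "score"), total_score(bbn_dag(names(d)), d))
})

test_that("the G2 test detects dependence and respects its null distribution", {
  set.seed(26)
  x <- make_binary(sample(c("C0", "C1"), 1000, TRUE))
  expect_lt(ci_test_g2(data.frame(X = x, Y = x), "X", "Y")$p.value, 1e-6)
  # moderate null check (the full 1000-replicate calibration runs in the
  # acceptance suite)
  rej <- mean(replicate(200, {
    d <- data.frame(X = make_binary(sample(c("C0", "C1"), 2000, TRUE)),
                    Y = make_binary(sample(c("C0", "C1"), 2000, TRUE)))
    ci_test_g2(d, "X", "Y")$p.value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.05)
  # conditioning on a common cause removes the marginal dependence
  nonsig <- mean(replicate(40, {
    z <- sample(c("C0", "C1"), 4000, TRUE)
    noisy <- function(v) ifelse(runif(4000) < 0.2,
                                sample(c("C0", "C1"), 4000, TRUE), v)
    d <- data.frame(X = make_binary(noisy(z)), Y = make_binary(noisy(z)),
                    Z = make_binary(z))
    ci_test_g2(d, "X", "Y", "Z")$p.value > 0.05
  }))
  expect_gte(nonsig, 0.9)
})

test_that("PC removes edges, orients colliders and leaves chains partially undirected", {
  set.seed(27)
  d2 <- data.frame(X = make_binary(sample(c("C0", "C1"), 3000, TRUE)),
                   Y = make_binary(sample(c("C0", "C1"), 3000, TRUE)))
  cp <- pc_algorithm(d2)
  expect_false(any(cp$directed) || any(cp$undirected))
  # collider X -> Z <- Y (AND gate keeps the marginal X-Z and Y-Z dependence)
  x <- sample(0:1, 8000, TRUE); y <- sample(0:1, 8000, TRUE)
  z <- ifelse(runif(8000) < 0.15, sample(0:1, 8000, TRUE), as.integer(x & y))
  dc <- data.frame(X = make_binary(paste0("C", x)), Y = make_binary(paste0("C", y)),
                   Z = make_binary(paste0("C", z)))
  cpc <- pc_algorithm(dc)
  expect_true(cpc$directed["X", "Z"] && cpc$directed["Y", "Z"])
  expect_false(any(cpc$undirected))
  # chain: skeleton recovered, orientation within the equivalence class stays open
  dch <- simulate_chain(8000, flip = 0.15)
  cph <- pc_algorithm(dch)
  und_pairs <- which(cph$undirected & upper.tri(cph$undirected))
  expect_identical(length(und_pairs), 2L)   # X-Y and Y-Z left undirected
  expect_false(cph$undirected["X", "Z"])
})

test_that("CPDAG extension keeps directed arcs and outputs a DAG", {
  set.seed(28)
  dch <- simulate_chain(5000, flip = 0.15)
  cp <- pc_algorithm(dch)
  g <- extend_to_dag(cp)
  expect_true(check_acyclic(g))
  dir_idx <- which(cp$directed, arr.ind = TRUE)
  a <- arcs(g)
  for (i in seq_len(nrow(dir_idx)))
    expect_true(any(a[, 1] == cp$nodes[dir_idx[i, 1]] &
                    a[, 2] == cp$nodes[dir_idx[i, 2]]))
  # a lone undirected edge orients in id order
  lone <- structure(list(
    nodes = c("S1", "S2"),
    directed = matrix(FALSE, 2, 2, dimnames = list(c("S1", "S2"), c("S1", "S2"))),
    undirected = matrix(c(FALSE, TRUE, TRUE, FALSE), 2,
                        dimnames = list(c("S1", "S2"), c("S1", "S2"))),
    sepset = list()), class = "bbn_cpdag")
  expect_identical(unname(arcs(extend_to_dag(lone))[1, ]), c("S1", "S2"))
})

test_that("all learners respect acyclicity and the parent limit", {
  cfg <- maternity_survey_config(seed = 31)
  d <- discretize(impute_mean(inject_missing(generate_sections(cfg), 0.07, 32)))
  for (alg in c("bs", "gtt", "pc")) {
    g <- learn_structure(d, alg, max_parents = 2, seed = 5)
    expect_true(check_acyclic(g))
    # score-based learners cap parent sets; PC caps conditioning-set size
    if (alg != "pc") expect_lte(max(vapply(g$parents, length, 0L)), 2L)
  }
})

test_that("the scheme-by-algorithm grid yields nine valid fitted models", {
  cfg <- maternity_survey_config(seed = 33)
  d <- impute_mean(inject_missing(generate_sections(cfg), 0.07, 34))
  grid <- learn_grid(d, seed = 35, restarts = 5)
  expect_length(grid, 9)
  expect_setequal(vapply(grid, function(m) m$algorithm, ""),
                  c("bs", "pc", "gtt"))
  expect_setequal(vapply(grid, function(m) m$scheme, ""),
                  c("two_state", "three_state", "mixed"))
  for (m in grid) {
    expect_true(check_acyclic(m$network))
    expect_true(is.numeric(m$seed))
    for (v in m$network$nodes) {
      tab <- matrix(as.numeric(m$network$cpt[[v]]),
                    nrow = length(m$network$states[[v]]))
      expect_equal(colSums(tab), rep(1, ncol(tab)), tolerance = 1e-9)
    }
  }
})
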