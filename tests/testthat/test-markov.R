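test_that("state space is ordered, disjoint and complete", {
  d <- two_branch_data(1)
  sp <- build_state_space(d$graph, d$ext)
  expect_equal(sp$n, length(d$graph$classes) + length(d$ext$instances))
  expect_equal(sp$states, c(sort(d$graph$classes), sort(d$ext$instances)))

  g <- ontology_graph(c("C1", "C2"), parents = list(C2 = "C1"))
  sp2 <- build_state_space(g, ontology_extension(character(0),
                                                 types = list()))
  expect_equal(sp2$n, 2L)
  expect_length(sp2$instance_states, 0L)

  e_clash <- ontology_extension("C1", types = list(C1 = "C2"), graph = g)
  expect_error(build_state_space(g, e_clash), "both a class and an instance")
})

test_that("jump distribution splits mass by omega and instance weights", {
  g <- ontology_graph(c("C1", "C2"), parents = list(C2 = "C1"))
  e <- ontology_extension("i1", types = list(i1 = "C2"), graph = g)
  sp <- build_state_space(g, e)
  expect_equal(unname(jump_distribution(sp, e, 0.01)),
               c(0.005, 0.005, 0.99))

  e0 <- ontology_extension(character(0), types = list())
  sp0 <- build_state_space(g, e0)
  expect_equal(unname(jump_distribution(sp0, e0, 0.01)), c(0.5, 0.5))

  e2 <- ontology_extension(c("a", "b"),
                           types = list(a = "C2", b = "C2"),
                           weights = c(a = 0.25, b = 0.75), graph = g)
  sp2 <- build_state_space(g, e2)
  expect_equal(unname(jump_distribution(sp2, e2, 0)), c(0, 0, 0.25, 0.75))

  # zero total weight: all jump mass reverts to the classes
  ez <- ontology_extension("i1", types = list(i1 = "C2"),
                           weights = c(i1 = 0), graph = g)
  spz <- build_state_space(g, ez)
  expect_equal(unname(jump_distribution(spz, ez, 0.01)), c(0.5, 0.5, 0))
})

test_that("two-state transition matrix matches hand substitution", {
  g <- ontology_graph("C1")
  e <- ontology_extension("i1", types = list(i1 = "C1"), graph = g)
  P <- as.matrix(build_transition_matrix(g, e, 0.15, 0.01))
  expect_equal(P["i1", ], c(C1 = 0.8515, i1 = 0.1485))
  expect_equal(P["C1", ], c(C1 = 0.01, i1 = 0.99))
})

test_that("alpha = 1 collapses every row to the jump distribution", {
  d <- two_branch_data(2)
  m <- build_transition_matrix(d$graph, d$ext, alpha = 1, omega = 0.3)
  P <- as.matrix(m)
  for (i in seq_len(nrow(P))) {
    expect_equal(unname(P[i, ]), unname(m$jump), tolerance = 1e-15)
  }
  expect_equal(as.numeric(stationary_distribution(m)), unname(m$jump),
               tolerance = 1e-10)
})

test_that("sparse-plus-rank-one matrix equals the naive dense build", {
  set.seed(101)
  for (rep in 1:10) {
    fx <- random_fixture(sample(3:25, 1), sample(2:20, 1))
    m <- build_transition_matrix(fx$graph, fx$ext, 0.15, 0.01)
    P <- as.matrix(m)
    expect_lt(max(abs(P - naive_dense_matrix(fx$graph, fx$ext,
                                             0.15, 0.01))), 1e-14)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  }
})

test_that("two-state stationary distribution solves the balance equation", {
  g <- ontology_graph("C1")
  e <- ontology_extension("i1", types = list(i1 = "C1"), graph = g)
  m <- build_transition_matrix(g, e, 0.15, 0.01)
  st <- stationary_distribution(m)
  # pi_C1 * (1 - 0.01) = (1 - pi_C1) * 0.8515
  expect_equal(unname(st["C1"]), 0.8515 / (0.99 + 0.8515),
               tolerance = 1e-12)
  expect_equal(sum(st), 1, tolerance = 1e-12)
})

test_that("power iteration agrees with the dense eigen oracle", {
  set.seed(202)
  for (rep in 1:10) {
    fx <- random_fixture(sample(3:40, 1), sample(2:40, 1))
    m <- build_transition_matrix(fx$graph, fx$ext, 0.15, 0.01)
    p1 <- stationary_distribution(m, method = "power")
    p2 <- stationary_distribution(m, method = "dense")
    expect_lt(max(abs(p1 - p2)), 1e-8)
    # stationarity residual
    expect_lt(sum(abs(as.numeric(p1 %*% as.matrix(m)) - p1)), 1e-10)
  }
})

test_that("ssp renormalizes over classes; information rank is -log2", {
  g <- ontology_graph("C1")
  e <- ontology_extension("i1", types = list(i1 = "C1"), graph = g)
  fit <- mcoa(g, e)
  expect_equal(unname(fit$ssp), 1)
  expect_equal(unname(fit$info_rank), 0)

  expect_equal(unname(information_rank(c(a = 0.25, b = 2^-10))), c(2, 10))
  expect_error(information_rank(c(a = 0)), "non-positive")

  # symmetric two-branch structure splits ssp evenly
  d <- two_branch_data(3)
  f2 <- mcoa(d$graph, d$ext)
  expect_equal(unname(f2$ssp["X"]), unname(f2$ssp["Y"]), tolerance = 1e-12)
  expect_equal(sum(f2$ssp), 1, tolerance = 1e-10)
})

test_that("relabeling states permutes the stationary vector identically", {
  set.seed(303)
  fx <- random_fixture(12, 10)
  st1 <- mcoa(fx$graph, fx$ext)$stationary
  # relabel classes and instances with reversed-sorting names
  map <- stats::setNames(
    c(sprintf("Z%02d", rev(seq_along(fx$graph$classes))),
      sprintf("y%02d", rev(seq_along(fx$ext$instances)))),
    c(fx$graph$classes, fx$ext$instances))
  g2 <- ontology_graph(unname(map[fx$graph$classes]),
                       parents = stats::setNames(
                         lapply(fx$graph$parents, function(p)
                           unname(map[p])),
                         unname(map[names(fx$graph$parents)])))
  e2 <- ontology_extension(
    unname(map[fx$ext$instances]),
    types = stats::setNames(lapply(fx$ext$types, function(t)
      unname(map[t])), unname(map[fx$ext$instances])),
    weights = stats::setNames(fx$ext$weights,
                              unname(map[names(fx$ext$weights)])),
    graph = g2)
  st2 <- mcoa(g2, e2)$stationary
  expect_equal(as.numeric(st2[map[names(st1)]]), as.numeric(st1),
               tolerance = 1e-10)
})

test_that("rescaling all instance weights leaves the chain unchanged", {
  set.seed(404)
  fx <- random_fixture(10, 12)
  m1 <- as.matrix(build_transition_matrix(fx$graph, fx$ext, 0.15, 0.01))
  ext2 <- ontology_extension(fx$ext$instances, fx$ext$types,
                             weights = fx$ext$weights * 0.37,
                             graph = fx$graph)
  m2 <- as.matrix(build_transition_matrix(fx$graph, ext2, 0.15, 0.01))
  expect_lt(max(abs(m1 - m2)), 1e-14)
})

test_that("rank decays up a pure chain and smooths unannotated classes", {
  # C1 <- C2, all instances on C2: the child outranks its parent
  sc <- challenge_scenario("semantic_distance")
  fit <- mcoa(sc$graph, sc$ext)
  expect_gt(fit$ssp[["C2"]], fit$ssp[["C1"]])
  expect_lt(fit$info_rank[["C2"]], fit$info_rank[["C1"]])

  sp <- challenge_scenario("sparse_class")
  f2 <- mcoa(sp$graph, sp$ext)
  expect_gt(f2$ssp[["C4"]], 0)
})

test_that("parameter validation rejects out-of-range alpha and omega", {
  g <- ontology_graph("C1")
  e <- ontology_extension("i1", types = list(i1 = "C1"), graph = g)
  expect_error(build_transition_matrix(g, e, alpha = 0), "alpha")
  expect_error(build_transition_matrix(g, e, alpha = 1.2), "alpha")
  expect_error(build_transition_matrix(g, e, omega = -0.1), "omega")
})
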