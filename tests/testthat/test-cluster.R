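tri_truth <- stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L), letters[1:6])

test_that("IIW cost matches hand evaluation on reference partitions", {
  net <- triangle_bridge_net(w0 = 0.5)       # M = 3.5, triangle W = 1.5
  expect_equal(iiw_cost(net, stats::setNames(rep(1L, 6), letters[1:6])), 1)
  expect_equal(iiw_cost(net, tri_truth), 0.5 * (3.5 / 1.5 + 3.5 / 1.5))
  # isolating one bridge endpoint leaves a cluster with zero internal weight
  star <- morbidity_network(c("h", "x", "y", "z"),
    data.frame(u = "h", v = c("x", "y", "z"), rr = 2, weight = 0.5), 10L)
  lone <- stats::setNames(c(2L, 1L, 1L, 1L), c("x", "h", "y", "z"))
  expect_equal(iiw_cost(star, lone), Inf)
  expect_error(iiw_cost(net, stats::setNames(c(1, 3, 1, 1, 1, 1), letters[1:6])),
               "empty cluster|labels")
})

test_that("cost breakdown satisfies sum(W) <= M with equality iff no cut edge", {
  net <- triangle_bridge_net()
  cb <- cost_breakdown(net, tri_truth)
  expect_lt(sum(cb$W), cb$M)                  # the bridge is a cut edge
  cb1 <- cost_breakdown(net, stats::setNames(rep(1L, 6), letters[1:6]))
  expect_equal(sum(cb1$W), cb1$M)
  expect_true(all(cb$W >= 0))
})

test_that("K-algorithm leaves an optimal partition unchanged and repairs a bad one", {
  net2 <- clique_net(2, 4)
  opt <- stats::setNames(rep(1:2, each = 4), net2$nodes)
  p <- k_algorithm(net2, opt, seed = 1)
  expect_identical(p$assign, opt)
  expect_equal(p$passes, 1L)
  # deliberately wrong split of the two-triangle graph converges to the triangles
  net <- triangle_bridge_net()
  bad <- stats::setNames(c(1L, 2L, 1L, 2L, 1L, 2L), letters[1:6])
  fixed <- k_algorithm(net, bad, seed = 5)
  expect_equal(adjusted_rand(fixed$assign, tri_truth), 1)
  expect_lte(fixed$cost, iiw_cost(net, bad))
})

test_that("K-algorithm cost never exceeds the initial cost across random starts", {
  for (s in 1:20) {
    set.seed(s)
    net <- random_net(10, p = 0.5, planted = TRUE)
    init <- stats::setNames(
      c(sample.int(3), sample.int(3, 7, replace = TRUE))[sample.int(10)],
      net$nodes)
    c0 <- iiw_cost(net, init)
    p <- k_algorithm(net, init)
    expect_lte(p$cost, c0)
    # reported cost equals a from-scratch recomputation
    expect_equal(p$cost, iiw_cost(net, p$assign), tolerance = 1e-9)
  }
})

test_that("M-algorithm recovers disconnected cliques and matches the exhaustive oracle", {
  net3 <- clique_net(3, 4)
  p <- m_algorithm(net3, 3, repeats = 50, seed = 2)
  truth <- stats::setNames(rep(1:3, each = 4), net3$nodes)
  expect_equal(adjusted_rand(p$assign, truth), 1)
  # 12-node planted toy: global optimum attained
  set.seed(99)
  net <- random_net(12, p = 0.5, planted = TRUE)
  ex <- exhaustive_best_partition(net, 2)
  m <- m_algorithm(net, 2, repeats = 200, seed = 4)
  expect_equal(m$cost, ex$cost, tolerance = 1e-12)
})

test_that("M-algorithm output is valid, deterministic, and strictly descending", {
  set.seed(123)
  net <- random_net(15, p = 0.4)
  p1 <- m_algorithm(net, 4, repeats = 100, seed = 11)
  p2 <- m_algorithm(net, 4, repeats = 100, seed = 11)
  expect_identical(p1, p2)
  expect_setequal(unique(p1$assign), 1:4)        # no empty cluster
  expect_true(all(diff(p1$accepted_costs) < 0))  # strict descent
  expect_lte(p1$cost, p1$accepted_costs[1])
  # repeats = 0 returns the tuned initialization
  p0 <- m_algorithm(net, 4, repeats = 0, seed = 11)
  expect_length(p0$accepted_costs, 1)
  expect_error(m_algorithm(net, 99), "between 1 and")
})

test_that("exhaustive enumeration returns the global minimum", {
  net <- triangle_bridge_net()
  ex <- exhaustive_best_partition(net, 2)
  expect_equal(adjusted_rand(ex$assign, tri_truth), 1)
  expect_equal(ex$cost, 0.5 * (3.5 / 1.5 + 3.5 / 1.5))
  ex1 <- exhaustive_best_partition(net, 1)
  expect_equal(ex1$cost, 1)
  # 6-node unit-weight path, k = 2: check against direct bipartition sweep
  nd <- sprintf("V%d", 1:6)
  path_net <- morbidity_network(nd,
    data.frame(u = nd[1:5], v = nd[2:6], rr = 2, weight = 0.5), 10L)
  best <- Inf
  for (mask in 1:(2^6 - 2)) {
    lab <- as.integer(intToBits(mask)[1:6]) + 1L
    if (length(unique(lab)) < 2) next
    cost <- tryCatch(iiw_cost(path_net, stats::setNames(lab, nd)),
                     error = function(e) Inf)
    best <- min(best, cost)
  }
  expect_equal(exhaustive_best_partition(path_net, 2)$cost, best)
  big <- clique_net(2, 7)
  expect_error(exhaustive_best_partition(big, 2), "13 nodes")
})

test_that("partition count matches the Stirling-number expectation", {
  # S(5,2) = 15, S(5,3) = 25
  net <- random_net(5, p = 1)
  expect_equal(exhaustive_best_partition(net, 2)$n_enumerated, 15)
  expect_equal(exhaustive_best_partition(net, 3)$n_enumerated, 25)
})

test_that("silhouette sweep finds the planted number of cliques", {
  net <- clique_net(4, 4)
  sel <- select_k_silhouette(net, k_min = 2, k_max = 8,
                             repeats = 50, seed = 17)
  expect_equal(sel$k_best, 4)
  expect_equal(nrow(sel$scores), 7)
  # structureless graph: every pairwise dissimilarity equal -> silhouette ~ 0
  n <- 8
  cmb <- t(utils::combn(n, 2))
  nd <- sprintf("U%d", 1:n)
  flat <- morbidity_network(nd,
    data.frame(u = nd[cmb[, 1]], v = nd[cmb[, 2]], rr = 2, weight = 0.5), 10L)
  D <- graph_dissimilarity(flat)
  for (k in 2:4) {
    lab <- rep(seq_len(k), length.out = n)
    expect_equal(mean_silhouette(D, lab), 0, tolerance = 1e-12)
  }
})

test_that("mean silhouette matches a hand-computed toy and scores singletons 0", {
  D <- matrix(c(0, 0.1, 0.9,
                0.1, 0, 0.8,
                0.9, 0.8, 0), 3, 3)
  lab <- c(1L, 1L, 2L)
  # node1: a=0.1, b=0.9 -> 8/9; node2: a=0.1, b=0.8 -> 7/8; node3 singleton -> 0
  expect_equal(mean_silhouette(D, lab), (8 / 9 + 7 / 8 + 0) / 3)
})

test_that("adjusted Rand index behaves at its reference points", {
  a <- rep(1:4, each = 25)
  expect_equal(adjusted_rand(a, a), 1)
  expect_equal(adjusted_rand(a, ((a + 1) %% 4) + 1), 1)  # relabelling
  expect_equal(adjusted_rand(rep(1L, 100), a), 0)        # degenerate k = 1
  set.seed(31)
  shuffles <- replicate(100, adjusted_rand(a, sample(a)))
  expect_lt(abs(mean(shuffles)), 0.05)
})

test_that("adjusted Rand index agrees with the mclust reference implementation", {
  set.seed(8)
  for (i in 1:10) {
    a <- sample.int(4, 40, replace = TRUE)
    b <- sample.int(3, 40, replace = TRUE)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b))
  }
})

test_that("partition files round-trip assignments and cost", {
  net <- triangle_bridge_net()
  p <- m_algorithm(net, 2, repeats = 20, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_partition(p, path)
  back <- read_partition(path)
  expect_identical(back[names(p$assign)], p$assign, ignore_attr = TRUE)
  expect_equal(attr(back, "cost"), p$cost)
})
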