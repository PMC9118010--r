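test_that("patient index deduplicates repeat diagnoses", {
  rec <- data.frame(patient_id = c("p1", "p1", "p1"),
                    block_id = c("I20-I25", "I20-I25", "E10-E14"))
  idx <- build_patient_index(rec)
  expect_equal(nrow(idx), 2L)
  expect_setequal(idx$block_id, c("I20-I25", "E10-E14"))
  # three patients with disjoint codes -> three singleton sets
  rec3 <- data.frame(patient_id = c("a", "b", "c"),
                     block_id = c("A", "B", "C"))
  expect_equal(nrow(build_patient_index(rec3)), 3L)
})

test_that("pair counts match hand arithmetic on tiny cohorts", {
  idx <- data.frame(patient_id = c("p1", "p1", "p2", "p2"),
                    block_id = c("A", "B", "A", "B"))
  pc <- pair_counts(idx)
  expect_equal(pc$P_xy, 2L)
  expect_equal(pc$P_x, 2L)
  expect_equal(pc$P_y, 2L)
  expect_equal(pc$N, 2L)
  expect_error(pair_counts(idx[0, ]), "empty")
})

test_that("pair counts agree with a literal double loop on small cohorts", {
  for (s in 1:3) {
    set.seed(s)
    rec <- random_records(sample(10:50, 1))
    idx <- build_patient_index(filter_visits(rec)$kept)
    got <- pair_counts(idx)
    want <- brute_force_pairs(idx)
    expect_equal(got[order(got$x, got$y), ],
                 want[order(want$x, want$y), ],
                 ignore_attr = TRUE)
    # sum over patients of C(|blocks|, 2) equals sum of P_xy
    sizes <- table(idx$patient_id)
    expect_equal(sum(choose(as.integer(sizes), 2)), sum(got$P_xy))
  }
})

test_that("relative risk follows the prevalence formula and is symmetric", {
  expect_equal(compute_rr(10, 20, 5, 100), 2.5)
  expect_equal(compute_rr(20, 10, 5, 100), 2.5)      # symmetry
  expect_equal(compute_rr(10, 10, 1, 100), 1.0)      # independence
  expect_error(compute_rr(0, 10, 0, 100), "undefined")
})

test_that("relative risk is invariant under cohort replication", {
  set.seed(7)
  rec <- random_records(25)
  idx <- build_patient_index(filter_visits(rec)$kept)
  pc1 <- pair_counts(idx)
  rr1 <- compute_rr(pc1$P_x, pc1$P_y, pc1$P_xy, pc1$N)
  idx3 <- do.call(rbind, lapply(1:3, function(m) {
    transform(idx, patient_id = paste0(patient_id, "_", m))
  }))
  pc3 <- pair_counts(idx3)
  rr3 <- compute_rr(pc3$P_x, pc3$P_y, pc3$P_xy, pc3$N)
  expect_equal(rr3[order(pc3$x, pc3$y)], rr1[order(pc1$x, pc1$y)])
})

test_that("sigmoid normalization has the stated fixed points and preserves ranking", {
  expect_equal(normalize_weight(5, half_point = 5), 0.5)
  expect_equal(normalize_weight(0), 0)
  expect_equal(normalize_weight(100, 5, 2), 10000 / 10025)
  rr <- c(0.3, 1, 2.5, 7, 40, 300)
  w <- normalize_weight(rr)
  expect_true(all(diff(w) > 0))
  expect_true(all(w > 0 & w < 1))
  expect_error(normalize_weight(1, half_point = 0), "positive")
  expect_error(normalize_weight(-1), "non-negative")
})

test_that("network filter applies inclusive rr and patient-count thresholds", {
  st <- data.frame(x = c("A", "A", "B"), y = c("B", "C", "C"),
                   P_x = c(100, 100, 120), P_y = c(120, 80, 80),
                   P_xy = c(12, 9, 50), N = 1000)
  # rr: A-B = 1.0, A-C = 1.125, B-C = 5.2083
  net <- build_network(st, min_rr = 1.0, min_pxy = 10)
  expect_setequal(paste(net$edges$u, net$edges$v), c("A B", "B C"))  # A-C has P_xy = 9
  st2 <- st
  st2$P_xy[1] <- 10  # rr drops below 1
  st2$P_x[1] <- 125
  net2 <- build_network(st2, min_rr = 1.0, min_pxy = 10)
  expect_false("A B" %in% paste(net2$edges$u, net2$edges$v))
})

test_that("raising either threshold never adds edges", {
  set.seed(3)
  rec <- random_records(60)
  st <- pair_counts(build_patient_index(filter_visits(rec)$kept))
  base <- build_network(st, min_rr = 0.5, min_pxy = 1)
  for (mr in c(0.8, 1.0, 1.5)) {
    for (mp in c(1, 3, 5)) {
      net <- suppressWarnings(build_network(st, min_rr = mr, min_pxy = mp))
      expect_true(all(paste(net$edges$u, net$edges$v) %in%
                        paste(base$edges$u, base$edges$v)))
    }
  }
})

test_that("isolated blocks stay as nodes by default and can be dropped", {
  st <- data.frame(x = c("A", "A"), y = c("B", "C"),
                   P_x = 100, P_y = 100, P_xy = c(50, 2), N = 1000)
  net <- build_network(st, min_rr = 1, min_pxy = 10)
  expect_setequal(net$nodes, c("A", "B", "C"))
  net2 <- build_network(st, min_rr = 1, min_pxy = 10, keep_isolated = FALSE)
  expect_setequal(net2$nodes, c("A", "B"))
})

test_that("edge list round-trips losslessly at full precision", {
  edges <- data.frame(u = c("A", "A", "B"), v = c("B", "C", "C"),
                      rr = c(1.23456789012345, 2.5, 100.0001),
                      weight = c(1 / 3, 0.2000000000000001, 0.97))
  net <- morbidity_network(c("A", "B", "C", "ISO"), edges, 4321L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, path)
  back <- read_edge_list(path)
  expect_identical(back$nodes, net$nodes)
  expect_identical(back$n_patients, net$n_patients)
  expect_identical(back$edges, net$edges)
})

test_that("corrupt edge-list files are rejected with the failing line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#N_patients=10", "#isolated=", "u\tv\trr\tweight",
               "A\tB\t2.0\t0.5", "B\tA\t2.0\t0.5"), path)
  expect_error(read_edge_list(path), "u >= v")
  writeLines(c("#N_patients=10", "#isolated=", "u\tv\trr\tweight",
               "A\tB\t2.0"), path)
  expect_error(read_edge_list(path), "line.*4|at 4")
  writeLines(c("#N_patients=10", "#isolated=", "u\tv\trr\tweight",
               "A\tB\t2.0\t0.5", "A\tB\t2.0\t0.5"), path)
  expect_error(read_edge_list(path), "duplicated")
})
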