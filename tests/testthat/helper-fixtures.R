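# graph and cohort fixtures built in code

# two unit-ish-weight triangles {a,b,c} and {d,e,f} joined by bridge c-d;
# all weights w0 (must be < 1)
triangle_bridge_net <- function(w0 = 0.5) {
  edges <- data.frame(
    u = c("a", "a", "b", "d", "d", "e", "c"),
    v = c("b", "c", "c", "e", "f", "f", "d"),
    rr = 2, weight = w0)
  morbidity_network(letters[1:6], edges, 100L)
}

# q disjoint cliques of m nodes each, uniform weight
clique_net <- function(q, m, w0 = 0.6) {
  nodes <- sprintf("C%d_%d", rep(seq_len(q), each = m), rep(seq_len(m), q))
  el <- do.call(rbind, lapply(seq_len(q), function(ci) {
    mem <- nodes[((ci - 1) * m + 1):(ci * m)]
    cmb <- t(utils::combn(mem, 2))
    data.frame(u = pmin(cmb[, 1], cmb[, 2]), v = pmax(cmb[, 1], cmb[, 2]),
               rr = 2, weight = w0)
  }))
  morbidity_network(nodes, el, 100L)
}

# random connected graph with n nodes: spanning path plus density p extras,
# weights uniform in (0.05, 0.95); 'planted' adds two heavy groups
random_net <- function(n, p = 0.4, planted = FALSE) {
  cmb <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(cmb)) < p
  path <- cbind(seq_len(n - 1), 2:n)
  m <- unique(rbind(cmb[keep, , drop = FALSE], path))
  w <- stats::runif(nrow(m), 0.05, 0.95)
  if (planted) {
    half <- n %/% 2
    inside <- (m[, 1] <= half & m[, 2] <= half) |
      (m[, 1] > half & m[, 2] > half)
    w[inside] <- stats::runif(sum(inside), 0.6, 0.95)
    w[!inside] <- stats::runif(sum(!inside), 0.05, 0.3)
  }
  nd <- sprintf("N%02d", seq_len(n))
  morbidity_network(nd, data.frame(u = nd[m[, 1]], v = nd[m[, 2]],
                                   rr = 2, weight = w), 100L)
}

# random small cohort of visit-diagnosis rows over given blocks
random_records <- function(n_patients, blocks = c("I21", "E11", "J45", "F32", "M54"),
                           max_codes = 4) {
  rows <- lapply(seq_len(n_patients), function(i) {
    codes <- sample(blocks, sample.int(max_codes, 1), replace = TRUE)
    data.frame(patient_id = sprintf("p%03d", i),
               visit_date = sample(c("2015-03-01", "2016-07-15", "2018-11-30"),
                                   length(codes), replace = TRUE),
               age = sample(18:90, 1),
               gender = sample(c("female", "male"), 1),
               icd10 = codes,
               cost_eur = round(stats::runif(length(codes), 10, 500), 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# literal double-loop pair-count oracle over a patient -> block-set list
brute_force_pairs <- function(index) {
  sets <- split(index$block_id, index$patient_id)
  sets <- lapply(sets, unique)
  N <- length(sets)
  blocks <- sort(unique(unlist(sets)))
  out <- list()
  for (i in seq_along(blocks)) {
    for (j in seq_along(blocks)) {
      if (i >= j) next
      x <- blocks[i]; y <- blocks[j]
      pxy <- sum(vapply(sets, function(s) x %in% s && y %in% s, TRUE))
      if (pxy >= 1) {
        out[[length(out) + 1]] <- data.frame(
          x = x, y = y,
          P_x = sum(vapply(sets, function(s) x %in% s, TRUE)),
          P_y = sum(vapply(sets, function(s) y %in% s, TRUE)),
          P_xy = pxy, N = N, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
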