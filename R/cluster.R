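# Internal edge-array representation used by all clustering routines.
# Nodes are indexed 1..n in the (sorted) order of net$nodes; edges are kept
# as parallel integer/double vectors plus a per-node adjacency list.
as_graph_arrays <- function(net) {
  stopifnot(inherits(net, "morbidity_network"))
  nodes <- net$nodes
  n <- length(nodes)
  ui <- match(net$edges$u, nodes)
  vi <- match(net$edges$v, nodes)
  w <- net$edges$weight
  adj <- vector("list", n)
  if (length(ui)) {
    ends <- c(ui, vi)
    other <- c(vi, ui)
    ww <- c(w, w)
    o <- order(ends)
    adj_nb <- split(other[o], factor(ends[o], levels = seq_len(n)))
    adj_w <- split(ww[o], factor(ends[o], levels = seq_len(n)))
    for (i in seq_len(n)) adj[[i]] <- list(nb = adj_nb[[i]], w = adj_w[[i]])
  } else {
    for (i in seq_len(n)) adj[[i]] <- list(nb = integer(0), w = numeric(0))
  }
  strength <- vapply(adj, function(a) sum(a$w), 0)
  list(nodes = nodes, n = n, ui = ui, vi = vi, w = w,
       M = sum(w), adj = adj, strength = strength)
}

check_assignment <- function(net, assign) {
  if (is.null(names(assign))) {
    if (length(assign) != length(net$nodes)) {
      stop("assignment length differs from node count")
    }
    names(assign) <- net$nodes
  }
  if (!setequal(names(assign), net$nodes)) {
    stop("assignment does not cover exactly the network's nodes")
  }
  assign <- assign[net$nodes]
  k <- max(assign)
  if (!all(assign %in% seq_len(k))) stop("cluster labels must lie in 1..k")
  if (!all(seq_len(k) %in% assign)) stop("empty cluster label in 1..k")
  storage.mode(assign) <- "integer"
  assign
}

# per-cluster internal weight for an integer label vector (full recomputation)
internal_weights <- function(g, lab, k) {
  same <- lab[g$ui] == lab[g$vi]
  W <- numeric(k)
  if (any(same)) {
    tw <- tapply(g$w[same], factor(lab[g$ui][same], levels = seq_len(k)), sum)
    W <- ifelse(is.na(tw), 0, as.numeric(tw))
  }
  W
}

# IIW value from per-cluster internal weights. Clusters whose members all
# have zero strength (isolated nodes) cannot have internal weight and are
# excluded from the mean; any other zero-weight cluster makes the cost +Inf.
# With eps > 0, zero weights are clamped to eps instead, giving the local
# search a finite but enormous cost that still decreases with every
# weight-starved cluster repaired; eps never alters the value of a
# partition whose contributing clusters all have positive weight.
iiw_from_W <- function(W, M, zero_ok, eps = 0) {
  contrib <- W > 0 | !zero_ok
  if (!any(contrib)) stop("no cluster with positive internal weight")
  if (any(W[contrib] <= 0)) {
    if (eps <= 0) return(Inf)
    return(mean(M / pmax(W[contrib], eps)))
  }
  mean(M / W[contrib])
}

# which clusters are allowed internal weight zero: those containing only
# strength-zero (isolated) nodes
zero_ok_clusters <- function(g, lab, k) {
  has_strength <- tapply(g$strength > 0, factor(lab, levels = seq_len(k)), any)
  !ifelse(is.na(has_strength), FALSE, as.logical(has_strength))
}

#' Inverse-internal-weight cost of a partition
#'
#' For a partition of the network into `k` clusters with internal weights
#' `W_i` (sum of edge weights with both endpoints inside cluster `i`) and
#' total graph weight `M`, the cost is
#' `(1/k) * sum_i M / W_i`,
#' to be minimized. Dividing the fixed mass `M` by each cluster's internal
#' weight penalizes clusters that capture little weight; by convexity of
#' `1/W` the minimum under a fixed total internal weight is at equal `W_i`,
#' which is what drives the balanced cluster sizes this cost is known for.
#' A cluster with internal weight zero gives `+Inf`, unless it consists only
#' of isolated nodes (zero strength), in which case it is excluded from the
#' mean with a warning: isolated nodes carry no weight anywhere, so they are
#' allowed to sit in clusters of their own.
#'
#' @param net A `morbidity_network`.
#' @param assign Integer cluster labels in `1..k`, named by node or in
#'   `net$nodes` order; every label in `1..k` must occur.
#' @return The scalar cost (possibly `Inf`).
#' @export
iiw_cost <- function(net, assign) {
  g <- as_graph_arrays(net)
  lab <- check_assignment(net, assign)
  k <- max(lab)
  W <- internal_weights(g, lab, k)
  zok <- zero_ok_clusters(g, lab, k)
  if (any(W == 0 & zok)) {
    warning("cluster(s) of isolated nodes excluded from the IIW mean")
  }
  iiw_from_W(W, g$M, zok)
}

#' Per-cluster internal weights and total mass
#'
#' @inheritParams iiw_cost
#' @return A list with `W` (per-cluster internal weight), `M` (total edge
#'   weight) and `k`.
#' @export
cost_breakdown <- function(net, assign) {
  g <- as_graph_arrays(net)
  lab <- check_assignment(net, assign)
  k <- max(lab)
  list(W = internal_weights(g, lab, k), M = g$M, k = k)
}

# One K-algorithm run on the internal representation. `lab` is a valid
# integer labelling; RNG state is consumed for the per-pass node shuffles.
# Returns list(lab, W, cost, passes, converged).
k_algorithm_core <- function(g, lab, k, max_passes = 100L, rel_tol = 1e-12) {
  W <- internal_weights(g, lab, k)
  sizes <- tabulate(lab, k)
  # per-cluster count of strength-positive nodes; a cluster with none is an
  # isolated-node cluster and may have internal weight zero
  pos <- tabulate(lab[g$strength > 0], k)
  eps <- 1e-9
  cost <- iiw_from_W(W, g$M, pos == 0L, eps)
  passes <- 0L
  repeat {
    passes <- passes + 1L
    moved <- 0L
    for (v in sample.int(g$n)) {
      a <- lab[v]
      if (sizes[a] == 1L) next  # moving v would empty its cluster
      nb <- g$adj[[v]]$nb
      if (!length(nb)) next     # isolated node: no move changes the cost
      conn <- numeric(k)
      cs <- rowsum(g$adj[[v]]$w, lab[nb])
      conn[as.integer(rownames(cs))] <- cs
      # candidate costs of moving v to each cluster b (sequential update);
      # v has positive strength here, so b can never become isolated-only
      Wa_out <- W[a] - conn[a]
      za_out <- (pos[a] - 1L) == 0L
      best_b <- a
      best_cost <- cost
      for (b in seq_len(k)) {
        if (b == a) next
        Wtry <- W
        Wtry[a] <- Wa_out
        Wtry[b] <- W[b] + conn[b]
        ztry <- pos == 0L
        ztry[a] <- za_out
        ztry[b] <- FALSE
        ctry <- iiw_from_W(Wtry, g$M, ztry, eps)
        if (ctry < best_cost * (1 - rel_tol)) {
          best_cost <- ctry
          best_b <- b
        }
      }
      if (best_b != a) {
        W[a] <- Wa_out
        W[best_b] <- W[best_b] + conn[best_b]
        sizes[a] <- sizes[a] - 1L
        sizes[best_b] <- sizes[best_b] + 1L
        pos[a] <- pos[a] - 1L
        pos[best_b] <- pos[best_b] + 1L
        lab[v] <- best_b
        cost <- best_cost
        moved <- moved + 1L
      }
    }
    if (moved == 0L || passes >= max_passes) {
      if (moved > 0L) warning("K-algorithm pass cap reached before convergence")
      true_cost <- iiw_from_W(W, g$M, pos == 0L)
      return(list(lab = lab, W = W, cost = cost, true_cost = true_cost,
                  passes = passes, converged = moved == 0L))
    }
  }
}

#' Sequential local search on cluster labels (K-algorithm)
#'
#' The graph analogue of sequential k-means: nodes are visited in random
#' order and each is reassigned to the cluster that most improves the
#' inverse-internal-weight cost, with the cluster weights updated
#' immediately so later moves in the same pass see the effect. Moves that
#' would empty a cluster are skipped; a node moves only on strict
#' improvement (relative tolerance 1e-12), which prevents oscillation.
#' Passes repeat until one completes with no move.
#'
#' @param net A `morbidity_network`.
#' @param init Initial labelling as accepted by [iiw_cost()].
#' @param seed Optional integer seed for the per-pass node shuffles; if
#'   `NULL` the current RNG state is used.
#' @param max_passes Safety cap on passes (default 100); reaching it returns
#'   the best labelling so far with a warning.
#' @return A `graph_partition`: list with `assign` (named integer vector),
#'   `k`, `cost`, `passes`, `converged`.
#' @export
k_algorithm <- function(net, init, seed = NULL, max_passes = 100L) {
  if (!is.null(seed)) set.seed(seed)
  g <- as_graph_arrays(net)
  lab <- check_assignment(net, init)
  k <- max(lab)
  res <- k_algorithm_core(g, lab, k, max_passes = max_passes)
  new_partition(res$lab, g$nodes, k, res$true_cost,
                passes = res$passes, converged = res$converged)
}

new_partition <- function(lab, nodes, k, cost, ...) {
  structure(list(assign = stats::setNames(as.integer(lab), nodes),
                 k = as.integer(k), cost = cost, ...),
            class = "graph_partition")
}

#' @export
print.graph_partition <- function(x, ...) {
  cat("Graph partition: k =", x$k, ", IIW cost =", format(x$cost), "\n")
  print(table(cluster = x$assign))
  invisible(x)
}

# random surjective k-labelling: each label gets one of k distinct random
# nodes, the rest are uniform
random_labelling <- function(n, k) {
  lab <- sample.int(k, n, replace = TRUE)
  lab[sample.int(n, k)] <- sample.int(k)
  lab
}

#' Merge/split graph clustering (M-algorithm)
#'
#' Wraps the K-algorithm in a randomized merge-and-split search to escape
#' the local minima that plain local search gets trapped in. A random
#' surjective `k`-labelling is first tuned with the K-algorithm. Then, for
#' `repeats` rounds: two distinct random clusters are merged, one random
#' cluster of size at least 2 is split by a uniform random bipartition with
#' both sides non-empty, the result is tuned with the K-algorithm, and the
#' new solution replaces the current one only if its cost is strictly
#' lower. The best solution seen is returned.
#'
#' RNG consumption order is fixed (initial labelling, then per round: merge
#' choice, split choice, bipartition, K-algorithm shuffles), so a fixed
#' `seed` and input give a byte-identical partition.
#'
#' @param net A `morbidity_network`.
#' @param k Number of clusters, `2 <= k <=` number of nodes.
#' @param repeats Number of merge/split rounds. Default 20000, sized for a
#'   final production run; use a few hundred for experimentation.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param max_passes Passed to the inner K-algorithm.
#' @return A `graph_partition` with additional fields `seed`, `repeats` and
#'   `accepted_costs` (the strictly decreasing sequence of accepted costs,
#'   starting at the tuned initialization).
#' @export
m_algorithm <- function(net, k, repeats = 20000L, seed = NULL,
                        max_passes = 100L) {
  if (!is.null(seed)) set.seed(seed)
  g <- as_graph_arrays(net)
  k <- as.integer(k)
  if (k < 1L || k > g$n) stop("k must be between 1 and the number of nodes")
  lab <- random_labelling(g$n, k)
  res <- k_algorithm_core(g, lab, k, max_passes = max_passes)
  best_lab <- res$lab
  best_cost <- res$cost
  best_true <- res$true_cost
  accepted <- best_cost
  if (repeats > 0L && k >= 2L) {
    for (r in seq_len(repeats)) {
      lab <- best_lab
      # merge two distinct random clusters
      mg <- sample.int(k, 2L)
      lab[lab == mg[2L]] <- mg[1L]
      # split one random cluster of size >= 2 into a random bipartition,
      # reusing the freed label mg[2]
      sizes <- tabulate(lab, k)
      cand <- which(sizes >= 2L)
      sp <- cand[sample.int(length(cand), 1L)]
      members <- which(lab == sp)
      side <- uniform_bipartition(length(members))
      lab[members[side]] <- mg[2L]
      res <- k_algorithm_core(g, lab, k, max_passes = max_passes)
      if (res$cost < best_cost) {
        best_cost <- res$cost
        best_true <- res$true_cost
        best_lab <- res$lab
        accepted <- c(accepted, best_cost)
      }
    }
  }
  new_partition(best_lab, g$nodes, k, best_true,
                seed = seed, repeats = repeats, accepted_costs = accepted)
}

# uniform random bipartition of m items with both sides non-empty; returns a
# logical vector marking the side that gets the new label
uniform_bipartition <- function(m) {
  repeat {
    side <- stats::runif(m) < 0.5
    s <- sum(side)
    if (s > 0L && s < m) return(side)
  }
}

#' Globally optimal partition by exhaustive enumeration
#'
#' Enumerates every partition of the nodes into exactly `k` non-empty
#' clusters (restricted growth strings, i.e. one representative per
#' labelling up to label permutation) and returns a labelling attaining the
#' minimum inverse-internal-weight cost. Intended as a test oracle; the
#' number of partitions is the Stirling number S(n, k), so the node count is
#' capped at 13.
#'
#' @param net A `morbidity_network` with at most 13 nodes.
#' @param k Number of clusters.
#' @return A `graph_partition` with field `n_enumerated`.
#' @export
exhaustive_best_partition <- function(net, k) {
  g <- as_graph_arrays(net)
  if (g$n > 13L) stop("exhaustive enumeration is capped at 13 nodes")
  k <- as.integer(k)
  if (k < 1L || k > g$n) stop("k must be between 1 and the number of nodes")
  rgs <- restricted_growth_strings(g$n, k)   # matrix, one row per partition
  zero_ok_any <- any(g$strength == 0)
  best_cost <- Inf
  best_lab <- NULL
  chunk <- 100000L
  for (start in seq(1L, nrow(rgs), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(rgs))
    L <- rgs[rows, , drop = FALSE]
    Lu <- L[, g$ui, drop = FALSE]
    Lv <- L[, g$vi, drop = FALSE]
    costs <- numeric(length(rows))
    Wmat <- matrix(0, length(rows), k)
    for (i in seq_len(k)) {
      inside <- (Lu == i) & (Lv == i)
      Wmat[, i] <- as.numeric(inside %*% g$w)
    }
    if (zero_ok_any) {
      costs <- vapply(seq_len(nrow(L)), function(j) {
        iiw_from_W(Wmat[j, ], g$M, zero_ok_clusters(g, L[j, ], k))
      }, 0)
    } else {
      bad <- apply(Wmat <= 0, 1, any)
      costs <- rowMeans(g$M / Wmat)
      costs[bad] <- Inf
    }
    j <- which.min(costs)
    if (costs[j] < best_cost) {
      best_cost <- costs[j]
      best_lab <- L[j, ]
    }
  }
  if (is.null(best_lab) || !is.finite(best_cost)) {
    # every k-partition leaves some weight-starved cluster
    best_lab <- rgs[1L, ]
    best_cost <- Inf
  }
  new_partition(best_lab, g$nodes, k, best_cost, n_enumerated = nrow(rgs))
}

# all restricted growth strings of length n with exactly k distinct labels,
# built column by column; rows are canonical representatives of set
# partitions into k non-empty blocks
restricted_growth_strings <- function(n, k) {
  M <- matrix(1L, 1L, 1L)
  mx <- 1L
  for (j in seq_len(n - 1L)) {
    opts <- pmin(mx + 1L, k)
    rows <- rep.int(seq_along(mx), opts)
    newlab <- sequence(opts)
    M <- cbind(M[rows, , drop = FALSE], newlab)
    mx <- pmax(mx[rows], newlab)
  }
  M <- M[mx == k, , drop = FALSE]
  dimnames(M) <- NULL
  M
}

#' Graph dissimilarity matrix for silhouette computation
#'
#' Dissimilarity `1 - weight` for adjacent node pairs, 1 for non-adjacent
#' pairs, 0 on the diagonal.
#'
#' @param net A `morbidity_network`.
#' @return A symmetric numeric matrix with node names.
#' @export
graph_dissimilarity <- function(net) {
  g <- as_graph_arrays(net)
  D <- matrix(1, g$n, g$n, dimnames = list(g$nodes, g$nodes))
  diag(D) <- 0
  if (length(g$ui)) {
    D[cbind(g$ui, g$vi)] <- 1 - g$w
    D[cbind(g$vi, g$ui)] <- 1 - g$w
  }
  D
}

#' Mean silhouette of a labelling under a dissimilarity matrix
#'
#' Standard silhouette: for node `i` with within-cluster mean dissimilarity
#' `a(i)` and smallest other-cluster mean dissimilarity `b(i)`,
#' `s(i) = (b - a) / max(a, b)`; nodes in singleton clusters score 0.
#'
#' @param D Symmetric dissimilarity matrix.
#' @param lab Integer labels.
#' @return Mean of `s(i)` over all nodes.
#' @export
mean_silhouette <- function(D, lab) {
  n <- nrow(D)
  stopifnot(length(lab) == n)
  k <- max(lab)
  if (k == 1L) return(0)
  sizes <- tabulate(lab, k)
  # column sums of D within each cluster, for every node at once
  G <- rowsum(D, lab)                      # k x n: sum of d(i, .) per cluster
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- lab[i]
    if (sizes[ci] == 1L) { s[i] <- 0; next }
    a <- G[ci, i] / (sizes[ci] - 1L)
    others <- setdiff(seq_len(k), ci)
    b <- min(G[others, i] / sizes[others])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Select the number of clusters by silhouette
#'
#' Runs the M-algorithm for each `k` in `k_min..k_max` and scores the
#' resulting partition by the mean silhouette under the graph dissimilarity
#' of [graph_dissimilarity()]; returns the `k` with the highest score.
#'
#' @param net A `morbidity_network`.
#' @param k_min,k_max Sweep range (defaults 5 and 25).
#' @param repeats M-algorithm rounds per `k`.
#' @param seed Integer seed; each `k` uses a sub-seed derived from it so the
#'   sweep is reproducible.
#' @return A list with `k_best` and `scores`, a `data.frame` of `k` and
#'   mean silhouette.
#' @export
select_k_silhouette <- function(net, k_min = 5L, k_max = 25L,
                                repeats = 2000L, seed = NULL) {
  if (k_max > length(net$nodes)) stop("k_max exceeds the node count")
  if (k_min < 2L) stop("k_min must be at least 2")
  D <- graph_dissimilarity(net)
  ks <- seq.int(k_min, k_max)
  scores <- vapply(seq_along(ks), function(i) {
    sk <- if (is.null(seed)) NULL else seed + i - 1L
    p <- m_algorithm(net, ks[i], repeats = repeats, seed = sk)
    mean_silhouette(D, p$assign[rownames(D)])
  }, 0)
  list(k_best = ks[which.max(scores)],
       scores = data.frame(k = ks, silhouette = scores))
}

#' Adjusted Rand index between two labellings
#'
#' Chance-corrected agreement between two partitions of the same node set,
#' computed from the contingency table; 1 means identical up to
#' relabelling, and the expected value under independent random labellings
#' is 0. When either partition is a single cluster the index is 0 by the
#' degenerate-case convention.
#'
#' @param a,b Labellings: vectors over the same nodes (matched by name when
#'   both are named).
#' @return A number in `[-1, 1]`.
#' @export
adjusted_rand <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) stop("labellings cover different nodes")
    b <- b[names(a)]
  }
  if (length(a) != length(b)) stop("labellings differ in length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' Write a partition to a TSV file
#'
#' Format: `#` header lines recording cost and seed, then
#' `block_id<TAB>cluster_label` rows.
#'
#' @param partition A `graph_partition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#cost=%.17g", partition$cost), con)
  writeLines(sprintf("#seed=%s",
                     if (is.null(partition$seed)) "NA" else partition$seed), con)
  writeLines(sprintf("%s\t%d", names(partition$assign), partition$assign), con)
  invisible(path)
}

#' Read a partition written by [write_partition()]
#'
#' @param path File path.
#' @return A named integer vector of cluster labels with attribute `"cost"`.
#' @export
read_partition <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(vapply(fields, length, 1L) != 2L)) stop("malformed partition file")
  m <- do.call(rbind, fields)
  out <- stats::setNames(as.integer(m[, 2]), m[, 1])
  cost_line <- hdr[startsWith(hdr, "#cost=")]
  attr(out, "cost") <- if (length(cost_line)) {
    as.numeric(sub("^#cost=", "", cost_line[1]))
  } else NA_real_
  out
}
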