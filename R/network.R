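#' Per-patient diagnosis block index
#'
#' Collapses filtered visit-diagnosis rows to one set of diagnosis blocks per
#' patient. Prevalence throughout the package is patient-level: a patient
#' either carries a block at least once during the study window or not;
#' repeat visits do not add weight.
#'
#' @param records Filtered records from [filter_visits()], i.e. rows carrying
#'   a `block_id` column.
#' @return A `data.table` with columns `patient_id` and `block_id`, one row
#'   per distinct (patient, block) pair.
#' @export
build_patient_index <- function(records) {
  stopifnot(all(c("patient_id", "block_id") %in% names(records)))
  dt <- data.table::as.data.table(records[, c("patient_id", "block_id")])
  unique(dt, by = c("patient_id", "block_id"))[order(patient_id, block_id)]
}

#' Co-occurrence counts for all diagnosis pairs
#'
#' Counts, for every unordered pair of blocks seen together in at least one
#' patient, the number of patients with both (`P_xy`), the marginal patient
#' counts (`P_x`, `P_y`) and the cohort size `N`.
#'
#' @param index Patient index from [build_patient_index()].
#' @return A `data.frame` with columns `x`, `y` (block ids, `x < y`
#'   lexicographically), `P_x`, `P_y`, `P_xy`, `N`.
#' @export
pair_counts <- function(index) {
  dt <- data.table::as.data.table(index)
  if (nrow(dt) == 0L) stop("empty patient index")
  n_pat <- data.table::uniqueN(dt$patient_id)
  marg <- dt[, .(P = .N), by = block_id]
  # join each patient's block set with itself, keep ordered pairs x < y
  pairs <- dt[dt, on = "patient_id", allow.cartesian = TRUE][block_id < i.block_id]
  out <- pairs[, .(P_xy = .N), by = .(x = block_id, y = i.block_id)]
  out[marg, P_x := i.P, on = c(x = "block_id")]
  out[marg, P_y := i.P, on = c(y = "block_id")]
  out[, N := n_pat]
  out <- as.data.frame(out[order(x, y), .(x, y, P_x, P_y, P_xy, N)])
  out
}

#' Relative risk of a diagnosis pair
#'
#' The observed probability of carrying both diagnoses divided by the
#' probability expected if they were independent:
#' `rr = p(xy) / (p(x) p(y)) = P_xy * N / (P_x * P_y)`.
#' A value above 1 means the pair co-occurs more often than chance.
#'
#' @param P_x,P_y Patient counts for each diagnosis (prevalence).
#' @param P_xy Patient count with both diagnoses.
#' @param N Total number of patients.
#' @return Numeric vector of relative risks.
#' @export
#' @examples
#' compute_rr(10, 20, 5, 100) # 2.5
compute_rr <- function(P_x, P_y, P_xy, N) {
  if (any(P_x <= 0) || any(P_y <= 0) || any(N <= 0)) {
    stop("relative risk undefined: marginal prevalence or N is zero")
  }
  as.numeric(P_xy) * as.numeric(N) / (as.numeric(P_x) * as.numeric(P_y))
}

#' Sigmoid normalization of relative risk to (0,1)
#'
#' Relative risks are mostly moderate but have a heavy right tail (values in
#' the hundreds occur); used raw they would dominate a clustering cost. This
#' maps them through the symmetric sigmoid
#' `w = rr^h / (rr^h + c^h)`,
#' which is strictly increasing, sends 0 to 0, the half-point `c` to 0.5 and
#' infinity to 1, so the ranking of edges is preserved while outliers are
#' compressed.
#'
#' @param rr Non-negative relative risks.
#' @param half_point `c`, the rr value mapped to 0.5. Default 5: the bulk of
#'   observed relative risks falls below this, so the steep part of the curve
#'   spans the informative range.
#' @param steepness `h`, the sigmoid exponent; default 2.
#' @return Weights in `[0, 1)` (strictly inside `(0, 1)` for `rr > 0`).
#' @export
normalize_weight <- function(rr, half_point = 5, steepness = 2) {
  if (half_point <= 0 || steepness <= 0) {
    stop("half_point and steepness must be positive")
  }
  if (any(rr < 0)) stop("rr must be non-negative")
  rr^steepness / (rr^steepness + half_point^steepness)
}

#' Assemble the multimorbidity network
#'
#' Keeps pairs with `rr >= min_rr` and at least `min_pxy` patients carrying
#' both diagnoses, attaches sigmoid-normalized weights, and returns the
#' network. By default every block observed in the pair statistics remains a
#' node even if none of its edges survive, so a subsequent partition covers
#' all diagnoses; set `keep_isolated = FALSE` to restrict nodes to edge
#' endpoints.
#'
#' @param stats Pair statistics from [pair_counts()].
#' @param min_rr Minimum relative risk, inclusive. Default 1.0.
#' @param min_pxy Minimum number of patients with both diagnoses, inclusive.
#'   Default 10.
#' @param half_point,steepness Sigmoid parameters, see [normalize_weight()].
#' @param keep_isolated Keep blocks with no surviving edge as isolated nodes.
#' @return An object of class `morbidity_network`: a list with `nodes`
#'   (sorted character vector), `edges` (`data.frame` with `u`, `v`, `rr`,
#'   `weight`; `u < v`) and `n_patients`.
#' @export
build_network <- function(stats, min_rr = 1.0, min_pxy = 10L,
                          half_point = 5, steepness = 2,
                          keep_isolated = TRUE) {
  stopifnot(all(c("x", "y", "P_x", "P_y", "P_xy", "N") %in% names(stats)))
  rr <- compute_rr(stats$P_x, stats$P_y, stats$P_xy, stats$N)
  keep <- rr >= min_rr & stats$P_xy >= min_pxy
  edges <- data.frame(u = stats$x[keep], v = stats$y[keep],
                      rr = rr[keep],
                      weight = normalize_weight(rr[keep], half_point, steepness),
                      stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) warning("no edge passed the rr/patient-count filter")
  nodes <- if (keep_isolated) {
    sort(unique(c(stats$x, stats$y)))
  } else {
    sort(unique(c(edges$u, edges$v)))
  }
  n_pat <- if (nrow(stats)) stats$N[1] else 0L
  morbidity_network(nodes, edges, n_pat)
}

#' Construct a morbidity_network object
#'
#' @param nodes Character vector of block ids.
#' @param edges `data.frame` with columns `u`, `v`, `rr`, `weight`.
#' @param n_patients Number of patients behind the pair statistics.
#' @return A `morbidity_network` object.
#' @export
morbidity_network <- function(nodes, edges, n_patients) {
  nodes <- sort(unique(as.character(nodes)))
  edges <- as.data.frame(edges)
  stopifnot(all(c("u", "v", "rr", "weight") %in% names(edges)))
  if (any(edges$u == edges$v)) stop("self-loop in edge list")
  if (!all(edges$u < edges$v)) stop("edges must be stored with u < v")
  key <- paste(edges$u, edges$v)
  if (anyDuplicated(key)) stop("duplicated undirected edge")
  if (!all(edges$u %in% nodes & edges$v %in% nodes)) {
    stop("edge endpoint not among nodes")
  }
  if (nrow(edges) && (any(edges$weight <= 0) || any(edges$weight >= 1))) {
    stop("edge weights must lie strictly in (0, 1)")
  }
  edges <- edges[order(edges$u, edges$v), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 n_patients = as.integer(n_patients)),
            class = "morbidity_network")
}

#' @export
print.morbidity_network <- function(x, ...) {
  cat("Multimorbidity network:", length(x$nodes), "diagnosis blocks,",
      nrow(x$edges), "edges,", x$n_patients, "patients\n")
  if (nrow(x$edges)) {
    cat("  rr range:", signif(min(x$edges$rr), 4), "-",
        signif(max(x$edges$rr), 4), "\n")
  }
  invisible(x)
}

#' Write a network as a tab-separated edge list
#'
#' Format: a header comment `#N_patients=<int>`, a column header line, then
#' one line per undirected edge `u v rr weight` with `u < v`. Isolated nodes
#' are recorded in a second comment line so the round trip is lossless.
#'
#' @param net A `morbidity_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "morbidity_network"))
  iso <- setdiff(net$nodes, unique(c(net$edges$u, net$edges$v)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#N_patients=%d", net$n_patients), con)
  writeLines(sprintf("#isolated=%s", paste(iso, collapse = ",")), con)
  writeLines("u\tv\trr\tweight", con)
  if (nrow(net$edges)) {
    writeLines(sprintf("%s\t%s\t%.17g\t%.17g",
                       net$edges$u, net$edges$v,
                       net$edges$rr, net$edges$weight), con)
  }
  invisible(path)
}

#' Read a network from a tab-separated edge list
#'
#' @param path File written by [write_edge_list()].
#' @return A `morbidity_network`.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 3 || !startsWith(lines[1], "#N_patients=")) {
    stop("not an edge-list file (missing #N_patients header): ", path)
  }
  n_pat <- as.integer(sub("^#N_patients=", "", lines[1]))
  iso <- sub("^#isolated=", "", lines[2])
  iso <- if (nzchar(iso)) strsplit(iso, ",", fixed = TRUE)[[1]] else character(0)
  body <- lines[-(1:3)]
  edges <- data.frame(u = character(0), v = character(0),
                      rr = numeric(0), weight = numeric(0))
  if (length(body)) {
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- vapply(fields, length, 1L)
    if (any(nf != 4L)) {
      stop("malformed edge line(s) at ",
           paste(which(nf != 4L) + 3L, collapse = ", "), " in ", path)
    }
    m <- do.call(rbind, fields)
    edges <- data.frame(u = m[, 1], v = m[, 2],
                        rr = as.numeric(m[, 3]), weight = as.numeric(m[, 4]),
                        stringsAsFactors = FALSE)
    if (any(is.na(edges$rr)) || any(is.na(edges$weight))) {
      stop("non-numeric rr/weight field in ", path)
    }
    if (any(edges$u >= edges$v)) {
      stop("edge with u >= v (self-loop or duplicated undirected edge): ", path)
    }
  }
  morbidity_network(c(iso, edges$u, edges$v), edges, n_pat)
}
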