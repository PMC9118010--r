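#' Cluster-level demographic, visit and cost summaries
#'
#' Attributes every visit-diagnosis row to the cluster containing its
#' diagnosis block and summarizes each cluster. A patient (and a visit) can
#' belong to several clusters; a visit-diagnosis row belongs to exactly
#' one. Reported quantities follow health-register reporting practice:
#' patient counts, visit counts and total costs are annual means (totals
#' divided by `n_years`), while cost per visit is the mean over the whole
#' period. Cost per patient is the annual cost divided by the annual mean
#' number of distinct patients.
#'
#' @param records Filtered visit-diagnosis rows (with `block_id`), as
#'   returned in `filter_visits()$kept`. Must have `patient_id`,
#'   `visit_date`, `age`, `gender`, `cost_eur`, `block_id`.
#' @param assign Named cluster labels covering every `block_id` present.
#' @param n_years Number of years the records span (annual means divide by
#'   this).
#' @param dedup_visits Count visits as distinct `(patient, date, cluster)`
#'   combinations (default), so a visit carrying several diagnoses from the
#'   same cluster is one visit there. Set `FALSE` to count diagnosis rows.
#' @return A `data.frame`, one row per cluster: `cluster`,
#'   `n_patients_annual_mean`, `pct_women`, `median_age`, `pct_age_ge70`,
#'   `n_visits_annual_mean`, `total_cost_annual_mean`, `cost_per_visit`,
#'   `cost_per_patient`. Clusters without records get an all-zero row
#'   (`median_age` `NA`).
#' @export
summarize_clusters <- function(records, assign, n_years,
                               dedup_visits = TRUE) {
  if (n_years <= 0) stop("n_years must be positive")
  need <- c("patient_id", "visit_date", "age", "gender", "cost_eur", "block_id")
  stopifnot(all(need %in% names(records)))
  miss <- setdiff(unique(records$block_id), names(assign))
  if (length(miss)) {
    stop("block(s) without a cluster label: ", paste(miss, collapse = ", "))
  }
  dt <- data.table::as.data.table(records[, need])
  dt[, cluster := as.integer(assign[block_id])]
  k <- max(assign)
  out <- lapply(seq_len(k), function(cl) {
    d <- dt[cluster == cl]
    if (nrow(d) == 0L) {
      return(data.frame(cluster = cl, n_patients_annual_mean = 0,
                        pct_women = 0, median_age = NA_real_,
                        pct_age_ge70 = 0, n_visits_annual_mean = 0,
                        total_cost_annual_mean = 0, cost_per_visit = 0,
                        cost_per_patient = 0))
    }
    # one row per distinct patient, demographics at first in-window record
    pat <- d[order(visit_date), .SD[1L], by = patient_id]
    n_visits <- if (dedup_visits) {
      nrow(unique(d[, .(patient_id, visit_date)]))
    } else {
      nrow(d)
    }
    total_cost <- sum(d$cost_eur)
    n_pat_annual <- data.table::uniqueN(d$patient_id) / n_years
    data.frame(
      cluster = cl,
      n_patients_annual_mean = n_pat_annual,
      pct_women = 100 * mean(pat$gender == "female"),
      median_age = stats::median(as.numeric(pat$age)),
      pct_age_ge70 = 100 * mean(pat$age >= 70),
      n_visits_annual_mean = n_visits / n_years,
      total_cost_annual_mean = total_cost / n_years,
      cost_per_visit = total_cost / n_visits,
      cost_per_patient = total_cost / n_years / n_pat_annual
    )
  })
  do.call(rbind, out)
}

#' Inter-cluster link counts
#'
#' Counts, for every ordered-unordered cluster pair `(a, b)`, the number of
#' network edges with relative risk strictly above `rr_threshold` joining a
#' node labelled `a` to a node labelled `b`. The diagonal holds
#' within-cluster link counts; the matrix is symmetric.
#'
#' @param net A `morbidity_network`.
#' @param assign Named cluster labels covering the network's nodes.
#' @param rr_threshold Strict lower bound on edge rr (default 2.0).
#' @return A `k x k` integer matrix with attribute `"rr_threshold"`.
#' @export
intercluster_links <- function(net, assign, rr_threshold = 2.0) {
  lab <- check_assignment(net, assign)
  k <- max(lab)
  M <- matrix(0L, k, k, dimnames = list(seq_len(k), seq_len(k)))
  e <- net$edges[net$edges$rr > rr_threshold, , drop = FALSE]
  if (nrow(e)) {
    a <- lab[e$u]
    b <- lab[e$v]
    for (i in seq_along(a)) {
      M[a[i], b[i]] <- M[a[i], b[i]] + 1L
      if (a[i] != b[i]) M[b[i], a[i]] <- M[b[i], a[i]] + 1L
    }
  }
  attr(M, "rr_threshold") <- rr_threshold
  M
}

#' Annual cost shares per cluster
#'
#' For each year, the share of that year's total cost attributable to each
#' cluster, in percent (columns sum to 100), alongside the absolute annual
#' costs.
#'
#' @param records Filtered visit-diagnosis rows with `block_id`,
#'   `visit_date` and `cost_eur`.
#' @param assign Named cluster labels covering every `block_id` present.
#' @param years Integer vector of calendar years to report.
#' @return A list with `share` (cluster x year matrix, percent) and
#'   `cost` (cluster x year matrix, absolute).
#' @export
cost_trends <- function(records, assign, years) {
  stopifnot(all(c("visit_date", "cost_eur", "block_id") %in% names(records)))
  miss <- setdiff(unique(records$block_id), names(assign))
  if (length(miss)) {
    stop("block(s) without a cluster label: ", paste(miss, collapse = ", "))
  }
  k <- max(assign)
  cl <- as.integer(assign[records$block_id])
  yr <- as.integer(format(as.Date(records$visit_date), "%Y"))
  keep <- yr %in% years
  cost <- matrix(0, k, length(years),
                 dimnames = list(seq_len(k), years))
  if (any(keep)) {
    agg <- rowsum(records$cost_eur[keep],
                  group = paste(cl[keep], yr[keep], sep = ":"))
    ij <- do.call(rbind, strsplit(rownames(agg), ":", fixed = TRUE))
    cost[cbind(ij[, 1], ij[, 2])] <- agg[, 1]
  }
  totals <- colSums(cost)
  share <- sweep(cost, 2, ifelse(totals > 0, totals, NA_real_), "/") * 100
  list(share = share, cost = cost)
}
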