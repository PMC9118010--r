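#' Run the full multimorbidity analysis pipeline
#'
#' Orchestrates generate/load -> filter -> network -> cluster -> summarize
#' as one reproducible run, writing each stage's artifact and a manifest to
#' `out_dir`. Rerunning with the same configuration reproduces the
#' artifacts byte for byte.
#'
#' The configuration is a list (or YAML file read with
#' [read_run_config()]) with components:
#' \describe{
#'   \item{input}{Either `list(csv = <path>)` for a visit-record CSV, or
#'     `list(synthetic = <cohort_config arguments>)`; exactly one.}
#'   \item{network}{`min_rr`, `min_pxy`, `half_point`, `steepness`
#'     (defaults 1.0, 10, 5, 2).}
#'   \item{cluster}{`k` (default 15), `repeats` (default 20000), `seed`,
#'     and optionally `k_sweep = c(k_min, k_max)` (default off; the
#'     conventional sweep is 5 to 25) to pick `k` by silhouette instead.}
#'   \item{summary}{`rr_threshold` for the inter-cluster link matrix
#'     (default 2.0) and `n_years` (default: number of distinct visit
#'     years).}
#' }
#'
#' @param config Configuration list as above.
#' @param out_dir Output directory, created if needed.
#' @return The manifest (also written as `manifest.json`): per-stage record
#'   and edge counts, configuration echo, seed, and artifact file names.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- normalize_run_config(config)
  stages <- list()

  # stage 1: input
  if (!is.null(cfg$input$synthetic)) {
    coh <- do.call(cohort_config, cfg$input$synthetic)
    gen <- generate_cohort(coh)
    records <- gen$records
    utils::write.csv(records, file.path(out_dir, "records.csv"),
                     row.names = FALSE, quote = FALSE)
    truth_df <- data.frame(block_id = names(gen$true_partition),
                           group = as.integer(gen$true_partition))
    utils::write.csv(truth_df, file.path(out_dir, "true_partition.csv"),
                     row.names = FALSE, quote = FALSE)
  } else {
    records <- utils::read.csv(cfg$input$csv, stringsAsFactors = FALSE)
  }
  stages$input <- list(n_records = nrow(records))

  # stage 2: filter
  table <- load_block_table()
  flt <- filter_visits(records, table)
  stages$filter <- list(n_kept = nrow(flt$kept),
                        dropped = as.list(flt$dropped_counts))
  message(sprintf("filter: kept %d of %d visit-diagnosis rows",
                  nrow(flt$kept), nrow(records)))

  # stage 3: network
  idx <- build_patient_index(flt$kept)
  st <- pair_counts(idx)
  net <- build_network(st,
                       min_rr = cfg$network$min_rr,
                       min_pxy = cfg$network$min_pxy,
                       half_point = cfg$network$half_point,
                       steepness = cfg$network$steepness)
  write_edge_list(net, file.path(out_dir, "network.tsv"))
  stages$network <- list(n_nodes = length(net$nodes),
                         n_edges = nrow(net$edges),
                         n_patients = net$n_patients)
  message(sprintf("network: %d nodes, %d edges from %d patients",
                  length(net$nodes), nrow(net$edges), net$n_patients))

  # stage 4: cluster
  k <- cfg$cluster$k
  sweep_scores <- NULL
  if (!is.null(cfg$cluster$k_sweep)) {
    sel <- select_k_silhouette(net,
                               k_min = cfg$cluster$k_sweep[1],
                               k_max = cfg$cluster$k_sweep[2],
                               repeats = cfg$cluster$repeats,
                               seed = cfg$cluster$seed)
    k <- sel$k_best
    sweep_scores <- sel$scores
    utils::write.csv(sweep_scores, file.path(out_dir, "silhouette_sweep.csv"),
                     row.names = FALSE)
  }
  part <- m_algorithm(net, k, repeats = cfg$cluster$repeats,
                      seed = cfg$cluster$seed)
  write_partition(part, file.path(out_dir, "partition.tsv"))
  stages$cluster <- list(k = part$k, cost = part$cost,
                         n_accepted = length(part$accepted_costs))
  message(sprintf("cluster: k = %d, IIW cost = %.6g", part$k, part$cost))

  # stage 5: summarize
  years <- sort(unique(as.integer(format(as.Date(flt$kept$visit_date), "%Y"))))
  n_years <- if (is.null(cfg$summary$n_years)) length(years) else
    cfg$summary$n_years
  summ <- summarize_clusters(flt$kept, part$assign, n_years = n_years)
  utils::write.csv(summ, file.path(out_dir, "cluster_summary.csv"),
                   row.names = FALSE)
  links <- intercluster_links(net, part$assign,
                              rr_threshold = cfg$summary$rr_threshold)
  utils::write.csv(as.data.frame(links),
                   file.path(out_dir, "intercluster_links.csv"))
  trends <- cost_trends(flt$kept, part$assign, years)
  utils::write.csv(as.data.frame(trends$share),
                   file.path(out_dir, "cost_shares.csv"))
  stages$summarize <- list(n_clusters = nrow(summ), n_years = n_years)

  manifest <- list(config = cfg,
                   config_hash = config_hash(cfg),
                   seed = cfg$cluster$seed,
                   r_version = as.character(getRversion()),
                   stages = stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

normalize_run_config <- function(config) {
  cfg <- config
  if (is.null(cfg$input) ||
      (is.null(cfg$input$csv) == is.null(cfg$input$synthetic))) {
    stop("config$input must set exactly one of 'csv' or 'synthetic'")
  }
  defaults <- list(
    network = list(min_rr = 1.0, min_pxy = 10L, half_point = 5, steepness = 2),
    cluster = list(k = 15L, repeats = 20000L, seed = 1L, k_sweep = NULL),
    summary = list(rr_threshold = 2.0, n_years = NULL)
  )
  for (sec in names(defaults)) {
    cfg[[sec]] <- utils::modifyList(defaults[[sec]],
                                    if (is.null(cfg[[sec]])) list() else cfg[[sec]])
  }
  if (cfg$network$min_rr < 0 || cfg$network$min_pxy < 0) {
    stop("network thresholds must be non-negative")
  }
  cfg
}

config_hash <- function(cfg) {
  # md5 of the canonical JSON form of the configuration
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the structure described in [run_pipeline()].
#' @return A configuration list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
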