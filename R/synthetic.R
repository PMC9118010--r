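#' Configuration for a synthetic visit-record cohort
#'
#' Defines a cohort with planted disease groups. Each patient draws a latent
#' group; their diagnoses come from a mixture that places `boost` times more
#' mass on the blocks of their own group than on the others, which induces
#' elevated within-group relative risk with one interpretable knob. The
#' demographic and utilization defaults emulate a nationwide adult
#' health-register population: 54% women; women carry on average 6.6
#' distinct diagnoses and men 5.4; 1.6 diagnoses are recorded per visit;
#' median age 54 with roughly a quarter of patients over 70; per-diagnosis
#' costs are lognormal to mimic the heavy right tail of health-care costs.
#'
#' @param n_patients Number of patients (default 5000).
#' @param n_blocks Number of diagnosis blocks in play (default 40; drawn
#'   from the shipped ICD-10 block table).
#' @param n_groups Number of planted groups the blocks are divided into
#'   (default 4, equal sizes).
#' @param group_prob Probability simplex over groups for the patient draw
#'   (default uniform).
#' @param boost Multiplier (>= 1) on the sampling mass of the patient's own
#'   group's blocks; 1 means no planted structure (default 20).
#' @param mean_diagnoses_women,mean_diagnoses_men Mean number of distinct
#'   diagnosis blocks per patient (defaults 6.6 and 5.4).
#' @param prop_women Proportion of women (default 0.54).
#' @param mean_diag_per_visit Mean diagnoses recorded per visit
#'   (default 1.6).
#' @param age_median,age_spread Median and standard deviation of the age
#'   distribution (normal truncated to 18..100; defaults 54 and 20).
#' @param cost_meanlog,cost_sdlog Lognormal parameters of the per-diagnosis
#'   cost in euro (defaults 5.5 and 1.0, i.e. a median of about 245 EUR per
#'   visit-diagnosis with a heavy tail).
#' @param years Calendar years the visits span (default 2015:2018).
#' @param seed Integer seed making the cohort reproducible.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 5000L, n_blocks = 40L, n_groups = 4L,
                          group_prob = rep(1 / n_groups, n_groups),
                          boost = 20,
                          mean_diagnoses_women = 6.6,
                          mean_diagnoses_men = 5.4,
                          prop_women = 0.54,
                          mean_diag_per_visit = 1.6,
                          age_median = 54, age_spread = 20,
                          cost_meanlog = 5.5, cost_sdlog = 1.0,
                          years = 2015:2018, seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_blocks = as.integer(n_blocks),
              n_groups = as.integer(n_groups),
              group_prob = group_prob, boost = boost,
              mean_diagnoses_women = mean_diagnoses_women,
              mean_diagnoses_men = mean_diagnoses_men,
              prop_women = prop_women,
              mean_diag_per_visit = mean_diag_per_visit,
              age_median = age_median, age_spread = age_spread,
              cost_meanlog = cost_meanlog, cost_sdlog = cost_sdlog,
              years = as.integer(years), seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (abs(sum(cfg$group_prob) - 1) > 1e-9) stop("group_prob must sum to 1")
  if (length(cfg$group_prob) != cfg$n_groups) {
    stop("group_prob length must equal n_groups")
  }
  if (cfg$boost < 1) stop("boost must be >= 1")
  if (cfg$n_groups > cfg$n_blocks) stop("more groups than blocks")
  if (max(cfg$mean_diagnoses_women, cfg$mean_diagnoses_men) > cfg$n_blocks) {
    stop("expected diagnoses per patient exceeds the number of blocks")
  }
  if (cfg$prop_women < 0 || cfg$prop_women > 1) stop("prop_women not in [0,1]")
  if (cfg$mean_diag_per_visit < 1) stop("mean_diag_per_visit must be >= 1")
  invisible(cfg)
}

#' Generate a synthetic visit-record cohort with planted disease groups
#'
#' Emits one row per visit-diagnosis, in the same schema consumed by
#' [filter_visits()] (`patient_id`, `visit_date`, `age`, `gender`, `icd10`,
#' `cost_eur`), plus the ground-truth block grouping.
#'
#' Per patient: gender and age are drawn once; a latent group `g` comes
#' from `group_prob`; the number of distinct diagnosis blocks is Poisson
#' with the gender-specific mean (at least 1); the blocks themselves are
#' sampled without replacement with probability proportional to `boost` for
#' blocks in `g` and 1 elsewhere. Diagnoses are then dealt into visits
#' whose sizes are `1 + Poisson(mean_diag_per_visit - 1)`, each visit gets
#' a date uniform over `years`, and every diagnosis row gets an
#' independent lognormal cost. Diagnoses are emitted as the first 3-char
#' code of their block (e.g. block `I20-I25` as `I20`) so the block-mapping
#' stage is exercised.
#'
#' @param cfg A [cohort_config()].
#' @return A list with `records` (data.frame of visit-diagnosis rows) and
#'   `true_partition` (named integer vector: block id -> planted group).
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  validate_cohort_config(cfg)
  set.seed(cfg$seed)
  tab <- load_block_table()
  blocks <- tab$block_id[tab$included][seq_len(cfg$n_blocks)]
  # equal-size contiguous planted groups over the chosen blocks
  group_of <- rep(seq_len(cfg$n_groups), length.out = cfg$n_blocks)
  group_of <- sort(group_of)
  names(group_of) <- blocks
  base_code <- substr(blocks, 1, 3)

  n <- cfg$n_patients
  gender <- ifelse(stats::runif(n) < cfg$prop_women, "female", "male")
  age <- round(stats::qnorm(stats::runif(
    n,
    stats::pnorm(18, cfg$age_median, cfg$age_spread),
    stats::pnorm(100, cfg$age_median, cfg$age_spread)
  ), cfg$age_median, cfg$age_spread))
  grp <- sample.int(cfg$n_groups, n, replace = TRUE, prob = cfg$group_prob)
  mu <- ifelse(gender == "female",
               cfg$mean_diagnoses_women, cfg$mean_diagnoses_men)
  n_diag <- pmin(pmax(stats::rpois(n, mu), 1L), cfg$n_blocks)

  date_lo <- as.Date(sprintf("%d-01-01", min(cfg$years)))
  date_hi <- as.Date(sprintf("%d-12-31", max(cfg$years)))
  span <- as.integer(date_hi - date_lo)
  diag_idx <- vector("list", n)
  date_chr <- vector("list", n)
  boost_p <- matrix(1, cfg$n_groups, cfg$n_blocks)
  for (gidx in seq_len(cfg$n_groups)) {
    boost_p[gidx, group_of == gidx] <- cfg$boost
  }
  for (i in seq_len(n)) {
    d <- sample.int(cfg$n_blocks, n_diag[i], prob = boost_p[grp[i], ])
    # deal the diagnoses into visits: sizes 1 + Poisson(mean - 1)
    m <- length(d)
    sizes <- 1L + stats::rpois(m, cfg$mean_diag_per_visit - 1)
    n_visits <- which(cumsum(sizes) >= m)[1L]
    visit_id <- rep(seq_len(n_visits), times = sizes[seq_len(n_visits)])[seq_len(m)]
    vdates <- date_lo + sample.int(span + 1L, n_visits, replace = TRUE) - 1L
    diag_idx[[i]] <- d
    date_chr[[i]] <- as.character(vdates[visit_id])
  }
  per_pat <- lengths(diag_idx)
  all_d <- unlist(diag_idx)
  records <- data.frame(
    patient_id = rep(sprintf("P%06d", seq_len(n)), times = per_pat),
    visit_date = unlist(date_chr),
    age = rep(age, times = per_pat),
    gender = rep(gender, times = per_pat),
    icd10 = base_code[all_d],
    cost_eur = round(stats::rlnorm(length(all_d),
                                   cfg$cost_meanlog, cfg$cost_sdlog), 2),
    stringsAsFactors = FALSE
  )
  list(records = records, true_partition = group_of)
}

#' Empirical within- versus between-group relative risk
#'
#' Runs the pair-statistics stack on a generated cohort and averages the
#' relative risk separately over block pairs inside the same planted group
#' and pairs straddling groups. Used to check that the generator's `boost`
#' knob actually separates the planted structure.
#'
#' @param records Visit records from [generate_cohort()].
#' @param true_partition Named block -> group vector from the same call.
#' @param table Block table for filtering.
#' @return A list with `mean_within_rr`, `mean_between_rr` and the pair
#'   statistics (`stats`, with an extra logical column `within`).
#' @export
empirical_rr_profile <- function(records, true_partition,
                                 table = load_block_table()) {
  if (is.null(records) || nrow(records) == 0L) stop("empty cohort")
  kept <- filter_visits(records, table)$kept
  idx <- build_patient_index(kept)
  st <- pair_counts(idx)
  st$rr <- compute_rr(st$P_x, st$P_y, st$P_xy, st$N)
  st$within <- true_partition[st$x] == true_partition[st$y]
  list(mean_within_rr = mean(st$rr[st$within]),
       mean_between_rr = mean(st$rr[!st$within]),
       stats = st)
}
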