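#' ICD-10 block table
#'
#' Reads a table of ICD-10 blocks (contiguous ranges of 3-character codes,
#' e.g. `"I20-I25"`) together with an inclusion flag. Excluded ranges mark
#' code regions that are filtered from the analysis because they do not
#' represent diseases: symptom codes (R chapter), external causes (V-Y),
#' contacts with health services (Z) and special-purpose codes (U).
#'
#' The range endpoints are parsed from `block_id` itself. Endpoints may have
#' different chapter letters (e.g. `"V01-Y98"`); codes are ordered first by
#' letter, then by their two-digit number.
#'
#' @param path Path to a CSV file with columns `block_id,included`. Defaults
#'   to the block table shipped with the package, which covers the standard
#'   ICD-10 blocks of chapters A-T (205 included blocks) plus the excluded
#'   ranges above. The shipped list is an approximation of any
#'   register-specific grouping: replace it via this argument if your
#'   register aggregates blocks differently.
#' @return A `data.frame` with columns `block_id` (character), `included`
#'   (logical), `lo` and `hi` (integer rank of the range endpoints).
#' @export
#' @examples
#' tab <- load_block_table()
#' sum(tab$included)
load_block_table <- function(path = system.file("extdata", "icd10_blocks.csv",
                                                package = "morbclust")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("block_id", "included") %in% names(tab))) {
    stop("block table must have columns 'block_id' and 'included'")
  }
  m <- regmatches(tab$block_id,
                  regexec("^([A-Z])([0-9]{2})-([A-Z])([0-9]{2})[A-Z]?$", tab$block_id))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("malformed block_id: ", paste(tab$block_id[bad], collapse = ", "))
  }
  parts <- do.call(rbind, m)
  tab$included <- as.logical(tab$included)
  tab$lo <- code_rank(parts[, 2], as.integer(parts[, 3]))
  tab$hi <- code_rank(parts[, 4], as.integer(parts[, 5]))
  if (any(tab$lo > tab$hi)) stop("block range with lo > hi")
  tab <- tab[order(tab$lo), , drop = FALSE]
  if (nrow(tab) > 1 && any(tab$lo[-1] <= tab$hi[-nrow(tab)])) {
    stop("overlapping block ranges")
  }
  rownames(tab) <- NULL
  tab
}

# total order on 3-character code prefixes: letter major, 2-digit number minor
code_rank <- function(letter, num) {
  (match(letter, LETTERS) - 1L) * 100L + num
}

#' Map ICD-10 codes to diagnosis blocks
#'
#' Maps each code (3 or 4 characters, e.g. `"I21"` or `"E118"`) to the block
#' whose range contains its first three characters. Codes falling into an
#' excluded range or outside every block map to `NA`.
#'
#' @param code Character vector of ICD-10 codes.
#' @param table Block table from [load_block_table()].
#' @return Character vector of block ids, `NA` where the code is excluded or
#'   unmappable. The attribute `"reason"` holds, for every element, one of
#'   `"mapped"`, `"excluded"` or `"unmappable"`.
#' @export
#' @examples
#' map_code_to_block(c("I21", "R52", "Z00"))
map_code_to_block <- function(code, table = load_block_table()) {
  code <- toupper(trimws(as.character(code)))
  m <- regexec("^([A-Z])([0-9]{2})", code)
  hit <- regmatches(code, m)
  bad <- vapply(hit, length, 1L) == 0L
  if (any(bad)) {
    stop("malformed ICD-10 code(s): ",
         paste(unique(code[bad]), collapse = ", "))
  }
  parts <- do.call(rbind, hit)
  r <- code_rank(parts[, 2], as.integer(parts[, 3]))
  # interval lookup against the lo-sorted table
  idx <- findInterval(r, table$lo)
  in_range <- idx >= 1L & r <= table$hi[pmax(idx, 1L)]
  block <- ifelse(in_range & table$included[pmax(idx, 1L)],
                  table$block_id[pmax(idx, 1L)], NA_character_)
  reason <- rep("unmappable", length(code))
  reason[in_range & !table$included[pmax(idx, 1L)]] <- "excluded"
  reason[!is.na(block)] <- "mapped"
  structure(block, reason = reason)
}

#' Filter visit records for network construction
#'
#' Applies the record inclusion rules: adults only (age >= 18 years) and
#' diagnoses mappable to an included ICD-10 block. Symptom codes (R00-R99),
#' external causes (V01-Y98), service contacts (Z chapter) and special codes
#' (U00-U99) are dropped as excluded ranges. Each kept record gains a
#' `block_id` column.
#'
#' A record failing several rules is counted once; underage takes precedence
#' over code-based reasons, and excluded-range over unmappable.
#'
#' @param records A `data.frame` of visit-diagnosis rows with columns
#'   `patient_id`, `visit_date`, `age`, `gender`, `icd10`, `cost_eur`.
#' @param table Block table from [load_block_table()].
#' @return A list with `kept` (the surviving rows plus `block_id`) and
#'   `dropped_counts`, a named integer vector with entries `underage`,
#'   `excluded` and `unmappable` such that
#'   `nrow(kept) + sum(dropped_counts) == nrow(records)`.
#' @export
filter_visits <- function(records, table = load_block_table()) {
  required <- c("patient_id", "age", "icd10")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("records is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  empty_counts <- c(underage = 0L, excluded = 0L, unmappable = 0L)
  if (nrow(records) == 0L) {
    kept <- records
    kept$block_id <- character(0)
    return(list(kept = kept, dropped_counts = empty_counts))
  }
  block <- map_code_to_block(records$icd10, table)
  reason <- attr(block, "reason")
  underage <- records$age < 18
  drop_reason <- rep(NA_character_, nrow(records))
  drop_reason[reason == "unmappable"] <- "unmappable"
  drop_reason[reason == "excluded"] <- "excluded"
  drop_reason[underage] <- "underage"
  keep <- is.na(drop_reason)
  kept <- records[keep, , drop = FALSE]
  kept$block_id <- as.character(block[keep])
  rownames(kept) <- NULL
  counts <- table(factor(drop_reason, levels = names(empty_counts)))
  dropped <- stats::setNames(as.integer(counts), names(empty_counts))
  list(kept = kept, dropped_counts = dropped)
}
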