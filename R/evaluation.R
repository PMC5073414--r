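# Linked-versus-unlinked evaluation: linkage rates, method mix,
# standardized differences across strata (Cohen's 0.2 / 0.5 / 0.8 read as
# small / moderate / large), era series, and — when ground truth exists —
# precision and recall. With registry-scale samples, p-values are useless
# for judging bias; standardized differences are the scale-free contrast.

.linked_statuses <- c("linked_deterministic", "linked_probabilistic",
                      "linked_review")

#' Linkage rate in percent
#'
#' `100 * n_linked / (n_linked + n_unlinked)`, reported to one decimal
#' (half-up). A zero denominator yields `NA`.
#'
#' @param n_linked,n_unlinked record counts.
#' @return percentage to 1 decimal.
#' @examples
#' linkage_rate(2692178, 425156)  # 86.4
#' @export
linkage_rate <- function(n_linked, n_unlinked) {
  denom <- n_linked + n_unlinked
  ifelse(denom > 0, round_half_up(100 * n_linked / denom, 1), NA_real_)
}

#' Standardized difference between two proportions
#'
#' `|p1 - p2| / sqrt((p1(1-p1) + p2(1-p2)) / 2)`, reported to two decimals
#' (half-up). Symmetric in its arguments and zero iff the proportions are
#' equal; defined as 0 when both proportions are 0 or both are 1 (the
#' pooled variance vanishes but the groups are identical).
#'
#' @param p_linked,p_unlinked proportions in `[0, 1]`.
#' @return dimensionless standardized difference to 2 decimals.
#' @examples
#' standardized_difference(279144 / 2692178, 89577 / 425156)  # 0.30
#' @export
standardized_difference <- function(p_linked, p_unlinked) {
  stopifnot(all(p_linked >= 0 & p_linked <= 1, na.rm = TRUE),
            all(p_unlinked >= 0 & p_unlinked <= 1, na.rm = TRUE))
  v <- (p_linked * (1 - p_linked) + p_unlinked * (1 - p_unlinked)) / 2
  d <- ifelse(v > 0, abs(p_linked - p_unlinked) / sqrt(v),
              ifelse(p_linked == p_unlinked, 0, NA_real_))
  round_half_up(d, 2)
}

#' Standardized difference between two means (continuous overload)
#'
#' `|mean1 - mean2| / sqrt((sd1^2 + sd2^2) / 2)` with the unpooled
#' two-group variance average.
#'
#' @param mean1,sd1,mean2,sd2 group means and standard deviations.
#' @return standardized difference to 2 decimals.
#' @export
standardized_difference_cont <- function(mean1, sd1, mean2, sd2) {
  v <- (sd1^2 + sd2^2) / 2
  d <- ifelse(v > 0, abs(mean1 - mean2) / sqrt(v),
              ifelse(mean1 == mean2, 0, NA_real_))
  round_half_up(d, 2)
}

#' Method mix of a decision table
#'
#' Percentages of all source records linked deterministically, linked
#' probabilistically (including review-accepted), and unlinked; the three
#' sum to 100 up to rounding.
#'
#' @param decisions decision table with a `status` column.
#' @param digits rounding digits (default 1).
#' @return named list `pct_deterministic`, `pct_probabilistic`,
#'   `pct_unlinked`.
#' @export
method_mix <- function(decisions, digits = 1) {
  n <- nrow(decisions)
  stopifnot(n > 0)
  st <- decisions$status
  list(
    pct_deterministic = round_half_up(100 * sum(st == "linked_deterministic") / n, digits),
    pct_probabilistic = round_half_up(100 * sum(st %in% c("linked_probabilistic", "linked_review")) / n, digits),
    pct_unlinked = round_half_up(100 * sum(st == "unlinked") / n, digits)
  )
}

#' Stratified linked-versus-unlinked table from counts
#'
#' Builds the standard reporting table — one row per stratum with linked and
#' unlinked counts, within-file percentages, the standardized difference of
#' the stratum indicator between the linked and unlinked files, and the
#' stratum linkage rate — from already-aggregated counts. Percentages use
#' the full file as base (missing is a stratum like any other). An
#' `Overall` row is prepended.
#'
#' @param counts data.frame with columns `stratum`, `n_linked`,
#'   `n_unlinked`.
#' @return data.frame with columns `stratum`, `n_linked`, `pct_linked`,
#'   `n_unlinked`, `pct_unlinked`, `std_diff`, `linkage_rate`.
#' @export
stratum_table_from_counts <- function(counts) {
  stopifnot(all(c("stratum", "n_linked", "n_unlinked") %in% names(counts)))
  tot_l <- sum(counts$n_linked)
  tot_u <- sum(counts$n_unlinked)
  p1 <- counts$n_linked / tot_l
  p2 <- counts$n_unlinked / tot_u
  rows <- data.frame(
    stratum = counts$stratum,
    n_linked = counts$n_linked,
    pct_linked = round_half_up(100 * p1, 1),
    n_unlinked = counts$n_unlinked,
    pct_unlinked = round_half_up(100 * p2, 1),
    std_diff = standardized_difference(p1, p2),
    linkage_rate = linkage_rate(counts$n_linked, counts$n_unlinked),
    stringsAsFactors = FALSE)
  overall <- data.frame(
    stratum = "Overall", n_linked = tot_l, pct_linked = 100,
    n_unlinked = tot_u, pct_unlinked = 100, std_diff = NA_real_,
    linkage_rate = linkage_rate(tot_l, tot_u), stringsAsFactors = FALSE)
  rbind(overall, rows)
}

#' Stratified linked-versus-unlinked table from record-level decisions
#'
#' @param decisions decision table joined to record attributes: needs a
#'   `status` column and the stratification variable. Missing attribute
#'   values form their own `"Missing"` stratum.
#' @param variable name of the stratification column.
#' @return as [stratum_table_from_counts()].
#' @export
build_stratum_table <- function(decisions, variable) {
  if (!variable %in% names(decisions)) {
    stop_config("build_stratum_table: unknown variable '%s'", variable)
  }
  d <- data.table::as.data.table(decisions)
  v <- as.character(d[[variable]])
  v[is_missing_chr(v)] <- "Missing"
  linked <- d$status %in% .linked_statuses
  counts <- data.table::data.table(stratum = v, linked = linked)[
    , .(n_linked = sum(linked), n_unlinked = sum(!linked)), by = stratum]
  data.table::setorder(counts, stratum)
  stratum_table_from_counts(as.data.frame(counts))
}

#' Linkage rate and method mix over period bands
#'
#' One point per band of the period variable (e.g. landing year, fiscal
#' year of death): the linkage rate and the deterministic / probabilistic /
#' unlinked percentages, which sum to 100 per band. Empty bands are
#' omitted.
#'
#' @param decisions decision table with `status` and a year column.
#' @param period_field name of the numeric year column.
#' @param band_width band width in years (default 5).
#' @return data.frame `band`, `band_start`, `n`, `linkage_rate`,
#'   `pct_deterministic`, `pct_probabilistic`, `pct_unlinked`.
#' @export
rates_by_period <- function(decisions, period_field = "event_year",
                            band_width = 5L) {
  if (!period_field %in% names(decisions)) {
    stop_config("rates_by_period: unknown period field '%s'", period_field)
  }
  d <- data.table::as.data.table(decisions)
  yr <- suppressWarnings(as.integer(d[[period_field]]))
  keep <- !is.na(yr)
  d <- d[keep]; yr <- yr[keep]
  if (!nrow(d)) {
    return(data.frame(band = character(), band_start = integer(),
                      n = integer(), linkage_rate = numeric(),
                      pct_deterministic = numeric(),
                      pct_probabilistic = numeric(),
                      pct_unlinked = numeric()))
  }
  start <- (yr %/% band_width) * band_width
  d[, .band_start := start]
  out <- d[, {
    mm <- method_mix(.SD, digits = 1)
    nl <- sum(status %in% .linked_statuses)
    .(n = .N, linkage_rate = linkage_rate(nl, .N - nl),
      pct_deterministic = mm$pct_deterministic,
      pct_probabilistic = mm$pct_probabilistic,
      pct_unlinked = mm$pct_unlinked)
  }, by = .band_start]
  data.table::setorder(out, .band_start)
  data.frame(band = sprintf("%d-%d", out$.band_start,
                            out$.band_start + band_width - 1L),
             band_start = out$.band_start, n = out$n,
             linkage_rate = out$linkage_rate,
             pct_deterministic = out$pct_deterministic,
             pct_probabilistic = out$pct_probabilistic,
             pct_unlinked = out$pct_unlinked, stringsAsFactors = FALSE)
}

#' Precision and recall against synthetic ground truth
#'
#' Precision: correct links over all links made. Recall: correct links over
#' truly linkable records (truth key nonempty). A link to the wrong
#' registry person counts against both. When no links were made, precision
#' is undefined and rendered as 1 with a warning.
#'
#' @param decisions decision table.
#' @param truth data.frame `source_id`, `registry_key` (`""` = no
#'   counterpart); must cover every decision.
#' @return list `precision`, `recall`, `f1`, `n_links`, `n_correct`,
#'   `false_links`, `missed_links`.
#' @export
truth_metrics <- function(decisions, truth) {
  d <- data.table::as.data.table(decisions)
  t <- data.table::as.data.table(truth)
  idx <- match(d$source_id, t$source_id)
  if (anyNA(idx)) {
    stop_config("truth_metrics: truth map missing %d source ids",
                sum(is.na(idx)))
  }
  true_key <- t$registry_key[idx]
  linked <- d$status %in% .linked_statuses
  correct <- linked & d$registry_key == true_key & true_key != ""
  n_links <- sum(linked)
  n_correct <- sum(correct)
  linkable <- sum(true_key != "")
  if (n_links == 0L) {
    warning("truth_metrics: no links made; precision undefined, rendered as 1")
    precision <- 1
  } else {
    precision <- n_correct / n_links
  }
  recall <- if (linkable > 0) n_correct / linkable else NA_real_
  f1 <- if (!is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  list(precision = precision, recall = recall, f1 = f1,
       n_links = n_links, n_correct = n_correct,
       false_links = n_links - n_correct,
       missed_links = linkable - n_correct)
}

#' Published stratified linked/unlinked counts shipped with the package
#'
#' Returns the stratified linked and unlinked record counts published for
#' two large Ontario registry linkages — an immigration landing file
#' (1985-2012) and a vital-statistics death file (1990-2013) linked to the
#' provincial insured-persons registry — together with the percentages,
#' standardized differences and linkage rates printed alongside them. The
#' printed derived columns are retained so the evaluation module can be
#' checked against them; recomputing them from the counts reproduces every
#' printed value to printed precision.
#'
#' @param which `"immigration"` or `"death"`.
#' @return data.frame with columns `variable`, `stratum`, `n_linked`,
#'   `printed_pct_linked`, `n_unlinked`, `printed_pct_unlinked`,
#'   `printed_std_diff`, `printed_linkage_rate`.
#' @export
published_count_table <- function(which = c("immigration", "death")) {
  which <- match.arg(which)
  f <- if (which == "immigration") "immigration_strata_counts.csv"
       else "death_strata_counts.csv"
  path <- system.file("extdata", f, package = "reglink")
  if (path == "") path <- file.path("inst", "extdata", f)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
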