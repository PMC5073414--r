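# End-to-end orchestration: configuration, validation, the full
# standardize -> deterministic cascade -> probabilistic passes -> review ->
# one-to-one -> dedup -> key assignment -> evaluation run, and artifact
# output. Identical configuration and seed give byte-identical outputs.

#' Build a linkage run configuration
#'
#' @param registry registry data.frame (or path to its CSV).
#' @param source source data.frame (or path to its CSV).
#' @param source_kind `"immigration"` or `"death"`; controls the dedup
#'   policy (earliest landing date vs closest death date) and whether the
#'   death-date window field joins pass 1.
#' @param passes list of [pass_spec()]s; default: the three-pass
#'   deterministic cascade followed by two probabilistic passes.
#' @param field_models named list of [field_model()]s.
#' @param t_lower,t_upper probabilistic thresholds in bits.
#' @param delta probabilistic runner-up margin in bits.
#' @param review a [review_rule()].
#' @param postal_table a [postal_city_table()] (or path to its CSV);
#'   `NULL` disables geographic evidence.
#' @param unique_per_person if `TRUE`, revert all but the strongest claimant
#'   of a registry person to unlinked before dedup. Default `FALSE`: genuine
#'   within-source duplicates (duplicate death registrations, repeat
#'   landings) stay linked and are resolved by the dedup rules instead.
#' @param stratify_by character vector of attribute columns to tabulate.
#' @param band_width era band width in years for the period series.
#' @param salt optional salt for cross-run-stable link keys.
#' @param seed integer seed (standardization and linkage are deterministic;
#'   the seed feeds key assignment and is recorded in the run log).
#' @param out_dir optional directory; when set, [run_pipeline()] writes the
#'   link table, review audit, dedup audit, stratified reports, era series
#'   and run log there as UTF-8 CSV/TSV.
#' @return a `run_config` object.
#' @export
run_config <- function(registry, source,
                       source_kind = c("immigration", "death"),
                       passes = NULL, field_models = NULL,
                       t_lower = 4, t_upper = 8, delta = 1,
                       review = review_rule(min_weight = t_lower),
                       postal_table = NULL,
                       unique_per_person = FALSE,
                       stratify_by = NULL,
                       band_width = 5L,
                       salt = NULL, seed = 1L, out_dir = NULL) {
  source_kind <- match.arg(source_kind)
  if (is.character(registry)) registry <- utils::read.csv(registry, colClasses = "character")
  if (is.character(source)) source <- utils::read.csv(source, colClasses = "character")
  if (is.character(postal_table)) postal_table <- read_postal_city_table(postal_table)
  if (is.null(passes)) {
    det <- default_deterministic_passes(
      death_event_window = if (source_kind == "death") 30L else NULL)
    passes <- c(det, default_probabilistic_passes(t_lower, t_upper))
  }
  if (is.null(field_models)) field_models <- default_field_models()
  if (source_kind == "death") {
    have <- vapply(field_models, function(m) m$field, character(1))
    if (!"event_date" %in% have) {
      field_models <- c(field_models, list(
        field_model("event_date", m = 0.9, u = 0.01, comparator = "date_within",
                    registry_field = "last_contact", window = 30L)))
    }
  }
  cfg <- structure(list(registry = registry, source = source,
                        source_kind = source_kind, passes = passes,
                        field_models = field_models,
                        t_lower = t_lower, t_upper = t_upper, delta = delta,
                        review = review, postal_table = postal_table,
                        unique_per_person = isTRUE(unique_per_person),
                        stratify_by = stratify_by,
                        band_width = as.integer(band_width),
                        salt = salt, seed = as.integer(seed),
                        out_dir = out_dir),
                   class = "run_config")
  viol <- validate_config(cfg)
  if (length(viol)) {
    stop_config("invalid run_config:\n  %s", paste(viol, collapse = "\n  "))
  }
  cfg
}

#' Validate a run configuration
#'
#' Always returns (never throws); an empty result means the configuration
#' is runnable. Messages name the offending key.
#'
#' @param config a `run_config` (or plain list with the same fields).
#' @return character vector of violations (empty if valid).
#' @export
validate_config <- function(config) {
  v <- character()
  chk <- function(cond, msg) if (isTRUE(cond)) v <<- c(v, msg)
  chk(is.null(config$registry) || !is.data.frame(config$registry) ||
        nrow(config$registry) == 0, "registry: missing or empty")
  chk(is.null(config$source) || !is.data.frame(config$source) ||
        nrow(config$source) == 0, "source: missing or empty")
  chk(!is.null(config$t_lower) && !is.null(config$t_upper) &&
        config$t_lower > config$t_upper,
      sprintf("thresholds: t_lower (%s) > t_upper (%s)",
              config$t_lower, config$t_upper))
  if (length(config$passes)) {
    ids <- vapply(config$passes, function(p) p$pass_id, integer(1))
    chk(any(diff(ids) <= 0), "passes: pass_ids not strictly increasing")
    known <- c("exact", "nysiis_exact", "year_exact", "date_exact",
               "date_transpose_tolerant", "date_within")
    for (p in config$passes) {
      for (mf in p$match_fields) {
        chk(!mf$comparator %in% known,
            sprintf("passes: unknown comparator '%s' (pass %d)",
                    mf$comparator, p$pass_id))
      }
      if (p$mode == "probabilistic") {
        mfields <- vapply(config$field_models, function(m) m$field, character(1))
        need <- vapply(p$match_fields, function(mf) mf$field, character(1))
        miss <- setdiff(need, mfields)
        chk(length(miss) > 0,
            sprintf("field_models: no model for %s (pass %d)",
                    paste(miss, collapse = ", "), p$pass_id))
      }
    }
  } else {
    v <- c(v, "passes: empty pass list")
  }
  if (inherits(config$review, "review_rule") && !is.null(config$t_lower)) {
    chk(config$review$min_weight < config$t_lower,
        sprintf("review: min_weight (%s) below t_lower (%s)",
                config$review$min_weight, config$t_lower))
  }
  v
}

#' Read a run configuration from a YAML file
#'
#' Supports the scalar keys of [run_config()] (`registry`, `source` and
#' `postal_table` as file paths, `source_kind`, thresholds, `delta`,
#' `seed`, `salt`, `band_width`, `stratify_by`, `out_dir`, review rule
#' fields under `review:`); passes and field models beyond the defaults are
#' declared in R.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  rev <- if (!is.null(y$review)) {
    review_rule(
      require_city_agreement = y$review$require_city_agreement %||% TRUE,
      min_weight = y$review$min_weight %||% (y$t_lower %||% 4),
      max_competitor_gap = y$review$max_competitor_gap %||% 0)
  } else {
    review_rule(min_weight = y$t_lower %||% 4)
  }
  run_config(registry = y$registry, source = y$source,
             source_kind = y$source_kind %||% "immigration",
             t_lower = y$t_lower %||% 4, t_upper = y$t_upper %||% 8,
             delta = y$delta %||% 1, review = rev,
             postal_table = y$postal_table,
             unique_per_person = y$unique_per_person %||% FALSE,
             stratify_by = unlist(y$stratify_by),
             band_width = y$band_width %||% 5L,
             salt = y$salt, seed = y$seed %||% 1L, out_dir = y$out_dir)
}

#' Execute a full linkage run
#'
#' Standardizes both files, runs the pass cascade, adjudicates the review
#' queue, enforces one-to-one linkage, deduplicates per source kind,
#' assigns opaque link keys, and evaluates. Identical config and seed give
#' identical outputs; when `out_dir` is set all artifacts are also written
#' as UTF-8 delimited files.
#'
#' @param config a [run_config()].
#' @return list with `decisions` (one final row per source record:
#'   `source_id`, `registry_key`, `status`, `pass_id`, `weight`,
#'   `link_key`), `key_map`, `review_audit`, `dedup_audit`, `pass_log`,
#'   `method_mix`, `stratum_tables`, `era_series`, `run_log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  viol <- validate_config(config)
  if (length(viol)) {
    stop_config("run_pipeline: invalid config:\n  %s",
                paste(viol, collapse = "\n  "))
  }
  reg_std <- standardize_records(config$registry, id_col = "key",
                                 postal_table = config$postal_table)
  src_std <- standardize_records(config$source, id_col = "source_id",
                                 postal_table = config$postal_table)

  seq_res <- run_pass_sequence(src_std, reg_std, config$passes,
                               models = config$field_models,
                               delta = config$delta)
  rev_res <- auto_review(seq_res$review_queue, config$review,
                         t_lower = config$t_lower)

  unlinked_ids <- c(seq_res$residual$source_id,
                    if (!is.null(rev_res$rejected))
                      rev_res$rejected[accepted == FALSE]$source_id)
  unlinked <- data.table::data.table(
    source_id = unlinked_ids, registry_key = "",
    status = rep("unlinked", length(unlinked_ids)),
    pass_id = NA_integer_, weight = NA_real_)
  decisions <- data.table::rbindlist(list(seq_res$decisions,
                                          rev_res$decisions, unlinked))
  # restore source order so runs are byte-identical regardless of pass
  # internals
  decisions <- decisions[match(src_std$source_id, source_id)]

  if (config$unique_per_person) decisions <- enforce_one_to_one(decisions)

  dd <- if (config$source_kind == "death") {
    dedup_death(decisions, config$source, config$registry)
  } else {
    dedup_immigration(decisions, config$source)
  }
  dedup_audit <- dd$discarded
  keep <- !decisions$source_id %in% dedup_audit$source_id
  kept_decisions <- decisions[keep]

  keyed <- assign_link_keys(decisions, salt = config$salt)
  decisions <- keyed$decisions
  decisions[, kept_after_dedup := keep]

  attrs <- data.table::as.data.table(config$source)
  eval_dt <- merge(decisions, attrs, by = "source_id", sort = FALSE)
  if ("event_date" %in% names(eval_dt)) {
    eval_dt[, event_year := suppressWarnings(as.integer(substr(event_date, 1, 4)))]
  }
  stratum_tables <- list()
  for (vvar in config$stratify_by %||% character()) {
    stratum_tables[[vvar]] <- build_stratum_table(eval_dt, vvar)
  }
  era <- if ("event_year" %in% names(eval_dt)) {
    rates_by_period(eval_dt, "event_year", config$band_width)
  } else {
    NULL
  }
  mm <- method_mix(decisions)
  nl <- sum(decisions$status %in% .linked_statuses)
  run_log <- list(
    seed = config$seed,
    n_registry = nrow(config$registry),
    n_source = nrow(config$source),
    pass_log = seq_res$pass_log,
    review_queue_size = if (is.null(seq_res$review_queue)) 0L
                        else nrow(seq_res$review_queue),
    review_accepted = nrow(rev_res$decisions),
    dedup_discards = if (is.null(dedup_audit)) 0L else nrow(dedup_audit),
    overall_linkage_rate = linkage_rate(nl, nrow(decisions) - nl),
    method_mix = mm)

  out <- list(decisions = decisions, key_map = keyed$key_map,
              review_audit = rev_res$rejected, dedup_audit = dedup_audit,
              kept_decisions = kept_decisions,
              pass_log = seq_res$pass_log, method_mix = mm,
              stratum_tables = stratum_tables, era_series = era,
              run_log = run_log)
  if (!is.null(config$out_dir)) .write_run_artifacts(out, config)
  out
}

.write_run_artifacts <- function(out, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) {
    if (!is.null(x) && nrow(x)) {
      utils::write.csv(x, file.path(config$out_dir, f), row.names = FALSE,
                       na = "")
    }
  }
  wr(out$decisions, "link_table.csv")
  wr(out$review_audit, "review_audit.csv")
  wr(out$dedup_audit, "dedup_audit.csv")
  wr(out$pass_log, "pass_log.csv")
  wr(out$era_series, "era_series.csv")
  for (vvar in names(out$stratum_tables)) {
    tab <- out$stratum_tables[[vvar]]
    f <- file.path(config$out_dir,
                   paste0("strata_", gsub("[^A-Za-z0-9]+", "_", vvar), ".tsv"))
    utils::write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  summ <- list(overall_linkage_rate = out$run_log$overall_linkage_rate,
               method_mix = out$run_log$method_mix,
               review_queue_size = out$run_log$review_queue_size,
               dedup_discards = out$run_log$dedup_discards,
               seed = out$run_log$seed)
  jsonlite::write_json(summ, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
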