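# Ordered exact-match passes. Records linked in a pass leave the pipeline;
# the remainder flow to the next pass, progressing from strict identifier
# agreement to more lenient variants (phonetic surname, sex-free) so records
# with misspelled names or miscoded fields still get a chance.

#' Declare one compared field of a pass
#'
#' @param field standardized source-side column name.
#' @param comparator one of `"exact"`, `"nysiis_exact"`, `"year_exact"`,
#'   `"date_exact"`, `"date_transpose_tolerant"`, `"date_within"`.
#' @param registry_field registry-side column (defaults to `field`; e.g.
#'   a death date compared against the registry `last_contact`).
#' @param window day window for `"date_within"` (default 30).
#' @return a `match_field` list.
#' @export
match_field <- function(field,
                        comparator = c("exact", "nysiis_exact", "year_exact",
                                       "date_exact", "date_transpose_tolerant",
                                       "date_within"),
                        registry_field = field, window = 30L) {
  comparator <- match.arg(comparator)
  structure(list(field = field, comparator = comparator,
                 registry_field = registry_field, window = as.integer(window)),
            class = "match_field")
}

#' Declare one linkage pass
#'
#' @param pass_id ordinal of the pass (strictly increasing across a
#'   sequence).
#' @param mode `"deterministic"` (link on unique full agreement) or
#'   `"probabilistic"` (Fellegi-Sunter scored).
#' @param block_scheme a [block_scheme()].
#' @param match_fields list of [match_field()]s compared inside blocks.
#' @param t_lower,t_upper weight thresholds in bits (probabilistic passes
#'   only; `t_lower <= t_upper`).
#' @return a `pass_spec` object.
#' @export
pass_spec <- function(pass_id, mode = c("deterministic", "probabilistic"),
                      block_scheme, match_fields,
                      t_lower = NULL, t_upper = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(block_scheme, "block_scheme"))
  if (!length(match_fields)) stop_config("pass_spec: match_fields is empty")
  match_fields <- lapply(match_fields, function(mf) {
    if (inherits(mf, "match_field")) mf
    else do.call(match_field, as.list(mf))
  })
  if (mode == "deterministic") {
    if (!is.null(t_lower) || !is.null(t_upper)) {
      stop_config("pass_spec %s: deterministic passes take no thresholds",
                  pass_id)
    }
  } else {
    if (is.null(t_lower) || is.null(t_upper)) {
      stop_config("pass_spec %s: probabilistic passes need t_lower and t_upper",
                  pass_id)
    }
    if (t_lower > t_upper) {
      stop_config("pass_spec %s: t_lower (%s) > t_upper (%s)",
                  pass_id, t_lower, t_upper)
    }
  }
  structure(list(pass_id = as.integer(pass_id), mode = mode,
                 block_scheme = block_scheme, match_fields = match_fields,
                 t_lower = t_lower, t_upper = t_upper),
            class = "pass_spec")
}

.date_parts <- function(x) {
  list(y = substr(x, 1, 4), m = substr(x, 6, 7), d = substr(x, 9, 10))
}

#' Compare aligned field values under a comparator
#'
#' Vectorized three-way comparison: a missing value on either side gives
#' `"missing"`; otherwise the comparator decides `"agree"` or
#' `"disagree"`. `date_transpose_tolerant` also accepts dates equal after
#' swapping day and month; `date_within` accepts dates at most `window`
#' days apart.
#'
#' @param src_vals,reg_vals character vectors of equal length.
#' @param comparator see [match_field()].
#' @param window day window for `date_within`.
#' @return character vector in `{"agree", "disagree", "missing"}`.
#' @export
compare_field <- function(src_vals, reg_vals, comparator, window = 30L) {
  s <- as.character(src_vals)
  r <- as.character(reg_vals)
  miss <- is_missing_chr(s) | is_missing_chr(r)
  agree <- switch(comparator,
    exact = s == r,
    nysiis_exact = {
      code <- function(v, vals) {
        # values may already be NYSIIS codes; otherwise code them here
        out <- rep("", length(vals))
        ok <- !is_missing_chr(vals)
        out[ok] <- nysiis(gsub("[^A-Z]", "", toupper(vals[ok])))
        out
      }
      code(NULL, s) == code(NULL, r)
    },
    year_exact = substr(s, 1, 4) == substr(r, 1, 4),
    date_exact = s == r,
    date_transpose_tolerant = {
      sp <- .date_parts(s); rp <- .date_parts(r)
      (s == r) | (sp$y == rp$y & sp$m == rp$d & sp$d == rp$m)
    },
    date_within = {
      ds <- suppressWarnings(as.Date(s))
      dr <- suppressWarnings(as.Date(r))
      ok <- !is.na(ds) & !is.na(dr)
      res <- rep(FALSE, length(s))
      res[ok] <- abs(as.numeric(ds[ok] - dr[ok])) <= window
      res
    },
    stop_config("unknown comparator '%s'", comparator)
  )
  out <- ifelse(miss, "missing", ifelse(agree, "agree", "disagree"))
  out
}

# Outcomes for every match_field of a spec over a candidate-pair table.
.pair_outcomes <- function(pairs, source, registry, match_fields) {
  out <- data.table::data.table(.n = seq_len(nrow(pairs)))
  for (mf in match_fields) {
    if (!mf$field %in% names(source)) {
      stop_config("unknown match field '%s' in source file", mf$field)
    }
    if (!mf$registry_field %in% names(registry)) {
      stop_config("unknown match field '%s' in registry file", mf$registry_field)
    }
    out[, (mf$field) := compare_field(source[[mf$field]][pairs$src_row],
                                      registry[[mf$registry_field]][pairs$reg_row],
                                      mf$comparator, mf$window)]
  }
  out[, .n := NULL]
  out
}

#' Run one deterministic pass
#'
#' A source record links iff exactly one registry record in its block agrees
#' on every compared field under its comparator; a missing value on either
#' side counts as disagreement. Records with two or more fully agreeing
#' candidates are ambiguous and deliberately flow onward unlinked rather than
#' being tie-broken — the conservative choice for very common surnames.
#'
#' @param source standardized, still-unlinked source records.
#' @param registry standardized registry.
#' @param spec a deterministic [pass_spec()].
#' @return list with `decisions` (source_id, registry_key, status, pass_id,
#'   weight), `residual` (unlinked source rows), `n_candidates`.
#' @export
run_deterministic_pass <- function(source, registry, spec) {
  stopifnot(inherits(spec, "pass_spec"), spec$mode == "deterministic")
  source <- data.table::as.data.table(source)
  registry <- data.table::as.data.table(registry)
  idx <- build_blocks(source, registry, spec$block_scheme)
  assert_partition(idx)
  pairs <- candidate_pairs(idx)
  n_cand <- nrow(pairs)
  if (n_cand) {
    oc <- .pair_outcomes(pairs, source, registry, spec$match_fields)
    all_agree <- Reduce(`&`, lapply(oc, function(col) col == "agree"))
    pairs <- pairs[all_agree]
  }
  if (nrow(pairs)) {
    counts <- pairs[, .N, by = src_row]
    unique_rows <- counts[N == 1L, src_row]
    linked <- pairs[src_row %in% unique_rows]
  } else {
    linked <- pairs
  }
  decisions <- data.table::data.table(
    source_id = source$source_id[linked$src_row],
    registry_key = registry$key[linked$reg_row],
    status = rep("linked_deterministic", nrow(linked)),
    pass_id = rep(spec$pass_id, nrow(linked)),
    weight = rep(NA_real_, nrow(linked))
  )
  residual <- source[!seq_len(nrow(source)) %in% linked$src_row]
  list(decisions = decisions, residual = residual, n_candidates = n_cand)
}

#' Run an ordered sequence of linkage passes
#'
#' Deterministic passes link on unique full agreement; probabilistic passes
#' score surviving candidates with log-odds weights, link definite matches
#' and queue grey-zone pairs for review. Records linked (or queued) in a
#' pass leave the cascade; records surviving every pass remain unlinked.
#'
#' @param source standardized source records.
#' @param registry standardized registry.
#' @param specs nonempty list of [pass_spec()]s, pass_ids increasing.
#' @param models named list of [field_model()]s (required if any pass is
#'   probabilistic).
#' @param delta margin in bits by which a definite best candidate must beat
#'   the runner-up to link without review (default 1).
#' @return list with `decisions` (linked records), `review_queue`,
#'   `residual` (never-linked source rows) and `pass_log` (per-pass
#'   candidate and link counts).
#' @export
run_pass_sequence <- function(source, registry, specs, models = NULL,
                              delta = 1) {
  if (!length(specs)) stop_config("run_pass_sequence: empty pass list")
  ids <- vapply(specs, function(s) s$pass_id, integer(1))
  if (any(diff(ids) <= 0)) {
    stop_config("run_pass_sequence: pass_ids must be strictly increasing")
  }
  residual <- data.table::as.data.table(source)
  decisions <- list()
  queue <- list()
  log <- list()
  for (spec in specs) {
    if (nrow(residual) == 0L) break
    if (spec$mode == "deterministic") {
      res <- run_deterministic_pass(residual, registry, spec)
      decisions[[length(decisions) + 1L]] <- res$decisions
      log[[length(log) + 1L]] <- data.table::data.table(
        pass_id = spec$pass_id, mode = spec$mode,
        n_in = nrow(residual), n_candidates = res$n_candidates,
        n_linked = nrow(res$decisions), n_review = 0L)
      residual <- res$residual
    } else {
      res <- run_probabilistic_pass(residual, registry, spec, models,
                                    delta = delta)
      decisions[[length(decisions) + 1L]] <- res$decisions
      queue[[length(queue) + 1L]] <- res$review_queue
      log[[length(log) + 1L]] <- data.table::data.table(
        pass_id = spec$pass_id, mode = spec$mode,
        n_in = nrow(residual), n_candidates = res$n_candidates,
        n_linked = nrow(res$decisions), n_review = nrow(res$review_queue))
      residual <- res$residual
    }
  }
  empty_dec <- data.table::data.table(source_id = character(),
                                      registry_key = character(),
                                      status = character(),
                                      pass_id = integer(), weight = numeric())
  list(decisions = if (length(decisions)) data.table::rbindlist(decisions) else empty_dec,
       review_queue = if (length(queue)) data.table::rbindlist(queue) else NULL,
       residual = residual,
       pass_log = if (length(log)) data.table::rbindlist(log) else NULL)
}

#' Default deterministic cascade
#'
#' Pass 1: exact cleaned surname + first given name + full birth date + sex,
#' blocked on sex and NYSIIS surname. Pass 2: NYSIIS surname + given initial
#' + full birth date + sex (catches misspellings that survive phonetic
#' coding). Pass 3: exact surname + full birth date without sex (catches
#' miscoded sex), blocked on NYSIIS surname and birth year. For death files,
#' an optional death-date-versus-last-contact window field is added to pass 1
#' via `death_event_window`.
#'
#' @param death_event_window if non-`NULL` and the source is a death file,
#'   compare `event_date` to registry `last_contact` within this many days
#'   in pass 1.
#' @return list of three deterministic [pass_spec()]s.
#' @export
default_deterministic_passes <- function(death_event_window = NULL) {
  f1 <- list(match_field("surname_clean"), match_field("given_first"),
             match_field("birth_date", "date_exact"), match_field("sex"))
  if (!is.null(death_event_window)) {
    f1 <- c(f1, list(match_field("event_date", "date_within",
                                 registry_field = "last_contact",
                                 window = death_event_window)))
  }
  list(
    pass_spec(1L, "deterministic",
              block_scheme(c("sex", "surname_nysiis")), f1),
    pass_spec(2L, "deterministic",
              block_scheme(c("sex", "surname_nysiis")),
              list(match_field("surname_nysiis"), match_field("given_initial"),
                   match_field("birth_date", "date_exact"),
                   match_field("sex"))),
    pass_spec(3L, "deterministic",
              block_scheme(c("surname_nysiis", "birth_year")),
              list(match_field("surname_clean"),
                   match_field("birth_date", "date_exact")))
  )
}
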