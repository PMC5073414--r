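# Fellegi-Sunter probabilistic scoring. Each compared field carries an
# m-probability (chance of agreement given a true match) and a
# u-probability (chance of agreement given a non-match); a candidate pair's
# weight is the sum of per-field log2 odds, i.e. the overall log-odds in
# favour of a true match under conditional independence (Bayes theorem).
# Weights are in bits; the base only rescales thresholds.

#' Declare the agreement model of one field
#'
#' @param field standardized source-side column name.
#' @param m probability the field agrees given a true match, in (0,1).
#' @param u probability the field agrees given a non-match, in (0,1).
#' @param comparator comparator used to decide agreement (see
#'   [match_field()]).
#' @param registry_field registry-side column (defaults to `field`).
#' @param window day window for the `"date_within"` comparator.
#' @return a `field_model` object. Models with `m <= u` are accepted but
#'   flagged non-informative with a warning.
#' @export
field_model <- function(field, m, u, comparator = "exact",
                        registry_field = field, window = 30L) {
  if (!is.numeric(m) || m <= 0 || m >= 1 || !is.numeric(u) || u <= 0 || u >= 1) {
    stop_config("field_model '%s': m and u must lie strictly in (0,1)", field)
  }
  if (m <= u) {
    warning("field_model '", field, "': m <= u; field is non-informative")
  }
  structure(list(field = field, m = m, u = u, comparator = comparator,
                 registry_field = registry_field, window = as.integer(window)),
            class = "field_model")
}

#' Log-odds weight contribution of one field outcome
#'
#' Agreement contributes `log2(m/u)`, disagreement `log2((1-m)/(1-u))`, and
#' a missing value contributes 0 — no evidence either way. (Death
#' registrations legally require only sex and dates; penalizing missing
#' identifiers would re-create the very bias the evaluation measures.)
#'
#' @param model a [field_model()].
#' @param outcome character vector in `{"agree", "disagree", "missing"}`.
#' @return numeric weight(s) in bits.
#' @export
field_weight <- function(model, outcome) {
  stopifnot(inherits(model, "field_model"))
  w_agree <- log2(model$m / model$u)
  w_disagree <- log2((1 - model$m) / (1 - model$u))
  ifelse(outcome == "agree", w_agree,
         ifelse(outcome == "disagree", w_disagree, 0))
}

#' Score one candidate pair
#'
#' Computes the per-field comparison vector with each model's comparator and
#' the total weight as the sum of per-field weights. Field order does not
#' affect the total.
#'
#' @param src_rec,reg_rec single standardized rows (lists or one-row data
#'   frames).
#' @param models named list of [field_model()]s covering all compared fields.
#' @return list with `vector` (named outcomes) and `weight` (bits).
#' @export
score_pair <- function(src_rec, reg_rec, models) {
  out <- character(length(models))
  names(out) <- vapply(models, function(m) m$field, character(1))
  w <- 0
  for (mo in models) {
    if (!inherits(mo, "field_model")) {
      stop_config("score_pair: models must be field_model objects")
    }
    oc <- compare_field(src_rec[[mo$field]], reg_rec[[mo$registry_field]],
                        mo$comparator, mo$window)
    out[mo$field] <- oc
    w <- w + field_weight(mo, oc)
  }
  list(vector = out, weight = unname(w))
}

# Vectorized scoring of a candidate-pair table; returns pairs with one
# outcome column per field and a total weight column.
score_pairs <- function(pairs, source, registry, models) {
  scored <- data.table::copy(pairs)
  weight <- rep(0, nrow(pairs))
  for (mo in models) {
    if (!mo$field %in% names(source)) {
      stop_config("score_pairs: no source column '%s'", mo$field)
    }
    oc <- compare_field(source[[mo$field]][pairs$src_row],
                        registry[[mo$registry_field]][pairs$reg_row],
                        mo$comparator, mo$window)
    scored[, (paste0("oc_", mo$field)) := oc]
    weight <- weight + field_weight(mo, oc)
  }
  scored[, weight := weight]
  scored
}

#' Classify a scored pair against the decision thresholds
#'
#' `weight >= t_upper` is a definite match; `t_lower <= weight < t_upper`
#' falls in the grey zone of possible matches subject to review; anything
#' below `t_lower` is a non-match.
#'
#' @param weight numeric weight(s) in bits.
#' @param t_lower,t_upper thresholds in bits, `t_lower <= t_upper`.
#' @return character vector in `{"definite", "possible", "nonmatch"}`.
#' @export
classify_weight <- function(weight, t_lower, t_upper) {
  if (t_lower > t_upper) stop_config("classify_weight: t_lower > t_upper")
  ifelse(weight >= t_upper, "definite",
         ifelse(weight >= t_lower, "possible", "nonmatch"))
}

#' Assign matches from scored candidate pairs
#'
#' For each source record the highest-weight candidate is taken. A definite
#' best candidate that beats the runner-up by at least `delta` bits links
#' immediately; a possible best candidate — or a definite one within `delta`
#' of its runner-up — goes to the review queue; anything else is left for
#' later passes.
#'
#' @param scored output of the internal scorer: a pair table with `src_row`,
#'   `reg_row`, `weight`.
#' @param t_lower,t_upper thresholds in bits.
#' @param delta runner-up margin in bits (default 1).
#' @return list of data.tables `linked` and `review` (columns `src_row`,
#'   `reg_row`, `weight`, `gap`).
#' @export
assign_matches <- function(scored, t_lower, t_upper, delta = 1) {
  empty <- data.table::data.table(src_row = integer(), reg_row = integer(),
                                  weight = numeric(), gap = numeric())
  if (nrow(scored) == 0L) return(list(linked = empty, review = empty))
  scored <- data.table::copy(data.table::as.data.table(scored))
  data.table::setorder(scored, src_row, -weight, reg_row)
  best <- scored[, {
    gap <- if (.N > 1L) weight[1] - weight[2] else Inf
    .(reg_row = reg_row[1], weight = weight[1], gap = gap)
  }, by = src_row]
  cls <- classify_weight(best$weight, t_lower, t_upper)
  linked <- best[cls == "definite" & best$gap >= delta]
  review <- best[(cls == "possible") | (cls == "definite" & best$gap < delta)]
  list(linked = linked[, .(src_row, reg_row, weight, gap)],
       review = review[, .(src_row, reg_row, weight, gap)])
}

#' Run one probabilistic pass
#'
#' Blocks the surviving records with the pass's scheme, scores within-block
#' candidate pairs under the field models named by the pass's match fields,
#' and links or queues records per [assign_matches()].
#'
#' @param source standardized, still-unlinked source records.
#' @param registry standardized registry.
#' @param spec a probabilistic [pass_spec()].
#' @param models named list of [field_model()]s; every match field of the
#'   pass must have a model.
#' @param delta runner-up margin in bits.
#' @return list with `decisions`, `review_queue`, `residual`,
#'   `n_candidates`.
#' @export
run_probabilistic_pass <- function(source, registry, spec, models, delta = 1) {
  stopifnot(inherits(spec, "pass_spec"), spec$mode == "probabilistic")
  source <- data.table::as.data.table(source)
  registry <- data.table::as.data.table(registry)
  fields <- vapply(spec$match_fields, function(mf) mf$field, character(1))
  model_fields <- vapply(models, function(m) m$field, character(1))
  missing_models <- setdiff(fields, model_fields)
  if (length(missing_models)) {
    stop_config("run_probabilistic_pass %d: no field_model for: %s",
                spec$pass_id, paste(missing_models, collapse = ", "))
  }
  use <- models[match(fields, model_fields)]
  idx <- build_blocks(source, registry, spec$block_scheme)
  pairs <- candidate_pairs(idx)
  scored <- score_pairs(pairs, source, registry, use)
  res <- assign_matches(scored, spec$t_lower, spec$t_upper, delta = delta)

  decisions <- data.table::data.table(
    source_id = source$source_id[res$linked$src_row],
    registry_key = registry$key[res$linked$reg_row],
    status = rep("linked_probabilistic", nrow(res$linked)),
    pass_id = rep(spec$pass_id, nrow(res$linked)),
    weight = res$linked$weight)
  review_queue <- data.table::data.table(
    source_id = source$source_id[res$review$src_row],
    registry_key = registry$key[res$review$reg_row],
    pass_id = rep(spec$pass_id, nrow(res$review)),
    weight = res$review$weight,
    gap = res$review$gap,
    city_source = if ("city_code" %in% names(source))
      source$city_code[res$review$src_row] else "UNKNOWN",
    city_registry = if ("city_code" %in% names(registry))
      registry$city_code[res$review$reg_row] else "UNKNOWN")
  gone <- c(res$linked$src_row, res$review$src_row)
  residual <- source[!seq_len(nrow(source)) %in% gone]
  list(decisions = decisions, review_queue = review_queue,
       residual = residual, n_candidates = nrow(pairs))
}

#' Default probabilistic passes and field models
#'
#' Two passes with different blocking (NYSIIS surname within sex, then birth
#' year within sex) so records failing one scheme get a second chance, with
#' explicit default thresholds `t_lower = 4`, `t_upper = 8` bits. The m/u
#' defaults are deliberately round, user-overridable starting values — not
#' estimates of any particular database; fit them with [em_estimate()] when
#' training pairs are available.
#'
#' @param t_lower,t_upper thresholds in bits.
#' @name default_probabilistic
#' @export
default_probabilistic_passes <- function(t_lower = 4, t_upper = 8) {
  list(
    pass_spec(4L, "probabilistic",
              block_scheme(c("sex", "surname_nysiis"),
                           missing_policy = "broadcast"),
              list(match_field("surname_clean"), match_field("given_first"),
                   match_field("birth_date", "date_transpose_tolerant"),
                   match_field("sex")),
              t_lower = t_lower, t_upper = t_upper),
    pass_spec(5L, "probabilistic",
              block_scheme(c("sex", "birth_year"),
                           missing_policy = "broadcast"),
              list(match_field("surname_nysiis"), match_field("given_first"),
                   match_field("birth_date", "date_transpose_tolerant"),
                   match_field("sex")),
              t_lower = t_lower, t_upper = t_upper)
  )
}

#' @rdname default_probabilistic
#' @export
default_field_models <- function() {
  list(
    field_model("surname_clean", m = 0.95, u = 0.02),
    field_model("surname_nysiis", m = 0.97, u = 0.05),
    field_model("given_first", m = 0.93, u = 0.05),
    field_model("birth_date", m = 0.97, u = 0.001,
                comparator = "date_transpose_tolerant"),
    field_model("sex", m = 0.99, u = 0.5)
  )
}

#' Estimate m- and u-probabilities by EM
#'
#' Classical two-class latent mixture under conditional independence:
#' comparison vectors are generated either by true matches (per-field
#' agreement probability `m[j]`) or non-matches (probability `u[j]`), with
#' unknown match proportion. Missing outcomes contribute no information.
#' The fit is deterministic given the initial values; if the classes
#' converge label-swapped (fitted m below u), they are relabelled so that
#' the match class is the high-agreement one.
#'
#' @param vectors matrix or data.frame of per-field outcomes: 1/`"agree"`,
#'   0/`"disagree"`, `NA`/`"missing"`; one row per candidate pair, at least
#'   two columns (identifiability).
#' @param m_init,u_init numeric vectors of initial probabilities (recycled).
#' @param p_init initial match proportion.
#' @param tol convergence tolerance on the largest parameter change.
#' @param max_iter iteration cap.
#' @return list with `m`, `u` (named per field), `p` (match proportion),
#'   `iterations`, `converged`, and `models` (ready-to-use
#'   [field_model()]s).
#' @export
em_estimate <- function(vectors, m_init = 0.9, u_init = 0.1, p_init = 0.1,
                        tol = 1e-6, max_iter = 1000L) {
  x <- as.matrix(vectors)
  if (is.character(x)) {
    x2 <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(x))
    x2[x == "agree"] <- 1
    x2[x == "disagree"] <- 0
    x <- x2
  }
  storage.mode(x) <- "double"
  if (ncol(x) < 2L) {
    stop_config("em_estimate: need >= 2 fields for identifiability")
  }
  if (nrow(x) < 2L || nrow(unique(x)) == 1L) {
    stop_config(paste0("em_estimate: degenerate data (all %d comparison",
                       " vectors identical); cannot separate classes"),
                nrow(x))
  }
  k <- ncol(x)
  m <- rep_len(m_init, k)
  u <- rep_len(u_init, k)
  p <- p_init
  eps <- 1e-12
  clamp <- function(v) pmin(pmax(v, eps), 1 - eps)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    # E-step: log-likelihood of each vector under each class; missing cells
    # contribute a factor of 1
    lm_ <- lu_ <- rep(0, nrow(x))
    for (j in seq_len(k)) {
      obs <- !is.na(x[, j])
      xi <- x[obs, j]
      lm_[obs] <- lm_[obs] + xi * log(m[j]) + (1 - xi) * log(1 - m[j])
      lu_[obs] <- lu_[obs] + xi * log(u[j]) + (1 - xi) * log(1 - u[j])
    }
    a <- log(p) + lm_
    b <- log(1 - p) + lu_
    mx <- pmax(a, b)
    g <- exp(a - mx) / (exp(a - mx) + exp(b - mx))
    # M-step
    m_new <- u_new <- numeric(k)
    for (j in seq_len(k)) {
      obs <- !is.na(x[, j])
      m_new[j] <- clamp(sum(g[obs] * x[obs, j]) / sum(g[obs]))
      u_new[j] <- clamp(sum((1 - g[obs]) * x[obs, j]) / sum(1 - g[obs]))
    }
    p_new <- clamp(mean(g))
    delta <- max(abs(c(m_new - m, u_new - u, p_new - p)))
    m <- m_new; u <- u_new; p <- p_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (mean(m) < mean(u)) {  # label switching: match class must agree more
    tmp <- m; m <- u; u <- tmp
    p <- 1 - p
  }
  fields <- colnames(x) %||% paste0("field", seq_len(k))
  names(m) <- names(u) <- fields
  models <- Map(function(f, mm, uu) field_model(f, mm, uu), fields, m, u)
  list(m = m, u = u, p = p, iterations = it, converged = converged,
       models = unname(models))
}

#' Simulate comparison vectors from known field models
#'
#' Testing aid: draws match/non-match pairs at proportion `p` and per-field
#' agreement indicators from `m` and `u`, with optional missingness.
#'
#' @param n number of vectors.
#' @param m,u per-field agreement probabilities.
#' @param p match proportion.
#' @param missing_rate probability a cell is missing.
#' @return matrix of 1/0/NA with `n` rows.
#' @export
simulate_comparison_vectors <- function(n, m, u, p = 0.1, missing_rate = 0) {
  k <- length(m)
  stopifnot(length(u) == k)
  is_match <- runif(n) < p
  x <- matrix(NA_real_, n, k,
              dimnames = list(NULL, paste0("field", seq_len(k))))
  for (j in seq_len(k)) {
    pr <- ifelse(is_match, m[j], u[j])
    x[, j] <- as.numeric(runif(n) < pr)
    if (missing_rate > 0) x[runif(n) < missing_rate, j] <- NA_real_
  }
  x
}
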