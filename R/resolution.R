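# Adjudication of the grey zone and post-linkage housekeeping: a rule-based
# reviewer standing in for manual clerical review (using postal-derived
# geography as the extra evidence), one-to-one enforcement, within-source
# deduplication, and assignment of opaque link keys.

#' Declare the automatic review rule
#'
#' @param require_city_agreement if `TRUE`, a queued pair is accepted only
#'   when the city codes of both records agree; an `UNKNOWN` city never
#'   counts as agreement (absence of geographic evidence is not evidence).
#' @param min_weight minimum weight in bits (must be at least the
#'   configured `t_lower` of the run).
#' @param max_competitor_gap minimum margin in bits by which the best
#'   candidate must beat its runner-up.
#' @return a `review_rule` object.
#' @export
review_rule <- function(require_city_agreement = TRUE, min_weight = 4,
                        max_competitor_gap = 0) {
  structure(list(require_city_agreement = isTRUE(require_city_agreement),
                 min_weight = min_weight,
                 max_competitor_gap = max_competitor_gap),
            class = "review_rule")
}

#' Adjudicate the review queue
#'
#' Accepts a queued pair (status `linked_review`) iff its weight reaches
#' `min_weight`, the city codes agree (or city agreement is not required;
#' `UNKNOWN` never agrees), and the best candidate beats the runner-up by at
#' least `max_competitor_gap` bits. Everything else is rejected.
#'
#' @param queue review queue from [run_pass_sequence()]: columns
#'   `source_id`, `registry_key`, `pass_id`, `weight`, `gap`,
#'   `city_source`, `city_registry`.
#' @param rule a [review_rule()].
#' @param t_lower the run's lower threshold, used to validate `min_weight`.
#' @return list with `decisions` (accepted, status `linked_review`) and
#'   `rejected` (queue rows with an `accepted` flag and reason).
#' @export
auto_review <- function(queue, rule, t_lower = NULL) {
  stopifnot(inherits(rule, "review_rule"))
  if (!is.null(t_lower) && rule$min_weight < t_lower) {
    stop_config("auto_review: min_weight (%s) below t_lower (%s)",
                rule$min_weight, t_lower)
  }
  empty <- data.table::data.table(source_id = character(),
                                  registry_key = character(),
                                  status = character(), pass_id = integer(),
                                  weight = numeric())
  if (is.null(queue) || nrow(queue) == 0L) {
    return(list(decisions = empty, rejected = NULL))
  }
  q <- data.table::as.data.table(queue)
  city_ok <- if (rule$require_city_agreement) {
    q$city_source == q$city_registry & q$city_source != "UNKNOWN" &
      q$city_registry != "UNKNOWN"
  } else {
    rep(TRUE, nrow(q))
  }
  accept <- q$weight >= rule$min_weight & city_ok &
    q$gap >= rule$max_competitor_gap
  decisions <- data.table::data.table(
    source_id = q$source_id[accept],
    registry_key = q$registry_key[accept],
    status = rep("linked_review", sum(accept)),
    pass_id = q$pass_id[accept],
    weight = q$weight[accept])
  rejected <- data.table::copy(q)
  rejected[, accepted := accept]
  rejected[, reason := ifelse(accept, "",
    ifelse(q$weight < rule$min_weight, "weight_below_minimum",
      ifelse(!city_ok & rule$require_city_agreement, "city_disagreement",
             "competitor_too_close")))]
  list(decisions = decisions, rejected = rejected)
}

.status_tier <- c(linked_deterministic = 3L, linked_probabilistic = 2L,
                  linked_review = 1L)

#' Enforce at most one source record per registry person
#'
#' For source files declared unique-per-person, when several source records
#' claim the same registry key only the strongest claimant keeps the link:
#' deterministic outranks probabilistic outranks review, then higher weight,
#' then the earlier pass, then stable record order. Losers revert to
#' unlinked.
#'
#' @param decisions linked decisions table (`source_id`, `registry_key`,
#'   `status`, `pass_id`, `weight`).
#' @return decisions with losers' status set to `"unlinked"` and their
#'   registry key cleared.
#' @export
enforce_one_to_one <- function(decisions) {
  d <- data.table::as.data.table(decisions)
  if (nrow(d) == 0L) return(d)
  d[, .ord := seq_len(.N)]
  d[, .tier := .status_tier[status]]
  d[, .w := data.table::fifelse(is.na(weight), 0, weight)]
  linked <- d[status != "unlinked"]
  data.table::setorder(linked, registry_key, -.tier, -.w, pass_id, .ord)
  losers <- linked[, .(loser = .ord[-1]), by = registry_key]$loser
  if (length(losers)) {
    d[.ord %in% losers, `:=`(status = "unlinked",
                             registry_key = "",
                             pass_id = NA_integer_, weight = NA_real_)]
  }
  d[, c(".ord", ".tier", ".w") := NULL]
  d[]
}

.abs_days <- function(a, b) {
  abs(as.numeric(suppressWarnings(as.Date(a)) - suppressWarnings(as.Date(b))))
}

#' Resolve duplicate death records linked to one registry person
#'
#' Retains, per registry key, the record with the best linkage quality
#' (deterministic, then probabilistic, then review; higher weight within a
#' tier), then the record whose death date lies closest to the registry
#' last-contact date, then the earliest death date, then stable order. A
#' survivor always exists.
#'
#' @param decisions linked decisions carrying `source_id`, `registry_key`,
#'   `status`, `pass_id`, `weight`.
#' @param source source records with `source_id` and `event_date` (death
#'   date).
#' @param registry registry with `key` and `last_contact`.
#' @return list with `kept` (deduplicated decisions) and `discarded`
#'   (audit table with a `reason` column).
#' @export
dedup_death <- function(decisions, source, registry) {
  d <- data.table::as.data.table(decisions)
  linked <- d[status %in% names(.status_tier)]
  if (nrow(linked) == 0L) return(list(kept = d, discarded = linked))
  src <- data.table::as.data.table(source)
  reg <- data.table::as.data.table(registry)
  linked[, .ord := seq_len(.N)]
  linked[, .tier := .status_tier[status]]
  linked[, .w := data.table::fifelse(is.na(weight), 0, weight)]
  linked[, event_date := src$event_date[match(source_id, src$source_id)]]
  linked[, last_contact := reg$last_contact[match(registry_key, reg$key)]]
  linked[, .dist := .abs_days(event_date, last_contact)]
  linked[is.na(.dist), .dist := Inf]
  data.table::setorder(linked, registry_key, -.tier, -.w, .dist, event_date,
                       .ord)
  keep_ids <- linked[, .(source_id = source_id[1]), by = registry_key]$source_id
  discarded <- linked[!source_id %in% keep_ids,
                      .(source_id, registry_key, status, weight,
                        event_date, last_contact,
                        reason = "duplicate_death_record")]
  kept <- d[status == "unlinked" | source_id %in% keep_ids]
  list(kept = kept, discarded = discarded)
}

#' Resolve duplicate immigration records of one person
#'
#' Keeps, per registry key, the record with the earliest landing date; ties
#' broken by stable order.
#'
#' @param decisions linked decisions.
#' @param source source records with `source_id` and `event_date` (landing
#'   date).
#' @return list with `kept` and `discarded` (audit table).
#' @export
dedup_immigration <- function(decisions, source) {
  d <- data.table::as.data.table(decisions)
  linked <- d[status %in% names(.status_tier)]
  if (nrow(linked) == 0L) return(list(kept = d, discarded = linked))
  src <- data.table::as.data.table(source)
  linked[, .ord := seq_len(.N)]
  linked[, event_date := src$event_date[match(source_id, src$source_id)]]
  linked[, .ev := data.table::fifelse(is.na(event_date), "9999-12-31",
                                      event_date)]
  data.table::setorder(linked, registry_key, .ev, .ord)
  keep_ids <- linked[, .(source_id = source_id[1]), by = registry_key]$source_id
  discarded <- linked[!source_id %in% keep_ids,
                      .(source_id, registry_key, status, weight, event_date,
                        reason = "later_landing_date")]
  kept <- d[status == "unlinked" | source_id %in% keep_ids]
  list(kept = kept, discarded = discarded)
}

.hash31 <- function(x, salt) {
  vapply(x, function(s) {
    h <- 7
    for (cc in utf8ToInt(paste0(salt, "|", s))) h <- (h * 131 + cc) %% 2147483647
    sprintf("LK%08X", as.integer(h))
  }, character(1), USE.NAMES = FALSE)
}

#' Assign opaque link keys to linked records
#'
#' Every linked registry person receives one opaque surrogate key — two
#' source records linked to the same person share a key, unlinked records
#' get none. Without a salt, keys are per-run counters; with a
#' user-supplied salt they are stable across runs via a salted hash
#' (regenerated with a fresh salt if a collision occurs, which is logged).
#' Injectivity is asserted on every call.
#'
#' @param decisions decisions table.
#' @param salt optional character salt for cross-run-stable keys.
#' @return list with `decisions` (plus a `link_key` column, `""` when
#'   unlinked) and `key_map` (registry_key to link_key).
#' @export
assign_link_keys <- function(decisions, salt = NULL) {
  d <- data.table::as.data.table(decisions)
  keys <- sort(unique(d$registry_key[d$status %in% names(.status_tier)]))
  if (is.null(salt)) {
    link <- sprintf("LK%07d", seq_along(keys))
  } else {
    link <- .hash31(keys, salt)
    tries <- 0L
    while (anyDuplicated(link) && tries < 32L) {
      tries <- tries + 1L
      salt <- paste0(salt, "#")
      message("assign_link_keys: hash collision; regenerating with new salt")
      link <- .hash31(keys, salt)
    }
  }
  if (anyDuplicated(link)) stop("assign_link_keys: link keys not injective")
  key_map <- data.table::data.table(registry_key = keys, link_key = link)
  d[, link_key := ifelse(status %in% names(.status_tier),
                         key_map$link_key[match(registry_key,
                                                key_map$registry_key)],
                         "")]
  list(decisions = d[], key_map = key_map)
}
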