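# Ground-truthed synthetic registries. The generator emulates the error
# structure a registry linkage has to overcome: skewed surname frequencies
# with a pool of very common short surnames, per-field corruption (typos,
# same-phonetic-code misspellings, day/month transposition, missingness)
# whose rates scale with an era-dependent quality multiplier, a fraction of
# source records with no registry counterpart (e.g. early neonatal deaths
# never issued a registration number), and within-source duplicates.

#' Configuration for the synthetic registry generator
#'
#' All probabilities are per-record (or per-field, for the corruption rates)
#' and must lie in `[0, 1]`. `era_quality` maps event-year bands to a
#' multiplier applied to every corruption rate for records whose event falls
#' in that band; larger multipliers emulate poorer historical data quality.
#'
#' @param n_registry number of registry persons (>= 1).
#' @param n_source number of source records (>= 1).
#' @param unlinkable_frac probability a source record has no registry
#'   counterpart (its identifiers are freshly invented, never copied).
#' @param dup_frac probability a truth person contributes more than one
#'   source record (duplicates differ in event date).
#' @param typo_rate per-field probability of one random character edit.
#' @param phonetic_swap_rate per-field probability of a same-NYSIIS
#'   misspelling (surname only).
#' @param date_transpose_rate probability of swapping day and month of the
#'   birth date (applied only where the swap is well defined).
#' @param missing_rate per-field probability of the value being dropped.
#' @param common_surname_frac fraction of persons drawn from the short
#'   common-surname pool rather than the Zipf-weighted main list.
#' @param common_surname_pool character vector of pool surnames (default: a
#'   shipped pool of 20 surnames of at most 4 letters).
#' @param era_quality data.frame with columns `year_from`, `year_to`,
#'   `multiplier` (multipliers >= 0); bands are looked up by event year.
#' @param source_kind `"immigration"` (event = landing date) or `"death"`
#'   (event = death date, drawn near the person's last registry contact).
#' @param event_years integer range of event years to simulate.
#' @param seed integer RNG seed; all randomness derives from it via named
#'   substreams.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_registry = 1000L,
                             n_source = 500L,
                             unlinkable_frac = 0.05,
                             dup_frac = 0.03,
                             typo_rate = 0.05,
                             phonetic_swap_rate = 0.03,
                             date_transpose_rate = 0.02,
                             missing_rate = 0.03,
                             common_surname_frac = 0.15,
                             common_surname_pool = NULL,
                             era_quality = NULL,
                             source_kind = c("immigration", "death"),
                             event_years = c(1985L, 2012L),
                             seed = 1L) {
  source_kind <- match.arg(source_kind)
  if (is.null(common_surname_pool)) common_surname_pool <- .pool_surnames_common
  if (is.null(era_quality)) {
    era_quality <- data.frame(year_from = c(1985L, 1995L, 2005L),
                              year_to = c(1994L, 2004L, 2030L),
                              multiplier = c(2.0, 1.5, 1.0))
  }
  cfg <- list(n_registry = n_registry, n_source = n_source,
              unlinkable_frac = unlinkable_frac, dup_frac = dup_frac,
              typo_rate = typo_rate, phonetic_swap_rate = phonetic_swap_rate,
              date_transpose_rate = date_transpose_rate,
              missing_rate = missing_rate,
              common_surname_frac = common_surname_frac,
              common_surname_pool = toupper(common_surname_pool),
              era_quality = era_quality, source_kind = source_kind,
              event_years = as.integer(event_years), seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  for (f in c("n_registry", "n_source")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1) {
      stop_config("synthetic_config: %s must be a count >= 1", f)
    }
  }
  for (f in c("unlinkable_frac", "dup_frac", "typo_rate",
              "phonetic_swap_rate", "date_transpose_rate", "missing_rate",
              "common_surname_frac")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop_config("synthetic_config: %s must be a probability in [0,1]", f)
    }
  }
  eq <- cfg$era_quality
  if (!is.data.frame(eq) ||
      !all(c("year_from", "year_to", "multiplier") %in% names(eq))) {
    stop_config("synthetic_config: era_quality needs year_from/year_to/multiplier")
  }
  if (any(eq$multiplier < 0)) {
    stop_config("synthetic_config: era_quality multipliers must be >= 0")
  }
  if (!length(cfg$common_surname_pool)) {
    stop_config("synthetic_config: common_surname_pool must be nonempty")
  }
  invisible(cfg)
}

.days_in_month <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

.random_dates <- function(n, year_min, year_max) {
  y <- sample(year_min:year_max, n, replace = TRUE)
  m <- sample(12L, n, replace = TRUE)
  d <- vapply(m, function(mm) sample(.days_in_month[mm], 1L), integer(1))
  sprintf("%04d-%02d-%02d", y, m, d)
}

.zipf_sample <- function(pool, n, exponent = 1) {
  w <- 1 / seq_along(pool)^exponent
  sample(pool, n, replace = TRUE, prob = w / sum(w))
}

.draw_person_identity <- function(n) {
  sex <- sample(c("F", "M"), n, replace = TRUE)
  given1 <- character(n)
  given1[sex == "F"] <- .zipf_sample(.pool_given_f, sum(sex == "F"))
  given1[sex == "M"] <- .zipf_sample(.pool_given_m, sum(sex == "M"))
  has_mid <- runif(n) < 0.3
  given2 <- character(n)
  given2[sex == "F" & has_mid] <- .zipf_sample(.pool_given_f, sum(sex == "F" & has_mid))
  given2[sex == "M" & has_mid] <- .zipf_sample(.pool_given_m, sum(sex == "M" & has_mid))
  given <- ifelse(has_mid, paste(given1, given2), given1)
  list(sex = sex, given = given)
}

#' Generate a synthetic population registry
#'
#' Emulates a base population file of all covered residents: one row per
#' person with a unique key, names, sex, birth date, coverage dates, a last
#' health-system-contact date and a residential postal code. Surnames come
#' from a Zipf-weighted list with `common_surname_frac` of persons drawn from
#' a small pool of very common short surnames. The full identifier tuple
#' (surname, first given name, birth date, sex) is unique in the registry,
#' so ground truth is unambiguous. Deterministic given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return data.frame with columns `key`, `surname`, `given_names`, `sex`,
#'   `birth_date`, `coverage_start`, `last_contact`, `postal_code`.
#' @export
generate_registry <- function(config) {
  validate_synthetic_config(config)
  n <- as.integer(config$n_registry)
  reg <- with_substream(config$seed, "registry", {
    key <- sprintf("R%07d", seq_len(n))
    common <- runif(n) < config$common_surname_frac
    surname <- character(n)
    surname[common] <- .zipf_sample(config$common_surname_pool, sum(common))
    surname[!common] <- .zipf_sample(.pool_surnames_main, sum(!common))
    idy <- .draw_person_identity(n)
    birth_date <- .random_dates(n, 1915L, min(config$event_years) + 15L)
    # enforce uniqueness of the identifying tuple: a real registry separates
    # such persons by registration number; here unique tuples keep ground
    # truth unambiguous
    for (it in 1:25) {
      tup <- paste(surname, idy$given, idy$sex, birth_date, sep = "|")
      dup <- duplicated(tup)
      if (!any(dup)) break
      birth_date[dup] <- .random_dates(sum(dup), 1915L,
                                       min(config$event_years) + 15L)
    }
    y0 <- min(config$event_years)
    cov_y <- pmax(as.integer(substr(birth_date, 1, 4)), y0 - 10L)
    coverage_start <- sprintf("%04d-%02d-%02d", cov_y,
                              sample(12L, n, replace = TRUE),
                              sample(28L, n, replace = TRUE))
    last_contact <- .random_dates(n, y0, max(config$event_years))
    last_contact <- pmax(last_contact, coverage_start)
    fsa <- sample(.postal_fsa, n, replace = TRUE)
    postal_code <- paste0(fsa, sample(9L, n, replace = TRUE),
                          sample(LETTERS, n, replace = TRUE),
                          sample(9L, n, replace = TRUE))
    data.frame(key = key, surname = surname, given_names = idy$given,
               sex = idy$sex, birth_date = birth_date,
               coverage_start = coverage_start, last_contact = last_contact,
               postal_code = postal_code, stringsAsFactors = FALSE)
  })
  reg
}

era_multiplier <- function(years, era_quality) {
  out <- rep(1, length(years))
  for (i in seq_len(nrow(era_quality))) {
    hit <- !is.na(years) & years >= era_quality$year_from[i] &
      years <= era_quality$year_to[i]
    out[hit] <- era_quality$multiplier[i]
  }
  out
}

.apply_typo <- function(x) {
  n <- nchar(x)
  if (n == 0L) return(x)
  ops <- c("substitute", "insert")
  if (n >= 2L) ops <- c(ops, "delete", "transpose")
  op <- sample(ops, 1L)
  pos <- sample(n, 1L)
  switch(op,
    substitute = {
      repl <- sample(setdiff(LETTERS, substr(x, pos, pos)), 1L)
      paste0(substr(x, 1, pos - 1L), repl, substring(x, pos + 1L))
    },
    insert = {
      at <- sample(n + 1L, 1L)
      paste0(substr(x, 1, at - 1L), sample(LETTERS, 1L), substring(x, at))
    },
    delete = paste0(substr(x, 1, pos - 1L), substring(x, pos + 1L)),
    transpose = {
      p <- if (pos == n) n - 1L else pos
      paste0(substr(x, 1, p - 1L), substr(x, p + 1L, p + 1L),
             substr(x, p, p), substring(x, p + 2L))
    }
  )
}

.apply_phonetic_swap <- function(x) {
  for (cls in .phonetic_variant_classes) {
    if (x %in% cls) {
      others <- setdiff(cls, x)
      return(others[sample(length(others), 1L)])
    }
  }
  # generic same-code misspelling: replace one interior vowel (away from the
  # head/tail replacement zones, and never an E directly before V) by another
  # vowel; verified NYSIIS-invariant, otherwise left unchanged
  n <- nchar(x)
  if (n < 6L) return(x)
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  cand <- which(ch %in% .nysiis_vowels)
  cand <- cand[cand >= 4L & cand <= n - 2L]
  cand <- cand[!(ch[cand] == "E" & ch[pmin(cand + 1L, n)] == "V")]
  if (!length(cand)) return(x)
  pos <- cand[sample(length(cand), 1L)]
  repl <- sample(setdiff(.nysiis_vowels, ch[pos]), 1L)
  y <- paste0(substr(x, 1, pos - 1L), repl, substring(x, pos + 1L))
  if (identical(nysiis(y), nysiis(x))) y else x
}

.apply_date_transpose <- function(x) {
  d <- as.integer(substr(x, 9, 10))
  m <- as.integer(substr(x, 6, 7))
  sprintf("%s-%02d-%02d", substr(x, 1, 4), d, m)
}

date_transposable <- function(x) {
  ok <- !is_missing_chr(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  d <- suppressWarnings(as.integer(substr(x, 9, 10)))
  m <- suppressWarnings(as.integer(substr(x, 6, 7)))
  ok & !is.na(d) & !is.na(m) & d <= 12L & d != m
}

#' Apply one corruption operator to a field value
#'
#' Operators: `typo` (one random character edit: substitute, insert, delete
#' or transpose adjacent), `phonetic_swap` (substitute a same-NYSIIS
#' spelling variant), `date_transpose` (swap day and month of an ISO date;
#' only defined when the day is at most 12 and differs from the month) and
#' `drop` (replace by the missing marker `""`). An operator that does not
#' apply to the value is a no-op with a warning. Uses the current RNG state.
#'
#' @param value a single character value (name or ISO date).
#' @param operator one of `"typo"`, `"phonetic_swap"`, `"date_transpose"`,
#'   `"drop"`.
#' @return the corrupted value.
#' @examples
#' corrupt_field("1987-04-09", "date_transpose")  # "1987-09-04"
#' corrupt_field("SMITH", "drop")                 # ""
#' @export
corrupt_field <- function(value,
                          operator = c("typo", "phonetic_swap",
                                       "date_transpose", "drop")) {
  operator <- match.arg(operator)
  value <- as.character(value)
  stopifnot(length(value) == 1L)
  if (operator == "drop") return("")
  if (is_missing_chr(value)) {
    warning("corrupt_field: operator '", operator,
            "' not applicable to a missing value; no-op")
    return(value)
  }
  switch(operator,
    typo = {
      if (grepl("[^A-Z]", value)) {
        warning("corrupt_field: typo operator expects A-Z text; no-op")
        value
      } else {
        .apply_typo(value)
      }
    },
    phonetic_swap = {
      if (grepl("[^A-Z]", value)) {
        warning("corrupt_field: phonetic_swap expects A-Z text; no-op")
        value
      } else {
        .apply_phonetic_swap(value)
      }
    },
    date_transpose = {
      if (!date_transposable(value)) {
        warning("corrupt_field: date not transposable (day > 12 or equal to month); no-op")
        value
      } else {
        .apply_date_transpose(value)
      }
    }
  )
}

# Vectorized corruption of one character column at rate*multiplier (capped
# at 1). Returns the column plus the count of records actually altered.
.corrupt_column <- function(x, rate, mult, fun, applicable = NULL) {
  p <- pmin(rate * mult, 1)
  hit <- runif(length(x)) < p & !is_missing_chr(x)
  if (!is.null(applicable)) hit <- hit & applicable
  if (any(hit)) x[hit] <- vapply(x[hit], fun, character(1), USE.NAMES = FALSE)
  list(x = x, n = sum(hit))
}

#' Derive a corrupted source extract from a registry, with ground truth
#'
#' Each source record is either a corrupted copy of a registry person's
#' identifiers plus an event date and stratification attributes, or (with
#' probability `unlinkable_frac`) an invention with freshly drawn
#' identifiers and no registry counterpart. Per-field corruption operators
#' fire independently at their configured rates scaled by the era multiplier
#' of the record's event year. Persons selected for duplication contribute a
#' second record with a different event date.
#'
#' @param config a [synthetic_config()].
#' @param registry output of [generate_registry()].
#' @return list with `source` (data.frame of source records), `truth`
#'   (data.frame `source_id`, `registry_key`, `""` meaning no counterpart)
#'   and `corruption_log` (per-field corruption counts).
#' @export
derive_source <- function(config, registry) {
  validate_synthetic_config(config)
  if (is.null(registry) || nrow(registry) == 0L) {
    stop_config("derive_source: registry must be nonempty")
  }
  n <- as.integer(config$n_source)
  with_substream(config$seed, "source", {
    unlinkable <- runif(n) < config$unlinkable_frac
    n_link <- sum(!unlinkable)

    # person slots for linkable records: persons drawn without replacement
    # (recycled if the source outnumbers the registry), then a dup_frac
    # share of them contribute one extra record each
    n_base <- max(1L, ceiling(n_link / (1 + config$dup_frac)))
    draw <- function(k) sample(nrow(registry), k,
                               replace = k > nrow(registry))
    persons <- draw(min(n_base, n_link))
    extra <- persons[runif(length(persons)) < config$dup_frac]
    slots <- c(persons, extra)
    while (length(slots) < n_link) slots <- c(slots, draw(n_link - length(slots)))
    slots <- slots[seq_len(n_link)]

    src <- data.frame(source_id = sprintf("S%07d", seq_len(n)),
                      stringsAsFactors = FALSE)
    truth_key <- rep("", n)
    truth_key[!unlinkable] <- registry$key[slots]

    surname <- given <- sex <- birth <- postal <- character(n)
    surname[!unlinkable] <- registry$surname[slots]
    given[!unlinkable] <- registry$given_names[slots]
    sex[!unlinkable] <- registry$sex[slots]
    birth[!unlinkable] <- registry$birth_date[slots]
    postal[!unlinkable] <- registry$postal_code[slots]
    if (any(unlinkable)) {
      k <- sum(unlinkable)
      common <- runif(k) < config$common_surname_frac
      sn <- character(k)
      sn[common] <- .zipf_sample(config$common_surname_pool, sum(common))
      sn[!common] <- .zipf_sample(.pool_surnames_main, sum(!common))
      idy <- .draw_person_identity(k)
      surname[unlinkable] <- sn
      given[unlinkable] <- idy$given
      sex[unlinkable] <- idy$sex
      birth[unlinkable] <- .random_dates(k, 1915L, min(config$event_years) + 15L)
      fsa <- sample(.postal_fsa, k, replace = TRUE)
      postal[unlinkable] <- paste0(fsa, sample(9L, k, replace = TRUE),
                                   sample(LETTERS, k, replace = TRUE),
                                   sample(9L, k, replace = TRUE))
    }

    # event dates: deaths sit near the person's last registry contact so a
    # death-date-vs-last-contact comparator has signal; landings are uniform
    y0 <- config$event_years[1]; y1 <- config$event_years[2]
    if (config$source_kind == "death" ) {
      event_date <- .random_dates(n, y0, y1)
      lc <- rep(NA_character_, n)
      lc[!unlinkable] <- registry$last_contact[slots]
      off <- sample(0:15, n, replace = TRUE)
      has_lc <- !is.na(lc)
      event_date[has_lc] <- format(as.Date(lc[has_lc]) + off[has_lc], "%Y-%m-%d")
      event_date <- pmin(event_date, sprintf("%04d-12-31", y1))
    } else {
      event_date <- .random_dates(n, y0, y1)
    }
    # duplicates of one person must differ in event date
    dup_of_person <- duplicated(paste0(truth_key, "|", truth_key != "")) &
      truth_key != ""
    if (any(dup_of_person)) {
      shift <- sample(30:400, sum(dup_of_person), replace = TRUE)
      event_date[dup_of_person] <-
        format(as.Date(event_date[dup_of_person]) + shift, "%Y-%m-%d")
    }
    event_year <- as.integer(substr(event_date, 1, 4))
    mult <- era_multiplier(event_year, config$era_quality)

    # stratification attributes
    if (config$source_kind == "immigration") {
      src$immigrant_class <- sample(.immigrant_classes, n, replace = TRUE,
                                    prob = c(0.32, 0.5, 0.15, 0.03))
      src$region_of_birth <- sample(.regions_of_birth, n, replace = TRUE)
    } else {
      src$cause_of_death <- sample(.death_causes, n, replace = TRUE,
                                   prob = c(0.29, 0.34, 0.08, 0.06, 0.01,
                                            0.01, 0.04, 0.02, 0.03, 0.12))
    }

    log <- list()
    r <- .corrupt_column(surname, config$typo_rate, mult, .apply_typo)
    surname <- r$x; log$surname_typo <- r$n
    r <- .corrupt_column(surname, config$phonetic_swap_rate, mult,
                         .apply_phonetic_swap)
    surname <- r$x; log$surname_phonetic <- r$n
    r <- .corrupt_column(surname, config$missing_rate, mult, function(z) "")
    surname <- r$x; log$surname_missing <- r$n

    r <- .corrupt_column(given, config$typo_rate, mult, function(z) {
      parts <- strsplit(z, " ", fixed = TRUE)[[1]]
      parts[1] <- .apply_typo(parts[1])
      paste(parts, collapse = " ")
    })
    given <- r$x; log$given_typo <- r$n
    r <- .corrupt_column(given, config$missing_rate, mult, function(z) "")
    given <- r$x; log$given_missing <- r$n

    r <- .corrupt_column(birth, config$date_transpose_rate, mult,
                         .apply_date_transpose,
                         applicable = date_transposable(birth))
    birth <- r$x; log$birth_transposed <- r$n
    r <- .corrupt_column(birth, config$missing_rate, mult, function(z) "")
    birth <- r$x; log$birth_missing <- r$n

    r <- .corrupt_column(sex, config$missing_rate, mult, function(z) "")
    sex <- r$x; log$sex_missing <- r$n
    r <- .corrupt_column(postal, config$missing_rate, mult, function(z) "")
    postal <- r$x; log$postal_missing <- r$n

    src$surname <- surname
    src$given_names <- given
    src$sex <- sex
    src$birth_date <- birth
    src$event_date <- event_date
    src$postal_code <- postal
    truth <- data.frame(source_id = src$source_id, registry_key = truth_key,
                        stringsAsFactors = FALSE)
    list(source = src, truth = truth,
         corruption_log = as.data.frame(log))
  })
}

#' Generate a registry and a matching source extract in one call
#'
#' @param config a [synthetic_config()].
#' @return list with `registry`, `source`, `truth`, `corruption_log`.
#' @export
simulate_registries <- function(config) {
  registry <- generate_registry(config)
  out <- derive_source(config, registry)
  c(list(registry = registry), out)
}

#' Write the synthetic files as UTF-8 CSV
#'
#' Registry and source files carry a header row; missing values are encoded
#' as empty strings; dates are ISO 8601. The truth map is a two-column CSV
#' (`source_id`, `registry_key`) with `""` for records that have no registry
#' counterpart.
#'
#' @param sim output of [simulate_registries()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_synthetic_csv <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(registry = file.path(dir, "registry.csv"),
             source = file.path(dir, "source.csv"),
             truth = file.path(dir, "truth.csv"))
  utils::write.csv(sim$registry, paths["registry"], row.names = FALSE, na = "")
  utils::write.csv(sim$source, paths["source"], row.names = FALSE, na = "")
  utils::write.csv(sim$truth, paths["truth"], row.names = FALSE, na = "")
  invisible(paths)
}
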