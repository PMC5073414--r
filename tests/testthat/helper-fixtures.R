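# Shared fixture builders; everything is generated in code at test time.

toy_postal_table <- function() {
  postal_city_table(prefix = c("M", "M1", "K", "K1", "L5"),
                    city = c("TORONTO", "SCARBOROUGH", "EASTERN", "OTTAWA",
                             "MISSISSAUGA"))
}

demo_postal_table <- function() {
  read_postal_city_table(system.file("extdata", "postal_city_demo.csv",
                                     package = "reglink"))
}

# Tiny hand-built registry/source pair with obvious truth, for rule-level
# tests where synthetic noise would get in the way.
mini_registry <- function() {
  data.frame(
    key = c("R1", "R2", "R3", "R4", "R5"),
    surname = c("BROWN", "BRAUN", "LEE", "LEE", "SCHMIDT"),
    given_names = c("ANNA", "ANNA", "WEI", "MING", "KARL"),
    sex = c("F", "F", "F", "M", "M"),
    birth_date = c("1950-02-10", "1950-02-10", "1961-07-03", "1972-11-30",
                   "1940-05-21"),
    coverage_start = rep("1985-01-01", 5),
    last_contact = c("2010-01-01", "2011-01-01", "2012-06-15", "2009-03-01",
                     "1999-12-31"),
    postal_code = c("M4N3M5", "M4N3M6", "K1Y4E9", "M1B2C3", "L5B1A1"),
    stringsAsFactors = FALSE)
}

mini_source <- function() {
  data.frame(
    source_id = c("S1", "S2", "S3", "S4"),
    surname = c("BROWN", "LEE", "LEE", "NOVAK"),
    given_names = c("ANNA", "WEI", "MING", "IVAN"),
    sex = c("F", "F", "M", "M"),
    birth_date = c("1950-02-10", "1961-07-03", "1972-11-30", "1980-01-01"),
    event_date = c("1990-05-01", "1995-07-01", "2000-01-01", "2005-06-06"),
    postal_code = c("M4N3M5", "K1Y4E9", "M1B2C3", "M5G1X1"),
    stringsAsFactors = FALSE)
}

std_mini <- function(postal = toy_postal_table()) {
  list(registry = standardize_records(mini_registry(), "key", postal),
       source = standardize_records(mini_source(), "source_id", postal))
}

noise_free_config <- function(n_registry = 300, n_source = 120, seed = 5) {
  synthetic_config(n_registry = n_registry, n_source = n_source,
                   unlinkable_frac = 0, dup_frac = 0, typo_rate = 0,
                   phonetic_swap_rate = 0, date_transpose_rate = 0,
                   missing_rate = 0, seed = seed)
}

# Brute-force candidate oracle: all pairs with equal (non-missing) key
# tuples, missing treated as its own value.
brute_force_pairs <- function(source, registry, key_fields) {
  sent <- "§MISSING§"
  keyval <- function(df, f) {
    v <- as.character(df[[f]])
    v[is.na(v) | v == ""] <- sent
    v
  }
  out <- list()
  for (i in seq_len(nrow(source))) {
    for (j in seq_len(nrow(registry))) {
      same <- all(vapply(key_fields, function(f) {
        keyval(source, f)[i] == keyval(registry, f)[j]
      }, logical(1)))
      if (same) out[[length(out) + 1L]] <- c(i, j)
    }
  }
  if (!length(out)) {
    return(data.frame(src_row = integer(), reg_row = integer()))
  }
  m <- do.call(rbind, out)
  df <- data.frame(src_row = m[, 1], reg_row = m[, 2])
  df[order(df$src_row, df$reg_row), ]
}
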