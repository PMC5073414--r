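# Identifier standardization: name cleaning, NYSIIS phonetic coding, and
# postal-code-to-city lookup. These run over both files before any matching,
# so every comparison downstream sees the same canonical form.

.diacritic_from <- "ÁÀÂÄÃÅáàâäãåÇçÉÈÊËéèêëÍÌÎÏíìîïÑñÓÒÔÖÕóòôöõÚÙÛÜúùûüÝýÿ"
.diacritic_to   <- "AAAAAAaaaaaaCcEEEEeeeeIIIIiiiiNnOOOOOoooooUUUUuuuuYyy"

#' Clean a raw name for matching
#'
#' Uppercases, maps accented Latin letters to their ASCII base letters, and
#' removes apostrophes, hyphens, spaces and every other non-letter. The
#' result contains only the letters A-Z, or is empty. The function is total
#' and idempotent.
#'
#' @param raw character vector of raw names (NA treated as empty).
#' @return character vector of cleaned names.
#' @examples
#' clean_name("O'Brien")        # "OBRIEN"
#' clean_name("Müller-Lopez") # "MULLERLOPEZ"
#' @export
clean_name <- function(raw) {
  x <- ifelse(is.na(raw), "", as.character(raw))
  x <- chartr(.diacritic_from, .diacritic_to, x)
  x <- toupper(x)
  gsub("[^A-Z]", "", x)
}

.nysiis_vowels <- c("A", "E", "I", "O", "U")

# One name, already A-Z only. Original (1970) rule set:
# head replacements MAC->MCC KN->NN K->C PH/PF->FF SCH->SSS; tail EE/IE->Y,
# DT/RT/RD/NT/ND->D; interior scan EV->AF, vowels->A, Q->G Z->S M->N, KN->N
# K->C, SCH->SSS PH->FF, H flanked by a non-vowel -> previous letter, W after
# vowel -> previous letter; no doubled letters emitted; trailing S dropped,
# AY->Y, trailing A dropped; first letter of the (head-replaced) name kept.
.nysiis_one <- function(name) {
  if (name == "") return("")
  if (grepl("MAC", substr(name, 1, 3), fixed = TRUE) && startsWith(name, "MAC")) {
    name <- paste0("MCC", substring(name, 4))
  } else if (startsWith(name, "KN")) {
    name <- paste0("NN", substring(name, 3))
  } else if (startsWith(name, "K")) {
    name <- paste0("C", substring(name, 2))
  } else if (startsWith(name, "PH") || startsWith(name, "PF")) {
    name <- paste0("FF", substring(name, 3))
  } else if (startsWith(name, "SCH")) {
    name <- paste0("SSS", substring(name, 4))
  }
  n <- nchar(name)
  tail2 <- if (n >= 2) substr(name, n - 1, n) else ""
  if (tail2 %in% c("EE", "IE")) {
    name <- paste0(substr(name, 1, n - 2), "Y")
  } else if (tail2 %in% c("DT", "RT", "RD", "NT", "ND")) {
    name <- paste0(substr(name, 1, n - 2), "D")
  }
  s <- strsplit(name, "", fixed = TRUE)[[1]]
  n <- length(s)
  key <- s[1]
  i <- 2
  while (i <= n) {
    ch <- s[i]
    if (ch %in% .nysiis_vowels) {
      if (ch == "E" && i < n && s[i + 1] == "V") {
        s[i] <- "A"; s[i + 1] <- "F"
      } else {
        s[i] <- "A"
      }
    } else if (ch == "Q") {
      s[i] <- "G"
    } else if (ch == "Z") {
      s[i] <- "S"
    } else if (ch == "M") {
      s[i] <- "N"
    } else if (ch == "K") {
      s[i] <- if (i < n && s[i + 1] == "N") "N" else "C"
    } else if (ch == "S" && i + 2 <= n && s[i + 1] == "C" && s[i + 2] == "H") {
      s[i] <- "S"; s[i + 1] <- "S"; s[i + 2] <- "S"
    } else if (ch == "P" && i < n && s[i + 1] == "H") {
      s[i] <- "F"; s[i + 1] <- "F"
    } else if (ch == "H") {
      prev_vowel <- s[i - 1] %in% .nysiis_vowels
      next_vowel <- i < n && s[i + 1] %in% .nysiis_vowels
      if (!prev_vowel || !next_vowel) s[i] <- s[i - 1]
    } else if (ch == "W" && s[i - 1] %in% .nysiis_vowels) {
      s[i] <- s[i - 1]
    }
    last <- substr(key, nchar(key), nchar(key))
    if (s[i] != last) key <- paste0(key, s[i])
    i <- i + 1
  }
  k <- nchar(key)
  if (k > 1 && substr(key, k, k) == "S") {
    key <- substr(key, 1, k - 1); k <- k - 1
  }
  if (k >= 2 && substr(key, k - 1, k) == "AY") {
    key <- paste0(substr(key, 1, k - 2), "Y"); k <- k - 1
  }
  if (k > 1 && substr(key, k, k) == "A") {
    key <- substr(key, 1, k - 1)
  }
  key
}

#' NYSIIS phonetic code of a cleaned surname
#'
#' Implements the original New York State Identification and Intelligence
#' System phonetic conversion, so that similar-sounding spellings (BROWN and
#' BRAUN, MACDONALD and MCDONALD) standardize to the same code and can share
#' a block. The code is uncapped by default; some descriptions truncate to 6
#' characters, available via `truncate`.
#'
#' @param name character vector of cleaned names (A-Z only; see
#'   [clean_name()]). Empty strings code to the empty string.
#' @param truncate if `TRUE`, codes are truncated to 6 characters.
#' @return character vector of NYSIIS codes.
#' @examples
#' nysiis("KNIGHT")                 # "NAGT"
#' nysiis("BROWN") == nysiis("BRAUN")
#' @export
nysiis <- function(name, truncate = FALSE) {
  name <- ifelse(is.na(name), "", as.character(name))
  bad <- grepl("[^A-Z]", name)
  if (any(bad)) {
    stop_config("nysiis(): input must be cleaned A-Z text; offending value: %s",
                name[bad][1])
  }
  out <- vapply(name, .nysiis_one, character(1), USE.NAMES = FALSE)
  if (truncate) out <- substr(out, 1, 6)
  out
}

#' Read a postal-prefix to city lookup table
#'
#' Two-column CSV (`prefix`, `city`); prefixes must be unique. Emulates the
#' role of a postal-code conversion file: mapping residential postal codes to
#' a city, used as geographic evidence when reviewing uncertain pairs.
#'
#' @param path CSV file path.
#' @return a `postal_city_table` data.frame with columns `prefix`, `city`.
#' @export
read_postal_city_table <- function(path) {
  tab <- utils::read.csv(path, colClasses = "character")
  postal_city_table(tab$prefix, tab$city)
}

#' Construct a postal-prefix to city lookup table
#'
#' @param prefix character vector of postal-code prefixes (unique).
#' @param city character vector of city codes, same length.
#' @return a `postal_city_table` data.frame.
#' @export
postal_city_table <- function(prefix, city) {
  if (anyDuplicated(prefix)) stop_config("postal_city_table: duplicate prefixes")
  if (length(prefix) != length(city)) {
    stop_config("postal_city_table: prefix and city lengths differ")
  }
  structure(data.frame(prefix = as.character(prefix),
                       city = as.character(city),
                       stringsAsFactors = FALSE),
            class = c("postal_city_table", "data.frame"))
}

#' Derive a city code from a postal code by longest-prefix lookup
#'
#' Total: a missing postal code or one matching no prefix yields `"UNKNOWN"`,
#' which downstream review treats as absence of geographic evidence, never as
#' agreement.
#'
#' @param postal character vector of postal codes.
#' @param table a [postal_city_table()].
#' @return character vector of city codes.
#' @export
city_of <- function(postal, table) {
  stopifnot(inherits(table, "postal_city_table"))
  postal <- toupper(ifelse(is.na(postal), "", as.character(postal)))
  out <- rep("UNKNOWN", length(postal))
  # try prefixes longest first so the most specific match wins
  for (len in sort(unique(nchar(table$prefix)), decreasing = TRUE)) {
    sub <- table[nchar(table$prefix) == len, ]
    idx <- match(substr(postal, 1, len), sub$prefix)
    hit <- out == "UNKNOWN" & !is.na(idx) & postal != ""
    out[hit] <- sub$city[idx[hit]]
  }
  out
}

#' Standardize a registry or source file for matching
#'
#' Produces one standardized row per input record: cleaned surname and given
#' names, NYSIIS surname code, given-name initial, birth-date parts, sex and
#' a postal-derived city code. Matching always runs on these fields, never on
#' the raw ones. The first given name is used for matching; the full cleaned
#' list is retained in `given_all`.
#'
#' @param records data.frame with columns `surname`, `given_names`, `sex`,
#'   `birth_date` (ISO 8601 or ""), `postal_code`, plus `key` (registry) or
#'   `source_id` (source); optional `event_date`, `last_contact`.
#' @param id_col name of the identifier column (`"key"` or `"source_id"`).
#' @param postal_table a [postal_city_table()], or `NULL` to emit
#'   `"UNKNOWN"` city codes throughout.
#' @param nysiis_given also NYSIIS-code the first given name (column
#'   `given_nysiis`); off by default — only surnames are phonetically coded.
#' @param truncate_nysiis truncate codes to 6 characters.
#' @return a `data.table`, one row per record, carrying the id column,
#'   standardized fields, and any extra columns of the input unchanged.
#' @export
standardize_records <- function(records, id_col, postal_table = NULL,
                                nysiis_given = FALSE, truncate_nysiis = FALSE) {
  need <- c(id_col, "surname", "given_names", "sex", "birth_date")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop_config("standardize_records: missing columns: %s",
                paste(miss, collapse = ", "))
  }
  dt <- data.table::as.data.table(records)
  out <- data.table::data.table(id = as.character(dt[[id_col]]))
  data.table::setnames(out, "id", id_col)

  out[, surname_clean := clean_name(dt$surname)]
  given_split <- strsplit(ifelse(is.na(dt$given_names), "", dt$given_names),
                          "[ ;]+")
  given_clean <- lapply(given_split, function(g) {
    g <- clean_name(g)
    g[g != ""]
  })
  out[, given_first := vapply(given_clean, function(g) {
    if (length(g)) g[1] else ""
  }, character(1))]
  out[, given_all := vapply(given_clean, paste, character(1), collapse = " ")]
  out[, given_initial := substr(given_first, 1, 1)]
  out[, surname_nysiis := nysiis(surname_clean, truncate = truncate_nysiis)]
  if (nysiis_given) {
    out[, given_nysiis := nysiis(given_first, truncate = truncate_nysiis)]
  }

  bd <- as.character(dt$birth_date)
  bd[is_missing_chr(bd)] <- NA_character_
  out[, birth_date := bd]
  out[, birth_year := suppressWarnings(as.integer(substr(bd, 1, 4)))]
  out[, birth_month := suppressWarnings(as.integer(substr(bd, 6, 7)))]
  out[, birth_day := suppressWarnings(as.integer(substr(bd, 9, 10)))]

  sex <- toupper(as.character(dt$sex))
  sex[!sex %in% c("F", "M")] <- ""
  out[, sex := sex]

  if (!is.null(postal_table) && "postal_code" %in% names(dt)) {
    out[, city_code := city_of(dt$postal_code, postal_table)]
  } else {
    out[, city_code := "UNKNOWN"]
  }

  for (col in c("event_date", "last_contact")) {
    if (col %in% names(dt)) {
      v <- as.character(dt[[col]])
      v[is_missing_chr(v)] <- NA_character_
      out[, (col) := v]
    }
  }
  extra <- setdiff(names(dt), c(need, "postal_code", "event_date",
                                "last_contact"))
  for (col in extra) out[, (col) := dt[[col]]]
  out[]
}
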