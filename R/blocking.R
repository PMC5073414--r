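# Blocking: partition both standardized files into mutually exclusive and
# exhaustive subsets keyed by a tuple of standardized fields, and enumerate
# candidate pairs only within blocks. Comparing all pairs is infeasible at
# registry scale (the pair count is the product of the file sizes), and a
# partition guarantees no pair is compared twice.

#' Declare a blocking scheme
#'
#' @param key_fields nonempty character vector of standardized field names
#'   (e.g. `c("sex", "surname_nysiis")`), no duplicates.
#' @param missing_policy `"own_block"` (a record missing a key field falls
#'   into a missing-value block for that field; the partition property holds)
#'   or `"broadcast"` (a record missing a key field is compared against every
#'   value of that field — used for missing sex, so those records still get a
#'   chance to link).
#' @return a `block_scheme` object.
#' @export
block_scheme <- function(key_fields, missing_policy = c("own_block", "broadcast")) {
  missing_policy <- match.arg(missing_policy)
  if (length(key_fields) == 0L) {
    stop_config("block_scheme: key_fields must be nonempty")
  }
  if (anyDuplicated(key_fields)) {
    stop_config("block_scheme: duplicate key fields: %s",
                paste(key_fields[duplicated(key_fields)], collapse = ", "))
  }
  structure(list(key_fields = as.character(key_fields),
                 missing_policy = missing_policy),
            class = "block_scheme")
}

.missing_sentinel <- "§MISSING§"

.block_key_values <- function(dt, field) {
  v <- as.character(dt[[field]])
  v[is_missing_chr(v)] <- .missing_sentinel
  v
}

#' Build the block index for one pass
#'
#' @param source standardized source records ([standardize_records()]).
#' @param registry standardized registry records.
#' @param scheme a [block_scheme()].
#' @return a `block_index` list holding the two keyed tables; use
#'   [candidate_pairs()] to enumerate within-block pairs.
#' @export
build_blocks <- function(source, registry, scheme) {
  stopifnot(inherits(scheme, "block_scheme"))
  for (f in scheme$key_fields) {
    if (!f %in% names(source) || !f %in% names(registry)) {
      stop_config("build_blocks: unknown blocking field '%s'", f)
    }
  }
  skey <- data.table::data.table(.row = seq_len(nrow(source)))
  rkey <- data.table::data.table(.row = seq_len(nrow(registry)))
  for (f in scheme$key_fields) {
    skey[, (f) := .block_key_values(source, f)]
    rkey[, (f) := .block_key_values(registry, f)]
  }
  if (scheme$missing_policy == "broadcast") {
    # replicate records missing a key field across every observed value of
    # that field (both files contribute to the value universe)
    for (f in scheme$key_fields) {
      vals <- setdiff(unique(c(skey[[f]], rkey[[f]])), .missing_sentinel)
      if (!length(vals)) next
      for (tab in c("skey", "rkey")) {
        tt <- get(tab)
        missing_rows <- tt[tt[[f]] == .missing_sentinel]
        if (nrow(missing_rows)) {
          expanded <- missing_rows[rep(seq_len(nrow(missing_rows)),
                                       each = length(vals))]
          expanded[, (f) := rep(vals, nrow(missing_rows))]
          assign(tab, rbind(tt[tt[[f]] != .missing_sentinel], expanded))
        }
      }
    }
  }
  structure(list(source_keys = skey, registry_keys = rkey,
                 scheme = scheme,
                 n_source = nrow(source), n_registry = nrow(registry)),
            class = "block_index")
}

#' Enumerate within-block candidate pairs
#'
#' Yields exactly the cross product of source and registry rows inside each
#' block, with no duplicate pairs; the total never exceeds the all-pairs
#' product.
#'
#' @param index a [build_blocks()] result.
#' @return data.table with columns `src_row`, `reg_row` (row indices into
#'   the standardized inputs).
#' @export
candidate_pairs <- function(index) {
  stopifnot(inherits(index, "block_index"))
  kf <- index$scheme$key_fields
  s <- index$source_keys
  r <- index$registry_keys
  pairs <- merge(s, r, by = kf, allow.cartesian = TRUE, suffixes = c(".s", ".r"))
  if (nrow(pairs) == 0L) {
    return(data.table::data.table(src_row = integer(), reg_row = integer()))
  }
  out <- data.table::data.table(src_row = pairs$.row.s, reg_row = pairs$.row.r)
  out <- unique(out)
  data.table::setorder(out, src_row, reg_row)
  out[]
}

# Partition check: under own_block every record appears in exactly one block.
assert_partition <- function(index) {
  if (index$scheme$missing_policy != "own_block") return(invisible(TRUE))
  if (nrow(index$source_keys) != index$n_source ||
      anyDuplicated(index$source_keys$.row) ||
      nrow(index$registry_keys) != index$n_registry ||
      anyDuplicated(index$registry_keys$.row)) {
    stop("blocking partition property violated")
  }
  invisible(TRUE)
}
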