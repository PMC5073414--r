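mk_queue <- function(weight, city_s, city_r, gap, id = "S1", key = "R1") {
  data.table::data.table(source_id = id, registry_key = key, pass_id = 4L,
                         weight = weight, gap = gap, city_source = city_s,
                         city_registry = city_r)
}

test_that("the review rule accepts and rejects as documented", {
  rule <- review_rule(require_city_agreement = TRUE, min_weight = 4,
                      max_competitor_gap = 0)
  ok <- auto_review(mk_queue(6, "TORONTO", "TORONTO", Inf), rule)
  expect_equal(nrow(ok$decisions), 1)
  expect_identical(ok$decisions$status, "linked_review")
  bad_city <- auto_review(mk_queue(6, "TORONTO", "OTTAWA", Inf), rule)
  expect_equal(nrow(bad_city$decisions), 0)
  expect_identical(bad_city$rejected$reason, "city_disagreement")
  # UNKNOWN never counts as agreement
  unk <- auto_review(mk_queue(6, "UNKNOWN", "UNKNOWN", Inf), rule)
  expect_equal(nrow(unk$decisions), 0)
  # city evidence not required -> accepted on weight alone
  lax <- review_rule(require_city_agreement = FALSE, min_weight = 4)
  expect_equal(nrow(auto_review(mk_queue(6, "TORONTO", "OTTAWA", Inf),
                                lax)$decisions), 1)
  expect_error(auto_review(mk_queue(6, "A", "A", Inf),
                           review_rule(min_weight = 2), t_lower = 4),
               "min_weight")
})

test_that("review decisions equal a truth-table evaluation over all case combinations", {
  rule <- review_rule(require_city_agreement = TRUE, min_weight = 4,
                      max_competitor_gap = 1)
  cases <- expand.grid(weight = c(3, 5, 9),
                       city = c("agree", "disagree", "unknown"),
                       gap = c(0, 1, 2), stringsAsFactors = FALSE)
  q <- data.table::data.table(
    source_id = sprintf("S%02d", seq_len(nrow(cases))),
    registry_key = sprintf("R%02d", seq_len(nrow(cases))),
    pass_id = 4L, weight = cases$weight, gap = cases$gap,
    city_source = ifelse(cases$city == "unknown", "UNKNOWN", "TORONTO"),
    city_registry = ifelse(cases$city == "agree", "TORONTO",
                           ifelse(cases$city == "disagree", "OTTAWA",
                                  "UNKNOWN")))
  res <- auto_review(q, rule)
  want <- cases$weight >= 4 & cases$city == "agree" & cases$gap >= 1
  expect_identical(sort(res$decisions$source_id), sort(q$source_id[want]))
  expect_identical(res$rejected$accepted, want)
})

test_that("review acceptance is monotone in min_weight", {
  q <- mk_queue(weight = c(4.5, 6, 9), city_s = "TORONTO",
                city_r = "TORONTO", gap = Inf,
                id = c("S1", "S2", "S3"), key = c("R1", "R2", "R3"))
  acc <- lapply(c(4, 6, 8), function(mw) {
    auto_review(q, review_rule(min_weight = mw))$decisions$source_id
  })
  expect_true(all(acc[[2]] %in% acc[[1]]))
  expect_true(all(acc[[3]] %in% acc[[2]]))
})

test_that("one-to-one enforcement keeps the strongest claimant", {
  d <- data.table::data.table(
    source_id = c("S1", "S2", "S3"),
    registry_key = c("R1", "R1", "R2"),
    status = c("linked_probabilistic", "linked_probabilistic",
               "linked_probabilistic"),
    pass_id = c(4L, 4L, 4L), weight = c(9, 5, 7))
  out <- enforce_one_to_one(d)
  expect_identical(out$status[out$source_id == "S1"], "linked_probabilistic")
  expect_identical(out$status[out$source_id == "S2"], "unlinked")
  expect_identical(out$registry_key[out$source_id == "S2"], "")
  expect_identical(out$status[out$source_id == "S3"], "linked_probabilistic")
  # deterministic outranks a heavier probabilistic claim
  d2 <- data.table::data.table(
    source_id = c("S1", "S2"), registry_key = "R1",
    status = c("linked_probabilistic", "linked_deterministic"),
    pass_id = c(4L, 1L), weight = c(15, NA))
  out2 <- enforce_one_to_one(d2)
  expect_identical(out2$status[out2$source_id == "S2"],
                   "linked_deterministic")
  expect_identical(out2$status[out2$source_id == "S1"], "unlinked")
  # no conflicts -> unchanged
  expect_equal(as.data.frame(enforce_one_to_one(d[c(1, 3)])),
               as.data.frame(d[c(1, 3)]))
})

test_that("after enforcement each registry key appears at most once", {
  set.seed(101)
  d <- data.table::data.table(
    source_id = sprintf("S%03d", 1:200),
    registry_key = sprintf("R%02d", sample(40, 200, replace = TRUE)),
    status = sample(c("linked_deterministic", "linked_probabilistic",
                      "linked_review"), 200, replace = TRUE),
    pass_id = sample(1:5, 200, replace = TRUE),
    weight = round(runif(200, 0, 20), 2))
  out <- enforce_one_to_one(d)
  linked <- out[out$status != "unlinked"]
  expect_equal(anyDuplicated(linked$registry_key), 0L)
  expect_equal(nrow(out), 200)
})

test_that("death dedup prefers quality tier, then closest death date", {
  reg <- data.frame(key = c("R1", "R2"),
                    last_contact = c("2000-06-01", "2001-01-01"),
                    stringsAsFactors = FALSE)
  src <- data.frame(source_id = c("S1", "S2", "S3", "S4"),
                    event_date = c("2000-06-04", "2000-07-11",
                                   "2001-01-04", "2001-02-10"),
                    stringsAsFactors = FALSE)
  d <- data.table::data.table(
    source_id = c("S1", "S2", "S3", "S4"),
    registry_key = c("R1", "R1", "R2", "R2"),
    status = c("linked_review", "linked_deterministic",
               "linked_probabilistic", "linked_probabilistic"),
    pass_id = c(5L, 1L, 4L, 4L), weight = c(6, NA, 9, 9))
  out <- dedup_death(d, src, reg)
  # R1: deterministic S2 beats review S1 despite farther death date
  expect_true("S2" %in% out$kept$source_id)
  expect_false("S1" %in% out$kept$source_id)
  # R2: equal tier and weight -> closest to last contact (3 vs 40 days)
  expect_true("S3" %in% out$kept$source_id)
  expect_identical(out$discarded$reason,
                   rep("duplicate_death_record", 2))
})

test_that("death dedup agrees with a brute-force ordering oracle", {
  set.seed(103)
  n_person <- 18
  rows <- list()
  for (p in seq_len(n_person)) {
    k <- sample(1:4, 1)
    for (j in seq_len(k)) {
      rows[[length(rows) + 1L]] <- data.frame(
        registry_key = sprintf("R%02d", p),
        status = sample(c("linked_deterministic", "linked_probabilistic",
                          "linked_review"), 1),
        weight = sample(c(5, 9, 12), 1),
        event_date = format(as.Date("2000-01-01") + sample(0:600, 1)),
        stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, rows)
  d$source_id <- sprintf("S%03d", seq_len(nrow(d)))
  d$pass_id <- 1L
  reg <- data.frame(key = sprintf("R%02d", seq_len(n_person)),
                    last_contact = format(as.Date("2000-06-01") +
                                            sample(0:200, n_person)),
                    stringsAsFactors = FALSE)
  src <- d[, c("source_id", "event_date")]
  out <- dedup_death(data.table::as.data.table(
    d[, c("source_id", "registry_key", "status", "pass_id", "weight")]),
    src, reg)
  tier <- c(linked_deterministic = 3, linked_probabilistic = 2,
            linked_review = 1)
  want <- vapply(split(d, d$registry_key), function(g) {
    lc <- reg$last_contact[match(g$registry_key[1], reg$key)]
    dist <- abs(as.numeric(as.Date(g$event_date) - as.Date(lc)))
    g$source_id[order(-tier[g$status], -g$weight, dist, g$event_date,
                      seq_len(nrow(g)))][1]
  }, character(1))
  kept <- out$kept$source_id[out$kept$status != "unlinked"]
  expect_setequal(kept, unname(want))
  # a survivor always exists per person
  expect_equal(length(kept), n_person)
})

test_that("immigration dedup keeps the earliest landing", {
  src <- data.frame(source_id = c("S1", "S2", "S3"),
                    event_date = c("1995-07-01", "1990-05-01", "2001-01-01"),
                    stringsAsFactors = FALSE)
  d <- data.table::data.table(
    source_id = c("S1", "S2", "S3"),
    registry_key = c("R1", "R1", "R2"),
    status = "linked_deterministic", pass_id = 1L, weight = NA_real_)
  out <- dedup_immigration(d, src)
  expect_true("S2" %in% out$kept$source_id)   # 1990 beats 1995
  expect_false("S1" %in% out$kept$source_id)
  expect_true("S3" %in% out$kept$source_id)   # singletons survive unchanged
})

test_that("immigration dedup equals the min-by-date oracle on a multi-record fixture", {
  set.seed(107)
  persons <- sprintf("R%03d", 1:100)
  reps <- sample(1:4, 100, replace = TRUE)
  d <- data.table::data.table(
    source_id = sprintf("S%03d", seq_len(sum(reps))),
    registry_key = rep(persons, reps),
    status = "linked_deterministic", pass_id = 1L, weight = NA_real_)
  src <- data.frame(source_id = d$source_id,
                    event_date = format(as.Date("1985-01-01") +
                                          sample(0:9000, nrow(d))),
                    stringsAsFactors = FALSE)
  out <- dedup_immigration(d, src)
  want <- vapply(split(seq_len(nrow(d)), d$registry_key), function(ix) {
    d$source_id[ix[which.min(as.Date(src$event_date[ix]))]]
  }, character(1))
  expect_setequal(out$kept$source_id, unname(want))
})

test_that("link keys are shared per person, injective, and salt-stable", {
  d <- data.table::data.table(
    source_id = c("S1", "S2", "S3", "S4"),
    registry_key = c("R1", "R1", "R2", ""),
    status = c("linked_deterministic", "linked_probabilistic",
               "linked_review", "unlinked"),
    pass_id = c(1L, 4L, 5L, NA), weight = c(NA, 9, 6, NA))
  res <- assign_link_keys(d)
  lk <- res$decisions$link_key
  expect_identical(lk[1], lk[2])            # same person, same key
  expect_false(lk[1] == lk[3])
  expect_identical(lk[4], "")               # unlinked records get no key
  expect_equal(anyDuplicated(res$key_map$link_key), 0L)
  # salted keys are stable across runs
  a <- assign_link_keys(d, salt = "pepper")$key_map
  b <- assign_link_keys(d, salt = "pepper")$key_map
  expect_identical(a, b)
  expect_false(identical(a$link_key,
                         assign_link_keys(d, salt = "other")$key_map$link_key))
})
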