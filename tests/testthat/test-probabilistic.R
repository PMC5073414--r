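test_that("field weights take their closed-form values", {
  flat <- suppressWarnings(field_model("x", 0.5, 0.5))
  expect_equal(field_weight(flat, "agree"), 0)
  expect_equal(field_weight(flat, "disagree"), 0)
  m <- field_model("x", 0.9, 0.1)
  expect_equal(field_weight(m, "agree"), log2(9), tolerance = 1e-12)
  expect_equal(field_weight(m, "disagree"), -log2(9), tolerance = 1e-12)
  expect_equal(field_weight(m, "missing"), 0)
  expect_error(field_model("x", 1.2, 0.1), "\\(0,1\\)")
  expect_error(field_model("x", 0.9, 0), "\\(0,1\\)")
  expect_warning(field_model("x", 0.1, 0.9), "non-informative")
})

test_that("pair scoring is additive and order-invariant", {
  models <- list(field_model("a", 0.9, 0.1), field_model("b", 0.9, 0.1),
                 field_model("c", 0.9, 0.1))
  src <- list(a = "X", b = "Y", c = "Z")
  reg <- list(a = "X", b = "Y", c = "Z")
  sc <- score_pair(src, reg, models)
  expect_equal(sc$weight, 3 * log2(9), tolerance = 1e-12)
  expect_true(all(sc$vector == "agree"))
  # all fields missing -> weight 0
  sc0 <- score_pair(list(a = "", b = "", c = ""), reg, models)
  expect_equal(sc0$weight, 0)
  # permuting field order leaves the weight unchanged
  sc_perm <- score_pair(src, reg, models[c(3, 1, 2)])
  expect_equal(sc_perm$weight, sc$weight)
})

test_that("weight classification respects the stated boundary conventions", {
  expect_identical(classify_weight(8, 4, 8), "definite")
  expect_identical(classify_weight(7.999, 4, 8), "possible")
  expect_identical(classify_weight(4, 4, 8), "possible")
  expect_identical(classify_weight(3.999, 4, 8), "nonmatch")
  expect_error(classify_weight(5, 8, 4), "t_lower")
})

test_that("raising m never decreases an agreeing pair's weight", {
  for (u in c(0.05, 0.3)) {
    ms <- seq(0.5, 0.99, by = 0.07)
    w <- vapply(ms, function(m) {
      field_weight(suppressWarnings(field_model("x", m, u)), "agree")
    }, numeric(1))
    expect_true(all(diff(w) >= 0))
  }
})

test_that("assign_matches links clear winners and queues close calls", {
  scored <- data.table::data.table(
    src_row = c(1L, 2L, 2L, 3L, 3L),
    reg_row = c(1L, 2L, 3L, 4L, 5L),
    weight = c(9, 9, 9, 9, 5))
  res <- assign_matches(scored, t_lower = 4, t_upper = 8, delta = 1)
  # single definite candidate -> linked
  expect_true(1L %in% res$linked$src_row)
  # two equally definite candidates -> review (delta rule)
  expect_true(2L %in% res$review$src_row)
  # definite beating runner-up by 4 bits -> linked
  expect_true(3L %in% res$linked$src_row)
  # possible-zone weight -> review
  res2 <- assign_matches(data.table::data.table(src_row = 1L, reg_row = 1L,
                                                weight = 5), 4, 8)
  expect_equal(nrow(res2$review), 1)
  # below t_lower -> neither linked nor queued
  res3 <- assign_matches(data.table::data.table(src_row = 1L, reg_row = 1L,
                                                weight = 2), 4, 8)
  expect_equal(nrow(res3$linked) + nrow(res3$review), 0)
})

test_that("blocked probabilistic assignment equals the all-pairs brute force", {
  sim <- simulate_registries(synthetic_config(n_registry = 60, n_source = 40,
                                              typo_rate = 0.15,
                                              missing_rate = 0.1, seed = 79))
  s <- standardize_records(sim$source, "source_id")
  r <- standardize_records(sim$registry, "key")
  s[, const := "x"]; r[, const := "x"]
  models <- default_field_models()
  spec <- pass_spec(1L, "probabilistic", block_scheme("const"),
                    list(match_field("surname_clean"),
                         match_field("given_first"),
                         match_field("birth_date", "date_transpose_tolerant"),
                         match_field("sex")),
                    t_lower = 4, t_upper = 8)
  res <- run_probabilistic_pass(s, r, spec, models)

  # independent oracle: scalar score_pair over every pair, manual argmax
  use <- models[match(c("surname_clean", "given_first", "birth_date", "sex"),
                      vapply(models, function(m) m$field, character(1)))]
  oracle_link <- list(); oracle_review <- list()
  for (i in seq_len(nrow(s))) {
    w <- vapply(seq_len(nrow(r)), function(j) {
      score_pair(as.list(s[i]), as.list(r[j]), use)$weight
    }, numeric(1))
    ord <- order(-w, seq_along(w))
    top <- ord[1]; gap <- if (length(w) > 1) w[top] - w[ord[2]] else Inf
    if (w[top] >= 8 && gap >= 1) {
      oracle_link[[length(oracle_link) + 1L]] <- c(i, top)
    } else if (w[top] >= 4) {
      oracle_review[[length(oracle_review) + 1L]] <- c(i, top)
    }
  }
  ol <- do.call(rbind, oracle_link)
  expect_equal(nrow(res$decisions), NROW(ol))
  expect_identical(sort(res$decisions$source_id), sort(s$source_id[ol[, 1]]))
  expect_identical(res$decisions$registry_key[order(res$decisions$source_id)],
                   r$key[ol[order(s$source_id[ol[, 1]]), 2]])
  orv <- do.call(rbind, oracle_review)
  expect_equal(nrow(res$review_queue), NROW(orv))
})

test_that("missing field models for a probabilistic pass are a configuration error", {
  std <- std_mini()
  spec <- pass_spec(1L, "probabilistic", block_scheme("sex"),
                    list(match_field("surname_clean")),
                    t_lower = 4, t_upper = 8)
  expect_error(run_probabilistic_pass(std$source, std$registry, spec,
                                      models = list(field_model("sex", 0.9, 0.5))),
               "surname_clean")
})

test_that("EM recovers known parameters and converges from the truth", {
  m_true <- c(0.95, 0.90, 0.85)
  u_true <- c(0.05, 0.10, 0.20)
  set.seed(83)
  x <- simulate_comparison_vectors(20000, m_true, u_true, p = 0.2)
  fit <- em_estimate(x, m_init = 0.8, u_init = 0.2, p_init = 0.5)
  expect_true(fit$converged)
  expect_true(all(abs(fit$m - m_true) < 0.03))
  expect_true(all(abs(fit$u - u_true) < 0.03))
  expect_lt(abs(fit$p - 0.2), 0.03)
  # initialized at the truth, the fixed point is reached almost immediately
  fit2 <- em_estimate(x, m_init = m_true, u_init = u_true, p_init = 0.2,
                      tol = 0.01)
  expect_lte(fit2$iterations, 2)
  expect_true(fit2$converged)
})

test_that("EM relabels a class-swapped initialization so that m > u", {
  m_true <- c(0.95, 0.9)
  u_true <- c(0.05, 0.1)
  set.seed(89)
  x <- simulate_comparison_vectors(10000, m_true, u_true, p = 0.2)
  fit <- em_estimate(x, m_init = u_true, u_init = m_true, p_init = 0.8)
  expect_true(mean(fit$m) > mean(fit$u))
  expect_true(all(abs(fit$m - m_true) < 0.05))
})

test_that("EM rejects unidentifiable or degenerate input", {
  expect_error(em_estimate(matrix(1, 10, 1)), "2 fields")
  expect_error(em_estimate(matrix(1, 10, 3)), "degenerate")
})

test_that("precision and recall respond monotonically to the upper threshold", {
  sim <- simulate_registries(synthetic_config(n_registry = 800,
                                              n_source = 400,
                                              typo_rate = 0.15,
                                              missing_rate = 0.1, seed = 97))
  s <- standardize_records(sim$source, "source_id")
  r <- standardize_records(sim$registry, "key")
  spec_at <- function(tu) {
    pass_spec(1L, "probabilistic", block_scheme("sex"),
              list(match_field("surname_clean"), match_field("given_first"),
                   match_field("birth_date", "date_transpose_tolerant"),
                   match_field("sex")),
              t_lower = 2, t_upper = tu)
  }
  prec <- rec <- numeric()
  for (tu in c(4, 8, 12)) {
    res <- run_probabilistic_pass(s, r, spec_at(tu), default_field_models())
    dec <- res$decisions
    truth <- sim$truth$registry_key[match(dec$source_id, sim$truth$source_id)]
    correct <- sum(dec$registry_key == truth & truth != "")
    prec <- c(prec, if (nrow(dec)) correct / nrow(dec) else 1)
    rec <- c(rec, correct / sum(sim$truth$registry_key != ""))
  }
  expect_true(all(diff(rec) <= 0))       # stricter threshold links less
  expect_true(all(diff(prec) >= -1e-12)) # but never less precisely
})
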