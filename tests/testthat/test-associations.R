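make_scores <- function(n, grp, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      participant_id = sprintf("%s%03d", substr(grp, 1, 1), 1:n),
      group = grp,
      cars_total = if (grp == "autistic") stats::rnorm(n, 35, 3) else NA_real_,
      aq_total = stats::rnorm(n, 70, 12),
      aq_social_skills = stats::rnorm(n, 14, 3),
      aq_attention_switching = stats::rnorm(n, 14, 3),
      aq_attention_to_detail = stats::rnorm(n, 14, 3),
      aq_communication = stats::rnorm(n, 14, 3),
      aq_imagination = stats::rnorm(n, 14, 3)
    )
  })
}

make_indices <- function(scores, f) {
  tibble::tibble(
    participant_id = scores$participant_id, group = scores$group,
    log_ratio_index = f(scores), individual_dp_ms = 1000 + 100 * f(scores),
    dp_run_bins = 4
  )
}

test_that("Pearson correlations match hand-computed reference values", {
  sc <- make_scores(5, "autistic", 1)
  sc$aq_total <- c(1, 2, 3, 4, 5)
  idx <- make_indices(sc, function(s) c(2, 1, 4, 3, 5))
  res <- correlation_suite(idx, sc)
  row <- res[res$measure == "aq_total" & res$index == "log_ratio_index", ]
  expect_equal(row$r, 0.8, tolerance = 1e-12)
  expect_equal(row$n, 5)
  # perfect linearity
  idx2 <- make_indices(sc, function(s) 2 * s$aq_total + 1)
  res2 <- correlation_suite(idx2, sc)
  row2 <- res2[res2$measure == "aq_total" & res2$index == "log_ratio_index", ]
  expect_equal(row2$r, 1, tolerance = 1e-12)
  expect_lt(row2$p, 1e-6)
})

test_that("Fisher CIs contain r and FDR adjustment is monotone within families", {
  sc <- make_scores(40, "autistic", 2)
  idx <- make_indices(sc, function(s) {
    -0.05 * s$aq_communication + stats::rnorm(nrow(s), 0, 0.2)
  })
  res <- correlation_suite(idx, sc)
  ok <- !is.na(res$r)
  expect_true(all(res$ci_lo[ok] <= res$r[ok] & res$r[ok] <= res$ci_hi[ok]))
  fam <- res[!is.na(res$family) & res$index == "log_ratio_index", ]
  expect_equal(nrow(fam), 5)
  expect_true(all(fam$fdr_p >= fam$p - 1e-12))
  # monotone in the raw p order (ties allowed after adjustment)
  expect_true(all(diff(fam$fdr_p[order(fam$p)]) >= -1e-12))
  # CARS rows exist only for the group that has CARS
  expect_true(all(res$group[res$measure == "cars_total"] == "autistic"))
})

test_that("missing divergence points are removed pairwise, small n flagged", {
  sc <- make_scores(10, "autistic", 3)
  idx <- make_indices(sc, function(s) seq_len(nrow(s)))
  idx$individual_dp_ms[1:4] <- NA
  res <- correlation_suite(idx, sc)
  dp_row <- res[res$measure == "aq_total" & res$index == "divergence_point", ]
  expect_equal(dp_row$n, 6)
  lr_row <- res[res$measure == "aq_total" & res$index == "log_ratio_index", ]
  expect_equal(lr_row$n, 10)
  idx$individual_dp_ms[1:8] <- NA
  res2 <- correlation_suite(idx, sc)
  dp2 <- res2[res2$measure == "aq_total" & res2$index == "divergence_point", ]
  expect_true(is.na(dp2$r))
  expect_match(dp2$note, "fewer than 3")
})

test_that("the score-link sign is recovered through the full association chain", {
  # the default link couples slower/weaker prediction to higher AQ, so
  # AQ vs log-ratio-index correlations should come out negative at the
  # generator's own effect size (single-cohort r is noisy at n ~ 50, so
  # the sign is checked across seeds and groups)
  rs <- unlist(lapply(1:5, function(seed) {
    coh <- simulate_cohort(cohort_spec(seed = seed), level = "tensor")
    idx <- participant_indices(coh$tensor)
    res <- correlation_suite(idx, coh$scores)
    res$r[res$measure == "aq_total" & res$index == "log_ratio_index"]
  }))
  expect_length(rs, 10)
  expect_lt(mean(rs), -0.1)
  expect_gte(mean(rs < 0), 0.8)
})

test_that("the accuracy model recovers group effects and flags separation", {
  sim_resp <- function(delta, seed, n1 = 40, n2 = 40) {
    withr::with_seed(seed, {
      rows <- list()
      for (g in c("a", "b")) {
        n <- if (g == "a") n1 else n2
        for (i in seq_len(n)) {
          u <- stats::rnorm(1, 0, 0.8)
          eta <- 2.8 + (g == "a") * delta + u
          rows[[length(rows) + 1]] <- tibble::tibble(
            participant_id = paste0(g, i), group = g,
            trial_id = 1:24,
            correct = as.integer(stats::runif(24) < stats::plogis(eta))
          )
        }
      }
      dplyr::bind_rows(rows)
    })
  }
  # null effect: estimate small relative to its SE in most replicates
  hits <- 0
  for (seed in 1:6) {
    fit <- suppressWarnings(accuracy_model(sim_resp(0, seed), ref_group = "b"))
    b <- fit$coefficients[fit$coefficients$term == "groupa", ]
    if (abs(b$estimate) < 2 * b$se) hits <- hits + 1
  }
  expect_gte(hits, 5)
  # injected effect recovered within 2 SE
  hits2 <- 0
  for (seed in 1:4) {
    fit <- suppressWarnings(accuracy_model(sim_resp(1.0, seed, 45, 52), ref_group = "b"))
    b <- fit$coefficients[fit$coefficients$term == "groupa", ]
    if (abs(b$estimate - 1.0) < 2 * b$se) hits2 <- hits2 + 1
  }
  expect_gte(hits2, 3)
  # all-correct responses: separation flagged, no silent estimate
  resp <- sim_resp(0, 1, 5, 5)
  resp$correct <- 1L
  fit <- accuracy_model(resp)
  expect_true(fit$separation)
  expect_null(fit$coefficients)
})
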