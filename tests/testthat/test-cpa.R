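# Five participants, six bins, constructed target-minus-unrelated
# differences with a known cluster structure (t_crit(4 df) = 2.776).
toy_tensor <- function() {
  # trial-level occupancies chosen so participant-level proportions give
  # strong positive differences in bins 2-4, nothing elsewhere
  tgt <- lapply(1:5, function(i) {
    m <- matrix(0L, 4, 6)
    m[, 3:5] <- 1L                      # bins 2,3,4
    if (i == 1) m[1, 3:5] <- 0L         # heterogeneity in every bin
    m
  })
  unrel <- lapply(1:5, function(i) {
    m <- matrix(0L, 4, 6)
    m[1, ] <- 1L
    m
  })
  make_tensor(target = tgt, unrelated = unrel, group = "g")
}

test_that("per-bin t statistics match the reference paired t-test", {
  tensor <- toy_tensor()
  suppressWarnings(cs <- cluster_stats(tensor, "target", "g"))
  tgt <- prop_matrix(tensor, "target", "g")
  unr <- prop_matrix(tensor, "unrelated", "g")
  for (b in 1:6) {
    d <- tgt[, b] - unr[, b]
    if (stats::sd(d) > 1e-12) {
      ref <- stats::t.test(tgt[, b], unr[, b], paired = TRUE)
      expect_equal(cs$bins$t[b], unname(ref$statistic), tolerance = 1e-10)
      expect_equal(cs$bins$df[b], unname(ref$parameter))
    } else {
      expect_true(is.na(cs$bins$t[b]))
    }
  }
})

test_that("clusters are maximal same-sign supra-threshold runs of at least two bins", {
  tensor <- toy_tensor()
  suppressWarnings(cs <- cluster_stats(tensor, "target", "g"))
  expect_equal(nrow(cs$clusters), 1)
  expect_equal(cs$clusters$start_ms, 2 * 50 + 25)
  expect_equal(cs$clusters$end_ms, 4 * 50 + 25)
  expect_equal(cs$clusters$sum_t,
               sum(cs$bins$t[3:5]), tolerance = 1e-12)
})

test_that("null data and isolated supra-threshold bins yield no clusters", {
  z <- lapply(1:5, function(i) matrix(0L, 4, 6))
  suppressWarnings(
    cs0 <- cluster_stats(make_tensor(target = z, unrelated = z, group = "g"),
                         "target", "g"))
  expect_equal(nrow(cs0$clusters), 0)
  # one strong isolated bin: bins 2 only
  tgt <- lapply(1:5, function(i) { m <- matrix(0L, 4, 6); m[, 3] <- 1L; m })
  tgt[[1]][1, 3] <- 0L
  suppressWarnings(
    cs1 <- cluster_stats(make_tensor(target = tgt, unrelated = z,
                                     group = "g"), "target", "g"))
  expect_true(any(cs1$bins$supra, na.rm = TRUE))
  expect_equal(nrow(cs1$clusters), 0)
})

test_that("Monte-Carlo permutation p matches exhaustive sign-flip enumeration", {
  tensor <- toy_tensor()
  suppressWarnings(
    res <- permutation_test(tensor, "target", "g", n_perm = 1000, seed = 5))
  expect_equal(nrow(res), 1)
  tgt <- prop_matrix(tensor, "target", "g")
  unr <- prop_matrix(tensor, "unrelated", "g")
  p_exact <- exact_perm_p(tgt - unr, res$sum_t)
  band <- 1.96 * sqrt(p_exact * (1 - p_exact) / 1000) + 2 / 1000
  expect_lt(abs(res$p - p_exact), band + 1e-9)
  expect_gte(res$p, 1 / 1001)
})

test_that("permutation p-values are seed-deterministic and order-invariant", {
  spec <- small_spec(n1 = 5, n2 = 2, seed = 3)
  tensor <- simulate_cohort(spec, level = "tensor")$tensor
  r1 <- permutation_test(tensor, "target", "autistic", n_perm = 200, seed = 9)
  r2 <- permutation_test(tensor, "target", "autistic", n_perm = 200, seed = 9)
  expect_equal(r1$p, r2$p)
  shuffled <- tensor[rev(seq_len(nrow(tensor))), ]
  r3 <- permutation_test(shuffled, "target", "autistic", n_perm = 200,
                         seed = 9)
  expect_equal(r1$p, r3$p)
  expect_error(permutation_test(tensor, "target", "autistic", n_perm = 0),
               "n_perm")
})

test_that("cpa_analysis covers all comparisons and groups", {
  spec <- small_spec(n1 = 5, n2 = 5, seed = 4)
  tensor <- simulate_cohort(spec, level = "tensor")$tensor
  res <- cpa_analysis(tensor, n_perm = 100, seed = 2)
  expect_setequal(unique(res$group), c("autistic", "nt"))
  expect_true(all(res$n_bins >= 2))
  expect_true(all(res$p >= 1 / 101 & res$p <= 1))
})
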