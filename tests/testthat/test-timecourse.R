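test_that("proportion curves aggregate participant means with CIs", {
  ones <- list(matrix(1L, 4, 10), matrix(1L, 4, 10))
  tensor <- make_tensor(target = ones)
  cur <- proportion_curves(tensor)
  tgt <- cur[cur$condition == "target", ]
  expect_true(all(tgt$prop == 1))
  expect_true(all(tgt$ci_hi - tgt$ci_lo == 0))
  # one participant, occupancy in half the trials
  half <- list(rbind(matrix(1L, 2, 10), matrix(0L, 2, 10)))
  cur2 <- proportion_curves(make_tensor(target = half))
  expect_true(all(cur2$prop[cur2$condition == "target"] == 0.5))
  expect_error(prop_matrix(tensor, "target", "nope"), "empty group")
})

test_that("the log-gaze proportion ratio follows the printed formula exactly", {
  one_zero <- list(matrix(1L, 1, 1))
  zero <- list(matrix(0L, 1, 1))
  t1 <- make_tensor(target = one_zero, unrelated = zero)
  expect_equal(log_ratio_series(t1)$value, log(3), tolerance = 1e-15)
  t2 <- make_tensor(target = zero, unrelated = one_zero)
  expect_equal(log_ratio_series(t2)$value, -log(3), tolerance = 1e-15)
  # equal occupancies cancel
  t3 <- make_tensor(target = one_zero, unrelated = one_zero)
  expect_identical(log_ratio_series(t3)$value, 0)
})

test_that("the log-ratio is exactly antisymmetric under swapping its conditions", {
  spec <- small_spec(n1 = 2, n2 = 2, seed = 8)
  tensor <- simulate_cohort(spec, level = "tensor")$tensor
  fwd <- log_ratio_series(tensor, "trial")
  swapped <- tensor
  swapped$target <- tensor$unrelated
  swapped$unrelated <- tensor$target
  rev <- log_ratio_series(swapped, "trial")
  expect_equal(fwd$value, -rev$value, tolerance = 1e-12)
  # participant level too
  expect_equal(log_ratio_series(tensor, "participant")$value,
               -log_ratio_series(swapped, "participant")$value,
               tolerance = 1e-12)
})

test_that("participant indices average the prediction window and locate sustained runs", {
  # target occupied from bin 20 (1000 ms) on; agent before that
  tgt <- matrix(0L, 3, 50); tgt[, 21:50] <- 1L
  agt <- matrix(0L, 3, 50); agt[, 1:20] <- 1L
  tensor <- make_tensor(target = list(tgt), agent = list(agt))
  idx <- participant_indices(tensor)
  # 26 window bins: bins 0..19 give -log(1/0.5... ) 0 vs 0 -> log(0.5/0.5)=0
  # wait: target 0, unrelated 0 -> 0; bins 20..25 give log(1.5/0.5)=log 3
  expect_equal(idx$log_ratio_index, 6 * log(3) / 26, tolerance = 1e-12)
  expect_equal(idx$individual_dp_ms, 1000)
  # all-zero participant
  z <- make_tensor(target = list(matrix(0L, 2, 50)))
  expect_identical(participant_indices(z)$log_ratio_index, 0)
})

test_that("the prediction window uses bins 0-25 only", {
  tgt <- matrix(0L, 1, 50); tgt[, 27] <- 1L  # bin 26 = [1300, 1350)
  tensor <- make_tensor(target = list(tgt))
  expect_equal(participant_indices(tensor)$log_ratio_index, 0)
  tgt2 <- matrix(0L, 1, 50); tgt2[, 26] <- 1L  # bin 25 = [1250, 1300)
  tensor2 <- make_tensor(target = list(tgt2))
  expect_equal(participant_indices(tensor2)$log_ratio_index, log(3) / 26,
               tolerance = 1e-12)
})

test_that("a participant whose target never beats agent-related has no divergence point", {
  tgt <- matrix(0L, 1, 50)
  agt <- matrix(1L, 1, 50)
  idx <- participant_indices(make_tensor(target = list(tgt),
                                         agent = list(agt)))
  expect_true(is.na(idx$individual_dp_ms))
  expect_type(idx$individual_dp_ms, "double")  # missing, not a sentinel
})

test_that("indices are invariant to trial and participant order", {
  spec <- small_spec(n1 = 3, n2 = 2, seed = 14)
  tensor <- simulate_cohort(spec, level = "tensor")$tensor
  shuffled <- tensor[sample.int(nrow(tensor)), ]
  a <- participant_indices(tensor)
  b <- participant_indices(shuffled)
  b <- b[match(a$participant_id, b$participant_id), ]
  expect_equal(a$log_ratio_index, b$log_ratio_index)
  expect_equal(a$individual_dp_ms, b$individual_dp_ms)
})
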