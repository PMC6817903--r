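test_that("network spec validates its fields", {
  s <- network_spec(10)
  expect_equal(s$hidden_widths, c(20L, 2L))
  expect_equal(s$max_epochs, 1000L)
  expect_equal(s$error_goal, 1e-4)
  expect_error(network_spec(0), "input_width")
  expect_error(network_spec(10, error_goal = 0))
})

test_that("analytic gradients match finite differences", {
  set.seed(5)
  X <- matrix(runif(12), 4, 3)
  Y <- matrix(runif(8), 4, 2)
  layers <- saiopt:::init_weights(c(3, 5, 2, 2), seed = 9)
  acts <- saiopt:::forward_pass(layers, X)
  grads <- saiopt:::backward_pass(layers, acts, Y)
  loss_at <- function(ls) {
    a <- saiopt:::forward_pass(ls, X)
    saiopt:::mse_loss(a[[length(a)]], Y)
  }
  h <- 1e-6
  for (l in seq_along(layers)) {
    for (idx in sample(length(layers[[l]]$W), 4)) {
      pert <- layers
      pert[[l]]$W[idx] <- pert[[l]]$W[idx] + h
      num <- (loss_at(pert) - loss_at(layers)) / h
      expect_equal(grads[[l]]$W[idx], num, tolerance = 1e-4)
    }
    pert <- layers
    pert[[l]]$b[1] <- pert[[l]]$b[1] + h
    num <- (loss_at(pert) - loss_at(layers)) / h
    expect_equal(grads[[l]]$b[1], num, tolerance = 1e-4)
  }
})

test_that("training is deterministic given the seed and loss history is non-increasing", {
  dm <- simplex_doses(12, seed = 31)
  resp <- simulate_bioassay(dm, recovery_ground_truth(), seed = 32)
  tg <- cbind(absorbance = resp$absorbance, swelling = resp$swelling_ratio)
  spec <- network_spec(10, max_epochs = 300, seed = 5)
  m1 <- fit_surrogate(dm, tg, spec)
  m2 <- fit_surrogate(dm, tg, spec)
  expect_identical(m1$layers, m2$layers)
  expect_identical(predict(m1, dm), predict(m2, dm))
  expect_false(is.unsorted(rev(m1$history)))
  expect_lt(m1$history[length(m1$history)], m1$history[1])
})

test_that("constant targets are reproduced in the degenerate fit", {
  dm <- simplex_doses(9, seed = 33)
  tg <- cbind(absorbance = rep(0.4, 9), swelling = rep(10, 9))
  m <- fit_surrogate(dm, tg, network_spec(10, max_epochs = 3000,
                                          error_goal = 1e-8, seed = 1))
  expect_lt(max(abs(predict(m, dm) - tg)), 1e-3)
})

test_that("a noiseless linear map is recovered within 5% held out", {
  dm <- simplex_doses(40, seed = 21)
  gt <- recovery_ground_truth(sd_abs = 0, sd_swell = 0)
  Y <- true_responses(dm, gt)
  rownames(Y) <- rownames(dm)
  m <- fit_surrogate(dm[1:32, ], Y[1:32, ],
                     network_spec(10, max_epochs = 20000, error_goal = 1e-10,
                                  momentum = 0.9, weight_decay = 1e-4,
                                  seed = 4))
  pred <- predict(m, dm[33:40, ])
  expect_lt(max(abs(pred - Y[33:40, ]) / abs(Y[33:40, ])), 0.05)
  # probing at the design midpoint stays close to the analytic value
  mid <- colMeans(dm)
  truth <- true_responses(matrix(mid, 1, dimnames = list(NULL, names(mid))), gt)
  expect_lt(max(abs(predict(m, mid) - truth) / abs(truth)), 0.05)
  # feeding back a training row interpolates its target
  expect_lt(max(abs(predict(m, dm[1, ]) - Y[1, ]) / abs(Y[1, ])), 0.05)
})

test_that("prediction is deterministic, shape-checked, and scaling-consistent", {
  dm <- simplex_doses(12, seed = 35)
  resp <- simulate_bioassay(dm, recovery_ground_truth(), seed = 36)
  tg <- cbind(absorbance = resp$absorbance, swelling = resp$swelling_ratio)
  m <- fit_surrogate(dm, tg, network_spec(10, max_epochs = 200, seed = 2))
  expect_identical(predict(m, dm[3, ]), predict(m, dm[3, ]))
  expect_error(predict(m, dm[, 1:5]), "input columns")
  # manual scaled pipeline equals predict()
  X <- saiopt:::apply_scaler(m$in_scaler, dm)
  acts <- saiopt:::forward_pass(m$layers, X)
  manual <- saiopt:::invert_scaler(m$out_scaler, acts[[length(acts)]])
  expect_equal(unname(predict(m, dm)), unname(manual), tolerance = 1e-9)
})

test_that("nine training rows can be driven below the error goal", {
  pt <- sai_peak_table()
  dm <- peak_doses(pt, sai_doses())
  resp <- simulate_bioassay(dm, seed = 11)
  tg <- cbind(absorbance = resp$absorbance, swelling = resp$swelling_ratio)
  rownames(tg) <- resp$sample
  keep <- rownames(dm) != "S5"
  m <- fit_surrogate(dm[keep, ], tg[keep, ],
                     network_spec(10, max_epochs = 20000, error_goal = 1e-4,
                                  momentum = 0.9, seed = 2))
  expect_true(m$converged)
  expect_lte(m$final_loss, 1e-4)
})

test_that("holdout validation reports prediction vs observation", {
  pt <- sai_peak_table()
  dm <- peak_doses(pt, sai_doses())
  resp <- simulate_bioassay(dm, seed = 11)
  tg <- cbind(absorbance = resp$absorbance, swelling = resp$swelling_ratio)
  rownames(tg) <- resp$sample
  spec <- network_spec(10, max_epochs = 2000, momentum = 0.9, seed = 3)
  v <- holdout_validate(dm, tg, "S5", spec)
  expect_s3_class(v, "validation_record")
  expect_equal(v$holdout_id, "S5")
  expect_equal(names(v$predicted), c("absorbance", "swelling"))
  expect_true(all(v$abs_error >= 0))
  expect_error(holdout_validate(dm, tg, "S99", spec), "unknown holdout")
  # a holdout duplicating a training row is predicted almost exactly
  dm2 <- rbind(dm, S5b = dm["S1", ])
  tg2 <- rbind(tg, S5b = tg["S1", ])
  v2 <- holdout_validate(dm2, tg2, "S5b",
                         network_spec(10, max_epochs = 5000,
                                      error_goal = 1e-7, momentum = 0.9,
                                      seed = 3))
  expect_lt(max(v2$rel_error), 0.01)
})

test_that("fit rejects degenerate inputs", {
  dm <- simplex_doses(4, seed = 37)
  tg <- cbind(absorbance = runif(4), swelling = runif(4))
  expect_error(fit_surrogate(dm[1, , drop = FALSE], tg[1, , drop = FALSE],
                             network_spec(10)), "at least 2")
  tg2 <- tg; tg2[1, 1] <- NA
  expect_error(fit_surrogate(dm, tg2, network_spec(10)), "non-finite")
})

test_that("surrogate survives a JSON round trip", {
  dm <- simplex_doses(10, seed = 39)
  resp <- simulate_bioassay(dm, recovery_ground_truth(), seed = 40)
  tg <- cbind(absorbance = resp$absorbance, swelling = resp$swelling_ratio)
  m <- fit_surrogate(dm, tg, network_spec(10, max_epochs = 150, seed = 6))
  f <- withr::local_tempfile(fileext = ".json")
  save_surrogate(m, f)
  m2 <- load_surrogate(f)
  expect_equal(predict(m2, dm), predict(m, dm), tolerance = 1e-12)
})
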