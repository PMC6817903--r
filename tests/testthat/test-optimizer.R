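# closed-form monotone surrogate used throughout: absorbance rises with the
# embedded A and B dosages only, swelling is flat and always acceptable
monotone_model <- function(X) {
  cbind(0.1 + 0.08 * X[, "A"] + 0.06 * X[, "B"], rep(5, nrow(X)))
}

box_midpoint <- function(ranges) colMeans(rbind(ranges["lo", ], ranges["hi", ]))

test_that("component ranges default to the published box and validate", {
  r <- component_ranges()
  expect_equal(colnames(r), LETTERS[1:6])
  expect_equal(unname(r[, "C"]), c(5, 10))
  expect_equal(unname(r[, "A"]), c(0.5, 4))
  expect_error(component_ranges(list(A = c(2, 1))), "lower bound exceeds")
  expect_error(component_ranges(list(A = c(-1, 1))), "finite and >= 0")
})

test_that("candidate sampling stays in bounds and is seed-deterministic", {
  r <- component_ranges()
  x <- sample_candidates(r, 10000, seed = 3)
  expect_true(all(sweep(x, 2, r["lo", ], ">=")))
  expect_true(all(sweep(x, 2, r["hi", ], "<=")))
  # mean near interval midpoint (law of large numbers)
  expect_equal(unname(colMeans(x)), unname(box_midpoint(r)), tolerance = 0.02)
  expect_identical(sample_candidates(r, 50, seed = 9),
                   sample_candidates(r, 50, seed = 9))
  deg <- component_ranges(list(A = c(2, 2), B = c(2, 2)))
  expect_true(all(sample_candidates(deg, 5, seed = 1) == 2))
})

test_that("candidate embedding zeroes eliminated components and conserves dose", {
  cand <- sample_candidates(component_ranges(), 20, seed = 4)
  emb <- embed_candidates(cand, LETTERS[1:10], reference_dose = 12.5)
  expect_equal(colnames(emb), LETTERS[1:10])
  expect_true(all(emb[, c("G", "H", "I", "J")] == 0))
  expect_equal(unname(rowSums(emb)), rep(12.5, 20), tolerance = 1e-9)
  # proportions within a row are preserved
  expect_equal(unname(emb[1, "C"] / emb[1, "A"]),
               unname(cand[1, "C"] / cand[1, "A"]), tolerance = 1e-12)
})

test_that("screening accepts only candidates strictly inside the criteria", {
  r <- component_ranges()
  thr <- monotone_model(embed_candidates(
    matrix(box_midpoint(r), 1, dimnames = list(NULL, colnames(r))),
    LETTERS[1:10]))[1, 1]
  crit <- acceptance_criteria(absorbance_max = thr, swelling_max = 19.198)
  cs <- screen_candidates(monotone_model, r, crit, target_size = 50, seed = 7,
                          input_labels = LETTERS[1:10])
  expect_s3_class(cs, "candidate_set")
  expect_equal(nrow(cs$proportions), 50L)
  re <- monotone_model(embed_candidates(cs$proportions, LETTERS[1:10]))
  expect_true(all(re[, 1] < crit$absorbance_max))
  expect_true(all(re[, 2] < crit$swelling_max))
  # determinism
  cs2 <- screen_candidates(monotone_model, r, crit, target_size = 50,
                           seed = 7, input_labels = LETTERS[1:10])
  expect_identical(cs$proportions, cs2$proportions)
  expect_identical(cs$draws_used, cs2$draws_used)
})

test_that("infinite thresholds accept the first draws; impossible ones error", {
  r <- component_ranges()
  open <- acceptance_criteria(Inf, Inf)
  cs <- screen_candidates(monotone_model, r, open, target_size = 10, seed = 2,
                          input_labels = LETTERS[1:10])
  expect_equal(cs$draws_used, 1000L) # one batch
  expect_equal(nrow(cs$proportions), 10L)
  expect_identical(cs$proportions,
                   sample_candidates(r, 1000, seed = 2)[
                     seq_len(10), , drop = FALSE])
  shut <- acceptance_criteria(-Inf, -Inf)
  expect_error(screen_candidates(monotone_model, r, shut, target_size = 5,
                                 max_draws = 2000, seed = 2,
                                 input_labels = LETTERS[1:10]),
               "no candidate met the criteria")
})

test_that("tight absorbance screening skews accepted A below its midpoint", {
  r <- component_ranges()
  thr <- monotone_model(embed_candidates(
    matrix(box_midpoint(r), 1, dimnames = list(NULL, colnames(r))),
    LETTERS[1:10]))[1, 1]
  crit <- acceptance_criteria(absorbance_max = thr, swelling_max = 19.198)
  mid_a <- box_midpoint(r)["A"]
  ok <- 0L
  for (s in 1:50) {
    cs <- screen_candidates(monotone_model, r, crit, target_size = 50,
                            seed = s, input_labels = LETTERS[1:10])
    if (mean(cs$proportions[, "A"]) < mid_a) ok <- ok + 1L
  }
  expect_gte(ok / 50, 0.95)
})

test_that("consensus matches a sort-based median oracle and handles edge cases", {
  r <- component_ranges()
  crit <- acceptance_criteria(Inf, Inf)
  cs <- screen_candidates(monotone_model, r, crit, target_size = 50, seed = 11,
                          input_labels = LETTERS[1:10])
  cons <- consensus_proportion(cs)
  oracle <- apply(cs$proportions, 2, function(v) {
    s <- sort(v)
    (s[25] + s[26]) / 2
  })
  expect_equal(cons, oracle, tolerance = 1e-15)
  expect_equal(consensus_proportion(cs, "mean"), colMeans(cs$proportions))
  # single candidate is its own consensus; 3-point median picks the middle
  cs1 <- cs
  cs1$proportions <- cs$proportions[1, , drop = FALSE]
  expect_equal(consensus_proportion(cs1), cs$proportions[1, ])
  cs3 <- cs
  cs3$proportions <- matrix(c(1, 2, 9), 3, 6,
                            dimnames = list(NULL, colnames(r)))
  expect_equal(unname(consensus_proportion(cs3)), rep(2, 6))
})

test_that("consensus aggregation concentrates relative to single candidates", {
  r <- component_ranges()
  crit <- acceptance_criteria(Inf, Inf)
  cons <- t(sapply(1:20, function(s) {
    consensus_proportion(screen_candidates(monotone_model, r, crit,
                                           target_size = 50, seed = s,
                                           input_labels = LETTERS[1:10]))
  }))
  singles <- screen_candidates(monotone_model, r, crit, target_size = 50,
                               seed = 99, input_labels = LETTERS[1:10])$proportions
  expect_true(all(apply(cons, 2, sd) < apply(singles, 2, sd)))
})

test_that("confirmation re-predicts, flags criteria, and attaches ten-point", {
  r <- component_ranges()
  crit <- acceptance_criteria(0.539, 19.198)
  p <- c(A = 1.2500, B = 0.8313, C = 9.0625, D = 2.3500, E = 1.3475,
         F = 1.7675)
  conf <- confirm_proportion(monotone_model, p, crit, ranges = r,
                             input_labels = LETTERS[1:10])
  expect_equal(unname(round_proportion(conf$ten_point)),
               c(0.7526, 0.5005, 5.4565, 1.4149, 0.8113, 1.0642))
  # analytic evaluation of the closed-form surrogate
  truth <- monotone_model(embed_candidates(
    matrix(p, 1, dimnames = list(NULL, names(p))), LETTERS[1:10]))[1, ]
  expect_equal(unname(conf$prediction), truth, tolerance = 1e-6)
  expect_true(confirm_proportion(monotone_model, p,
                                 acceptance_criteria(Inf, Inf),
                                 input_labels = LETTERS[1:10])$pass)
  expect_warning(confirm_proportion(monotone_model,
                                    c(A = 99, B = 1, C = 6, D = 2, E = 1,
                                      F = 1), crit, ranges = r,
                                    input_labels = LETTERS[1:10]),
                 "outside sampling box")
})
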