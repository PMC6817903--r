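test_that("mean normalization divides by the mean", {
  expect_equal(mean_normalize(c(1, 2, 3)), c(0.5, 1.0, 1.5))
  expect_equal(mean_normalize(rep(4.2, 5)), rep(1, 5))
  a_seq <- unclass(sai_peak_table())[, "A"]
  n <- mean_normalize(a_seq)
  expect_equal(mean(n), 1, tolerance = 1e-12)
  expect_equal(unname(n[1]), 7.2004 / mean(a_seq))
  expect_error(mean_normalize(c(-1, 0, 1)), "mean must be > 0")
})

test_that("relational coefficients hit their closed-form boundary values", {
  # a factor identical to the behavior: delta_min = 0 there, xi = 1
  x0 <- c(1, 2, 3)
  xi <- deng_coefficients(x0, cbind(f1 = x0, f2 = c(3, 2, 1)), rho = 0.5)
  expect_true(all(xi > 0 & xi <= 1))
  expect_equal(unname(xi[, "f1"]), rep(1, 3))
  # at the position attaining delta_max (with delta_min = 0, rho = 0.5):
  # xi = rho / (1 + rho) = 1/3
  expect_equal(min(xi), 1 / 3)
  expect_equal(gray_correlation_degree(xi[, "f1"]), 1)
  expect_equal(gray_correlation_degree(c(1, 1 / 3)), 2 / 3)
})

test_that("pipeline coefficients match the brute-force oracle", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    k <- sample(1:5, 1)
    x0 <- runif(n, 0.1, 5)
    fac <- matrix(runif(n * k, 0.1, 5), n, k)
    colnames(fac) <- paste0("f", seq_len(k))
    rho <- runif(1, 0.05, 0.95)
    xi <- deng_coefficients(x0, fac, rho = rho)
    expect_equal(unname(xi), deng_oracle(x0, fac, rho), tolerance = 1e-12)
    expect_equal(unname(colMeans(xi)),
                 unname(colMeans(deng_oracle(x0, fac, rho))),
                 tolerance = 1e-12)
  }
})

test_that("degenerate all-identical factors warn and give coefficient 1", {
  x0 <- c(1, 2, 3)
  expect_warning(xi <- deng_coefficients(x0, cbind(a = x0, b = 2 * x0)),
                 "identical")
  expect_true(all(xi == 1))
})

test_that("grey analysis is scale invariant and permutation stable", {
  set.seed(7)
  x0 <- runif(8, 0.5, 2)
  fac <- matrix(runif(40, 0.1, 3), 8, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
  g <- gca(x0, fac)
  # multiplying any raw sequence by c > 0 changes nothing
  fac2 <- fac
  fac2[, 2] <- fac2[, 2] * 137
  g2 <- gca(x0 * 0.01, fac2)
  expect_equal(g2$degrees, g$degrees, tolerance = 1e-12)
  expect_equal(g2$ranking, g$ranking)
  # permuting sample order permutes coefficient rows, degrees unchanged
  perm <- sample(8)
  g3 <- gca(x0[perm], fac[perm, ])
  expect_equal(g3$degrees, g$degrees, tolerance = 1e-12)
  expect_equal(unname(g3$coefficients), unname(g$coefficients[perm, ]))
})

test_that("degree is non-decreasing in rho for non-minimal factors", {
  set.seed(13)
  x0 <- runif(6, 0.5, 2)
  fac <- matrix(runif(18, 0.1, 3), 6, 3,
                dimnames = list(NULL, c("p", "q", "r")))
  rhos <- seq(0.05, 0.95, by = 0.05)
  degs <- sapply(rhos, function(r) gca(x0, fac, rho = r)$degrees)
  for (i in 1:3) expect_true(all(diff(degs[i, ]) >= -1e-12))
})

test_that("ranking reproduces the published component orders from the published grades", {
  expect_equal(rank_components(published_grades_irritation(), "descending"),
               c("B", "A", "G", "J", "I", "H", "D", "F", "E", "C"))
  expect_equal(rank_components(published_grades_effectiveness(), "ascending"),
               c("D", "C", "B", "A", "F", "E", "H", "I", "G", "J"))
})

test_that("ranking breaks ties lexicographically and rejects NaN", {
  expect_equal(rank_components(c(b = 0.5, a = 0.5, c = 0.9), "descending"),
               c("c", "a", "b"))
  expect_equal(rank_components(c(b = 0.5, a = 0.5), "ascending"), c("a", "b"))
  expect_error(rank_components(c(a = NaN, b = 1)), "NA")
})

test_that("zero-mean factor columns are excluded with a warning, not an error", {
  x0 <- c(1, 2, 3)
  fac <- cbind(live = c(1, 2, 4), dead = c(0, 0, 0))
  expect_warning(g <- gca(x0, fac), "zero mean")
  expect_equal(names(g$degrees), "live")
  expect_equal(g$dropped, "dead")
})

test_that("a dominant irritant component recovers rank 1 under low noise", {
  gt <- dominant_irritant_truth()
  hits <- 0L
  n_rep <- 100L
  for (s in seq_len(n_rep)) {
    dm <- peak_doses(generate_fingerprints(20, jitter_cv = 0.1,
                                           seed = 3000 + s),
                     stats::setNames(rep(12.5, 20), sprintf("SYN%03d", 1:20)))
    resp <- simulate_bioassay(dm, gt, seed = 4000 + s)
    g <- suppressWarnings(gca(resp$absorbance, dm, direction = "descending"))
    if (g$ranking[1] == "B") hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})
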