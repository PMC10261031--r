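test_that("register marks exactly the cue's cells and accumulates weight", {
  a <- amr(4, 8)
  a <- amr_register(a, c(3, 1, 6, 7))
  expect_equal(sum(a$weights > 0L), 4L)
  expect_equal(a$weights[cbind(c(4, 2, 7, 8), 1:4)], rep(1L, 4))

  # repeated registration increments the same cells
  k <- 5L
  b <- amr(4, 8)
  for (j in seq_len(k)) b <- amr_register(b, c(3, 1, 6, 7))
  expect_equal(b$weights[cbind(c(4, 2, 7, 8), 1:4)], rep(k, 4))
  expect_equal(sum(b$weights), 4L * k)

  # two cues differing only at column 1: two singleton cells there,
  # weight-2 cells elsewhere
  d <- amr_register(amr(4, 8), rbind(c(3, 1, 6, 7), c(0, 1, 6, 7)))
  expect_equal(sort(d$weights[, 1]), c(rep(0L, 6), 1L, 1L))
  for (i in 2:4) expect_equal(sort(d$weights[, i]), c(rep(0L, 7), 2L))
})

test_that("batch registration equals sequential registration", {
  set.seed(3)
  cues <- matrix(sample.int(6, 10 * 5, replace = TRUE) - 1L, nrow = 10)
  a <- amr_register(amr(5, 6), cues)
  b <- amr(5, 6)
  for (r in seq_len(nrow(cues))) b <- amr_register(b, cues[r, ])
  expect_identical(a$weights, b$weights)
})

test_that("register is monotone and conserves added weight", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(2:8, 1); m <- sample(2:6, 1)
    fx <- random_filled_amr(n, m, sample(1:10, 1), seed)
    before <- fx$amr$weights
    cue <- random_cue(n, m)
    after <- amr_register(fx$amr, cue)$weights
    expect_true(all(after >= before))
    expect_equal(sum(after) - sum(before), n)
  }
})

test_that("register saturates at the maximum weight", {
  a <- amr(2, 2, l = 3L)
  for (j in 1:5) a <- amr_register(a, c(0, 1))
  expect_equal(max(a$weights), 3L)
  # batch saturation too
  b <- amr_register(amr(2, 2, l = 3L),
                    matrix(rep(c(0L, 1L), each = 5), ncol = 2))
  expect_equal(max(b$weights), 3L)
})

test_that("register and recognize validate arity and level range", {
  a <- amr(4, 8)
  expect_error(amr_register(a, c(1, 2)), "arity")
  expect_error(amr_register(a, c(1, 2, 3, 8)), "levels")
  expect_error(amr_register(a, c(1, 2, 3, -1)), "levels")
  expect_error(amr_recognize(a, c(1, 2)), "arity")
  expect_error(amr_retrieve(a, c(1, 2, 3, 4), sigma = -0.1), "sigma")
  expect_error(amr(0, 4))
})

test_that("a just-registered cue is accepted with default parameters", {
  a <- amr_register(amr(4, 8), c(3, 1, 6, 7))
  rec <- amr_recognize(a, c(3, 1, 6, 7))
  expect_true(rec$accepted)
  expect_length(rec$failing_columns, 0)
  expect_equal(rec$rho, 1.0)
})

test_that("an empty register rejects every cue, with all columns failing", {
  a <- amr(5, 4)
  rec <- amr_recognize(a, c(0, 1, 2, 3, 0))
  expect_false(rec$accepted)
  expect_length(rec$failing_columns, 5)
  expect_equal(rec$rho, 0)
  expect_equal(rec$Omega, 0)
})

test_that("xi relaxes the column-wise implication", {
  a <- amr_register(amr(4, 8), c(3, 1, 6, 7))
  g <- c(3, 1, 6, 0)  # differs at exactly one column
  expect_false(amr_recognize(a, g, xi = 0)$accepted)
  expect_true(amr_recognize(a, g, xi = 1)$accepted)
  expect_equal(amr_recognize(a, g)$failing_columns, 4L)
})

test_that("iota and kappa thresholds control marginal-cue acceptance", {
  # column weights {3,1}: the weight-1 cell is off once iota > 1/2
  a <- amr(2, 2)
  a <- amr_register(a, rbind(c(0, 0), c(0, 0), c(0, 0), c(1, 1)))
  weak <- c(1, 1)  # hits the weight-1 cells; omega_i = 2
  expect_true(amr_recognize(a, weak, iota = 0)$accepted)
  expect_false(amr_recognize(a, weak, iota = 0.75)$accepted)
  # kappa: rho = 1 < kappa * Omega = 1.5 rejects; the strong cue passes
  expect_false(amr_recognize(a, weak, kappa = 0.75)$accepted)
  expect_true(amr_recognize(a, c(0, 0), kappa = 0.75)$accepted)
})

test_that("recognition statistics match the defining formulas", {
  a <- amr(2, 3)
  a <- amr_register(a, rbind(c(0, 1), c(0, 2), c(1, 1)))
  rec <- amr_recognize(a, c(0, 1))
  expect_equal(rec$omega, c(3 / 2, 3 / 2))  # mean over non-zero cells
  expect_equal(rec$Omega, 1.5)
  expect_equal(rec$rho, 2)                  # (w[0,1] + w[1,2]) / 2 = (2+2)/2
})

test_that("self-recognition holds over random registers and cues", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(2:10, 1); m <- sample(2:8, 1)
    fx <- random_filled_amr(n, m, sample(1:20, 1), seed)
    cue <- fx$cues[sample(nrow(fx$cues), 1), ]
    expect_true(amr_recognize(fx$amr, cue)$accepted)
  }
})

test_that("retrieval at sigma = 0 is reproductive", {
  fx <- random_filled_amr(8, 6, 12, seed = 21)
  for (r in seq_len(nrow(fx$cues)))
    expect_identical(amr_retrieve(fx$amr, fx$cues[r, ], sigma = 0),
                     fx$cues[r, ])
})

test_that("rejected cues yield an undefined (NULL) retrieval", {
  a <- amr(3, 4)
  expect_null(amr_retrieve(a, c(0, 1, 2), sigma = 0.1))
})

test_that("retrieved levels always lie in the column support", {
  for (seed in 1:15) {
    fx <- random_filled_amr(6, 5, 8, seed = seed)
    cue <- fx$cues[1, ]
    for (s in c(0, 0.05, 0.3, 1, 10)) {
      out <- amr_retrieve(fx$amr, cue, sigma = s)
      expect_false(is.null(out))
      expect_true(all(fx$amr$weights[cbind(out + 1L, seq_along(out))] > 0L))
    }
  }
})

test_that("a single-support column retrieves its only level at any sigma", {
  a <- amr_register(amr(2, 6), rbind(c(2, 0), c(2, 3), c(2, 5)))
  for (s in c(0, 0.1, 2)) {
    out <- amr_retrieve(a, c(2, 3), sigma = s)
    expect_equal(out[1], 2L)
  }
})

test_that("partial cues recognize on defined arguments and retrieve complete", {
  a <- amr_register(amr(4, 8), rbind(c(3, 1, 6, 7), c(2, 1, 5, 7)))
  partial <- c(3, NA, 6, NA)
  rec <- amr_recognize(a, partial)
  expect_true(rec$accepted)
  expect_equal(rec$rho, 1)  # averaged over the two defined arguments
  out <- amr_retrieve(a, partial, sigma = 0.1)
  expect_false(anyNA(out))  # undefined arguments sampled from the prior
  expect_true(all(a$weights[cbind(out + 1L, 1:4)] > 0L))
})

test_that("xi-relaxed retrieval falls back to the prior in failing columns", {
  a <- amr_register(amr(3, 4), rbind(c(0, 1, 2), c(0, 1, 3)))
  cue <- c(3, 1, 2)  # column 1 unsupported at level 3
  expect_null(amr_retrieve(a, cue, sigma = 0))
  out <- amr_retrieve(a, cue, sigma = 0, xi = 1, seed = 5)
  expect_equal(out[1], 0L)  # the only supported level in column 1
  expect_equal(out[2:3], c(1L, 2L))
})

test_that("retrieval under a seed is reproducible and restores RNG state", {
  fx <- random_filled_amr(6, 8, 20, seed = 31)
  cue <- fx$cues[1, ]
  set.seed(1234); ref <- stats::runif(1)
  set.seed(1234)
  a1 <- amr_retrieve(fx$amr, cue, sigma = 0.4, seed = 99)
  a2 <- amr_retrieve(fx$amr, cue, sigma = 0.4, seed = 99)
  expect_identical(a1, a2)
  expect_equal(stats::runif(1), ref)  # caller's RNG stream untouched
})

test_that("column_distribution matches the product-of-distributions formula", {
  a <- amr(1, 4)
  a$weights[, 1] <- c(4L, 2L, 0L, 2L)
  psi <- c(4, 2, 0, 2) / 8
  zeta <- dnorm(0:3, mean = 1, sd = 0.5 * 4)
  expect_equal(column_distribution(a, 1, level = 1, sigma = 0.5),
               psi * zeta / sum(psi * zeta))
  expect_equal(column_distribution(a, 1, level = NA), psi)
  expect_equal(column_distribution(a, 1, level = 1, sigma = 0),
               c(0, 1, 0, 0))
})

test_that("empirical retrieval frequencies match the analytic distribution", {
  a <- amr(1, 4)
  a$weights[, 1] <- c(5L, 3L, 0L, 1L)
  sigma <- 0.4
  phi <- column_distribution(a, 1, level = 0, sigma = sigma)
  set.seed(77)
  draws <- replicate(4000, amr_retrieve(a, 0L, sigma = sigma))
  counts <- tabulate(draws + 1L, nbins = 4)
  expect_equal(counts[3], 0L)  # zero-weight level never drawn
  p <- suppressWarnings(
    chisq.test(counts[phi > 0], p = phi[phi > 0])$p.value
  )
  expect_gt(p, 0.01)
})
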