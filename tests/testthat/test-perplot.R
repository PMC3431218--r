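test_that("A-tract scan counts overlapping AA/TT matches, skips ambiguity", {
  expect_equal(find_atracts("AAAA")$positions, c(0L, 1L, 2L))
  expect_equal(find_atracts("AATT")$positions, c(0L, 2L))
  expect_equal(find_atracts("ACGCGC")$positions, integer(0))
  expect_equal(find_atracts("ANATNT")$positions, integer(0))
  expect_error(find_atracts("AAAA", method = "A4T4"), "unknown")
  set.seed(11)
  for (i in 1:10) {
    res <- random_residues(5000, gc = runif(1, 0.2, 0.8))
    expect_identical(find_atracts(res)$positions, naive_atract_scan(res))
  }
})

test_that("spacing histogram equals exhaustive pair counting", {
  h <- spacing_histogram(find_atracts("AAAA"), s_hi = 5)
  expect_equal(h$raw, c(2L, 1L, 0L, 0L, 0L))
  expect_equal(spacing_histogram(integer(0), s_hi = 4)$raw, rep(0L, 4))
  set.seed(12)
  for (i in 1:5) {
    pos <- sort(sample.int(3000, 300)) - 1L
    expect_equal(spacing_histogram(pos, s_hi = 101)$raw,
                 brute_spacing_hist(pos, 101))
  }
})

test_that("pair-count conservation bounds the histogram mass", {
  set.seed(13)
  for (i in 1:10) {
    tr <- find_atracts(random_residues(2000, gc = runif(1, 0.3, 0.7)))
    h <- spacing_histogram(tr, s_hi = 101)
    expect_lte(sum(h$raw), tr$n * (tr$n - 1) / 2)
  }
  # all pairwise distances within s_hi -> equality
  tr <- find_atracts("AAAAAAAAAA")
  h <- spacing_histogram(tr, s_hi = 20)
  expect_equal(sum(h$raw), tr$n * (tr$n - 1) / 2)
})

test_that("normalization divides by the uniform-placement expectation", {
  tr <- find_atracts(random_residues(5000, 0.5))
  h <- spacing_histogram(tr, s_hi = 101)
  M <- tr$L - 1
  E <- (tr$n / M)^2 * (M - h$s)
  h$raw <- E  # force N(s) = E(s)
  hn <- normalize_histogram(h)
  expect_equal(hn$normalized, rep(1, 101))

  h1 <- spacing_histogram(integer(0), s_hi = 101)
  h1$L <- 5000L
  expect_error(normalize_histogram(h1), "insufficient")

  # on long i.i.d. sequences h(s) is ~1 over the analysis range
  set.seed(14)
  pp <- perplot(random_sequence(1e6, gc = 0.5, id = "null"))
  expect_equal(mean(pp$histogram$normalized[30:100]), 1, tolerance = 0.05)
})

test_that("3-bp smoother averages with a shrinking window at the ends", {
  expect_equal(smooth3(rep(2.5, 7)), rep(2.5, 7))
  sig <- rep(c(1, 0, 0), 5)
  expect_equal(smooth3(sig)[2:14], rep(1 / 3, 13))
  set.seed(15)
  v <- rnorm(50)
  direct <- sapply(seq_along(v), function(i)
    mean(v[max(1, i - 1):min(length(v), i + 1)]))
  expect_equal(smooth3(v), direct)
})

test_that("parabolic detrending removes quadratic trends exactly", {
  tr <- find_atracts(random_residues(2000, 0.5))
  h <- spacing_histogram(tr, s_hi = 101)
  s <- h$s
  h$normalized <- 2 + 0.1 * s - 0.001 * s^2
  h <- smooth3(h)  # smoothing a parabola stays near-parabolic; refit below
  h$smoothed <- 2 + 0.1 * s - 0.001 * s^2  # exact parabola in
  hd <- detrend_parabola(h, 30, 100)
  expect_lt(max(abs(hd$detrended)), 1e-9)

  # residual orthogonality to {1, s, s^2}
  h$smoothed <- 2 + 0.1 * s - 0.001 * s^2 + 0.2 * cos(2 * pi * s / 10.5)
  hd <- detrend_parabola(h, 30, 100)
  ss <- 30:100
  scale <- sum(abs(hd$detrended))
  expect_lt(abs(sum(hd$detrended)) / scale, 1e-6)
  expect_lt(abs(sum(ss * hd$detrended)) / (scale * 100), 1e-6)
  expect_lt(abs(sum(ss^2 * hd$detrended)) / (scale * 100^2), 1e-6)
  # and the cosine survives detrending nearly unchanged
  cosfit <- lm.fit(cbind(1, ss, ss^2), 0.2 * cos(2 * pi * ss / 10.5))
  expect_lt(max(abs(hd$detrended - cosfit$residuals)), 1e-9)
})

test_that("spectrum peaks at the injected period and Q* is mean-1 normalized", {
  tr <- find_atracts(random_residues(2000, 0.5))
  h <- spacing_histogram(tr, s_hi = 101)
  h$normalized <- rep(1, 101)
  h <- smooth3(h)
  h$smoothed <- 1 + cos(2 * pi * h$s / 10.5)
  hd <- detrend_parabola(h, 30, 100)
  sp <- power_spectrum(hd)
  band <- sp$period >= 9.5 & sp$period <= 11.5
  expect_equal(sp$period[band][which.max(sp$q_star[band])], 10.5,
               tolerance = 0.051)
  in_norm <- sp$period >= 5 - 1e-9 & sp$period <= 20 + 1e-9
  expect_equal(mean(sp$q_star[in_norm]), 1, tolerance = 1e-9)
  expect_true(all(sp$q_star >= 0))

  hd$detrended <- rep(0, 71)
  expect_error(power_spectrum(hd), "degenerate")
})

test_that("index extraction takes band maxima with smallest-period ties", {
  grid <- seq(3, 25, by = 0.05)
  flat <- structure(list(period = grid, q_raw = rep(1, length(grid)),
                         q_star = rep(1, length(grid)),
                         norm_range = c(5, 20), star_range = c(9.5, 11.5)),
                    class = "period_spectrum")
  ix <- perplot_indices(flat)
  expect_equal(ix$max_q, 1)
  expect_equal(ix$p_max_q, 5)
  expect_equal(ix$p_max_q_star, 9.5)

  spiked <- flat
  spiked$q_star[which.min(abs(grid - 10.9))] <- 7
  ix2 <- perplot_indices(spiked)
  expect_equal(ix2$p_max_q, 10.9)
  expect_equal(ix2$p_max_q_star, 10.9)
  expect_equal(ix2$max_q, 7)

  set.seed(16)
  for (i in 1:10) {
    pp <- perplot(random_sequence(30000, gc = runif(1, 0.3, 0.7)))
    expect_gte(pp$indices$max_q, pp$indices$max_q_star)
    expect_true(pp$indices$p_max_q >= 5 && pp$indices$p_max_q <= 20)
    expect_true(pp$indices$p_max_q_star >= 9.5 &&
                  pp$indices$p_max_q_star <= 11.5)
  }
})

test_that("perplot recovers a planted period and flags hopeless input", {
  ps <- planted_periodic_sequence(60000, period = 10.9, seed = 21)
  pp <- perplot(ps$sequence)
  expect_true(pp$valid)
  expect_equal(pp$indices$p_max_q_star, 10.9, tolerance = 0.05)
  expect_gt(pp$indices$max_q_star, 3)
  expect_equal(unname(coef(pp)["MaxQ_star"]), pp$indices$max_q_star)
  expect_length(residuals(pp), 71L)

  allg <- genome_sequence(strrep("G", 2000), "allG")
  flagged <- perplot(allg)
  expect_false(flagged$valid)
  expect_match(flagged$reason, "insufficient")
  expect_true(is.na(flagged$indices$max_q))
  expect_error(perplot(genome_sequence("ACGT", "tiny")), "too short")
})

test_that("N(s) is strand-symmetric and translation-invariant", {
  set.seed(17)
  for (i in 1:5) {
    res <- random_residues(4000, gc = runif(1, 0.3, 0.7))
    h <- spacing_histogram(find_atracts(res), s_hi = 101)
    h_rc <- spacing_histogram(find_atracts(revcomp(res)), s_hi = 101)
    expect_identical(h$raw, h_rc$raw)
    shifted <- paste0(strrep("G", 13), res)
    h_sh <- spacing_histogram(find_atracts(shifted), s_hi = 101)
    expect_identical(h$raw, h_sh$raw)
    expect_identical(find_atracts(shifted)$positions,
                     find_atracts(res)$positions + 13L)
  }
  # and the full spectrum/indices are strand-symmetric too
  res <- random_residues(30000, 0.45)
  a <- perplot(res); b <- perplot(revcomp(res))
  expect_equal(a$spectrum$q_star, b$spectrum$q_star)
  expect_equal(coef(a), coef(b))
})
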