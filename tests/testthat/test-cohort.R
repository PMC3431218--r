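test_that("Fisher's exact test matches exhaustive hypergeometric enumeration", {
  expect_equal(fisher_exact(1, 1, 1, 1)$p_value, 1.0)
  # the published prophage-persistence table, against the oracle
  expect_equal(fisher_exact(23, 284, 5, 353)$p_value,
               enum_fisher_p(23, 284, 5, 353), tolerance = 1e-12)
  expect_lt(fisher_exact(23, 284, 5, 353)$p_value, 2e-4)

  set.seed(51)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    cells <- as.vector(rmultinom(1, n, prob = runif(4, 0.1, 1)))
    tab <- matrix(cells, 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p_value,
                 enum_fisher_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-12)
  }

  # invariance under row and column swaps
  tab <- matrix(c(7, 2, 3, 9), 2, 2)
  p <- fisher_exact(tab)$p_value
  expect_equal(fisher_exact(tab[2:1, ])$p_value, p)
  expect_equal(fisher_exact(tab[, 2:1])$p_value, p)

  expect_warning(res <- fisher_exact(0, 0, 3, 5), "degenerate")
  expect_equal(res$p_value, 1)
  expect_true(res$degenerate)
})

test_that("Mann-Whitney U matches full permutation enumeration when exact", {
  r <- mann_whitney_u(1:3, 4:6)
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "mann_whitney_exact")

  x <- c(1, 2, 3, 4, 5)
  expect_gte(mann_whitney_u(x, x)$p_value, 0.99)

  set.seed(52)
  for (sizes in list(c(3, 5), c(5, 5), c(7, 8), c(6, 4), c(2, 9))) {
    x <- runif(sizes[1]); y <- runif(sizes[2])
    expect_equal(mann_whitney_u(x, y)$p_value, enum_mw_p(x, y),
                 tolerance = 1e-12)
  }

  # invariance under a strictly monotone transform of both samples
  x <- rnorm(12); y <- rnorm(15, 0.5)
  expect_equal(mann_whitney_u(exp(x), exp(y))$p_value,
               mann_whitney_u(x, y)$p_value)

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney type-I error sits at the nominal level", {
  set.seed(53)
  hits <- mean(replicate(1000, {
    mann_whitney_u(rnorm(50), rnorm(50))$p_value <= 0.05
  }))
  expect_equal(hits, 0.05, tolerance = 0.02 / 0.05)
})

test_that("cohorts join indices, prophage flags and species with declared fallbacks", {
  idx <- data.frame(replicon_id = c("r1", "r2", "r3"),
                    length = c(2e6, 3e6, 1e6), gc = c(0.4, 0.5, 0.6),
                    n_atracts = c(1e5, 2e5, 5e4),
                    MaxQ = c(4, 2, 3), PMaxQ = c(11, 8, 10.5),
                    MaxQ_star = c(4, 1.5, 3), PMaxQ_star = c(11, 10, 10.5),
                    n_windows = c(100L, 150L, 50L),
                    Max2 = c(60, 10, 30), PMax2 = c(11, 8, 10.5),
                    Max3 = c(40, 5, 20), PMax3 = c(11, 8, 10.5),
                    MaxMax = c(45, 8, 25), PMaxMax = c(11, 8, 10.5))
  pro <- data.frame(replicon_id = "r2", start = 100L, end = 5000L)
  spc <- data.frame(replicon_id = c("r1", "r2"),
                    organism_name = c("Genus alpha 1", "Genus beta 2"),
                    species_key = c("genus alpha", "genus beta"))
  ch <- build_cohort(idx, pro, spc)
  expect_equal(ch$has_prophage, c(FALSE, TRUE, FALSE))
  expect_equal(ch$species_key, c("genus alpha", "genus beta", "r3"))
  expect_equal(ch$persistent, c(TRUE, FALSE, TRUE))
  expect_equal(sum(!ch$has_prophage), 2L)

  # empty prophage table -> everything prophage-free
  ch0 <- build_cohort(idx, pro[0, ], spc)
  expect_false(any(ch0$has_prophage))

  rep <- cohort_report(ch, n_iter = 5, seed = 1)
  expect_equal(sum(rep$table), 3)
  expect_s3_class(rep, "cohort_report")
  ch_all_free <- build_cohort(idx, NULL, spc)
  rep2 <- suppressWarnings(cohort_report(ch_all_free, n_iter = 2,
                                         seed = 1))
  expect_true(rep2$fisher$degenerate)
})

test_that("one-per-species resampling is seeded and degenerate-safe", {
  idx <- data.frame(replicon_id = sprintf("r%02d", 1:12),
                    MaxMax = c(rnorm(6, 60, 3), rnorm(6, 10, 3)))
  ch <- idx
  ch$species_key <- c("a a", "a a", "b b", "c c", "d d", "e e",
                      "f f", "f f", "g g", "h h", "i i", "j j")
  ch$has_prophage <- rep(c(FALSE, TRUE), each = 6)

  r1 <- one_per_species_resampling(ch, "MaxMax", n_iter = 50, seed = 7)
  r2 <- one_per_species_resampling(ch, "MaxMax", n_iter = 50, seed = 7)
  expect_identical(r1$p_values, r2$p_values)

  # every species has one record -> no sampling variance
  ch1 <- ch[!duplicated(ch$species_key), ]
  r3 <- one_per_species_resampling(ch1, "MaxMax", n_iter = 20, seed = 1)
  expect_true(r3$n_significant %in% c(0L, 20L))

  # a species straddling the groups can empty one side
  ch2 <- ch[ch$species_key %in% c("a a", "f f"), ]
  ch2$species_key <- "a a"
  expect_warning(
    r4 <- one_per_species_resampling(ch2, "MaxMax", n_iter = 30, seed = 2),
    "non-significant")
  expect_equal(r4$n_degenerate + sum(r4$p_values < 1), r4$n_iter)
})

test_that("segment sampling honours the length range and is uniform in start", {
  sq <- random_sequence(40000, 0.5, seed = 61, id = "chr")
  whole <- sample_chromosome_segment(sq, 40000, 40000, seed = 1)
  expect_equal(whole$residues, sq$residues)

  seg <- sample_chromosome_segment(sq, 5000, 20000, seed = 2)
  expect_true(seg$length >= 5000 && seg$length <= 20000)
  at <- as.integer(strsplit(sub("^chr:", "", seg$id), "-")[[1]])
  expect_equal(substr(sq$residues, at[1], at[2]), seg$residues)

  expect_error(sample_chromosome_segment(sq, 5000, 50000), "shorter")

  set.seed(62)
  fr <- replicate(1000, {
    s <- sample_chromosome_segment(sq, 5000, 20000)
    at <- as.integer(strsplit(sub("^chr:", "", s$id), "-")[[1]])
    len <- at[2] - at[1] + 1L
    (at[1] - 1 + runif(1)) / (sq$length - len + 1)
  })
  expect_gt(suppressWarnings(ks.test(fr, "punif"))$p.value, 0.001)
})
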