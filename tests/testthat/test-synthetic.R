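test_that("random sequences honour composition and are byte-reproducible", {
  expect_true(grepl("^[AT]+$", random_sequence(500, gc = 0, seed = 1)$residues))
  expect_true(grepl("^[GC]+$", random_sequence(500, gc = 1, seed = 1)$residues))
  expect_error(random_sequence(100, gc = 1.2), "gc")

  s <- random_sequence(1e6, gc = 0.5, seed = 71)
  expect_lt(abs(s$gc - 0.5), 3 * sqrt(0.25 / 1e6))

  a <- random_sequence(10000, 0.42, seed = 72)
  b <- random_sequence(10000, 0.42, seed = 72)
  expect_identical(a$residues, b$residues)
  fa <- tempfile(fileext = ".fasta"); fb <- tempfile(fileext = ".fasta")
  write_fasta(a, fa); write_fasta(b, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("phase-accumulated plants realize non-integer periods", {
  # coverage 0 is exactly the background draw under the same seed
  p0 <- planted_periodic_sequence(20000, 10.9, coverage = 0, seed = 73)
  bg <- random_sequence(20000, 0.5, seed = 73)
  expect_identical(p0$sequence$residues, bg$residues)
  expect_false(any(p0$blocks$periodic))

  # a 10.9 bp plant produces spacings alternating 11 and 10, mean 10.9
  ps <- planted_periodic_sequence(5000, 10.9, gc = 0, seed = 74,
                                  motif = "AA")
  # with gc = 0 the background is A/T; check planted positions directly
  k <- 0:floor((5000 - 2) / 10.9)
  pos <- round(k * 10.9)
  sp <- diff(pos)
  expect_true(all(sp %in% c(10, 11)))
  expect_equal(mean(sp), 10.9, tolerance = 0.01)

  expect_error(planted_periodic_sequence(1000, 2, motif = "AAA"),
               "longer than the period")

  # block map covers the sequence and matches the requested coverage
  ps2 <- planted_periodic_sequence(100000, 10.9, coverage = 0.5,
                                   block_size = 10000, seed = 75)
  b <- ps2$blocks
  expect_equal(min(b$start), 1L)
  expect_equal(max(b$end), 100000L)
  cov <- sum((b$end - b$start + 1)[b$periodic]) / 100000
  expect_equal(cov, 0.5, tolerance = 0.05)
})

test_that("planted periods are recovered by the whole-sequence analysis", {
  set.seed(76)
  for (p in c(10.0, 10.5, 10.9, 11.4)) {
    ps <- planted_periodic_sequence(60000, period = p)
    pp <- perplot(ps$sequence)
    expect_equal(pp$indices$p_max_q_star, p, tolerance = 0.1)
    expect_gt(pp$indices$max_q_star, 3)
  }
})

test_that("splicing an aperiodic insert erodes persistency at matched seeds", {
  ps <- planted_periodic_sequence(120000, 10.9, seed = 77)
  base <- persistency_indices(perscan(ps$sequence))
  ins <- random_sequence(15000, 0.5, seed = 78, id = "prophage")
  sp <- splice_segment(ps$sequence, ins, at = 60000)
  expect_equal(sp$sequence$length, 135000L)
  expect_equal(unname(sp$interval), c(60001L, 75000L))
  expect_equal(substr(sp$sequence$residues, 60001, 75000), ins$residues)
  eroded <- persistency_indices(perscan(sp$sequence))
  expect_lt(eroded$max_max, base$max_max)

  # windows inside the insert lose the dominant period
  sc <- perscan(sp$sequence)
  inside <- sc$window_starts >= 60000 & sc$window_starts + 10000 <= 75000
  expect_false(any(abs(sc$window_pmax[inside] - 10.9) <= 0.2, na.rm = TRUE))

  # more aperiodic material -> persistency non-increasing in expectation
  ins2 <- random_sequence(45000, 0.5, seed = 78, id = "prophage2")
  sp2 <- splice_segment(ps$sequence, ins2, at = 60000)
  eroded2 <- persistency_indices(perscan(sp2$sequence))
  expect_lt(eroded2$max_max, base$max_max)
})

test_that("synthetic cohorts carry consistent labels, flags and intervals", {
  co <- synthetic_cohort(5, 4, 3, chrom_length = c(15000, 20000),
                         phage_length = c(11000, 14000),
                         prophage_length = c(2000, 3000), seed = 79)
  expect_equal(sum(co$truth$group == "periodic"), 5L)
  expect_equal(sum(co$truth$group == "aperiodic"), 4L)
  expect_equal(sum(co$truth$group == "phage"), 3L)
  expect_equal(names(co$sequences), co$truth$replicon_id)
  expect_setequal(co$prophages$replicon_id,
                  co$truth$replicon_id[co$truth$has_prophage])
  expect_true(all(co$truth$has_prophage ==
                    (co$truth$group == "aperiodic")))
  # recorded prophage intervals lie within their replicons
  for (i in seq_len(nrow(co$prophages))) {
    L <- co$sequences[[co$prophages$replicon_id[i]]]$length
    expect_true(co$prophages$start[i] >= 1 && co$prophages$end[i] <= L)
  }
  # multiplicities: strains of a species share the species key and group
  tt <- co$truth
  for (sp in unique(tt$species_key))
    expect_length(unique(tt$group[tt$species_key == sp]), 1L)

  # no phage records when n_phage = 0
  co0 <- synthetic_cohort(1, 1, 0, seed = 2,
                          chrom_length = c(12000, 15000))
  expect_false(any(co0$truth$group == "phage"))

  # determinism of the whole bundle
  c1 <- synthetic_cohort(2, 2, 1, chrom_length = c(12000, 15000),
                         phage_length = c(11000, 12000), seed = 80)
  c2 <- synthetic_cohort(2, 2, 1, chrom_length = c(12000, 15000),
                         phage_length = c(11000, 12000), seed = 80)
  expect_identical(lapply(c1$sequences, `[[`, "residues"),
                   lapply(c2$sequences, `[[`, "residues"))
  expect_identical(c1$prophages, c2$prophages)
})
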