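.BASE_RAW <- as.raw(c(65L, 67L, 71L, 84L))  # A C G T

# i.i.d. base draws as a raw byte vector: P(G) = P(C) = gc/2,
# P(A) = P(T) = (1-gc)/2
.random_raw <- function(length, gc) {
  .BASE_RAW[sample.int(4L, length, replace = TRUE,
                       prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                (1 - gc) / 2))]
}

#' Random i.i.d. nucleotide sequence
#'
#' Draws bases independently with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1-gc)/2`: a length- and G+C-preserving null model for
#' the periodicity analysis.
#'
#' @param length sequence length in bp.
#' @param gc target G+C fraction in `[0, 1]`.
#' @param seed optional integer; identical seeds give byte-identical
#'   sequences.
#' @param id record identifier.
#' @return A [genome_sequence()].
#' @examples
#' random_sequence(50, gc = 0, seed = 1)$residues  # A/T only
#' @export
random_sequence <- function(length, gc = 0.5, seed = NULL,
                            id = "random") {
  length <- as.integer(length)
  stopifnot(length >= 1L)
  if (is.na(gc) || gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  genome_sequence(rawToChar(.random_raw(length, gc)), id = id)
}

#' Sequence with planted A-tract periodicity
#'
#' Builds an i.i.d. background and overwrites the tract motif at positions
#' generated by phase accumulation, `round(block_start + phase + k * period
#' [+ jitter_k])`, inside periodic blocks. Phase accumulation realizes
#' non-integer periods: a 10.9 bp plant produces spacings alternating
#' between 11 and 10 bp with mean 10.9. Periodic blocks of `block_size`
#' alternate with aperiodic gaps sized so that the periodic blocks cover
#' approximately `coverage` of the sequence.
#'
#' @param length sequence length in bp.
#' @param period planted period in bp (real-valued, >= 2).
#' @param coverage fraction of the sequence inside periodic blocks in
#'   `[0, 1]`; 1 plants throughout, 0 returns the pure background.
#' @param block_size periodic block length in bp (default 10000).
#' @param gc background G+C fraction.
#' @param motif tract motif written at each planted position (default
#'   `"AA"`; must not be longer than the period).
#' @param jitter standard deviation (bp) of Gaussian placement noise.
#' @param phase phase offset (bp) of the first tract in each block.
#' @param seed optional integer seed.
#' @param id record identifier.
#' @return List with `sequence` (a `genome_sequence`) and `blocks`
#'   (data frame of 1-based inclusive `start`, `end`, logical `periodic`:
#'   the ground-truth block map).
#' @examples
#' ps <- planted_periodic_sequence(30000, period = 10.9, seed = 7)
#' subset(ps$blocks, periodic)
#' @export
planted_periodic_sequence <- function(length, period, coverage = 1,
                                      block_size = 10000L, gc = 0.5,
                                      motif = "AA", jitter = 0, phase = 0,
                                      seed = NULL, id = "planted") {
  length <- as.integer(length)
  stopifnot(length >= 1L, period >= 2, coverage >= 0, coverage <= 1,
            jitter >= 0)
  block_size <- min(as.integer(block_size), length)
  stopifnot(block_size >= 1L)
  w <- nchar(motif)
  if (w > period) stop("motif is longer than the period")
  mb <- charToRaw(toupper(motif))
  if (!is.null(seed)) set.seed(seed)
  b <- .random_raw(length, gc)
  blocks <- data.frame(start = integer(0), end = integer(0),
                       periodic = logical(0))
  if (coverage > 0) {
    gap <- if (coverage >= 1) 0L
           else as.integer(round(block_size * (1 - coverage) / coverage))
    start <- 0L  # 0-based block start
    while (start < length) {
      bend <- min(start + block_size, length)  # 0-based exclusive
      k <- 0:max(0L, floor((bend - start - w - phase) / period))
      pos <- as.integer(round(start + phase + k * period +
                                if (jitter > 0)
                                  rnorm(length(k), 0, jitter) else 0))
      pos <- pos[pos >= start & pos + w <= bend]
      for (off in seq_len(w) - 1L) b[pos + 1L + off] <- mb[off + 1L]
      blocks <- rbind(blocks,
                      data.frame(start = start + 1L, end = bend,
                                 periodic = TRUE))
      if (gap > 0L && bend < length)
        blocks <- rbind(blocks,
                        data.frame(start = bend + 1L,
                                   end = min(bend + gap, length),
                                   periodic = FALSE))
      start <- bend + gap
    }
  } else {
    blocks <- data.frame(start = 1L, end = length, periodic = FALSE)
  }
  list(sequence = genome_sequence(rawToChar(b), id = id), blocks = blocks)
}

#' Splice a segment into a sequence
#'
#' Inserts `insert` into `seq` starting after position `at` (0 = prepend),
#' recording the interval the insert occupies -- the in-silico analogue of
#' a prophage integrating into a chromosome.
#'
#' @param seq host `genome_sequence` or character string.
#' @param insert inserted `genome_sequence` or character string.
#' @param at 0-based insertion point in `[0, L]`.
#' @return List with `sequence` (the spliced `genome_sequence`) and
#'   `interval` (1-based inclusive `start`, `end` of the insert).
#' @export
splice_segment <- function(seq, insert, at) {
  seq <- as_genome_sequence(seq)
  insert <- as_genome_sequence(insert, id = "insert")
  at <- as.integer(at)
  stopifnot(at >= 0L, at <= seq$length)
  res <- paste0(substr(seq$residues, 1L, at), insert$residues,
                substr(seq$residues, at + 1L, seq$length))
  list(sequence = genome_sequence(res, id = seq$id),
       interval = c(start = at + 1L, end = at + insert$length))
}

#' Labelled synthetic cohort
#'
#' Generates a cohort of "chromosomes" and optional "phages" with species
#' labels and prophage annotations, for end-to-end testing of the cohort
#' statistics without downloads. Periodic chromosomes carry a planted
#' periodicity at `period` covering `periodic_coverage` of their length
#' and are prophage-free; aperiodic chromosomes are i.i.d. backgrounds
#' into which an aperiodic "prophage" segment is spliced at a random,
#' recorded interval. Phage-like records are plain i.i.d. backgrounds.
#' Species multiplicities (strains per species) are drawn uniformly from
#' `species_multiplicity`; a species never straddles groups.
#'
#' @param n_periodic,n_aperiodic,n_phage record counts per group.
#' @param chrom_length,phage_length length ranges in bp (uniform draws).
#' @param period planted period in bp for the periodic group.
#' @param periodic_coverage coverage of the plant in periodic chromosomes.
#' @param gc_range G+C range (uniform draws per record).
#' @param species_multiplicity integer vector of possible strains per
#'   species.
#' @param prophage_length length range of the spliced prophage segment.
#' @param seed optional integer seed; the whole cohort is reproducible
#'   from it.
#' @return List with `sequences` (named list of `genome_sequence`),
#'   `species` (data frame `replicon_id`, `organism_name`, `species_key`),
#'   `prophages` (data frame `replicon_id`, `start`, `end`), and `truth`
#'   (data frame `replicon_id`, `group`, `species_key`, `has_prophage`).
#' @export
synthetic_cohort <- function(n_periodic = 30L, n_aperiodic = 30L,
                             n_phage = 0L,
                             chrom_length = c(120000L, 200000L),
                             phage_length = c(50000L, 120000L),
                             period = 10.9, periodic_coverage = 1,
                             gc_range = c(0.35, 0.6),
                             species_multiplicity = 1:3,
                             prophage_length = c(10000L, 20000L),
                             seed = NULL) {
  stopifnot(n_periodic >= 0L, n_aperiodic >= 0L, n_phage >= 0L)
  if (!is.null(seed)) set.seed(seed)
  draw_len <- function(range)
    as.integer(round(runif(1, range[1], range[2])))
  sequences <- list()
  truth <- data.frame(replicon_id = character(0), group = character(0),
                      species_key = character(0),
                      has_prophage = logical(0), stringsAsFactors = FALSE)
  prophages <- data.frame(replicon_id = character(0), start = integer(0),
                          end = integer(0), stringsAsFactors = FALSE)
  species_rows <- list()
  n_species <- 0L

  add_group <- function(n, group) {
    made <- 0L
    while (made < n) {
      n_species <<- n_species + 1L
      organism <- sprintf("Genus%03d species%03d", n_species, n_species)
      strains <- min(sample(species_multiplicity, 1L), n - made)
      for (k in seq_len(strains)) {
        made <- made + 1L
        id <- sprintf("%s_chr_%03d", group, made)
        gc <- runif(1, gc_range[1], gc_range[2])
        if (group == "periodic") {
          sq <- planted_periodic_sequence(
            draw_len(chrom_length), period = period,
            coverage = periodic_coverage, gc = gc, id = id)$sequence
          has_pp <- FALSE
        } else if (group == "aperiodic") {
          host <- random_sequence(draw_len(chrom_length), gc = gc,
                                  id = id)
          ins <- random_sequence(draw_len(prophage_length), gc = gc,
                                 id = "prophage")
          sp <- splice_segment(host, ins,
                               at = sample.int(host$length + 1L, 1L) - 1L)
          sq <- sp$sequence
          prophages <<- rbind(prophages, data.frame(
            replicon_id = id, start = sp$interval["start"],
            end = sp$interval["end"], stringsAsFactors = FALSE))
          has_pp <- TRUE
        } else {
          sq <- random_sequence(draw_len(phage_length), gc = gc, id = id)
          has_pp <- FALSE
        }
        sequences[[id]] <<- sq
        species_rows[[id]] <<- data.frame(
          replicon_id = id,
          organism_name = paste(organism, "strain", k),
          stringsAsFactors = FALSE)
        truth <<- rbind(truth, data.frame(
          replicon_id = id, group = group,
          species_key = species_key(organism), has_prophage = has_pp,
          stringsAsFactors = FALSE))
      }
    }
  }
  add_group(n_periodic, "periodic")
  add_group(n_aperiodic, "aperiodic")
  add_group(n_phage, "phage")
  species <- do.call(rbind, species_rows)
  rownames(species) <- NULL
  species$species_key <- species_key(species$organism_name)
  rownames(prophages) <- NULL
  rownames(truth) <- NULL
  list(sequences = sequences, species = species, prophages = prophages,
       truth = truth)
}

#' Null calibration of the MaxQ index
#'
#' Fraction of i.i.d. random sequences whose `MaxQ` reaches a threshold --
#' the false-positive rate of the `MaxQ >= 3` significance convention.
#' G+C content is drawn uniformly over `gc_range` for each replicate.
#'
#' @param n number of replicates (>= 1).
#' @param length sequence length per replicate in bp (default 500 kb).
#' @param gc_range G+C range for the uniform draws.
#' @param threshold `MaxQ` exceedance threshold (default 3).
#' @param seed optional integer seed.
#' @param params a [periodicity_params()] bundle.
#' @return List of class `null_calibration`: `fraction` (in `[0, 1]`),
#'   `percent`, `n`, `length`, `threshold`, `gc_range`, and the vector
#'   `max_q` of all replicate values.
#' @export
null_maxq_calibration <- function(n = 2000L, length = 500000L,
                                  gc_range = c(0.30, 0.65), threshold = 3,
                                  seed = NULL,
                                  params = periodicity_params()) {
  n <- as.integer(n)
  stopifnot(n >= 1L, length > params$s_max + 2L)
  if (!is.null(seed)) set.seed(seed)
  maxq <- numeric(n)
  for (i in seq_len(n)) {
    gc <- runif(1, gc_range[1], gc_range[2])
    res <- .pp_chain(.random_raw(length, gc), params)
    maxq[i] <- if (res$valid) res$indices$max_q else NA_real_
  }
  frac <- mean(maxq >= threshold, na.rm = TRUE)
  structure(list(fraction = frac, percent = 100 * frac, n = n,
                 length = length, threshold = threshold,
                 gc_range = gc_range, max_q = maxq),
            class = "null_calibration")
}

#' @export
print.null_calibration <- function(x, ...) {
  cat(sprintf(
    "null calibration: %.2f%% of %d random %s bp sequences reach MaxQ >= %g\n",
    x$percent, x$n, format(x$length, big.mark = ","), x$threshold))
  invisible(x)
}
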