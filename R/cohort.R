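#' Per-replicon periodicity indices
#'
#' Convenience driver: runs [perplot()] and [perscan()] on each sequence
#' and returns one row per replicon with composition and all indices. The
#' row layout matches the package's indices TSV.
#'
#' @param seqs list of `genome_sequence` objects (e.g. from [read_fasta()]).
#' @param params a [periodicity_params()] bundle.
#' @param scan set `FALSE` to skip the sliding-window scan (persistency
#'   columns become `NA`).
#' @return Data frame with columns `replicon_id`, `length`, `gc`,
#'   `n_atracts`, `MaxQ`, `PMaxQ`, `MaxQ_star`, `PMaxQ_star`, `n_windows`,
#'   `Max2`, `PMax2`, `Max3`, `PMax3`, `MaxMax`, `PMaxMax`.
#' @export
analyze_replicons <- function(seqs, params = periodicity_params(),
                              scan = TRUE) {
  if (inherits(seqs, "genome_sequence")) seqs <- list(seqs)
  rows <- lapply(seqs, function(s) {
    s <- as_genome_sequence(s)
    pp <- perplot(s, params, keep_histogram = FALSE, keep_spectrum = FALSE)
    row <- data.frame(replicon_id = s$id, length = s$length, gc = s$gc,
                      n_atracts = pp$n_tracts,
                      MaxQ = pp$indices$max_q, PMaxQ = pp$indices$p_max_q,
                      MaxQ_star = pp$indices$max_q_star,
                      PMaxQ_star = pp$indices$p_max_q_star,
                      n_windows = NA_integer_, Max2 = NA_real_,
                      PMax2 = NA_real_, Max3 = NA_real_, PMax3 = NA_real_,
                      MaxMax = NA_real_, PMaxMax = NA_real_,
                      stringsAsFactors = FALSE)
    if (scan && s$length >= params$window) {
      pi <- persistency_indices(perscan(s, params = params))
      row$n_windows <- pi$n_windows
      row$Max2 <- pi$max2; row$PMax2 <- pi$p_max2
      row$Max3 <- pi$max3; row$PMax3 <- pi$p_max3
      row$MaxMax <- pi$max_max; row$PMaxMax <- pi$p_max_max
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble a cohort of replicon records
#'
#' Joins per-replicon indices with prophage annotations and species labels.
#' Replicons with no annotation rows are prophage-free; replicons absent
#' from the species table fall back to their own id as species key.
#'
#' @param indices data frame from [analyze_replicons()] (or read from an
#'   indices TSV with the same columns).
#' @param prophages data frame from [read_prophage_table()], or `NULL` for
#'   an all-prophage-free cohort.
#' @param species data frame from [read_species_table()] (columns
#'   `replicon_id`, `species_key`), or `NULL`.
#' @param persistent_threshold `MaxMax` cutoff for the persistent flag.
#' @return Data frame of class `c("cohort", "data.frame")`: the indices
#'   plus `species_key`, `has_prophage` and `persistent`.
#' @export
build_cohort <- function(indices, prophages = NULL, species = NULL,
                         persistent_threshold = 20) {
  stopifnot(is.data.frame(indices), "replicon_id" %in% names(indices))
  out <- indices
  ids <- out$replicon_id
  if (anyDuplicated(ids)) stop("duplicated replicon_id in indices")
  with_prophage <- if (is.null(prophages) || nrow(prophages) == 0L)
    character(0) else unique(prophages$replicon_id)
  unknown <- setdiff(with_prophage, ids)
  if (length(unknown))
    warning("prophage annotations for replicons without indices: ",
            paste(unknown, collapse = ", "))
  out$has_prophage <- ids %in% with_prophage
  out$species_key <- ids
  if (!is.null(species)) {
    m <- match(ids, species$replicon_id)
    hit <- !is.na(m)
    out$species_key[hit] <- species$species_key[m[hit]]
  }
  if (any(!nzchar(out$species_key))) stop("empty species key")
  out$persistent <- !is.na(out$MaxMax) &
    out$MaxMax >= persistent_threshold
  class(out) <- c("cohort", "data.frame")
  out
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the point-probability criterion (the sum of
#' hypergeometric probabilities of all tables with the same margins that
#' are no more probable than the observed one), as implemented in
#' [stats::fisher.test()]. Degenerate margins give `p = 1` with a warning
#' flag instead of an error.
#'
#' @param x 2x2 integer matrix, or the count `a` with `b`, `c`, `d`
#'   supplied. Layout for prophage cohorts: rows prophage-free /
#'   prophage-containing, columns persistent / not persistent.
#' @param b,c,d remaining cells when `x` is scalar.
#' @return List of class `periodicity_test`: `statistic` (odds ratio
#'   estimate, `NA` when degenerate), `p_value`, `method`, `degenerate`.
#' @examples
#' fisher_exact(23, 284, 5, 353)$p_value  # < 1e-4
#' @export
fisher_exact <- function(x, b = NULL, c = NULL, d = NULL) {
  tab <- if (is.matrix(x)) x else matrix(c(x, c, b, d), 2L, 2L)
  if (!all(dim(tab) == 2L)) stop("need a 2x2 table")
  storage.mode(tab) <- "integer"
  if (any(is.na(tab)) || any(tab < 0L)) stop("cell counts must be >= 0")
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    warning("degenerate 2x2 margins; p set to 1")
    return(structure(list(statistic = NA_real_, p_value = 1,
                          method = "fisher_exact", degenerate = TRUE),
                     class = "periodicity_test"))
  }
  ft <- fisher.test(tab)
  structure(list(statistic = unname(ft$estimate), p_value = ft$p.value,
                 method = "fisher_exact", degenerate = FALSE),
            class = "periodicity_test")
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. The exact null distribution is enumerated when
#' the smaller sample has at most 8 observations and there are no ties;
#' otherwise the normal approximation with tie correction and a 0.5
#' continuity correction is used (via [stats::wilcox.test()]).
#'
#' @param x,y numeric samples.
#' @return List of class `periodicity_test`: `statistic` (U for `x`),
#'   `p_value`, `method` (`"mann_whitney_exact"` or
#'   `"mann_whitney_normal"`), `degenerate`.
#' @examples
#' mann_whitney_u(1:3, 4:6)$p_value  # exact: 0.1
#' @export
mann_whitney_u <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= 8L && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 method = if (exact) "mann_whitney_exact"
                          else "mann_whitney_normal",
                 degenerate = FALSE),
            class = "periodicity_test")
}

#' @export
print.periodicity_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, two-sided p = %.4g%s\n", x$method,
              format(x$statistic, digits = 4), x$p_value,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' One-strain-per-species resampled rank tests
#'
#' Repeats the Mann-Whitney comparison of an index between prophage-free
#' and prophage-containing replicons, drawing uniformly one replicon per
#' species in each iteration to reduce bias from multiply sequenced
#' species. Iterations where either group empties are recorded as
#' non-significant with a warning.
#'
#' @param cohort a [build_cohort()] data frame.
#' @param index column to compare: one of `"Max2"`, `"Max3"`, `"MaxMax"`,
#'   `"MaxQ_star"` (any numeric cohort column works).
#' @param n_iter number of resampling iterations (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed optional integer; set for reproducibility.
#' @return List of class `resampling_result`: `n_significant`, `n_iter`,
#'   `n_degenerate`, `alpha`, `index`, and the vector `p_values`.
#' @export
one_per_species_resampling <- function(cohort, index = "MaxMax",
                                       n_iter = 1000L, alpha = 0.05,
                                       seed = NULL) {
  stopifnot(is.data.frame(cohort), index %in% names(cohort),
            "species_key" %in% names(cohort),
            "has_prophage" %in% names(cohort))
  if (!is.null(seed)) set.seed(seed)
  n_iter <- as.integer(n_iter)
  stopifnot(n_iter >= 1L)
  keep <- !is.na(cohort[[index]])
  cohort <- cohort[keep, , drop = FALSE]
  if (!nrow(cohort)) stop("no usable values in index '", index, "'")
  by_species <- split(seq_len(nrow(cohort)), cohort$species_key)
  flag <- cohort$has_prophage
  vals <- cohort[[index]]
  p <- rep(NA_real_, n_iter)
  n_degenerate <- 0L
  for (it in seq_len(n_iter)) {
    pick <- vapply(by_species, function(i)
      if (length(i) == 1L) i else i[sample.int(length(i), 1L)], integer(1))
    g <- flag[pick]
    if (!any(g) || all(g)) {
      n_degenerate <- n_degenerate + 1L
      p[it] <- 1
      next
    }
    p[it] <- mann_whitney_u(vals[pick][!g], vals[pick][g])$p_value
  }
  if (n_degenerate > 0L)
    warning(n_degenerate, " iteration(s) left a prophage group empty; ",
            "counted as non-significant")
  structure(list(n_significant = sum(p <= alpha), n_iter = n_iter,
                 n_degenerate = n_degenerate, alpha = alpha, index = index,
                 p_values = p),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf(
    "one-strain-per-species resampling of %s: %d / %d tests with p <= %g\n",
    x$index, x$n_significant, x$n_iter, x$alpha))
  invisible(x)
}

#' Extract a random chromosomal segment
#'
#' Draws a contiguous subsequence whose length is uniform on
#' `[len_lo, len_hi]` and whose start is uniform over the admissible range
#' (used to compare phage genomes with size-matched chromosomal segments).
#'
#' @param seq a `genome_sequence` or character string.
#' @param len_lo,len_hi segment length range in bp (defaults 50--200 kb).
#' @param seed optional integer seed.
#' @return A `genome_sequence`; its id records the source coordinates
#'   (1-based inclusive).
#' @export
sample_chromosome_segment <- function(seq, len_lo = 50000L,
                                      len_hi = 200000L, seed = NULL) {
  seq <- as_genome_sequence(seq)
  len_lo <- as.integer(len_lo); len_hi <- as.integer(len_hi)
  stopifnot(len_lo >= 1L, len_lo <= len_hi)
  if (seq$length < len_hi)
    stop("sequence '", seq$id, "' (", seq$length,
         " bp) shorter than len_hi (", len_hi, " bp)")
  if (!is.null(seed)) set.seed(seed)
  len <- if (len_lo == len_hi) len_lo else
    len_lo + sample.int(len_hi - len_lo + 1L, 1L) - 1L
  start <- sample.int(seq$length - len + 1L, 1L)  # 1-based
  genome_sequence(substr(seq$residues, start, start + len - 1L),
                  id = sprintf("%s:%d-%d", seq$id, start, start + len - 1L))
}

#' Cohort summary report
#'
#' Computes the package's cohort-level outputs in one object: the 2x2
#' persistent-by-prophage contingency table with its Fisher test, the
#' one-strain-per-species resampling counts for each persistency index, and
#' the scatter data behind the usual cohort figures (`MaxQ*` vs length;
#' `MaxMax` vs G+C and vs length, split by prophage status).
#'
#' @param cohort a [build_cohort()] data frame.
#' @param indices cohort columns to resample; defaults to the three
#'   persistency indices and `MaxQ_star`.
#' @param n_iter,alpha resampling protocol (defaults 1000 and 0.05).
#' @param seed optional integer seed for the resampling.
#' @return Object of class `cohort_report`: `n`, `table` (2x2 matrix, rows
#'   prophage-free/containing, columns persistent/not), `fisher`,
#'   `resampling` (named list of [one_per_species_resampling()] results),
#'   `scatter` (data frame), `alpha`.
#' @export
cohort_report <- function(cohort,
                          indices = c("Max2", "Max3", "MaxMax",
                                      "MaxQ_star"),
                          n_iter = 1000L, alpha = 0.05, seed = NULL) {
  stopifnot(inherits(cohort, "data.frame"), nrow(cohort) >= 1L,
            all(c("has_prophage", "persistent") %in% names(cohort)))
  tab <- matrix(c(
    sum(!cohort$has_prophage & cohort$persistent),
    sum(!cohort$has_prophage & !cohort$persistent),
    sum(cohort$has_prophage & cohort$persistent),
    sum(cohort$has_prophage & !cohort$persistent)),
    nrow = 2L, byrow = TRUE,
    dimnames = list(c("prophage_free", "prophage_containing"),
                    c("persistent", "not_persistent")))
  fisher <- withCallingHandlers(
    fisher_exact(tab),
    warning = function(w) invokeRestart("muffleWarning"))
  if (!is.null(seed)) set.seed(seed)
  resampling <- lapply(setNames(indices, indices), function(ix)
    if (ix %in% names(cohort) && !all(is.na(cohort[[ix]])))
      one_per_species_resampling(cohort, ix, n_iter = n_iter,
                                 alpha = alpha)
    else NULL)
  scatter <- cohort[, intersect(
    c("replicon_id", "length", "gc", "MaxQ_star", "MaxMax",
      "has_prophage", "persistent"), names(cohort)), drop = FALSE]
  structure(list(n = nrow(cohort), table = tab, fisher = fisher,
                 resampling = resampling, scatter = scatter,
                 alpha = alpha),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort periodicity report (", x$n, " replicons)\n", sep = "")
  cat("\nPersistent periodicity vs prophage presence:\n")
  print(x$table)
  pf <- x$table[1, 1] / sum(x$table[1, ])
  pc <- x$table[2, 1] / sum(x$table[2, ])
  if (is.finite(pf) && is.finite(pc))
    cat(sprintf("  persistent: %.2f%% of prophage-free vs %.2f%% of ",
                100 * pf, 100 * pc),
        "prophage-containing\n", sep = "")
  cat(sprintf("  Fisher's exact test: two-sided p = %.3g%s\n",
              x$fisher$p_value,
              if (x$fisher$degenerate) " (degenerate table)" else ""))
  done <- !vapply(x$resampling, is.null, logical(1))
  if (any(done)) {
    cat("\nOne-strain-per-species Mann-Whitney resampling",
        sprintf("(p <= %g):\n", x$alpha))
    for (nm in names(x$resampling)[done])
      cat(sprintf("  %-9s %4d / %d significant\n", nm,
                  x$resampling[[nm]]$n_significant,
                  x$resampling[[nm]]$n_iter))
  }
  invisible(x)
}
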