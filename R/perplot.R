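# A-tract vocabularies. Each method maps to the set of motifs whose exact
# forward-strand matches count as tracts. A2T2 = {AA, TT}; since TT is the
# reverse complement of AA, a forward-strand scan captures both strands.
.atract_registry <- list(A2T2 = c("AA", "TT"))

#' Locate A-tracts in a sequence
#'
#' Finds every exact match of the registered tract motifs on the forward
#' strand; partially overlapping matches are each counted (a run of k >= 2
#' consecutive A's yields k-1 AA tracts). Matches containing ambiguity codes
#' are impossible by construction (only exact A/T bytes match).
#'
#' @param seq a `genome_sequence` or character string.
#' @param method A-tract definition tag; only `"A2T2"` ships.
#' @return Object of class `atract_positions`: list with `positions`
#'   (sorted 0-based match start coordinates), `n` (match count), `method`,
#'   and `L` (sequence length).
#' @examples
#' find_atracts("AATT")$positions  # 0 2
#' find_atracts("AAAA")$positions  # 0 1 2
#' @export
find_atracts <- function(seq, method = "A2T2") {
  if (!method %in% names(.atract_registry))
    stop("unknown A-tract method '", method, "'; registered: ",
         paste(names(.atract_registry), collapse = ", "))
  seq <- as_genome_sequence(seq)
  b <- charToRaw(seq$residues)
  pos <- .atract_positions_raw(b, method)
  structure(list(positions = pos, n = length(pos), method = method,
                 L = length(b)),
            class = "atract_positions")
}

# motif scan on a raw byte vector; returns sorted 0-based starts
.atract_positions_raw <- function(b, method = "A2T2") {
  L <- length(b)
  motifs <- .atract_registry[[method]]
  w <- unique(nchar(motifs))
  if (length(w) != 1L)
    stop("mixed motif widths are not supported in method '", method, "'")
  if (L < w) return(integer(0))
  hit <- logical(L - w + 1L)
  for (m in motifs) {
    mb <- charToRaw(m)
    ok <- b[seq_len(L - w + 1L)] == mb[1L]
    for (k in seq_len(w - 1L))
      ok <- ok & (b[(1L + k):(L - w + 1L + k)] == mb[k + 1L])
    hit <- hit | ok
  }
  which(hit) - 1L
}

#' @export
print.atract_positions <- function(x, ...) {
  cat(sprintf("<atract_positions> %d %s tracts in %d bp\n",
              x$n, x$method, x$L))
  invisible(x)
}

#' Histogram of A-tract pair spacings
#'
#' `N(s)` counts ordered pairs of tract start positions at mutual distance
#' `s`, for `s = 1 .. s_hi`. The histogram is computed one bin past `s_max`
#' so the 3-bp smoother has full support at `s_max`.
#'
#' @param tracts an `atract_positions` object (or sorted 0-based integer
#'   vector of positions).
#' @param s_hi largest spacing tallied (bp).
#' @return Object of class `spacing_histogram`: list with `s` (`1:s_hi`),
#'   `raw` counts, and metadata `n_tracts`, `L`. The `normalized`,
#'   `smoothed` and `detrended` fields are filled by the later stages.
#' @examples
#' h <- spacing_histogram(find_atracts("AAAA"), s_hi = 5)
#' h$raw  # 2 1 0 0 0
#' @export
spacing_histogram <- function(tracts, s_hi = 101L) {
  if (inherits(tracts, "atract_positions")) {
    pos <- tracts$positions; L <- tracts$L
  } else {
    pos <- as.integer(tracts); L <- NA_integer_
    if (is.unsorted(pos, strictly = TRUE))
      stop("positions must be strictly increasing")
  }
  s_hi <- as.integer(s_hi)
  stopifnot(s_hi >= 1L)
  structure(list(s = seq_len(s_hi), raw = .pair_spacing_counts(pos, s_hi),
                 normalized = NULL, smoothed = NULL, detrended = NULL,
                 s_min = NA_integer_, s_max = NA_integer_,
                 n_tracts = length(pos), L = L),
            class = "spacing_histogram")
}

# pair counts by increasing position lag: for lag k the spacings
# pos[i+k]-pos[i] are non-decreasing in k at fixed i, so once every spacing
# at some lag exceeds s_hi no larger lag can contribute.
.pair_spacing_counts <- function(pos, s_hi) {
  n <- length(pos)
  N <- integer(s_hi)
  if (n < 2L) return(N)
  k <- 1L
  while (k < n) {
    d <- pos[(1L + k):n] - pos[seq_len(n - k)]
    d <- d[d <= s_hi]
    if (!length(d)) break
    N <- N + tabulate(d, nbins = s_hi)
    k <- k + 1L
  }
  N
}

#' @export
print.spacing_histogram <- function(x, ...) {
  cat(sprintf("<spacing_histogram> s = 1..%d, %d tracts, %s pairs counted\n",
              max(x$s), x$n_tracts, format(sum(x$raw), big.mark = ",")))
  stages <- c(normalized = !is.null(x$normalized),
              smoothed = !is.null(x$smoothed),
              detrended = !is.null(x$detrended))
  cat("  stages done:", if (any(stages))
    paste(names(stages)[stages], collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Normalize spacing counts against the random-placement expectation
#'
#' `h(s) = N(s) / E(s)` with `E(s) = (n_t/M)^2 (M - s)`, where `M = L - 1`
#' is the number of possible dinucleotide start sites: the expected count if
#' the observed number of tracts were placed uniformly at random. Any smooth
#' misfit of this expectation is absorbed by the later parabolic detrending.
#'
#' @param hist a `spacing_histogram` with raw counts.
#' @param n_tracts,L tract count and sequence length; default to the values
#'   recorded in `hist`.
#' @return The histogram with the `normalized` field filled.
#' @export
normalize_histogram <- function(hist, n_tracts = hist$n_tracts, L = hist$L) {
  stopifnot(inherits(hist, "spacing_histogram"))
  if (is.na(n_tracts) || n_tracts < 2L)
    stop("insufficient signal: need at least 2 A-tracts, got ",
         if (is.na(n_tracts)) 0L else n_tracts)
  if (is.na(L) || L <= max(hist$s) + 1L)
    stop("sequence length (", L, ") must exceed s_hi + 1 = ",
         max(hist$s) + 1L)
  M <- L - 1
  E <- (n_tracts / M)^2 * (M - hist$s)
  if (any(E <= 0)) stop("expected counts vanish; sequence too short")
  hist$normalized <- hist$raw / E
  hist$n_tracts <- n_tracts
  hist$L <- L
  hist
}

#' 3-bp sliding-window average
#'
#' Removes the 3-bp periodic component arising from biased codon usage in
#' genes. At the range ends the window shrinks to the available bins.
#'
#' @param hist a `spacing_histogram` with normalized values, or a plain
#'   numeric vector.
#' @return The histogram with `smoothed` filled, or the smoothed vector.
#' @export
smooth3 <- function(hist) {
  if (is.numeric(hist)) return(.smooth3_vec(hist))
  stopifnot(inherits(hist, "spacing_histogram"))
  if (is.null(hist$normalized))
    stop("normalize_histogram() must run before smooth3()")
  hist$smoothed <- .smooth3_vec(hist$normalized)
  hist
}

.smooth3_vec <- function(h) {
  n <- length(h)
  if (n == 1L) return(h)
  num <- c(0, h[-n]) + h + c(h[-1L], 0)
  num / c(2, rep(3, max(0L, n - 2L)), 2)
}

#' Subtract a parabolic trend
#'
#' Fits `a + b s + c s^2` by least squares to the smoothed histogram over
#' `s` in `[s_min, s_max]` and keeps the residuals: compositional drift along
#' the sequence produces a slow trend in `h(s)` that would otherwise leak
#' into the low-frequency end of the spectrum.
#'
#' @param hist a `spacing_histogram` with smoothed values.
#' @param s_min,s_max fit range (bp); defaults 30 and 100.
#' @return The histogram with `detrended` filled (defined on
#'   `[s_min, s_max]`) and `s_min`, `s_max` recorded.
#' @export
detrend_parabola <- function(hist, s_min = 30L, s_max = 100L) {
  stopifnot(inherits(hist, "spacing_histogram"))
  if (is.null(hist$smoothed))
    stop("smooth3() must run before detrend_parabola()")
  s_min <- as.integer(s_min); s_max <- as.integer(s_max)
  if (s_min >= s_max) stop("s_min must be smaller than s_max")
  if (s_min < min(hist$s) || s_max > max(hist$s))
    stop("detrending range [", s_min, ", ", s_max,
         "] outside histogram range")
  ss <- s_min:s_max
  if (length(ss) < 3L) stop("need at least 3 bins to fit a parabola")
  fit <- lm.fit(cbind(1, ss, ss^2), hist$smoothed[ss])
  hist$detrended <- unname(fit$residuals)
  hist$s_min <- s_min
  hist$s_max <- s_max
  hist
}

# Trig/design matrices for direct spectral summation are reused across
# windows and replicates; cached per (s_min, s_max, grid).
.plan_cache <- new.env(parent = emptyenv())

.spectrum_plan <- function(s_min, s_max, grid, norm_range, star_range) {
  key <- paste(s_min, s_max, length(grid), min(grid), max(grid),
               paste(norm_range, collapse = ","),
               paste(star_range, collapse = ","), sep = "|")
  plan <- .plan_cache[[key]]
  if (!is.null(plan)) return(plan)
  ss <- s_min:s_max
  theta <- 2 * pi * outer(ss, 1 / grid)
  plan <- list(
    ss = ss, grid = grid, C = cos(theta), S = sin(theta),
    band = grid >= norm_range[1] - 1e-9 & grid <= norm_range[2] + 1e-9,
    star = grid >= star_range[1] - 1e-9 & grid <= star_range[2] + 1e-9)
  .plan_cache[[key]] <- plan
  plan
}

#' Period spectrum of the detrended spacing histogram
#'
#' Evaluates the amplitude spectrum
#' `Q(P) = |sum_{s = s_min}^{s_max} d(s) exp(2 pi i s / P)|`
#' by direct summation at every grid period (the grid is uniform in period,
#' not frequency, because all indices are defined in period units), then
#' scales it so that the mean of `Q*` over periods 5--20 bp equals 1. The
#' amplitude scale is what makes the conventional `MaxQ >= 3` significance
#' threshold hold its published ~1.5% false-positive rate on random
#' sequences; see the package vignette.
#'
#' @param hist a `spacing_histogram` with detrended values.
#' @param grid period grid (bp); default `seq(3, 25, by = 0.05)`.
#' @param norm_range periods over which the `Q*` mean is fixed to 1.
#' @param star_range curvature band recorded for downstream index
#'   extraction.
#' @return Object of class `period_spectrum`: list with `period`, `q_raw`,
#'   `q_star`, `norm_range`, `star_range`.
#' @export
power_spectrum <- function(hist, grid = seq(3, 25, by = 0.05),
                           norm_range = c(5, 20),
                           star_range = c(9.5, 11.5)) {
  stopifnot(inherits(hist, "spacing_histogram"))
  if (is.null(hist$detrended))
    stop("detrend_parabola() must run before power_spectrum()")
  plan <- .spectrum_plan(hist$s_min, hist$s_max, grid, norm_range,
                         star_range)
  .spectrum_from_detrended(hist$detrended, plan, norm_range, star_range)
}

.spectrum_from_detrended <- function(d, plan, norm_range, star_range) {
  q <- sqrt(drop(d %*% plan$C)^2 + drop(d %*% plan$S)^2)
  m <- mean(q[plan$band])
  if (m == 0)
    stop("degenerate spectrum: signal identically zero over the ",
         "normalization band")
  structure(list(period = plan$grid, q_raw = q, q_star = q / m,
                 norm_range = norm_range, star_range = star_range),
            class = "period_spectrum")
}

#' @export
print.period_spectrum <- function(x, ...) {
  band <- x$period >= x$norm_range[1] - 1e-9 &
    x$period <= x$norm_range[2] + 1e-9
  i <- which(band)[which.max(x$q_star[band])]
  cat(sprintf(
    "<period_spectrum> %d periods %.2f-%.2f bp; peak Q* = %.2f at %.2f bp\n",
    length(x$period), min(x$period), max(x$period), x$q_star[i],
    x$period[i]))
  invisible(x)
}

#' Peak indices of a period spectrum
#'
#' `MaxQ`/`PMaxQ` are the height and period of the highest `Q*` peak within
#' the 5--20 bp band; `MaxQ*`/`PMaxQ*` restrict the search to the
#' curvature-relevant 9.5--11.5 bp band (the 5--20 bp band still sets the
#' normalization). Ties break toward the smaller period.
#'
#' @param spectrum a `period_spectrum`.
#' @param norm_range,star_range index bands; default to those recorded in
#'   the spectrum.
#' @return Named list with `max_q`, `p_max_q`, `max_q_star`, `p_max_q_star`.
#' @export
perplot_indices <- function(spectrum, norm_range = spectrum$norm_range,
                            star_range = spectrum$star_range) {
  stopifnot(inherits(spectrum, "period_spectrum"))
  peak <- function(range) {
    in_band <- spectrum$period >= range[1] - 1e-9 &
      spectrum$period <= range[2] + 1e-9
    i <- which(in_band)[which.max(spectrum$q_star[in_band])]
    c(spectrum$q_star[i], spectrum$period[i])
  }
  q <- peak(norm_range)
  qs <- peak(star_range)
  list(max_q = q[1], p_max_q = q[2], max_q_star = qs[1], p_max_q_star = qs[2])
}

#' Whole-sequence periodicity analysis (periodicity plot)
#'
#' Runs the full chain on one sequence: A-tract scan, spacing histogram,
#' normalization, 3-bp smoothing, parabolic detrending, period spectrum,
#' peak indices. Sequences with fewer than `params$min_tracts_genome`
#' A-tracts give a flagged missing result (`valid = FALSE`, `NA` indices)
#' rather than an error, because below that the normalized histogram is
#' dominated by shot noise.
#'
#' @param x sequence: `genome_sequence`, character string, or anything
#'   [as_genome_sequence()] accepts.
#' @param params a [periodicity_params()] bundle.
#' @param keep_histogram,keep_spectrum set `FALSE` to drop the bulky stage
#'   outputs (used internally by mass simulations).
#' @return Object of class `perplot`: fields `id`, `length`, `gc`,
#'   `n_tracts`, `valid`, `reason`, `histogram` (a `spacing_histogram`),
#'   `spectrum` (a `period_spectrum`), `indices` (see [perplot_indices()]),
#'   `params`.
#' @examples
#' pp <- perplot(planted_periodic_sequence(60000, period = 10.9,
#'                                         seed = 1)$sequence)
#' coef(pp)
#' @export
perplot <- function(x, params = periodicity_params(),
                    keep_histogram = TRUE, keep_spectrum = TRUE) {
  seq <- as_genome_sequence(x)
  if (seq$length <= params$s_max + 2L)
    stop("sequence '", seq$id, "' (", seq$length,
         " bp) is too short: need length > s_max + 2 = ", params$s_max + 2L)
  b <- charToRaw(seq$residues)
  res <- .pp_chain(b, params)
  out <- structure(list(id = seq$id, length = seq$length, gc = seq$gc,
                        n_tracts = res$n_tracts, valid = res$valid,
                        reason = res$reason,
                        histogram = if (keep_histogram) res$histogram,
                        spectrum = if (keep_spectrum) res$spectrum,
                        indices = res$indices, params = params),
                   class = "perplot")
  out
}

# full stage chain on a raw byte vector; never throws for low signal --
# returns valid = FALSE with a reason instead. min_tracts selects the
# whole-genome or per-window floor.
.pp_chain <- function(b, params, min_tracts = params$min_tracts_genome) {
  pos <- .atract_positions_raw(b, params$atract_method)
  n_t <- length(pos)
  miss <- function(reason)
    list(valid = FALSE, reason = reason, n_tracts = n_t,
         histogram = NULL, spectrum = NULL,
         indices = list(max_q = NA_real_, p_max_q = NA_real_,
                        max_q_star = NA_real_, p_max_q_star = NA_real_))
  if (n_t < max(2L, min_tracts))
    return(miss(sprintf("insufficient A-tracts (%d < %d)", n_t,
                        max(2L, min_tracts))))
  L <- length(b)
  s_hi <- params$s_max + 1L
  if (L <= s_hi + 1L) return(miss("sequence shorter than spacing range"))
  hist <- structure(list(s = seq_len(s_hi),
                         raw = .pair_spacing_counts(pos, s_hi),
                         normalized = NULL, smoothed = NULL,
                         detrended = NULL, s_min = NA_integer_,
                         s_max = NA_integer_, n_tracts = n_t, L = L),
                    class = "spacing_histogram")
  hist <- normalize_histogram(hist)
  hist <- smooth3(hist)
  hist <- detrend_parabola(hist, params$s_min, params$s_max)
  plan <- .spectrum_plan(params$s_min, params$s_max, params$grid,
                         params$norm_range, params$star_range)
  spectrum <- tryCatch(
    .spectrum_from_detrended(hist$detrended, plan, params$norm_range,
                             params$star_range),
    error = function(e) NULL)
  if (is.null(spectrum)) return(miss("degenerate spectrum"))
  list(valid = TRUE, reason = NA_character_, n_tracts = n_t,
       histogram = hist, spectrum = spectrum,
       indices = perplot_indices(spectrum))
}

#' @export
print.perplot <- function(x, ...) {
  cat(sprintf("<perplot> %s: %s bp, G+C = %.3f, %d A-tracts\n",
              x$id, format(x$length, big.mark = ","), x$gc, x$n_tracts))
  if (!x$valid) {
    cat("  no valid spectrum:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("  MaxQ  = %6.2f at period %5.2f bp   (band %.1f-%.1f bp)\n",
              x$indices$max_q, x$indices$p_max_q,
              x$params$norm_range[1], x$params$norm_range[2]))
  cat(sprintf("  MaxQ* = %6.2f at period %5.2f bp   (band %.1f-%.1f bp)\n",
              x$indices$max_q_star, x$indices$p_max_q_star,
              x$params$star_range[1], x$params$star_range[2]))
  invisible(x)
}

#' @export
summary.perplot <- function(object, ...) {
  print(object)
  if (object$valid) {
    cat(sprintf("  pairs counted (s <= %d): %s\n",
                max(object$histogram$s),
                format(sum(object$histogram$raw), big.mark = ",")))
    cat(sprintf("  MaxQ >= 3 convention (~1.5%% of random sequences): %s\n",
                if (object$indices$max_q >= 3)
                  "signal above the noise criterion"
                else "no signal above the noise criterion"))
  }
  invisible(object)
}

#' @export
coef.perplot <- function(object, ...) {
  c(MaxQ = object$indices$max_q, PMaxQ = object$indices$p_max_q,
    MaxQ_star = object$indices$max_q_star,
    PMaxQ_star = object$indices$p_max_q_star)
}

#' @export
residuals.perplot <- function(object, ...) {
  if (!object$valid || is.null(object$histogram)) return(NULL)
  setNames(object$histogram$detrended,
           object$histogram$s_min:object$histogram$s_max)
}

#' Plot a periodicity spectrum
#'
#' Draws `Q*(P)` against period, shades the curvature band and marks the
#' `MaxQ` threshold convention.
#'
#' @param x a `perplot` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.perplot <- function(x, ...) {
  if (!x$valid || is.null(x$spectrum))
    stop("no valid spectrum to plot (", x$reason, ")")
  sp <- x$spectrum
  plot(sp$period, sp$q_star, type = "l", xlab = "period (bp)",
       ylab = expression(Q^"*" * (P)),
       main = paste0(x$id, ": A-tract spacing periodicity"), ...)
  rect(x$params$star_range[1], par("usr")[3], x$params$star_range[2],
       par("usr")[4], col = "#4a90d920", border = NA)
  abline(h = 3, lty = 3)
  abline(h = 1, lty = 3, col = "grey60")
  lines(sp$period, sp$q_star)
  invisible(x)
}
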