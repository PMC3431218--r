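#' Analysis parameters for the periodicity pipeline
#'
#' Bundles every tunable of the perplot/perscan chain with its default.
#' Defaults follow the published protocol where one is printed: spacing
#' range 30--100 bp, spectrum normalized to mean 1 over periods 5--20 bp,
#' curvature band 9.5--11.5 bp, 10 kb window moved in 5 kb steps, and the
#' MaxMax >= 20 persistency threshold.
#'
#' @param s_min,s_max spacing range (bp) of the histogram section that is
#'   detrended and Fourier-transformed. Default 30 and 100.
#' @param grid period grid (bp) on which the spectrum is evaluated by direct
#'   summation. Default `seq(3, 25, by = 0.05)`; the 0.05 bp step keeps grid
#'   error well below the 0.2 bp period tolerance used by `MaxMax`.
#' @param norm_range periods (bp) over which the mean of `Q*` is fixed to 1
#'   and within which `MaxQ`/`PMaxQ` are taken. Default `c(5, 20)`.
#' @param star_range curvature-relevant period band for `MaxQ*`/`PMaxQ*`.
#'   Default `c(9.5, 11.5)`.
#' @param window,step sliding-window size and step (bp) for [perscan()].
#'   Default 10000 and 5000.
#' @param maxmax_threshold `MaxMax` percentage at or above which a replicon
#'   is called persistently periodic. Default 20.
#' @param period_tol period tolerance (bp) used by the `MaxMax` index.
#'   Default 0.2.
#' @param min_tracts_genome,min_tracts_window minimum number of A-tracts for
#'   a valid whole-sequence spectrum (default 50) and per window (default 20);
#'   below these the result is flagged missing rather than computed from shot
#'   noise.
#' @param atract_method A-tract definition tag; `"A2T2"` (the AA/TT
#'   dinucleotide vocabulary) is the only definition that ships.
#' @param n_iter,alpha iterations and significance level of the
#'   one-strain-per-species resampling protocol. Defaults 1000 and 0.05.
#'
#' @return A named list of class `periodicity_params`.
#' @examples
#' p <- periodicity_params(window = 20000)
#' p$window
#' @export
periodicity_params <- function(s_min = 30L,
                               s_max = 100L,
                               grid = seq(3, 25, by = 0.05),
                               norm_range = c(5, 20),
                               star_range = c(9.5, 11.5),
                               window = 10000L,
                               step = 5000L,
                               maxmax_threshold = 20,
                               period_tol = 0.2,
                               min_tracts_genome = 50L,
                               min_tracts_window = 20L,
                               atract_method = "A2T2",
                               n_iter = 1000L,
                               alpha = 0.05) {
  s_min <- as.integer(s_min); s_max <- as.integer(s_max)
  stopifnot(s_min >= 1L, s_min < s_max,
            length(norm_range) == 2L, norm_range[1] < norm_range[2],
            length(star_range) == 2L, star_range[1] < star_range[2],
            window > 0, step > 0, period_tol > 0,
            n_iter >= 1, alpha > 0, alpha < 1)
  if (min(grid) > norm_range[1] || max(grid) < norm_range[2])
    stop("period grid must cover the normalization range [",
         norm_range[1], ", ", norm_range[2], "]")
  if (min(grid) > star_range[1] || max(grid) < star_range[2])
    stop("period grid must cover the curvature band [",
         star_range[1], ", ", star_range[2], "]")
  structure(list(
    s_min = s_min, s_max = s_max, grid = grid,
    norm_range = norm_range, star_range = star_range,
    window = as.integer(window), step = as.integer(step),
    maxmax_threshold = maxmax_threshold, period_tol = period_tol,
    min_tracts_genome = as.integer(min_tracts_genome),
    min_tracts_window = as.integer(min_tracts_window),
    atract_method = atract_method,
    n_iter = as.integer(n_iter), alpha = alpha
  ), class = "periodicity_params")
}

#' @export
print.periodicity_params <- function(x, ...) {
  cat("Periodicity analysis parameters\n")
  cat(sprintf("  spacing range      : %d-%d bp\n", x$s_min, x$s_max))
  cat(sprintf("  period grid        : %.2f-%.2f bp, step %.3g bp\n",
              min(x$grid), max(x$grid), x$grid[2] - x$grid[1]))
  cat(sprintf("  normalization band : %.1f-%.1f bp (mean Q* = 1)\n",
              x$norm_range[1], x$norm_range[2]))
  cat(sprintf("  curvature band     : %.1f-%.1f bp\n",
              x$star_range[1], x$star_range[2]))
  cat(sprintf("  scan window/step   : %d / %d bp\n", x$window, x$step))
  cat(sprintf("  persistent if MaxMax >= %.0f%%\n", x$maxmax_threshold))
  invisible(x)
}

# serialize params into "key=value;..." for provenance headers
.params_string <- function(params) {
  paste(sprintf(
    "s_min=%d;s_max=%d;grid=%.2f:%.2f:%.3g;norm=%.1f-%.1f;star=%.1f-%.1f;window=%d;step=%d;maxmax_thr=%g;tol=%g;min_tracts=%d/%d;method=%s",
    params$s_min, params$s_max, min(params$grid), max(params$grid),
    params$grid[2] - params$grid[1], params$norm_range[1], params$norm_range[2],
    params$star_range[1], params$star_range[2], params$window, params$step,
    params$maxmax_threshold, params$period_tol, params$min_tracts_genome,
    params$min_tracts_window, params$atract_method))
}
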