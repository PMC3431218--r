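#' Sliding-window periodicity scan
#'
#' Applies the [perplot()] stage chain to a window of size `W` moved along
#' the replicon in steps of `step` bp (defaults 10 kb / 5 kb). Windows with
#' fewer than `params$min_tracts_window` A-tracts are flagged missing; a
#' trailing stretch shorter than `W` is not scanned.
#'
#' @param x sequence: `genome_sequence`, character string, or anything
#'   [as_genome_sequence()] accepts.
#' @param window,step window size and step in bp; default from `params`.
#' @param params a [periodicity_params()] bundle.
#' @return Object of class `perscan`: fields `id`, `length`, `gc`,
#'   `window`, `step`, `window_starts` (0-based), `n_windows`, `valid`
#'   (logical per window), `spectra` (matrix, grid periods x windows, `NA`
#'   columns for missing windows), `window_pmax` (dominant period of each
#'   window over the 5--20 bp band), `window_maxq`, `params`.
#' @examples
#' sc <- perscan(planted_periodic_sequence(40000, period = 10.9,
#'                                         seed = 1)$sequence)
#' persistency_indices(sc)
#' @export
perscan <- function(x, window = params$window, step = params$step,
                    params = periodicity_params()) {
  seq <- as_genome_sequence(x)
  window <- as.integer(window); step <- as.integer(step)
  if (window <= params$s_max + 2L)
    stop("window (", window, " bp) must exceed s_max + 2 = ",
         params$s_max + 2L)
  if (step < 1L) stop("step must be positive")
  L <- seq$length
  if (L < window)
    stop("sequence '", seq$id, "' (", L,
         " bp) is shorter than the window (", window, " bp)")
  n_win <- (L - window) %/% step + 1L
  starts <- (seq_len(n_win) - 1L) * step
  b <- charToRaw(seq$residues)
  plan <- .spectrum_plan(params$s_min, params$s_max, params$grid,
                         params$norm_range, params$star_range)
  band_idx <- which(plan$band)
  spectra <- matrix(NA_real_, nrow = length(params$grid), ncol = n_win)
  pmax_w <- rep(NA_real_, n_win)
  maxq_w <- rep(NA_real_, n_win)
  valid <- logical(n_win)
  for (w in seq_len(n_win)) {
    sub <- b[(starts[w] + 1L):(starts[w] + window)]
    res <- .pp_chain(sub, params, min_tracts = params$min_tracts_window)
    if (!res$valid) next
    valid[w] <- TRUE
    spectra[, w] <- res$spectrum$q_star
    i <- band_idx[which.max(res$spectrum$q_star[band_idx])]
    pmax_w[w] <- params$grid[i]
    maxq_w[w] <- res$spectrum$q_star[i]
  }
  structure(list(id = seq$id, length = L, gc = seq$gc, window = window,
                 step = step, window_starts = starts, n_windows = n_win,
                 valid = valid, spectra = spectra, window_pmax = pmax_w,
                 window_maxq = maxq_w, params = params),
            class = "perscan")
}

#' @export
print.perscan <- function(x, ...) {
  cat(sprintf(
    "<perscan> %s: %s bp, %d windows of %d bp every %d bp (%d valid)\n",
    x$id, format(x$length, big.mark = ","), x$n_windows, x$window, x$step,
    sum(x$valid)))
  invisible(x)
}

#' @export
summary.perscan <- function(object, ...) {
  print(object)
  print(persistency_indices(object))
  invisible(object)
}

#' Persistency indices of a periodicity scan
#'
#' For each candidate period `P` in the 5--20 bp band, `f_t(P)` is the
#' fraction of all windows whose `Q*(P)` reaches the threshold `t`;
#' `Max3`/`PMax3` are `100 * max` and argmax of `f_3`, `Max2`/`PMax2` of
#' `f_2`. `MaxMax`/`PMaxMax` use the dominant period instead: the fraction
#' of windows whose window `PMax` falls within `period_tol` (0.2 bp) of a
#' common period. Missing windows count in denominators and never satisfy a
#' criterion; ties break toward the smaller period.
#'
#' @param scan a `perscan` object.
#' @param thresholds `Q*` thresholds for the `Max2`/`Max3` family.
#' @param tol period tolerance (bp) for `MaxMax`; default from the scan's
#'   parameters.
#' @return Object of class `persistency_indices`: `max2`, `p_max2`, `max3`,
#'   `p_max3`, `max_max`, `p_max_max` (percent / bp), plus `n_windows`,
#'   `n_valid`.
#' @export
persistency_indices <- function(scan, thresholds = c(2, 3),
                                tol = scan$params$period_tol) {
  stopifnot(inherits(scan, "perscan"))
  if (scan$n_windows < 1L) stop("scan has no windows")
  params <- scan$params
  band <- params$grid >= params$norm_range[1] - 1e-9 &
    params$grid <= params$norm_range[2] + 1e-9
  cand <- params$grid[band]
  n <- scan$n_windows
  vcols <- which(scan$valid)
  sub <- scan$spectra[band, vcols, drop = FALSE]
  thr_peak <- function(t) {
    f <- if (length(vcols)) rowSums(sub >= t) / n else rep(0, nrow(sub))
    i <- which.max(f)
    c(100 * f[i], cand[i])
  }
  m2 <- thr_peak(min(thresholds))
  m3 <- thr_peak(max(thresholds))
  pm <- scan$window_pmax
  g <- vapply(cand, function(P0)
    sum(!is.na(pm) & abs(pm - P0) <= tol + 1e-9), numeric(1)) / n
  i <- which.max(g)
  structure(list(max2 = m2[1], p_max2 = m2[2], max3 = m3[1],
                 p_max3 = m3[2], max_max = 100 * g[i], p_max_max = cand[i],
                 n_windows = n, n_valid = length(vcols)),
            class = "persistency_indices")
}

#' @export
print.persistency_indices <- function(x, ...) {
  cat("Persistency of the dominant periodic signal\n")
  cat(sprintf("  Max2   = %5.1f%% of %d windows at period %5.2f bp\n",
              x$max2, x$n_windows, x$p_max2))
  cat(sprintf("  Max3   = %5.1f%% of %d windows at period %5.2f bp\n",
              x$max3, x$n_windows, x$p_max3))
  cat(sprintf("  MaxMax = %5.1f%% of %d windows at period %5.2f bp\n",
              x$max_max, x$n_windows, x$p_max_max))
  invisible(x)
}

#' Is the periodic signal persistent?
#'
#' A replicon is called exceptionally persistent when its `MaxMax` score
#' reaches the threshold (default 20%).
#'
#' @param idx a `persistency_indices` object (or a `perscan`, from which
#'   indices are computed).
#' @param threshold `MaxMax` percentage cutoff.
#' @return `TRUE` or `FALSE`.
#' @export
classify_persistent <- function(idx, threshold = 20) {
  if (inherits(idx, "perscan")) idx <- persistency_indices(idx)
  stopifnot(inherits(idx, "persistency_indices"))
  idx$max_max >= threshold
}

#' Heatmap matrix of a periodicity scan
#'
#' Maps each window spectrum to grey levels: `Q*` at `q_lo` (default 1, the
#' post-normalization noise level) renders white, `q_hi` (default 4, a
#' strong peak) black, linearly in between, clamped outside. Missing
#' windows render white.
#'
#' @param scan a `perscan` object.
#' @param q_lo,q_hi `Q*` values mapped to white and black.
#' @return List with `grey` (matrix in `[0, 1]`, 0 = white; rows = grid
#'   periods ascending, columns = windows by position), `period`,
#'   `window_start`.
#' @export
heatmap_matrix <- function(scan, q_lo = 1, q_hi = 4) {
  stopifnot(inherits(scan, "perscan"), q_hi > q_lo)
  g <- (scan$spectra - q_lo) / (q_hi - q_lo)
  g[is.na(g)] <- 0
  g[g < 0] <- 0
  g[g > 1] <- 1
  list(grey = g, period = scan$params$grid,
       window_start = scan$window_starts)
}

#' Write a scan heatmap as TSV and/or a greyscale image
#'
#' The TSV has the period as its first column and one column per window
#' (header = 0-based window start). The image is a portable greymap
#' (ASCII `P2` PGM) or a PNG (requires the `png` package), with the
#' largest period in the top row, matching the usual orientation of
#' periodicity-scan figures.
#'
#' @param scan a `perscan` object.
#' @param path output file; format chosen by extension (`.tsv`, `.pgm`,
#'   `.png`).
#' @param q_lo,q_hi grey mapping, see [heatmap_matrix()].
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(scan, path, q_lo = 1, q_hi = 4) {
  hm <- heatmap_matrix(scan, q_lo, q_hi)
  ext <- tolower(tools::file_ext(path))
  if (ext == "tsv") {
    df <- data.frame(period = hm$period, hm$grey, check.names = FALSE)
    names(df) <- c("period", hm$window_start)
    con <- file(path, "w")
    on.exit(close(con))
    .provenance_header(con, "perscan heatmap", scan$params,
                       inputs = scan$id)
    write.table(format(df, digits = 6, trim = TRUE), con, sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else if (ext == "pgm") {
    # P2: 255 = white; flip rows so the longest period is on top
    pix <- round(255 * (1 - hm$grey))[rev(seq_along(hm$period)), ,
                                      drop = FALSE]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2",
                 sprintf("# perioscan heatmap %s", scan$id),
                 sprintf("%d %d", ncol(pix), nrow(pix)), "255"), con)
    write.table(pix, con, sep = " ", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("writing PNG requires the 'png' package; use .pgm instead")
    img <- (1 - hm$grey)[rev(seq_along(hm$period)), , drop = FALSE]
    png::writePNG(img, path)
  } else {
    stop("unsupported heatmap extension '.", ext, "' (tsv, pgm, png)")
  }
  invisible(path)
}

#' Plot a periodicity scan as a greyscale heatmap
#'
#' Horizontal axis: window midpoint along the replicon; vertical axis:
#' period; darkness: `Q*` (see [heatmap_matrix()]).
#'
#' @param x a `perscan` object.
#' @param q_lo,q_hi grey mapping.
#' @param ... passed to [graphics::image()].
#' @export
plot.perscan <- function(x, q_lo = 1, q_hi = 4, ...) {
  hm <- heatmap_matrix(x, q_lo, q_hi)
  mid <- (x$window_starts + x$window / 2) / 1e3
  image(x = mid, y = hm$period, z = t(1 - hm$grey),
        col = gray(seq(0, 1, length.out = 256)), zlim = c(0, 1),
        xlab = "position (kb, window midpoint)", ylab = "period (bp)",
        main = paste0(x$id, ": periodicity scan"), useRaster = TRUE, ...)
  invisible(x)
}
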