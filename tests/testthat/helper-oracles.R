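# Independent brute-force oracles; deliberately naive, never shared with
# the implementation under test.

# scan every offset for AA/TT (0-based starts)
naive_atract_scan <- function(residues) {
  L <- nchar(residues)
  if (L < 2) return(integer(0))
  dimers <- substring(residues, 1:(L - 1), 2:L)
  which(dimers %in% c("AA", "TT")) - 1L
}

# O(n^2) pair spacing count
brute_spacing_hist <- function(positions, s_hi) {
  d <- outer(positions, positions, `-`)
  d <- d[d > 0 & d <= s_hi]
  tabulate(d, nbins = s_hi)
}

# two-sided Fisher p by full hypergeometric enumeration over all tables
# with the observed margins (point-probability criterion)
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  x <- max(0, c1 - r2):min(r1, c1)
  pr <- dhyper(x, r1, r2, c1)
  obs <- dhyper(a, r1, r2, c1)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# two-sided Mann-Whitney p by full enumeration of group assignments
enum_mw_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  u_of <- function(xx, yy) sum(outer(xx, yy, `>`)) +
    0.5 * sum(outer(xx, yy, `==`))
  pool <- c(x, y)
  idx <- combn(nx + ny, nx)
  us <- apply(idx, 2, function(i) u_of(pool[i], pool[-i]))
  u <- u_of(x, y)
  p_lo <- mean(us <= u)
  p_hi <- mean(us >= u)
  min(1, 2 * min(p_lo, p_hi))
}

random_residues <- function(L, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp <- function(residues) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(residues, "")[[1]]), collapse = ""))
}

write_tmp_fasta <- function(records, path = tempfile(fileext = ".fasta")) {
  lines <- unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]])))
  writeLines(lines, path)
  path
}

# fake perscan object with prescribed per-window dominant periods, for
# testing the persistency bookkeeping in isolation
fake_scan <- function(window_pmax, q_at = NULL,
                      params = periodicity_params()) {
  n <- length(window_pmax)
  spectra <- matrix(1, nrow = length(params$grid), ncol = n)
  if (!is.null(q_at))
    for (w in seq_len(n))
      spectra[which.min(abs(params$grid - q_at$period)), w] <- q_at$q
  structure(list(id = "fake", length = NA_integer_, gc = NA_real_,
                 window = params$window, step = params$step,
                 window_starts = (seq_len(n) - 1L) * params$step,
                 n_windows = n, valid = !is.na(window_pmax),
                 spectra = spectra, window_pmax = window_pmax,
                 window_maxq = rep(1, n), params = params),
            class = "perscan")
}
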