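# comment header recording version, effective config and input checksums;
# every machine-readable output starts with one
.provenance_header <- function(con, what, params = NULL, inputs = NULL) {
  writeLines(sprintf("# perioscan %s | %s",
                     as.character(packageVersion("perioscan")), what), con)
  if (!is.null(params))
    writeLines(paste0("# config: ", .params_string(params)), con)
  if (!is.null(inputs)) {
    files <- inputs[file.exists(inputs)]
    if (length(files)) {
      sums <- tools::md5sum(files)
      writeLines(sprintf("# input: %s md5=%s", names(sums), sums), con)
    }
    other <- setdiff(inputs, files)
    if (length(other))
      writeLines(paste0("# input: ", other), con)
  }
  invisible(con)
}

.write_tsv_with_header <- function(df, path, what, params = NULL,
                                   inputs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  .provenance_header(con, what, params, inputs)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Write per-replicon indices to TSV
#'
#' One row per replicon with composition, whole-sequence indices and (when
#' present) persistency indices; a provenance comment header records the
#' package version, effective configuration and input checksums.
#'
#' @param indices data frame from [analyze_replicons()] or a cohort.
#' @param path output file.
#' @param params parameter bundle echoed into the header.
#' @param inputs input file paths to checksum in the header.
#' @return `path`, invisibly.
#' @export
write_indices_tsv <- function(indices, path,
                              params = periodicity_params(),
                              inputs = NULL) {
  .write_tsv_with_header(as.data.frame(indices), path,
                         "per-replicon periodicity indices", params,
                         inputs)
}

#' Write a perplot spectrum or histogram dump to TSV
#'
#' @param pp a `perplot` object (with spectrum/histogram retained).
#' @param path output file.
#' @param what `"spectrum"` (columns period, Q, Q_star) or `"histogram"`
#'   (columns s, N, h, h3, d; `d` is `NA` outside the detrending range).
#' @return `path`, invisibly.
#' @export
write_perplot_tsv <- function(pp, path,
                              what = c("spectrum", "histogram")) {
  stopifnot(inherits(pp, "perplot"))
  what <- match.arg(what)
  if (!pp$valid) stop("no valid result to dump (", pp$reason, ")")
  if (what == "spectrum") {
    if (is.null(pp$spectrum)) stop("spectrum was not retained")
    df <- data.frame(period = pp$spectrum$period, Q = pp$spectrum$q_raw,
                     Q_star = pp$spectrum$q_star)
  } else {
    h <- pp$histogram
    if (is.null(h)) stop("histogram was not retained")
    d <- rep(NA_real_, length(h$s))
    d[h$s_min:h$s_max] <- h$detrended
    df <- data.frame(s = h$s, N = h$raw, h = h$normalized,
                     h3 = h$smoothed, d = d)
  }
  .write_tsv_with_header(df, path, paste("perplot", what, "for", pp$id),
                         pp$params)
}

#' Write per-window scan results to TSV
#'
#' Columns: `window_start`, `window_end` (1-based inclusive), `MaxQ_w`
#' (peak `Q*` in the window) and `PMax_w` (its period); `NA` for windows
#' flagged missing.
#'
#' @param scan a `perscan` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_windows_tsv <- function(scan, path) {
  stopifnot(inherits(scan, "perscan"))
  df <- data.frame(window_start = scan$window_starts + 1L,
                   window_end = scan$window_starts + scan$window,
                   MaxQ_w = scan$window_maxq, PMax_w = scan$window_pmax)
  .write_tsv_with_header(df, path,
                         paste("perscan windows for", scan$id),
                         scan$params)
}

#' Write a cohort report as a key-value summary
#'
#' Machine-readable lines `key<TAB>value`: the 2x2 counts, Fisher p-value,
#' and per-index resampling counts.
#'
#' @param report a [cohort_report()] object.
#' @param path output file.
#' @param params,inputs provenance header contents.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path, params = periodicity_params(),
                             inputs = NULL) {
  stopifnot(inherits(report, "cohort_report"))
  kv <- c(
    n_replicons = report$n,
    persistent_prophage_free = report$table[1, 1],
    not_persistent_prophage_free = report$table[1, 2],
    persistent_prophage_containing = report$table[2, 1],
    not_persistent_prophage_containing = report$table[2, 2],
    fisher_p = format(report$fisher$p_value, digits = 6),
    fisher_degenerate = report$fisher$degenerate,
    alpha = report$alpha)
  for (nm in names(report$resampling)) {
    r <- report$resampling[[nm]]
    if (is.null(r)) next
    kv[paste0("resampling_", nm, "_significant")] <- r$n_significant
    kv[paste0("resampling_", nm, "_iterations")] <- r$n_iter
  }
  df <- data.frame(key = names(kv), value = unname(kv))
  .write_tsv_with_header(df, path, "cohort report", params, inputs)
}
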