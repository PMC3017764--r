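#' Signal-to-noise ratio of a spot
#'
#' The ratio of the background-corrected foreground intensity to the
#' standard deviation of the background pixels:
#' `(fg_mean - bg_mean) / bg_sd`. Spots are retained downstream only when
#' this ratio strictly exceeds 1.
#'
#' @param fg_mean Foreground mean intensity (linear scale).
#' @param bg_mean Background mean intensity.
#' @param bg_sd Standard deviation of the background pixels; must be
#'   positive (a zero SD makes the ratio undefined).
#' @return Numeric vector of ratios.
#' @export
signal_to_noise <- function(fg_mean, bg_mean, bg_sd) {
  if (any(bg_sd <= 0))
    stop("degenerate background: bg_sd must be > 0 to form a ",
         "signal-to-noise ratio")
  (fg_mean - bg_mean) / bg_sd
}

#' Mean/median agreement ratio of a spot
#'
#' The smaller of the foreground mean and median divided by the larger,
#' a value in (0, 1] that drops when a spot's pixel distribution is skewed
#' by artefacts. Requires positive foreground statistics.
#'
#' @param fg_mean,fg_median Foreground mean and median intensities.
#' @return Numeric vector of ratios in (0, 1].
#' @export
mean_median_agreement <- function(fg_mean, fg_median) {
  if (any(fg_mean <= 0) || any(fg_median <= 0))
    stop("foreground statistics must be positive")
  pmin(fg_mean, fg_median) / pmax(fg_mean, fg_median)
}

#' Apply spot quality filters, background correction and log2 transform
#'
#' A spot passes when (i) its signal-to-noise ratio strictly exceeds
#' `snr_threshold`, (ii) its mean/median agreement ratio meets `r_threshold`
#' (at-or-above by default; set `r_strict = TRUE` for a strict inequality),
#' and (iii) its background-corrected intensity `fg_mean - bg_mean` is
#' positive. Passing spots receive `log2(fg_mean - bg_mean)`; failing spots
#' are marked missing for modelling (reported as a literal zero only when
#' tables are written out, since a zero would corrupt log-scale means). A
#' non-positive background SD cannot form a signal-to-noise ratio and fails
#' the spot with a warning.
#'
#' @param spots Data frame of spot records with at least `fg_mean`,
#'   `fg_median`, `bg_mean`, `bg_sd`; design coordinate columns are carried
#'   through.
#' @param snr_threshold Signal-to-noise threshold (default 1, strict `>`).
#' @param r_threshold Mean/median agreement threshold (default 0.85).
#' @param r_strict Use `>` instead of `>=` for the agreement filter.
#' @return The input with columns `s`, `r`, `passed` and `log2_intensity`
#'   (NA for failing spots) appended; attribute `qc_counts` holds the
#'   pass/fail tally.
#' @export
apply_qc <- function(spots, snr_threshold = 1, r_threshold = 0.85,
                     r_strict = FALSE) {
  if (nrow(spots) == 0L) {
    warning("no spots supplied to apply_qc")
    spots$s <- numeric(0)
    spots$r <- numeric(0)
    spots$passed <- logical(0)
    spots$log2_intensity <- numeric(0)
    return(spots)
  }
  corrected <- spots$fg_mean - spots$bg_mean
  bad_bg <- spots$bg_sd <= 0
  if (any(bad_bg))
    warning(sum(bad_bg), " spot(s) with non-positive background SD failed QC")
  s <- ifelse(bad_bg, NA_real_, corrected / spots$bg_sd)
  pos_fg <- spots$fg_mean > 0 & spots$fg_median > 0
  r <- ifelse(pos_fg,
              pmin(spots$fg_mean, spots$fg_median) /
                pmax(spots$fg_mean, spots$fg_median),
              NA_real_)
  r_ok <- if (r_strict) r > r_threshold else r >= r_threshold
  passed <- !bad_bg & !is.na(s) & s > snr_threshold &
    !is.na(r) & r_ok & corrected > 0
  out <- spots
  out$s <- s
  out$r <- r
  out$passed <- passed
  out$log2_intensity <- ifelse(passed, log2(pmax(corrected, .Machine$double.xmin)), NA_real_)
  attr(out, "qc_counts") <- c(passed = sum(passed), failed = sum(!passed))
  out
}

#' Per-dye summary of background-corrected log2 intensities
#'
#' Arithmetic mean and SD of the log2 intensities of passing spots in each
#' dye channel; channels with fewer than two passing spots get an NA SD
#' (and NA mean when empty).
#'
#' @param qc Output of [apply_qc()] (needs `dye`, `passed`,
#'   `log2_intensity`).
#' @return Data frame with columns `dye`, `n`, `mean`, `sd`.
#' @export
channel_summary <- function(qc) {
  dyes <- unique(qc$dye)
  res <- lapply(dyes, function(d) {
    v <- qc$log2_intensity[qc$dye == d & qc$passed]
    data.frame(dye = d, n = length(v),
               mean = if (length(v) >= 1L) mean(v) else NA_real_,
               sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
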