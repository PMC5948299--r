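# Plausibility stage: peak extraction from load traces, group summaries,
# Wilcoxon signed-rank on CoV pairs, predicted-vs-in-vivo comparison.

#' Subject peak loads and inclination range from load traces
#'
#' The subject peak is the sample of maximal resultant magnitude across
#' all of that subject's activities (earliest sample on ties); the
#' inclination range is the (min, max) frontal-plane inclination over all
#' samples, subjects and activities.  Samples with negligible resultant
#' (below `min_force`) carry no direction information and are excluded
#' from the range.
#'
#' @param traces data frame with columns `subject`, `activity`, `time_s`,
#'   `f_ml_N`, `f_ap_N`, `f_vert_N` (implant coordinate system).
#' @param min_force magnitude floor (N) for direction evaluation.
#' @return list with `peaks` (data frame: subject, magnitude_N,
#'   inclination_deg, f_ml_N, f_ap_N, f_vert_N, activity, time_s) and
#'   `inclination_range` (length-2 numeric, degrees).
#' @export
extract_peaks_and_range <- function(traces, min_force = 1e-6) {
  need <- c("subject", "activity", "time_s", "f_ml_N", "f_ap_N", "f_vert_N")
  if (is.null(traces) || nrow(traces) == 0L) stop("empty trace set")
  if (!all(need %in% names(traces)))
    stop("traces must have columns: ", paste(need, collapse = ", "))
  mag <- sqrt(traces$f_ml_N^2 + traces$f_ap_N^2 + traces$f_vert_N^2)
  incl <- frontal_inclination(
    cbind(traces$f_ml_N, traces$f_ap_N, traces$f_vert_N))

  peaks <- do.call(rbind, lapply(split(seq_len(nrow(traces)),
                                       traces$subject), function(ix) {
    i <- ix[which.max(mag[ix])]  # earliest sample on ties
    data.frame(subject = traces$subject[i], magnitude_N = mag[i],
               inclination_deg = incl[i], f_ml_N = traces$f_ml_N[i],
               f_ap_N = traces$f_ap_N[i], f_vert_N = traces$f_vert_N[i],
               activity = traces$activity[i], time_s = traces$time_s[i],
               stringsAsFactors = FALSE)
  }))
  rownames(peaks) <- NULL
  ok <- mag > min_force
  if (!any(ok)) stop("no sample exceeds the magnitude floor")
  list(peaks = peaks, inclination_range = range(incl[ok]))
}

#' Mean and sample standard deviation
#'
#' Group summary used throughout the comparison reports: arithmetic mean
#' and sample SD (n - 1 denominator).
#'
#' @param values numeric vector.
#' @return list with `mean`, `sd` (NA with `sd_defined = FALSE` for
#'   n < 2) and `n`.
#' @export
summarize_mean_sd <- function(values) {
  n <- length(values)
  if (n < 1L) stop("no values to summarize")
  list(mean = mean(values),
       sd = if (n >= 2L) stats::sd(values) else NA_real_,
       sd_defined = n >= 2L, n = n)
}

#' Wilcoxon signed-rank test on paired values
#'
#' Tests whether `after` is systematically different from `before`.
#' Reports the signed-rank statistic `W` (the smaller of the positive and
#' negative rank sums) and the two-sided p value: exact distribution by
#' default (n <= 25, no ties), or the normal approximation with
#' continuity correction when `exact = FALSE`.
#'
#' @param before,after paired numeric vectors.
#' @param exact use the exact null distribution (default TRUE).
#' @return list with `statistic` (W), `p_value`, `n` (non-zero
#'   differences) and `method`.
#' @export
wilcoxon_signed_rank <- function(before, after, exact = TRUE) {
  if (length(before) != length(after)) stop("unequal pair lengths")
  d <- before - after
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all paired differences are zero")
  if (n < 5L) stop("need at least 5 non-zero differences")
  rk <- rank(abs(d))
  Wpos <- sum(rk[d > 0])
  Wneg <- sum(rk[d < 0])
  ht <- suppressWarnings(
    stats::wilcox.test(before, after, paired = TRUE, exact = exact,
                       correct = TRUE, alternative = "two.sided"))
  list(statistic = min(Wpos, Wneg), p_value = ht$p.value, n = n,
       method = if (exact) "exact" else "normal approximation")
}

#' Compare predicted peak loads with in-vivo measurements
#'
#' Side-by-side group summaries (mean +/- sample SD of peak magnitudes
#' and frontal-plane inclinations) and inclination ranges for the
#' predicted and in-vivo sets.
#'
#' @param predicted_peaks data frame (or matrix) with columns
#'   `magnitude_N` and `inclination_deg` — or n x 3 force vectors, which
#'   are converted.
#' @param invivo_peaks same format for the in-vivo subject peaks.
#' @param predicted_range,invivo_range length-2 inclination ranges
#'   (degrees).
#' @return object of class `comparison_report`: per-set summaries, ranges
#'   and predicted-minus-in-vivo deltas.
#' @export
compare_invivo <- function(predicted_peaks, invivo_peaks,
                           predicted_range = NULL, invivo_range = NULL) {
  as_peaks <- function(x) {
    if (is.matrix(x) && ncol(x) == 3L)
      x <- data.frame(magnitude_N = sqrt(rowSums(x^2)),
                      inclination_deg = frontal_inclination(x))
    if (!all(c("magnitude_N", "inclination_deg") %in% names(x)))
      stop("peaks need columns magnitude_N and inclination_deg")
    x
  }
  pred <- as_peaks(predicted_peaks)
  invv <- as_peaks(invivo_peaks)
  if (nrow(pred) == 0L || nrow(invv) == 0L) stop("empty peak set")
  rng_ok <- function(r) is.null(r) ||
    (length(r) == 2L && r[1] <= r[2])
  if (!rng_ok(predicted_range) || !rng_ok(invivo_range))
    stop("ranges must satisfy min <= max")

  sm <- function(x) list(magnitude = summarize_mean_sd(x$magnitude_N),
                         inclination = summarize_mean_sd(x$inclination_deg))
  ps <- sm(pred); is <- sm(invv)
  structure(list(
    predicted = ps, invivo = is,
    predicted_range = predicted_range, invivo_range = invivo_range,
    delta_magnitude = ps$magnitude$mean - is$magnitude$mean,
    delta_inclination = ps$inclination$mean - is$inclination$mean,
    n_predicted = nrow(pred), n_invivo = nrow(invv)),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  fmt <- function(s) sprintf("%.1f +/- %s", s$mean,
                             ifelse(s$sd_defined, sprintf("%.1f", s$sd),
                                    "(SD undefined)"))
  cat("<comparison_report>\n")
  cat(sprintf("  predicted: %s N at %s deg (n = %d)\n",
              fmt(x$predicted$magnitude), fmt(x$predicted$inclination),
              x$n_predicted))
  cat(sprintf("  in vivo:   %s N at %s deg (n = %d)\n",
              fmt(x$invivo$magnitude), fmt(x$invivo$inclination),
              x$n_invivo))
  if (!is.null(x$predicted_range))
    cat(sprintf("  predicted inclination range: %.1f to %.1f deg\n",
                x$predicted_range[1], x$predicted_range[2]))
  if (!is.null(x$invivo_range))
    cat(sprintf("  in vivo inclination range:   %.1f to %.1f deg\n",
                x$invivo_range[1], x$invivo_range[2]))
  cat(sprintf("  deltas (predicted - in vivo): %.1f N, %.1f deg\n",
              x$delta_magnitude, x$delta_inclination))
  invisible(x)
}

#' Write a comparison report (CSV + readable text)
#'
#' @param report a `comparison_report`.
#' @param path output CSV path; a `.txt` rendering sits alongside.
#' @export
write_comparison_report <- function(report, path) {
  df <- data.frame(
    set = c("predicted", "invivo"),
    magnitude_mean_N = c(report$predicted$magnitude$mean,
                         report$invivo$magnitude$mean),
    magnitude_sd_N = c(report$predicted$magnitude$sd,
                       report$invivo$magnitude$sd),
    inclination_mean_deg = c(report$predicted$inclination$mean,
                             report$invivo$inclination$mean),
    inclination_sd_deg = c(report$predicted$inclination$sd,
                           report$invivo$inclination$sd),
    range_min_deg = c(report$predicted_range[1] %||% NA,
                      report$invivo_range[1] %||% NA),
    range_max_deg = c(report$predicted_range[2] %||% NA,
                      report$invivo_range[2] %||% NA))
  utils::write.csv(df, path, row.names = FALSE)
  txt <- sub("\\.csv$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  sink(txt); print(report); sink()
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
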