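#' Construct an ATPase assay trace
#'
#' A fluorescence time series from an NADH-coupled ATPase assay, in which the
#' regenerating pyruvate-kinase / lactate-dehydrogenase system oxidizes one
#' NADH per hydrolyzed ATP, so the NADH fluorescence decay rate reports the
#' hydrolysis rate.
#'
#' @param times minutes, strictly increasing.
#' @param signal fluorescence (arbitrary units), same length as `times`,
#'   at least 5 points.
#' @param enzyme_conc enzyme concentration in micromolar (> 0; the assays
#'   used 0.1 uM enzyme).
#' @param ring_count AAA rings per enzyme molecule (>= 1; 1 for a protein
#'   carrying its six AAA units in one chain).
#' @return list of class `assay_trace`.
#' @export
assay_trace <- function(times, signal, enzyme_conc = 0.1, ring_count = 1L) {
  sk_assert(length(times) == length(signal), "times and signal lengths differ",
            "ragged-trace")
  sk_assert(length(times) >= 5, "a trace needs at least 5 points", "short-trace")
  sk_assert(all(diff(times) > 0), "times must be strictly increasing", "bad-times")
  sk_assert(enzyme_conc > 0, "enzyme_conc must be > 0", "bad-concentration")
  sk_assert(ring_count >= 1, "ring_count must be >= 1", "bad-ring-count")
  structure(list(times = as.numeric(times), signal = as.numeric(signal),
                 enzyme_conc = as.numeric(enzyme_conc),
                 ring_count = as.integer(ring_count)),
            class = "assay_trace")
}

#' Read an assay trace from CSV
#'
#' @param path CSV with columns `time_min` and `signal`.
#' @inheritParams assay_trace
#' @return an [assay_trace()].
#' @export
read_trace <- function(path, enzyme_conc = 0.1, ring_count = 1L) {
  sk_assert(file.exists(path), paste("file not found:", path), "missing-file")
  d <- utils::read.csv(path)
  sk_assert(all(c("time_min", "signal") %in% names(d)),
            "trace CSV must have columns time_min and signal", "bad-columns")
  assay_trace(d$time_min, d$signal, enzyme_conc, ring_count)
}

#' Fit an NADH calibration line
#'
#' Ordinary least-squares line `signal = slope * conc + intercept` over a
#' dilution series (e.g. 0.05-100 uM NADH standards). The slope converts
#' fluorescence to concentration.
#'
#' @param conc concentrations in micromolar (at least two distinct values),
#'   or a data.frame with columns `conc` and `signal`.
#' @param signal fluorescence readings.
#' @return list of class `calibration`: `slope` (a.u. per uM), `intercept`
#'   (a.u.), `r_squared`.
#' @export
fit_calibration <- function(conc, signal = NULL) {
  if (is.data.frame(conc)) { signal <- conc$signal; conc <- conc$conc }
  sk_assert(length(unique(conc)) >= 2, "need at least 2 distinct concentrations",
            "degenerate-standards")
  fit <- lm(signal ~ conc)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((signal - mean(signal))^2)
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_),
            class = "calibration")
}

# slope, intercept and r^2 of y ~ x over index window [i, j], from prefix sums
.window_fit_stats <- function(sx, sxx, sy, syy, sxy, i, j) {
  n <- j - i + 1
  Sx <- sx[j + 1] - sx[i]; Sy <- sy[j + 1] - sy[i]
  Sxx <- sxx[j + 1] - sxx[i]; Syy <- syy[j + 1] - syy[i]
  Sxy <- sxy[j + 1] - sxy[i]
  vx <- Sxx - Sx * Sx / n
  vy <- Syy - Sy * Sy / n
  cxy <- Sxy - Sx * Sy / n
  slope <- cxy / vx
  r2 <- ifelse(vy > 0 & vx > 0, cxy * cxy / (vx * vy), NA_real_)
  list(slope = slope, r2 = r2)
}

#' Detect the linearly decaying region of a trace
#'
#' Scans all contiguous index windows of at least `min_fraction` of the trace
#' and returns the longest one whose internal linear fit has `r^2 >= r2_min`
#' and a negative slope (signal decaying); ties are broken toward the
#' earliest start. This isolates the pseudo-zero-order regime before the
#' NADH pool is exhausted.
#'
#' Because an `r^2` threshold alone lets the window creep past the kink where
#' the NADH pool runs out (a few plateau points barely dent `r^2` but bias
#' the slope), the selected window is refined by default: contiguous runs of
#' points at either end whose residuals exceed 2.5 standard deviations of the
#' window fit are peeled off and the fit repeated until the boundaries are
#' clean.
#'
#' @param trace an [assay_trace()].
#' @param min_fraction minimum window length as a fraction of the trace.
#' @param r2_min minimum coefficient of determination of the window fit.
#' @param refine peel systematic boundary outliers off the selected window.
#' @return list of class `linear_region`: `start`, `end` (indices), `found`.
#'   When no window qualifies, `found = FALSE` and the indices are `NA`
#'   (an explicit no-linear-region result).
#' @export
detect_linear_region <- function(trace, min_fraction = 0.2, r2_min = 0.99,
                                 refine = TRUE) {
  sk_assert(inherits(trace, "assay_trace"), "not an assay_trace", "bad-trace")
  x <- trace$times; y <- trace$signal
  n <- length(x)
  minlen <- max(3L, as.integer(ceiling(min_fraction * n)))
  sx <- c(0, cumsum(x)); sxx <- c(0, cumsum(x * x))
  sy <- c(0, cumsum(y)); syy <- c(0, cumsum(y * y))
  sxy <- c(0, cumsum(x * y))
  grid <- expand.grid(i = seq_len(n), len = minlen:n)
  grid <- grid[grid$i + grid$len - 1L <= n, , drop = FALSE]
  j <- grid$i + grid$len - 1L
  st <- .window_fit_stats(sx, sxx, sy, syy, sxy, grid$i, j)
  ok <- !is.na(st$r2) & st$r2 >= r2_min & st$slope < 0
  if (!any(ok))
    return(structure(list(start = NA_integer_, end = NA_integer_, found = FALSE),
                     class = "linear_region"))
  cand <- grid[ok, , drop = FALSE]
  best <- cand[order(-cand$len, cand$i)[1], ]
  s <- as.integer(best$i); e <- as.integer(best$i + best$len - 1L)
  if (refine) {
    repeat {
      idx <- s:e
      if (length(idx) <= max(3L, minlen %/% 2L)) break
      fit <- lm(y[idx] ~ x[idx])
      rs <- stats::residuals(fit)
      sdr <- stats::sd(rs)
      # an essentially exact fit has nothing left to peel
      if (!is.finite(sdr) || sdr <= 1e-9 * max(abs(y[idx]), 1)) break
      out <- abs(rs) > 2.5 * sdr
      k1 <- 0L
      while (k1 < length(idx) - 3L && out[k1 + 1L]) k1 <- k1 + 1L
      k2 <- 0L
      while (k2 < length(idx) - 3L - k1 && out[length(idx) - k2]) k2 <- k2 + 1L
      if (k1 == 0L && k2 == 0L) break
      s <- s + k1; e <- e - k2
    }
  }
  structure(list(start = s, end = e, found = TRUE), class = "linear_region")
}

#' ATP hydrolysis rate from a trace
#'
#' Under the pseudo-zero-order approximation (ATP in large excess, regenerated
#' by the coupled system) the NADH signal decays linearly; with a 1:1
#' NADH:ATP stoichiometry the hydrolysis rate is
#' `(-signal slope / calibration slope) / enzyme concentration`, in ATP per
#' enzyme molecule per minute. The per-ring rate divides by the number of AAA
#' rings per molecule.
#'
#' @param trace an [assay_trace()].
#' @param calibration a [fit_calibration()] result (slope must be positive).
#' @param region a [detect_linear_region()] result, a manual `c(start, end)`
#'   index pair, or `NULL` to auto-detect.
#' @return list: `rate` (ATP per enzyme per minute), `rate_per_ring`,
#'   `signal_slope` (a.u. per minute), `region`.
#' @export
atpase_rate <- function(trace, calibration, region = NULL) {
  sk_assert(inherits(trace, "assay_trace"), "not an assay_trace", "bad-trace")
  sk_assert(calibration$slope > 0, "calibration slope must be positive",
            "bad-calibration")
  if (is.null(region)) region <- detect_linear_region(trace)
  if (inherits(region, "linear_region")) {
    sk_assert(isTRUE(region$found), "no linear decay region in trace",
              "no-linear-region")
    idx <- region$start:region$end
  } else {
    idx <- region[1]:region[2]
  }
  fit <- lm(trace$signal[idx] ~ trace$times[idx])
  slope <- unname(coef(fit)[2])
  sk_assert(slope <= 0, "signal rises over the selected region", "rising-signal")
  rate <- (-slope / calibration$slope) / trace$enzyme_conc
  list(rate = rate, rate_per_ring = rate / trace$ring_count,
       signal_slope = slope,
       region = c(start = idx[1], end = idx[length(idx)]))
}
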