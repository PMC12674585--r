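TREATMENT_NAMES <- c("raw", "d1", "snv", "msc", "d1_dt", "d1_msc", "sg_snv")

#' Specify a spectral pre-treatment
#'
#' The seven treatment configurations compared in the pipeline: raw spectra,
#' first derivative (`d1`, gap-segment), SNV, MSC, derivative plus detrend
#' (`d1_dt`), derivative plus MSC (`d1_msc`), and Savitzky-Golay smoothing
#' followed by the gap-segment derivative and SNV (`sg_snv`).
#'
#' @param name One of `"raw"`, `"d1"`, `"snv"`, `"msc"`, `"d1_dt"`,
#'   `"d1_msc"`, `"sg_snv"`.
#' @param sg_window,sg_polyorder Savitzky-Golay window (odd, > polyorder) and
#'   polynomial order.
#' @param gap_window,gap_segment Gap-segment derivative gap span and segment
#'   length (channels).
#' @param detrend_degree Polynomial degree for detrending.
#' @return A `treatment_spec` record; `name` determines which params are used.
#' @export
treatment_spec <- function(name, sg_window = 11, sg_polyorder = 3,
                           gap_window = 11, gap_segment = 7, detrend_degree = 2) {
  name <- match.arg(name, TREATMENT_NAMES)
  if (sg_window %% 2 != 1 || sg_window <= sg_polyorder) {
    stopf("sg_window must be odd and greater than sg_polyorder")
  }
  if (gap_window < 1 || gap_segment < 1) stopf("gap_window and gap_segment must be >= 1")
  structure(list(name = name,
                 params = list(sg_window = sg_window, sg_polyorder = sg_polyorder,
                               gap_window = gap_window, gap_segment = gap_segment,
                               detrend_degree = detrend_degree)),
            class = "treatment_spec")
}

#' Standard normal variate transform
#'
#' Centers a single spectrum to mean zero and scales it to unit sample
#' standard deviation (n-1 denominator), removing additive offsets and
#' multiplicative scatter.
#'
#' @param x Numeric absorbance vector with at least 2 channels.
#' @return The transformed vector.
#' @export
snv <- function(x) {
  if (length(x) < 2) stopf("snv needs at least 2 channels")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stopf("snv undefined for a constant spectrum")
  (x - mean(x)) / s
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum (by default the
#' column-wise mean of the dataset itself) and replaces it with
#' `(x - b0) / b1` from the OLS fit `x = b0 + b1 * ref + e`, correcting both
#' baseline offset and multiplicative slope. The reference actually used is
#' stored in the result (attribute `msc_reference`), so holdout or external
#' spectra can be corrected against a calibration-set reference without
#' information leakage.
#'
#' @param ds A [spectral_dataset()] or numeric matrix (readings x channels).
#' @param reference Optional reference spectrum; default is the mean spectrum.
#' @return Same class as `ds`, corrected, with the reference attached as
#'   attribute `msc_reference`.
#' @export
msc <- function(ds, reference = NULL) {
  X <- if (inherits(ds, "spectral_dataset")) ds$absorbance else as.matrix(ds)
  if (is.null(reference)) {
    if (nrow(X) < 2) stopf("msc needs >= 2 spectra when no reference is given")
    reference <- colMeans(X)
  }
  ref_c <- reference - mean(reference)
  denom <- sum(ref_c^2)
  if (denom == 0) stopf("msc reference is constant")
  out <- t(apply(X, 1, function(x) {
    b1 <- sum((x - mean(x)) * ref_c) / denom
    if (abs(b1) < 1e-12) stopf("msc degenerate: spectrum uncorrelated with reference")
    b0 <- mean(x) - b1 * mean(reference)
    (x - b0) / b1
  }))
  if (inherits(ds, "spectral_dataset")) {
    res <- spectral_dataset(ds$wavelengths, out, ds$metadata, ds$treatment)
    attr(res, "msc_reference") <- reference
    res
  } else {
    attr(out, "msc_reference") <- reference
    out
  }
}

#' Savitzky-Golay filtering and differentiation
#'
#' Local least-squares polynomial smoothing: each point is replaced by the
#' `deriv_order`-th derivative of the polynomial of order `polyorder` fitted
#' to the surrounding `window` points, with asymmetric (truncated-window) fits
#' at the spectrum edges so the output length equals the input length.
#' Derivatives are scaled by the channel spacing, i.e. reported per nm.
#'
#' @param x Numeric spectrum, length >= `window`.
#' @param window Odd window length, greater than `polyorder`.
#' @param polyorder Polynomial order.
#' @param deriv_order Derivative order (0 = smoothing).
#' @param spacing Channel spacing in nm (default 1).
#' @return Filtered vector, same length as `x`.
#' @export
savitzky_golay <- function(x, window = 11, polyorder = 3, deriv_order = 0, spacing = 1) {
  if (window %% 2 != 1 || window <= polyorder) {
    stopf("window must be odd and greater than polyorder")
  }
  if (length(x) < window) stopf("spectrum shorter than the filter window")
  as.numeric(signal::sgolayfilt(x, p = polyorder, n = window,
                                m = deriv_order, ts = spacing))
}

#' Gap-segment first derivative
#'
#' Noise-robust first derivative: at each channel, the mean of a `segment`
#' of channels to the right of a gap of span `window` is differenced against
#' the mean of a `segment` to the left, and divided by the distance (in nm)
#' between the two segment centers. Edge channels, where a full gap-segment
#' stencil does not fit, are filled with the nearest valid value so the
#' output length is preserved. Any additive baseline is removed exactly and a
#' linear spectrum maps to its constant slope.
#'
#' @param x Numeric spectrum.
#' @param window Gap span (channels); the half-gap is `(window - 1) / 2`.
#' @param segment Segment length (channels) averaged on each side.
#' @param spacing Channel spacing in nm.
#' @return Derivative vector (absorbance per nm), same length as `x`.
#' @export
gap_segment_derivative <- function(x, window = 11, segment = 7, spacing = 1) {
  n <- length(x)
  h <- (window - 1) %/% 2
  lo <- h + segment        # first valid center (1-based)
  hi <- n - h - segment + 1
  if (lo > hi) stopf("spectrum too short for gap-segment derivative (need >= %d channels)",
                     2 * h + 2 * segment - 1)
  cs <- cumsum(c(0, x))
  seg_mean <- function(from, to) (cs[to + 1] - cs[from]) / segment
  i <- lo:hi
  left  <- seg_mean(i - h - segment + 1, i - h)
  right <- seg_mean(i + h, i + h + segment - 1)
  dist_nm <- (2 * h + segment - 1) * spacing  # distance between segment centers
  d <- (right - left) / dist_nm
  out <- numeric(n)
  out[i] <- d
  out[seq_len(lo - 1)] <- d[1]
  if (hi < n) out[(hi + 1):n] <- d[length(d)]
  out
}

#' Polynomial detrend
#'
#' Fits an OLS polynomial of the given degree in wavelength to the spectrum
#' and subtracts it, leaving a residual orthogonal to the polynomial basis.
#'
#' @param x Numeric spectrum.
#' @param wavelengths Wavelength axis (defaults to channel index).
#' @param degree Polynomial degree (must be < number of channels).
#' @return Detrended vector.
#' @export
detrend <- function(x, wavelengths = seq_along(x), degree = 2) {
  if (degree >= length(x)) stopf("detrend degree must be below the channel count")
  if (degree == 0) return(x - mean(x))
  B <- cbind(1, stats::poly(wavelengths, degree, raw = FALSE, simple = TRUE))
  as.numeric(stats::lm.fit(B, x)$residuals)
}

apply_rowwise <- function(ds, f) {
  out <- t(apply(ds$absorbance, 1, f))
  spectral_dataset(ds$wavelengths, out, ds$metadata, ds$treatment)
}

#' Apply a named pre-treatment to a spectral dataset
#'
#' Dispatches on the treatment name and composes the primitive transforms in
#' the documented order: `d1` is the gap-segment derivative; `d1_dt` is
#' derivative then detrend; `d1_msc` derivative then MSC; `sg_snv` is
#' Savitzky-Golay smoothing, then the gap-segment derivative, then SNV
#' row-wise; `snv`/`msc` apply row-wise/dataset-wise; `raw` is the identity.
#' The treatment spec is recorded in the returned dataset's provenance so the
#' transform can be replayed bit-identically.
#'
#' @param ds A [spectral_dataset()].
#' @param spec A [treatment_spec()] (or a treatment name).
#' @param msc_reference Optional reference spectrum for MSC-containing
#'   treatments; pass the stored calibration reference when treating holdout
#'   spectra.
#' @return Treated [spectral_dataset()] with `$treatment` set; MSC-containing
#'   results carry attribute `msc_reference`.
#' @export
apply_treatment <- function(ds, spec, msc_reference = NULL) {
  if (is.character(spec)) spec <- treatment_spec(spec)
  p <- spec$params
  sp <- channel_spacing(ds)
  d1 <- function(d) apply_rowwise(d, function(x) {
    gap_segment_derivative(x, p$gap_window, p$gap_segment, sp)
  })
  out <- switch(spec$name,
    raw = ds,
    d1 = d1(ds),
    snv = apply_rowwise(ds, snv),
    msc = msc(ds, msc_reference),
    d1_dt = apply_rowwise(d1(ds), function(x) detrend(x, ds$wavelengths, p$detrend_degree)),
    d1_msc = msc(d1(ds), msc_reference),
    sg_snv = {
      sm <- apply_rowwise(ds, function(x) {
        savitzky_golay(x, p$sg_window, p$sg_polyorder, deriv_order = 0, spacing = sp)
      })
      apply_rowwise(d1(sm), snv)
    }
  )
  res <- spectral_dataset(out$wavelengths, out$absorbance, out$metadata, spec)
  attr(res, "msc_reference") <- attr(out, "msc_reference")
  res
}

#' Interquartile-range outlier screen for spectral readings
#'
#' Computes per-channel Tukey fences `[Q1 - k*IQR, Q3 + k*IQR]` (type-7
#' quartiles) over readings and flags a reading when the fraction of its
#' channels falling outside the fences exceeds `channel_fraction`. Intended to
#' be applied independently to raw and to each treated dataset.
#'
#' @param ds A [spectral_dataset()].
#' @param k Fence multiplier (default 1.5).
#' @param channel_fraction Fraction of out-of-fence channels beyond which a
#'   reading is flagged (default 0.10).
#' @param fences Optional precomputed fences (as returned in `$fences`) so the
#'   screen learned on a calibration partition can be applied to holdout data.
#' @return A list: `kept` ([spectral_dataset()]), `flagged_ids` (character),
#'   `fences` (2 x channels matrix).
#' @export
iqr_outlier_filter <- function(ds, k = 1.5, channel_fraction = 0.10, fences = NULL) {
  X <- ds$absorbance
  if (is.null(fences)) {
    if (nrow(X) < 4) {
      warnf("fewer than 4 readings: IQR filter skipped (quartiles unstable)")
      return(list(kept = ds, flagged_ids = character(0), fences = NULL))
    }
    q <- apply(X, 2, stats::quantile, probs = c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2, ] - q[1, ]
    fences <- rbind(lower = q[1, ] - k * iqr, upper = q[2, ] + k * iqr)
  }
  out_frac <- rowMeans(sweep(X, 2, fences["lower", ], "<") |
                         sweep(X, 2, fences["upper", ], ">"))
  flag <- out_frac > channel_fraction
  list(kept = subset_readings(ds, !flag),
       flagged_ids = ds$metadata$reading_id[flag],
       fences = fences)
}
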