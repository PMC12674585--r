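#' Construct a spectral dataset
#'
#' Container for a set of absorbance readings on a common wavelength grid,
#' with per-reading metadata linking each spectrum to its field plot and
#' sample preparation ("fresh" intact root surface or "mashed" homogenized
#' pulp).
#'
#' @param wavelengths Numeric vector of wavelengths (nm), strictly increasing.
#' @param absorbance Numeric matrix, readings x channels.
#' @param metadata Data frame with columns `reading_id`, `plot_id`,
#'   `sample_type`; one row per reading.
#' @param treatment Optional treatment provenance record (see
#'   [treatment_spec()]); `NULL` for raw spectra.
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(wavelengths, absorbance, metadata, treatment = NULL) {
  absorbance <- as.matrix(absorbance)
  if (ncol(absorbance) != length(wavelengths)) {
    stopf("absorbance has %d columns but %d wavelengths were given",
          ncol(absorbance), length(wavelengths))
  }
  if (any(diff(wavelengths) <= 0)) stopf("wavelength grid must be strictly increasing")
  if (nrow(absorbance) != nrow(metadata)) {
    stopf("metadata rows (%d) must match readings (%d)", nrow(metadata), nrow(absorbance))
  }
  need <- c("reading_id", "plot_id", "sample_type")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stopf("metadata lacks columns: %s", paste(miss, collapse = ", "))
  if (anyNA(absorbance)) stopf("absorbance matrix contains missing values")
  st <- unique(metadata$sample_type)
  if (length(st) > 1) stopf("sample_type must be uniform within a dataset")
  rownames(absorbance) <- metadata$reading_id
  structure(
    list(wavelengths = as.numeric(wavelengths),
         absorbance = absorbance,
         metadata = as.data.frame(metadata, stringsAsFactors = FALSE),
         treatment = treatment),
    class = "spectral_dataset"
  )
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d readings x %d channels (%g-%g nm), sample_type=%s, treatment=%s\n",
              nrow(x$absorbance), ncol(x$absorbance),
              min(x$wavelengths), max(x$wavelengths),
              unique(x$metadata$sample_type),
              if (is.null(x$treatment)) "raw/none" else x$treatment$name))
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$absorbance)

## channel spacing in nm (assumed regular grid; checked to 1e-8)
channel_spacing <- function(ds) {
  d <- diff(ds$wavelengths)
  if (diff(range(d)) > 1e-8) stopf("wavelength grid is not regular")
  d[1]
}

subset_readings <- function(ds, idx) {
  spectral_dataset(ds$wavelengths, ds$absorbance[idx, , drop = FALSE],
                   ds$metadata[idx, , drop = FALSE], ds$treatment)
}
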