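#' Write spectra to CSV
#'
#' Header: `reading_id,plot_id,sample_type,wl_740,...` — RFC-4180, '.'
#' decimal, UTF-8.
#'
#' @param ds A [spectral_dataset()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(ds, path) {
  wl_cols <- sprintf("wl_%g", ds$wavelengths)
  dt <- data.table::data.table(ds$metadata[, c("reading_id", "plot_id", "sample_type")])
  dt <- cbind(dt, data.table::as.data.table(ds$absorbance))
  data.table::setnames(dt, c("reading_id", "plot_id", "sample_type", wl_cols))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read spectra from CSV (inverse of [write_spectra_csv()])
#'
#' @param path CSV file with `reading_id,plot_id,sample_type,wl_*` columns.
#' @return A [spectral_dataset()].
#' @export
read_spectra_csv <- function(path) {
  dt <- data.table::fread(path)
  wl_cols <- grep("^wl_", names(dt), value = TRUE)
  wl <- as.numeric(sub("^wl_", "", wl_cols))
  spectral_dataset(wl, as.matrix(dt[, wl_cols, with = FALSE]),
                   as.data.frame(dt[, c("reading_id", "plot_id", "sample_type")]))
}

#' Write a trait table to CSV
#'
#' @param traits Trait table (as from [simulate_traits()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_traits_csv <- function(traits, path) {
  data.table::fwrite(
    traits[, c("clone_id", "env_id", "rep_id", "block_id", "plot_id",
               "StC", "DMCo", "DMCg")], path)
  invisible(path)
}

#' Read a trait table from CSV
#'
#' @param path CSV file in the [write_traits_csv()] schema.
#' @return Trait table data frame.
#' @export
read_traits_csv <- function(path) {
  as.data.frame(data.table::fread(path))
}
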