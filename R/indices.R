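# Vegetation indices from plot-level mean band reflectances.

VI_NAMES <- c("NDVI", "GNDVI", "NDRE", "SAVI", "EVI", "Ratio")

# Which bands each index needs (reflectance fractions in [0, 1]).
vi_required_bands <- function(index) {
  switch(index,
    NDVI  = c("r_nir", "r_red"),
    GNDVI = c("r_nir", "r_green"),
    NDRE  = c("r_nir", "r_rededge"),
    SAVI  = c("r_nir", "r_red"),
    EVI   = c("r_nir", "r_red", "r_blue"),
    Ratio = c("r_nir", "r_red"),
    stop(sprintf("unknown vegetation index '%s'", index), call. = FALSE))
}

# Raw formulas, vectorized; return NaN/Inf where denominators vanish.
vi_value <- function(index, nir, red = NULL, green = NULL, rededge = NULL,
                     blue = NULL, soil_L = 0.5) {
  switch(index,
    NDVI  = (nir - red) / (nir + red),
    GNDVI = (nir - green) / (nir + green),
    NDRE  = (nir - rededge) / (nir + rededge),
    SAVI  = (nir - red) * (1 + soil_L) / (nir + red + soil_L),
    EVI   = 2.5 * (nir - red) / (nir + 6 * red - 7.5 * blue + 1),
    Ratio = nir / red)
}

#' Compute one vegetation index for a single plot record
#'
#' Computes one of the six supported vegetation indices from mean band
#' reflectances (fractions in \[0, 1\]):
#' \itemize{
#'   \item NDVI = (NIR - R) / (NIR + R)
#'   \item GNDVI, NDRE: as NDVI with the green / red-edge band in place of red
#'   \item SAVI = (NIR - R)(1 + L) / (NIR + R + L), soil factor L = 0.5 by default
#'   \item EVI = 2.5 (NIR - R) / (NIR + 6R - 7.5B + 1)
#'   \item Ratio = NIR / R
#' }
#' In single-record mode an undefined value (zero denominator) is an error;
#' use [compute_all_indices()] for batch processing where undefined values
#' are flagged instead.
#'
#' @param bands named numeric vector or one-row data.frame with (a subset of)
#'   `r_nir`, `r_red`, `r_green`, `r_rededge`, `r_blue`.
#' @param index one of `"NDVI"`, `"GNDVI"`, `"NDRE"`, `"SAVI"`, `"EVI"`,
#'   `"Ratio"`.
#' @param soil_L soil background correction factor for SAVI.
#' @return The index value (numeric scalar).
#' @examples
#' compute_vi(c(r_nir = 0.5, r_red = 0.1), "NDVI")   # 0.6667
#' compute_vi(c(r_nir = 0.5, r_red = 0.1), "SAVI")   # 0.54545
#' @export
compute_vi <- function(bands, index, soil_L = 0.5) {
  index <- match.arg(index, VI_NAMES)
  if (is.data.frame(bands)) {
    if (nrow(bands) != 1)
      stop("compute_vi() takes a single record; use compute_all_indices() for tables",
           call. = FALSE)
    bands <- unlist(bands[intersect(names(bands),
                                    c("r_nir", "r_red", "r_green",
                                      "r_rededge", "r_blue"))])
  }
  need <- vi_required_bands(index)
  miss <- setdiff(need, names(bands))
  if (length(miss) > 0)
    stop(sprintf("missing band(s) for %s: %s", index,
                 paste(miss, collapse = ", ")), call. = FALSE)
  b <- as.list(bands[need])
  if (any(vapply(b, function(v) !is.finite(v) || v < 0, logical(1))))
    stop("band reflectances must be finite and non-negative", call. = FALSE)
  val <- vi_value(index,
                  nir = bands[["r_nir"]],
                  red = if ("r_red" %in% names(bands)) bands[["r_red"]],
                  green = if ("r_green" %in% names(bands)) bands[["r_green"]],
                  rededge = if ("r_rededge" %in% names(bands)) bands[["r_rededge"]],
                  blue = if ("r_blue" %in% names(bands)) bands[["r_blue"]],
                  soil_L = soil_L)
  if (!is.finite(val))
    stop(sprintf("undefined %s value (zero denominator)", index), call. = FALSE)
  unname(val)
}

#' Compute all six vegetation indices for a table of band reflectances
#'
#' One output row per plot x time point x index. Rows whose denominator is
#' undefined are kept with `value = NA` and `flagged = TRUE` rather than
#' dropped, so batch pipelines never lose records silently.
#'
#' @param bands data.frame with columns `plot_id`, `time_label`, `gdd`,
#'   `r_blue`, `r_green`, `r_red`, `r_rededge`, `r_nir`.
#' @param soil_L soil background correction factor for SAVI.
#' @return data.frame with columns `plot_id`, `time_label`, `gdd`, `index`,
#'   `value`, `flagged`.
#' @export
compute_all_indices <- function(bands, soil_L = 0.5) {
  check_columns(bands, c("plot_id", "time_label", "gdd", "r_blue", "r_green",
                         "r_red", "r_rededge", "r_nir"), "band table")
  key <- paste(bands$plot_id, bands$time_label, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (plot_id, time_label) rows in band table", call. = FALSE)
  if (nrow(bands) == 0) {
    return(data.frame(plot_id = character(), time_label = character(),
                      gdd = numeric(), index = character(), value = numeric(),
                      flagged = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(VI_NAMES, function(ix) {
    val <- vi_value(ix, nir = bands$r_nir, red = bands$r_red,
                    green = bands$r_green, rededge = bands$r_rededge,
                    blue = bands$r_blue, soil_L = soil_L)
    bad <- !is.finite(val)
    data.frame(plot_id = bands$plot_id, time_label = bands$time_label,
               gdd = bands$gdd, index = ix,
               value = ifelse(bad, NA_real_, val), flagged = bad,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Apply a log10 transform to a table of vegetation-index values
#'
#' The transform is occasionally used to reduce the negative skew of
#' ratio-type indices; downstream models default to untransformed values
#' because the transform rarely changes mixed-model results.
#'
#' @param vi data.frame as returned by [compute_all_indices()] (needs a
#'   `value` column).
#' @return The same data.frame with `value` replaced by `log10(value)` and an
#'   attribute `transform = "log10"`.
#' @export
log10_transform <- function(vi) {
  check_columns(vi, "value", "VI table")
  ok <- is.na(vi$value) | vi$value > 0
  if (!all(ok))
    stop("log10 transform requires strictly positive values; offending rows: ",
         paste(utils::head(which(!ok), 5), collapse = ", "), call. = FALSE)
  vi$value <- log10(vi$value)
  attr(vi, "transform") <- "log10"
  vi
}
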