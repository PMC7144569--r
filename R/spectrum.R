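# Emission-spectrum container and I/O.  Spectra live on a strictly
# increasing, uniform wavelength grid; cohorts travel as long-format CSV
# (sample_id, group, excitation_nm, wavelength_nm, intensity_au).

.trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)

.window_idx <- function(wavelengths, window) {
  wavelengths >= window[1] & wavelengths <= window[2]
}

#' Construct an emission spectrum
#'
#' @param wavelength Strictly increasing, uniformly spaced wavelengths (nm).
#' @param intensity Fluorescence intensities (arbitrary units), same length.
#' @param excitation Excitation wavelength (nm), typically 310 or 366.
#' @param sample_id Sample identifier.
#' @param group Treatment group: `"sham"`, `"ir_60_60"`, `"ir_60_120"` or
#'   `"other"`.
#' @return An object of class `"af_spectrum"`.
#' @export
af_spectrum <- function(wavelength, intensity, excitation,
                        sample_id = "sample", group = "other") {
  stopifnot(is.numeric(wavelength), is.numeric(intensity),
            length(wavelength) == length(intensity), length(wavelength) >= 3L)
  d <- diff(wavelength)
  if (any(d <= 0)) stop("wavelengths must be strictly increasing")
  if (diff(range(d)) > 1e-9 * mean(d)) stop("wavelength grid must be uniform")
  structure(list(wavelength = wavelength, intensity = intensity,
                 excitation = excitation, sample_id = sample_id,
                 group = group, raw_integrated_area = NA_real_,
                 normalized = FALSE),
            class = "af_spectrum")
}

#' @export
print.af_spectrum <- function(x, ...) {
  cat(sprintf("Emission spectrum '%s' (group %s, excitation %g nm)\n",
              x$sample_id, x$group, x$excitation))
  cat(sprintf("  %d points, %g-%g nm; max intensity %.4g a.u.%s\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              max(x$intensity),
              if (isTRUE(x$normalized)) " (peak-normalized)" else ""))
  if (is.finite(x$raw_integrated_area))
    cat(sprintf("  raw integrated area: %.6g a.u.*nm\n", x$raw_integrated_area))
  invisible(x)
}

#' Peak-normalize a spectrum to 100 a.u.
#'
#' Scales the intensities so the maximum equals 100 a.u. The
#' pre-normalization trapezoidal integral over the analysis window is
#' recorded as `raw_integrated_area`; it is the measured amplitude used
#' later to convert percentage contributions into absolute ones. Already
#' normalized spectra pass through unchanged (the recorded raw area is
#' kept).
#'
#' @param x An [af_spectrum()].
#' @param window Analysis window in nm, default `c(390, 600)`.
#' @return The normalized `"af_spectrum"`.
#' @export
normalize_spectrum <- function(x, window = c(390, 600)) {
  stopifnot(inherits(x, "af_spectrum"))
  m <- max(x$intensity)
  if (!is.finite(m) || m <= 0)
    stop("cannot normalize: maximum intensity is not positive")
  if (!is.finite(x$raw_integrated_area)) {
    idx <- .window_idx(x$wavelength, window)
    if (sum(idx) < 2L) stop("analysis window contains fewer than 2 points")
    x$raw_integrated_area <- .trapz(x$wavelength[idx], x$intensity[idx])
  }
  x$intensity <- x$intensity * (100 / m)
  x$normalized <- TRUE
  x
}

#' Read or write cohorts of spectra
#'
#' Long-format CSV with columns `sample_id, group, excitation_nm,
#' wavelength_nm, intensity_au`, one row per measured point.
#'
#' @param path CSV file path.
#' @param spectra List of [af_spectrum()] objects (for writing).
#' @return `read_spectra()` returns a named list of `"af_spectrum"`
#'   objects; `write_spectra()` returns `path` invisibly.
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "group", "excitation_nm", "wavelength_nm",
           "intensity_au")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("spectra CSV missing columns: ", paste(miss, collapse = ", "))
  for (v in c("wavelength_nm", "intensity_au", "excitation_nm")) {
    raw <- df[[v]]
    df[[v]] <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.finite(df[[v]]))
    if (length(bad))
      stop("non-numeric ", v, " value at CSV line ", bad[1] + 1L)
  }
  out <- lapply(split(df, df$sample_id), function(s) {
    s <- s[order(s$wavelength_nm), ]
    af_spectrum(s$wavelength_nm, s$intensity_au,
                excitation = s$excitation_nm[1],
                sample_id = s$sample_id[1], group = s$group[1])
  })
  out[unique(df$sample_id)]
}

#' @rdname read_spectra
#' @export
write_spectra <- function(spectra, path) {
  rows <- lapply(spectra, function(s) {
    data.frame(sample_id = s$sample_id, group = s$group,
               excitation_nm = s$excitation,
               wavelength_nm = s$wavelength, intensity_au = s$intensity,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
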