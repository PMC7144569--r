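# Component registry: one row per candidate emission band, per excitation.
# Starting (peak, FWHM) pairs for the four fluorophores come from emission
# spectra of the pure compounds in ethanol; minor bands (protein tail,
# undefined 440 nm contributor, negative hemoglobin-absorption band, flavin
# band in injured samples at 366 nm) have free widths and serve to reach a
# satisfying goodness of fit.

.component_defs <- function() {
  # name, role, per-excitation (peak, fwhm)
  list(
    retinol          = list(role = "fluorophore",
                            `310` = c(490, 112), `366` = c(490, 112)),
    arachidonic_acid = list(role = "fluorophore",
                            `310` = c(425, 120), `366` = c(470, 93)),
    oleic_acid       = list(role = "fluorophore",
                            `310` = c(370, 85),  `366` = c(462, 90)),
    linoleic_acid    = list(role = "fluorophore",
                            `310` = c(417, 92),  `366` = c(428, 73)),
    proteins         = list(role = "tail",
                            `310` = c(400, 80),  `366` = c(400, 80)),
    undefined_440    = list(role = "auxiliary",
                            `310` = c(440, 60),  `366` = c(440, 60)),
    hemoglobin_neg   = list(role = "negative",
                            `310` = c(410, 30),  `366` = c(410, 30)),
    flavin_560       = list(role = "auxiliary",
                            `310` = c(560, 60),  `366` = c(560, 60))
  )
}

.default_rho <- 0.3

.make_component <- function(name, excitation, enabled = TRUE) {
  defs <- .component_defs()[[name]]
  pk <- defs[[as.character(excitation)]]
  role <- defs$role
  minor <- role %in% c("tail", "auxiliary", "negative")
  peak <- pk[1]; fwhm <- pk[2]
  # fluorophore peaks are bounded +-10 nm to preserve component identity;
  # the protein tail must stay below 420 nm; minor-band widths are free
  peak_lo <- if (role == "tail") 380 else peak - 10
  peak_hi <- if (role == "tail") 419 else peak + 10
  fwhm_lo <- if (minor) 20 else fwhm - 15
  fwhm_hi <- if (minor) 150 else fwhm + 15
  amp_lo <- if (role == "negative") -Inf else 0
  amp_hi <- if (role == "negative") 0 else Inf
  data.frame(
    name = name, role = role, excitation = excitation,
    peak_lambda = peak, fwhm = fwhm, rho = .default_rho,
    peak_lo = peak_lo, peak_hi = peak_hi,
    fwhm_lo = fwhm_lo, fwhm_hi = fwhm_hi,
    rho_lo = 0, rho_hi = 1.5,
    amp_lo = amp_lo, amp_hi = amp_hi,
    enabled = enabled, stringsAsFactors = FALSE
  )
}

#' Endogenous-fluorophore component library
#'
#' Returns the component definitions used to decompose a serum emission
#' spectrum at a given excitation wavelength: the four named fluorophores
#' (retinol, arachidonic, oleic and linoleic acid) with their published
#' starting (peak, FWHM) values, a protein emission tail constrained below
#' 420 nm, an undefined auxiliary band near 440 nm, a negative
#' hemoglobin-absorption band near 410 nm (enabled by default at 310 nm
#' excitation, where reabsorption distorts the signal), and a flavin band
#' near 560 nm enabled only for ischemia/reperfusion samples at 366 nm.
#'
#' @param excitation Excitation wavelength, 310 or 366 (nm).
#' @param context `"control"` or `"ir"`: ischemia/reperfusion samples at
#'   366 nm additionally enable the 560 nm flavin band.
#' @param hemoglobin_366 Enable the negative hemoglobin band at 366 nm
#'   excitation (off by default; the distortion it compensates is tied to
#'   310 nm excitation).
#' @return A data frame of class `"af_components"`, one row per enabled
#'   component, with starting values (`peak_lambda`, `fwhm`, `rho`) and box
#'   bounds (`*_lo`, `*_hi`) for every fitted parameter.
#' @examples
#' af_components(310)
#' af_components(366, context = "ir")
#' @export
af_components <- function(excitation, context = c("control", "ir"),
                          hemoglobin_366 = FALSE) {
  context <- match.arg(context)
  if (!excitation %in% c(310, 366))
    stop("unsupported excitation wavelength: ", excitation,
         " (must be 310 or 366 nm)")
  names <- c("retinol", "arachidonic_acid", "oleic_acid", "linoleic_acid",
             "proteins", "undefined_440")
  if (excitation == 310 || hemoglobin_366)
    names <- c(names, "hemoglobin_neg")
  if (excitation == 366 && context == "ir")
    names <- c(names, "flavin_560")
  out <- do.call(rbind, lapply(names, .make_component, excitation = excitation))
  class(out) <- c("af_components", "data.frame")
  out
}

.validate_components <- function(x) {
  req <- c("name", "role", "excitation", "peak_lambda", "fwhm", "rho",
           "peak_lo", "peak_hi", "fwhm_lo", "fwhm_hi", "rho_lo", "rho_hi",
           "amp_lo", "amp_hi", "enabled")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("component table missing fields: ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$name))
    stop("component names must be unique: ",
         paste(x$name[duplicated(x$name)], collapse = ", "))
  known <- names(.component_defs())
  bad <- setdiff(x$name, known)
  if (length(bad)) stop("unknown component name: ", paste(bad, collapse = ", "))
  if (!all(x$role %in% c("fluorophore", "tail", "auxiliary", "negative")))
    stop("invalid role in component table")
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    where <- paste0("components[", r$name, "]")
    if (!is.finite(r$fwhm) || r$fwhm <= 0)
      stop(where, ".fwhm: must be > 0")
    if (r$peak_lambda < 300 || r$peak_lambda > 700)
      stop(where, ".peak_lambda: outside [300, 700] nm")
    if (r$rho < 0) stop(where, ".rho: must be >= 0")
    for (p in c("peak", "fwhm", "rho", "amp")) {
      lo <- r[[paste0(p, "_lo")]]; hi <- r[[paste0(p, "_hi")]]
      if (lo > hi) stop(where, ".", p, ": inverted bounds [", lo, ", ", hi, "]")
    }
    if (r$role == "negative") {
      if (r$amp_hi > 0)
        stop(where, ".amp: negative-role band must have upper bound <= 0")
    } else if (r$amp_lo < 0) {
      stop(where, ".amp: lower bound must be >= 0 for non-negative roles")
    }
  }
  invisible(x)
}

#' Read or write a component library
#'
#' The component registry round-trips through a human-editable YAML file so
#' that starting values and bounds can be adjusted without touching code.
#' `write_component_library()` serializes a component table;
#' `read_component_library()` loads and validates one, rejecting unknown
#' component names, non-positive widths and inverted bounds with the
#' offending field named.
#'
#' @param x An `"af_components"` table, e.g. from [af_components()].
#' @param path File path of the YAML library.
#' @return `read_component_library()` returns an `"af_components"` table;
#'   `write_component_library()` returns `path` invisibly.
#' @export
write_component_library <- function(x, path) {
  .validate_components(x)
  comps <- lapply(seq_len(nrow(x)), function(i) {
    r <- as.list(x[i, setdiff(names(x), "excitation")])
    r
  })
  yaml::write_yaml(list(excitation = unique(x$excitation),
                        components = comps), path)
  invisible(path)
}

#' @rdname write_component_library
#' @export
read_component_library <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("malformed library file: ",
                                           conditionMessage(e)))
  if (is.null(cfg$excitation) || is.null(cfg$components))
    stop("library file must contain 'excitation' and 'components'")
  rows <- lapply(cfg$components, function(cc) {
    cc$excitation <- cfg$excitation
    as.data.frame(cc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  canon <- c("name", "role", "excitation", "peak_lambda", "fwhm", "rho",
             "peak_lo", "peak_hi", "fwhm_lo", "fwhm_hi", "rho_lo", "rho_hi",
             "amp_lo", "amp_hi", "enabled")
  out <- out[, intersect(canon, names(out)), drop = FALSE]
  num <- setdiff(names(out), c("name", "role", "enabled"))
  for (v in num) out[[v]] <- as.numeric(out[[v]])
  out$enabled <- as.logical(out$enabled)
  class(out) <- c("af_components", "data.frame")
  .validate_components(out)
  out
}
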