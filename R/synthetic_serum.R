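# Synthetic serum-spectrum generator.  Emulates the sham vs
# ischemia/reperfusion study design: per-sample component percentages are
# drawn around the published group means (truncated normal, renormalized),
# the total emission area around the published group magnitudes
# (lognormal), bands are realized GMG shapes from the component library
# with small per-sample peak jitter, a negative hemoglobin dip distorts
# the 310 nm spectra, an extra flavin band appears in injured samples at
# 366 nm, and homoscedastic Gaussian noise is added on the normalized
# scale.  Every draw is deterministic given the seed, and the exact
# composition is returned alongside each spectrum for recovery testing.

# group-mean percentage compositions (% of overall fitted area) and their
# standard errors at n = 7; unprinted minor cells are set to 2% and the
# remainder of each row is assigned to the undefined 440 nm band
.profile_table <- function() {
  list(
    `310` = list(
      sham = list(
        mean = c(retinol = 44.26, arachidonic_acid = 25.13,
                 linoleic_acid = 2, oleic_acid = 7.93, proteins = 12.48),
        se = c(retinol = 1.95, arachidonic_acid = 1.12, linoleic_acid = NA,
               oleic_acid = 0.39, proteins = 0.60),
        total_area = 39284.20),
      ir_60_60 = list(
        mean = c(retinol = 31.39, arachidonic_acid = 38.93,
                 linoleic_acid = 2, oleic_acid = 8.86, proteins = 8.20),
        se = c(retinol = 0.84, arachidonic_acid = 1.04, linoleic_acid = NA,
               oleic_acid = 0.23, proteins = 0.21),
        total_area = 57836.14),
      ir_60_120 = list(
        mean = c(retinol = 29.09, arachidonic_acid = 39.16,
                 linoleic_acid = 2, oleic_acid = 8.56, proteins = 10.24),
        se = c(retinol = 3.63, arachidonic_acid = 4.95, linoleic_acid = NA,
               oleic_acid = 0.90, proteins = 1.45),
        total_area = 50453.79)),
    `366` = list(
      sham = list(
        mean = c(retinol = 33.43, arachidonic_acid = 20.22,
                 linoleic_acid = 23.32, oleic_acid = 12.88, proteins = 2),
        se = c(retinol = 2.68, arachidonic_acid = 1.52, linoleic_acid = 1.86,
               oleic_acid = 1.03, proteins = NA),
        total_area = 16218.19),
      ir_60_60 = list(
        mean = c(retinol = 24.03, arachidonic_acid = 26.50,
                 linoleic_acid = 27.47, oleic_acid = 16.97, proteins = 2),
        se = c(retinol = 1.35, arachidonic_acid = 1.49, linoleic_acid = 1.55,
               oleic_acid = 0.67, proteins = NA),
        total_area = 24444.97),
      ir_60_120 = list(
        mean = c(retinol = 23.76, arachidonic_acid = 27.17,
                 linoleic_acid = 27.02, oleic_acid = 16.97, proteins = 2),
        se = c(retinol = 3.34, arachidonic_acid = 3.82, linoleic_acid = 3.93,
               oleic_acid = 2.38, proteins = NA),
        total_area = 20402.38))
  )
}

#' Define a synthetic serum group profile
#'
#' A group profile holds the statistical structure of one treatment group
#' at one excitation: mean and SD of each component's percentage
#' contribution, the mean total emission area with its coefficient of
#' variation, the hemoglobin dip depth (310 nm), the flavin percentage
#' (ischemia/reperfusion at 366 nm), and the noise level. Percent means
#' must sum to at most 100; the remainder is assigned to the undefined
#' 440 nm band.
#'
#' @param group Group label (`"sham"`, `"ir_60_60"`, `"ir_60_120"`, ...).
#' @param excitation Excitation wavelength (310 or 366 nm).
#' @param percent_mean Named vector of component percentage means.
#' @param percent_sd Named vector of per-sample SDs; defaults to 20% of
#'   each mean where not supplied.
#' @param total_area_mean Mean total integrated area (a.u. x nm) over the
#'   analysis window.
#' @param total_area_cv Coefficient of variation of the total area
#'   (lognormal), default 0.15.
#' @param flavin_percent Flavin-band percentage added for
#'   ischemia/reperfusion groups at 366 nm, default 3 (0 disables).
#' @param hemoglobin_depth Depth of the negative hemoglobin dip as percent
#'   of the spectrum maximum, default 5 at 310 nm, 0 at 366 nm.
#' @param noise_sd Additive Gaussian noise SD on the peak-normalized scale
#'   (a.u., max = 100), default 0.5.
#' @param peak_jitter Half-range of the uniform per-sample band-peak
#'   jitter (nm), default 2.
#' @param rho Asymmetry ratio used for all generated bands, default 0.3.
#' @return An object of class `"af_group_profile"`.
#' @export
group_profile <- function(group, excitation, percent_mean, percent_sd = NULL,
                          total_area_mean, total_area_cv = 0.15,
                          flavin_percent = if (excitation == 366 &&
                                               grepl("^ir", group)) 3 else 0,
                          hemoglobin_depth = if (excitation == 310) 5 else 0,
                          noise_sd = 0.5, peak_jitter = 2, rho = 0.3) {
  stopifnot(excitation %in% c(310, 366), !is.null(names(percent_mean)))
  if (flavin_percent > 0)
    percent_mean <- c(percent_mean, flavin_560 = flavin_percent)
  if (is.null(percent_sd)) percent_sd <- 0.2 * percent_mean
  percent_sd <- percent_sd[names(percent_mean)]
  percent_sd[is.na(percent_sd)] <- 0.2 * percent_mean[is.na(percent_sd)]
  tot <- sum(percent_mean)
  if (tot > 100 + 1e-9)
    stop("percent means sum to ", round(tot, 2), " > 100")
  remainder <- 100 - tot
  if (!"undefined_440" %in% names(percent_mean)) {
    percent_mean <- c(percent_mean, undefined_440 = remainder)
    percent_sd <- c(percent_sd, undefined_440 = 0.2 * remainder)
  }
  if (any(percent_sd < 0)) stop("percent SDs must be >= 0")
  structure(list(group = group, excitation = excitation,
                 percent_mean = percent_mean, percent_sd = percent_sd,
                 total_area_mean = total_area_mean,
                 total_area_cv = total_area_cv,
                 hemoglobin_depth = hemoglobin_depth,
                 noise_sd = noise_sd, peak_jitter = peak_jitter, rho = rho),
            class = "af_group_profile")
}

#' Default group profiles
#'
#' Profiles for the sham and ischemia/reperfusion groups at a given
#' excitation, parameterized by the published group compositions (percent
#' means with SE x sqrt(7) per-sample SDs) and total-area magnitudes.
#'
#' @param excitation 310 or 366 (nm).
#' @param groups Which groups to return.
#' @param n_published Cohort size behind the published SEs (per-sample SD
#'   is SE x sqrt(n)), default 7.
#' @param ... Passed on to [group_profile()] (e.g. `noise_sd`).
#' @return Named list of `"af_group_profile"` objects.
#' @export
default_profiles <- function(excitation,
                             groups = c("sham", "ir_60_60", "ir_60_120"),
                             n_published = 7, ...) {
  tab <- .profile_table()[[as.character(excitation)]]
  if (is.null(tab)) stop("unsupported excitation wavelength: ", excitation)
  bad <- setdiff(groups, names(tab))
  if (length(bad)) stop("no default profile for group: ",
                        paste(bad, collapse = ", "))
  out <- lapply(groups, function(g) {
    row <- tab[[g]]
    group_profile(g, excitation, percent_mean = row$mean,
                  percent_sd = row$se * sqrt(n_published),
                  total_area_mean = row$total_area, ...)
  })
  names(out) <- groups
  out
}

# starting (peak, fwhm) of a component at an excitation, from the library
.gen_band_start <- function(name, excitation) {
  defs <- .component_defs()[[name]]
  defs[[as.character(excitation)]]
}

#' Generate one synthetic serum spectrum
#'
#' Draws a per-sample composition and total area from the profile, builds
#' the corresponding GMG bands (component-library starting shapes with
#' uniform per-sample peak jitter) with analytic band areas proportional
#' to the drawn percentages, adds the negative hemoglobin dip and, where
#' the profile says so, the flavin band, scales the summed curve so its
#' trapezoidal integral over `window` equals the drawn total area, and
#' adds Gaussian noise.
#'
#' The ground-truth table reports each component's share of the positive
#' modeled area *within the analysis window* (`percent`), which is the
#' quantity the fitting pipeline estimates; the drawn analytic-area share
#' is kept as `percent_drawn`. For bands well inside the window the two
#' coincide; bands truncated at the window edges (the oleic band under
#' 310 nm excitation, the protein tail) contribute only their in-window
#' part.
#'
#' @param profile An `"af_group_profile"`.
#' @param sample_id Sample identifier.
#' @param seed Integer seed; the draw is fully deterministic given it.
#' @param grid Wavelength grid (nm), default 390-630 at 1 nm.
#' @param window Analysis window used to scale the total area, default
#'   `c(390, 600)`.
#' @return List with elements `spectrum` (an [af_spectrum()], raw scale)
#'   and `truth` (data frame: component, percent, percent_drawn, absolute,
#'   total_area).
#' @export
generate_spectrum <- function(profile, sample_id, seed,
                              grid = seq(390, 630, by = 1),
                              window = c(390, 600)) {
  stopifnot(inherits(profile, "af_group_profile"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  pm <- profile$percent_mean
  ps <- profile$percent_sd
  # truncated-normal percentages renormalized to the profile total (100)
  draw <- pmax(stats::rnorm(length(pm), pm, ps), 0)
  draw <- draw * sum(pm) / sum(draw)
  names(draw) <- names(pm)

  cv <- profile$total_area_cv
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(profile$total_area_mean) - sdlog^2 / 2
  total_area <- stats::rlnorm(1, meanlog, sdlog)

  fine <- seq(window[1], window[2], by = 0.25)
  curve <- numeric(length(grid))
  warea <- setNames(numeric(length(draw)), names(draw))
  for (comp in names(draw)) {
    st <- .gen_band_start(comp, profile$excitation)
    peak <- st[1] + stats::runif(1, -profile$peak_jitter, profile$peak_jitter)
    band <- solve_band(peak, st[2], profile$rho, amplitude = draw[[comp]])
    warea[comp] <- .trapz(fine, gmg_value(band, fine))
    curve <- curve + gmg_value(band, grid)
  }
  window_share <- 100 * warea / sum(warea)
  if (profile$hemoglobin_depth > 0) {
    st <- .gen_band_start("hemoglobin_neg", profile$excitation)
    peak <- st[1] + stats::runif(1, -profile$peak_jitter, profile$peak_jitter)
    unit <- solve_band(peak, st[2], profile$rho, amplitude = 1)
    upeak <- max(gmg_value(unit, seq(peak - 50, peak + 50, by = 0.1)))
    amp <- -(profile$hemoglobin_depth / 100) * max(curve) / upeak
    curve <- curve + gmg_value(unit, grid) * amp
  }

  idx <- .window_idx(grid, window)
  scale <- total_area / .trapz(grid[idx], curve[idx])
  curve <- curve * scale
  noise <- stats::rnorm(length(grid), 0, profile$noise_sd * max(curve) / 100)
  spec <- af_spectrum(grid, curve + noise, excitation = profile$excitation,
                      sample_id = sample_id, group = profile$group)

  truth <- data.frame(sample_id = sample_id, group = profile$group,
                      excitation = profile$excitation,
                      component = names(draw),
                      percent = as.numeric(window_share),
                      percent_drawn = as.numeric(draw),
                      absolute = as.numeric(window_share) / 100 * total_area,
                      total_area = total_area, row.names = NULL,
                      stringsAsFactors = FALSE)
  list(spectrum = spec, truth = truth)
}

#' Generate a synthetic cohort
#'
#' Generates `n_per_group` spectra for each profile. Per-sample seeds are
#' derived counter-style from the master seed
#' (`seed + 1000 * group_index + sample_index`), so any sample can be
#' regenerated in isolation and the whole cohort is reproducible.
#'
#' @param profiles List of `"af_group_profile"` objects (see
#'   [default_profiles()]).
#' @param n_per_group Samples per group (>= 2), default 7.
#' @param seed Master integer seed.
#' @param ... Passed to [generate_spectrum()].
#' @return List with `spectra` (named list of [af_spectrum()]) and `truth`
#'   (row-bound ground-truth table).
#' @export
generate_cohort <- function(profiles, n_per_group = 7, seed = 1, ...) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (inherits(profiles, "af_group_profile")) profiles <- list(profiles)
  spectra <- list()
  truth <- list()
  for (gi in seq_along(profiles)) {
    pr <- profiles[[gi]]
    for (j in seq_len(n_per_group)) {
      id <- sprintf("%s_%02d", pr$group, j)
      g <- generate_spectrum(pr, sample_id = id,
                             seed = seed + 1000L * gi + j, ...)
      spectra[[id]] <- g$spectrum
      truth[[id]] <- g$truth
    }
  }
  list(spectra = spectra, truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}
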