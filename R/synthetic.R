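#' Built-in tablet formulations
#'
#' The seven-strength chlorpheniramine maleate composition series: the
#' active rises from 4 to 30 mg/tablet while lactose monohydrate compensates
#' so every formulation weighs 132.0 mg; tapioca starch, croscarmellose
#' sodium, corn starch and magnesium stearate are constant.
#'
#' @return A tibble, one row per strength, component masses in mg/tablet
#'   plus a `total_mg` column.
#' @export
builtin_formulations <- function() {
  strengths <- c(4, 8, 10, 15, 20, 25, 30)
  tibble(
    strength_mg = strengths,
    cpm = strengths,
    lactose_monohydrate = c(80, 76, 74, 69, 64, 59, 54),
    tapioca_starch = rep(40, 7),
    croscarmellose_sodium = rep(3.7, 7),
    corn_starch = rep(3.6, 7),
    magnesium_stearate = rep(0.7, 7),
    total_mg = rep(132, 7)
  )
}

formulation_components <- c(
  "cpm", "lactose_monohydrate", "tapioca_starch",
  "croscarmellose_sodium", "corn_starch", "magnesium_stearate"
)

# Composition rule underlying the builtin series: lactose fills to a
# constant 132 mg tablet. Lets the generator handle strengths between the
# tabulated ones.
formulation_for_strength <- function(strength_mg) {
  lactose <- 84 - strength_mg
  if (lactose < 0) {
    stop_chemocal("strength too high for a 132 mg tablet (lactose would be negative)",
                  "design_error")
  }
  c(cpm = strength_mg, lactose_monohydrate = lactose, tapioca_starch = 40,
    croscarmellose_sodium = 3.7, corn_starch = 3.6, magnesium_stearate = 0.7)
}

#' Built-in vibrational band library
#'
#' Lorentzian band parameters (center cm^-1, half-width at half-maximum
#' cm^-1, amplitude in a.u. per unit mass fraction) for the active and the
#' five excipients. The active's bands sit at the characteristic
#' chlorpheniramine maleate positions (C=O ~1700, C-H stretch ~2900, C=N
#' ~1640, C=C ~1600, C-O stretch ~1100, C-H bend ~880 cm^-1). Excipient
#' libraries use standard carbohydrate/stearate features (broad O-H ~3350,
#' C-H ~2920, C-O-C ~1000-1150 cm^-1) that deliberately overlap the
#' active's fingerprint region, reproducing the real difficulty of
#' quantifying a minor component under a dominant excipient background.
#'
#' @return A tibble: `component`, `center`, `width`, `amplitude`, `shape`.
#' @export
builtin_band_library <- function() {
  band <- function(component, center, width, amplitude) {
    tibble(component = component, center = center, width = width,
           amplitude = amplitude, shape = "lorentzian")
  }
  dplyr::bind_rows(
    band("cpm", 1700, 15, 1.00),   # C=O
    band("cpm", 2900, 30, 0.60),   # C-H stretch
    band("cpm", 1640, 12, 0.80),   # C=N
    band("cpm", 1600, 12, 0.70),   # aromatic C=C
    band("cpm", 1100, 20, 0.90),   # C-O stretch
    band("cpm",  880, 15, 0.50),   # C-H bend
    band("lactose_monohydrate", 3350, 150, 0.50),
    band("lactose_monohydrate", 2920,  40, 0.35),
    band("lactose_monohydrate", 1070,  60, 0.80),
    band("lactose_monohydrate", 1030,  40, 0.60),
    band("lactose_monohydrate",  900,  30, 0.20),
    band("tapioca_starch", 3320, 150, 0.45),
    band("tapioca_starch", 2925,  40, 0.30),
    band("tapioca_starch", 1640,  30, 0.15),
    band("tapioca_starch", 1150,  40, 0.40),
    band("tapioca_starch",  995,  50, 0.85),
    band("croscarmellose_sodium", 3350, 150, 0.40),
    band("croscarmellose_sodium", 2900,  40, 0.25),
    band("croscarmellose_sodium", 1590,  40, 0.50),
    band("croscarmellose_sodium", 1050,  60, 0.70),
    band("corn_starch", 3320, 150, 0.45),
    band("corn_starch", 2925,  40, 0.30),
    band("corn_starch", 1645,  30, 0.15),
    band("corn_starch", 1150,  40, 0.40),
    band("corn_starch", 1000,  50, 0.85),
    band("magnesium_stearate", 2915, 25, 1.00),
    band("magnesium_stearate", 2850, 20, 0.80),
    band("magnesium_stearate", 1575, 30, 0.60),
    band("magnesium_stearate", 1465, 25, 0.40)
  )
}

band_profile <- function(grid, center, width, amplitude, shape) {
  z <- (grid - center) / width
  if (shape == "lorentzian") {
    amplitude / (1 + z^2)
  } else if (shape == "gaussian") {
    amplitude * exp(-log(2) * z^2)
  } else {
    stop_chemocal(sprintf("unknown band shape '%s'", shape), "parameter_error")
  }
}

# component spectra on the grid: one row per component in `components` order
component_spectra <- function(grid, band_library, components) {
  out <- matrix(0, length(components), length(grid),
                dimnames = list(components, NULL))
  for (i in seq_len(nrow(band_library))) {
    comp <- band_library$component[i]
    if (!comp %in% components) next
    out[comp, ] <- out[comp, ] + band_profile(
      grid, band_library$center[i], band_library$width[i],
      band_library$amplitude[i], band_library$shape[i]
    )
  }
  out
}

#' Describe a synthetic measurement campaign
#'
#' Bundles everything [generate_set()] needs: the dosage form, the strength
#' series with its replicate count, the wavenumber grid, the band library,
#' and the disturbance magnitudes. Defaults emulate a seven-level
#' concentration series measured by a DTGS-detector ATR accessory: 30
#' replicate tablets (10 replicate granule samples) per strength on a
#' 400-4000 cm^-1 grid at 2 cm^-1 spacing.
#'
#' The single modelled difference between the two dosage forms is
#' `tablet_surface_sd`: a multiplicative jitter on the per-sample component
#' mass fractions representing an intact compact's surface composition
#' deviating from the bulk mass ratio. Ground granules present a
#' homogenized surface, so the granule default is 0; the tablet default is
#' 0.03 (3 percent relative), which makes the absolute content error grow
#' with strength and yields heteroscedastic validation residuals.
#'
#' @param form `"tablet"` or `"granule"`.
#' @param strengths Nominal contents, mg/unit.
#' @param replicates_per_strength Samples per strength (default 30 for
#'   tablets, 10 for granules).
#' @param grid Wavenumber grid (cm^-1).
#' @param band_library Band table (see [builtin_band_library()]).
#' @param noise_sd Additive detector noise, a.u.
#' @param scatter_sd Multiplicative scatter sd (mean-1 factor per sample).
#' @param baseline_offset_sd,baseline_slope_sd Linear baseline drift:
#'   intercept sd (a.u.) and slope sd (a.u. per cm^-1).
#' @param tablet_surface_sd Relative surface-composition jitter (see
#'   above).
#' @param reference_recovery,reference_rsd Reference-method mean relative
#'   recovery and relative sd (defaults 1.015 and 0.0126, the midpoint and
#'   repeatability of a validated HPLC assay).
#' @param seed Master seed; spectra and reference noise use documented
#'   child seeds so stages can be regenerated in isolation.
#' @return A `synthetic_design` object.
#' @export
synthetic_design <- function(form = c("tablet", "granule"),
                             strengths = c(4, 8, 10, 15, 20, 25, 30),
                             replicates_per_strength = NULL,
                             grid = seq(400, 4000, by = 2),
                             band_library = builtin_band_library(),
                             noise_sd = 0.002,
                             scatter_sd = 0.05,
                             baseline_offset_sd = 0.02,
                             baseline_slope_sd = 1e-5,
                             tablet_surface_sd = NULL,
                             reference_recovery = 1.015,
                             reference_rsd = 0.0126,
                             seed = 1L) {
  form <- match.arg(form)
  replicates_per_strength <- replicates_per_strength %||%
    if (form == "tablet") 30L else 10L
  tablet_surface_sd <- tablet_surface_sd %||%
    if (form == "tablet") 0.03 else 0
  if (any(strengths <= 0) || replicates_per_strength < 1) {
    stop_chemocal("strengths must be positive and replicates >= 1", "design_error")
  }
  sds <- c(noise_sd, scatter_sd, baseline_offset_sd, baseline_slope_sd,
           tablet_surface_sd, reference_rsd)
  if (any(sds < 0) || reference_recovery <= 0) {
    stop_chemocal("noise magnitudes must be >= 0 and recovery > 0", "design_error")
  }
  structure(list(
    form = form, strengths = as.numeric(strengths),
    replicates_per_strength = as.integer(replicates_per_strength),
    grid = as.numeric(grid), band_library = band_library,
    noise_sd = noise_sd, scatter_sd = scatter_sd,
    baseline_offset_sd = baseline_offset_sd,
    baseline_slope_sd = baseline_slope_sd,
    tablet_surface_sd = tablet_surface_sd,
    reference_recovery = reference_recovery, reference_rsd = reference_rsd,
    seed = as.integer(seed)
  ), class = "synthetic_design")
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat(sprintf(
    "<synthetic_design> %s: %d strengths x %d replicates, %d grid points, seed %d\n",
    x$form, length(x$strengths), x$replicates_per_strength,
    length(x$grid), x$seed))
  invisible(x)
}

# deterministic per-stage child seeds from the master seed (kept < 2^31)
child_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 7919 + stage * 104729) %% 2147483647)
}

#' Generate a synthetic spectrum set
#'
#' Each sample's absorbance is the mass-fraction-weighted sum of the
#' component band spectra (fractions jittered by `tablet_surface_sd` for
#' tablets), scaled by a per-sample multiplicative scatter factor, plus a
#' random linear baseline and i.i.d. additive noise. True contents are the
#' nominal strengths; reference values come from [simulate_reference()]
#' under a child seed. With all disturbance terms at zero, absorbance at
#' every grid point is exactly affine in the active's mass fraction.
#'
#' @param design A [synthetic_design()].
#' @param seed Optional override of the design's master seed.
#' @return A `spectra_set` whose sample table carries `form`, `nominal_mg`,
#'   `truth_mg` and `reference_mg`.
#' @export
generate_set <- function(design, seed = design$seed) {
  comps <- formulation_components
  C <- component_spectra(design$grid, design$band_library, comps)
  strengths <- rep(design$strengths, each = design$replicates_per_strength)
  reps <- rep(seq_len(design$replicates_per_strength),
              times = length(design$strengths))
  n <- length(strengths)
  p <- length(design$grid)

  F <- t(vapply(strengths,
                function(s) formulation_for_strength(s) / 132,
                numeric(length(comps))))
  colnames(F) <- comps

  spectra_seed <- child_seed(seed, 1)
  X <- withr::with_seed(spectra_seed, {
    if (design$tablet_surface_sd > 0) {
      F <- F * (1 + matrix(rnorm(n * ncol(F), 0, design$tablet_surface_sd),
                           n, ncol(F)))
    }
    A <- F %*% C
    scatter <- rnorm(n, 0, design$scatter_sd)
    b0 <- rnorm(n, 0, design$baseline_offset_sd)
    b1 <- rnorm(n, 0, design$baseline_slope_sd)
    wc <- design$grid - mean(design$grid)
    A <- A * (1 + scatter) + outer(b0, rep(1, p)) + outer(b1, wc)
    A + matrix(rnorm(n * p, 0, design$noise_sd), n, p)
  })

  reference <- simulate_reference(strengths, design$reference_recovery,
                                  design$reference_rsd,
                                  seed = child_seed(seed, 2))
  samples <- tibble(
    sample_id = sprintf("%s_%gmg_r%02d",
                        substr(design$form, 1, 4), strengths, reps),
    form = design$form,
    nominal_mg = strengths,
    truth_mg = strengths,
    reference_mg = reference
  )
  spectra_set(design$grid, X, samples)
}

#' Simulate reference-method determinations
#'
#' Emulates an HPLC assay of the true contents: each value is scaled by the
#' method's mean relative recovery and perturbed by seeded Gaussian noise
#' with the given relative standard deviation.
#'
#' @param true_contents True analyte contents, mg/unit.
#' @param recovery Mean relative recovery (1 = unbiased; default 1.015).
#' @param rsd Relative standard deviation of the assay (default 0.0126).
#' @param seed Integer seed.
#' @return Numeric vector of simulated reference values.
#' @export
simulate_reference <- function(true_contents, recovery = 1.015, rsd = 0.0126,
                               seed = 1L) {
  if (recovery <= 0 || rsd < 0) {
    stop_chemocal("recovery must be > 0 and rsd >= 0", "parameter_error")
  }
  withr::with_seed(seed, {
    true_contents * recovery * (1 + rnorm(length(true_contents), 0, rsd))
  })
}
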