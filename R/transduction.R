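#' Particle geometry of a core--double-shell magnetoelectric nanodisc
#'
#' Describes a hexagonal/cylindrical nanodisc as a coaxial core disc wrapped by
#' concentric shells of equal thickness (all lengths in metres). The default
#' geometry is a 250 nm diameter, 50 nm thick disc with a 150 nm magnetite core
#' and two 25 nm shells (cobalt ferrite, barium titanate).
#'
#' @param diameter Disc diameter in metres (> 0).
#' @param thickness Disc thickness in metres (> 0).
#' @param core_diameter Diameter of the core disc in metres.
#' @param shell_thicknesses Numeric vector of radial shell thicknesses (m),
#'   ordered from the core outwards.
#' @return An object of class `particle_geometry`.
#' @examples
#' particle_geometry()
#' @export
particle_geometry <- function(diameter = 250e-9, thickness = 50e-9,
                              core_diameter = 150e-9,
                              shell_thicknesses = c(25e-9, 25e-9)) {
  check_number(diameter, "diameter", min = 0, strict_min = TRUE)
  check_number(thickness, "thickness", min = 0, strict_min = TRUE)
  check_number(core_diameter, "core_diameter", min = 0, strict_min = TRUE)
  check_numeric_vec(shell_thicknesses, "shell_thicknesses")
  if (any(shell_thicknesses < 0)) {
    abort_bad_arg("shell_thicknesses", "be non-negative")
  }
  if (core_diameter + 2 * sum(shell_thicknesses) > diameter * (1 + 1e-12)) {
    rlang::abort(
      "Invalid geometry: core diameter plus shells exceeds the disc diameter.",
      class = c("menmod_invalid_geometry", "menmod_error")
    )
  }
  structure(
    list(diameter = diameter, thickness = thickness,
         core_diameter = core_diameter,
         shell_thicknesses = shell_thicknesses),
    class = "particle_geometry"
  )
}

#' @export
print.particle_geometry <- function(x, ...) {
  cat(sprintf(
    "<particle_geometry> disc %.0f nm x %.0f nm; core %.0f nm + shells %s nm\n",
    x$diameter * 1e9, x$thickness * 1e9, x$core_diameter * 1e9,
    paste(format(x$shell_thicknesses * 1e9), collapse = "/")
  ))
  invisible(x)
}

#' Material properties of a magnetoelectric composite layer
#'
#' @param magnetostriction_ppm Magnetostriction constant in parts per million.
#' @param mass_density Mass density in g cm^-3 (> 0).
#' @param piezo_coefficient Effective linear piezoelectric coefficient
#'   (polarization per unit strain, arbitrary units, >= 0).
#' @return An object of class `material_props`.
#' @export
material_props <- function(magnetostriction_ppm = NA_real_,
                           mass_density, piezo_coefficient = 0) {
  check_number(mass_density, "mass_density", min = 0, strict_min = TRUE)
  check_number(piezo_coefficient, "piezo_coefficient", min = 0)
  structure(
    list(magnetostriction_ppm = magnetostriction_ppm,
         mass_density = mass_density,
         piezo_coefficient = piezo_coefficient),
    class = "material_props"
  )
}

# handbook densities (g cm^-3) of the three layers
.layer_densities <- c(fe3o4 = 5.17, cofe2o4 = 5.30, batio3 = 6.02)

#' Volume-weighted composite mass density of a layered nanodisc
#'
#' The disc is modelled as a core disc plus concentric annular shells, all of
#' the full disc thickness, so volume fractions reduce to annular area
#' fractions. Defaults use handbook densities for magnetite (5.17), cobalt
#' ferrite (5.30) and barium titanate (6.02 g cm^-3).
#'
#' @param geometry A [particle_geometry()].
#' @param layer_densities Densities (g cm^-3) of core then shells, one per
#'   layer; recycled error otherwise.
#' @return Composite density in g cm^-3.
#' @examples
#' composite_density(particle_geometry())
#' @export
composite_density <- function(geometry = particle_geometry(),
                              layer_densities = .layer_densities) {
  stopifnot(inherits(geometry, "particle_geometry"))
  radii <- cumsum(c(geometry$core_diameter / 2, geometry$shell_thicknesses))
  if (length(layer_densities) != length(radii)) {
    abort_bad_arg("layer_densities", "have one density per layer (core + shells)")
  }
  areas <- diff(c(0, radii^2)) # annular area factors (pi cancels)
  sum(areas * layer_densities) / sum(areas)
}

#' Single-particle membrane potential
#'
#' Potential generated on the membrane by one nanodisc: the magnetoelectric
#' coefficient times the alternating-field amplitude times a characteristic
#' length (disc diameter by default). With the measured peak coefficient of
#' 150 mV mT^-1 cm^-1, a 10 mT field and a 250 nm disc this evaluates to
#' 37.5 uV.
#'
#' @param alpha_me Magnetoelectric coefficient in mV mT^-1 cm^-1 (> 0 for a
#'   physical particle; 0 field amplitude is allowed and gives 0).
#' @param h_amf Alternating magnetic field amplitude in mT (>= 0).
#' @param length_scale Characteristic length in metres (> 0); defaults to the
#'   250 nm disc diameter.
#' @return Potential in microvolts. Exactly multilinear in all arguments.
#' @examples
#' single_particle_potential(150, 10, 250e-9) # 37.5 uV
#' @export
single_particle_potential <- function(alpha_me, h_amf, length_scale = 250e-9) {
  check_numeric_vec(alpha_me, "alpha_me")
  check_numeric_vec(h_amf, "h_amf")
  check_numeric_vec(length_scale, "length_scale")
  if (any(alpha_me < 0)) abort_bad_arg("alpha_me", "be non-negative")
  if (any(h_amf < 0)) abort_bad_arg("h_amf", "be non-negative")
  if (any(length_scale <= 0)) {
    rlang::abort("Invalid geometry: `length_scale` must be positive.",
                 class = c("menmod_invalid_geometry", "menmod_error"))
  }
  # mV mT^-1 cm^-1 * mT * (m -> cm) -> mV; * 1000 -> uV
  alpha_me * h_amf * (length_scale * 100) * 1000
}

#' Enhancement ratio between two effective deformations
#'
#' Ratio of two magnetostrictive deformations (ppm). The disc-over-sphere
#' comparison 0.83026 / 0.000808 ppm gives ~1028; disc over same-volume
#' magnetite disc, 0.83026 / 0.01898 ppm, gives ~43.7.
#'
#' @param deformation_a,deformation_b Strains in ppm; `deformation_b` must be
#'   strictly positive.
#' @return `deformation_a / deformation_b` (dimensionless).
#' @examples
#' enhancement_ratio(0.83026, 0.000808)
#' @export
enhancement_ratio <- function(deformation_a, deformation_b) {
  check_numeric_vec(deformation_a, "deformation_a")
  check_numeric_vec(deformation_b, "deformation_b")
  if (any(deformation_b <= 0)) {
    rlang::abort("`deformation_b` must be strictly positive (division).",
                 class = c("menmod_invalid_input", "menmod_error"))
  }
  deformation_a / deformation_b
}

#' Polarization generated by a magnetostrictive strain
#'
#' Linear piezoelectric scaling: polarization = strain x coefficient.
#'
#' @param strain_ppm Strain in ppm.
#' @param piezo_coefficient Linear coefficient (polarization per ppm strain,
#'   arbitrary units, >= 0).
#' @return Polarization in the coefficient's units.
#' @export
polarization_from_strain <- function(strain_ppm, piezo_coefficient) {
  check_numeric_vec(strain_ppm, "strain_ppm")
  check_numeric_vec(piezo_coefficient, "piezo_coefficient")
  if (any(piezo_coefficient < 0)) {
    abort_bad_arg("piezo_coefficient", "be non-negative")
  }
  strain_ppm * piezo_coefficient
}

#' Magnetoelectric coefficient model
#'
#' Separable empirical model of the coupling coefficient
#' `alpha(f, H) = alpha_ref * (f / f_ref)^freq_exponent * G(H) / G(h_omf_ref)`
#' where `G` is a Gaussian bump centred on the offset field at which the
#' measured coefficient peaks (220 mT by default, near magnetic saturation).
#' The model returns exactly `alpha_ref` at the reference point.
#'
#' @param alpha_ref Coefficient at the reference point, mV mT^-1 cm^-1 (> 0).
#' @param f_ref Reference frequency in Hz (> 0).
#' @param h_omf_ref Reference offset field in mT; defaults to `omf_peak`.
#' @param freq_exponent Power-law exponent of the frequency dependence
#'   (>= 0 so the coefficient is non-decreasing in frequency).
#' @param omf_peak Offset field of the peak response, mT.
#' @param omf_width Gaussian width of the offset-field response, mT (> 0).
#' @return An object of class `me_model`.
#' @examples
#' m <- me_model()
#' alpha_eval(m, f = 150, h_omf = 220) # 150
#' @export
me_model <- function(alpha_ref = 150, f_ref = 150, h_omf_ref = omf_peak,
                     freq_exponent = 1, omf_peak = 220, omf_width = 80) {
  check_number(alpha_ref, "alpha_ref", min = 0, strict_min = TRUE)
  check_number(f_ref, "f_ref", min = 0, strict_min = TRUE)
  check_number(freq_exponent, "freq_exponent", min = 0)
  check_number(omf_peak, "omf_peak", min = 0)
  check_number(omf_width, "omf_width", min = 0, strict_min = TRUE)
  check_number(h_omf_ref, "h_omf_ref", min = 0)
  structure(
    list(alpha_ref = alpha_ref, f_ref = f_ref, h_omf_ref = h_omf_ref,
         freq_exponent = freq_exponent, omf_peak = omf_peak,
         omf_width = omf_width),
    class = "me_model"
  )
}

#' @export
print.me_model <- function(x, ...) {
  cat(sprintf(
    paste0("<me_model> alpha_ref = %g mV/mT/cm at (%g Hz, %g mT); ",
           "f-exponent %g; OMF peak %g mT (width %g mT)\n"),
    x$alpha_ref, x$f_ref, x$h_omf_ref, x$freq_exponent, x$omf_peak, x$omf_width
  ))
  invisible(x)
}

#' Evaluate a magnetoelectric coefficient model
#'
#' @param model An [me_model()].
#' @param f Alternating-field frequency in Hz (> 0); vectorised.
#' @param h_omf Offset field in mT (>= 0); vectorised, defaults to the model's
#'   peak field.
#' @return Coefficient(s) in mV mT^-1 cm^-1.
#' @export
alpha_eval <- function(model, f, h_omf = model$omf_peak) {
  stopifnot(inherits(model, "me_model"))
  check_numeric_vec(f, "f")
  check_numeric_vec(h_omf, "h_omf")
  if (any(f <= 0)) {
    rlang::abort("`f` must be strictly positive.",
                 class = c("menmod_invalid_input", "menmod_error"))
  }
  g <- function(h) exp(-((h - model$omf_peak)^2) / (2 * model$omf_width^2))
  model$alpha_ref * (f / model$f_ref)^model$freq_exponent *
    g(h_omf) / g(model$h_omf_ref)
}

#' Fit the frequency exponent of a coefficient model to measured data
#'
#' Least-squares fit of `log(alpha) ~ log(f)` (offset field held at the
#' model's reference) to estimate the power-law exponent of the frequency
#' dependence; returns the model with `freq_exponent` and `alpha_ref` updated
#' so the fitted curve passes through the data at `f_ref`.
#'
#' @param data A data frame with columns `f` (Hz) and `alpha` (mV mT^-1 cm^-1),
#'   all positive.
#' @param model Starting [me_model()] supplying the reference frequency.
#' @return The updated `me_model`, with the `lm` fit attached as attribute
#'   `"fit"`.
#' @export
calibrate_freq_exponent <- function(data, model = me_model()) {
  stopifnot(inherits(model, "me_model"), is.data.frame(data))
  if (!all(c("f", "alpha") %in% names(data))) {
    abort_bad_arg("data", "have columns `f` and `alpha`")
  }
  if (any(data$f <= 0) || any(data$alpha <= 0)) {
    abort_bad_arg("data", "have strictly positive `f` and `alpha`")
  }
  fit <- stats::lm(log(alpha) ~ log(f), data = data)
  exponent <- unname(coef(fit)[2])
  if (exponent < 0) {
    rlang::warn("Fitted frequency exponent is negative; model monotonicity in f no longer holds.")
  }
  alpha_ref <- exp(unname(coef(fit)[1]) + exponent * log(model$f_ref))
  out <- me_model(alpha_ref = alpha_ref, f_ref = model$f_ref,
                  h_omf_ref = model$h_omf_ref,
                  freq_exponent = max(exponent, 0),
                  omf_peak = model$omf_peak, omf_width = model$omf_width)
  attr(out, "fit") <- fit
  attr(out, "freq_exponent_raw") <- exponent
  out
}

#' Mean interparticle spacing at a given surface mass density
#'
#' Converts a particle surface mass density (ug mm^-2, as measured on
#' cultured neurons) into a particle count per unit area and a mean spacing.
#' Particle mass is disc volume `pi (D/2)^2 t` times the volume-weighted
#' composite density; the count density is `n = sigma / m_p`; the mean spacing
#' is the square-lattice value `n^(-1/2)`. The mean nearest-neighbour distance
#' for Poisson (uniform random) placement, `0.5 n^(-1/2)`, is also reported.
#'
#' @param surface_density Mass density in ug mm^-2 (> 0); vectorised.
#' @param geometry A [particle_geometry()].
#' @param density Composite mass density in g cm^-3; defaults to the
#'   volume-weighted [composite_density()] of `geometry`.
#' @return A tibble with one row per density: `surface_density_ug_mm2`,
#'   `particle_mass_g`, `count_per_mm2`, `spacing_lattice_nm`,
#'   `spacing_poisson_nm`.
#' @examples
#' interparticle_spacing(0.75)
#' @export
interparticle_spacing <- function(surface_density,
                                  geometry = particle_geometry(),
                                  density = composite_density(geometry)) {
  check_numeric_vec(surface_density, "surface_density")
  if (any(surface_density <= 0)) {
    abort_bad_arg("surface_density", "be strictly positive")
  }
  check_number(density, "density", min = 0, strict_min = TRUE)
  stopifnot(inherits(geometry, "particle_geometry"))
  volume_m3 <- pi * (geometry$diameter / 2)^2 * geometry$thickness
  mass_g <- volume_m3 * 1e6 * density # m^3 -> cm^3 times g/cm^3
  if (mass_g <= 0) {
    rlang::abort("Invalid geometry/material: particle mass is zero.",
                 class = c("menmod_invalid_geometry", "menmod_error"))
  }
  n_per_mm2 <- surface_density * 1e-6 / mass_g # ug -> g
  spacing_mm <- n_per_mm2^(-1 / 2)
  tibble(
    surface_density_ug_mm2 = surface_density,
    particle_mass_g = mass_g,
    count_per_mm2 = n_per_mm2,
    spacing_lattice_nm = spacing_mm * 1e6,
    spacing_poisson_nm = 0.5 * spacing_mm * 1e6
  )
}

#' Field stimulation protocol
#'
#' Schedule of combined offset + alternating magnetic field stimulation.
#'
#' @param h_omf Offset field in mT (>= 0).
#' @param h_amf Alternating field amplitude in mT (>= 0).
#' @param f_amf Alternating field frequency in Hz; must be > 0 when
#'   `h_amf > 0`.
#' @param epoch_duration Stimulation epoch length in seconds (> 0).
#' @param inter_epoch_interval Rest interval between epochs in seconds (>= 0).
#' @param n_epochs Number of epochs (>= 1).
#' @return An object of class `field_protocol` with an `onsets(first_onset)`
#'   helper accessible through [protocol_onsets()].
#' @export
field_protocol <- function(h_omf = 220, h_amf = 10, f_amf = 150,
                           epoch_duration = 2, inter_epoch_interval = 30,
                           n_epochs = 5) {
  check_number(h_omf, "h_omf", min = 0)
  check_number(h_amf, "h_amf", min = 0)
  check_number(f_amf, "f_amf", min = 0)
  if (h_amf > 0 && f_amf <= 0) {
    abort_bad_arg("f_amf", "be positive when `h_amf` > 0")
  }
  check_number(epoch_duration, "epoch_duration", min = 0, strict_min = TRUE)
  check_number(inter_epoch_interval, "inter_epoch_interval", min = 0)
  check_number(n_epochs, "n_epochs", min = 1)
  structure(
    list(h_omf = h_omf, h_amf = h_amf, f_amf = f_amf,
         epoch_duration = epoch_duration,
         inter_epoch_interval = inter_epoch_interval,
         n_epochs = as.integer(n_epochs)),
    class = "field_protocol"
  )
}

#' Epoch onset times of a field protocol
#'
#' @param protocol A [field_protocol()].
#' @param first_onset Time of the first epoch onset in seconds.
#' @return Numeric vector of onset times (s).
#' @export
protocol_onsets <- function(protocol, first_onset = 30) {
  stopifnot(inherits(protocol, "field_protocol"))
  check_number(first_onset, "first_onset", min = 0)
  first_onset + (seq_len(protocol$n_epochs) - 1) *
    (protocol$epoch_duration + protocol$inter_epoch_interval)
}

#' Transduction report for a field protocol and particle description
#'
#' Convenience one-stop summary: single-particle potential under the protocol,
#' coefficient at the protocol's frequency/offset field, and interparticle
#' spacing at the given surface density.
#'
#' @param protocol A [field_protocol()].
#' @param model An [me_model()].
#' @param geometry A [particle_geometry()].
#' @param surface_density Surface mass density in ug mm^-2.
#' @return A one-row tibble.
#' @export
transduction_report <- function(protocol = field_protocol(),
                                model = me_model(),
                                geometry = particle_geometry(),
                                surface_density = 0.75) {
  alpha <- alpha_eval(model, f = protocol$f_amf, h_omf = protocol$h_omf)
  v0 <- single_particle_potential(alpha, protocol$h_amf, geometry$diameter)
  sp <- interparticle_spacing(surface_density, geometry)
  tibble(
    alpha_me_mv_mt_cm = alpha,
    v0_uv = v0,
    surface_density_ug_mm2 = surface_density,
    count_per_mm2 = sp$count_per_mm2,
    spacing_lattice_nm = sp$spacing_lattice_nm,
    spacing_poisson_nm = sp$spacing_poisson_nm
  )
}
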