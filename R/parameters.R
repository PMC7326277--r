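#' Default simulation parameters
#'
#' Single source of truth for every model constant. Units are fixed
#' throughout the package: lengths in nm, times in s, forces in pN,
#' energies in pN nm, concentrations in uM. All copy numbers are integers.
#'
#' The kinetic rates follow the compartment convention of compartment-based
#' reaction-diffusion models: a bimolecular rate printed as \code{r} per
#' second means a propensity of \code{r} per reactant molecule present in a
#' \code{compartment_size}-sided cubic compartment. For the plus-end
#' polymerization rate 0.151/s per molecule in a (0.5 um)^3 compartment this
#' is equivalent to the familiar bulk constant of about 11.4 per uM per s.
#' In \code{well_mixed} mode the whole box is one effective compartment and
#' the per-molecule propensity is scaled by
#' \code{compartment_size^3 / box volume}.
#'
#' @param ... named overrides of any default field.
#' @return A named list of class \code{acto_params}.
#' @examples
#' p <- default_parameters(actin_conc = 10)
#' p$actin_conc
#' @export
default_parameters <- function(...) {
  p <- list(
    # concentrations (uM); motor_conc is NMII head-equivalent
    actin_conc = 20, motor_conc = 2, linker_conc = 2,
    # diffusion (compartment-hop rate per molecule per s)
    diff_actin = 80, diff_linker = 8, diff_motor = 0.8,
    # treadmilling rates (per s, compartment convention for polymerization)
    poly_plus = 0.151, poly_minus = 0.017,
    depoly_plus = 1.4, depoly_minus = 0.8,
    # binding / unbinding (per s)
    motor_bind = 0.2, motor_unbind0 = 0.2,
    linker_bind = 0.009, linker_unbind0 = 0.3,
    # filament discretization
    cylinder_length = 108, monomer_rise = 2.7,
    monomers_per_cylinder = 40L, binding_sites_per_cylinder = 4L,
    min_monomers = 3L,
    # mechanics
    bending_energy = 672.5, stretch_k = 100,
    excluded_volume_k = 1e5, motor_head_k = 2.5, linker_k = 8,
    boundary_eps = 41, boundary_lambda = 2.7,
    anchor_k = 100,
    # mechanochemistry (characteristic forces, pN, per head where noted)
    motor_unbind_force = 12.6, motor_stall_force = 15,
    linker_char_force = 17.2, poly_char_force = 1.5,
    # bond rest-length ranges (nm)
    motor_rest_min = 175, motor_rest_max = 225,
    linker_rest_min = 30, linker_rest_max = 40,
    # geometry
    box_x = 3000, box_y = 3000, box_z = 1250,
    compartment_size = 500, well_mixed = TRUE,
    probe_radius = 250,
    # network construction
    n_free = 300L, n_attached = 30L, seed_monomers = 40L,
    # motors
    heads_per_minifilament = 20L, heads_per_side = 10L,
    motor_walk_rate0 = 0.2,
    # protocol / numerics
    chem_mech_interval = 0.5, motor_release_time = 5,
    snapshot_interval = 1,
    force_tol = 1, minimize_maxit = 1e5
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  class(p) <- "acto_params"
  validate_parameters(p)
  p
}

#' Desk-scale preset
#'
#' A reduced network (1.5 x 1.5 x 1 um box, 60 free + 8 probe-attached
#' filaments, two pulling events) with the same physical constants, intended
#' for replicated property checks on one CPU. The mechanochemical cycle is
#' coarsened to 1 s and the minimizer tolerance relaxed to 2 pN -- numerical
#' settings, not physics; see the methods vignette.
#'
#' @param ... overrides forwarded to [default_parameters()].
#' @return An \code{acto_params} list.
#' @export
desk_small_parameters <- function(...) {
  default_parameters(box_x = 1500, box_y = 1500, box_z = 1000,
                     n_free = 60L, n_attached = 8L,
                     chem_mech_interval = 1, force_tol = 2, ...)
}

#' Validate a parameter set
#'
#' Checks positivity of rates and stiffnesses, the monomer-rise identity
#' (\code{monomer_rise * monomers_per_cylinder == cylinder_length}), ordered
#' rest-length ranges, and that the probe fits the box.
#'
#' @param p an \code{acto_params} list.
#' @return \code{p}, invisibly, or an error.
#' @export
validate_parameters <- function(p) {
  rates <- c("diff_actin", "diff_linker", "diff_motor", "poly_plus",
             "poly_minus", "depoly_plus", "depoly_minus", "motor_bind",
             "motor_unbind0", "linker_bind", "linker_unbind0",
             "motor_walk_rate0")
  for (r in rates) if (p[[r]] < 0) stop("rate ", r, " must be >= 0")
  stiff <- c("stretch_k", "motor_head_k", "linker_k", "anchor_k")
  for (s in stiff) if (p[[s]] <= 0) stop("stiffness ", s, " must be > 0")
  if (abs(p$monomer_rise * p$monomers_per_cylinder - p$cylinder_length) > 1e-9)
    stop("monomer_rise * monomers_per_cylinder must equal cylinder_length")
  if (p$motor_rest_min > p$motor_rest_max ||
      p$linker_rest_min > p$linker_rest_max)
    stop("rest-length ranges must be ordered (min <= max)")
  if (p$probe_radius > p$box_x / 2)
    stop("probe_radius must be <= half the box x-dimension")
  for (d in c("box_x", "box_y", "box_z", "compartment_size"))
    if (p[[d]] <= 0) stop(d, " must be > 0")
  invisible(p)
}

#' Concentration to copy number
#'
#' Converts a molar concentration and a volume to an integer molecule count,
#' \code{round(conc * N_A * V)}.
#'
#' @param conc_uM concentration in uM (>= 0).
#' @param volume_um3 volume in um^3 (> 0).
#' @return Integer-valued count.
#' @examples
#' copy_number(20, 11.25)   # G+F actin copies in the default box
#' @export
copy_number <- function(conc_uM, volume_um3) {
  if (any(conc_uM < 0)) stop("concentration must be >= 0")
  if (any(volume_um3 <= 0)) stop("volume must be > 0")
  # conc[uM] * 1e-6 mol/L * 6.02214076e23 /mol * V[um^3] * 1e-15 L
  round(conc_uM * volume_um3 * 602.214076)
}

box_volume_um3 <- function(state) {
  prod(state$box) * 1e-9   # nm^3 -> um^3
}

#' Write a parameter set to a YAML config file
#'
#' Flat key/value schema mirroring the field names of
#' [default_parameters()]; units as documented there.
#'
#' @param p an \code{acto_params} list.
#' @param path output file.
#' @export
save_config <- function(p, path) {
  stopifnot(inherits(p, "acto_params"))
  q <- unclass(p)
  yaml::write_yaml(q, path)
  invisible(path)
}

#' Read a parameter set from a YAML config file
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path config file written by [save_config()] or by hand.
#' @return An \code{acto_params} list.
#' @export
load_config <- function(path) {
  q <- yaml::read_yaml(path)
  do.call(default_parameters, q)
}
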