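## Electrokinetics: radial charge density of the mobile species, Gauss-law
## electric field, electrostatic potential, and the zeta potential at the
## shear plane (placed where the water RDF reaches its bulk value of 1).
## Vacuum permittivity is used throughout: the solvent is explicit, so its
## polarization is carried by the particle charges themselves.

#' Radial charge density profile
#'
#' The per-type radial number densities multiplied by the type partial
#' charge and summed; computed directly as the time-averaged charge per
#' spherical shell divided by the shell volume.
#'
#' @inheritParams radial_number_density
#' @param sel atom selection to include (typically polymer + water + ions)
#' @return \code{radial_profile} of kind \code{"charge_density"} (e/A^3)
#' @export
charge_density_profile <- function(traj, sel, topo,
                                   center = center_convention(),
                                   window = NULL, bin_width = 0.1,
                                   r_max = NULL) {
  traj <- window_frames(traj, window)
  if (is.null(r_max))
    r_max <- min(vapply(traj$frames, function(f) min(f$box),
                        numeric(1))) / 2
  edges <- seq(0, r_max, by = bin_width)
  q <- topo$atoms$charge
  if (length(sel) && any(is.na(q[sel])))
    stop("missing partial charges for atoms: ",
         paste(sel[is.na(q[sel])], collapse = ", "))
  acc <- numeric(length(edges) - 1)
  for (fr in traj$frames) {
    if (!length(sel)) next
    ctr <- resolve_center(fr, topo, center)
    r <- min_image_radii(fr$positions[sel, , drop = FALSE], ctr, fr$box)
    keep <- r < edges[length(edges)]
    if (any(keep)) {
      bin <- findInterval(r[keep], edges)
      acc <- acc + as.numeric(
        tapply(q[sel][keep], factor(bin, levels = seq_along(acc)), sum,
               default = 0))
    }
  }
  sigma <- acc / n_frames(traj) / shell_volumes(edges)
  new_radial_profile(bin_width, edges, sigma, "charge_density",
                     n_frames(traj))
}

#' Gauss-law electric field from a radial charge density
#'
#' Spherically symmetric Gauss law: the field at radius r is set by the
#' charge enclosed between the particle surface r0 and r,
#' \deqn{E(r) = \frac{1}{4\pi\epsilon_0 r^2} \int_{r_0}^{r}
#'   \sigma(r') 4\pi r'^2 dr' + \frac{Q_{core}}{4\pi\epsilon_0 r^2},}
#' evaluated by trapezoidal quadrature on the bin grid and converted to
#' V/A with the CODATA value of \eqn{e/4\pi\epsilon_0}.
#'
#' @param sigma \code{radial_profile} of kind \code{"charge_density"}
#' @param r0 particle surface radius in Angstrom (integration start)
#' @param core_charge optional enclosed core charge in e
#' @return \code{radial_profile} of kind \code{"efield"} (V/A) on the same
#'   grid, zero below r0
#' @export
electric_field_profile <- function(sigma, r0, core_charge = 0) {
  if (sigma$kind != "charge_density")
    stop("electric_field_profile needs a charge_density profile")
  r <- sigma$r_mid
  if (r0 < r[1] - sigma$bin_width || r0 > r[length(r)])
    stop("r0 = ", r0, " A lies outside the profile grid")
  f <- sigma$values * r^2
  inside <- r < r0
  f[inside] <- 0
  ## cumulative trapezoid of sigma * r'^2 from r0
  dr <- diff(r)
  cumint <- c(0, cumsum(dr * (f[-1] + f[-length(f)]) / 2))
  i0 <- which(r >= r0)[1]
  enclosed <- cumint - cumint[i0]
  enclosed[inside] <- 0
  E <- .const$k_coulomb_volt * (4 * pi * enclosed + core_charge) / r^2
  E[inside] <- 0
  new_radial_profile(sigma$bin_width, sigma$edges, E, "efield",
                     sigma$n_frames)
}

#' Electrostatic potential by inward integration of the field
#'
#' \eqn{\phi(r) = \int_r^{r_{bulk}} E(r') dr'} with the additive constant
#' fixed so the potential vanishes at the bulk reference radius; reported
#' in mV.
#'
#' @param efield \code{radial_profile} of kind \code{"efield"} (V/A)
#' @param bulk_radius reference radius in Angstrom where phi = 0
#' @return \code{radial_profile} of kind \code{"potential"} (mV)
#' @export
electrostatic_potential_profile <- function(efield, bulk_radius) {
  if (efield$kind != "efield")
    stop("electrostatic_potential_profile needs an efield profile")
  r <- efield$r_mid
  if (bulk_radius > r[length(r)] + efield$bin_width / 2)
    stop("bulk_radius = ", bulk_radius, " A is beyond the profile grid")
  E <- efield$values
  dr <- diff(r)
  cumint <- c(0, cumsum(dr * (E[-1] + E[-length(E)]) / 2))  # int_{r1}^{r}
  int_at <- stats::approx(r, cumint, xout = bulk_radius, rule = 2)$y
  phi <- (int_at - cumint) * 1000  # V -> mV
  new_radial_profile(efield$bin_width, efield$edges, phi, "potential",
                     efield$n_frames)
}

#' Zeta potential at the shear plane
#'
#' The electrostatic potential linearly interpolated at the shear radius,
#' conventionally taken where the bulk water phase begins (the water RDF
#' reaches 1, \code{\link{bulk_onset_radius}}).
#'
#' @param potential \code{radial_profile} of kind \code{"potential"} (mV)
#' @param shear_radius shear-plane radius in Angstrom
#' @return zeta potential in mV
#' @export
zeta_potential <- function(potential, shear_radius) {
  if (potential$kind != "potential")
    stop("zeta_potential needs a potential profile")
  r <- potential$r_mid
  if (shear_radius < r[1] || shear_radius > r[length(r)])
    stop("shear radius ", shear_radius, " A is outside the potential grid")
  stats::approx(r, potential$values, xout = shear_radius)$y
}

#' Full electrokinetic chain for a trajectory
#'
#' Convenience wrapper running charge density, Gauss-law field, potential
#' and zeta in one call. The shear plane defaults to the bulk onset of the
#' water RDF; the bulk reference radius for the potential defaults to the
#' outer edge of the grid.
#'
#' @inheritParams charge_density_profile
#' @param r0 particle surface radius (A)
#' @param water_sel selection used for the water RDF (oxygen positions)
#'   when \code{shear_radius} is not given
#' @param shear_radius optional explicit shear-plane radius (A)
#' @param bulk_radius optional potential reference radius (A)
#' @param core_charge enclosed core charge (e)
#' @param shear_tol,shear_run sustained-crossing tolerance and run length
#'   passed to \code{\link{bulk_onset_radius}}; loosen the tolerance when
#'   the water RDF estimate is noisy (few frames or wide shells)
#' @param rdf_bin_width bin width for the water RDF used to locate the
#'   shear plane (defaults to \code{bin_width})
#' @return object of class \code{"electrokinetics"}: profiles
#'   \code{sigma}, \code{efield}, \code{potential}, plus \code{r0},
#'   \code{shear_radius} and \code{zeta} (mV)
#' @export
electrokinetic_profiles <- function(traj, sel, topo, r0,
                                    center = center_convention(),
                                    window = NULL, bin_width = 0.1,
                                    r_max = NULL, water_sel = NULL,
                                    shear_radius = NULL,
                                    bulk_radius = NULL, core_charge = 0,
                                    shear_tol = 0.05, shear_run = 2,
                                    rdf_bin_width = bin_width) {
  sigma <- charge_density_profile(traj, sel, topo, center, window,
                                  bin_width, r_max)
  E <- electric_field_profile(sigma, r0, core_charge)
  if (is.null(bulk_radius)) bulk_radius <- max(E$r_mid)
  phi <- electrostatic_potential_profile(E, bulk_radius)
  if (is.null(shear_radius)) {
    if (is.null(water_sel))
      stop("either shear_radius or water_sel must be given")
    wrdf <- radial_rdf(traj, water_sel, topo, center, window,
                       rdf_bin_width, r_max)
    shear_radius <- bulk_onset_radius(wrdf, tol = shear_tol,
                                      run_length = shear_run)
  }
  structure(list(sigma = sigma, efield = E, potential = phi, r0 = r0,
                 shear_radius = shear_radius,
                 zeta = zeta_potential(phi, shear_radius)),
            class = "electrokinetics")
}

#' @export
print.electrokinetics <- function(x, ...) {
  cat(sprintf(
    "Electrokinetics: r0 = %.1f A, shear plane at %.2f A, zeta = %.2f mV\n",
    x$r0, x$shear_radius, x$zeta))
  invisible(x)
}
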