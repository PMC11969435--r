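## Spherically averaged radial profiles about the nanoparticle center:
## number density, RDF, cumulative fraction, and bulk-onset detection.
## Default bin width 0.1 A.

new_radial_profile <- function(bin_width, edges, values, kind, n_frames) {
  structure(list(bin_width = bin_width, edges = edges,
                 r_mid = (edges[-1] + edges[-length(edges)]) / 2,
                 values = values, kind = kind, n_frames = n_frames),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat("Radial profile (", x$kind, "): ", length(x$values), " bins of ",
      x$bin_width, " A, r in [0, ", max(x$edges), "] A, averaged over ",
      x$n_frames, " frame(s)\n", sep = "")
  invisible(x)
}

shell_volumes <- function(edges) {
  4 * pi / 3 * diff(edges^3)
}

## time-averaged per-bin counts of minimum-image radii about the center
radial_counts <- function(traj, sel, topo, center, edges) {
  counts <- numeric(length(edges) - 1)
  for (fr in traj$frames) {
    if (!length(sel)) next
    ctr <- resolve_center(fr, topo, center)
    r <- min_image_radii(fr$positions[sel, , drop = FALSE], ctr, fr$box)
    r <- r[r < edges[length(edges)]]
    if (length(r))
      counts <- counts + tabulate(findInterval(r, edges), length(counts))
  }
  counts / n_frames(traj)
}

#' Radial number density profile about the particle center
#'
#' Per-bin value is the time-averaged atom count in the spherical shell
#' divided by the shell volume \eqn{4\pi/3 (r_2^3 - r_1^3)}. Positions are
#' wrapped by minimum image about the center before binning. Radii beyond
#' half the shortest box edge are excluded (shells there are not fully
#' inside the box).
#'
#' @param traj trajectory
#' @param sel atom-index selection (may be empty: all-zero profile)
#' @param topo topology (to resolve the center)
#' @param center \code{\link{center_convention}} or an xyz triple
#' @param window time window passed to \code{\link{window_frames}}
#' @param bin_width bin width in Angstrom (default 0.1)
#' @param r_max outer radius; default half the shortest box edge
#' @return \code{radial_profile} of kind \code{"number_density"} (1/A^3)
#' @export
radial_number_density <- function(traj, sel, topo,
                                  center = center_convention(),
                                  window = NULL, bin_width = 0.1,
                                  r_max = NULL) {
  traj <- window_frames(traj, window)
  half_min <- min(vapply(traj$frames, function(f) min(f$box), numeric(1))) / 2
  if (is.null(r_max)) r_max <- half_min
  if (r_max > half_min + 1e-9)
    warning("r_max ", r_max, " A exceeds half the shortest box edge (",
            round(half_min, 3), " A); outer shells sample the box corners")
  edges <- seq(0, r_max, by = bin_width)
  counts <- radial_counts(traj, sel, topo, center, edges)
  new_radial_profile(bin_width, edges, counts / shell_volumes(edges),
                     "number_density", n_frames(traj))
}

#' Radial distribution function about the particle center
#'
#' The number-density profile divided by the selection's mean density over
#' the box volume, so that the RDF tends to 1 in the bulk.
#'
#' @inheritParams radial_number_density
#' @return \code{radial_profile} of kind \code{"rdf"} (dimensionless)
#' @export
radial_rdf <- function(traj, sel, topo, center = center_convention(),
                       window = NULL, bin_width = 0.1, r_max = NULL) {
  if (!length(sel)) stop("RDF needs a nonempty selection")
  traj <- window_frames(traj, window)
  vols <- vapply(traj$frames, function(f) prod(f$box), numeric(1))
  if (any(vols <= 0)) stop("zero box volume")
  dens <- radial_number_density(traj, sel, topo, center, NULL,
                                bin_width, r_max)
  rho_bulk <- mean(length(sel) / vols)
  new_radial_profile(dens$bin_width, dens$edges, dens$values / rho_bulk,
                     "rdf", dens$n_frames)
}

#' Normalized cumulative radial fraction
#'
#' Cumulative shell-weighted count divided by the total, evaluated at bin
#' right edges; ends at 1 for any profile with nonzero total. Input must be
#' a number-density or RDF profile.
#'
#' @param p radial profile (kind \code{number_density} or \code{rdf})
#' @return \code{radial_profile} of kind \code{"cumulative_fraction"}
#' @export
cumulative_fraction <- function(p) {
  if (!p$kind %in% c("number_density", "rdf"))
    stop("cumulative_fraction needs a number_density or rdf profile")
  w <- p$values * shell_volumes(p$edges)
  tot <- sum(w)
  if (tot <= 0) stop("all-zero profile: cumulative fraction undefined")
  cf <- cumsum(w) / tot
  out <- new_radial_profile(p$bin_width, p$edges, cf,
                            "cumulative_fraction", p$n_frames)
  out
}

#' Radius where the bulk phase begins
#'
#' Smallest radius where the linearly interpolated RDF first reaches 1 and
#' stays at or above \code{1 - tol} over the following \code{run_length}
#' Angstrom (a sustained crossing, robust to the sub-bulk oscillations an
#' RDF shows inside the polymer coating). Used to place the shear plane for
#' the zeta potential: the bulk water onset is where the water RDF reaches 1.
#'
#' @param water_rdf radial profile of kind \code{"rdf"}
#' @param tol sustained-crossing tolerance (default 0.05)
#' @param run_length length of the sustained window in Angstrom (default 2)
#' @return radius in Angstrom
#' @export
bulk_onset_radius <- function(water_rdf, tol = 0.05, run_length = 2) {
  if (water_rdf$kind != "rdf") stop("bulk_onset_radius needs an rdf profile")
  r <- water_rdf$r_mid; v <- water_rdf$values
  n_run <- max(1L, ceiling(run_length / water_rdf$bin_width))
  sustained <- function(i) {
    j <- seq(i, min(length(v), i + n_run))
    all(v[j] >= 1 - tol)
  }
  if (v[1] >= 1 && sustained(1)) return(r[1])
  for (i in seq_len(length(v) - 1)) {
    if (v[i] < 1 && v[i + 1] >= 1 && sustained(i + 1)) {
      return(r[i] + (1 - v[i]) * (r[i + 1] - r[i]) / (v[i + 1] - v[i]))
    }
  }
  stop("no bulk phase in box: RDF never sustains a value of 1")
}
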