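## Dynamics: mean-square displacement with multiple time origins, the
## Einstein-relation diffusion coefficient, and the two-particle
## aggregation analysis.

#' Mean-square displacement with multiple time origins
#'
#' MSD(tau) averaged over all time origins, either of the selection's
#' center of mass (default; the whole nanoconjugate's self-diffusion) or
#' averaged over the individual selected atoms (independent walkers).
#' Coordinates must be unwrapped: a per-step displacement larger than half
#' the box is rejected as a periodic jump.
#'
#' @param traj trajectory (uniform time step)
#' @param sel atom-index selection
#' @param topo topology, for masses in COM mode; equal masses assumed if
#'   \code{NULL}
#' @param max_lag maximum lag in frames (default: half the trajectory)
#' @param mode \code{"com"} (center of mass) or \code{"atom"}
#' @return object of class \code{"msd_curve"}: \code{lag_ps},
#'   \code{msd} (A^2), plus the dimensionality \code{n = 3}
#' @export
mean_square_displacement <- function(traj, sel, topo = NULL,
                                     max_lag = NULL,
                                     mode = c("com", "atom")) {
  mode <- match.arg(mode)
  nf <- n_frames(traj)
  if (nf < 2) stop("MSD needs >= 2 frames")
  if (is.null(max_lag)) max_lag <- nf %/% 2
  max_lag <- min(max_lag, nf - 1)
  arr <- positions_array(traj, sel)

  half <- min(vapply(traj$frames, function(f) min(f$box), numeric(1))) / 2
  step <- arr[-1, , , drop = FALSE] - arr[-nf, , , drop = FALSE]
  if (max(abs(step)) > half)
    stop("per-step displacement exceeds half the box: trajectory appears ",
         "wrapped; unwrap before computing the MSD")

  if (mode == "com") {
    m <- if (is.null(topo)) rep(1, length(sel)) else topo$atoms$mass[sel]
    w <- m / sum(m)
    X <- apply(arr, c(1, 3), function(p) sum(p * w))  # nf x 3
    msd <- vapply(seq_len(max_lag), function(lag) {
      d <- X[(1 + lag):nf, , drop = FALSE] - X[1:(nf - lag), , drop = FALSE]
      mean(rowSums(d * d))
    }, numeric(1))
  } else {
    n_sel <- dim(arr)[2]
    msd <- vapply(seq_len(max_lag), function(lag) {
      d <- arr[(1 + lag):nf, , , drop = FALSE] -
           arr[1:(nf - lag), , , drop = FALSE]
      sum(d * d) / ((nf - lag) * n_sel)
    }, numeric(1))
  }
  dt <- traj$times[2] - traj$times[1]
  structure(list(lag_ps = c(0, seq_len(max_lag) * dt), msd = c(0, msd),
                 n = 3L, mode = mode),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("MSD curve (%s mode): %d lags up to %.4g ps, MSD max %.4g A^2\n",
              x$mode, length(x$lag_ps) - 1, max(x$lag_ps), max(x$msd)))
  invisible(x)
}

#' Diffusion coefficient from the linear MSD regime
#'
#' Einstein relation MSD = 2 n D t with dimensionality n = 3: the
#' least-squares slope of the MSD over the fit window divided by 2n, unit
#' converted from A^2/ps to m^2/s. Warns when the linear fit has
#' R^2 < 0.9 (the window is then outside the diffusive regime).
#'
#' @param msd \code{msd_curve}
#' @param fit_window \code{c(t0, t1)} in ps, or \code{"last:P\%"} for the
#'   final P percent of the curve (default \code{"last:10\%"}, mirroring a
#'   fit over the last tenth of a production run)
#' @return object of class \code{"diffusion_fit"} with \code{D} (m^2/s),
#'   \code{slope} (A^2/ps), \code{r_squared} and the window;
#'   \code{coef()} returns D
#' @export
diffusion_coefficient <- function(msd, fit_window = "last:10%") {
  t <- msd$lag_ps; y <- msd$msd
  if (is.character(fit_window)) {
    m <- regmatches(fit_window,
                    regexec("^last:([0-9.]+)%$", fit_window))[[1]]
    if (length(m) != 2) stop("unrecognized fit window: ", fit_window)
    t0 <- max(t) * (1 - as.numeric(m[2]) / 100)
    keep <- t >= t0 - 1e-12
  } else {
    keep <- t >= fit_window[1] & t <= fit_window[2]
  }
  if (sum(keep) < 2) stop("empty fit window")
  if (sum(keep) < 10)
    warning("fewer than 10 MSD points in the fit window")
  fit <- stats::lm(y[keep] ~ t[keep])
  slope <- unname(stats::coef(fit)[2])
  tss <- sum((y[keep] - mean(y[keep]))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  if (r2 < 0.9)
    warning(sprintf("MSD fit R^2 = %.3f < 0.9: window may not be diffusive",
                    r2))
  D <- slope / (2 * msd$n) * .const$A2_per_ps_to_m2_per_s
  structure(list(D = D, slope = slope, r_squared = r2,
                 n = msd$n, n_points = sum(keep)),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("D = %.4g m^2/s (slope %.4g A^2/ps over %d points, R^2 %.3f)\n",
              x$D, x$slope, x$n_points, x$r_squared))
  invisible(x)
}

#' @export
coef.diffusion_fit <- function(object, ...) c(D = object$D)

#' Two-particle aggregation analysis
#'
#' Tracks the per-frame minimum-image minimum atom-atom separation between
#' two particle cores and, optionally, their intersystem nonbonded energy.
#' The verdict is \code{"non-aggregated"} when the separation exceeds the
#' contact threshold in more than \code{persistence} of the window frames,
#' \code{"aggregated"} when it stays at or below the threshold that often,
#' and \code{"transient-contact"} otherwise. Symmetric in the two cores.
#'
#' @param traj trajectory
#' @param coreA_sel,coreB_sel disjoint core selections
#' @param topo topology (needed when \code{scheme} is given)
#' @param scheme optional \code{\link{nonbonded_scheme}} for the
#'   intersystem energy (evaluated between the full A and B selections)
#' @param contact_threshold contact distance in Angstrom (default 10)
#' @param persistence fraction of frames required for a verdict
#'   (default 0.9)
#' @param window time window
#' @return object of class \code{"aggregation_report"}
#' @export
aggregation_analysis <- function(traj, coreA_sel, coreB_sel, topo = NULL,
                                 scheme = NULL, contact_threshold = 10,
                                 persistence = 0.9, window = NULL) {
  if (length(intersect(coreA_sel, coreB_sel)))
    stop("core selections overlap")
  traj <- window_frames(traj, window)
  dmin <- vapply(traj$frames, function(fr) {
    min(min_image_cross_dist(fr$positions[coreA_sel, , drop = FALSE],
                             fr$positions[coreB_sel, , drop = FALSE],
                             fr$box))
  }, numeric(1))
  frac_sep <- mean(dmin > contact_threshold)
  verdict <- if (frac_sep > persistence) "non-aggregated"
             else if (frac_sep < 1 - persistence) "aggregated"
             else "transient-contact"
  energy <- NULL
  if (!is.null(scheme)) {
    es <- energy_series(traj, topo,
                        list(AB = list(coreA_sel, coreB_sel)), scheme)
    energy <- list(mean = es$AB$mean, sd = es$AB$sd)
  }
  structure(list(min_distance = dmin, times = traj$times,
                 fraction_separated = frac_sep, verdict = verdict,
                 contact_threshold = contact_threshold,
                 persistence = persistence, intersystem_energy = energy),
            class = "aggregation_report")
}

#' @export
print.aggregation_report <- function(x, ...) {
  cat(sprintf(
    "Aggregation: %s (separation > %.1f A in %.0f%% of %d frames)\n",
    x$verdict, x$contact_threshold, 100 * x$fraction_separated,
    length(x$min_distance)))
  if (!is.null(x$intersystem_energy))
    cat(sprintf("  intersystem energy %.2f (+/- %.2f) kcal/mol\n",
                x$intersystem_energy$mean, x$intersystem_energy$sd))
  invisible(x)
}
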