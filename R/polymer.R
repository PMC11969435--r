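## Chain-level structural metrics of the grafted polymer layer: radius of
## gyration, end-to-end distance, chain-terminus-to-core distance, layer
## thickness from the cumulative radial fraction, volume-fraction profiles
## and the Daoud-Cotton brush-scaling fit.

#' Radius of gyration of a chain
#'
#' Square root of the mean squared deviation of the N heavy atoms from the
#' chain reference center. The default is the unweighted sum about the
#' heavy-atom centroid, for which the pairwise identity
#' \eqn{Rg^2 = \frac{1}{2N^2}\sum_i\sum_j |r_i - r_j|^2} holds exactly;
#' a mass-weighted mode about the center of mass is also provided.
#'
#' @param pos N x 3 matrix of heavy-atom positions (unwrapped)
#' @param mass atom masses, used when \code{weighting = "mass"}
#' @param weighting \code{"unweighted"} (default) or \code{"mass"}
#' @param box optional box edges; if given, consecutive rows further apart
#'   than half the shortest edge trigger a wrapped-chain error
#' @return Rg in Angstrom
#' @export
radius_of_gyration <- function(pos, mass = NULL,
                               weighting = c("unweighted", "mass"),
                               box = NULL) {
  weighting <- match.arg(weighting)
  pos <- as.matrix(pos)
  if (!nrow(pos)) stop("radius_of_gyration needs >= 1 heavy atom")
  check_chain_unwrapped(pos, box)
  if (weighting == "mass") {
    if (is.null(mass)) stop("mass weighting requested but no masses given")
    w <- mass / sum(mass)
  } else w <- rep(1 / nrow(pos), nrow(pos))
  ctr <- colSums(pos * w)
  d <- sweep(pos, 2, ctr)
  sqrt(sum(w * rowSums(d * d)))
}

check_chain_unwrapped <- function(pos, box) {
  if (is.null(box) || nrow(pos) < 2) return(invisible(TRUE))
  step <- sqrt(rowSums(diff(pos)^2))
  if (any(step > min(box) / 2))
    stop("chain appears wrapped across the periodic box ",
         "(bonded pair separated by > half box); unwrap first")
  invisible(TRUE)
}

#' End-to-end distance of a chain
#'
#' Euclidean distance between the first and last heavy atoms of the chain
#' (anchor-side first heavy atom to the solution-side terminal heavy atom),
#' on unwrapped coordinates.
#'
#' @param pos chain heavy-atom positions in chain order (anchor first)
#' @param box optional box for wrapped-chain detection
#' @return distance in Angstrom
#' @export
end_to_end <- function(pos, box = NULL) {
  pos <- as.matrix(pos)
  if (nrow(pos) < 2) stop("end_to_end needs >= 2 heavy atoms")
  check_chain_unwrapped(pos, box)
  sqrt(sum((pos[nrow(pos), ] - pos[1, ])^2))
}

#' Distance from a chain's terminal heavy atom to the particle center
#'
#' @param pos chain heavy-atom positions in chain order (terminus last)
#' @param np_center xyz of the particle center
#' @return distance in Angstrom
#' @export
peg_np_distance <- function(pos, np_center) {
  pos <- as.matrix(pos)
  sqrt(sum((pos[nrow(pos), ] - np_center)^2))
}

## unwrap an ordered chain from its anchor by accumulating minimum-image
## bond vectors
unwrap_chain <- function(pos, box) {
  if (nrow(pos) < 2) return(pos)
  d <- diff(pos)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  out <- pos
  out[-1, ] <- matrix(rep(pos[1, ], nrow(pos) - 1), ncol = 3, byrow = TRUE) +
    apply(d, 2, cumsum)
  out
}

#' Polymer layer thickness from a cumulative radial fraction
#'
#' The layer is the radial span holding 90 percent of the polymer:
#' \code{r_min} and \code{r_max} are the radii where the cumulative
#' fraction crosses 0.05 and 0.95 (linear interpolation between bin
#' edges), and the thickness is their difference.
#'
#' @param peg_cdf \code{radial_profile} of kind \code{"cumulative_fraction"}
#' @param lo,hi crossing levels (defaults 0.05 and 0.95)
#' @return list with \code{thk}, \code{r_min}, \code{r_max} (Angstrom)
#' @export
layer_thickness <- function(peg_cdf, lo = 0.05, hi = 0.95) {
  if (peg_cdf$kind != "cumulative_fraction")
    stop("layer_thickness needs a cumulative_fraction profile")
  v <- peg_cdf$values
  if (any(diff(v) < -1e-12)) stop("non-monotone cumulative fraction")
  r <- c(peg_cdf$edges[1], peg_cdf$edges[-1])
  v <- c(0, v)
  cross <- function(level) {
    i <- which(v >= level)[1]
    if (is.na(i)) stop("cumulative fraction never reaches ", level)
    if (i == 1) return(r[1])
    r[i - 1] + (level - v[i - 1]) * (r[i] - r[i - 1]) / (v[i] - v[i - 1])
  }
  r_min <- cross(lo); r_max <- cross(hi)
  list(thk = r_max - r_min, r_min = r_min, r_max = r_max)
}

#' Polymer and water volume-fraction profiles
#'
#' Fraction of each 0.1 A spherical shell's volume occupied by polymer or
#' water, using fixed displaced volumes: each polymer heavy group
#' (CH2-equivalent carbon or ether/hydroxyl oxygen) contributes 20 A^3 at
#' its position, each water molecule 30 A^3 at its oxygen position.
#' Computed from the geometric center of the particle core by default.
#'
#' @inheritParams radial_number_density
#' @param volumes named displaced volumes in A^3
#'   (\code{peg_heavy}, \code{water})
#' @return list with \code{radial_profile}s \code{peg} and \code{water},
#'   both of kind \code{"volume_fraction"}
#' @export
volume_fraction_profile <- function(traj, topo,
                                    center = center_convention(),
                                    window = NULL, bin_width = 0.1,
                                    r_max = NULL,
                                    volumes = c(peg_heavy = 20, water = 30)) {
  traj <- window_frames(traj, window)
  if (is.null(r_max))
    r_max <- min(vapply(traj$frames, function(f) min(f$box),
                        numeric(1))) / 2
  edges <- seq(0, r_max, by = bin_width)
  vols <- shell_volumes(edges)

  peg <- topo$groups[["PEG"]]
  if (is.null(peg)) peg <- integer(0)
  peg_heavy <- peg[topo$atoms$is_heavy[peg]]
  wat <- topo$groups[["WATER"]]
  if (is.null(wat)) wat <- integer(0)
  wat_o <- wat[topo$atoms$element[wat] == "O"]

  prof <- function(sel, vol_per) {
    counts <- radial_counts(traj, sel, topo, center, edges)
    new_radial_profile(bin_width, edges, counts * vol_per / vols,
                       "volume_fraction", n_frames(traj))
  }
  list(peg = prof(peg_heavy, volumes[["peg_heavy"]]),
       water = prof(wat_o, volumes[["water"]]))
}

#' Daoud-Cotton brush-scaling fit of a volume-fraction profile
#'
#' Least-squares fit of \eqn{\log \phi} against \eqn{\log r}, with r the
#' distance from the particle surface, over a stated window. In the
#' semidilute brush regime of the Daoud-Cotton model for star-like grafted
#' polymers the volume fraction scales as \eqn{r^{-4/3}}; the fitted slope
#' is the measured exponent.
#'
#' @param vfp volume-fraction \code{radial_profile} (polymer component)
#' @param window \code{c(r_lo, r_hi)} in Angstrom from the particle surface
#' @param surface_radius particle surface radius r0 in Angstrom (0 if the
#'   profile is already on a from-surface axis)
#' @return object of class \code{"brush_fit"} with the fitted
#'   \code{exponent}, \code{log_prefactor}, \code{r_squared}, window and
#'   bin count; \code{coef()} returns exponent and prefactor
#' @export
daoud_cotton_fit <- function(vfp, window, surface_radius = 0) {
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be c(r_lo, r_hi) with r_hi > r_lo")
  x <- vfp$r_mid - surface_radius
  keep <- x >= window[1] & x <= window[2]
  x <- x[keep]; y <- vfp$values[keep]
  if (any(y <= 0)) {
    warning(sum(y <= 0), " nonpositive volume-fraction bin(s) dropped ",
            "from the log-log fit")
    x <- x[y > 0]; y <- y[y > 0]
  }
  if (length(x) < 5)
    stop("Daoud-Cotton fit needs >= 5 positive bins in the window; got ",
         length(x))
  fit <- stats::lm(log(y) ~ log(x))
  tss <- sum((log(y) - mean(log(y)))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  structure(list(exponent = unname(stats::coef(fit)[2]),
                 log_prefactor = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 window = window, surface_radius = surface_radius,
                 n_bins = length(x)),
            class = "brush_fit")
}

#' @export
print.brush_fit <- function(x, ...) {
  cat(sprintf(
    "Brush-scaling fit: phi ~ r^%.4f (prefactor %.4g, R^2 %.4f)\n",
    x$exponent, exp(x$log_prefactor), x$r_squared))
  cat(sprintf("  window %.1f-%.1f A from surface (r0 = %.1f A), %d bins\n",
              x$window[1], x$window[2], x$surface_radius, x$n_bins))
  invisible(x)
}

#' @export
coef.brush_fit <- function(object, ...) {
  c(exponent = object$exponent, prefactor = exp(object$log_prefactor))
}

#' Grafting density
#'
#' @param n_chains number of grafted chains
#' @param surface_area_nm2 particle surface area in nm^2
#' @return chains per nm^2
#' @export
grafting_density <- function(n_chains, surface_area_nm2) {
  if (surface_area_nm2 <= 0) stop("surface area must be > 0")
  n_chains / surface_area_nm2
}

#' Per-chain structural metrics over a trajectory window
#'
#' For every chain and frame: radius of gyration, end-to-end distance and
#' terminal-heavy-atom-to-core distance, each on anchor-rooted unwrapped
#' coordinates; plus the polymer layer thickness from the cumulative radial
#' fraction of the polymer heavy atoms. Standard deviations are reported
#' over all chain-frame samples, and also decomposed into the sd of
#' per-chain means and of per-frame means.
#'
#' @inheritParams radial_number_density
#' @param weighting Rg weighting mode, see \code{\link{radius_of_gyration}}
#' @return object of class \code{"chain_metrics"}: \code{samples}
#'   data.frame (chain, frame, time, rg, h, d), \code{summary} named list
#'   of means/sds, and the layer thickness triple
#' @export
chain_metrics <- function(traj, topo, center = center_convention(),
                          window = NULL, weighting = "unweighted",
                          bin_width = 0.1) {
  if (!length(topo$chains)) stop("topology has no chains")
  traj <- window_frames(traj, window)
  rows <- vector("list", length(topo$chains) * n_frames(traj))
  k <- 0
  for (f in seq_len(n_frames(traj))) {
    fr <- traj$frames[[f]]
    ctr <- resolve_center(fr, topo, center)
    for (cn in names(topo$chains)) {
      idx <- topo$chains[[cn]]
      pos <- unwrap_chain(fr$positions[idx, , drop = FALSE], fr$box)
      k <- k + 1
      rows[[k]] <- data.frame(
        chain = cn, frame = f, time = fr$time,
        rg = radius_of_gyration(pos, mass = topo$atoms$mass[idx],
                                weighting = weighting),
        h = end_to_end(pos),
        d = peg_np_distance(pos, ctr))
    }
  }
  samples <- do.call(rbind, rows)

  peg <- topo$groups[["PEG"]]
  peg_heavy <- peg[topo$atoms$is_heavy[peg]]
  dens <- radial_number_density(traj, peg_heavy, topo, center,
                                bin_width = bin_width)
  thk <- layer_thickness(cumulative_fraction(dens))

  smry <- list()
  for (q in c("rg", "h", "d")) {
    x <- samples[[q]]
    smry[[paste0(q, "_mean")]] <- mean(x)
    smry[[paste0(q, "_sd")]] <- stats::sd(x)
    smry[[paste0(q, "_sd_over_chains")]] <-
      stats::sd(tapply(x, samples$chain, mean))
    smry[[paste0(q, "_sd_over_frames")]] <-
      stats::sd(tapply(x, samples$frame, mean))
  }
  structure(c(list(samples = samples, summary = smry), thk),
            class = "chain_metrics")
}

#' @export
print.chain_metrics <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Chain metrics over %d chain-frame samples:\n",
              nrow(x$samples)))
  cat(sprintf("  Rg       = %.2f (+/- %.2f) A\n", s$rg_mean, s$rg_sd))
  cat(sprintf("  <h^2>^.5 = %.2f (+/- %.2f) A\n", s$h_mean, s$h_sd))
  cat(sprintf("  d(PEG-NP)= %.2f (+/- %.2f) A\n", s$d_mean, s$d_sd))
  cat(sprintf("  thk      = %.2f A (r_min %.2f, r_max %.2f)\n",
              x$thk, x$r_min, x$r_max))
  invisible(x)
}
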