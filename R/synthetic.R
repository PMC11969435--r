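## Seeded synthetic-configuration generators with closed-form ground truth:
## polymer-grafted spheres (freely-jointed or straight chains), a random
## water bath with ions, charged shells with analytic fields, Brownian
## walkers, and planted power-law volume-fraction profiles. The ground
## truth travels in the returned `truth` element and is consumed by tests,
## never by the analysis code.

#' Generate a polymer-grafted spherical particle
#'
#' A rigid core (central pseudo-atom plus a quasi-uniform Fibonacci shell
#' of surface atoms at the core radius) with \code{n_chains} bead chains
#' anchored at quasi-uniform surface points. Each chain has
#' \code{n_bonds} bonds of fixed length: the anchor bead sits on the
#' surface, the first bond points radially outward, and the remaining
#' bonds are either radial too (\code{mode = "straight"}) or uniformly
#' random (\code{mode = "fjc"}, the freely-jointed chain, whose end-to-end
#' statistics have the closed form \eqn{<h^2> = N_b b^2}). Multi-frame
#' output resamples the chain conformations each frame.
#'
#' @param n_chains number of grafted chains
#' @param n_bonds bonds per chain (beads per chain = n_bonds + 1)
#' @param bond_length bond length b in Angstrom
#' @param core_radius core radius R in Angstrom
#' @param box box edge in Angstrom (default: large enough that no chain
#'   can wrap)
#' @param n_frames number of frames (conformations resampled per frame)
#' @param mode \code{"fjc"} or \code{"straight"}
#' @param n_core_surface surface atoms on the core shell
#' @param seed RNG seed
#' @return list with \code{topology}, \code{trajectory} and \code{truth}
#'   (generator bookkeeping: expected end-to-end moments, chain counts,
#'   the common terminus radius in straight mode)
#' @export
generate_grafted_np <- function(n_chains, n_bonds, bond_length = 1.5,
                                core_radius = 10, box = NULL,
                                n_frames = 1, mode = c("fjc", "straight"),
                                n_core_surface = 50, seed = 1) {
  mode <- match.arg(mode)
  if (n_chains < 1 || n_bonds < 1) stop("need >= 1 chain and >= 1 bond")
  max_extent <- core_radius + n_bonds * bond_length
  if (is.null(box)) box <- 2 * max_extent + 20
  ctr <- rep(box / 2, 3)

  core_pos <- rbind(ctr,
                    sweep(fibonacci_sphere(n_core_surface) * core_radius,
                          2, ctr, "+"))
  n_core <- nrow(core_pos)
  anchors_u <- fibonacci_sphere(n_chains)

  beads_per <- n_bonds + 1
  n_peg <- n_chains * beads_per
  n_tot <- n_core + n_peg

  chain_positions <- function() {
    pos <- matrix(0, n_peg, 3)
    for (c in seq_len(n_chains)) {
      u <- anchors_u[c, ]
      p <- matrix(0, beads_per, 3)
      p[1, ] <- u * core_radius
      p[2, ] <- u * (core_radius + bond_length)
      if (n_bonds >= 2) {
        if (mode == "straight") {
          for (j in 3:beads_per)
            p[j, ] <- u * (core_radius + (j - 1) * bond_length)
        } else {
          v <- matrix(stats::rnorm(3 * (n_bonds - 1)), ncol = 3)
          v <- v / sqrt(rowSums(v * v)) * bond_length
          p[3:beads_per, ] <- p[rep(2, n_bonds - 1), , drop = FALSE] +
            apply(v, 2, cumsum)
        }
      }
      pos[((c - 1) * beads_per + 1):(c * beads_per), ] <- p
    }
    sweep(pos, 2, ctr, "+")
  }

  frames <- with_seed(seed, lapply(seq_len(n_frames), function(f) {
    frame(rbind(core_pos, chain_positions()), time = f - 1, box = box)
  }))

  chains <- lapply(seq_len(n_chains), function(c)
    n_core + ((c - 1) * beads_per + 1):(c * beads_per))
  names(chains) <- as.character(seq_len(n_chains))
  bonds <- do.call(rbind, lapply(chains, function(idx)
    cbind(idx[-length(idx)], idx[-1])))

  atoms <- data.frame(
    element = "C", charge = 0, mass = 12.011,
    lj_epsilon = 0.06, lj_sigma = 3.5, is_heavy = TRUE,
    hbond_role = "none", stringsAsFactors = FALSE)[rep(1, n_tot), ]
  rownames(atoms) <- NULL

  topo <- topology(atoms, bonds = bonds,
                   groups = list(NP_CORE = seq_len(n_core),
                                 PEG = (n_core + 1):n_tot),
                   chains = chains)
  list(topology = topo, trajectory = trajectory(frames),
       truth = list(n_chains = n_chains, n_bonds = n_bonds,
                    bond_length = bond_length, core_radius = core_radius,
                    beads_per_chain = beads_per, center = ctr,
                    expected_h2 = n_bonds * bond_length^2,
                    straight_terminus_radius = max_extent,
                    mode = mode))
}

## rigid water geometry: O at origin, two H at the TIP3P-like bond
## length/angle, randomly oriented
water_site_offsets <- function() {
  r_oh <- 0.9572; ang <- 104.52 * pi / 180
  h1 <- c(r_oh, 0, 0)
  h2 <- c(r_oh * cos(ang), r_oh * sin(ang), 0)
  rbind(c(0, 0, 0), h1, h2)
}

random_rotation <- function() {
  ## QR of a Gaussian matrix gives a Haar-random rotation (det fixed to +1)
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a random aqueous bath of 3-site molecules with ions
#'
#' Neutral 3-site water-like molecules (TIP3P-like charges: O -0.834 e,
#' H +0.417 e) at uniform random non-overlapping positions at the
#' requested molecular density, an optional spherical exclusion cavity
#' about the box center, and Na+/Cl- ion pairs at the requested molarity
#' (pair count rounded, preserving exact neutrality). The packing is
#' random, not an equilibrated liquid: right for density/RDF/charge
#' estimator tests, silent on real water structure.
#'
#' @param box box edge in Angstrom
#' @param density molecules per A^3 (default 0.0334, bulk water)
#' @param cavity_radius exclusion-sphere radius about the box center (A)
#' @param ion_molarity NaCl molarity (mol/L); 0 for no ions
#' @param min_dist minimum O-O / ion distance during packing (A)
#' @param max_attempts packing attempts per molecule before giving up
#' @param seed RNG seed
#' @return list with \code{topology}, \code{trajectory} (1 frame) and
#'   \code{truth} (molecule and ion counts, cavity radius, center)
#' @export
generate_water_bath <- function(box, density = 0.0334, cavity_radius = 0,
                                ion_molarity = 0, min_dist = 2.0,
                                max_attempts = 200, seed = 1) {
  vol <- box^3
  n_mol <- floor(density * vol)
  ctr <- rep(box / 2, 3)
  n_ion_pairs <- if (ion_molarity > 0)
    round(ion_molarity * .const$avogadro * vol * 1e-27) else 0L

  n_sites <- n_mol + 2L * n_ion_pairs
  pts <- with_seed(seed, {
    acc <- matrix(0, 0, 3)
    for (i in seq_len(n_sites)) {
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        p <- stats::runif(3, 0, box)
        if (cavity_radius > 0 &&
            sqrt(sum((p - ctr)^2)) < cavity_radius) next
        if (nrow(acc)) {
          d <- min_image_radii(acc, p, rep(box, 3))
          if (min(d) < min_dist) next
        }
        acc <- rbind(acc, p); placed <- TRUE; break
      }
      if (!placed)
        stop("packing failed after ", max_attempts,
             " attempts for site ", i, "; lower the density")
    }
    list(acc = acc,
         rots = lapply(seq_len(n_mol), function(i) random_rotation()))
  })
  o_pos <- pts$acc[seq_len(n_mol), , drop = FALSE]
  ion_pos <- if (n_ion_pairs > 0)
    pts$acc[(n_mol + 1):n_sites, , drop = FALSE] else matrix(0, 0, 3)

  offs <- water_site_offsets()
  wpos <- matrix(0, 3 * n_mol, 3)
  for (i in seq_len(n_mol))
    wpos[(3 * i - 2):(3 * i), ] <-
      sweep(offs %*% t(pts$rots[[i]]), 2, o_pos[i, ], "+")

  pos <- rbind(wpos, ion_pos)
  n_tot <- nrow(pos)
  el <- c(rep(c("O", "H", "H"), n_mol),
          rep("Na", n_ion_pairs), rep("Cl", n_ion_pairs))
  q <- c(rep(c(-0.834, 0.417, 0.417), n_mol),
         rep(1, n_ion_pairs), rep(-1, n_ion_pairs))
  mass <- c(rep(c(15.999, 1.008, 1.008), n_mol),
            rep(22.99, n_ion_pairs), rep(35.45, n_ion_pairs))
  role <- c(rep(c("both", "polar-hydrogen", "polar-hydrogen"), n_mol),
            rep("none", 2 * n_ion_pairs))
  heavy <- el != "H"
  atoms <- data.frame(element = el, charge = q, mass = mass,
                      lj_epsilon = ifelse(el == "O", 0.1521, 0),
                      lj_sigma = ifelse(el == "O", 3.1507, 0),
                      is_heavy = heavy, hbond_role = role,
                      stringsAsFactors = FALSE)
  bonds <- if (n_mol > 0) {
    o <- 3 * seq_len(n_mol) - 2
    rbind(cbind(o, o + 1), cbind(o, o + 2))
  } else NULL
  groups <- list(WATER = seq_len(3 * n_mol))
  if (n_ion_pairs > 0) {
    groups$ION_NA <- 3 * n_mol + seq_len(n_ion_pairs)
    groups$ION_CL <- 3 * n_mol + n_ion_pairs + seq_len(n_ion_pairs)
  }
  topo <- topology(atoms, bonds = bonds, groups = groups)
  list(topology = topo,
       trajectory = trajectory(list(frame(pos, time = 0, box = box))),
       truth = list(n_molecules = n_mol, n_ion_pairs = n_ion_pairs,
                    cavity_radius = cavity_radius, center = ctr,
                    density = density))
}

#' Generate concentric charged shells with closed-form fields
#'
#' Point charges spread quasi-uniformly (Fibonacci sphere) over spheres of
#' the given radii and total charges, centered in the box. The returned
#' truth carries the closed-form Coulomb superposition for the field and
#' potential of ideal shells, for use as an oracle.
#'
#' @param radii shell radii in Angstrom
#' @param charges total shell charges in e
#' @param n_points point charges per shell
#' @param box box edge in Angstrom
#' @return list with \code{topology}, \code{frame} and \code{truth};
#'   \code{truth$E_closed(r)} in V/A and \code{truth$phi_closed(r, r_ref)}
#'   in mV include all shells
#' @export
generate_charged_shells <- function(radii, charges, n_points = 400,
                                    box = NULL) {
  stopifnot(length(radii) == length(charges))
  if (is.null(box)) box <- 4 * max(radii, 1) + 40
  ctr <- rep(box / 2, 3)
  pos <- NULL; q <- NULL
  for (s in seq_along(radii)) {
    u <- fibonacci_sphere(n_points)
    pos <- rbind(pos, sweep(u * radii[s], 2, ctr, "+"))
    q <- c(q, rep(charges[s] / n_points, n_points))
  }
  if (is.null(pos)) { pos <- matrix(ctr, 1, 3); q <- 0 }
  atoms <- data.frame(element = "X", charge = q, mass = 1,
                      lj_epsilon = 0, lj_sigma = 0, is_heavy = TRUE,
                      hbond_role = "none", stringsAsFactors = FALSE)
  topo <- topology(atoms, groups = list(CHARGES = seq_len(nrow(pos))))
  kV <- .const$k_coulomb_volt
  E_closed <- function(r) {
    vapply(r, function(ri)
      sum(ifelse(ri > radii, kV * charges / ri^2, 0)), numeric(1))
  }
  phi_closed <- function(r, r_ref) {
    phi1 <- function(ri)
      sum(kV * charges / pmax(ri, radii))
    (vapply(r, phi1, numeric(1)) - phi1(r_ref)) * 1000
  }
  list(topology = topo, frame = frame(pos, time = 0, box = box),
       truth = list(radii = radii, charges = charges, center = ctr,
                    E_closed = E_closed, phi_closed = phi_closed))
}

#' Generate Brownian walkers with a known diffusion coefficient
#'
#' Independent random walkers with per-step Gaussian displacements of
#' per-dimension variance \eqn{2 D dt}, the discrete realization of
#' isotropic diffusion with coefficient D.
#'
#' @param n_walkers number of walkers
#' @param steps number of time steps
#' @param dt time step in ps
#' @param D diffusion coefficient in m^2/s
#' @param seed RNG seed
#' @return list with \code{topology}, \code{trajectory}
#'   (\code{steps + 1} frames) and \code{truth} (\code{D}, \code{dt})
#' @export
generate_brownian <- function(n_walkers = 100, steps = 1000, dt = 1,
                              D = 1e-10, seed = 1) {
  if (dt <= 0 || steps < 1 || D < 0) stop("need dt > 0, steps >= 1, D >= 0")
  D_A <- D / .const$A2_per_ps_to_m2_per_s  # A^2/ps
  sd_step <- sqrt(2 * D_A * dt)
  span <- 20 * sqrt(max(2 * D_A * dt * steps, 1)) + 100
  paths <- with_seed(seed, {
    start <- matrix(stats::runif(3 * n_walkers, span / 2 - 5, span / 2 + 5),
                    ncol = 3)
    disp <- array(stats::rnorm(steps * n_walkers * 3, sd = sd_step),
                  dim = c(steps, n_walkers, 3))
    list(start = start, disp = disp)
  })
  frames <- vector("list", steps + 1)
  cur <- paths$start
  frames[[1]] <- frame(cur, time = 0, box = span)
  for (s in seq_len(steps)) {
    cur <- cur + paths$disp[s, , ]
    frames[[s + 1]] <- frame(cur, time = s * dt, box = span)
  }
  atoms <- data.frame(element = "C", charge = 0, mass = 12.011,
                      lj_epsilon = 0, lj_sigma = 0, is_heavy = TRUE,
                      hbond_role = "none",
                      stringsAsFactors = FALSE)[rep(1, n_walkers), ]
  rownames(atoms) <- NULL
  topo <- topology(atoms, groups = list(WALKERS = seq_len(n_walkers)))
  list(topology = topo, trajectory = trajectory(frames),
       truth = list(D = D, dt = dt, sd_step = sd_step))
}

#' Generate a planted power-law volume-fraction profile
#'
#' \eqn{\phi(r) = A r^{\alpha}} on a 0.1 A grid with optional
#' multiplicative lognormal noise; the oracle input for the brush-scaling
#' fit.
#'
#' @param exponent planted exponent alpha
#' @param prefactor planted prefactor A
#' @param r_range \code{c(r_lo, r_hi)} in Angstrom
#' @param bin_width grid spacing (default 0.1)
#' @param noise_sd sdlog of the multiplicative lognormal noise (0.01 for
#'   1 percent noise); 0 for noiseless
#' @param seed RNG seed
#' @return \code{radial_profile} of kind \code{"volume_fraction"} with the
#'   planted parameters in \code{attr(, "truth")}
#' @export
generate_power_law_profile <- function(exponent, prefactor = 1,
                                       r_range = c(5, 30),
                                       bin_width = 0.1, noise_sd = 0,
                                       seed = 1) {
  if (!is.finite(exponent)) stop("exponent must be finite")
  if (r_range[1] <= 0) stop("r_range must be positive")
  edges <- seq(r_range[1], r_range[2], by = bin_width)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  v <- prefactor * mids^exponent
  if (noise_sd > 0)
    v <- v * with_seed(seed, exp(stats::rnorm(length(v), sd = noise_sd)))
  p <- new_radial_profile(bin_width, edges, v, "volume_fraction", 1L)
  attr(p, "truth") <- list(exponent = exponent, prefactor = prefactor,
                           noise_sd = noise_sd)
  p
}
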