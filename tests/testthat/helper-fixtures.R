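# Small builders used across the suite. All fixtures are generated in
# code; nothing is read from disk except the shipped system tables.

withr_like_tempdir <- function() {
  d <- tempfile("nanobrush-test-")
  dir.create(d)
  d
}

# minimal topology of n like atoms with optional charges and groups
tiny_topology <- function(n, charge = 0, groups = list(ALL = seq_len(n)),
                          element = "C", mass = 12.011, bonds = NULL,
                          lj_epsilon = 0, lj_sigma = 0,
                          hbond_role = "none", chains = list()) {
  topology(
    data.frame(element = rep_len(element, n),
               charge = rep_len(charge, n),
               mass = rep_len(mass, n),
               lj_epsilon = rep_len(lj_epsilon, n),
               lj_sigma = rep_len(lj_sigma, n),
               is_heavy = TRUE,
               hbond_role = rep_len(hbond_role, n),
               stringsAsFactors = FALSE),
    bonds = bonds, groups = groups, chains = chains)
}

one_frame_traj <- function(positions, box = 100, time = 0) {
  trajectory(list(frame(positions, time = time, box = box)))
}

# water-like donor/acceptor triple: donor heavy at d_pos with one hydrogen,
# acceptor heavy at a_pos; hydrogen placed so the donor-vertex angle
# between donor->H and donor->acceptor equals `angle_deg`
hbond_geometry <- function(d_pos, a_pos, angle_deg, box = 100,
                           r_dh = 1.0) {
  u <- a_pos - d_pos; u <- u / sqrt(sum(u * u))
  # any vector orthogonal to u
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u; v <- v / sqrt(sum(v * v))
  ang <- angle_deg * pi / 180
  h_pos <- d_pos + r_dh * (cos(ang) * u + sin(ang) * v)
  topo <- topology(
    data.frame(element = c("O", "H", "O"), charge = 0,
               mass = c(15.999, 1.008, 15.999),
               lj_epsilon = 0, lj_sigma = 0,
               is_heavy = c(TRUE, FALSE, TRUE),
               hbond_role = c("donor-heavy", "polar-hydrogen",
                              "acceptor-heavy"),
               stringsAsFactors = FALSE),
    bonds = rbind(c(1L, 2L)),
    groups = list(D = 1L, A = 3L))
  list(topology = topo,
       frame = frame(rbind(d_pos, h_pos, a_pos), box = box))
}

# brute-force oracles -------------------------------------------------

# per-bin histogram of radii about `center` (no periodic wrap assumed:
# callers use boxes large enough that wrapping is a no-op)
oracle_radial_counts <- function(pos, center, edges) {
  r <- sqrt(rowSums(sweep(pos, 2, center)^2))
  counts <- numeric(length(edges) - 1)
  for (i in seq_along(r)) {
    for (b in seq_along(counts)) {
      if (r[i] >= edges[b] && r[i] < edges[b + 1]) {
        counts[b] <- counts[b] + 1
        break
      }
    }
  }
  counts
}

# Rg via the pairwise-sum identity sqrt(1/(2N^2) sum_ij |ri - rj|^2)
oracle_rg_pairwise <- function(pos) {
  n <- nrow(pos)
  s <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      s <- s + sum((pos[i, ] - pos[j, ])^2)
  sqrt(s / (2 * n^2))
}

# triple-loop H-bond count, donor-vertex convention, minimum image
oracle_hbond_count <- function(pos, box, donors, hydrogens_of, acceptors,
                               d_max = 3.0, angle_max = 20) {
  mi <- function(v) v - box * round(v / box)
  count <- 0L
  for (d in donors) {
    for (a in acceptors) {
      if (a == d) next
      da <- mi(pos[a, ] - pos[d, ])
      if (sqrt(sum(da * da)) >= d_max) next
      for (h in hydrogens_of[[as.character(d)]]) {
        dh <- mi(pos[h, ] - pos[d, ])
        cosang <- sum(dh * da) / sqrt(sum(dh * dh) * sum(da * da))
        ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        if (ang < angle_max) count <- count + 1L
      }
    }
  }
  count
}

# O(N^2) nonbonded double loop with minimum image, cutoff, exclusions
oracle_pair_energy <- function(pos, box, charge, eps, sig, selA, selB,
                               cutoff = 12, excluded = NULL,
                               k_coulomb = 332.0637133) {
  mi <- function(v) v - box * round(v / box)
  pairs_seen <- character(0)
  ecoul <- 0; elj <- 0
  for (i in selA) {
    for (j in selB) {
      if (i == j) next
      key <- paste(min(i, j), max(i, j))
      if (key %in% pairs_seen) next
      pairs_seen <- c(pairs_seen, key)
      if (!is.null(excluded) && key %in% excluded) next
      r <- sqrt(sum(mi(pos[i, ] - pos[j, ])^2))
      if (r >= cutoff) next
      ecoul <- ecoul + k_coulomb * charge[i] * charge[j] / r
      e <- sqrt(eps[i] * eps[j]); s <- (sig[i] + sig[j]) / 2
      sr6 <- (s / r)^6
      elj <- elj + 4 * e * (sr6^2 - sr6)
    }
  }
  list(coulomb = ecoul, lj = elj, total = ecoul + elj)
}
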