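test_that("hydrogen-bond criteria gate on distance and angle", {
  count_at <- function(dist, angle) {
    geo <- hbond_geometry(c(50, 50, 50), c(50 + dist, 50, 50), angle)
    count_hbonds(geo$frame, geo$topology, 1L, 3L)
  }
  expect_equal(count_at(2.9, 0), 1)    # in range, collinear
  expect_equal(count_at(3.2, 0), 0)    # too far
  expect_equal(count_at(2.9, 25), 0)   # angle too wide
  expect_equal(count_at(2.9, 19.5), 1) # just inside the cone
  expect_equal(count_at(2.999, 0), 1)  # strict < on distance
  expect_equal(count_at(3.0, 0), 0)

  # a donor with two hydrogens can form two bonds (two acceptors)
  topo <- topology(
    data.frame(element = c("O", "H", "H", "O", "O"),
               charge = 0, mass = c(16, 1, 1, 16, 16),
               lj_epsilon = 0, lj_sigma = 0,
               is_heavy = c(TRUE, FALSE, FALSE, TRUE, TRUE),
               hbond_role = c("donor-heavy", "polar-hydrogen",
                              "polar-hydrogen", "acceptor-heavy",
                              "acceptor-heavy")),
    bonds = rbind(c(1L, 2L), c(1L, 3L)))
  pos <- rbind(c(50, 50, 50), c(51, 50, 50), c(50, 51, 50),
               c(52.8, 50, 50), c(50, 52.8, 50))
  expect_equal(count_hbonds(frame(pos, box = 100), topo, 1L, 4:5), 2)

  # donor without a bonded polar hydrogen is a hard error
  bad <- topology(
    data.frame(element = c("O", "O"), charge = 0, mass = 16,
               lj_epsilon = 0, lj_sigma = 0, is_heavy = TRUE,
               hbond_role = c("donor-heavy", "acceptor-heavy")))
  expect_error(count_hbonds(frame(matrix(50, 2, 3), box = 100),
                            bad, 1L, 2L), "polar hydrogen")
})

test_that("hydrogen-bond counter matches the triple-loop oracle on random geometries", {
  # 100 seeded random donor/acceptor clouds, counted both ways
  set.seed(77)
  mismatches <- 0
  for (g in 1:100) {
    nd <- sample(2:4, 1); na <- sample(2:5, 1)
    L <- 12
    d_pos <- matrix(runif(3 * nd, 2, 10), ncol = 3)
    h_pos <- d_pos + matrix(rnorm(3 * nd, sd = 0.6), ncol = 3)
    a_pos <- matrix(runif(3 * na, 2, 10), ncol = 3)
    pos <- rbind(d_pos, h_pos, a_pos)
    topo <- topology(
      data.frame(element = c(rep("O", nd), rep("H", nd), rep("O", na)),
                 charge = 0, mass = 16, lj_epsilon = 0, lj_sigma = 0,
                 is_heavy = c(rep(TRUE, nd), rep(FALSE, nd),
                              rep(TRUE, na)),
                 hbond_role = c(rep("donor-heavy", nd),
                                rep("polar-hydrogen", nd),
                                rep("acceptor-heavy", na))),
      bonds = cbind(seq_len(nd), nd + seq_len(nd)))
    fr <- frame(pos, box = L)
    got <- count_hbonds(fr, topo, seq_len(nd), 2 * nd + seq_len(na))
    hyd <- as.list(nd + seq_len(nd)); names(hyd) <- seq_len(nd)
    want <- oracle_hbond_count(pos, rep(L, 3), seq_len(nd), hyd,
                               2 * nd + seq_len(na))
    if (got != want) mismatches <- mismatches + 1
  }
  expect_equal(mismatches, 0)
})

test_that("pair energies have their closed-form anchors", {
  # two +1e charges 5 A apart, LJ off: Coulomb = k_C / 5
  topo <- tiny_topology(2, charge = 1)
  fr <- frame(rbind(c(10, 10, 10), c(15, 10, 10)), box = 100)
  e <- pair_interaction_energy(fr, topo, 1L, 2L, nonbonded_scheme(40))
  expect_equal(e$coulomb, 332.0637133 / 5, tolerance = 1e-7)
  expect_equal(e$lennard_jones, 0)
  expect_equal(e$total, e$coulomb + e$lennard_jones)

  # single LJ pair at r = 2^(1/6) sigma: exactly -epsilon
  topo2 <- tiny_topology(2, lj_epsilon = 0.25, lj_sigma = 3)
  fr2 <- frame(rbind(c(10, 10, 10), c(10 + 2^(1 / 6) * 3, 10, 10)),
               box = 100)
  e2 <- pair_interaction_energy(fr2, topo2, 1L, 2L, nonbonded_scheme(40))
  expect_equal(e2$lennard_jones, -0.25, tolerance = 1e-12)

  # pair beyond the cutoff contributes nothing
  topo3 <- tiny_topology(2, charge = 1, lj_epsilon = 0.2, lj_sigma = 3)
  fr3 <- frame(rbind(c(10, 10, 10), c(23, 10, 10)), box = 100)
  e3 <- pair_interaction_energy(fr3, topo3, 1L, 2L, nonbonded_scheme(12))
  expect_equal(e3$total, 0)

  # cutoff must stay below half the box
  expect_error(pair_interaction_energy(fr3, topo3, 1L, 2L,
                                       nonbonded_scheme(60)), "cutoff")

  # switching window tapers LJ to zero at the cutoff, smoothly
  topo4 <- tiny_topology(2, lj_epsilon = 0.25, lj_sigma = 3)
  sw <- nonbonded_scheme(12, lj_switch = c(10, 12))
  at <- function(r) pair_interaction_energy(
    frame(rbind(c(20, 20, 20), c(20 + r, 20, 20)), box = 100),
    topo4, 1L, 2L, sw)$lennard_jones
  plain <- function(r) pair_interaction_energy(
    frame(rbind(c(20, 20, 20), c(20 + r, 20, 20)), box = 100),
    topo4, 1L, 2L, nonbonded_scheme(12))$lennard_jones
  expect_equal(at(9.5), plain(9.5))            # untouched below r_on
  expect_equal(at(11.999) / plain(11.999), 0, tolerance = 1e-4)
  expect_lt(abs(at(11)), abs(plain(11)))       # tapered in between
})

test_that("group energies match the O(N^2) brute-force oracle", {
  set.seed(33)
  n <- 50; L <- 30
  pos <- matrix(runif(3 * n, 0, L), ncol = 3)
  charge <- round(runif(n, -0.8, 0.8), 3)
  eps <- runif(n, 0.05, 0.3); sig <- runif(n, 2.5, 3.5)
  topo <- topology(
    data.frame(element = "C", charge = charge, mass = 12,
               lj_epsilon = eps, lj_sigma = sig, is_heavy = TRUE,
               hbond_role = "none"),
    groups = list(A = 1:20, B = 15:50))
  fr <- frame(pos, box = L)
  selA <- 1:20; selB <- 15:50

  got <- pair_interaction_energy(fr, topo, selA, selB,
                                 nonbonded_scheme(12))
  want <- oracle_pair_energy(pos, L, charge, eps, sig, selA, selB,
                             cutoff = 12)
  expect_equal(got$coulomb, want$coulomb, tolerance = 1e-8)
  expect_equal(got$lennard_jones, want$lj, tolerance = 1e-8)

  # symmetry and additivity over a disjoint split of B
  rev <- pair_interaction_energy(fr, topo, selB, selA,
                                 nonbonded_scheme(12))
  expect_equal(got$total, rev$total, tolerance = 1e-12)
  b1 <- 15:30; b2 <- 31:50
  e1 <- pair_interaction_energy(fr, topo, selA, b1, nonbonded_scheme(12))
  e2 <- pair_interaction_energy(fr, topo, selA, b2, nonbonded_scheme(12))
  expect_equal(e1$total + e2$total, got$total, tolerance = 1e-10)

  # identical selections: each unique pair once
  small <- pair_interaction_energy(fr, topo, 1:3, 1:3,
                                   nonbonded_scheme(12))
  want3 <- oracle_pair_energy(pos, L, charge, eps, sig, 1:3, 1:3,
                              cutoff = 12)
  expect_equal(small$total, want3$total, tolerance = 1e-10)
})

test_that("bonded 1-2 and 1-3 pairs are excluded, 1-4 kept", {
  # linear 4-atom chain, 1.5 A spacing, all charged
  pos <- cbind(10 + 1.5 * (0:3), 10, 10)
  topo <- topology(
    data.frame(element = "C", charge = 0.5, mass = 12,
               lj_epsilon = 0, lj_sigma = 0, is_heavy = TRUE,
               hbond_role = "none")[rep(1, 4), ],
    bonds = rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L)))
  fr <- frame(pos, box = 60)
  e <- pair_interaction_energy(fr, topo, 1:4, 1:4, nonbonded_scheme(25))
  # only the single 1-4 pair (distance 4.5 A) survives the exclusions
  expect_equal(e$coulomb, 332.0637133 * 0.25 / 4.5, tolerance = 1e-7)
})

test_that("energy series over a frozen trajectory has zero spread", {
  g <- generate_grafted_np(4, 5, core_radius = 8, seed = 10)
  g$topology$atoms$charge <- 0.1
  fr <- g$trajectory$frames[[1]]
  frozen <- trajectory(list(fr, frame(fr$positions, 1, fr$box),
                            frame(fr$positions, 2, fr$box)))
  es <- energy_series(frozen, g$topology,
                      list(np_peg = list(select_atoms(g$topology, "NP_CORE"),
                                         select_atoms(g$topology, "PEG"))),
                      nonbonded_scheme(12))
  expect_equal(es$np_peg$sd, 0)
  expect_equal(nrow(es$np_peg$series), 3)
  expect_equal(es$np_peg$series$total,
               es$np_peg$series$coulomb + es$np_peg$series$lennard_jones,
               tolerance = 1e-9)
})

test_that("a separated pair of opposite dipoles decays faster than monopoles", {
  mk <- function(charges, sep) {
    n <- length(charges)
    pos <- rbind(cbind(10, 10 + 0.5 * seq_len(n / 2), 10),
                 cbind(10 + sep, 10 + 0.5 * seq_len(n / 2), 10))
    topo <- tiny_topology(n, charge = charges)
    abs(pair_interaction_energy(frame(pos, box = 200), topo,
                                seq_len(n / 2), n / 2 + seq_len(n / 2),
                                nonbonded_scheme(90))$coulomb)
  }
  # neutral dipole pair vs like-signed monopole pair at the same distance
  dip <- mk(c(1, -1, 1, -1), 40)
  mono <- mk(c(1, 1, 1, 1) / 2, 40)
  expect_lt(dip, mono)
})
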