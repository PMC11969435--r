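test_that("radius of gyration obeys the pairwise-sum identity", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  # two atoms 2 A apart: Rg = 1
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1)

  set.seed(21)
  for (rep in 1:5) {
    pos <- matrix(rnorm(3 * 20, sd = 4), ncol = 3)
    expect_equal(radius_of_gyration(pos), oracle_rg_pairwise(pos),
                 tolerance = 1e-10)
  }

  # mass weighting moves the center toward the heavy end
  pos <- rbind(c(0, 0, 0), c(2, 0, 0))
  rg_m <- radius_of_gyration(pos, mass = c(3, 1), weighting = "mass")
  expect_equal(rg_m, sqrt(3 / 4 * 0.5^2 + 1 / 4 * 1.5^2))

  # wrapped chain detection
  expect_error(
    radius_of_gyration(rbind(c(1, 1, 1), c(19, 1, 1)), box = rep(20, 3)),
    "unwrap")
})

test_that("end-to-end and terminus-core distances have their constructions", {
  chain <- t(sapply(0:10, function(i) c(i * 1.5, 0, 0)))
  expect_equal(end_to_end(chain), 15)
  expect_equal(end_to_end(rbind(c(1, 2, 3), c(0, 0, 0), c(1, 2, 3))), 0)
  expect_error(end_to_end(matrix(0, 1, 3)), ">= 2")

  expect_equal(peg_np_distance(rbind(c(0, 0, 0), c(30, 0, 0)),
                               c(0, 0, 0)), 30)

  # radially grafted straight chains: every terminus at R + Nb * b
  # (measured from the central core atom, the exact sphere center)
  g <- generate_grafted_np(6, 10, 1.5, core_radius = 10,
                           mode = "straight", seed = 3)
  ctr <- center_convention("fixed-atom-index", index = 1)
  cm <- chain_metrics(g$trajectory, g$topology, center = ctr)
  expect_equal(unique(round(cm$samples$d, 9)), 25)
  # ensemble mean equals the direct average of the same samples
  expect_equal(cm$summary$d_mean, mean(cm$samples$d), tolerance = 1e-12)
})

test_that("freely-jointed ensembles recover closed-form chain statistics", {
  # <h^2> = Nb * b^2 within 3 standard errors (2000 chain samples)
  g <- generate_grafted_np(400, 100, 1.5, core_radius = 10,
                           n_frames = 5, seed = 42, box = 500)
  cm <- chain_metrics(g$trajectory, g$topology)
  h2 <- cm$samples$h^2
  expect_equal(length(h2), 2000)
  se <- sd(h2) / sqrt(length(h2))
  expect_lt(abs(mean(h2) - 100 * 1.5^2), 3 * se)

  # <h^2>/<Rg^2> -> 6 for long ideal chains (N = 200, within 5%)
  g2 <- generate_grafted_np(300, 200, 1.5, core_radius = 10,
                            n_frames = 2, seed = 43, box = 700)
  cm2 <- chain_metrics(g2$trajectory, g2$topology)
  ratio <- mean(cm2$samples$h^2) / mean(cm2$samples$rg^2)
  expect_lt(abs(ratio - 6) / 6, 0.05)
})

test_that("layer thickness recovers closed forms and scale invariance", {
  edges <- seq(0, 30, by = 0.1)
  mids <- (edges[-1] + edges[-length(edges)]) / 2

  # uniform shell 10-20 A: r_min = 1350^(1/3), r_max = 7650^(1/3)
  p <- nanobrush:::new_radial_profile(
    0.1, edges, as.numeric(mids >= 10 & mids <= 20), "number_density", 1L)
  lt <- layer_thickness(cumulative_fraction(p))
  expect_equal(lt$r_min, 1350^(1 / 3), tolerance = 1e-3)
  expect_equal(lt$r_max, 7650^(1 / 3), tolerance = 1e-3)
  expect_equal(lt$thk, 7650^(1 / 3) - 1350^(1 / 3), tolerance = 1e-3)

  # uniform ball of radius 20: thk = 20 (0.95^(1/3) - 0.05^(1/3))
  pb <- nanobrush:::new_radial_profile(
    0.1, edges, as.numeric(mids <= 20), "number_density", 1L)
  ltb <- layer_thickness(cumulative_fraction(pb))
  expect_equal(ltb$thk, 20 * (0.95^(1 / 3) - 0.05^(1 / 3)),
               tolerance = 1e-3)

  # delta shell: thickness below one bin width
  pd <- nanobrush:::new_radial_profile(
    0.1, edges, as.numeric(abs(mids - 15.05) < 0.049),
    "number_density", 1L)
  expect_lt(layer_thickness(cumulative_fraction(pd))$thk, 0.1 + 1e-12)

  # invariance under uniform amplitude rescaling
  p5 <- nanobrush:::new_radial_profile(
    0.1, edges, 5 * as.numeric(mids >= 10 & mids <= 20),
    "number_density", 1L)
  expect_equal(layer_thickness(cumulative_fraction(p5))$thk, lt$thk)
})

test_that("volume fraction does the shell-volume arithmetic", {
  # one water molecule (O) in the shell [10.0, 10.1)
  pos <- rbind(c(60.05, 50, 50), c(60.5, 50.8, 50), c(60.5, 49.2, 50))
  topo <- topology(
    data.frame(element = c("O", "H", "H"),
               charge = c(-0.834, 0.417, 0.417),
               mass = c(16, 1, 1), lj_epsilon = 0, lj_sigma = 0,
               is_heavy = c(TRUE, FALSE, FALSE), hbond_role = "none"),
    bonds = rbind(c(1L, 2L), c(1L, 3L)),
    groups = list(WATER = 1:3))
  tr <- one_frame_traj(pos, box = 100)
  vfp <- volume_fraction_profile(tr, topo, center = rep(50, 3))
  hit <- which(vfp$water$values > 0)
  expect_equal(vfp$water$edges[hit], 10.0)
  expect_equal(vfp$water$values[hit],
               30 / (4 * pi / 3 * (10.1^3 - 10^3)))
  expect_true(all(vfp$peg$values == 0))

  # per-bin equality with a brute-force membership oracle on a grafted
  # system: 20 A^3 per polymer heavy atom at its binned radius
  g <- generate_grafted_np(8, 6, core_radius = 8, seed = 14)
  vf <- volume_fraction_profile(g$trajectory, g$topology,
                                center = g$truth$center)
  peg <- select_atoms(g$topology, "PEG")
  counts <- oracle_radial_counts(g$trajectory$frames[[1]]$positions[peg, ],
                                 g$truth$center, vf$peg$edges)
  vols <- 4 * pi / 3 * diff(vf$peg$edges^3)
  expect_equal(vf$peg$values, counts * 20 / vols, tolerance = 1e-12)
})

test_that("brush-scaling fit recovers planted exponents", {
  # noiseless phi = r^(-4/3): exact recovery
  p <- generate_power_law_profile(-4 / 3, r_range = c(5, 30))
  fit <- daoud_cotton_fit(p, window = c(6, 28))
  expect_equal(fit$exponent, -4 / 3, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # phi = 5 r^(-1): exponent -1, prefactor 5
  p5 <- generate_power_law_profile(-1, prefactor = 5, r_range = c(5, 30))
  f5 <- daoud_cotton_fit(p5, window = c(6, 28))
  expect_equal(unname(coef(f5)["exponent"]), -1, tolerance = 1e-10)
  expect_equal(unname(coef(f5)["prefactor"]), 5, tolerance = 1e-8)

  # constant profile: exponent 0
  pc <- generate_power_law_profile(0, prefactor = 0.3, r_range = c(5, 30))
  expect_equal(daoud_cotton_fit(pc, window = c(6, 28))$exponent, 0,
               tolerance = 1e-12)

  # planted exponents at 1% multiplicative noise, 100 bins: |error| < 0.02
  for (alpha in c(-2, -4 / 3, -1, 0)) {
    pn <- generate_power_law_profile(alpha, r_range = c(10, 20.1),
                                     noise_sd = 0.01, seed = 3)
    fn <- daoud_cotton_fit(pn, window = c(10, 20))
    expect_lt(abs(fn$exponent - alpha), 0.02)
  }

  # doubling the prefactor doubles the fitted prefactor only
  pa <- generate_power_law_profile(-4 / 3, prefactor = 1,
                                   r_range = c(5, 30), noise_sd = 0.01,
                                   seed = 6)
  pb <- generate_power_law_profile(-4 / 3, prefactor = 2,
                                   r_range = c(5, 30), noise_sd = 0.01,
                                   seed = 6)
  fa <- daoud_cotton_fit(pa, c(6, 28)); fb <- daoud_cotton_fit(pb, c(6, 28))
  expect_equal(fb$exponent, fa$exponent, tolerance = 1e-10)
  expect_equal(unname(coef(fb)["prefactor"] / coef(fa)["prefactor"]), 2,
               tolerance = 1e-8)

  # too few positive bins is an error
  short <- generate_power_law_profile(-1, r_range = c(5, 5.4))
  expect_error(daoud_cotton_fit(short, c(5, 5.4)), ">= 5")
})

test_that("grafting density is chains per area with the documented cases", {
  # 360 chains on a 2.5 nm-radius sphere: about 4.6 chains/nm^2
  area <- 4 * pi * 2.5^2
  expect_equal(grafting_density(360, area), 4.584, tolerance = 1e-3)
  expect_equal(grafting_density(0, area), 0)
  # inversion: 50 chains at 2.3 chains/nm^2 implies ~21.7 nm^2
  expect_equal(50 / 2.3, 21.7, tolerance = 0.01)
  expect_error(grafting_density(10, 0), "> 0")
})
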