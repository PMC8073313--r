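test_that("extension plans scale both in-plane axes linearly", {
  p <- plan_extensions(c(30, 30), step_pct = 5, max_pct = 25)
  expect_equal(p$level_pct, c(0, 5, 10, 15, 20, 25))
  expect_equal(p$Lx[p$level_pct == 5], 31.5)
  expect_equal(p$area_ratio[p$level_pct == 25], 1.5625)
  expect_equal(p$area_ratio, (1 + p$level_pct / 100)^2)

  p1 <- plan_extensions(c(20, 40), step_pct = 5, max_pct = 5)
  expect_equal(nrow(p1), 2) # equilibrium + one level
  expect_error(plan_extensions(c(-1, 30)), "positive")
  expect_error(plan_extensions(c(30, 30), step_pct = 0), "step_pct")
  expect_error(plan_extensions(c(30, 30), step_pct = 10, max_pct = 5), "max_pct")
})

test_that("chain angles match the exact geometric oracles", {
  expect_equal(chain_angle(c(0, 0, 0), c(0, 0, 1)), 0)
  expect_equal(chain_angle(c(0, 0, 0), c(0, 0, -1)), 180)
  expect_equal(chain_angle(c(0, 0, 0), c(1, 0, 0)), 90)
  expect_equal(chain_angle(c(0, 0, 0), c(1, 0, 1)), 45)
  expect_equal(chain_angle(c(1, 2, 3), c(2, 2, 3 + sqrt(3))), 30, tolerance = 1e-10)
  expect_error(chain_angle(c(1, 1, 1), c(1, 1, 1)), "zero-length")
})

test_that("chain extension distances are Euclidean and rotation-invariant", {
  expect_equal(chain_extension_distance(c(0, 0, 0), c(0, 0, 1)), 1)
  expect_equal(chain_extension_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  set.seed(2)
  for (i in 1:5) {
    a <- rnorm(3)
    b <- rnorm(3)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    expect_equal(
      chain_extension_distance(R %*% a, R %*% b),
      chain_extension_distance(a, b),
      tolerance = 1e-12
    )
  }
})

test_that("angle distributions recover imposed laws and leaflet symmetry", {
  # delta law at 46 deg (off bin edges): all mass in the 46 and 134 bins
  tr <- gen_trajectory(
    n_lipids_per_leaflet = 32,
    angle_law = list(type = "delta", value = 46),
    n_frames = 3, seed = 2
  )
  ad <- angle_distribution(tr$frames, tr$topology)
  expect_equal(sum(ad$probability), 1, tolerance = 1e-12)
  hit <- ad$probability[abs(ad$mid - 46.25) < 1.3 | abs(ad$mid - 133.75) < 1.3]
  expect_equal(sum(hit), 1, tolerance = 1e-12)

  # folding merges the two lobes
  adf <- angle_distribution(tr$frames, tr$topology, fold = TRUE)
  expect_equal(sum(adf$probability[abs(adf$mid - 46.25) < 1.3]), 1, tolerance = 1e-12)

  # uniform law on [80, 100]: >= 99% of the mass in that range
  tru <- gen_trajectory(
    n_lipids_per_leaflet = 64,
    angle_law = list(type = "uniform", min = 80, max = 100),
    n_frames = 5, seed = 3
  )
  adu <- angle_distribution(tru$frames, tru$topology)
  expect_gte(sum(adu$probability[adu$bin_low >= 80 & adu$bin_high <= 100]), 0.99)

  # pooled symmetric leaflets: distribution symmetric about 90 degrees
  trs <- gen_trajectory(
    n_lipids_per_leaflet = 128,
    angle_law = list(type = "normal", mean = 30, sd = 10),
    n_frames = 10, seed = 4
  )
  ads <- angle_distribution(trs$frames, trs$topology)
  p <- ads$probability
  expect_lt(max(abs(p - rev(p))), 0.02) # sampling-error symmetric
  # per-leaflet selections land on opposite lobes
  up <- angle_distribution(trs$frames, trs$topology,
    selection = function(t) t[t$leaflet == "upper", ]
  )
  expect_lt(sum(up$probability[up$mid > 90]), 1e-6)
  expect_error(
    angle_distribution(trs$frames, trs$topology,
      selection = function(t) t[t$leaflet == "nope", ]
    ),
    "empty selection"
  )
})

test_that("distributions are invariant to frame order and lipid relabeling", {
  tr <- gen_trajectory(
    n_lipids_per_leaflet = 16,
    angle_law = list(type = "normal", mean = 40, sd = 15),
    n_frames = 4, seed = 6
  )
  a1 <- angle_distribution(tr$frames, tr$topology)
  a2 <- angle_distribution(rev(tr$frames), tr$topology)
  expect_equal(a1$probability, a2$probability)
  # relabel lipids (permute lipid_id values)
  top2 <- tr$topology
  perm <- sample(unique(top2$lipid_id))
  top2$lipid_id <- perm[top2$lipid_id]
  a3 <- angle_distribution(tr$frames, top2)
  expect_equal(a1$probability, a3$probability)
})

test_that("2D angle x distance histograms have exact marginals and find modes", {
  # bimodal distances at fixed in-plane angle: two separated modes
  tr <- gen_trajectory(
    n_lipids_per_leaflet = 64,
    angle_law = list(type = "delta", value = 90),
    distance_law = list(
      type = "mixture", weight1 = 0.5,
      mean1 = 0.55, sd1 = 0.02, mean2 = 0.95, sd2 = 0.02
    ),
    n_frames = 5, seed = 7
  )
  h <- angle_distance_histogram(tr$frames, tr$topology)
  expect_equal(sum(h$probability), 1, tolerance = 1e-12)

  # marginal over distance equals the 1D angle distribution
  ad <- angle_distribution(tr$frames, tr$topology)
  expect_equal(unname(rowSums(h$probability)), ad$probability, tolerance = 1e-12)

  dmarg <- colSums(h$probability)
  m1 <- sum(dmarg[h$dist_mid > 0.45 & h$dist_mid < 0.65])
  m2 <- sum(dmarg[h$dist_mid > 0.85 & h$dist_mid < 1.05])
  expect_gt(m1, 0.4)
  expect_gt(m2, 0.4)
  expect_lt(sum(dmarg[h$dist_mid >= 0.65 & h$dist_mid <= 0.85]), 0.05)

  # single conformation -> single nonzero cell
  tr1 <- gen_trajectory(
    n_lipids_per_leaflet = 8,
    angle_law = list(type = "delta", value = 90),
    distance_law = list(type = "delta", value = 1.23),
    n_frames = 1, seed = 8
  )
  h1 <- angle_distance_histogram(
    tr1$frames, tr1$topology,
    selection = function(t) t[t$leaflet == "upper", ]
  )
  expect_equal(sum(h1$probability > 0), 1)
})

test_that("surface tension follows the pressure anisotropy and Lz", {
  # isotropic pressure -> zero tension
  iso <- data.frame(
    time_ns = 1:10, Pxx_bar = 5, Pyy_bar = 5, Pzz_bar = 5, Lz_nm = 12
  )
  st0 <- surface_tension(iso)
  expect_equal(st0$gamma, 0)
  expect_equal(st0$stderr, 0)

  # constant anisotropy: gamma = 0.05 * Lz * dP mN/m (two interfaces)
  con <- data.frame(
    time_ns = 1:10, Pxx_bar = 1, Pyy_bar = 1, Pzz_bar = 101, Lz_nm = 10
  )
  expect_equal(surface_tension(con)$gamma, 50)
  expect_equal(surface_tension(con, per_interface = FALSE)$gamma, 100)

  # linear in anisotropy and in Lz
  for (f in c(0.5, 2, 3)) {
    scaled <- con
    scaled$Pzz_bar <- 1 + 100 * f
    expect_equal(surface_tension(scaled)$gamma, 50 * f)
    taller <- con
    taller$Lz_nm <- 10 * f
    expect_equal(surface_tension(taller)$gamma, 50 * f)
  }

  # stretched membranes give positive tension by sign convention
  expect_gt(surface_tension(con)$gamma, 0)

  expect_error(surface_tension(con[1, ]), ">= 2")
  expect_error(surface_tension(con[1:3, ], n_blocks = 5), "5-block")
})

test_that("a noisy synthetic pressure series recovers its target tension", {
  ser <- gen_pressure_series(5, Lz = 10, noise_sd = 100, n = 10000, seed = 12)
  st <- surface_tension(ser)
  expect_lt(abs(st$gamma - 5), 2 * st$stderr)

  exact <- gen_pressure_series(0, noise_sd = 0, n = 100, seed = 1)
  expect_equal(surface_tension(exact)$gamma, 0)
})

test_that("area per lipid scales with the box and extension level", {
  expect_equal(area_per_lipid(c(30, 30), 1500), 0.6)
  expect_equal(area_per_lipid(c(60, 60), 1500), 4 * 0.6)
  p <- plan_extensions(c(30, 30), 5, 25)
  apl0 <- area_per_lipid(c(p$Lx[1], p$Ly[1]), 1500)
  apl25 <- area_per_lipid(c(p$Lx[6], p$Ly[6]), 1500)
  expect_equal(apl25 / apl0, 1.5625)
  expect_error(area_per_lipid(c(30, 30), 0), "> 0")
})

test_that("trajectory and pressure tables round-trip through plain text", {
  tr <- gen_trajectory(
    n_lipids_per_leaflet = 4, n_frames = 2, seed = 3,
    angle_law = list(type = "normal", mean = 30, sd = 5)
  )
  f <- tempfile(fileext = ".csv")
  write_trajectory_table(tr$frames, f)
  back <- read_trajectory_table(f)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$coordinates, tr$frames[[1]]$coordinates, tolerance = 1e-6)
  expect_equal(back[[2]]$box, tr$frames[[2]]$box)
  unlink(f)

  ser <- gen_pressure_series(3, n = 50, seed = 5)
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(ser), f2, row.names = FALSE)
  ser2 <- read_pressure_series(f2)
  expect_equal(surface_tension(ser2)$gamma, surface_tension(ser)$gamma, tolerance = 1e-8)
  unlink(f2)
})

test_that("minimal GRO files parse into a trajectory frame", {
  atoms <- sprintf(
    "%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
    1:4, "DPPC", c("GL1", "C1A", "C2A", "C3A"), 1:4,
    c(1.0, 1.1, 1.2, 1.3), c(2.0, 2.0, 2.1, 2.1), c(5.0, 4.8, 4.6, 4.4)
  )
  lines <- c(
    "synthetic membrane frame",
    "    4",
    atoms,
    "  10.00000  10.00000  10.00000"
  )
  f <- tempfile(fileext = ".gro")
  writeLines(lines, f)
  fr <- read_gro(f)
  expect_equal(dim(fr$coordinates), c(4L, 3L))
  expect_equal(fr$coordinates[1, ], c(1.0, 2.0, 5.0))
  expect_equal(fr$box, c(10, 10, 10))
  expect_equal(attr(fr, "atoms")$atom_name[2], "C1A")
  unlink(f)
})
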