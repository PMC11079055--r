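# Geometry metrics: principal axis, orientation angle, side-chain COM
# distances, length proxy, metric series and replicate pooling.

make_line_frame <- function(jitter_sd = 0.05, seed = 4, flip_z = FALSE) {
  rng <- local_rng(seed)
  n <- 30L
  z <- seq(-15, 15, length.out = n)
  xy <- matrix(rng$rnorm(2 * n, 0, jitter_sd), ncol = 2)
  atoms <- data.frame(
    chain_id = "A", resseq = seq_len(n), resname = "ALA",
    atom_name = "CA", element = "C",
    x = xy[, 1], y = xy[, 2], z = if (flip_z) -z else z,
    stringsAsFactors = FALSE)
  # reference residue at the top (or, mirrored, at the bottom)
  atoms$resseq[n] <- 67L
  structure_frame(atoms)
}

test_that("principal axis of a z-aligned cloud is (0,0,1), sign by His67", {
  f <- make_line_frame()
  ax <- principal_axis(f)
  expect_equal(sqrt(sum(ax$axis^2)), 1, tolerance = 1e-9)
  expect_gt(abs(ax$axis[3]), cos(5 * pi / 180))
  expect_gt(ax$axis[3], 0)  # His67 sits at +z
  # mirroring in z flips the axis to keep the reference positive
  f2 <- make_line_frame(flip_z = TRUE)
  ax2 <- principal_axis(f2)
  expect_lt(ax2$axis[3], 0)
})

test_that("principal axis equals an independent eigen-decomposition", {
  rng <- local_rng(19)
  for (rep in 1:5) {
    n <- 40L
    xyz <- cbind(rng$rnorm(n, 0, 1), rng$rnorm(n, 0, 2.5),
                 rng$rnorm(n, 0, 7))
    atoms <- data.frame(chain_id = "A", resseq = seq_len(n),
                        resname = "ALA", atom_name = "CA", element = "C",
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        stringsAsFactors = FALSE)
    atoms$resseq[which.max(xyz[, 3])] <- 67L
    f <- structure_frame(atoms)
    ax <- principal_axis(f)
    # independent: SVD of centred coordinates
    cxyz <- scale(xyz, scale = FALSE)
    v <- svd(cxyz)$v[, 1]
    if (sum((xyz[which.max(xyz[, 3]), ] - colMeans(xyz)) * v) < 0) v <- -v
    expect_lt(max(abs(ax$axis - v)), 1e-9)
  }
})

test_that("degenerate selections raise the documented errors", {
  atoms <- data.frame(chain_id = "A", resseq = 1:2, resname = "ALA",
                      atom_name = "CA", element = "C",
                      x = c(0, 1), y = 0, z = 0, stringsAsFactors = FALSE)
  expect_error(principal_axis(structure_frame(atoms)), "at least 3")
  # isotropic cloud: two leading eigenvalues equal -> ambiguity
  ring <- data.frame(chain_id = "A", resseq = 1:4, resname = "ALA",
                     atom_name = "CA", element = "C",
                     x = c(1, -1, 0, 0), y = c(0, 0, 1, -1), z = 0,
                     stringsAsFactors = FALSE)
  ring$resseq[1] <- 67L
  expect_error(principal_axis(structure_frame(ring)), "ambiguous")
})

make_angle_frame <- function(mid_offset) {
  # z-aligned backbone plus a HIS at the centre whose ND1/NE2 midpoint
  # sits at CA + mid_offset
  rng <- local_rng(2)
  n <- 20L
  spine <- data.frame(chain_id = "A", resseq = seq_len(n) + 200L,
                      resname = "ALA", atom_name = "CA", element = "C",
                      x = rng$rnorm(n, 0, 0.01), y = rng$rnorm(n, 0, 0.01),
                      z = seq(-10, 10, length.out = n),
                      stringsAsFactors = FALSE)
  spine$resseq[n] <- 67L
  his <- data.frame(chain_id = "A", resseq = 122L, resname = "HIS",
                    atom_name = c("CA", "ND1", "NE2"),
                    element = c("C", "N", "N"),
                    x = c(0, mid_offset[1] + 0.4, mid_offset[1] - 0.4),
                    y = c(0, mid_offset[2], mid_offset[2]),
                    z = c(0, mid_offset[3], mid_offset[3]),
                    stringsAsFactors = FALSE)
  structure_frame(rbind(spine, his))
}

test_that("orientation angle: perpendicular gives 90, axial gives 0", {
  f90 <- make_angle_frame(c(3, 0, 0))
  ax <- principal_axis(f90)
  expect_equal(residue_orientation_angle(f90, ax, "A", 122), 90,
               tolerance = 0.2)
  f0 <- make_angle_frame(c(0, 0, 3))  # toward the CAP (+axis)
  ax0 <- principal_axis(f0)
  expect_equal(residue_orientation_angle(f0, ax0, "A", 122), 0,
               tolerance = 0.2)
  # missing pair atom errors name the residue and atom
  f_bad <- f90
  f_bad$atoms <- f_bad$atoms[f_bad$atoms$atom_name != "NE2", ]
  expect_error(residue_orientation_angle(f_bad, ax, "A", 122), "NE2")
})

test_that("1000 random placements match an independent computation", {
  rng <- local_rng(33)
  axis <- c(0, 0, 1)
  axisframe <- structure(list(axis = axis, origin = c(0, 0, 0)),
                         class = "AxisFrame")
  max_err <- 0
  for (i in 1:1000) {
    xyz <- matrix(rng$runif(9, -5, 5), 3, 3)
    atoms <- data.frame(chain_id = "A", resseq = 122L, resname = "HIS",
                        atom_name = c("CA", "ND1", "NE2"),
                        element = c("C", "N", "N"),
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        stringsAsFactors = FALSE)
    f <- structure_frame(atoms)
    got <- residue_orientation_angle(f, axisframe, "A", 122)
    want <- oracle_angle(axis, xyz[1, ], xyz[2, ], xyz[3, ])
    max_err <- max(max_err, abs(got - want))
    # pair order must not matter: swap ND1/NE2 coordinates
    atoms2 <- atoms
    atoms2[2:3, c("x", "y", "z")] <- atoms[3:2, c("x", "y", "z")]
    got2 <- residue_orientation_angle(structure_frame(atoms2), axisframe,
                                      "A", 122)
    expect_equal(got2, got, tolerance = 1e-9)
  }
  expect_lt(max_err, 1e-9)
})

test_that("side-chain COM distance: trivial and oracle cases", {
  # two single-atom side chains 3-4-5 apart
  atoms <- data.frame(
    chain_id = "A", resseq = c(1L, 1L, 2L, 2L),
    resname = c("SER", "SER", "SER", "SER"),
    atom_name = c("CA", "OG", "CA", "OG"),
    element = c("C", "O", "C", "O"),
    x = c(0, 0, 1, 3), y = c(0, 0, 1, 4), z = 0,
    stringsAsFactors = FALSE)
  f <- structure_frame(atoms)
  expect_equal(sidechain_com_distance(f, c("A", 1), c("A", 2)), 5)
  expect_equal(sidechain_com_distance(f, c("A", 2), c("A", 1)), 5)
  # identical side-chain coordinates -> 0
  atoms0 <- atoms
  atoms0$x[4] <- 0; atoms0$y[4] <- 0
  expect_equal(sidechain_com_distance(structure_frame(atoms0),
                                      c("A", 1), c("A", 2)), 0)
  # glycine has no side-chain heavy atom
  gly <- data.frame(chain_id = "A", resseq = 3L, resname = "GLY",
                    atom_name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
                    x = 1:4, y = 0, z = 0, stringsAsFactors = FALSE)
  f_gly <- structure_frame(rbind(atoms, gly))
  expect_error(sidechain_com_distance(f_gly, c("A", 1), c("A", 3)),
               "no side-chain heavy atoms")
})

test_that("multi-atom COM distances match a hand-computed oracle", {
  rng <- local_rng(45)
  for (rep in 1:200) {
    f <- random_geometry_frame(rng)
    got <- sidechain_com_distance(f, c("A", 1), c("A", 2))
    a <- oracle_sidechain_com(f, "A", 1L)
    b <- oracle_sidechain_com(f, "A", 2L)
    expect_equal(got, sqrt(sum((a - b)^2)), tolerance = 1e-9)
  }
})

test_that("length proxy is the plain Calpha-Calpha norm, translation-invariant", {
  rng <- local_rng(52)
  for (rep in 1:200) {
    f <- random_geometry_frame(rng)
    got <- channel_length_proxy(f)
    a <- f$atoms
    p <- as.numeric(a[a$resseq == 67 & a$atom_name == "CA",
                      c("x", "y", "z")])
    q <- as.numeric(a[a$resseq == 171 & a$atom_name == "CA",
                      c("x", "y", "z")])
    expect_equal(got, sqrt(sum((p - q)^2)), tolerance = 1e-12)
  }
  f <- random_geometry_frame(rng)
  d0 <- channel_length_proxy(f)
  f$atoms$x <- f$atoms$x + 11.3
  f$atoms$y <- f$atoms$y - 4.2
  expect_equal(channel_length_proxy(f), d0, tolerance = 1e-12)
  # separation on z of exactly 10
  f10 <- f
  f10$atoms[f10$atoms$resseq == 67, c("x", "y", "z")] <- rep(c(0, 0, 10), each = 1)
  f10$atoms[f10$atoms$resseq == 171, c("x", "y", "z")] <- rep(c(0, 0, 0), each = 1)
  expect_equal(channel_length_proxy(f10), 10)
})

test_that("all metrics are rigid-motion invariant", {
  rng <- local_rng(61)
  f <- build_toy_channel()
  ax <- principal_axis(f)
  angle0 <- residue_orientation_angle(f, ax, "A", 122)
  dist0 <- sidechain_com_distance(f, c("A", 235), c("B", 246))
  len0 <- channel_length_proxy(f)
  for (rep in 1:10) {
    g <- apply_rigid_motion(f, rng)
    axg <- principal_axis(g)
    expect_equal(residue_orientation_angle(g, axg, "A", 122), angle0,
                 tolerance = 1e-6)
    expect_equal(sidechain_com_distance(g, c("A", 235), c("B", 246)),
                 dist0, tolerance = 1e-6)
    expect_equal(channel_length_proxy(g), len0, tolerance = 1e-6)
  }
})

test_that("metric series masks pre-cutoff frames and pools replicates", {
  base <- build_toy_channel()
  frames <- lapply(0:99, function(i) {
    f <- base
    f$time_ns <- i
    f
  })
  tr <- trajectory(frames, condition = list(pH_label = "high",
                                            variant = "WT",
                                            replicate_id = "t1"))
  # constant metric -> replicate average equals the constant
  s_const <- metric_series(tr, function(fr, ch) 5.0)
  ra <- replicate_averages(s_const, "subunit")
  expect_equal(nrow(ra), 2L)  # one per subunit
  expect_equal(ra$mean_value, c(5, 5))
  expect_setequal(ra$replicate, c("t1.A", "t1.B"))
  # step metric: 1 before 50 ns, 3 after -> masked mean is 3
  s_step <- metric_series(tr, function(fr, ch) if (fr$time_ns < 50) 1 else 3)
  expect_equal(replicate_averages(s_step, "subunit")$mean_value, c(3, 3))
  # channel pooling gives one replicate per trajectory
  s_len <- metric_series(tr, "length")
  ra_len <- replicate_averages(s_len, "channel")
  expect_equal(nrow(ra_len), 1L)
  expect_equal(ra_len$replicate, "t1")
  # all frames pre-cutoff is an error
  s_bad <- metric_series(tr, function(fr, ch) 1,
                         equilibration_cutoff_ns = 1000)
  expect_error(replicate_averages(s_bad), "before the equilibration cutoff")
})

test_that("masked replicate means match a scripted recomputation", {
  cfg <- preset_config("high_pH_WT", n_frames = 120, seed = 88)
  tr <- simulate_conformational_trajectory(cfg)
  s <- metric_series(tr, function(fr, ch)
    sidechain_com_distance(fr, c(ch, 122), c(ch, 235)),
    equilibration_cutoff_ns = 50)
  ra <- replicate_averages(s, "subunit")
  for (ch in c("A", "B")) {
    manual <- mean(s$value[s$subunit == ch & s$time_ns >= 50])
    expect_equal(ra$mean_value[grepl(paste0("\\.", ch, "$"),
                                     ra$replicate)], manual)
  }
})
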