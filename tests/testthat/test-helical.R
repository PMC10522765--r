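# Base frames, step parameters, grooves and torsions.

test_that("base frames recover imposed rigid transforms", {
  tpl <- nuctraj:::BASE_TEMPLATES$G
  f0 <- base_reference_frame(tpl$coords, tpl$atoms, "G")
  expect_equal(f0$origin, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(f0$axes, diag(3), tolerance = 1e-9)
  R <- rot_axis_test(c(2, -1, 3), 55)
  tr <- c(4, -7, 2)
  moved <- sweep(tpl$coords %*% t(R), 2, tr, "+")
  f1 <- base_reference_frame(moved, tpl$atoms, "G")
  expect_equal(f1$axes, R, tolerance = 1e-9)
  expect_equal(f1$origin, tr, tolerance = 1e-9)
  expect_error(base_reference_frame(tpl$coords[1:4, ], tpl$atoms[1:4], "G"),
               "missing ring atom")
})

test_that("builder round trip recovers all six step parameters to 1e-6", {
  set.seed(71)
  for (rep in 1:20) {
    n <- 6
    sp <- tibble::tibble(
      shift = runif(n - 1, -2, 2), slide = runif(n - 1, -2, 2),
      rise = runif(n - 1, 2.5, 4), tilt = runif(n - 1, -15, 15),
      roll = runif(n - 1, -15, 15), twist = runif(n - 1, 20, 45))
    d <- build_ideal_duplex(duplex_spec("ACGTAC", "B_DNA", step_params = sp))
    ps <- pair_and_step_parameters(d$system, d$coords, d$pairing)
    err <- max(abs(as.matrix(ps$steps[, -1]) - as.matrix(sp)))
    expect_lt(err, 1e-6)
  }
})

test_that("form presets measure back to their defining parameters", {
  dB <- build_ideal_duplex(duplex_spec("ACGTACGTAC", "B_DNA"))
  psB <- pair_and_step_parameters(dB$system, dB$coords, dB$pairing)
  expect_equal(psB$steps$twist, rep(36, 9), tolerance = 1e-6)
  expect_equal(psB$steps$rise, rep(3.38, 9), tolerance = 1e-6)
  expect_equal(psB$pairs$x_displacement, rep(0, 10), tolerance = 1e-6)
  dA <- build_ideal_duplex(duplex_spec("ACGUACGUAC", "A_RNA"))
  psA <- pair_and_step_parameters(dA$system, dA$coords, dA$pairing)
  expect_equal(psA$steps$twist, rep(32.7, 9), tolerance = 1e-6)
  expect_equal(psA$steps$rise, rep(2.81, 9), tolerance = 1e-6)
  expect_equal(psA$steps$roll, rep(8, 9), tolerance = 1e-6)
  expect_equal(psA$pairs$x_displacement, rep(-4, 10), tolerance = 1e-6)
})

test_that("propeller twist round-trips through the pair construction", {
  pp <- tibble::tibble(propeller = rep(-14, 6), x_displacement = 0)
  d <- build_ideal_duplex(duplex_spec("ACGTAC", "B_DNA", pair_params = pp))
  ps <- pair_and_step_parameters(d$system, d$coords, d$pairing)
  expect_equal(ps$pairs$propeller, rep(-14, 6), tolerance = 1e-6)
  # base z-axes differ by the imposed propeller
  at <- d$system$atoms
  sel1 <- which(at$res_index == 3)
  sel2 <- which(at$res_index == d$pairing$strand2[3])
  f1 <- base_reference_frame(d$coords[sel1, , drop = FALSE], at$name[sel1],
                             "G")
  f2 <- base_reference_frame(d$coords[sel2, , drop = FALSE], at$name[sel2],
                             "C")
  ang <- acos(min(max(-sum(f1$axes[, 3] * f2$axes[, 3]), -1), 1)) * 180 / pi
  expect_equal(ang, 14, tolerance = 1e-6)
})

test_that("pure-rise steps have zero rotational parameters", {
  sp <- tibble::tibble(shift = 0, slide = 0, rise = 3.4, tilt = 0, roll = 0,
                       twist = 0)
  d <- build_ideal_duplex(duplex_spec("AT", "B_DNA", step_params = sp))
  ps <- pair_and_step_parameters(d$system, d$coords, d$pairing)
  expect_equal(abs(ps$steps$twist), 0, tolerance = 1e-9)
  expect_equal(abs(ps$steps$roll), 0, tolerance = 1e-9)
  expect_equal(abs(ps$steps$tilt), 0, tolerance = 1e-9)
  expect_equal(ps$steps$rise, 3.4, tolerance = 1e-9)
})

test_that("all parameters are rigid-motion invariant", {
  d <- build_ideal_duplex(duplex_spec("ACGTAC", "B_DNA"))
  ps <- pair_and_step_parameters(d$system, d$coords, d$pairing)
  g0 <- groove_geometry(d$system, d$coords, d$pairing)
  moved <- sweep(d$coords %*% t(rot_axis_test(c(1, 2, -1), 67)), 2,
                 c(15, -8, 3), "+")
  ps2 <- pair_and_step_parameters(d$system, moved, d$pairing)
  g2 <- groove_geometry(d$system, moved, d$pairing)
  expect_equal(as.matrix(ps$steps), as.matrix(ps2$steps), tolerance = 1e-9)
  expect_equal(ps$pairs$x_displacement, ps2$pairs$x_displacement,
               tolerance = 1e-9)
  expect_equal(g0$width, g2$width, tolerance = 1e-9)
  expect_equal(g0$depth, g2$depth, tolerance = 1e-9)
})

test_that("strand relabelling flips shift and tilt only", {
  set.seed(72)
  sp <- tibble::tibble(
    shift = runif(5, -1, 1), slide = runif(5, -1, 1),
    rise = runif(5, 3, 3.6), tilt = runif(5, -8, 8),
    roll = runif(5, -8, 8), twist = runif(5, 30, 40))
  d <- build_ideal_duplex(duplex_spec("ACGTAC", "B_DNA", step_params = sp))
  ps <- pair_and_step_parameters(d$system, d$coords, d$pairing)
  # relabel: strand II becomes the reference, levels reversed
  n <- nrow(d$pairing)
  flipped <- tibble::tibble(strand1 = rev(d$pairing$strand2),
                            strand2 = rev(d$pairing$strand1))
  ps2 <- pair_and_step_parameters(d$system, d$coords, flipped)
  s1 <- ps$steps
  s2 <- ps2$steps[rev(seq_len(n - 1)), ]
  expect_equal(s2$shift, -s1$shift, tolerance = 1e-6)
  expect_equal(s2$tilt, -s1$tilt, tolerance = 1e-6)
  expect_equal(s2$slide, s1$slide, tolerance = 1e-6)
  expect_equal(s2$rise, s1$rise, tolerance = 1e-6)
  expect_equal(s2$roll, s1$roll, tolerance = 1e-6)
  expect_equal(s2$twist, s1$twist, tolerance = 1e-6)
})

test_that("B-form grooves: minor narrower than major at interior levels", {
  d <- build_ideal_duplex(duplex_spec("ACGTACGTACGT", "B_DNA"))
  g <- groove_geometry(d$system, d$coords, d$pairing)
  wide <- tidyr::pivot_wider(g, names_from = "groove",
                             values_from = c("width", "depth"))
  interior <- wide[!is.na(wide$width_minor) & !is.na(wide$width_major), ]
  expect_gt(nrow(interior), 3)
  expect_true(all(interior$width_minor < interior$width_major))
  expect_true(all(g$width >= 0))
})

test_that("A-form major groove is deeper and narrower than B-form's", {
  dB <- build_ideal_duplex(duplex_spec("ACGTACGTACGT", "B_DNA"))
  dA <- build_ideal_duplex(duplex_spec("ACGUACGUACGU", "A_RNA"))
  gB <- groove_geometry(dB$system, dB$coords, dB$pairing)
  gA <- groove_geometry(dA$system, dA$coords, dA$pairing)
  mB <- gB[gB$groove == "major" & gB$level == 6, ]
  mA <- gA[gA$groove == "major" & gA$level == 6, ]
  expect_lt(mA$width, mB$width)
  expect_gt(mA$depth, mB$depth)
})

test_that("torsion angles follow the standard sign conventions", {
  # four coplanar atoms: cis = 0, trans = 180
  expect_equal(dihedral_angle(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(2, 1, 0)), 0)
  expect_equal(abs(dihedral_angle(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                  c(2, -1, 0))), 180)
  d <- build_ideal_duplex(duplex_spec("ACGTAC", "B_DNA"))
  traj <- traj_ensemble(d$system, matrix(as.numeric(t(d$coords)), 1))
  tor <- backbone_torsions(traj)
  expect_setequal(unique(tor$angle),
                  c("alpha", "beta", "gamma", "delta", "epsilon", "zeta",
                    "chi"))
  # 5'-terminal residues lack a phosphate: alpha/beta undefined there
  expect_true(all(is.na(tor$value[tor$angle == "alpha" &
                                  tor$res_index == 1])))
  expect_true(all(!is.na(tor$value[tor$angle == "delta"])))
  # mirror image flips every defined torsion's sign
  mirrored <- d$coords %*% diag(c(1, 1, -1))
  traj_m <- traj_ensemble(d$system, matrix(as.numeric(t(mirrored)), 1))
  tor_m <- backbone_torsions(traj_m)
  ok <- !is.na(tor$value)
  expect_equal(tor_m$value[ok], -tor$value[ok], tolerance = 1e-9)
})

test_that("series summaries use circular statistics for angles", {
  series <- tibble::tibble(
    frame = rep(1:2, each = 2),
    step = rep(1:2, 2),
    parameter = "twist",
    value = c(179, 25, -179, 45))
  sm <- parameter_series_summary(series, "step")
  tw1 <- sm$summary[sm$summary$position == 1, ]
  expect_equal(abs(tw1$mean), 180, tolerance = 1e-9)  # not 0
  tw2 <- sm$summary[sm$summary$position == 2, ]
  expect_equal(tw2$mean, 35, tolerance = 1e-9)
  # constant series: SD 0, single occupied bin
  const <- tibble::tibble(frame = 1:5, step = 1, parameter = "rise",
                          value = rep(3.38, 5))
  smc <- parameter_series_summary(const, "step", n_bins = 10)
  expect_equal(smc$summary$sd, 0)
  expect_equal(sum(smc$histogram$count > 0), 1)
  # two-state series: visibly bimodal histogram
  two <- tibble::tibble(frame = 1:100, step = 1, parameter = "twist",
                        value = rep(c(25, 45), 50))
  smt <- parameter_series_summary(two, "step", n_bins = 10)
  occ <- smt$histogram$count > 0
  expect_equal(sum(occ), 2)
})
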