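# Pairwise energies, group sums, and the specific/nonspecific decomposition.

test_that("pair energies match the analytic forms", {
  # neutral pair: zero Coulomb at any distance
  expect_equal(pair_energy(5, 0, 0, 3.4, 0.1)$coulomb, 0)
  # opposite unit charges at 3 A
  expect_equal(pair_energy(3, 1, -1, 3.4, 0.1)$coulomb, -332.0637 / 3)
  # LJ minimum: r = 2^(1/6) sigma gives exactly -epsilon
  expect_equal(pair_energy(2^(1 / 6) * 3.2, 0, 0, 3.2, 0.37)$lj, -0.37)
  expect_error(pair_energy(0, 1, 1, 3, 0.1), "positive")
})

make_energy_toy <- function() {
  fx <- make_probe_fixture(n_frames = 3)
  sys <- load_parameters(fx$system, fx$param_table)
  traj <- fx$traj
  traj$system <- sys
  list(system = sys, traj = traj)
}

test_that("group energies match the O(N^2) double-loop oracle", {
  toy <- make_energy_toy()
  coords <- frame_coords(toy$traj, 1)
  pro <- select_atoms(toy$system, polymer = "protein")
  nuc <- select_atoms(toy$system, polymer = "nucleic")
  expect_lte(n_atoms(toy$system), 500)
  mine <- group_interaction_energy(coords, toy$system,
                                   group_pair_spec("x", pro, nuc, 10))
  oracle <- oracle_group_energy(coords, toy$system, pro, nuc, 10)
  expect_equal(mine[["coulomb"]], oracle[["coulomb"]], tolerance = 1e-9)
  expect_equal(mine[["lj"]], oracle[["lj"]], tolerance = 1e-9)
  # and at a different cutoff
  mine2 <- group_interaction_energy(coords, toy$system,
                                    group_pair_spec("x", pro, nuc, 6))
  oracle2 <- oracle_group_energy(coords, toy$system, pro, nuc, 6)
  expect_equal(mine2[["coulomb"]], oracle2[["coulomb"]], tolerance = 1e-9)
})

test_that("pairs beyond the cutoff contribute nothing", {
  atoms <- tibble::tibble(
    name = c("NZ", "OP1"), element = c("N", "O"),
    resname = c("LYS", "DA"), resid = 1:2, chain = c("P", "B"))
  sys <- classify_atoms(mol_system(atoms))
  sys$atoms$charge <- c(1, -1)
  sys$atoms$lj_sigma <- c(3.25, 2.96)
  sys$atoms$lj_epsilon <- c(0.17, 0.21)
  sys$atoms$mass <- c(14, 16)
  coords <- rbind(c(0, 0, 0), c(12, 0, 0))
  spec <- group_pair_spec("far", 1, 2, 10)
  expect_equal(unname(group_interaction_energy(coords, sys, spec)), c(0, 0))
  # inside the cutoff the same pair interacts
  coords[2, 1] <- 3
  e <- group_interaction_energy(coords, sys, spec)
  expect_lt(e[["coulomb"]], 0)
})

test_that("Coulomb is bilinear in charge; LJ is charge-independent", {
  toy <- make_energy_toy()
  coords <- frame_coords(toy$traj, 1)
  pro <- select_atoms(toy$system, polymer = "protein")
  nuc <- select_atoms(toy$system, polymer = "nucleic")
  spec <- group_pair_spec("x", pro, nuc, 10)
  e1 <- group_interaction_energy(coords, toy$system, spec)
  doubled <- toy$system
  doubled$atoms$charge <- 2 * doubled$atoms$charge
  e2 <- group_interaction_energy(coords, doubled, spec)
  expect_equal(e2[["coulomb"]], 4 * e1[["coulomb"]], tolerance = 1e-12)
  expect_equal(e2[["lj"]], e1[["lj"]], tolerance = 1e-12)
})

test_that("role decomposition partitions the interface energy", {
  toy <- make_energy_toy()
  ed <- decompose_interaction_energy(toy$traj, 10)
  expect_s3_class(ed$per_frame, "tbl_df")
  # the three group pairings partition all protein-nucleic pairs: their sum
  # equals the all-protein x all-nucleic energy
  coords <- frame_coords(toy$traj, 1)
  pro <- select_atoms(toy$system, polymer = "protein")
  nuc <- select_atoms(toy$system, polymer = "nucleic")
  full <- group_interaction_energy(coords, toy$system,
                                   group_pair_spec("all", pro, nuc, 10))
  f1 <- ed$per_frame[ed$per_frame$frame == 1, ]
  expect_equal(f1$coulomb[f1$group == "total"], full[["coulomb"]],
               tolerance = 1e-9)
  expect_equal(f1$lj[f1$group == "total"], full[["lj"]], tolerance = 1e-9)
  # the only charged probe atom is Lys NZ vs phosphates: all Coulomb lands in
  # the backbone-vs-protein pairing
  expect_equal(f1$coulomb[f1$group == "specific"], 0, tolerance = 1e-9)
  expect_equal(
    f1$coulomb[f1$group == "nonspecific_proteinbackbone_vs_bases"], 0,
    tolerance = 1e-9)
  expect_lt(f1$coulomb[f1$group == "nonspecific_backbone_vs_protein"], 0)
})

test_that("energies are rigid-motion invariant and frozen SDs vanish", {
  toy <- make_energy_toy()
  coords <- frame_coords(toy$traj, 1)
  pro <- select_atoms(toy$system, polymer = "protein")
  nuc <- select_atoms(toy$system, polymer = "nucleic")
  spec <- group_pair_spec("x", pro, nuc, 10)
  e1 <- group_interaction_energy(coords, toy$system, spec)
  moved <- sweep(coords %*% t(rot_axis_test(c(1, 1, 0), 73)), 2,
                 c(10, -4, 2), "+")
  e2 <- group_interaction_energy(moved, toy$system, spec)
  expect_equal(e1, e2, tolerance = 1e-9)
  # frozen trajectory: SD identically zero
  frozen <- traj_ensemble(toy$system,
                          toy$traj$xyz[c(1, 1, 1), , drop = FALSE])
  ed <- decompose_interaction_energy(frozen, 10)
  expect_true(all(ed$summary$sd == 0))
})

test_that("unparameterized atoms abort the energy evaluation", {
  fx <- make_probe_fixture(n_frames = 2)
  stripped <- fx$traj
  stripped$system$atoms$charge <- NA_real_
  expect_error(decompose_interaction_energy(stripped, 10), "unparameterized")
})
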