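# Topology/trajectory data model, PDB I/O, classification, superposition.

glycine_pdb_text <- c(
  "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   GLY A   1       2.009   1.420   0.000  1.00  0.00           C",
  "ATOM      4  O   GLY A   1       1.251   2.390   0.000  1.00  0.00           O",
  "ATOM      5  OXT GLY A   1       3.246   1.540   0.100  1.00  0.00           O",
  "ATOM      6  H   GLY A   1      -0.500  -0.850   0.000  1.00  0.00           H",
  "ATOM      7  HA2 GLY A   1       1.800  -0.520   0.880  1.00  0.00           H",
  "END")

write_glycine_pdb <- function(path) {
  writeLines(glycine_pdb_text, path)
  path
}

test_that("single-residue PDB reads back identically", {
  path <- write_glycine_pdb(withr::local_tempfile(fileext = ".pdb"))
  st <- read_structure(path)
  expect_equal(n_atoms(st$system), 7)
  expect_equal(nrow(st$system$residues), 1)
  expect_equal(st$system$residues$polymer, "protein")
  expect_equal(st$system$atoms$name,
               c("N", "CA", "C", "O", "OXT", "H", "HA2"))
  expect_equal(st$coords[2, ], c(1.458, 0, 0))
  # charges/LJ unset: reading never invents physics
  expect_true(all(is.na(st$system$atoms$charge)))
})

test_that("polymer kind is assigned per residue from name tables", {
  dup <- build_ideal_duplex(duplex_spec("ACGT", "B_DNA"))
  sched <- contact_schedule_entry("salt_bridge", 3, "OP1", TRUE)
  pc <- make_probe_complex(dup, sched)
  pk <- pc$system$residues$polymer
  expect_equal(sum(pk == "nucleic"), 8)
  expect_equal(sum(pk == "protein"), 1)
})

test_that("unknown residues get polymer kind 'other' with a warning", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  C1  XYZ A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  C2  XYZ A   1       1.500   0.000   0.000  1.00  0.00           C",
    "END"), path)
  expect_warning(st <- read_structure(path), "other")
  expect_equal(st$system$residues$polymer, "other")
})

test_that("trajectory read/write round-trips to PDB precision", {
  dup <- build_ideal_duplex(duplex_spec("ACGT", "B_DNA"))
  xyz <- rbind(coords_to_xyz_test(dup$coords),
               coords_to_xyz_test(dup$coords + 0.25),
               coords_to_xyz_test(dup$coords - 1.5))
  traj <- traj_ensemble(dup$system, xyz)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(dup$system, traj, path)
  back <- read_trajectory(path, dup$system)
  expect_equal(n_frames(back), 3)
  expect_lt(max(abs(back$xyz - traj$xyz)), 1e-3 + 1e-9)
  # atom order and residue identity preserved
  st <- read_structure(path)
  expect_equal(st$system$atoms$name, dup$system$atoms$name)
  expect_equal(st$system$atoms$resname, dup$system$atoms$resname)
})

test_that("atom-count mismatch names the offending model", {
  path <- write_glycine_pdb(withr::local_tempfile(fileext = ".pdb"))
  st <- read_structure(path)
  bad <- withr::local_tempfile(fileext = ".pdb")
  lines <- c("MODEL     1", glycine_pdb_text[1:7], "ENDMDL",
             "MODEL     2", glycine_pdb_text[1:6], "ENDMDL", "END")
  writeLines(lines, bad)
  expect_error(read_trajectory(bad, st$system), "model 2: 6 atoms, expected 7")
})

test_that("load_parameters fills every atom or reports all missing pairs", {
  dup <- build_ideal_duplex(duplex_spec("ACGTAC", "B_DNA"))
  sys <- load_parameters(dup$system, dup$param_table)
  expect_false(anyNA(sys$atoms$charge))
  expect_false(anyNA(sys$atoms$lj_sigma))
  # net charge of a strand = -(number of phosphates)
  s1 <- sys$atoms$charge[sys$atoms$chain == "B"]
  expect_equal(sum(s1), -5, tolerance = 1e-6)
  # missing entry -> aggregated error naming the pair
  tab <- dup$param_table[!(dup$param_table$resname == "DA" &
                           dup$param_table$atom == "N1"), ]
  expect_error(load_parameters(dup$system, tab), "DA N1")
})

test_that("atom roles partition protein and nucleic residues correctly", {
  dup <- build_ideal_duplex(duplex_spec("CAGT", "B_DNA"))
  a <- dup$system$atoms
  # adenosine split: backbone = phosphate + sugar; base = ring + exocyclic
  ade <- a[a$res_index == 2 & a$resname == "DA", ]  # res 2 has a phosphate
  expect_setequal(ade$name[ade$role == "nucleic_backbone"],
                  c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'",
                    "O3'", "C2'", "C1'"))
  expect_setequal(ade$name[ade$role == "base"],
                  c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3",
                    "C4"))
  # every protein/nucleic atom has exactly one non-other role
  sched <- contact_schedule_entry("salt_bridge", 3, "OP1", TRUE)
  pc <- make_probe_complex(dup, sched)
  pol <- pc$system$residues$polymer[pc$system$atoms$res_index]
  expect_true(all(pc$system$atoms$role[pol != "other"] != "other"))
})

test_that("role split matches hand-written residue tables", {
  # hand lists of heavy side-chain atoms for representative amino acids
  aa_atoms <- list(
    ARG = c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
    GLY = c("N", "CA", "C", "O"),
    LYS = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
    VAL = c("N", "CA", "C", "O", "CB", "CG1", "CG2"),
    SER = c("N", "CA", "C", "O", "CB", "OG"),
    TRP = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1", "CE2",
            "CE3", "CZ2", "CZ3", "CH2"))
  expected_sidechain <- c(ARG = 7, GLY = 0, LYS = 5, VAL = 3, SER = 2,
                          TRP = 10)
  atoms <- dplyr::bind_rows(lapply(seq_along(aa_atoms), function(i) {
    nm <- aa_atoms[[i]]
    tibble::tibble(name = nm, element = substr(nm, 1, 1),
                   resname = names(aa_atoms)[i], resid = i, chain = "A")
  }))
  sys <- classify_atoms(mol_system(atoms))
  counts <- role_counts(sys)
  sc_tab <- counts[counts$role == "protein_sidechain", ]
  sc <- stats::setNames(sc_tab$n, sc_tab$resname)
  want <- expected_sidechain[expected_sidechain > 0]
  expect_equal(sc[names(want)], want)
  bb <- counts[counts$role == "protein_backbone", ]
  expect_true(all(bb$n == 4))
  expect_false("GLY" %in% counts$resname[counts$role == "protein_sidechain"])
})

test_that("superposition recovers rigid transforms and the d/sqrt(N) law", {
  set.seed(11)
  ref <- matrix(rnorm(30, sd = 4), 10, 3)
  # pure translation
  fit <- superpose(sweep(ref, 2, c(5, 0, 0), "+"), ref)
  expect_lt(fit$rmsd, 1e-10)
  # pure rotation, 90 deg about z
  R <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  fit <- superpose(ref %*% t(R), ref)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  # one atom displaced by d, fit on the identical subset
  d <- 1.7
  mob <- ref
  mob[10, ] <- mob[10, ] + c(d, 0, 0)
  fit <- superpose(mob, ref, selection = 1:9)
  expect_equal(rmsd_raw(fit$coords, ref), d / sqrt(10), tolerance = 1e-10)
  # idempotency and <3-atom failure
  fit2 <- superpose(fit$coords, ref, selection = 1:9)
  expect_lt(abs(fit2$rmsd - fit$rmsd), 1e-10)
  expect_error(superpose(ref[1:2, ], ref[1:2, ]), "at least 3")
})

test_that("superposition agrees with an independent implementation", {
  set.seed(21)
  ref <- matrix(rnorm(36, sd = 3), 12, 3)
  mob <- ref %*% t(rot_axis_test(c(1, 2, 3), 40)) + 2.5
  mob <- mob + matrix(rnorm(36, sd = 0.3), 12, 3)
  ours <- superpose(mob, ref)
  b3d <- suppressWarnings(bio3d::fit.xyz(fixed = as.numeric(t(ref)),
                                         mobile = as.numeric(t(mob))))
  expect_equal(as.numeric(t(ours$coords)), as.numeric(b3d),
               tolerance = 1e-6)
})

test_that("average structure converges and undoes rigid-body scatter", {
  set.seed(31)
  sys <- toy_particle_system(8)
  ref <- matrix(rnorm(24, sd = 4), 8, 3)
  # frames are rigid-body images of one structure -> average is that shape
  xyz <- t(vapply(1:6, function(i) {
    R <- rot_axis_test(rnorm(3), runif(1, -120, 120))
    as.numeric(t(sweep(ref %*% t(R), 2, rnorm(3, sd = 10), "+")))
  }, numeric(24)))
  traj <- traj_ensemble(sys, xyz)
  avg <- compute_average_structure(traj)
  fit <- superpose(avg$coords, ref)
  expect_lt(fit$rmsd, 1e-3)
  # identical frames converge in one iteration
  frozen <- traj_ensemble(sys, xyz[c(1, 1, 1), ])
  expect_equal(compute_average_structure(frozen)$iterations, 1)
})

test_that("rmsd series flags the planted displacement frame", {
  sys <- toy_particle_system(16)
  ref <- matrix(rnorm(48, sd = 5), 16, 3)
  xyz <- matrix(rep(as.numeric(t(ref)), 5), nrow = 5, byrow = TRUE)
  xyz[3, 1] <- xyz[3, 1] + 2      # displace atom 1 of frame 3 by 2 A in x
  traj <- traj_ensemble(sys, xyz)
  # fit on the unperturbed atoms, measure over all atoms
  fits <- vapply(1:5, function(f) {
    rmsd_raw(superpose(frame_coords(traj, f), ref, 2:16)$coords, ref)
  }, numeric(1))
  expect_equal(fits[3], 2 / sqrt(16), tolerance = 1e-10)
  expect_true(all(fits[-3] < 1e-10))
  rs <- rmsd_series(traj, ref)
  expect_equal(nrow(rs), 5)
  expect_true(all(rs$rmsd[-3] < 1e-10))
})

test_that("rmsd is symmetric under mutual fit", {
  set.seed(41)
  a <- matrix(rnorm(30), 10, 3)
  b <- a + matrix(rnorm(30, sd = 0.4), 10, 3)
  expect_lt(abs(superpose(a, b)$rmsd - superpose(b, a)$rmsd), 1e-10)
})

test_that("equilibration discard keeps frames strictly after the cut", {
  sys <- toy_particle_system(2)
  traj <- traj_ensemble(sys, matrix(rnorm(600 * 6), 600, 6))  # 1 ps spacing
  kept <- discard_equilibration(traj, 100)
  expect_equal(n_frames(kept), 500)
  expect_equal(min(kept$times), 101)
  expect_equal(n_frames(traj), 600)  # original untouched
  expect_equal(n_frames(discard_equilibration(traj, 0)), 600)
  expect_error(discard_equilibration(traj, 600), "no frames")
})
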