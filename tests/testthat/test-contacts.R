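# Contact detectors, classification, and the dynamic contact map.

toy_hbond_system <- function(no_dist = 2.9, angle = 180) {
  # LYS NZ-HZ1 donor over a DA N1 acceptor, geometry fully controlled
  h <- c(1.0, 0, 0)
  acc <- h + (no_dist - 1.0) *
    c(cos((180 - angle) * pi / 180), sin((180 - angle) * pi / 180), 0)
  atoms <- tibble::tibble(
    name = c("NZ", "HZ1", "N1"),
    element = c("N", "H", "N"),
    resname = c("LYS", "LYS", "DA"),
    resid = c(1, 1, 2), chain = c("P", "P", "B"))
  sys <- classify_atoms(mol_system(atoms))
  sys$bonds <- cbind(1L, 2L)
  list(system = sys, coords = rbind(c(0, 0, 0), h, acc))
}

test_that("hydrogen bonds require both distance and angle", {
  crit <- contact_criteria()
  tb <- toy_hbond_system(2.9, 180)
  hits <- detect_hbonds(tb$coords, tb$system, crit)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$donor, 1L)
  expect_equal(hits$acceptor, 3L)
  # angle below cutoff
  tb2 <- toy_hbond_system(2.9, 90)
  expect_equal(nrow(detect_hbonds(tb2$coords, tb2$system, crit)), 0)
  # distance beyond cutoff
  tb3 <- toy_hbond_system(10, 180)
  expect_equal(nrow(detect_hbonds(tb3$coords, tb3$system, crit)), 0)
})

test_that("salt bridges use the N...O distance to phosphate oxygens", {
  dup <- build_ideal_duplex(duplex_spec("ACGTAC", "B_DNA"))
  on <- make_probe_complex(dup,
    contact_schedule_entry("salt_bridge", 4, "OP1", TRUE))
  hits <- detect_salt_bridges(frame_coords(on$traj, 1), on$system)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$class, "nonspecific")  # phosphate is backbone
  # beyond threshold (off frame): 3.5 + 2.5 = 6.0 A > 4.0
  off <- make_probe_complex(dup,
    contact_schedule_entry("salt_bridge", 4, "OP1", FALSE))
  expect_equal(nrow(detect_salt_bridges(frame_coords(off$traj, 1),
                                        off$system)), 0)
})

test_that("apolar contacts pair non-polar carbons only", {
  dup <- build_ideal_duplex(duplex_spec("ACGTAC", "B_DNA"))
  on <- make_probe_complex(dup,
    contact_schedule_entry("apolar", 4, "C7", TRUE))
  hits <- detect_apolar(frame_coords(on$traj, 1), on$system)
  expect_true(nrow(hits) >= 1)
  a <- on$system$atoms
  cg1 <- which(a$name == "CG1")
  c7 <- which(a$name == "C7" & a$res_index == 4)
  expect_true(any(hits$protein_atom == cg1 & hits$nucleic_atom == c7))
  expect_equal(hits$class[hits$protein_atom == cg1 & hits$nucleic_atom == c7],
               "specific")  # Val methyl vs thymine methyl
  off <- make_probe_complex(dup,
    contact_schedule_entry("apolar", 4, "C7", FALSE))
  expect_equal(nrow(detect_apolar(frame_coords(off$traj, 1), off$system)), 0)
})

test_that("contact classification follows the side-chain/base rule", {
  fx <- make_probe_fixture(n_frames = 4)
  a <- fx$system$atoms
  og <- which(a$name == "OG")                         # Ser side chain
  o6 <- which(a$name == "O6" & a$res_index == 3)      # guanine base
  op <- which(a$name == "OP1" & a$res_index == 6)     # phosphate backbone
  expect_equal(classify_contact(fx$system, og, o6), "specific")
  expect_equal(classify_contact(fx$system, og, op), "nonspecific")
  bbN <- which(a$name == "N" & a$resname == "SER")    # protein backbone
  expect_equal(classify_contact(fx$system, bbN, o6), "nonspecific")
})

test_that("scheduled occupancies are recovered exactly with unit strengths", {
  fx <- make_probe_fixture(n_frames = 200)
  cm <- build_dynamic_contact_map(fx$traj)
  ev <- cm$events[cm$events$occupancy > 0, ]
  expect_equal(nrow(ev), 3)  # exactly the scheduled events, nothing else
  expect_equal(sort(ev$occupancy), c(0.4, 0.5, 1.0))
  m <- cm$map
  expect_equal(m$mean_strength[m$class == "nonspecific"], 1.0)
  expect_equal(m$sd[m$class == "nonspecific"], 0.0)
  # Bernoulli moments for the 40% hydrogen bond
  hb <- m[m$nucleic_res == 3, ]
  expect_equal(hb$mean_strength, 0.4)
  expect_equal(hb$sd, sqrt(0.4 * 0.6))
})

test_that("persistence filter removes rare events, strict threshold", {
  n_f <- 100
  dup <- build_ideal_duplex(duplex_spec("ACGTACGTAC", "B_DNA"))
  sched <- dplyr::bind_rows(
    contact_schedule_entry("hbond", 3, "O6", pattern_fraction(n_f, 0.05)),
    contact_schedule_entry("salt_bridge", 6, "OP1",
                           pattern_fraction(n_f, 0.4)))
  pc <- make_probe_complex(dup, sched)
  cm <- build_dynamic_contact_map(pc$traj, persistence = 0.10)
  ev <- cm$events[cm$events$occupancy > 0, ]
  expect_equal(ev$kept, c(FALSE, TRUE))
  expect_false(3 %in% cm$map$nucleic_res)   # 5% event absent from the map
  # raising the threshold never increases any pair's strength
  cm50 <- build_dynamic_contact_map(pc$traj, persistence = 0.50)
  expect_equal(nrow(cm50$map), 0)
})

test_that("an atom pair that is both H-bond and salt bridge counts once", {
  # place a LYS NZ-H pointing straight at OP1 at 2.9 A: qualifies as both
  dup <- build_ideal_duplex(duplex_spec("ACGTAC", "B_DNA"))
  at <- dup$system$atoms
  op1 <- which(at$res_index == 4 & at$name == "P")
  tgt <- which(at$res_index == 4 & at$name == "OP1")
  u <- (dup$coords[tgt, ] - dup$coords[op1, ])
  u <- u / sqrt(sum(u^2))
  probe_atoms <- tibble::tibble(
    name = c("NZ", "HZ1", "CE"), element = c("N", "H", "C"),
    resname = "LYS", resid = 1, chain = "P")
  nz <- dup$coords[tgt, ] + 2.9 * u
  coords <- rbind(dup$coords, nz, nz - 1.0 * u, nz + 1.5 * u)
  atoms <- dplyr::bind_rows(
    at[c("name", "element", "resname", "resid", "chain")], probe_atoms)
  sys <- classify_atoms(mol_system(atoms))
  sys$bonds <- infer_bonds(sys, coords)
  traj <- traj_ensemble(sys, matrix(rep(coords_to_xyz_test(coords), 2),
                                    nrow = 2, byrow = TRUE))
  cm <- build_dynamic_contact_map(traj)
  ev <- cm$events[cm$events$occupancy > 0, ]
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "salt_bridge")
  expect_equal(cm$map$mean_strength, 1.0)
})

test_that("production detectors match the brute-force oracle", {
  set.seed(101)
  dup <- build_ideal_duplex(duplex_spec("ACGT", "B_DNA"))
  sched <- dplyr::bind_rows(
    contact_schedule_entry("hbond", 3, "O6", TRUE),
    contact_schedule_entry("salt_bridge", 2, "OP1", TRUE))
  pc <- make_probe_complex(dup, sched)
  crit <- contact_criteria()
  expect_lte(n_atoms(pc$system), 200)
  base <- frame_coords(pc$traj, 1)
  for (rep in 1:12) {
    coords <- base + matrix(rnorm(length(base), sd = 0.8), nrow(base), 3)
    hb <- detect_hbonds(coords, pc$system, crit)
    sb <- detect_salt_bridges(coords, pc$system, crit)
    ap <- detect_apolar(coords, pc$system, crit)
    # assemble with the production tie-break: salt bridge wins a shared pair
    as_events <- function(type, df) data.frame(
      type = rep(type, nrow(df)), protein_atom = df$protein_atom,
      nucleic_atom = df$nucleic_atom)
    mine <- rbind(as_events("hbond", hb), as_events("salt_bridge", sb),
                  as_events("apolar", ap))
    dup_pair <- mine$type == "hbond" &
      paste(mine$protein_atom, mine$nucleic_atom) %in%
        paste(sb$protein_atom, sb$nucleic_atom)
    mine <- mine[!dup_pair, ]
    oracle <- oracle_contacts(pc$system, coords, crit)
    expect_setequal(event_key(mine), event_key(oracle))
  }
})

test_that("map statistics are invariant to frame order and merge additively", {
  fx <- make_probe_fixture(n_frames = 120)
  cm <- build_dynamic_contact_map(fx$traj)
  perm <- sample(seq_len(n_frames(fx$traj)))
  shuffled <- traj_ensemble(fx$system, fx$traj$xyz[perm, , drop = FALSE])
  cm2 <- build_dynamic_contact_map(shuffled)
  m1 <- dplyr::arrange(cm$map, protein_res, nucleic_res, class)
  m2 <- dplyr::arrange(cm2$map, protein_res, nucleic_res, class)
  expect_equal(m1$mean_strength, m2$mean_strength)
  expect_equal(m1$sd, m2$sd)
  expect_equal(sort(cm$events$occupancy), sort(cm2$events$occupancy))
  # strength additivity: disjoint event sets on one pair add their means
  dup <- fx$duplex
  sched <- contact_schedule_entry("hbond_apolar", 4, "O4",
                                  rep(TRUE, 50), secondary_atom = "C7")
  both <- make_probe_complex(dup, sched)
  cmb <- build_dynamic_contact_map(both$traj)
  expect_equal(cmb$map$mean_strength, 2.0)
  expect_equal(cmb$map$n_events, 2L)
})

test_that("empty schedules yield no events after filtering", {
  dup <- build_ideal_duplex(duplex_spec("ACGTAC", "B_DNA"))
  pc <- make_probe_complex(dup,
    contact_schedule_entry("hbond", 3, "O6", rep(FALSE, 10)))
  cm <- build_dynamic_contact_map(pc$traj)
  expect_equal(nrow(cm$map), 0)
  expect_true(all(cm$events$occupancy == 0))
})

test_that("hydrogen-free systems warn that donors are skipped", {
  atoms <- tibble::tibble(
    name = c("NZ", "N1"), element = c("N", "N"),
    resname = c("LYS", "DA"), resid = 1:2, chain = c("P", "B"))
  sys <- classify_atoms(mol_system(atoms))
  sys$bonds <- matrix(integer(0), ncol = 2)
  coords <- rbind(c(0, 0, 0), c(2.9, 0, 0))
  expect_warning(hits <- detect_hbonds(coords, sys), "no hydrogens")
  expect_equal(nrow(hits), 0)
})
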