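# Independent brute-force oracles used to cross-check the production code.
# These are written as naive all-pairs loops, on purpose: they share no code
# path with the implementations they verify.

oracle_bonded_h <- function(system) {
  a <- system$atoms
  b <- system$bonds
  out <- vector("list", nrow(a))
  for (k in seq_len(nrow(b))) {
    i <- b[k, 1]; j <- b[k, 2]
    if (a$element[j] == "H") out[[i]] <- c(out[[i]], j)
    if (a$element[i] == "H") out[[j]] <- c(out[[j]], i)
  }
  out
}

# all three detectors, naive O(N^2), returning a data.frame of events
oracle_contacts <- function(system, coords, criteria) {
  a <- system$atoms
  polymer <- system$residues$polymer[a$res_index]
  pro <- which(polymer == "protein")
  nuc <- which(polymer == "nucleic")
  hof <- oracle_bonded_h(system)
  dist <- function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))
  events <- list()
  add <- function(type, p, n) {
    events[[length(events) + 1]] <<- data.frame(
      type = type, protein_atom = p, nucleic_atom = n)
  }
  bonded_to_P <- function(i) {
    nb <- c(system$bonds[system$bonds[, 1] == i, 2],
            system$bonds[system$bonds[, 2] == i, 1])
    any(a$element[nb] == "P")
  }
  bonded_to_NO <- function(i) {
    nb <- c(system$bonds[system$bonds[, 1] == i, 2],
            system$bonds[system$bonds[, 2] == i, 1])
    any(a$element[nb] %in% c("N", "O"))
  }
  for (p in pro) {
    for (n in nuc) {
      ep <- a$element[p]; en <- a$element[n]
      # hydrogen bond, either direction
      hb <- FALSE
      for (dir in 1:2) {
        don <- if (dir == 1) p else n
        acc <- if (dir == 1) n else p
        if (!a$element[don] %in% c("N", "O")) next
        if (!a$element[acc] %in% c("N", "O")) next
        hs <- hof[[don]]
        if (length(hs) == 0) next
        if (dist(don, acc) > criteria$hbond_da_max) next
        for (h in hs) {
          v1 <- coords[don, ] - coords[h, ]
          v2 <- coords[acc, ] - coords[h, ]
          ang <- acos(min(max(sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
          if (ang >= criteria$hbond_dha_min) { hb <- TRUE; break }
        }
        if (hb) break
      }
      # salt bridge: cationic protein N vs O bonded to P
      rn <- sub("[35]$", "", toupper(a$resname[p]))
      cation <- (rn == "LYS" && a$name[p] == "NZ") ||
        (rn == "ARG" && a$name[p] %in% c("NH1", "NH2", "NE")) ||
        (criteria$his_protonated && rn %in% c("HIS", "HIP") &&
           a$name[p] %in% c("ND1", "NE2"))
      sb <- cation && en == "O" && bonded_to_P(n) &&
        dist(p, n) <= criteria$salt_no_max
      if (sb) add("salt_bridge", p, n)
      if (hb && !sb) add("hbond", p, n)
      # apolar
      if (ep == "C" && en == "C" && !bonded_to_NO(p) && !bonded_to_NO(n) &&
          dist(p, n) <= criteria$apolar_cc_max) {
        add("apolar", p, n)
      }
    }
  }
  if (length(events) == 0) {
    return(data.frame(type = character(0), protein_atom = integer(0),
                      nucleic_atom = integer(0)))
  }
  out <- do.call(rbind, events)
  out[order(out$type, out$protein_atom, out$nucleic_atom), ]
}

# naive double-loop group interaction energy
oracle_group_energy <- function(coords, system, ga, gb, cutoff) {
  a <- system$atoms
  ec <- 0; el <- 0
  for (i in ga) {
    for (j in gb) {
      r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (r > cutoff || r == 0) next
      ec <- ec + 332.0637 * a$charge[i] * a$charge[j] / r
      sij <- (a$lj_sigma[i] + a$lj_sigma[j]) / 2
      eij <- sqrt(a$lj_epsilon[i] * a$lj_epsilon[j])
      el <- el + 4 * eij * ((sij / r)^12 - (sij / r)^6)
    }
  }
  c(coulomb = ec, lj = el)
}

# Schlitter TS via log-determinant (LU), not eigenvalues
oracle_schlitter <- function(C, masses, temperature = 300) {
  kB_si <- 1.380649e-23; hbar <- 1.054571817e-34; amu <- 1.66053906660e-27
  alpha <- kB_si * temperature * exp(2) / hbar^2 * amu * 1e-20
  D <- sqrt(rep(masses, each = 3))
  M <- diag(nrow(C)) + alpha * (C * outer(D, D))
  ld <- determinant(M, logarithm = TRUE)
  0.5 * 1.987204259e-3 * temperature * as.numeric(ld$modulus)
}

# deterministic presence pattern with an exact on-fraction
pattern_fraction <- function(n_frames, fraction) {
  k <- round(n_frames * fraction)
  rep(c(TRUE, FALSE), c(k, n_frames - k))
}

event_key <- function(df) {
  paste(df$type, df$protein_atom, df$nucleic_atom, sep = ":")
}

# shared small fixtures ------------------------------------------------------

make_probe_fixture <- function(n_frames = 200,
                               sequence = "ACGTACGTAC",
                               schedule = NULL) {
  dup <- build_ideal_duplex(duplex_spec(sequence, "B_DNA"))
  if (is.null(schedule)) {
    schedule <- dplyr::bind_rows(
      contact_schedule_entry("hbond", 3, "O6",
                             pattern_fraction(n_frames, 0.4)),
      contact_schedule_entry("salt_bridge", 6, "OP1", rep(TRUE, n_frames)),
      contact_schedule_entry("apolar", 4, "C7",
                             pattern_fraction(n_frames, 0.5)))
  }
  c(make_probe_complex(dup, schedule), list(duplex = dup))
}

# local geometry helpers for tests
rot_axis_test <- function(axis, ang) {
  u <- axis / sqrt(sum(axis^2)); th <- ang * pi / 180
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  cos(th) * diag(3) + sin(th) * ux + (1 - cos(th)) * outer(u, u)
}
coords_to_xyz_test <- function(m) as.numeric(t(m))
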