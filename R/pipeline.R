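#' Analysis configuration
#'
#' Bundles every setting of the full analysis.  Defaults encode the standard
#' production protocol: 100 ns (100000 ps) equilibration discard, 10\%
#' contact persistence, 10 A short-range energy cutoff, Schlitter entropy of
#' backbone P atoms at 300 K with 100 ns windows, and the two PCA
#' superposition protocols.
#'
#' @param topology Path to the topology PDB.
#' @param trajectory Path to the multi-model PDB trajectory.
#' @param parameter_table Path to the flat parameter table (`NULL` to skip
#'   the energy stage).
#' @param pairing Path to a two-column whitespace text file of paired residue
#'   indices (`NULL` to skip the helical stage).
#' @param out_dir Output directory.
#' @param equilibration_ps Equilibration cut (ps).  Default 100000.
#' @param persistence Contact persistence threshold.  Default 0.10.
#' @param criteria A [contact_criteria].
#' @param energy_cutoff Short-range cutoff (A).  Default 10.
#' @param entropy_selection Atom name for the entropy selection (default
#'   `"P"`).
#' @param entropy_window_ps Entropy window length (ps).  Default 100000.
#' @param temperature K.  Default 300.
#' @param helical_max_frames Cap on frames analysed by the helical stage
#'   (evenly subsampled; default 200).
#' @param stages Character vector of stages to run, from
#'   `c("contacts", "energies", "entropy", "helical", "pca", "rmsd")`.
#' @param seed Integer seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(topology, trajectory, parameter_table = NULL,
                            pairing = NULL, out_dir = "nuctraj_out",
                            equilibration_ps = 100000, persistence = 0.10,
                            criteria = contact_criteria(),
                            energy_cutoff = 10.0,
                            entropy_selection = "P",
                            entropy_window_ps = 100000,
                            temperature = 300,
                            helical_max_frames = 200,
                            stages = c("contacts", "energies", "entropy",
                                       "helical", "pca", "rmsd"),
                            seed = 1) {
  stopifnot(equilibration_ps >= 0, persistence >= 0, energy_cutoff > 0,
            temperature > 0, entropy_window_ps > 0)
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(
    topology = topology, trajectory = trajectory,
    parameter_table = parameter_table, pairing = pairing,
    out_dir = out_dir, equilibration_ps = equilibration_ps,
    persistence = persistence, criteria = criteria,
    energy_cutoff = energy_cutoff, entropy_selection = entropy_selection,
    entropy_window_ps = entropy_window_ps, temperature = temperature,
    helical_max_frames = helical_max_frames, stages = stages,
    seed = as.integer(seed)),
    class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Any field of [analysis_config()] may appear; contact criteria go under a
#' `criteria:` block.
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  crit <- do.call(contact_criteria, y$criteria %||% list())
  y$criteria <- NULL
  do.call(analysis_config, c(y, list(criteria = crit)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_pairing_map <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("strand1", "strand2"))
  tibble::tibble(strand1 = as.integer(tab$strand1),
                 strand2 = as.integer(tab$strand2))
}

pipeline_log <- function(...) message("[nuctraj] ", ...)

#' Run the full analysis pipeline
#'
#' Loads topology and trajectory, discards equilibration, and runs the
#' configured stages in the standard order (contacts, energies, entropy,
#' helical/groove, PCA, RMSD), writing per-stage CSV/JSON artifacts plus a
#' run manifest into `out_dir`.  A failure in one stage is logged and
#' re-raised after the remaining stages have run, so completed outputs are
#' never corrupted.
#'
#' @param config An [analysis_config()].
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  for (f in c(config$topology, config$trajectory, config$parameter_table,
              config$pairing)) {
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  st <- read_structure(config$topology)
  system <- classify_atoms(st$system)
  if (!is.null(config$parameter_table)) {
    system <- load_parameters(system, config$parameter_table)
  }
  traj <- read_trajectory(config$trajectory, system)
  if (config$equilibration_ps > 0) {
    traj <- discard_equilibration(traj, config$equilibration_ps)
  }
  pipeline_log("analysing ", n_frames(traj), " frames x ", n_atoms(system),
               " atoms")

  results <- list()
  failures <- list()
  run_stage <- function(name, fn) {
    if (!name %in% config$stages) return(invisible(NULL))
    pipeline_log("stage: ", name)
    res <- tryCatch(fn(), error = function(e) {
      pipeline_log("stage ", name, " FAILED: ", conditionMessage(e))
      failures[[name]] <<- conditionMessage(e)
      NULL
    })
    results[[name]] <<- res
  }
  out <- function(...) file.path(config$out_dir, paste0(...))

  run_stage("contacts", function() {
    cm <- build_dynamic_contact_map(traj, config$criteria,
                                    config$persistence)
    kept <- sum(cm$events$kept)
    pipeline_log("  ", nrow(cm$events), " candidate events, ",
                 sum(cm$events$occupancy > 0), " observed, ", kept,
                 " past the ", config$persistence, " persistence filter")
    write_contact_map(cm, out("contacts"))
    cm
  })
  run_stage("energies", function() {
    if (is.null(config$parameter_table)) {
      stop("energy stage needs a parameter table")
    }
    ed <- decompose_interaction_energy(traj, config$energy_cutoff)
    write_energy_decomposition(ed, out("energies"))
    ed
  })
  run_stage("entropy", function() {
    sel <- select_atoms(system, polymer = "nucleic",
                        elety = config$entropy_selection)
    er <- windowed_entropy(traj, sel, config$temperature,
                           config$entropy_window_ps)
    write_entropy_result(er, out("entropy"))
    er
  })
  run_stage("helical", function() {
    if (is.null(config$pairing)) stop("helical stage needs a pairing map")
    pairing <- read_pairing_map(config$pairing)
    frames <- seq_len(n_frames(traj))
    if (length(frames) > config$helical_max_frames) {
      frames <- unique(round(seq(1, length(frames),
                                 length.out = config$helical_max_frames)))
    }
    hs <- helical_series(traj, pairing, frames)
    utils::write.csv(hs$steps, out("helical_steps.csv"), row.names = FALSE)
    utils::write.csv(hs$pairs, out("helical_pairs.csv"), row.names = FALSE)
    utils::write.csv(hs$grooves, out("helical_grooves.csv"),
                     row.names = FALSE)
    sm <- parameter_series_summary(hs$steps, "step")
    utils::write.csv(sm$summary, out("helical_steps_summary.csv"),
                     row.names = FALSE)
    c(hs, list(summary = sm$summary))
  })
  run_stage("pca", function() {
    nuc <- select_atoms(system, polymer = "nucleic", heavy = TRUE)
    all_heavy <- select_atoms(system, heavy = TRUE)
    p1 <- pca_protocol(traj, nuc, all_heavy)
    p2 <- pca_protocol(traj, nuc, nuc)
    write_pca_result(p1, out("pca_protocol1"))
    write_pca_result(p2, out("pca_protocol2"))
    for (m in seq_len(min(3, sum(p2$eigenvalues > 1e-12)))) {
      anim <- mode_animation(p2, m)
      write_pdb(anim$system, anim, out("pca_protocol2_mode", m, ".pdb"))
    }
    list(protocol1 = p1, protocol2 = p2)
  })
  run_stage("rmsd", function() {
    nuc_heavy <- select_atoms(system, polymer = "nucleic", heavy = TRUE)
    avg <- compute_average_structure(traj, nuc_heavy)
    rs <- rmsd_series(traj, avg$coords, nuc_heavy)
    utils::write.csv(rs, out("rmsd_series.csv"), row.names = FALSE)
    write_pdb(system, avg$coords, out("average_structure.pdb"))
    rs
  })

  manifest <- list(
    package = "nuctraj",
    version = as.character(utils::packageVersion("nuctraj")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    seed = config$seed,
    n_frames_analysed = n_frames(traj),
    n_atoms = n_atoms(system),
    stages = config$stages,
    completed = names(results)[!vapply(results, is.null, logical(1))],
    failed = names(failures))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)

  if (length(failures) > 0) {
    stop("pipeline stage(s) failed: ",
         paste(names(failures), unlist(failures), sep = ": ",
               collapse = "; "))
  }
  invisible(list(results = results, manifest = manifest))
}
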