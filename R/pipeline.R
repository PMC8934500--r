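#' Pipeline run configuration
#'
#' A nested key/value configuration (YAML on disk) covering every stage:
#' design window and ensemble sizes, the energy model, trajectory
#' generation, the analysis window, and monitored interactions. A single
#' global `seed` drives all randomness; stage seeds are derived
#' deterministically as `seed + 1000 * stage_index` (build 1, ensemble 2,
#' single screen 3, double screen 4, trajectory 5 + replicate).
#'
#' @return `default_run_config()` returns the default configuration as an
#'   object of class `run_config`.
#' @export
default_run_config <- function() {
  cfg <- list(
    seed = 1L,
    output_dir = ".",
    sequence = sip_cc_demo_sequence(),
    design = list(
      first_position = 3L,
      last_position = 46L,
      max_intervening = 4L,
      ensemble_size = 100L,
      n_models = 20L,
      epsilon_mono = 0.5,
      ensemble_sigma = 0.3
    ),
    potential = list(
      # `file` may be set to a potential-table path; absent = built-in toy
      contact_cutoff = 8.0,
      clash_distance = 2.5,
      clash_penalty = 10
    ),
    trajectory = list(
      n_frames = 100L,
      dt = 1.0,
      sigma = 0.5,
      n_replicates = 2L
    ),
    analysis = list(
      window_fraction = 0.5,
      persistence_thresholds = list(
        salt_bridge = 0.90,
        stacking = 0.85,
        generic_contact = 0.85
      )
    ),
    interactions = list()
  )
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  d <- cfg$design
  if (d$ensemble_size < 1 || d$n_models < 1 || cfg$trajectory$n_frames < 1) {
    abort("all counts must be >= 1", class = "coilscreen_validation_error")
  }
  wf <- cfg$analysis$window_fraction
  if (wf <= 0 || wf > 1) {
    abort("analysis window_fraction must be in (0, 1]",
          class = "coilscreen_validation_error")
  }
  if (!is.numeric(cfg$seed) || cfg$seed != as.integer(cfg$seed)) {
    abort("seed must be an integer", class = "coilscreen_validation_error")
  }
  invisible(cfg)
}

#' @rdname default_run_config
#' @param path Path to a YAML configuration file.
#' @return `read_run_config()` returns the file merged over the defaults.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(default_run_config()), user)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

#' @rdname default_run_config
#' @export
config_init <- function(path) {
  yaml::write_yaml(unclass(default_run_config()), path)
  log_line("INFO", "config", paste0("wrote default config to ", path))
  invisible(path)
}

stage_seed <- function(cfg, stage_index) {
  as.integer(cfg$seed + 1000L * stage_index)
}

log_line <- function(level, stage, msg) {
  message(sprintf("[%s] %s: %s", level, stage, msg))
}

config_potential <- function(cfg) {
  pt <- cfg$potential
  if (!is.null(pt$file)) {
    read_potential(pt$file, contact_cutoff = pt$contact_cutoff,
                   clash_distance = pt$clash_distance,
                   clash_penalty = pt$clash_penalty)
  } else {
    default_contact_potential(pt$contact_cutoff, pt$clash_distance,
                              pt$clash_penalty)
  }
}

write_manifest <- function(path, cfg, stage, extra = list()) {
  manifest <- c(list(stage = stage,
                     package_version =
                       as.character(utils::packageVersion("coilscreen")),
                     config_hash = rlang::hash(unclass(cfg)),
                     seed = cfg$seed,
                     config = unclass(cfg)),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the synthetic homodimer and its design ensemble
#'
#' Writes `dimer.pdb` (the ideal coiled-coil homodimer for the configured
#' sequence), `ensemble.pdb` (a multi-model PDB of perturbed copies), and a
#' JSON manifest into the configured output directory.
#'
#' @param cfg A `run_config` (see [default_run_config()]).
#' @return Invisibly, a list with the written paths.
#' @export
pipeline_build <- function(cfg = default_run_config()) {
  validate_run_config(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_line("INFO", "build", paste0("building homodimer, ",
                                   nchar(cfg$sequence), " residues/chain"))
  dimer <- build_coiled_coil(cfg$sequence)
  ens <- generate_ensemble(dimer, n = cfg$design$ensemble_size,
                           sigma = cfg$design$ensemble_sigma,
                           seed = stage_seed(cfg, 2L))
  dimer_path <- file.path(cfg$output_dir, "dimer.pdb")
  ens_path <- file.path(cfg$output_dir, "ensemble.pdb")
  writeLines(write_pdb(dimer), dimer_path, sep = "")
  writeLines(write_pdb(ens), ens_path, sep = "")
  manifest <- file.path(cfg$output_dir, "build_manifest.json")
  write_manifest(manifest, cfg, "build",
                 list(n_ensemble = length(ens),
                      dimer_file = "dimer.pdb",
                      ensemble_file = "ensemble.pdb"))
  log_line("INFO", "build", paste0("wrote ", ens_path, " (",
                                   length(ens), " models)"))
  invisible(list(dimer = dimer_path, ensemble = ens_path,
                 manifest = manifest))
}

#' Run the single- or double-site design screen
#'
#' Reads the ensemble written by [pipeline_build()], enumerates sites from
#' the configured design window, runs [run_design()], groups and references
#' the records with [summarize_variants()], selects candidates, and writes
#' `screen_<mode>.tsv` plus a manifest recording the record count.
#'
#' @param cfg A `run_config`.
#' @param mode `"single"` or `"double"`.
#' @param scoring Passed to [run_design()]; `"none"` verifies bookkeeping
#'   without scoring.
#' @return Invisibly, a list with `records`, `summaries`, `selected`,
#'   and `n_records`.
#' @export
pipeline_screen <- function(cfg = default_run_config(),
                            mode = c("single", "double"),
                            scoring = c("contact", "none")) {
  validate_run_config(cfg)
  mode <- match.arg(mode)
  scoring <- match.arg(scoring)
  ens_path <- file.path(cfg$output_dir, "ensemble.pdb")
  if (!file.exists(ens_path)) {
    abort(paste0("missing ensemble file: ", ens_path, " (run build first)"),
          class = "coilscreen_io_error")
  }
  ensemble <- read_pdb(paste(readLines(ens_path), collapse = "\n"))
  w <- design_window(cfg$design$first_position, cfg$design$last_position,
                     cfg$design$max_intervening)
  sites <- if (mode == "single") enumerate_single_sites(w) else
    enumerate_pairs(w)
  n_sites <- if (is.data.frame(sites)) nrow(sites) else length(sites)
  log_line("INFO", "screen", sprintf(
    "%s-site screen: %d members x %d sites x %d models", mode,
    length(ensemble), n_sites, cfg$design$n_models))
  seed <- stage_seed(cfg, if (mode == "single") 3L else 4L)
  records <- run_design(ensemble, sites, n_models = cfg$design$n_models,
                        p = config_potential(cfg), seed = seed,
                        scoring = scoring)
  out <- list(records = records, n_records = nrow(records))
  if (scoring == "contact") {
    summaries <- summarize_variants(records)
    selected <- select_candidates(summaries, cfg$design$epsilon_mono)
    summaries$selected <- summaries$signature %in% selected$signature
    write_tsv(summaries, file.path(cfg$output_dir,
                                   paste0("screen_", mode, ".tsv")))
    out$summaries <- summaries
    out$selected <- selected
    log_line("INFO", "screen", sprintf("%d variant groups, %d selected",
                                       sum(summaries$signature != ""),
                                       nrow(selected)))
  }
  write_manifest(file.path(cfg$output_dir,
                           paste0("screen_", mode, "_manifest.json")),
                 cfg, paste0("screen_", mode),
                 list(mode = mode, n_sites = n_sites,
                      n_records = nrow(records), scoring = scoring,
                      stage_seed = seed))
  invisible(out)
}

config_interaction_specs <- function(cfg) {
  lapply(cfg$interactions, function(it) {
    interaction_spec(
      id = it$id, kind = it$kind,
      selector_a = list(chain = it$chain_a, residue_index = it$residue_a,
                        atom = it$atom_a %||% "SC"),
      selector_b = list(chain = it$chain_b, residue_index = it$residue_b,
                        atom = it$atom_b %||% "SC"),
      distance_cutoff = it$cutoff %||% NULL)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analyse one or more trajectory replicates
#'
#' Reads multi-model-PDB trajectories, restricts each to the configured
#' analysis window, and writes per-replicate RMSD profiles, an interaction
#' occupancy table with persistence flags at the configured thresholds, and
#' a pooled binding-energy report.
#'
#' @param cfg A `run_config`.
#' @param trajectory_files Character vector of multi-model PDB paths, one
#'   per replicate.
#' @return Invisibly, a list with `profiles`, `occupancy`, `binding`
#'   (per-replicate) and `pooled`.
#' @export
pipeline_analyze <- function(cfg = default_run_config(), trajectory_files) {
  validate_run_config(cfg)
  if (length(trajectory_files) == 0) {
    abort("at least one trajectory file is required",
          class = "coilscreen_validation_error")
  }
  trajs <- lapply(seq_along(trajectory_files), function(i) {
    read_trajectory(paste(readLines(trajectory_files[i]), collapse = "\n"),
                    dt = cfg$trajectory$dt, replicate_id = i)
  })
  n_atoms <- vapply(trajs, function(t) nrow(t$topology$atoms), integer(1))
  if (length(unique(n_atoms)) != 1) {
    abort("replicates have mismatching topologies",
          class = "coilscreen_topology_error")
  }
  p <- config_potential(cfg)
  specs <- config_interaction_specs(cfg)
  thresholds <- cfg$analysis$persistence_thresholds
  profiles <- list()
  occupancy <- list()
  binding <- list()
  for (i in seq_along(trajs)) {
    tw <- window_frames(trajs[[i]], fraction = cfg$analysis$window_fraction)
    prof <- rmsd_profile(trajs[[i]])
    write_tsv(prof, file.path(cfg$output_dir,
                              sprintf("rmsd_profile_rep%d.tsv", i)))
    profiles[[i]] <- prof
    if (length(specs) > 0) {
      occ <- interaction_occupancy(tw, specs)
      occ$replicate_id <- i
      occ$persistent <- occ$occupancy >
        vapply(occ$kind, function(k) thresholds[[k]], numeric(1))
      occupancy[[i]] <- occ
    }
    binding[[i]] <- binding_energy_over_frames(tw, p)
    log_line("INFO", "analyze", sprintf(
      "replicate %d: %d analysis frames, mean dG %.3f", i,
      tw$frame_times |> length(), binding[[i]]$mean_dG))
  }
  occupancy_tbl <- if (length(occupancy) > 0) bind_rows(occupancy) else
    tibble()
  if (nrow(occupancy_tbl) > 0) {
    write_tsv(occupancy_tbl, file.path(cfg$output_dir, "occupancy.tsv"))
  }
  pooled <- merge_replicates(binding)
  report <- list(replicates = lapply(binding, function(b)
    as.list(glance(b))),
    pooled = as.list(glance(pooled)))
  jsonlite::write_json(report,
                       file.path(cfg$output_dir, "binding_energy.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(profiles = profiles, occupancy = occupancy_tbl,
                 binding = binding, pooled = pooled))
}

#' Sequence-property report
#'
#' Reads protein sequences from FASTA and writes an ExPASy-style TSV of
#' length, average molecular weight and isoelectric point.
#'
#' @param fasta_path Input amino-acid FASTA path.
#' @param out_path Output TSV path.
#' @return Invisibly, the property tibble.
#' @export
pipeline_seqprops <- function(fasta_path, out_path) {
  props <- seq_properties(read_fasta_sequences(fasta_path))
  write_tsv(props, out_path)
  log_line("INFO", "seqprops", paste0("wrote ", out_path))
  invisible(props)
}

parse_cli_options <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    if (startsWith(args[i], "--")) {
      key <- sub("^--", "", args[i])
      if (i == length(args) || startsWith(args[i + 1], "--")) {
        opts[[key]] <- TRUE
        i <- i + 1
      } else {
        opts[[key]] <- args[i + 1]
        i <- i + 2
      }
    } else {
      opts$positional <- c(opts$positional, args[i])
      i <- i + 1
    }
  }
  opts
}

cli_config <- function(opts) {
  if (!is.null(opts$config)) read_run_config(opts$config) else
    default_run_config()
}

#' Command-line entry point
#'
#' Dispatches the subcommands `build`, `screen`, `analyze`, `seqprops` and
#' `config init`; the installed script `inst/scripts/coilscreen` is a thin
#' wrapper around this function. Options: `--config <yaml>`,
#' `--out <dir>`, `--mode single|double`, `--scoring contact|none`,
#' `--fasta <file>`, trajectory paths as positional arguments.
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, the subcommand's result.
#' @export
coilscreen_cli <- function(args) {
  if (length(args) == 0) {
    abort("usage: coilscreen <build|screen|analyze|seqprops|config> [options]",
          class = "coilscreen_cli_error")
  }
  cmd <- args[1]
  opts <- parse_cli_options(args[-1])
  if (!is.null(opts$out)) {
    out_dir <- opts$out
  } else {
    out_dir <- NULL
  }
  result <- switch(
    cmd,
    config = {
      if (is.null(opts$positional) || opts$positional[1] != "init") {
        abort("usage: coilscreen config init --out <path>",
              class = "coilscreen_cli_error")
      }
      config_init(opts$out %||% "coilscreen.yaml")
    },
    build = {
      cfg <- cli_config(opts)
      if (!is.null(out_dir)) cfg$output_dir <- out_dir
      if (!is.null(opts$ensemble)) {
        cfg$design$ensemble_size <- as.integer(opts$ensemble)
      }
      pipeline_build(cfg)
    },
    screen = {
      cfg <- cli_config(opts)
      if (!is.null(out_dir)) cfg$output_dir <- out_dir
      pipeline_screen(cfg, mode = opts$mode %||% "single",
                      scoring = opts$scoring %||% "contact")
    },
    analyze = {
      cfg <- cli_config(opts)
      if (!is.null(out_dir)) cfg$output_dir <- out_dir
      pipeline_analyze(cfg, trajectory_files = opts$positional)
    },
    seqprops = {
      if (is.null(opts$fasta)) {
        abort("seqprops requires --fasta <file>",
              class = "coilscreen_cli_error")
      }
      pipeline_seqprops(opts$fasta, opts$out %||% "seqprops.tsv")
    },
    abort(paste0("unknown subcommand: ", cmd),
          class = "coilscreen_cli_error")
  )
  invisible(result)
}
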