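# End-to-end orchestration: run configuration, bundled system presets,
# and the simulate / scan / evolve commands.

#' Default run configuration
#'
#' All defaults are the standard protocol values: 250 K, 10 fs time step,
#' 10 ps thermostat relaxation, 150 profile bins, s = 5 nm^3, population
#' 20. An empty override list therefore reproduces the reference setup at
#' the chosen scale.
#'
#' @param ... Named overrides merged (recursively) into the defaults,
#'   e.g. `system = "desk"`, `seed = 7`.
#' @return A `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    forcefield = "toy",
    system = "desk",
    seed = 1L,
    out_dir = NULL,
    integrator = list(dt = 0.01, friction_time = 10, temperature = 250,
                      save_interval = NULL, com_motion_removal = TRUE),
    protocol = list(equil_time = NULL, prod_time = NULL),  # preset defaults
    analysis = list(n_bins = 150, smooth = 5, s = 5,
                    fitness_kind = "demix"),
    ga = list(population_size = 20, mutation_prob = 0.05,
              tournament_size = 5, n_parents = 8, n_pairs = 4,
              mode = "both", forbidden_targets = character(0),
              n_rounds = 10)
  )
  ov <- list(...)
  structure(modifyList(defaults, ov), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Values in the file override the defaults of [run_config()].
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  ov <- yaml::read_yaml(path)
  do.call(run_config, ov)
}

# polynomial rolling hash of the serialized config, for output manifests
config_hash <- function(config) {
  bytes <- as.integer(serialize(unclass(config), NULL))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

resolve_forcefield <- function(config) {
  if (identical(config$forcefield, "toy")) toy_forcefield()
  else if (inherits(config$forcefield, "forcefield")) config$forcefield
  else load_forcefield(config$forcefield)
}

#' Bundled system presets
#'
#' * `"reference"`: 96 R50 + 96 K50 + charge-matched U10 (960 chains),
#'   box 17.5 x 17.5 x 87.5 nm, 40 ns + 20 ns.
#' * `"desk"`: 16 + 16 chains + matched U10, 7 x 7 x 35 nm, 2 ns + 1 ns.
#' * `"micro"`: 6 + 6 chains + matched U10, 7 x 7 x 25 nm,
#'   0.2 ns + 0.15 ns — exercises every code path in minutes.
#' * `"rna_inner"`: 96 R50 + 96 (NNNGG)10 + 96 U50,
#'   10 x 10 x 153.2 nm.
#' * `"rna_outer"`: 96 (FFFGG)10 + 96 K50 + 96 U50, same box.
#'
#' @param name Preset name.
#' @param ff A [forcefield] (for charge matching).
#' @param rna_length Override poly-U chain length (with re-matched copy
#'   count); applies to the R50/K50 presets.
#' @return List with `spec` (a [system_spec]) and protocol defaults
#'   `equil_time`, `prod_time` (ps).
#' @export
system_preset <- function(name = c("desk", "micro", "reference",
                                   "rna_inner", "rna_outer"),
                          ff = toy_forcefield(), rna_length = 10) {
  name <- match.arg(name)
  rk_mix <- function(count, box, equil, prod) {
    A <- make_homopolymer("R", 50)
    B <- make_homopolymer("K", 50)
    prot <- list(list(seq = A, count = count, role = "A"),
                 list(seq = B, count = count, role = "B"))
    ncop <- charge_matched_rna_count(prot, rna_length, ff)
    comps <- prot
    if (ncop > 0) {
      comps <- c(comps, list(list(seq = make_homopolymer("U", rna_length),
                                  count = ncop, role = "RNA")))
    }
    list(spec = system_spec(comps, box), equil_time = equil, prod_time = prod,
         save_interval = if (prod >= 10000) 100 else 10)
  }
  switch(name,
    reference = rk_mix(96, c(17.5, 17.5, 87.5), 40000, 20000),
    desk = rk_mix(16, c(7, 7, 35), 2000, 1000),
    micro = rk_mix(6, c(7, 7, 25), 200, 150),
    rna_inner = list(
      spec = system_spec(list(
        list(seq = make_homopolymer("R", 50), count = 96, role = "A"),
        list(seq = make_repeat("NNNGG", 10), count = 96, role = "B"),
        list(seq = make_homopolymer("U", 50), count = 96, role = "RNA")),
        c(10, 10, 153.2)),
      equil_time = 40000, prod_time = 20000),
    rna_outer = list(
      spec = system_spec(list(
        list(seq = make_repeat("FFFGG", 10), count = 96, role = "A"),
        list(seq = make_homopolymer("K", 50), count = 96, role = "B"),
        list(seq = make_homopolymer("U", 50), count = 96, role = "RNA")),
        c(10, 10, 153.2)),
      equil_time = 40000, prod_time = 20000))
}

config_system <- function(config, ff, rna_length = 10) {
  if (inherits(config$system, "system_spec")) {
    ps <- list(spec = config$system,
               equil_time = config$protocol$equil_time %||% 40000,
               prod_time = config$protocol$prod_time %||% 20000)
  } else {
    ps <- system_preset(config$system, ff, rna_length = rna_length)
    if (!is.null(config$protocol$equil_time)) ps$equil_time <- config$protocol$equil_time
    if (!is.null(config$protocol$prod_time)) ps$prod_time <- config$protocol$prod_time
  }
  # frames sparse enough for reference-scale runs, dense enough for desk runs
  ps$save_interval <- config$integrator$save_interval %||%
    ps$save_interval %||% (if (ps$prod_time >= 10000) 100 else 10)
  ps
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_settings <- function(config, save_interval = 100) {
  integrator_settings(dt = config$integrator$dt,
                      friction_time = config$integrator$friction_time,
                      temperature = config$integrator$temperature,
                      seed = config$seed,
                      com_motion_removal = config$integrator$com_motion_removal,
                      save_interval = config$integrator$save_interval %||%
                        save_interval)
}

write_manifest <- function(config, out_dir, extra = list()) {
  jsonlite::write_json(c(list(config_hash = config_hash(config),
                              seed = config$seed,
                              timestamp = format(Sys.time())), extra),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Simulate, profile and report one system
#'
#' Runs the direct-coexistence protocol for the configured system, then
#' writes (when `out_dir` is set) the production trajectory
#' (extended XYZ), density profiles (CSV), region spec and phase metrics
#' (JSON), energy report (JSON) and a manifest with the config hash and
#' seed.
#'
#' @param config A [run_config()].
#' @param dry_run Validate the configuration and return without running
#'   or writing anything.
#' @return List with `trajectory`, `topology`, `profile`, `regions`,
#'   `metrics`, `energy` (invisible `config` for dry runs).
#' @export
cmd_simulate <- function(config = run_config(), dry_run = FALSE) {
  ff <- resolve_forcefield(config)
  sys <- config_system(config, ff)
  if (dry_run) return(invisible(config))
  settings <- config_settings(config, sys$save_interval)
  run <- coexistence_protocol(sys$spec, ff, settings,
                              equil_time = sys$equil_time,
                              prod_time = sys$prod_time)
  prof <- compute_profile(run$trajectory, run$topology,
                          n_bins = config$analysis$n_bins)
  regions <- find_regions(prof, smooth = config$analysis$smooth)
  metrics <- phase_metrics(prof, regions, s = config$analysis$s)
  erep <- total_energy(run$state, run$topology, ff, by_group = TRUE)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_extxyz(run$trajectory, run$topology,
                 file.path(config$out_dir, "production.extxyz"))
    write_profile_csv(prof, file.path(config$out_dir, "profile.csv"))
    jsonlite::write_json(list(center = regions$center,
                              vapor = regions$vapor,
                              fallback = regions$fallback),
                         file.path(config$out_dir, "regions.json"))
    jsonlite::write_json(list(rho_center = as.list(metrics$rho_center),
                              rho_vapor = as.list(metrics$rho_vapor),
                              f_demix = metrics$f_demix,
                              f_multiphase = metrics$f_multiphase,
                              s = metrics$s),
                         file.path(config$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    write_energy_json(erep, file.path(config$out_dir, "energy.json"))
    write_manifest(config, config$out_dir)
  }
  list(trajectory = run$trajectory, topology = run$topology, profile = prof,
       regions = regions, metrics = metrics, energy = erep)
}

#' Parameter scans: RNA length or arginine split
#'
#' `"rna_length"` reruns the configured R50/K50 mixture with poly-U chains
#' of each length n, re-matching the RNA copy count so the net charge
#' stays zero. `"arginine_split"` simulates equimolar RmK(50-m) +
#' R(50-m)Km mixtures plus matched U10 for each m.
#'
#' @param config A [run_config()].
#' @param variable `"rna_length"` or `"arginine_split"`.
#' @param values Integer vector of n or m values (empty gives an empty
#'   table).
#' @param arrangement Residue patterning for the arginine split (see
#'   [make_rk_sequence()]).
#' @return Data frame: one row per value with multiphasicity, region
#'   densities and the arginine-uracil vs lysine-uracil energy difference.
#' @export
cmd_scan <- function(config = run_config(),
                     variable = c("rna_length", "arginine_split"),
                     values = integer(0), arrangement = "block") {
  variable <- match.arg(variable)
  ff <- resolve_forcefield(config)
  rows <- list()
  for (v in values) {
    cfg <- config
    if (variable == "rna_length") {
      sys <- config_system(config, ff, rna_length = v)
      cfg$system <- sys$spec
      cfg$protocol <- list(equil_time = sys$equil_time,
                           prod_time = sys$prod_time)
    } else {
      base <- config_system(config, ff)
      counts <- vapply(base$spec$components,
                       function(c) c$count, numeric(1))
      nprot <- counts[1]
      A <- make_rk_sequence(v, 50, arrangement, seed = config$seed)
      B <- make_rk_sequence(50 - v, 50, arrangement, seed = config$seed)
      prot <- list(list(seq = A, count = nprot, role = "A"),
                   list(seq = B, count = nprot, role = "B"))
      ncop <- charge_matched_rna_count(prot, 10, ff)
      comps <- c(prot, list(list(seq = make_homopolymer("U", 10),
                                 count = ncop, role = "RNA")))
      cfg$system <- system_spec(comps, base$spec$box)
      cfg$protocol <- list(equil_time = base$equil_time,
                           prod_time = base$prod_time)
    }
    res <- cmd_simulate(cfg)
    dE <- species_pair_energy(res$trajectory, res$topology, ff,
                              "R", "U", by = "code")$mean -
      species_pair_energy(res$trajectory, res$topology, ff,
                          "K", "U", by = "code")$mean
    rows[[length(rows) + 1]] <- data.frame(
      value = v,
      f_multiphase = res$metrics$f_multiphase,
      f_demix = res$metrics$f_demix,
      rhoA_center = res$metrics$rhoA_center,
      rhoB_center = res$metrics$rhoB_center,
      rhoRNA_center = res$metrics$rhoRNA_center,
      delta_E_RU_KU = dE,
      arginine_fraction_inner = if (variable == "arginine_split")
        max(v, 50 - v) / 50 else 1)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(value = numeric(0), f_multiphase = numeric(0),
               f_demix = numeric(0), rhoA_center = numeric(0),
               rhoB_center = numeric(0), rhoRNA_center = numeric(0),
               delta_E_RU_KU = numeric(0),
               arginine_fraction_inner = numeric(0))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(config$out_dir,
                                    paste0("scan_", variable, ".csv")),
                     row.names = FALSE)
    write_manifest(config, config$out_dir)
  }
  out
}

#' Evolve the configured system with the genetic algorithm
#'
#' Simulates the reference system first to freeze the center/vapor region
#' definition, then runs the GA with the simulation-backed evaluator (or
#' a caller-supplied evaluator for smoke tests). Writes a JSON-lines log
#' and the final population as FASTA with fitness in the headers.
#'
#' @param config A [run_config()].
#' @param evaluator Optional evaluator (individual -> fitness) replacing
#'   the simulation-backed one.
#' @param reference Optional precomputed output of [cmd_simulate()] for
#'   the reference system.
#' @param resume Reuse the checkpoint in `out_dir` (written after every
#'   round) to continue an interrupted run; the continuation is identical
#'   under the same seed.
#' @return Output of [run_ga()] plus the frozen `regions`.
#' @export
cmd_evolve <- function(config = run_config(), evaluator = NULL,
                       reference = NULL, resume = FALSE) {
  ff <- resolve_forcefield(config)
  sys <- config_system(config, ff)
  gcfg <- ga_config(population_size = config$ga$population_size,
                    mutation_prob = config$ga$mutation_prob,
                    tournament_size = config$ga$tournament_size,
                    n_parents = config$ga$n_parents,
                    n_pairs = config$ga$n_pairs,
                    mode = config$ga$mode,
                    forbidden_targets = config$ga$forbidden_targets,
                    s = config$analysis$s,
                    fitness_kind = config$analysis$fitness_kind,
                    seed = config$seed)
  comps <- sys$spec$components
  seqA <- comps[[which(vapply(comps, function(c) c$role == "A", logical(1)))]]$seq
  seqB <- comps[[which(vapply(comps, function(c) c$role == "B", logical(1)))]]$seq
  base <- individual(seqA, seqB)
  regions <- NULL
  if (is.null(evaluator)) {
    if (is.null(reference)) reference <- cmd_simulate(config)
    regions <- find_regions(reference$profile,
                            smooth = config$analysis$smooth, freeze = TRUE)
    evaluator <- make_simulation_evaluator(sys$spec, ff,
                                           config_settings(config,
                                                           sys$save_interval),
                                           regions,
                                           gcfg, sys$equil_time,
                                           sys$prod_time,
                                           n_bins = config$analysis$n_bins)
  }
  checkpoint <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    checkpoint <- file.path(config$out_dir, "ga_checkpoint.rds")
    if (!resume && file.exists(checkpoint)) unlink(checkpoint)
  }
  res <- run_ga(base, evaluator, gcfg, n_rounds = config$ga$n_rounds,
                checkpoint = checkpoint)
  res$regions <- regions
  if (!is.null(config$out_dir)) {
    log_path <- file.path(config$out_dir, "ga_log.jsonl")
    detail <- if (is.null(res$child_log)) res$log else res$child_log
    writeLines(vapply(seq_len(nrow(detail)), function(r) {
      jsonlite::toJSON(as.list(detail[r, ]), auto_unbox = TRUE, digits = NA)
    }, character(1)), log_path)
    fit <- population_fitness(res$population)
    write_fasta(unlist(lapply(res$population,
                              function(i) list(i$seqA, i$seqB)),
                       recursive = FALSE),
                file.path(config$out_dir, "final_population.fasta"),
                roles = rep(c("A", "B"), length(res$population)),
                extra = sprintf("fitness=%.6g", rep(fit, each = 2)))
    write_manifest(config, config$out_dir)
  }
  res
}
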