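# Genetic algorithm over the combined two-protein sequence: tournament
# selection, single-point crossover, uniform substitution mutation, weak
# population replacement, and a fitness cache so no sequence is simulated
# twice in a run.

#' An individual: the combined sequence of the two proteins
#'
#' @param seqA,seqB `cg_sequence`s of the two protein species.
#' @param fitness Fitness value, or `NA` when unevaluated.
#' @return An `individual`.
#' @export
individual <- function(seqA, seqB, fitness = NA_real_) {
  structure(list(seqA = seqA, seqB = seqB, fitness = fitness),
            class = "individual")
}

ind_key <- function(ind) paste(ind$seqA$residues, ind$seqB$residues)

#' Genetic-algorithm configuration
#'
#' Defaults are the standard values for this procedure: population 20,
#' mutation probability 0.05 per site, tournament of 5, eight parents
#' forming four pairs per round.
#'
#' @param population_size Population size (default 20).
#' @param mutation_prob Per-site substitution probability (default 0.05).
#' @param tournament_size Tournament subset size (default 5).
#' @param n_parents Parents selected per round (default 8).
#' @param n_pairs Crossover pairs per round (default 4; must be
#'   `n_parents / 2`).
#' @param mode Which protein evolves: `"both"`, `"A"` or `"B"` (the other
#'   sequence is held fixed).
#' @param forbidden_targets Residues mutations may not introduce (e.g.
#'   `"R"`, or `c("Y", "F", "W")` for constrained runs).
#' @param allow_self Mutation draws uniformly from the allowed alphabet
#'   including the incumbent residue (effective change rate
#'   `mutation_prob * 19/20` with an unconstrained alphabet). Set `FALSE`
#'   to force a different residue.
#' @param s Vapor-penalty weight passed to the fitness (nm^3).
#' @param fitness_kind `"demix"` (toward homogeneous condensates) or
#'   `"multiphase"` (toward layered ones).
#' @param seed Master seed; per-round streams are derived by counter.
#' @return A `ga_config`.
#' @export
ga_config <- function(population_size = 20, mutation_prob = 0.05,
                      tournament_size = 5, n_parents = 8, n_pairs = 4,
                      mode = c("both", "A", "B"),
                      forbidden_targets = character(0), allow_self = TRUE,
                      s = 5, fitness_kind = c("demix", "multiphase"),
                      seed = 1L) {
  mode <- match.arg(mode)
  fitness_kind <- match.arg(fitness_kind)
  stopifnot(n_parents == 2 * n_pairs, tournament_size <= population_size,
            mutation_prob >= 0, mutation_prob <= 1)
  alphabet <- setdiff(.AA20, forbidden_targets)
  if (!length(alphabet)) stop("ga_config: allowed alphabet is empty")
  structure(list(population_size = population_size,
                 mutation_prob = mutation_prob,
                 tournament_size = tournament_size,
                 n_parents = n_parents, n_pairs = n_pairs, mode = mode,
                 forbidden_targets = forbidden_targets,
                 allow_self = allow_self, alphabet = alphabet, s = s,
                 fitness_kind = fitness_kind, seed = seed),
            class = "ga_config")
}

# per-round RNG stream derived from the master seed by counter
ga_seed <- function(master, round) {
  (as.integer(master) %% 100003L) * 10007L + 13L * as.integer(round)
}

#' Mutate a sequence by uniform per-site substitution
#'
#' Each position is independently replaced with probability
#' `config$mutation_prob` by a residue drawn uniformly from the allowed
#' alphabet (the 20 canonical amino acids minus `forbidden_targets`;
#' the incumbent is included unless `allow_self = FALSE`). Length is
#' always preserved. Uses the current RNG state.
#'
#' @param seq A protein `cg_sequence`.
#' @param config A [ga_config()].
#' @return Mutated `cg_sequence`.
#' @export
mutate_sequence <- function(seq, config) {
  ch <- seq_chars(seq)
  hit <- runif(length(ch)) < config$mutation_prob
  if (any(hit)) {
    for (k in which(hit)) {
      pool <- config$alphabet
      if (!config$allow_self) pool <- setdiff(pool, ch[k])
      ch[k] <- pool[sample.int(length(pool), 1)]
    }
  }
  new_sequence(seq$id, seq$kind, paste(ch, collapse = ""))
}

mutate_individual <- function(ind, config) {
  if (config$mode %in% c("both", "A")) ind$seqA <- mutate_sequence(ind$seqA, config)
  if (config$mode %in% c("both", "B")) ind$seqB <- mutate_sequence(ind$seqB, config)
  ind$fitness <- NA_real_
  ind
}

#' Initial population: randomly mutated copies of a base individual
#'
#' @param base An [individual()] (the reference system's sequences).
#' @param config A [ga_config()]; the population is seeded from
#'   `config$seed`.
#' @return List of `population_size` individuals (unevaluated).
#' @export
init_population <- function(base, config) {
  with_seed(config$seed, {
    lapply(seq_len(config$population_size), function(k) {
      mutate_individual(base, config)
    })
  })
}

population_fitness <- function(population) {
  vapply(population, function(i) i$fitness, numeric(1))
}

#' Tournament selection
#'
#' Picks the highest-fitness individual from a uniformly drawn subset of
#' `tournament_size` members; ties go to the lowest index. Uses the
#' current RNG state.
#'
#' @param population List of evaluated individuals.
#' @param config A [ga_config()].
#' @return The selected individual.
#' @export
tournament_select <- function(population, config) {
  fit <- population_fitness(population)
  if (anyNA(fit)) stop("tournament_select: population not fully evaluated")
  idx <- sort(sample.int(length(population), config$tournament_size))
  population[[idx[which.max(fit[idx])]]]
}

#' Single-point crossover of two individuals
#'
#' A cut position is drawn uniformly from `0 .. L-1` of the evolvable
#' region (the evolved protein under modes `"A"`/`"B"`, the combined
#' two-protein sequence under `"both"`); the suffixes beyond the cut are
#' exchanged. A cut at 0 yields the swapped parents.
#'
#' @param p1,p2 Parent individuals with equal sequence lengths.
#' @param config A [ga_config()].
#' @return List of two child individuals (unevaluated).
#' @export
crossover_pair <- function(p1, p2, config) {
  a1 <- seq_chars(p1$seqA); b1 <- seq_chars(p1$seqB)
  a2 <- seq_chars(p2$seqA); b2 <- seq_chars(p2$seqB)
  stopifnot(length(a1) == length(a2), length(b1) == length(b2))
  la <- length(a1); lb <- length(b1)
  L <- switch(config$mode, A = la, B = lb, both = la + lb)
  cut <- sample.int(L, 1) - 1L  # 0-based cut in the evolvable region
  swap_tail <- function(x, y, from) {
    if (from <= length(x)) {
      tmp <- x[from:length(x)]
      x[from:length(x)] <- y[from:length(y)]
      y[from:length(y)] <- tmp
    }
    list(x, y)
  }
  if (config$mode == "A") {
    sw <- swap_tail(a1, a2, cut + 1L)
    a1 <- sw[[1]]; a2 <- sw[[2]]
  } else if (config$mode == "B") {
    sw <- swap_tail(b1, b2, cut + 1L)
    b1 <- sw[[1]]; b2 <- sw[[2]]
  } else {
    comb1 <- c(a1, b1); comb2 <- c(a2, b2)
    sw <- swap_tail(comb1, comb2, cut + 1L)
    a1 <- sw[[1]][seq_len(la)]; b1 <- sw[[1]][la + seq_len(lb)]
    a2 <- sw[[2]][seq_len(la)]; b2 <- sw[[2]][la + seq_len(lb)]
  }
  mk <- function(tmpl, ch) new_sequence(tmpl$id, tmpl$kind,
                                        paste(ch, collapse = ""))
  list(individual(mk(p1$seqA, a1), mk(p1$seqB, b1)),
       individual(mk(p2$seqA, a2), mk(p2$seqB, b2)))
}

#' Weak population replacement
#'
#' The child enters the population only if strictly fitter than the
#' current weakest member, replacing that member; ties leave the
#' population unchanged. Size is preserved.
#'
#' @param population List of evaluated individuals.
#' @param child An individual.
#' @param fitness The child's fitness.
#' @return The (possibly updated) population.
#' @export
weak_replace <- function(population, child, fitness) {
  fit <- population_fitness(population)
  w <- which.min(fit)
  if (fitness > fit[w]) {
    child$fitness <- fitness
    population[[w]] <- child
  }
  population
}

#' Cache-aware fitness evaluation
#'
#' @param ind An individual.
#' @param evaluator Function mapping an individual to a fitness.
#' @param cache Environment mapping combined sequences to fitness values.
#' @return List with `fitness` and logical `hit`.
#' @export
evaluate_fitness <- function(ind, evaluator, cache) {
  key <- ind_key(ind)
  if (!is.null(cache[[key]])) {
    return(list(fitness = cache[[key]], hit = TRUE))
  }
  f <- evaluator(ind)
  cache[[key]] <- f
  list(fitness = f, hit = FALSE)
}

#' One genetic-algorithm round
#'
#' Selects `n_parents` parents by tournaments, shuffles them into
#' `n_pairs` random pairs, crosses each pair over, mutates the children,
#' evaluates them (via the cache), and applies weak replacement child by
#' child (the population updates incrementally within the round).
#'
#' @param population List of evaluated individuals.
#' @param evaluator Function individual -> fitness.
#' @param cache Fitness cache environment (see [new_fitness_cache()]).
#' @param config A [ga_config()].
#' @return List with the updated `population`, the `children`, and
#'   per-child `cache_hits`.
#' @export
run_round <- function(population, evaluator, cache, config) {
  parents <- lapply(seq_len(config$n_parents), function(k) {
    tournament_select(population, config)
  })
  ord <- sample.int(config$n_parents)
  children <- list()
  for (p in seq_len(config$n_pairs)) {
    pr <- crossover_pair(parents[[ord[2 * p - 1]]], parents[[ord[2 * p]]],
                         config)
    children <- c(children, pr)
  }
  children <- lapply(children, mutate_individual, config = config)
  hits <- logical(length(children))
  fit <- numeric(length(children))
  for (k in seq_along(children)) {
    ev <- evaluate_fitness(children[[k]], evaluator, cache)
    hits[k] <- ev$hit
    fit[k] <- ev$fitness
    population <- weak_replace(population, children[[k]], ev$fitness)
  }
  list(population = population, children = children, cache_hits = hits,
       child_fitness = fit)
}

#' @rdname evaluate_fitness
#' @export
new_fitness_cache <- function() new.env(parent = emptyenv())

#' Run a genetic algorithm
#'
#' Initializes the population from `base` (20 mutated copies), evaluates
#' it, then iterates [run_round()] for `n_rounds`, with a per-round RNG
#' stream derived from the master seed by counter.
#'
#' @param base An [individual()].
#' @param evaluator Function individual -> fitness (e.g. from
#'   [make_simulation_evaluator()] or a fast surrogate).
#' @param config A [ga_config()].
#' @param n_rounds Number of rounds.
#' @param cache Optional pre-filled fitness cache.
#' @param checkpoint Optional RDS path; the run state is saved there after
#'   every round, and an existing file resumes the run (identical
#'   continuation under the same seed, since per-round RNG streams are
#'   derived by counter).
#' @param verbose Print per-round progress.
#' @return List with `population`, `log` (data frame: round, best, mean,
#'   cache hits), `child_log` (one row per generated child: round, child
#'   index, sequences, fitness, cache-hit flag, rng stream id), `cache`,
#'   and `best` (fittest individual).
#' @export
run_ga <- function(base, evaluator, config, n_rounds, cache = NULL,
                   checkpoint = NULL, verbose = FALSE) {
  start_round <- 0L
  child_log <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    st <- readRDS(checkpoint)
    pop <- st$population
    cache <- new_fitness_cache()
    for (k in names(st$cache)) cache[[k]] <- st$cache[[k]]
    log <- st$log
    child_log <- st$child_log
    start_round <- st$round
  } else {
    if (is.null(cache)) cache <- new_fitness_cache()
    pop <- init_population(base, config)
    pop <- with_seed(ga_seed(config$seed, 0L), {
      lapply(pop, function(ind) {
        ind$fitness <- evaluate_fitness(ind, evaluator, cache)$fitness
        ind
      })
    })
    log <- data.frame(round = 0L, best = max(population_fitness(pop)),
                      mean = mean(population_fitness(pop)), cache_hits = 0L)
  }
  for (r in seq_len(n_rounds)) {
    if (r <= start_round) next
    res <- with_seed(ga_seed(config$seed, r), {
      run_round(pop, evaluator, cache, config)
    })
    pop <- res$population
    log <- rbind(log, data.frame(round = r,
                                 best = max(population_fitness(pop)),
                                 mean = mean(population_fitness(pop)),
                                 cache_hits = sum(res$cache_hits)))
    rows <- data.frame(
      round = r, child = seq_along(res$children),
      seqA = vapply(res$children, function(i) i$seqA$residues, character(1)),
      seqB = vapply(res$children, function(i) i$seqB$residues, character(1)),
      fitness = res$child_fitness, cache_hit = res$cache_hits,
      rng_stream = ga_seed(config$seed, r))
    child_log <- if (is.null(child_log)) rows else rbind(child_log, rows)
    if (!is.null(checkpoint)) {
      saveRDS(list(population = pop, cache = as.list(cache), log = log,
                   child_log = child_log, round = r), checkpoint)
    }
    if (verbose) {
      message(sprintf("round %d: best %.4f mean %.4f", r,
                      log$best[nrow(log)], log$mean[nrow(log)]))
    }
  }
  fit <- population_fitness(pop)
  list(population = pop, log = log, child_log = child_log, cache = cache,
       best = pop[[which.max(fit)]])
}

#' Simulation-backed fitness evaluator
#'
#' Returns a closure that, given an individual, rebuilds the mixture with
#' the individual's protein sequences (the RNA amount stays fixed at the
#' reference system's value even when evolved sequences are not charge
#' neutral), runs the direct-coexistence protocol, computes per-region
#' densities with the frozen region specification from the reference
#' system, and returns the configured fitness.
#'
#' @param template_spec The reference [system_spec] (copy counts, box,
#'   temperature are reused; components with roles `"A"` and `"B"` get the
#'   individual's sequences).
#' @param ff A [forcefield].
#' @param settings [integrator_settings()] (its seed makes evaluations
#'   deterministic per individual).
#' @param regions A frozen `region_spec` from the reference system.
#' @param config A [ga_config()] (fitness kind and `s`).
#' @param equil_time,prod_time Protocol times, ps.
#' @param n_bins Profile bins (default 150).
#' @return Function individual -> fitness.
#' @export
make_simulation_evaluator <- function(template_spec, ff, settings, regions,
                                      config, equil_time, prod_time,
                                      n_bins = 150) {
  force(template_spec); force(ff); force(settings); force(regions)
  force(config); force(equil_time); force(prod_time); force(n_bins)
  function(ind) {
    spec <- template_spec
    for (k in seq_along(spec$components)) {
      role <- spec$components[[k]]$role
      if (role == "A") spec$components[[k]]$seq <- ind$seqA
      if (role == "B") spec$components[[k]]$seq <- ind$seqB
    }
    run <- coexistence_protocol(spec, ff, settings, equil_time, prod_time)
    prof <- compute_profile(run$trajectory, run$topology, n_bins = n_bins)
    m <- phase_metrics(prof, regions, s = config$s)
    if (config$fitness_kind == "demix") m$f_demix else m$f_multiphase
  }
}
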