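base_ind <- individual(make_homopolymer("R", 50), make_homopolymer("K", 50))

test_that("initial population: 20 mutated copies, deterministic under
          seed, identical at zero mutation rate", {
  cfg <- ga_config(seed = 3)
  pop <- init_population(base_ind, cfg)
  expect_length(pop, 20)
  expect_identical(init_population(base_ind, cfg), pop)
  cfg0 <- ga_config(mutation_prob = 0, seed = 3)
  pop0 <- init_population(base_ind, cfg0)
  for (ind in pop0) {
    expect_identical(ind$seqA$residues, base_ind$seqA$residues)
    expect_identical(ind$seqB$residues, base_ind$seqB$residues)
  }
})

test_that("per-site substitution frequency sits in the 99% binomial band
          around 0.05 * 19/20", {
  cfg <- ga_config(seed = 1)
  n_trials <- 200   # 200 sequences x 50 sites = 10^4 site draws
  base <- make_homopolymer("A", 50)
  set.seed(101)
  changed <- 0
  for (k in seq_len(n_trials)) {
    mut <- mutate_sequence(base, cfg)
    changed <- changed + sum(strsplit(mut$residues, "")[[1]] != "A")
  }
  n <- n_trials * 50
  p <- 0.05 * 19 / 20
  band <- qbinom(c(0.005, 0.995), n, p)
  expect_gte(changed, band[1])
  expect_lte(changed, band[2])
})

test_that("forbidden mutation targets are never introduced and length is
          preserved", {
  cfg <- ga_config(forbidden_targets = c("Y", "F", "W"), seed = 2,
                   mutation_prob = 0.5)
  base <- make_homopolymer("A", 200)
  set.seed(7)
  for (k in 1:20) {
    mut <- mutate_sequence(base, cfg)
    ch <- strsplit(mut$residues, "")[[1]]
    expect_length(ch, 200)
    expect_false(any(ch %in% c("Y", "F", "W")))
  }
  cfg_r <- ga_config(forbidden_targets = "R", mutation_prob = 1, seed = 2)
  mut <- mutate_sequence(make_homopolymer("K", 100), cfg_r)
  expect_false(any(strsplit(mut$residues, "")[[1]] == "R"))
})

test_that("tournament selection: global best at full tournament size, and
          a unique top individual wins 1/4 of draws", {
  cfg <- ga_config(seed = 1)
  pop <- init_population(base_ind, cfg)
  for (k in seq_along(pop)) pop[[k]]$fitness <- k / 10
  cfg_all <- ga_config(tournament_size = 20)
  set.seed(5)
  for (k in 1:10) {
    expect_equal(tournament_select(pop, cfg_all)$fitness, 2.0)
  }
  # dominant individual at index 20; P(selected) = 1 - C(19,5)/C(20,5) = 1/4
  set.seed(42)
  wins <- sum(replicate(4000, tournament_select(pop, cfg)$fitness == 2.0))
  p_hat <- wins / 4000
  expect_lt(abs(p_hat - 0.25), 3 * sqrt(0.25 * 0.75 / 4000) + 0.005)
  expect_error(tournament_select(init_population(base_ind, cfg), cfg),
               "not fully evaluated")
})

test_that("crossover exchanges suffixes, preserves per-position multisets,
          and respects the evolvable region", {
  p1 <- individual(make_homopolymer("A", 10), make_homopolymer("C", 10))
  p2 <- individual(make_homopolymer("G", 10), make_homopolymer("S", 10))
  cfg <- ga_config(mode = "both")
  set.seed(3)
  for (k in 1:25) {
    ch <- crossover_pair(p1, p2, cfg)
    comb1 <- paste0(ch[[1]]$seqA$residues, ch[[1]]$seqB$residues)
    comb2 <- paste0(ch[[2]]$seqA$residues, ch[[2]]$seqB$residues)
    par1 <- paste0(p1$seqA$residues, p1$seqB$residues)
    par2 <- paste0(p2$seqA$residues, p2$seqB$residues)
    for (pos in 1:20) {
      expect_setequal(c(substr(comb1, pos, pos), substr(comb2, pos, pos)),
                      c(substr(par1, pos, pos), substr(par2, pos, pos)))
    }
  }
  # identical parents -> children equal parents
  ch <- crossover_pair(p1, p1, cfg)
  expect_identical(ch[[1]]$seqA$residues, p1$seqA$residues)
  expect_identical(ch[[2]]$seqB$residues, p1$seqB$residues)
  # mode B leaves seqA untouched
  cfgB <- ga_config(mode = "B")
  set.seed(4)
  for (k in 1:10) {
    ch <- crossover_pair(p1, p2, cfgB)
    expect_identical(ch[[1]]$seqA$residues, p1$seqA$residues)
    expect_identical(ch[[2]]$seqA$residues, p2$seqA$residues)
  }
})

test_that("weak replacement: strictly-fitter rule, one member replaced,
          ties rejected", {
  cfg <- ga_config(seed = 1)
  pop <- init_population(base_ind, cfg)
  for (k in seq_along(pop)) pop[[k]]$fitness <- k
  child <- individual(make_homopolymer("G", 50), make_homopolymer("G", 50))
  same <- weak_replace(pop, child, 0.5)
  expect_identical(population_fitness(same), population_fitness(pop))
  same2 <- weak_replace(pop, child, 1)  # tie with the weakest
  expect_identical(population_fitness(same2), population_fitness(pop))
  up <- weak_replace(pop, child, 1.5)
  expect_length(up, 20)
  expect_equal(sort(population_fitness(up))[1], 1.5)
  expect_identical(up[[1]]$seqA$residues, child$seqA$residues)
})

test_that("a round produces 8 children, keeps size 20, and never lowers
          the best fitness", {
  cfg <- ga_config(seed = 6)
  cache <- new_fitness_cache()
  pop <- init_population(base_ind, cfg)
  pop <- lapply(pop, function(i) {
    i$fitness <- stub_evaluator(i)
    i
  })
  best <- max(population_fitness(pop))
  set.seed(11)
  for (r in 1:10) {
    res <- run_round(pop, stub_evaluator, cache, cfg)
    pop <- res$population
    expect_length(res$children, 8)
    expect_length(pop, 20)
    nb <- max(population_fitness(pop))
    expect_gte(nb, best)
    best <- nb
  }
})

test_that("the fitness cache prevents repeat evaluations", {
  calls <- 0
  counting_eval <- function(ind) {
    calls <<- calls + 1
    stub_evaluator(ind)
  }
  cache <- new_fitness_cache()
  ind <- base_ind
  r1 <- evaluate_fitness(ind, counting_eval, cache)
  expect_false(r1$hit)
  expect_equal(calls, 1)
  r2 <- evaluate_fitness(ind, counting_eval, cache)
  expect_true(r2$hit)
  expect_equal(calls, 1)
  expect_equal(r2$fitness, r1$fitness)
})

test_that("full GA run: reproducible, monotone best fitness, seqA frozen
          under mode B", {
  cfg <- ga_config(mode = "B", seed = 9)
  res <- run_ga(base_ind, stub_evaluator, cfg, n_rounds = 25)
  expect_length(res$population, 20)
  expect_true(all(diff(res$log$best) >= 0))
  for (ind in res$population) {
    expect_identical(ind$seqA$residues, base_ind$seqA$residues)
  }
  res2 <- run_ga(base_ind, stub_evaluator, cfg, n_rounds = 25)
  expect_identical(res2$log, res$log)
  expect_identical(vapply(res2$population, condevol:::ind_key, character(1)),
                   vapply(res$population, condevol:::ind_key, character(1)))
  # with zero mutation and a constant evaluator the population is invariant
  cfg0 <- ga_config(mutation_prob = 0, seed = 2)
  resc <- run_ga(base_ind, function(ind) 1, cfg0, n_rounds = 5)
  expect_true(all(resc$log$best == 1))
  for (ind in resc$population) {
    expect_identical(ind$seqA$residues, base_ind$seqA$residues)
  }
})
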