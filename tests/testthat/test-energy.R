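test_that("neighbor list equals the brute-force pair scan and honors the
          minimum image", {
  # two beads beyond cutoff: empty list
  cfg <- make_config(rbind(c(1, 1, 1), c(1, 1, 3.5)), c(10, 10, 10))
  nl <- build_neighbor_list(cfg, cutoff = 2, skin = 0.3)
  expect_equal(nrow(nl$pairs), 0)
  # beads 0.1 nm apart across the periodic boundary are listed
  cfg2 <- make_config(rbind(c(0.05, 5, 5), c(9.95, 5, 5)), c(10, 10, 10))
  nl2 <- build_neighbor_list(cfg2, cutoff = 2, skin = 0.3)
  expect_equal(nrow(nl2$pairs), 1)
  # minimum-image validity precondition
  expect_error(build_neighbor_list(cfg, cutoff = 5, skin = 0.3),
               "min\\(box\\)/2")
  # equality with an O(N^2) scan on random beads
  set.seed(21)
  for (rep in 1:5) {
    n <- 200
    box <- c(6, 7, 8)
    pos <- cbind(runif(n) * box[1], runif(n) * box[2], runif(n) * box[3])
    got <- condevol:::cpp_neighbor_pairs(pos, box, 2.5)
    want <- 0
    for (i in 1:(n - 1)) {
      dv <- sweep(pos[(i + 1):n, , drop = FALSE], 2, pos[i, ])
      for (k in 1:3) dv[, k] <- dv[, k] - box[k] * round(dv[, k] / box[k])
      want <- want + sum(rowSums(dv^2) < 2.5^2)
    }
    expect_equal(nrow(got), want)
  }
})

test_that("cell-list energy and forces match the all-pairs R oracle to
          1e-9 on randomized periodic systems", {
  worst_e <- 0
  worst_f <- 0
  for (seed in 1:25) {
    gas <- random_gas(n = 120, box = c(5.5, 6, 6.5), seed = seed)
    e <- total_energy(gas$config, gas$topology, toy_ff)
    ref <- energy_reference(gas$config, gas$topology, toy_ff)
    worst_e <- max(worst_e, abs(e$total - ref$total) /
                     max(abs(ref$total), 1e-6))
    worst_f <- max(worst_f, max(abs(e$forces - ref$forces)) /
                     max(abs(ref$forces)))
  }
  for (seed in 1:25) {
    ch <- random_chains(n_chains = 4, len = 10, seed = seed)
    e <- total_energy(ch$config, ch$topology, toy_ff)
    ref <- energy_reference(ch$config, ch$topology, toy_ff)
    worst_e <- max(worst_e, abs(e$total - ref$total) /
                     max(abs(ref$total), 1e-6))
    worst_f <- max(worst_f, max(abs(e$forces - ref$forces)) /
                     max(abs(ref$forces)))
  }
  expect_lt(worst_e, 1e-9)
  expect_lt(worst_f, 1e-9)
})

test_that("directly bonded pairs interact only through the harmonic term", {
  spec <- system_spec(list(list(seq = make_homopolymer("R", 2), count = 1,
                                role = "A")), box = c(5, 5, 5))
  topo <- suppressWarnings(build_topology(spec, toy_ff))
  topo$charge <- c(0, 0)  # isolate the bond term
  pos <- rbind(c(2, 2, 2), c(2, 2, 2.381))
  e <- total_energy(make_config(pos, c(5, 5, 5)), topo, toy_ff)
  expect_equal(e$total, 0, tolerance = 1e-12)
  expect_equal(unname(e$by_term["short_range"]), 0)
  expect_equal(unname(e$by_term["electrostatic"]), 0)
  # unbonding them switches the nonbonded terms back on
  topo$bonds <- matrix(integer(0), 0, 2)
  topo$bond_ref <- numeric(0)
  e2 <- total_energy(make_config(pos, c(5, 5, 5)), topo, toy_ff)
  expect_true(abs(e2$by_term[["short_range"]]) > 0)
})

test_that("two disconnected neutral beads at r = sigma have zero energy", {
  spec <- system_spec(list(list(seq = make_homopolymer("G", 1), count = 2,
                                role = "A")), box = c(5, 5, 5))
  topo <- suppressWarnings(build_topology(spec, toy_ff))
  sig <- pair_params(toy_ff, "G", "G")$sigma
  pos <- rbind(c(1, 1, 1), c(1, 1, 1 + sig))
  e <- total_energy(make_config(pos, c(5, 5, 5)), topo, toy_ff)
  expect_equal(e$total, 0, tolerance = 1e-12)
})

test_that("forces: Newton's third law, translation invariance, and
          agreement with central differences of the energy", {
  gas <- random_gas(n = 60, box = c(5, 5, 5), seed = 3)
  f <- forces(gas$config, gas$topology, toy_ff)
  expect_lt(max(abs(colSums(f))), 1e-9)
  # translation invariance (including across the boundary)
  shifted <- gas$config
  shifted$pos <- sweep(gas$config$pos, 2, c(1.3, -0.7, 2.9), "+")
  e0 <- total_energy(gas$config, gas$topology, toy_ff)$total
  e1 <- total_energy(shifted, gas$topology, toy_ff)$total
  expect_equal(e1, e0, tolerance = 1e-9)
  # central differences on the largest-force coordinates (the relative
  # check is meaningful there; tiny components are roundoff-limited)
  h <- 1e-5
  ord <- order(abs(f), decreasing = TRUE)[1:8]
  for (idx in ord) {
    i <- (idx - 1) %% 60 + 1
    dim <- (idx - 1) %/% 60 + 1
    cp <- gas$config
    cp$pos[i, dim] <- cp$pos[i, dim] + h
    ep <- total_energy(cp, gas$topology, toy_ff)$total
    cp$pos[i, dim] <- cp$pos[i, dim] - 2 * h
    em <- total_energy(cp, gas$topology, toy_ff)$total
    fd <- -(ep - em) / (2 * h)
    expect_lt(abs(f[i, dim] - fd) / abs(f[i, dim]), 1e-5)
  }
  # isolated bead: zero force
  lone <- random_gas(n = 1, box = c(5, 5, 5), seed = 1, codes = "R")
  expect_equal(max(abs(forces(lone$config, lone$topology, toy_ff))), 0)
})

test_that("overlapping beads raise a singularity error naming the pair", {
  spec <- system_spec(list(list(seq = make_homopolymer("G", 1), count = 2,
                                role = "A")), box = c(5, 5, 5))
  topo <- suppressWarnings(build_topology(spec, toy_ff))
  pos <- rbind(c(1, 1, 1), c(1, 1, 1))
  expect_error(total_energy(make_config(pos, c(5, 5, 5)), topo, toy_ff),
               "overlapping")
})

test_that("species-group decomposition is complete, conservative and
          bilinear", {
  ps <- system_preset("micro", toy_ff)
  topo <- build_topology(ps$spec, toy_ff)
  set.seed(31)
  box <- ps$spec$box
  pos <- cbind(runif(topo$n) * box[1], runif(topo$n) * box[2],
               runif(topo$n) * box[3])
  cfg <- make_config(pos, box)
  rep <- total_energy(cfg, topo, toy_ff, by_group = TRUE)
  g <- rep$by_group
  # sum over unordered group pairs = total nonbonded energy
  tot_nb <- rep$by_term[["short_range"]] + rep$by_term[["electrostatic"]]
  expect_equal(sum(g[upper.tri(g, diag = TRUE)]), tot_nb, tolerance = 1e-9)
  expect_equal(rep$total, sum(rep$by_term), tolerance = 1e-12)
  # groupA = groupB = everything reproduces the total nonbonded energy
  all_e <- species_pair_energy(list(pos), topo, toy_ff,
                               seq_len(topo$n), seq_len(topo$n), box = box)
  expect_equal(all_e$mean, tot_nb, tolerance = 1e-9)
  # bilinearity: merging A and B adds their rows
  ab <- species_pair_energy(list(pos), topo, toy_ff, c("A", "B"), "RNA",
                            box = box)$mean
  a_rna <- species_pair_energy(list(pos), topo, toy_ff, "A", "RNA",
                               box = box)$mean
  b_rna <- species_pair_energy(list(pos), topo, toy_ff, "B", "RNA",
                               box = box)$mean
  expect_equal(ab, a_rna + b_rna, tolerance = 1e-9)
  expect_equal(g["A", "RNA"], a_rna, tolerance = 1e-9)
  # overlapping but non-identical groups are rejected
  expect_error(species_pair_energy(list(pos), topo, toy_ff, 1:10, 5:20,
                                   box = box), "disjoint")
})

test_that("arginine-uracil pairs are more cohesive than lysine-uracil in a
          mixed condensed configuration", {
  # energetic ordering at equal geometry: swap R and K identities
  ps <- system_preset("micro", toy_ff)
  sys <- build_system(ps$spec, toy_ff, seed = 2)
  e_ru <- species_pair_energy(list(sys$configuration$pos), sys$topology,
                              toy_ff, "R", "U", by = "code",
                              box = sys$configuration$box)$mean
  e_ku <- species_pair_energy(list(sys$configuration$pos), sys$topology,
                              toy_ff, "K", "U", by = "code",
                              box = sys$configuration$box)$mean
  # both attractive overall in the grown slab; R-U more negative
  expect_lt(e_ru, e_ku)
})
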