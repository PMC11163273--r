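# Shared fixtures: small randomized systems built in code.

toy_ff <- toy_forcefield()

# a configuration is a plain list; tests build them directly
make_config <- function(pos, box, vel = NULL) {
  if (is.null(vel)) vel <- matrix(0, nrow(pos), 3)
  structure(list(pos = pos, vel = vel, box = box, time = 0),
            class = "configuration")
}

# random unbonded gas of beads drawn from the toy alphabet
random_gas <- function(n = 200, box = c(6, 6, 6), seed = 1,
                       codes = c("R", "K", "U", "G", "Y")) {
  set.seed(seed)
  code <- sample(codes, n, replace = TRUE)
  spec <- system_spec(lapply(seq_len(n), function(k) {
    list(seq = make_homopolymer(code[k], 1), count = 1,
         role = if (code[k] == "U") "RNA" else "A")
  }), box = box, temperature = 250)
  topo <- suppressWarnings(build_topology(spec, toy_ff))
  pos <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), runif(n, 0, box[3]))
  list(topology = topo, config = make_config(pos, box))
}

# a few short chains with bonds, random walk positions
random_chains <- function(n_chains = 3, len = 8, box = c(8, 8, 8), seed = 1,
                          code = "G") {
  spec <- system_spec(list(list(seq = make_homopolymer(code, len),
                                count = n_chains, role = "A")),
                      box = box, temperature = 250)
  topo <- suppressWarnings(build_topology(spec, toy_ff))
  set.seed(seed)
  pos <- matrix(0, topo$n, 3)
  min2 <- 0.38^2  # keep nonbonded contacts off the steep repulsive wall
  at <- 1
  for (c in seq_len(n_chains)) {
    repeat {
      p <- runif(3) * box
      if (at == 1) break
      d2 <- sweep(pos[1:(at - 1), , drop = FALSE], 2, p)
      if (min(rowSums(d2^2)) > min2) break
    }
    for (b in seq_len(len)) {
      pos[at, ] <- p
      repeat {
        d <- rnorm(3)
        cand <- p + 0.381 * d / sqrt(sum(d^2))
        d2 <- sweep(pos[1:at, , drop = FALSE], 2, cand)
        if (min(rowSums(d2^2)) > min2) break
      }
      p <- cand
      at <- at + 1
    }
  }
  list(topology = topo, config = make_config(pos, box))
}

# step-function density profile fixture
step_profile <- function(n_bins = 150, box = c(7, 7, 25),
                         a_bins, b_bins, rna_bins = integer(0),
                         value = 1) {
  dens <- matrix(0, n_bins, 3, dimnames = list(NULL, c("A", "B", "RNA")))
  dens[a_bins, "A"] <- value
  dens[b_bins, "B"] <- value
  dens[rna_bins, "RNA"] <- value
  structure(list(n_bins = n_bins,
                 edges = seq(0, box[3], length.out = n_bins + 1),
                 z = seq(0, box[3], length.out = n_bins + 1)[-1] -
                   box[3] / (2 * n_bins),
                 density = dens, species = c("A", "B", "RNA"),
                 bin_volume = box[1] * box[2] * box[3] / n_bins,
                 n_frames = 1, box = box), class = "density_profile")
}

# deterministic stub fitness: rewards arginine content of seqA minus seqB
stub_evaluator <- function(ind) {
  a <- mean(strsplit(ind$seqA$residues, "")[[1]] == "R")
  b <- mean(strsplit(ind$seqB$residues, "")[[1]] == "R")
  a - b
}
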