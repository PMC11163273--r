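test_that("wf_alpha matches hand evaluation and depends on R/sigma only", {
  # (R/sigma)^2 = 9, nu = 1: alpha = 2*9*(3/16)^3 * ... = 18*(3/16)^3
  expect_equal(wf_alpha(0.5, 1, 1, 1.5), 18 * (3 / 16)^3, tolerance = 1e-12)
  expect_equal(wf_alpha(1.0, 2, 1, 3.0), wf_alpha(0.3, 2, 1, 0.9),
               tolerance = 1e-12)
  set.seed(42)
  for (k in 1:10) {
    sig <- runif(1, 0.3, 0.8)
    expect_gt(wf_alpha(sig, sample(1:3, 1), 1, 3 * sig), 0)
  }
  expect_error(wf_alpha(-1, 1, 1, 1), "non-positive|R > sigma")
  expect_error(wf_alpha(0.5, 1, 1, 0.4), "R > sigma")
  expect_error(wf_alpha(NaN, 1, 1, 1), "non-finite")
})

test_that("Wang-Frenkel potential vanishes at sigma and beyond R, and has
          well depth -epsilon (numerical-minimization oracle)", {
  set.seed(7)
  for (k in 1:20) {
    p <- list(epsilon = runif(1, 0.2, 3), sigma = runif(1, 0.3, 0.8),
              mu = sample(1:3, 1), nu = 1)
    p$R <- 3 * p$sigma
    expect_equal(wf_pair(p$sigma, p)$energy, 0, tolerance = 1e-14)
    expect_identical(wf_pair(p$R, p)$energy, 0)
    expect_identical(wf_pair(p$R, p)$force, 0)
    expect_identical(wf_pair(p$R * 1.2, p)$energy, 0)
    # independent oracle: scalar minimization of the energy curve
    opt <- optimize(function(r) wf_pair(r, p)$energy,
                    c(p$sigma, p$R), tol = 1e-10)
    expect_equal(opt$objective, -p$epsilon, tolerance = 1e-6)
    # smooth at the cutoff: energy (~ d^2) and force (~ d) both tend to 0
    expect_lt(abs(wf_pair(p$R - 1e-5, p)$energy), 1e-7)
    expect_lt(abs(wf_pair(p$R - 1e-5, p)$force), 1e-2)
    expect_lt(abs(wf_pair(p$R - 1e-7, p)$force),
              abs(wf_pair(p$R - 1e-5, p)$force) / 50 + 1e-12)
  }
  expect_error(wf_pair(0, list(epsilon = 1, sigma = 0.5, mu = 2, nu = 1,
                               R = 1.5)), "singular")
})

test_that("Wang-Frenkel force agrees with central differences", {
  p <- list(epsilon = 1.7, sigma = 0.5, mu = 2, nu = 1, R = 1.5)
  h <- 1e-6
  for (r in c(0.45, 0.55, 0.7, 1.0, 1.3)) {
    fd <- -(wf_pair(r + h, p)$energy - wf_pair(r - h, p)$energy) / (2 * h)
    expect_equal(wf_pair(r, p)$force, fd, tolerance = 1e-6)
  }
})

test_that("Debye-Hueckel pair obeys the screening law and the cutoff", {
  ff <- toy_ff
  expect_identical(dh_pair(3.6, 1, 1, ff)$energy, 0)
  expect_identical(dh_pair(0.5, 0, 1, ff)$energy, 0)
  expect_identical(dh_pair(0.5, 0, 1, ff)$force, 0)
  # 138.935458/(80*0.795) * exp(-1)
  expect_equal(dh_pair(0.795, 1, 1, ff)$energy, 0.80, tolerance = 0.005)
  # E * r * exp(r/lambda_D) constant below cutoff
  r <- seq(0.4, 3.4, by = 0.2)
  e <- dh_pair(r, 1, -1, ff)$energy
  const <- e * r * exp(r / ff$debye_length)
  expect_lt(diff(range(const)) / abs(mean(const)), 1e-12)
  # force from central differences
  h <- 1e-6
  fd <- -(dh_pair(1 + h, 1, -1, ff)$energy -
            dh_pair(1 - h, 1, -1, ff)$energy) / (2 * h)
  expect_equal(dh_pair(1, 1, -1, ff)$force, fd, tolerance = 1e-6)
  expect_error(dh_pair(0, 1, 1, ff), "singular")
})

test_that("harmonic bond energy: printed constant converts to 40.15 kJ/mol
          at a 100 pm stretch, and the well is symmetric", {
  expect_equal(bond_pair(0.381, 0.381, 8030)$energy, 0)
  expect_equal(bond_pair(0.481, 0.381, 8030)$energy, 40.15, tolerance = 1e-10)
  for (d in c(0.01, 0.05, 0.2)) {
    expect_equal(bond_pair(0.381 + d, 0.381, 8030)$energy,
                 bond_pair(0.381 - d, 0.381, 8030)$energy)
  }
  expect_error(bond_pair(-0.1, 0.381, 8030), "negative")
})

test_that("toy force field satisfies the stated interaction orderings and
          charge assignments", {
  ff <- toy_ff
  eps <- function(i, j) pair_params(ff, i, j)$epsilon
  expect_gt(eps("R", "U"), eps("K", "U"))
  for (a in c("Y", "F", "W")) {
    expect_gt(eps(a, a), eps(a, "U"))
    expect_gt(eps(a, "U"), eps("R", "U"))
  }
  q <- setNames(ff$beads$charge, ff$beads$code)
  expect_equal(unname(q[c("R", "K", "D", "E", "U")]), c(1, 1, -1, -1, -1))
  expect_equal(seq_charge(make_homopolymer("R", 50), ff), 50)
  # symmetry of all pair lookups
  expect_equal(pair_params(ff, "U", "R"), pair_params(ff, "R", "U"))
  tabs <- condevol:::ff_tables(ff)
  expect_identical(tabs$epsilon, t(tabs$epsilon))
  expect_identical(tabs$sigma, t(tabs$sigma))
})

test_that("force-field files round-trip and are validated", {
  ff <- toy_ff
  path <- withr::local_tempfile(fileext = ".ff")
  write_forcefield(ff, path)
  ff2 <- load_forcefield(path)
  expect_equal(ff2$pairs$epsilon, ff$pairs$epsilon, tolerance = 1e-9)
  expect_equal(ff2$pairs$alpha, ff$pairs$alpha, tolerance = 1e-9)
  expect_equal(ff2$beads, ff$beads, tolerance = 1e-9)
  expect_equal(ff2$bond_k, ff$bond_k)
  expect_equal(ff2$coulomb_cutoff, ff$coulomb_cutoff)

  # removing the U bead must fail validation naming "U"
  lines <- readLines(path)
  no_u <- lines[!grepl("(^U\t)|(\tU\t)", lines)]
  path2 <- withr::local_tempfile(fileext = ".ff")
  writeLines(no_u, path2)
  expect_error(load_forcefield(path2), "\"U\"")

  # non-positive sigma is rejected with row identification
  pr <- ff$pairs
  pr$sigma[3] <- -1
  expect_error(forcefield(ff$beads, pr), "sigma")

  # conflicting duplicate asymmetric entries are rejected
  pr <- ff$pairs
  dup <- pr[1, ]
  tmp <- dup$i; dup$i <- dup$j; dup$j <- tmp
  dup$epsilon <- dup$epsilon + 1
  expect_error(forcefield(ff$beads, rbind(pr, dup)), "duplicate")
})

test_that("the bundled toy parameter file loads, validates, and equals the
          programmatic defaults", {
  path <- system.file("extdata", "toy_forcefield.ff", package = "condevol")
  expect_true(nzchar(path))
  ff <- load_forcefield(path)
  ref <- toy_ff
  expect_equal(ff$beads, ref$beads, tolerance = 1e-9)
  expect_equal(ff$pairs$epsilon, ref$pairs$epsilon, tolerance = 1e-9)
  expect_equal(ff$coulomb_cutoff, 3.5)
})

test_that("missing nu and R default to 1 and 3*sigma at load time", {
  path <- withr::local_tempfile(fileext = ".ff")
  writeLines(c("[beads]",
               paste(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                       "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                     "protein", "0", "100", sep = "\t"),
               "U\trna\t-1\t306",
               "[pairs]",
               apply(expand.grid(i = c("A", "R", "N", "D", "C", "Q", "E",
                                       "G", "H", "I", "L", "K", "M", "F",
                                       "P", "S", "T", "W", "Y", "V", "U"),
                                 j = "U"), 1,
                     function(r) paste(r[1], r[2], "1.0", "0.5", sep = "\t")),
               apply(combn(c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
                             "I", "L", "K", "M", "F", "P", "S", "T", "W",
                             "Y", "V"), 2), 2,
                     function(p) paste(p[1], p[2], "1.0", "0.5", sep = "\t")),
               paste(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                       "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                     c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                       "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                     "1.0", "0.5", sep = "\t")), path)
  ff <- load_forcefield(path)
  expect_true(all(ff$pairs$nu == 1))
  expect_true(all(abs(ff$pairs$R - 3 * ff$pairs$sigma) < 1e-12))
  expect_equal(ff$dielectric, 80)
  expect_equal(ff$debye_length, 0.795)
  expect_equal(ff$coulomb_cutoff, 3.5)
})
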