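kB <- 0.008314462618

mb_velocities <- function(topo, temperature, seed) {
  set.seed(seed)
  matrix(rnorm(3 * topo$n), ncol = 3) * sqrt(kB * temperature / topo$mass)
}

test_that("zero forces and zero velocities are a fixed point of NVE", {
  spec <- system_spec(list(list(seq = make_homopolymer("G", 1), count = 2,
                                role = "A")), box = c(8, 8, 8))
  topo <- suppressWarnings(build_topology(spec, toy_ff))
  pos <- rbind(c(1, 1, 1), c(1, 1, 5))  # beyond every cutoff
  st <- make_config(pos, c(8, 8, 8))
  set <- integrator_settings(dt = 0.01, save_interval = 0.1)
  traj <- run_nve(st, topo, toy_ff, set, 100)
  expect_equal(traj$final$pos, pos, tolerance = 1e-14)
  expect_equal(max(abs(traj$final$vel)), 0)
})

test_that("a bonded dimer oscillates at the analytic harmonic period", {
  spec <- system_spec(list(list(seq = make_homopolymer("G", 2), count = 1,
                                role = "A")), box = c(8, 8, 8))
  topo <- suppressWarnings(build_topology(spec, toy_ff))
  st <- make_config(rbind(c(4, 4, 4), c(4, 4, 4.45)), c(8, 8, 8))
  set <- integrator_settings(dt = 0.001, save_interval = 0.001)
  traj <- run_nve(st, topo, toy_ff, set, 3000)
  r <- vapply(traj$frames, function(p) abs(p[2, 3] - p[1, 3]), numeric(1))
  x <- r - 0.381
  up <- which(x[-1] > 0 & x[-length(x)] <= 0)
  period <- mean(diff(up)) * set$dt
  mu_red <- topo$mass[1] / 2
  expect_equal(period, 2 * pi * sqrt(mu_red / 8030), tolerance = 0.01)
})

test_that("NVE conserves energy (drift < 1e-4 over 2e4 steps at 1 fs) on a
          3-chain system", {
  ch <- random_chains(n_chains = 3, len = 8, box = c(8, 8, 8), seed = 2,
                      code = "G")
  ch$config$vel <- mb_velocities(ch$topology, 250, seed = 3)
  set <- integrator_settings(dt = 0.001, save_interval = 0.05,
                             com_motion_removal = FALSE)
  traj <- run_nve(ch$config, ch$topology, toy_ff, set, 20000)
  save_every <- round(set$save_interval / set$dt)
  etot <- traj$pe + traj$ke_trace[seq_along(traj$pe) * save_every]
  drift <- max(abs(etot - etot[1])) / abs(etot[1])
  expect_lt(drift, 1e-4)
})

test_that("NVE is reversible: velocity negation retraces the trajectory", {
  ch <- random_chains(n_chains = 2, len = 6, box = c(8, 8, 8), seed = 5,
                      code = "G")
  ch$config$vel <- mb_velocities(ch$topology, 250, seed = 6)
  set <- integrator_settings(dt = 0.001, save_interval = 1,
                             com_motion_removal = FALSE)
  fwd <- run_nve(ch$config, ch$topology, toy_ff, set, 2000)
  back_state <- fwd$final
  back_state$vel <- -back_state$vel
  back <- run_nve(back_state, ch$topology, toy_ff, set, 2000)
  # compare modulo the box (positions are kept wrapped)
  d <- back$final$pos - ch$config$pos
  for (k in 1:3) d[, k] <- d[, k] - 8 * round(d[, k] / 8)
  expect_lt(max(abs(d)), 1e-6)
})

test_that("Langevin trajectories are bitwise reproducible under a seed and
          differ across seeds", {
  ch <- random_chains(n_chains = 3, len = 8, box = c(8, 8, 8), seed = 2)
  ch$config$vel <- mb_velocities(ch$topology, 250, seed = 3)
  set1 <- integrator_settings(dt = 0.01, seed = 42, save_interval = 1)
  t1 <- run_langevin(ch$config, ch$topology, toy_ff, set1, 500)
  t2 <- run_langevin(ch$config, ch$topology, toy_ff, set1, 500)
  expect_identical(t1$final$pos, t2$final$pos)
  expect_identical(t1$frames, t2$frames)
  set2 <- integrator_settings(dt = 0.01, seed = 43, save_interval = 1)
  t3 <- run_langevin(ch$config, ch$topology, toy_ff, set2, 500)
  expect_false(identical(t1$final$pos, t3$final$pos))
})

test_that("thermostatted velocities are Maxwell-Boltzmann: variance kT/m
          within 5% and component-wise normality", {
  # dilute gas of monomers so sampling is fast and nearly ideal
  spec <- system_spec(list(list(seq = make_homopolymer("G", 1), count = 60,
                                role = "A")), box = c(12, 12, 12))
  topo <- suppressWarnings(build_topology(spec, toy_ff))
  set.seed(9)
  pos <- matrix(runif(180) * 12, ncol = 3)
  st <- make_config(pos, c(12, 12, 12))
  st$vel <- mb_velocities(topo, 250, seed = 10)
  set <- integrator_settings(dt = 0.01, seed = 5, save_interval = 2,
                             save_velocities = TRUE,
                             com_motion_removal = FALSE)
  traj <- run_langevin(st, topo, toy_ff, set, 20000)  # 200 ps
  v <- do.call(rbind, traj$vel_frames[50:100])
  expect_equal(var(as.numeric(v)), kB * 250 / topo$mass[1], tolerance = 0.05)
  sub <- as.numeric(v)
  sub <- sub[seq(1, length(sub), length.out = 4000)]
  expect_gt(stats::shapiro.test(sub)$p.value, 0.01)
})

test_that("center-of-mass motion removal keeps net momentum at zero", {
  ch <- random_chains(n_chains = 3, len = 8, box = c(8, 8, 8), seed = 2)
  ch$config$vel <- mb_velocities(ch$topology, 250, seed = 3)
  set <- integrator_settings(dt = 0.01, seed = 1, save_interval = 1,
                             save_velocities = TRUE,
                             com_motion_removal = TRUE)
  traj <- run_langevin(ch$config, ch$topology, toy_ff, set, 300)
  for (v in traj$vel_frames) {
    expect_lt(max(abs(colSums(v * ch$topology$mass))), 1e-8)
  }
})

test_that("Langevin at very large friction time approaches NVE drift
          behavior over short windows", {
  ch <- random_chains(n_chains = 3, len = 8, box = c(8, 8, 8), seed = 2)
  ch$config$vel <- mb_velocities(ch$topology, 250, seed = 3)
  set <- integrator_settings(dt = 0.001, friction_time = 1e9, seed = 1,
                             save_interval = 0.05,
                             com_motion_removal = FALSE)
  traj <- run_langevin(ch$config, ch$topology, toy_ff, set, 2000)
  save_every <- round(set$save_interval / set$dt)
  etot <- traj$pe + traj$ke_trace[seq_along(traj$pe) * save_every]
  expect_lt(max(abs(etot - etot[1])) / abs(etot[1]), 1e-3)
})

test_that("coexistence protocol bookkeeping: frame counts and the
          zero-equilibration identity", {
  spec <- system_spec(list(list(seq = make_homopolymer("G", 5), count = 4,
                                role = "A")), box = c(6, 6, 12))
  ff <- toy_ff
  set <- integrator_settings(dt = 0.01, seed = 2, save_interval = 1)
  run <- coexistence_protocol(spec, ff, set, equil_time = 0, prod_time = 10)
  expect_length(run$trajectory$frames, 10)
  sys <- build_system(spec, ff, seed = set$seed)
  wrapped <- sys$configuration$pos
  for (k in 1:3) wrapped[, k] <- wrapped[, k] %% spec$box[k]
  expect_equal(run$trajectory$frames[[1]], wrapped, tolerance = 1e-12)
  run2 <- coexistence_protocol(spec, ff, set, equil_time = 5, prod_time = 10)
  expect_length(run2$trajectory$frames, 10)
  expect_false(identical(run2$trajectory$frames[[1]],
                         run$trajectory$frames[[1]]))
})
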