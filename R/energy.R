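# Energy and force evaluation: cell-list accelerated C++ kernels plus a
# plain-R all-pairs reference used as an independent oracle in the tests.

#' Build a Verlet neighbor list
#'
#' Complete list of bead pairs within `cutoff + skin` under periodic
#' minimum image. The list remains valid until any bead has moved by more
#' than `skin / 2` from its build-time position.
#'
#' @param config A `configuration`.
#' @param cutoff Interaction cutoff, nm (typically
#'   `max(R_ij, coulomb_cutoff)`).
#' @param skin Verlet skin, nm (default 0.3).
#' @return A `neighbor_list` with the pair index matrix (1-based), the
#'   build-time positions and the radii.
#' @export
build_neighbor_list <- function(config, cutoff, skin = 0.3) {
  if (cutoff + skin >= min(config$box) / 2) {
    stop("build_neighbor_list: cutoff + skin must be < min(box)/2 ",
         "for minimum-image validity")
  }
  pairs <- cpp_neighbor_pairs(config$pos, config$box, cutoff + skin)
  structure(list(pairs = pairs, ref_pos = config$pos, cutoff = cutoff,
                 skin = skin), class = "neighbor_list")
}

# Internal: assemble C++ kernel arguments from (topology, ff).
ff_kernel_args <- function(topology, ff) {
  tabs <- ff_tables(ff)
  list(tabs = tabs,
       kq = .COULOMB / ff$dielectric,
       kappa = 1 / ff$debye_length,
       rcoul = ff$coulomb_cutoff,
       rlist = max(max(ff$pairs$R), ff$coulomb_cutoff))
}

#' Total energy of a configuration
#'
#' Bond term over all bonds; Wang-Frenkel and Debye-Hueckel terms over all
#' non-bonded pairs within their cutoffs. Directly bonded pairs interact
#' only through the harmonic term (the 1-2 exclusion rule).
#'
#' @param config A `configuration`.
#' @param topology A `topology`.
#' @param ff A [forcefield].
#' @param by_group If `TRUE`, also decompose the nonbonded energy over
#'   species-label pairs (each unordered bead pair counted once).
#' @return An `energy_report`: `total`, `by_term` (bond, short_range,
#'   electrostatic), optionally `by_group` (symmetric matrix over species
#'   labels) and `forces`.
#' @export
total_energy <- function(config, topology, ff, by_group = FALSE) {
  ka <- ff_kernel_args(topology, ff)
  groups <- integer(topology$n)
  labels <- character(0)
  ngroup <- 0L
  if (by_group) {
    labels <- sort(unique(topology$species))
    groups <- match(topology$species, labels) - 1L
    ngroup <- length(labels)
  }
  res <- cpp_energy_forces(config$pos, config$box, topology$type,
                           topology$charge, topology$bonds - 1L,
                           topology$bond_ref, topology$bond_k,
                           ka$tabs$eps_alpha, ka$tabs$sigma, ka$tabs$mu,
                           ka$tabs$nu, ka$tabs$R, ka$kq, ka$kappa, ka$rcoul,
                           ka$rlist, groups, ngroup)
  rep <- list(total = res$total,
              by_term = c(bond = res$e_bond, short_range = res$e_wf,
                          electrostatic = res$e_elec),
              forces = res$forces)
  if (by_group) {
    g <- res$group_energy
    dimnames(g) <- list(labels, labels)
    rep$by_group <- g
  }
  structure(rep, class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat("<energy_report> total ", format(x$total), " kJ/mol\n", sep = "")
  cat("  bond ", format(x$by_term[["bond"]]),
      " | short-range ", format(x$by_term[["short_range"]]),
      " | electrostatic ", format(x$by_term[["electrostatic"]]), "\n",
      sep = "")
  if (!is.null(x$by_group)) {
    cat("  by species-pair group (kJ/mol):\n")
    print(round(x$by_group, 3))
  }
  invisible(x)
}

#' Forces on every bead
#'
#' Negative gradient of [total_energy()]; obeys Newton's third law
#' pairwise, so forces sum to zero.
#'
#' @inheritParams total_energy
#' @return N x 3 matrix, kJ mol^-1 nm^-1.
#' @export
forces <- function(config, topology, ff) {
  total_energy(config, topology, ff)$forces
}

#' All-pairs reference energy and forces (oracle)
#'
#' Brute-force O(N^2) evaluation in plain R, written directly from the
#' potential formulas and independent of the cell-list C++ path. Intended
#' for validation on small systems.
#'
#' @inheritParams total_energy
#' @return List with `e_bond`, `e_wf`, `e_elec`, `total`, `forces`.
#' @export
energy_reference <- function(config, topology, ff) {
  pos <- config$pos
  box <- config$box
  n <- nrow(pos)
  tabs <- ff_tables(ff)
  ti <- topology$type + 1L
  # all unordered pairs
  up <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- up[, 1]; j <- up[, 2]
  d <- pos[i, , drop = FALSE] - pos[j, , drop = FALSE]
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  r <- sqrt(rowSums(d^2))
  # drop directly bonded pairs from the nonbonded terms
  bkey <- paste(pmin(topology$bonds[, 1], topology$bonds[, 2]),
                pmax(topology$bonds[, 1], topology$bonds[, 2]))
  bonded <- paste(i, j) %in% bkey
  eps <- tabs$epsilon[cbind(ti[i], ti[j])]
  alp <- tabs$alpha[cbind(ti[i], ti[j])]
  sig <- tabs$sigma[cbind(ti[i], ti[j])]
  mu <- tabs$mu[cbind(ti[i], ti[j])]
  nu <- tabs$nu[cbind(ti[i], ti[j])]
  Rc <- tabs$R[cbind(ti[i], ti[j])]
  qq <- topology$charge[i] * topology$charge[j]

  act <- !bonded & r < Rc
  e_wf_v <- numeric(length(r))
  f_v <- numeric(length(r))  # fscal: F_i += fscal * d_ij
  if (any(act)) {
    u <- (sig[act] / r[act])^(2 * mu[act])
    w <- (Rc[act] / r[act])^(2 * mu[act])
    A <- u - 1; B <- w - 1
    e_wf_v[act] <- eps[act] * alp[act] * A * B^(2 * nu[act])
    f_v[act] <- eps[act] * alp[act] * (2 * mu[act] / r[act]^2) *
      (u * B^(2 * nu[act]) + A * 2 * nu[act] * B^(2 * nu[act] - 1) * w)
  }
  ael <- !bonded & qq != 0 & r < ff$coulomb_cutoff
  e_el_v <- numeric(length(r))
  if (any(ael)) {
    kq <- .COULOMB / ff$dielectric
    kappa <- 1 / ff$debye_length
    e <- kq * qq[ael] * exp(-kappa * r[ael]) / r[ael]
    e_el_v[ael] <- e
    f_v[ael] <- f_v[ael] + e * (kappa + 1 / r[ael]) / r[ael]
  }
  F <- matrix(0, n, 3)
  for (k in 1:3) {
    fk <- f_v * d[, k]
    F[, k] <- tapply(c(fk, -fk), c(i, j), sum)[as.character(seq_len(n))]
  }
  F[is.na(F)] <- 0
  # bonds
  bi <- topology$bonds[, 1]; bj <- topology$bonds[, 2]
  db <- pos[bi, , drop = FALSE] - pos[bj, , drop = FALSE]
  for (k in 1:3) db[, k] <- db[, k] - box[k] * round(db[, k] / box[k])
  rb <- sqrt(rowSums(db^2))
  e_bond <- sum(0.5 * topology$bond_k * (rb - topology$bond_ref)^2)
  fs <- -topology$bond_k * (rb - topology$bond_ref) / rb
  for (k in 1:3) {
    fk <- fs * db[, k]
    add <- tapply(c(fk, -fk), c(bi, bj), sum)
    idx <- as.integer(names(add))
    F[idx, k] <- F[idx, k] + add
  }
  list(e_bond = e_bond, e_wf = sum(e_wf_v), e_elec = sum(e_el_v),
       total = e_bond + sum(e_wf_v) + sum(e_el_v), forces = F)
}

# Resolve a bead selector to indices: integer indices pass through;
# character vectors match species labels (by = "species") or bead codes
# (by = "code").
resolve_beads <- function(topology, sel, by = c("species", "code")) {
  if (is.numeric(sel)) return(as.integer(sel))
  by <- match.arg(by)
  if (by == "species") which(topology$species %in% sel)
  else which(topology$code %in% sel)
}

#' Time-averaged interaction energy between two bead groups
#'
#' Nonbonded (short-range + electrostatic) energy between two groups,
#' averaged over trajectory frames. Supports the arginine-uracil vs
#' lysine-uracil comparison (via `by = "code"`) and inner/outer/RNA
#' species decompositions (via `by = "species"`).
#'
#' @param frames List of N x 3 position matrices (or a `trajectory`).
#' @param topology,ff As elsewhere.
#' @param groupA,groupB Bead selectors (indices, species labels or codes).
#' @param by How character selectors are resolved.
#' @param box Box lengths; taken from the trajectory if available.
#' @return List with `mean`, `sd` and the per-frame energies (kJ/mol).
#' @export
species_pair_energy <- function(frames, topology, ff, groupA, groupB,
                                by = c("species", "code"), box = NULL) {
  by <- match.arg(by)
  if (inherits(frames, "trajectory")) {
    box <- frames$box
    frames <- frames$frames
  }
  stopifnot(!is.null(box))
  ia <- resolve_beads(topology, groupA, by)
  ib <- resolve_beads(topology, groupB, by)
  same <- identical(sort(ia), sort(ib))
  overlap <- length(intersect(ia, ib)) > 0
  if (!same && overlap) {
    stop("species_pair_energy: groups must be disjoint or identical")
  }
  groups <- integer(topology$n) + 2L  # rest
  groups[ia] <- 0L
  groups[ib] <- 1L
  if (same) groups[ia] <- 0L
  ka <- ff_kernel_args(topology, ff)
  per <- vapply(frames, function(p) {
    res <- cpp_energy_forces(p, box, topology$type, topology$charge,
                             topology$bonds - 1L, topology$bond_ref,
                             topology$bond_k, ka$tabs$eps_alpha,
                             ka$tabs$sigma, ka$tabs$mu, ka$tabs$nu,
                             ka$tabs$R, ka$kq, ka$kappa, ka$rcoul, ka$rlist,
                             groups, 3L)
    if (same) res$group_energy[1, 1] else res$group_energy[1, 2]
  }, numeric(1))
  list(mean = mean(per), sd = stats::sd(per), per_frame = per)
}
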