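# Synthetic-data stage: sequence families, charge-matched mixtures,
# topologies and initial slab configurations.

new_sequence <- function(id, kind, residues) {
  stopifnot(nchar(residues) >= 1, kind %in% c("protein", "rna"))
  structure(list(id = id, kind = kind, residues = residues),
            class = "cg_sequence")
}

#' @export
print.cg_sequence <- function(x, ...) {
  cat("<cg_sequence> ", x$id, " (", x$kind, ", L=", nchar(x$residues), ")\n",
      sep = "")
  invisible(x)
}

seq_chars <- function(seq) strsplit(seq$residues, "")[[1]]

#' Net charge of a sequence under a force field
#' @param seq A sequence from [make_homopolymer()] and friends.
#' @param ff A [forcefield].
#' @return Total charge in elementary-charge units.
#' @export
seq_charge <- function(seq, ff) {
  q <- setNames(ff$beads$charge, ff$beads$code)
  ch <- seq_chars(seq)
  unknown <- setdiff(unique(ch), names(q))
  if (length(unknown)) {
    stop("sequence ", seq$id, " uses bead(s) absent from force field: ",
         paste(unknown, collapse = ", "))
  }
  sum(q[ch])
}

#' Homopolymer sequence
#'
#' @param code One-letter bead code (e.g. `"R"`, `"K"`, `"U"`).
#' @param n Chain length (>= 1).
#' @param kind `"protein"` or `"rna"`; inferred (`"U"` is RNA) when `NULL`.
#' @return A `cg_sequence`, e.g. R50 or U10.
#' @export
make_homopolymer <- function(code, n, kind = NULL) {
  stopifnot(n >= 1, nchar(code) == 1)
  if (is.null(kind)) kind <- if (code == "U") "rna" else "protein"
  new_sequence(sprintf("%s%d", code, n), kind,
               paste(rep(code, n), collapse = ""))
}

#' Mixed arginine/lysine sequence RmK(L-m)
#'
#' Builds a protein chain with exactly `m` arginines and `L - m` lysines in
#' one of three arrangements: a contiguous `block` (R-block then K-block),
#' a seeded `random` shuffle, or an `alternating` pattern that spreads the
#' minority residue as evenly as possible.
#'
#' @param m Number of arginines, `0 <= m <= L`.
#' @param L Chain length (default 50).
#' @param arrangement `"block"`, `"random"` or `"alternating"`.
#' @param seed Integer seed used by the `"random"` arrangement.
#' @return A `cg_sequence` whose id encodes `m`, the arrangement and seed.
#' @export
make_rk_sequence <- function(m, L = 50,
                             arrangement = c("block", "random", "alternating"),
                             seed = 1L) {
  arrangement <- match.arg(arrangement)
  stopifnot(m >= 0, m <= L)
  res <- switch(arrangement,
    block = c(rep("R", m), rep("K", L - m)),
    random = {
      res <- c(rep("R", m), rep("K", L - m))
      with_seed(seed, sample(res))
    },
    alternating = {
      res <- rep("K", L)
      if (m > 0) res[unique(round(seq(1, L, length.out = m)))] <- "R"
      # rounding can collide; patch up to exact composition
      need <- m - sum(res == "R")
      if (need > 0) res[which(res == "K")[seq_len(need)]] <- "R"
      res
    })
  tag <- if (arrangement == "random") sprintf("_s%d", seed) else ""
  new_sequence(sprintf("R%dK%d_%s%s", m, L - m, arrangement, tag), "protein",
               paste(res, collapse = ""))
}

#' Repeat-motif sequence
#'
#' @param motif Nonempty residue motif, e.g. `"NNNGG"` or `"FFFGG"`.
#' @param copies Number of repeats.
#' @param kind `"protein"` (default) or `"rna"`.
#' @return A `cg_sequence`, e.g. (NNNGG)10.
#' @export
make_repeat <- function(motif, copies, kind = "protein") {
  stopifnot(nchar(motif) >= 1, copies >= 1)
  new_sequence(sprintf("(%s)%d", motif, copies), kind,
               paste(rep(motif, copies), collapse = ""))
}

#' Charge-matched poly-uracil copy count
#'
#' Smallest number of Un chains that brings the net charge of a protein
#' mixture to exactly zero.
#'
#' @param protein_components List of `list(seq =, count =)` entries.
#' @param rna_length Length n of the poly-uracil chains.
#' @param ff A [forcefield].
#' @return Integer copy count of Un.
#' @export
charge_matched_rna_count <- function(protein_components, rna_length, ff) {
  stopifnot(rna_length >= 1)
  qtot <- sum(vapply(protein_components,
                     function(comp) comp$count * seq_charge(comp$seq, ff),
                     numeric(1)))
  if (qtot < 0) stop("charge_matched_rna_count: net protein charge is negative")
  qU <- abs(ff$beads$charge[ff$beads$code == "U"])
  if (length(qU) != 1 || qU == 0) {
    stop("charge_matched_rna_count: force field lacks a charged \"U\" bead")
  }
  per_chain <- rna_length * qU
  copies <- qtot / per_chain
  if (abs(copies - round(copies)) > 1e-9) {
    stop(sprintf(paste0("charge_matched_rna_count: protein charge %+g e is not",
                        " divisible by U%d chain charge %g e (residual %g e)"),
                 qtot, rna_length, per_chain,
                 qtot - floor(copies) * per_chain))
  }
  as.integer(round(copies))
}

#' Declarative mixture description
#'
#' @param components List of `list(seq =, count =, role =)`; `role` labels
#'   the species for profile analysis and energy decomposition (defaults:
#'   `"A"`, `"B"`, ... for proteins in order, `"RNA"` for RNA).
#' @param box Box lengths `c(Lx, Ly, Lz)` in nm; slab geometry expects the
#'   long axis on z (warned otherwise).
#' @param temperature Kelvin.
#' @param charge_overrides List of `list(selector =, charge =, fraction =)`
#'   applied after topology construction (see [apply_charge_override()]).
#' @return A `system_spec`.
#' @export
system_spec <- function(components, box, temperature = 250,
                        charge_overrides = list()) {
  stopifnot(length(box) == 3, all(box > 0))
  nprot <- 0
  for (k in seq_along(components)) {
    comp <- components[[k]]
    stopifnot(!is.null(comp$seq), comp$count > 0)
    if (is.null(comp$role)) {
      if (comp$seq$kind == "rna") {
        components[[k]]$role <- "RNA"
      } else {
        nprot <- nprot + 1
        components[[k]]$role <- LETTERS[nprot]
      }
    }
  }
  if (box[3] < max(box[1:2])) {
    warning("system_spec: Lz < Lx/Ly; slab geometry expects an elongated z axis")
  }
  structure(list(components = components, box = box,
                 temperature = temperature,
                 charge_overrides = charge_overrides),
            class = "system_spec")
}

#' Build a topology from a system specification
#'
#' Lays out beads chain by chain, assigns per-bead type/charge/mass/species
#' labels, creates consecutive-bead harmonic bonds, and applies charge
#' overrides. Positions are not involved; see [build_configuration()].
#'
#' @param spec A [system_spec].
#' @param ff A [forcefield].
#' @return A `topology`.
#' @export
build_topology <- function(spec, ff) {
  codes <- ff$beads$code
  qtab <- setNames(ff$beads$charge, codes)
  mtab <- setNames(ff$beads$mass, codes)
  code <- character(0)
  chain <- integer(0)
  species <- character(0)
  kind <- character(0)
  chain_id <- 0L
  for (comp in spec$components) {
    ch <- seq_chars(comp$seq)
    unknown <- setdiff(unique(ch), codes)
    if (length(unknown)) {
      stop("build_topology: force field missing bead(s) ",
           paste(unknown, collapse = ", "), " required by ", comp$seq$id)
    }
    for (cc in seq_len(comp$count)) {
      chain_id <- chain_id + 1L
      code <- c(code, ch)
      chain <- c(chain, rep(chain_id, length(ch)))
      species <- c(species, rep(comp$role, length(ch)))
      kind <- c(kind, rep(comp$seq$kind, length(ch)))
    }
  }
  n <- length(code)
  # bonds between consecutive beads within each chain
  same <- chain[-1] == chain[-n]
  i <- which(same)
  bonds <- cbind(i, i + 1L)
  bond_ref <- unname(ff$bond_ref[kind[i]])
  structure(list(
    n = n,
    code = code,
    type = match(code, codes) - 1L,  # 0-based for the C++ kernels
    charge = unname(qtab[code]),
    charge0 = unname(qtab[code]),
    mass = unname(mtab[code]),
    chain = chain,
    species = species,
    kind = kind,
    bonds = bonds,
    bond_ref = bond_ref,
    bond_k = ff$bond_k,
    codes = codes
  ), class = "topology") -> topo
  for (ov in spec$charge_overrides) {
    topo <- apply_charge_override(topo, ov$selector, ov$charge,
                                  fraction = if (is.null(ov$fraction)) 1 else ov$fraction,
                                  seed = if (is.null(ov$seed)) 1L else ov$seed)
  }
  topo
}

#' @export
print.topology <- function(x, ...) {
  cat("<topology> ", x$n, " beads, ", max(x$chain), " chains, ",
      nrow(x$bonds), " bonds; net charge ", sum(x$charge), " e\n", sep = "")
  invisible(x)
}

#' Set the charge of (a fraction of) selected beads
#'
#' Implements charge-zeroing variants such as neutralizing all arginine and
#' lysine beads, or zeroing the charge of a random fraction of the
#' negatively charged species.
#'
#' @param topology A `topology`.
#' @param selector Character vector of bead codes to match (e.g.
#'   `c("R", "K")`).
#' @param charge New charge (e).
#' @param fraction Fraction of matching beads to modify, in (0, 1].
#' @param seed Seed for the random subset when `fraction < 1`.
#' @return Modified `topology` (original charges stay in `$charge0`).
#' @export
apply_charge_override <- function(topology, selector, charge, fraction = 1,
                                  seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  idx <- which(topology$code %in% selector)
  if (fraction < 1) {
    k <- round(fraction * length(idx))
    idx <- with_seed(seed, sample(idx, k))
  }
  topology$charge[idx] <- charge
  topology
}

#' Restore pre-override charges
#' @param topology A `topology`.
#' @return `topology` with the original force-field charges.
#' @export
reset_charges <- function(topology) {
  topology$charge <- topology$charge0
  topology
}

#' Grow an initial slab configuration
#'
#' Chains are grown as self-avoiding random walks with bonded spacing at
#' the reference bond length, confined to the middle third of the long
#' axis so that direct coexistence equilibrates quickly. A short capped
#' steepest-descent relaxation removes residual overlaps, then velocities
#' are drawn from the Maxwell-Boltzmann distribution at the spec
#' temperature with zero total momentum.
#'
#' @param topology A `topology` from [build_topology()].
#' @param spec The originating [system_spec] (box, temperature).
#' @param ff A [forcefield].
#' @param seed Integer seed (growth, relaxation and velocities).
#' @param relax_steps Steepest-descent iterations (default 200).
#' @return A `configuration` (positions nm, velocities nm/ps, box).
#' @export
build_configuration <- function(topology, spec, ff, seed = 1L,
                                relax_steps = 200L) {
  box <- spec$box
  chains <- split(seq_len(topology$n), topology$chain)
  chain_len <- vapply(chains, length, integer(1))
  chain_bl <- vapply(chains, function(ix) {
    unname(ff$bond_ref[topology$kind[ix[1]]])
  }, numeric(1))
  min_sigma <- min(ff$pairs$sigma)
  pos <- cpp_grow_chains(as.integer(chain_len), chain_bl, box,
                         zlo = box[3] / 3, zhi = 2 * box[3] / 3,
                         min_dist = 0.7 * min_sigma,
                         seed = as.double(seed), max_retry = 200L)
  tabs <- ff_tables(ff)
  rlist <- max(max(ff$pairs$R), ff$coulomb_cutoff)
  relax <- cpp_minimize(pos, box, topology$type, topology$charge,
                        topology$bonds - 1L, topology$bond_ref,
                        topology$bond_k, tabs$eps_alpha, tabs$sigma,
                        tabs$mu, tabs$nu, tabs$R,
                        .COULOMB / ff$dielectric, 1 / ff$debye_length,
                        ff$coulomb_cutoff, rlist,
                        max_steps = as.integer(relax_steps),
                        max_disp = 0.02, fmax_tol = 50)
  pos <- relax$pos
  vel <- with_seed(seed + 7L, {
    sdv <- sqrt(.kB * spec$temperature / topology$mass)
    matrix(rnorm(3 * topology$n), ncol = 3) * sdv
  })
  # zero total momentum
  p <- colSums(vel * topology$mass) / sum(topology$mass)
  vel <- sweep(vel, 2, p)
  structure(list(pos = pos, vel = vel, box = box, time = 0),
            class = "configuration")
}

#' Build topology and initial configuration in one call
#'
#' @inheritParams build_configuration
#' @param spec A [system_spec].
#' @return List with elements `topology` and `configuration`.
#' @export
build_system <- function(spec, ff, seed = 1L, relax_steps = 200L) {
  topo <- build_topology(spec, ff)
  conf <- build_configuration(topo, spec, ff, seed = seed,
                              relax_steps = relax_steps)
  list(topology = topo, configuration = conf)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
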