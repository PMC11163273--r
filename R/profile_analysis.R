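# Axial density profiles, center/vapor region detection and the
# multiphasicity fitness functions.

# circular moving average (periodic z axis)
smooth_circular <- function(x, window) {
  if (window <= 1) return(x)
  as.numeric(stats::filter(x, rep(1 / window, window), circular = TRUE))
}

# circular mean of coordinates on [0, L)
circular_mean <- function(z, L) {
  th <- z / L * 2 * pi
  (atan2(mean(sin(th)), mean(cos(th))) %% (2 * pi)) / (2 * pi) * L
}

#' Axial number-density profile
#'
#' Bins bead positions along the long (z) axis into `n_bins` bins and
#' reports per-species number densities (nm^-3) averaged over frames.
#' Each frame is first recentred: the periodic circular mean of the
#' protein bead z coordinates is shifted to the box middle, so the
#' condensate is tracked without biasing toward vapor-phase RNA.
#'
#' @param frames List of N x 3 position matrices, or a `trajectory`.
#' @param topology The matching `topology`.
#' @param species Species labels to profile (default: all in the
#'   topology).
#' @param n_bins Number of bins along z (default 150; must be >= 3).
#' @param box Box lengths (taken from a `trajectory` automatically).
#' @param recentre Recentre each frame on the protein condensate.
#' @return A `density_profile`: bin centers `z`, matrix `density`
#'   (n_bins x species), `bin_volume`, `n_frames`.
#' @export
compute_profile <- function(frames, topology, species = NULL, n_bins = 150,
                            box = NULL, recentre = TRUE) {
  if (inherits(frames, "trajectory")) {
    box <- frames$box
    frames <- frames$frames
  }
  stopifnot(!is.null(box))
  if (n_bins < 3) stop("compute_profile: n_bins must be >= 3")
  if (is.null(species)) species <- sort(unique(topology$species))
  Lz <- box[3]
  edges <- seq(0, Lz, length.out = n_bins + 1)
  bin_volume <- box[1] * box[2] * (Lz / n_bins)
  prot <- topology$kind == "protein"
  dens <- matrix(0, n_bins, length(species),
                 dimnames = list(NULL, species))
  for (p in frames) {
    z <- p[, 3] %% Lz
    if (recentre && any(prot)) {
      shift <- Lz / 2 - circular_mean(z[prot], Lz)
      z <- (z + shift) %% Lz
    }
    bin <- pmin(floor(z / Lz * n_bins) + 1L, n_bins)
    for (sp in species) {
      cnt <- tabulate(bin[topology$species == sp], nbins = n_bins)
      dens[, sp] <- dens[, sp] + cnt / bin_volume
    }
  }
  dens <- dens / length(frames)
  structure(list(n_bins = n_bins, edges = edges,
                 z = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                 density = dens, species = species,
                 bin_volume = bin_volume, n_frames = length(frames),
                 box = box), class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat("<density_profile> ", x$n_bins, " bins x ",
      paste(x$species, collapse = ", "), "; ", x$n_frames, " frame(s)\n",
      sep = "")
  invisible(x)
}

#' Detect center and vapor regions from two protein profiles
#'
#' The center region is the set of bins between the two sign changes of
#' the (smoothed) difference of the two protein density profiles nearest
#' the condensate midpoint — i.e. the contiguous run of constant sign
#' containing the bin of maximum total protein density. The vapor region
#' is a block of `vapor_bins` bins placed diametrically opposite the
#' center-region midpoint on the periodic axis, so its first and last bins
#' are equidistant from the middle of the center region.
#'
#' If the difference never changes sign (monophasic or identical
#' profiles), the fallback takes the contiguous bins where total protein
#' density is at least half its maximum, and flags the result.
#'
#' @param profile A `density_profile` containing both protein species.
#' @param speciesA,speciesB Column names of the two protein species.
#' @param smooth Moving-average window (bins) applied before crossing
#'   detection (default 5).
#' @param vapor_bins Size of the vapor region (default 50).
#' @param freeze Mark the returned regions as frozen (reused across a
#'   genetic-algorithm run rather than re-detected).
#' @return A `region_spec`: integer bin sets `center` and `vapor`,
#'   `fallback` flag, `frozen` flag.
#' @export
find_regions <- function(profile, speciesA = "A", speciesB = "B",
                         smooth = 5, vapor_bins = 50, freeze = FALSE) {
  nb <- profile$n_bins
  sA <- smooth_circular(profile$density[, speciesA], smooth)
  sB <- smooth_circular(profile$density[, speciesB], smooth)
  d <- sA - sB
  tot <- sA + sB
  # condensate midpoint: density-weighted circular mean of the total
  # protein profile (robust to flat-topped profiles), snapped to a bin
  if (sum(tot) > 0) {
    th <- (seq_len(nb) - 0.5) / nb * 2 * pi
    mth <- atan2(sum(tot * sin(th)), sum(tot * cos(th))) %% (2 * pi)
    mid <- pmin(nb, floor(mth / (2 * pi) * nb) + 1L)
  } else {
    mid <- which.max(tot)
  }
  sgn <- sign(d)
  fallback <- FALSE
  run_from <- function(values, start) {
    # maximal circular contiguous run of TRUE containing `start`
    stopifnot(values[start])
    if (all(values)) return(seq_len(nb))
    lo <- start
    while (values[((lo - 2) %% nb) + 1] && lo != start - nb) lo <- lo - 1
    hi <- start
    while (values[(hi %% nb) + 1] && hi != start + nb) hi <- hi + 1
    ((seq(lo, hi) - 1) %% nb) + 1
  }
  if (all(sgn >= 0) || all(sgn <= 0) || sgn[mid] == 0) {
    fallback <- TRUE
    vals <- tot >= 0.5 * max(tot)
    center <- run_from(vals, if (vals[mid]) mid else which.max(tot))
  } else {
    center <- run_from(sgn == sgn[mid], mid)
  }
  # circular midpoint of the center run
  k <- length(center)
  cmid <- center[ceiling(k / 2)]
  opposite <- ((cmid - 1 + nb %/% 2) %% nb)
  vapor <- ((opposite - vapor_bins %/% 2 + seq_len(vapor_bins) - 1) %% nb) + 1
  structure(list(center = center, vapor = vapor, center_mid = cmid,
                 fallback = fallback, frozen = freeze, n_bins = nb),
            class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat("<region_spec> center ", length(x$center), " bins (mid ", x$center_mid,
      "), vapor ", length(x$vapor), " bins",
      if (x$fallback) " [fallback]", if (x$frozen) " [frozen]", "\n", sep = "")
  invisible(x)
}

#' Per-region densities and multiphasicity fitness values
#'
#' Averages each species' density over the center and vapor bins and
#' evaluates both fitness functions (see [fitness_demix()] and
#' [fitness_multiphase()]).
#'
#' @param profile A `density_profile`.
#' @param regions A `region_spec`.
#' @param speciesA,speciesB,rna Species labels; `rna = NULL` contributes
#'   zero density.
#' @param s Vapor-penalty weight, nm^3 (default 5).
#' @param floor Density-difference floor engaging the demixing-fitness cap;
#'   default one bead per bin slab volume.
#' @return A `phase_metrics` with fields `rho_center`, `rho_vapor`
#'   (named vectors), `f_demix`, `f_multiphase`, `s`, `floor`, `capped`.
#' @export
phase_metrics <- function(profile, regions, speciesA = "A", speciesB = "B",
                          rna = "RNA", s = 5, floor = NULL) {
  if (is.null(floor)) floor <- 1 / profile$bin_volume
  rc <- colMeans(profile$density[regions$center, , drop = FALSE])
  rv <- colMeans(profile$density[regions$vapor, , drop = FALSE])
  rna_c <- if (!is.null(rna) && rna %in% names(rc)) rc[[rna]] else 0
  rna_v <- if (!is.null(rna) && rna %in% names(rv)) rv[[rna]] else 0
  m <- structure(list(
    rhoA_center = rc[[speciesA]], rhoB_center = rc[[speciesB]],
    rhoRNA_center = rna_c,
    rhoA_vapor = rv[[speciesA]], rhoB_vapor = rv[[speciesB]],
    rhoRNA_vapor = rna_v,
    rho_center = rc, rho_vapor = rv,
    s = s, floor = floor), class = "phase_metrics")
  m$f_demix <- fitness_demix(m)
  m$f_multiphase <- fitness_multiphase(m)
  m
}

#' Demixing fitness (drives toward a homogeneous condensate)
#'
#' \deqn{f = \frac{\mathrm{nm}^{-3}}{|\rho_{A,c} - \rho_{B,c}|}
#'  - s(\rho_{A,v} + \rho_{B,v} + \rho_{RNA,v})}
#' The first term rewards similar protein densities in the condensate
#' core; the second penalizes accumulation of any species in the dilute
#' phase. The printed reciprocal diverges when the two densities coincide,
#' so the difference is floored at `metrics$floor` (one bead per bin slab
#' volume by default), capping the fitness.
#'
#' @param metrics A `phase_metrics` (or any list with the density fields,
#'   `s` and `floor`).
#' @return Dimensionless fitness (densities in nm^-3).
#' @export
fitness_demix <- function(metrics) {
  stopifnot(metrics$s >= 0)
  d <- abs(metrics$rhoA_center - metrics$rhoB_center)
  1 / max(d, metrics$floor) -
    metrics$s * (metrics$rhoA_vapor + metrics$rhoB_vapor + metrics$rhoRNA_vapor)
}

#' Multiphasicity fitness (drives toward layered condensates)
#'
#' \deqn{f = |\rho_{A,c} - \rho_{B,c}|\,\mathrm{nm}^3
#'  + \rho_{RNA,c}\,\mathrm{nm}^3
#'  - s(\rho_{A,v} + \rho_{B,v} + \rho_{RNA,v})}
#'
#' @inheritParams fitness_demix
#' @return Dimensionless fitness.
#' @export
fitness_multiphase <- function(metrics) {
  stopifnot(metrics$s >= 0)
  abs(metrics$rhoA_center - metrics$rhoB_center) + metrics$rhoRNA_center -
    metrics$s * (metrics$rhoA_vapor + metrics$rhoB_vapor + metrics$rhoRNA_vapor)
}

#' Residue-class composition of a sequence or population
#'
#' Fractions by residue class (aromatic Y/F/W, positive R/K, negative D/E,
#' arginine, lysine, glycine), mean net charge, and — when a reference is
#' supplied — the enrichment, defined as the difference in fraction of
#' each class between the sequence (or population average) and the
#' reference.
#'
#' @param x A `cg_sequence` or a list of them (e.g. a final population;
#'   fractions are then averaged across all members).
#' @param reference Optional reference `cg_sequence`.
#' @param charges Named charge map used for the net charge.
#' @return List with `fractions` (named vector), `net_charge`, and
#'   `enrichment` when a reference is given.
#' @export
composition_stats <- function(x, reference = NULL,
                              charges = c(R = 1, K = 1, D = -1, E = -1,
                                          U = -1)) {
  classes <- list(aromatic = c("Y", "F", "W"), positive = c("R", "K"),
                  negative = c("D", "E"), arginine = "R", lysine = "K",
                  glycine = "G")
  one <- function(seq) {
    ch <- seq_chars(seq)
    fr <- vapply(classes, function(cl) mean(ch %in% cl), numeric(1))
    q <- sum(charges[ch], na.rm = TRUE)
    list(fractions = fr, net_charge = q)
  }
  if (inherits(x, "cg_sequence")) x <- list(x)
  per <- lapply(x, one)
  fr <- Reduce(`+`, lapply(per, `[[`, "fractions")) / length(per)
  q <- mean(vapply(per, `[[`, numeric(1), "net_charge"))
  out <- list(fractions = fr, net_charge = q)
  if (!is.null(reference)) {
    ref <- one(reference)
    out$enrichment <- fr - ref$fractions
  }
  out
}

#' Write a density profile to CSV
#'
#' Long format: `bin_center_nm, species, density_nm3`.
#' @param profile A `density_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  long <- do.call(rbind, lapply(profile$species, function(sp) {
    data.frame(bin_center_nm = profile$z, species = sp,
               density_nm3 = profile$density[, sp])
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
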