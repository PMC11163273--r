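# Standard-format I/O: FASTA sequences, extended-XYZ trajectories,
# JSON/CSV analysis outputs.

#' Write sequences as FASTA
#'
#' Headers carry the sequence id plus `kind=` and optional `role=` tags so
#' mixed protein/RNA alphabets round-trip.
#'
#' @param seqs A `cg_sequence` or list of them.
#' @param path Output path.
#' @param roles Optional character vector of component roles (A/B/RNA).
#' @param extra Optional character vector appended to each header (e.g.
#'   `fitness=...`).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, roles = NULL, extra = NULL) {
  if (inherits(seqs, "cg_sequence")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(seqs)) {
    hdr <- sprintf(">%s kind=%s", seqs[[k]]$id, seqs[[k]]$kind)
    if (!is.null(roles)) hdr <- paste0(hdr, " role=", roles[k])
    if (!is.null(extra)) hdr <- paste(hdr, extra[k])
    writeLines(hdr, con)
    writeLines(seqs[[k]]$residues, con)
  }
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA path (headers may carry `kind=` and `role=` tags).
#' @return List of `cg_sequence`s; roles, when present, in
#'   `attr(, "roles")`.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  at <- grep("^>", lines)
  if (!length(at)) stop("read_fasta: no records in ", path)
  ends <- c(at[-1] - 1, length(lines))
  seqs <- list()
  roles <- character(0)
  for (k in seq_along(at)) {
    hdr <- sub("^>", "", lines[at[k]])
    parts <- strsplit(hdr, "\\s+")[[1]]
    id <- parts[1]
    kind <- sub("kind=", "", grep("^kind=", parts, value = TRUE)[1])
    if (is.na(kind)) kind <- "protein"
    role <- sub("role=", "", grep("^role=", parts, value = TRUE)[1])
    body <- paste(lines[(at[k] + 1):ends[k]], collapse = "")
    body <- gsub("\\s", "", body)
    seqs[[k]] <- new_sequence(id, kind, body)
    roles[k] <- if (is.na(role)) NA_character_ else role
  }
  if (any(!is.na(roles))) attr(seqs, "roles") <- roles
  seqs
}

#' Write a trajectory as extended XYZ
#'
#' One block per frame: atom count, a comment line with
#' `Lattice="..." Properties=species:S:1:pos:R:3 Time=...`, then one row
#' per bead (`code x y z`).
#'
#' @param traj A `trajectory` (or list of position matrices).
#' @param topology The matching `topology` (bead codes).
#' @param path Output path.
#' @param box Box lengths; taken from the trajectory if available.
#' @return `path`, invisibly.
#' @export
write_extxyz <- function(traj, topology, path, box = NULL) {
  if (inherits(traj, "trajectory")) {
    frames <- traj$frames
    times <- traj$times
    box <- traj$box
  } else {
    frames <- traj
    times <- seq_along(frames) - 1
  }
  stopifnot(!is.null(box))
  con <- file(path, "w")
  on.exit(close(con))
  lat <- sprintf("Lattice=\"%.6f 0 0 0 %.6f 0 0 0 %.6f\"",
                 box[1], box[2], box[3])
  for (k in seq_along(frames)) {
    p <- frames[[k]]
    writeLines(as.character(nrow(p)), con)
    writeLines(sprintf("%s Properties=species:S:1:pos:R:3 Time=%.6f",
                       lat, times[k]), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", topology$code,
                       p[, 1], p[, 2], p[, 3]), con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' @param path File written by [write_extxyz()] (or compatible).
#' @return List with `frames` (position matrices), `species` (bead codes),
#'   `box`, `times`.
#' @export
read_extxyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  times <- numeric(0)
  box <- NULL
  species <- NULL
  k <- 1
  while (k <= length(lines)) {
    n <- as.integer(lines[k])
    hdr <- lines[k + 1]
    lat <- regmatches(hdr, regexpr("Lattice=\"[^\"]*\"", hdr))
    if (length(lat)) {
      v <- as.numeric(strsplit(gsub("Lattice=|\"", "", lat), "\\s+")[[1]])
      box <- v[c(1, 5, 9)]
    }
    tm <- regmatches(hdr, regexpr("Time=[-0-9.eE+]+", hdr))
    times <- c(times, if (length(tm)) as.numeric(sub("Time=", "", tm)) else NA)
    rows <- strsplit(lines[(k + 2):(k + 1 + n)], "\\s+")
    sp <- vapply(rows, `[[`, character(1), 1)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    if (is.null(species)) species <- sp
    frames[[length(frames) + 1]] <- xyz
    k <- k + 2 + n
  }
  list(frames = frames, species = species, box = box, times = times)
}

#' Serialize an energy report to JSON
#' @param report An `energy_report` from [total_energy()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_energy_json <- function(report, path) {
  out <- list(total = report$total, by_term = as.list(report$by_term))
  if (!is.null(report$by_group)) {
    g <- report$by_group
    rows <- which(upper.tri(g, diag = TRUE), arr.ind = TRUE)
    out$by_group <- data.frame(groupA = rownames(g)[rows[, 1]],
                               groupB = colnames(g)[rows[, 2]],
                               energy = g[rows])
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write per-frame group-pair energies to CSV
#' @param result Output of [species_pair_energy()].
#' @param groupA,groupB Labels for the two groups.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_species_energy_csv <- function(result, groupA, groupB, path) {
  utils::write.csv(data.frame(frame = seq_along(result$per_frame),
                              groupA = groupA, groupB = groupB,
                              energy = result$per_frame),
                   path, row.names = FALSE)
  invisible(path)
}
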