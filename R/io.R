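## Coordinate-file readers/writers (extended XYZ, GRO, PDB) and the JSON
## topology sidecar. Coordinate formats carry no charges/LJ/bonds, so the
## sidecar travels next to them. Only orthorhombic boxes are supported;
## triclinic input raises an explicit unsupported-format error.

#' Read a configuration: coordinate file plus topology sidecar
#'
#' Dispatches on the coordinate-file extension: \code{.xyz} (extended XYZ
#' with a \code{Lattice="..."} comment line), \code{.gro} (box on the last
#' line of each block, coordinates in nm) or \code{.pdb} (\code{CRYST1}).
#'
#' @param path coordinate file
#' @param topo_path JSON topology sidecar (see \code{\link{write_topology_json}})
#' @return list with elements \code{topology} and \code{trajectory}
#' @export
read_configuration <- function(path, topo_path) {
  if (!file.exists(path)) stop("coordinate file not found: ", path)
  topo <- read_topology_json(topo_path)
  ext <- tolower(tools::file_ext(path))
  traj <- switch(ext,
    xyz = read_xyz(path),
    gro = read_gro(path),
    pdb = read_pdb_frame(path),
    stop("unsupported coordinate format: .", ext,
         " (supported: xyz, gro, pdb)"))
  nt <- n_atoms(topo)
  for (f in seq_along(traj$frames))
    if (nrow(traj$frames[[f]]$positions) != nt)
      stop("frame ", f, " has ", nrow(traj$frames[[f]]$positions),
           " atoms but topology has ", nt)
  list(topology = topo, trajectory = traj)
}

#' Write a configuration to a coordinate file
#'
#' @param traj trajectory (or a single frame)
#' @param topo topology (element symbols are taken from it)
#' @param path output path; format chosen by extension (.xyz/.gro/.pdb)
#' @export
write_configuration <- function(traj, topo, path) {
  if (inherits(traj, "frame")) traj <- trajectory(list(traj))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    xyz = write_xyz(traj, topo, path),
    gro = write_gro(traj, topo, path),
    pdb = write_pdb_frame(traj, topo, path),
    stop("unsupported coordinate format: .", ext))
  invisible(path)
}

parse_lattice <- function(comment) {
  m <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]]
  if (length(m) != 2) stop("XYZ comment line lacks Lattice=\"...\" box")
  v <- as.numeric(strsplit(trimws(m[2]), "\\s+")[[1]])
  if (length(v) != 9) stop("Lattice must have 9 components")
  L <- matrix(v, 3, 3, byrow = TRUE)
  off <- L; diag(off) <- 0
  if (any(abs(off) > 1e-9))
    stop("triclinic boxes are not supported (non-orthorhombic Lattice)")
  diag(L)
}

read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); i <- 1; fno <- 0
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i)
    fno <- fno + 1
    comment <- lines[i + 1]
    box <- parse_lattice(comment)
    tm <- regmatches(comment, regexec("Time=([-0-9.eE+]+)", comment))[[1]]
    time <- if (length(tm) == 2) as.numeric(tm[2]) else fno - 1
    rows <- lines[(i + 2):(i + 1 + n)]
    if (length(rows) < n || any(is.na(rows)))
      stop("frame ", fno, ": truncated XYZ block")
    parts <- strsplit(trimws(rows), "\\s+")
    pos <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[fno]] <- frame(pos, time = time, box = box)
    i <- i + 2 + n
  }
  trajectory(frames)
}

write_xyz <- function(traj, topo, path) {
  con <- file(path, "w"); on.exit(close(con))
  el <- topo$atoms$element
  for (fr in traj$frames) {
    b <- fr$box
    writeLines(as.character(nrow(fr$positions)), con)
    writeLines(sprintf(
      'Lattice="%g 0 0 0 %g 0 0 0 %g" Properties=species:S:1:pos:R:3 Time=%g',
      b[1], b[2], b[3], fr$time), con)
    writeLines(sprintf("%-3s %14.8f %14.8f %14.8f", el,
                       fr$positions[, 1], fr$positions[, 2],
                       fr$positions[, 3]), con)
  }
}

read_gro <- function(path) {
  lines <- readLines(path)
  frames <- list(); i <- 1; fno <- 0
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    n <- suppressWarnings(as.integer(trimws(lines[i + 1])))
    if (is.na(n)) stop("malformed GRO: expected atom count at line ", i + 1)
    fno <- fno + 1
    tm <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
    time <- if (length(tm) == 2) as.numeric(tm[2]) else fno - 1
    rows <- lines[(i + 2):(i + 1 + n)]
    pos <- t(vapply(rows, function(r) {
      as.numeric(strsplit(trimws(substring(r, 21)), "\\s+")[[1]][1:3])
    }, numeric(3), USE.NAMES = FALSE)) * 10  # nm -> A
    bv <- as.numeric(strsplit(trimws(lines[i + 2 + n]), "\\s+")[[1]])
    if (length(bv) > 3 && any(abs(bv[4:length(bv)]) > 1e-9))
      stop("triclinic boxes are not supported (GRO box has off-diagonal terms)")
    frames[[fno]] <- frame(pos, time = time, box = bv[1:3] * 10)
    i <- i + 3 + n
  }
  trajectory(frames)
}

write_gro <- function(traj, topo, path) {
  con <- file(path, "w"); on.exit(close(con))
  el <- topo$atoms$element
  n <- n_atoms(topo)
  resname <- rep("MOL", n)
  for (g in names(topo$groups)) resname[topo$groups[[g]]] <- substr(g, 1, 5)
  for (fr in traj$frames) {
    writeLines(sprintf("synthetic configuration, t= %g", fr$time), con)
    writeLines(sprintf("%5d", n), con)
    ## wide-precision GRO (5 decimals in nm); GROMACS accepts variable width
    writeLines(sprintf("%5d%-5s%5s%5d%10.5f%10.5f%10.5f",
                       rep(1L, n), resname, substr(el, 1, 5),
                       seq_len(n) %% 100000,
                       fr$positions[, 1] / 10, fr$positions[, 2] / 10,
                       fr$positions[, 3] / 10), con)
    writeLines(sprintf("%12.5f%12.5f%12.5f",
                       fr$box[1] / 10, fr$box[2] / 10, fr$box[3] / 10), con)
  }
}

read_pdb_frame <- function(path) {
  lines <- readLines(path)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cr)) stop("PDB lacks a CRYST1 record (box required)")
  ## fixed-width CRYST1 fields: a, b, c then the three angles
  ln <- cr[1]
  abc <- as.numeric(c(substring(ln, 7, 15), substring(ln, 16, 24),
                      substring(ln, 25, 33)))
  angles <- as.numeric(c(substring(ln, 34, 40), substring(ln, 41, 47),
                         substring(ln, 48, 54)))
  if (any(abs(angles - 90) > 1e-6))
    stop("triclinic boxes are not supported (CRYST1 angles != 90)")
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  pos <- cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z)
  trajectory(list(frame(pos, time = 0, box = abc)))
}

write_pdb_frame <- function(traj, topo, path) {
  if (n_frames(traj) != 1)
    stop("PDB writer emits a single frame; got ", n_frames(traj))
  fr <- traj$frames[[1]]
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    fr$box[1], fr$box[2], fr$box[3], 90, 90, 90), path)
  n <- n_atoms(topo)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(fr$positions)),
                   type = rep("ATOM", n), resno = rep(1L, n),
                   resid = rep("MOL", n), eleno = seq_len(n),
                   elety = topo$atoms$element,
                   elesy = topo$atoms$element,
                   o = rep(1, n), b = rep(0, n), append = TRUE)
}

#' Write a topology to a JSON sidecar
#'
#' Schema (all indices 1-based): \code{atoms} (column arrays
#' \code{element}, \code{charge}, \code{mass}, \code{lj_epsilon},
#' \code{lj_sigma}, \code{is_heavy}, \code{hbond_role}), \code{bonds}
#' (N x 2 array), \code{groups} (label to index array), \code{chains}
#' (chain id to ordered heavy-atom index array, anchor first).
#'
#' @param topo topology
#' @param path output path
#' @export
write_topology_json <- function(topo, path) {
  obj <- list(
    index_base = 1L,
    atoms = as.list(topo$atoms),
    bonds = topo$bonds,
    groups = topo$groups,
    chains = topo$chains
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a topology JSON sidecar
#' @param path sidecar path
#' @return topology
#' @export
read_topology_json <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  atoms <- as.data.frame(obj$atoms, stringsAsFactors = FALSE)
  bonds <- if (length(obj$bonds)) matrix(as.integer(obj$bonds), ncol = 2)
           else NULL
  groups <- lapply(obj$groups, as.integer)
  chains <- lapply(obj$chains, as.integer)
  topology(atoms, bonds = bonds, groups = groups, chains = chains)
}

#' Write a radial profile as CSV
#'
#' Columns: \code{r_mid}, \code{value}, \code{kind}, \code{n_frames}.
#' @param p radial profile
#' @param path output path
#' @export
write_profile_csv <- function(p, path) {
  utils::write.csv(
    data.frame(r_mid = p$r_mid, value = p$values, kind = p$kind,
               n_frames = p$n_frames),
    path, row.names = FALSE)
  invisible(path)
}
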