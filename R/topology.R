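## Shared data model: Topology, Frame, Trajectory.
## Atom indices are 1-based everywhere inside the package; file writers emit
## each format's native serial convention.

#' Construct a topology
#'
#' A topology carries the static chemistry of a system: per-atom element,
#' partial charge (e), mass (amu), Lennard-Jones parameters
#' (kcal/mol, Angstrom), heavy-atom and hydrogen-bond role flags, the bond
#' list, named atom groups (e.g. \code{NP_CORE}, \code{PEG}, \code{WATER},
#' \code{ION_NA}, \code{ION_CL}) and, for grafted polymer chains, the ordered
#' heavy-atom index list of each chain from anchor to terminus.
#'
#' @param atoms data.frame with columns \code{element}, \code{charge},
#'   \code{mass}, \code{lj_epsilon}, \code{lj_sigma}, \code{is_heavy},
#'   \code{hbond_role} (one of \code{"none"}, \code{"donor-heavy"},
#'   \code{"acceptor-heavy"}, \code{"polar-hydrogen"}, or \code{"both"}
#'   for heavy atoms that donate and accept, like a water oxygen).
#'   Missing columns are filled with neutral defaults.
#' @param bonds two-column integer matrix of bonded atom index pairs
#'   (1-based), or \code{NULL} for no bonds.
#' @param groups named list of integer index vectors.
#' @param chains named list of ordered heavy-atom index vectors, anchor
#'   first, terminus last. Every chain needs at least 2 heavy atoms.
#' @return object of class \code{"topology"}.
#' @export
topology <- function(atoms, bonds = NULL, groups = list(), chains = list()) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  n <- nrow(atoms)
  defaults <- list(element = "C", charge = 0, mass = 12.011,
                   lj_epsilon = 0, lj_sigma = 0, is_heavy = TRUE,
                   hbond_role = "none")
  for (nm in names(defaults))
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  atoms <- atoms[names(defaults)]
  if (any(atoms$mass <= 0)) stop("atom masses must be > 0")
  if (any(atoms$lj_sigma < 0) || any(atoms$lj_epsilon < 0))
    stop("Lennard-Jones parameters must be >= 0")
  bad_role <- setdiff(unique(atoms$hbond_role),
                      c("none", "donor-heavy", "acceptor-heavy",
                        "polar-hydrogen", "both"))
  if (length(bad_role))
    stop("unknown hbond_role: ", paste(bad_role, collapse = ", "))

  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) && (min(bonds) < 1 || max(bonds) > n))
    stop("bond indices out of range 1..", n)

  if (length(groups)) {
    for (g in names(groups)) {
      idx <- as.integer(groups[[g]])
      if (length(idx) && (min(idx) < 1 || max(idx) > n))
        stop("group '", g, "' has indices out of range 1..", n)
      if (anyDuplicated(idx))
        stop("group '", g, "' has duplicate indices")
      groups[[g]] <- sort(idx)
    }
  }

  chain_id <- rep(NA_character_, n)
  if (length(chains)) {
    if (is.null(names(chains)) || any(names(chains) == ""))
      names(chains) <- as.character(seq_along(chains))
    for (cn in names(chains)) {
      idx <- as.integer(chains[[cn]])
      if (length(idx) < 2)
        stop("chain '", cn, "' has fewer than 2 heavy atoms")
      if (min(idx) < 1 || max(idx) > n)
        stop("chain '", cn, "' has indices out of range")
      if (anyDuplicated(idx))
        stop("chain '", cn, "' has duplicate atom indices")
      if (any(!is.na(chain_id[idx])))
        stop("chain '", cn, "' overlaps another chain")
      chain_id[idx] <- cn
      chains[[cn]] <- idx
    }
  }

  structure(list(atoms = atoms, bonds = bonds, groups = groups,
                 chains = chains, chain_id = chain_id),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("Topology:", nrow(x$atoms), "atoms,", nrow(x$bonds), "bonds,",
      length(x$chains), "chains\n")
  if (length(x$groups))
    cat("  groups:",
        paste(sprintf("%s(%d)", names(x$groups),
                      lengths(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

n_atoms <- function(topo) nrow(topo$atoms)

#' Check that every water molecule is net neutral
#'
#' Waters are identified as the connected bond components of the
#' \code{WATER} group; each must carry zero net partial charge to 1e-9 e.
#' @param topo topology
#' @param tol tolerance in e
#' @return invisibly TRUE, or an error
#' @export
check_water_neutrality <- function(topo, tol = 1e-9) {
  w <- topo$groups[["WATER"]]
  if (is.null(w) || !length(w)) return(invisible(TRUE))
  comp <- bond_components(topo, w)
  q <- vapply(comp, function(idx) sum(topo$atoms$charge[idx]), numeric(1))
  if (any(abs(q) > tol))
    stop("water molecule(s) with nonzero net charge (max |q| = ",
         format(max(abs(q))), " e)")
  invisible(TRUE)
}

## connected components of the bond graph restricted to `within`
bond_components <- function(topo, within = seq_len(n_atoms(topo))) {
  within <- sort(as.integer(within))
  pos <- integer(n_atoms(topo)); pos[within] <- seq_along(within)
  adj <- vector("list", length(within))
  b <- topo$bonds
  keep <- b[, 1] %in% within & b[, 2] %in% within
  b <- b[keep, , drop = FALSE]
  for (k in seq_len(nrow(b))) {
    i <- pos[b[k, 1]]; j <- pos[b[k, 2]]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(length(within))
  out <- list()
  for (s in seq_along(within)) {
    if (seen[s]) next
    stack <- s; comp <- integer(0)
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE; comp <- c(comp, v)
      stack <- c(stack, adj[[v]][!seen[adj[[v]]]])
    }
    out[[length(out) + 1L]] <- within[sort(comp)]
  }
  out
}

#' Construct a single trajectory frame
#'
#' @param positions N x 3 matrix of Cartesian coordinates (Angstrom)
#' @param time frame time (ps)
#' @param box three orthorhombic edge lengths (Angstrom)
#' @return object of class \code{"frame"}
#' @export
frame <- function(positions, time = 0, box) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be N x 3")
  if (!all(is.finite(positions))) stop("positions must be finite")
  box <- as.numeric(box)
  if (length(box) == 1) box <- rep(box, 3)
  if (length(box) != 3 || any(box <= 0))
    stop("box must be three positive orthorhombic edge lengths")
  structure(list(positions = positions, time = as.numeric(time), box = box),
            class = "frame")
}

#' Construct a trajectory from frames
#'
#' Frames must share one atom count and have strictly increasing times.
#' @param frames list of \code{frame} objects
#' @return object of class \code{"trajectory"}
#' @export
trajectory <- function(frames) {
  if (!length(frames)) stop("trajectory needs at least one frame")
  counts <- vapply(frames, function(f) nrow(f$positions), integer(1))
  if (length(unique(counts)) != 1) {
    bad <- which(counts != counts[1])[1]
    stop("frame ", bad, " has ", counts[bad],
         " atoms but frame 1 has ", counts[1])
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(frames = frames, times = times, n_atoms = counts[1]),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$frames), "frames,", x$n_atoms, "atoms, t = ",
      x$times[1], "..", x$times[length(x$times)], "ps\n")
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

#' Restrict a trajectory to a time window
#'
#' @param traj trajectory
#' @param window \code{NULL} for all frames, \code{c(t0, t1)} in ps
#'   (inclusive), or \code{"last:P"} with P a percentage, e.g.
#'   \code{"last:10\%"} for the final tenth of the run.
#' @return trajectory restricted to the window
#' @export
window_frames <- function(traj, window = NULL) {
  if (is.null(window)) return(traj)
  t <- traj$times
  if (is.character(window)) {
    m <- regmatches(window, regexec("^last:([0-9.]+)%$", window))[[1]]
    if (length(m) != 2) stop("unrecognized window spec: ", window)
    frac <- as.numeric(m[2]) / 100
    t0 <- t[length(t)] - frac * (t[length(t)] - t[1])
    keep <- t >= t0 - 1e-12
  } else {
    if (length(window) != 2) stop("window must be c(t0, t1)")
    keep <- t >= window[1] - 1e-12 & t <= window[2] + 1e-12
  }
  if (!any(keep)) stop("window contains no frames")
  trajectory(traj$frames[keep])
}

#' Select atoms by group label and chain id
#'
#' Supports expressions combining group labels with \code{and}, \code{or},
#' \code{not} and \code{chain <id>} terms, e.g. \code{"PEG"},
#' \code{"PEG and chain 7"}, \code{"WATER or ION_NA"},
#' \code{"PEG and not chain 2"}. \code{and} binds tighter than \code{or}.
#'
#' @param topo topology
#' @param expression selection expression
#' @return sorted integer vector of atom indices (1-based)
#' @export
select_atoms <- function(topo, expression) {
  toks <- strsplit(trimws(expression), "\\s+")[[1]]
  if (!length(toks)) stop("empty selection expression")
  all_idx <- seq_len(n_atoms(topo))
  term_set <- function(toks) {
    neg <- FALSE
    while (length(toks) && tolower(toks[1]) == "not") {
      neg <- !neg; toks <- toks[-1]
    }
    if (!length(toks)) stop("dangling 'not' in selection")
    if (tolower(toks[1]) == "chain") {
      if (length(toks) < 2) stop("'chain' needs an id")
      id <- toks[2]
      if (!id %in% names(topo$chains))
        stop("unknown chain '", id, "'; available: ",
             paste(names(topo$chains), collapse = ", "))
      s <- topo$chains[[id]]; used <- 2L
    } else {
      lab <- toks[1]
      if (!lab %in% names(topo$groups))
        stop("unknown group label '", lab, "'; available: ",
             paste(names(topo$groups), collapse = ", "))
      s <- topo$groups[[lab]]; used <- 1L
    }
    if (neg) s <- setdiff(all_idx, s)
    list(set = s, rest = toks[-seq_len(used)])
  }
  or_sets <- list(); cur <- NULL
  toks_left <- toks
  repeat {
    r <- term_set(toks_left)
    cur <- if (is.null(cur)) r$set else intersect(cur, r$set)
    toks_left <- r$rest
    if (!length(toks_left)) { or_sets <- c(or_sets, list(cur)); break }
    op <- tolower(toks_left[1]); toks_left <- toks_left[-1]
    if (op == "and") next
    if (op == "or") { or_sets <- c(or_sets, list(cur)); cur <- NULL; next }
    stop("unexpected token '", op, "' in selection")
  }
  sort(unique(unlist(or_sets)))
}
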