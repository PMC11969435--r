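## Geometry helpers shared across modules.

## minimum-image displacement of points `pos` (N x 3) relative to `ref`
## (length-3) under an orthorhombic box; returns N x 3 displacements
min_image_disp <- function(pos, ref, box) {
  d <- sweep(pos, 2, ref)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

min_image_radii <- function(pos, ref, box) {
  d <- min_image_disp(pos, ref, box)
  sqrt(rowSums(d * d))
}

## minimum-image pairwise distance matrix between two coordinate sets
min_image_cross_dist <- function(a, b, box) {
  out <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    out <- out + dk * dk
  }
  sqrt(out)
}

#' Resolve the reference center of a frame
#'
#' Center conventions mirror the two used for radial analyses: the
#' geometric center of the particle core (default, used for volume
#' fractions), its center of mass, or a fixed atom index (the core's
#' central atom, used for RDFs).
#'
#' @param mode one of \code{"core-geometric-center"},
#'   \code{"core-center-of-mass"}, \code{"fixed-atom-index"}
#' @param index atom index when \code{mode = "fixed-atom-index"}
#' @param group group label the core convention resolves against
#' @return object of class \code{"center_convention"}
#' @export
center_convention <- function(mode = c("core-geometric-center",
                                       "core-center-of-mass",
                                       "fixed-atom-index"),
                              index = NULL, group = "NP_CORE") {
  mode <- match.arg(mode)
  if (mode == "fixed-atom-index" && is.null(index))
    stop("fixed-atom-index convention needs an atom index")
  structure(list(mode = mode, index = index, group = group),
            class = "center_convention")
}

resolve_center <- function(fr, topo, center) {
  if (!inherits(center, "center_convention")) {
    if (is.numeric(center) && length(center) == 3) return(as.numeric(center))
    stop("center must be a center_convention or an xyz triple")
  }
  if (center$mode == "fixed-atom-index") {
    if (center$index < 1 || center$index > nrow(fr$positions))
      stop("center atom index out of range")
    return(fr$positions[center$index, ])
  }
  idx <- topo$groups[[center$group]]
  if (is.null(idx) || !length(idx))
    stop("cannot resolve center: group '", center$group, "' is empty/absent")
  p <- fr$positions[idx, , drop = FALSE]
  if (center$mode == "core-geometric-center") return(colMeans(p))
  m <- topo$atoms$mass[idx]
  colSums(p * m) / sum(m)
}

## run `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## quasi-uniform points on the unit sphere (deterministic)
fibonacci_sphere <- function(n) {
  if (n == 1) return(matrix(c(0, 0, 1), 1, 3))
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

## stack trajectory positions for a selection into an n_frames x n_sel x 3 array
positions_array <- function(traj, sel = NULL) {
  if (is.null(sel)) sel <- seq_len(traj$n_atoms)
  nf <- n_frames(traj)
  arr <- array(0, dim = c(nf, length(sel), 3))
  for (f in seq_len(nf)) arr[f, , ] <- traj$frames[[f]]$positions[sel, , drop = FALSE]
  arr
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
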