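## Geometric hydrogen-bond counting and group-pair nonbonded
## (Coulomb + Lennard-Jones) interaction energies under minimum image.

#' Geometric hydrogen-bond criteria
#'
#' A (donor-H, acceptor) pair counts as an H-bond when the donor-heavy to
#' acceptor-heavy distance is below \code{d_max} and the angle is below
#' \code{angle_max}. Two angle conventions are selectable: vertex at the
#' donor (angle between donor-to-H and donor-to-acceptor, default) or
#' vertex at the hydrogen (angle between H-to-donor and H-to-acceptor,
#' measured from 180 degrees collinearity is 0).
#'
#' @param d_max donor-acceptor heavy-atom distance cutoff, A (default 3.0)
#' @param angle_max angle cutoff in degrees (default 20)
#' @param vertex \code{"donor"} (default) or \code{"hydrogen"}
#' @return object of class \code{"hbond_criteria"}
#' @export
hbond_criteria <- function(d_max = 3.0, angle_max = 20,
                           vertex = c("donor", "hydrogen")) {
  vertex <- match.arg(vertex)
  if (d_max <= 0) stop("d_max must be > 0")
  if (angle_max <= 0 || angle_max >= 90)
    stop("angle_max must be in (0, 90) degrees")
  structure(list(d_max = d_max, angle_max = angle_max, vertex = vertex),
            class = "hbond_criteria")
}

## polar hydrogens bonded to each donor-heavy atom
donor_hydrogens <- function(topo, donors) {
  b <- topo$bonds
  role <- topo$atoms$hbond_role
  out <- lapply(donors, function(d) {
    nb <- c(b[b[, 1] == d, 2], b[b[, 2] == d, 1])
    nb[role[nb] == "polar-hydrogen"]
  })
  names(out) <- as.character(donors)
  empty <- donors[lengths(out) == 0]
  if (length(empty))
    stop("donor atom(s) without a bonded polar hydrogen: ",
         paste(empty, collapse = ", "))
  out
}

#' Count hydrogen bonds in a frame
#'
#' Counts (donor-H, acceptor) pairs meeting the geometric criteria under
#' minimum image. A donor with two polar hydrogens can contribute two
#' bonds. Donor and acceptor heavy atoms are the selection members whose
#' \code{hbond_role} is \code{"donor-heavy"} / \code{"acceptor-heavy"}.
#'
#' @param fr frame
#' @param topo topology (roles and bonds)
#' @param donors_sel,acceptors_sel atom-index selections
#' @param criteria \code{\link{hbond_criteria}}
#' @return integer count
#' @export
count_hbonds <- function(fr, topo, donors_sel, acceptors_sel,
                         criteria = hbond_criteria()) {
  role <- topo$atoms$hbond_role
  donors <- donors_sel[role[donors_sel] %in% c("donor-heavy", "both")]
  acceptors <- acceptors_sel[role[acceptors_sel] %in%
                               c("acceptor-heavy", "both")]
  if (!length(donors) || !length(acceptors)) return(0L)
  hyd <- donor_hydrogens(topo, donors)
  pos <- fr$positions; box <- fr$box
  cosmax <- cos(criteria$angle_max * pi / 180)
  count <- 0L
  for (di in seq_along(donors)) {
    d <- donors[di]
    acc <- acceptors[acceptors != d]
    if (!length(acc)) next
    da <- min_image_disp(pos[acc, , drop = FALSE], pos[d, ], box)
    rda <- sqrt(rowSums(da * da))
    near <- rda < criteria$d_max
    if (!any(near)) next
    for (h in hyd[[di]]) {
      if (criteria$vertex == "donor") {
        dh <- min_image_disp(pos[h, , drop = FALSE], pos[d, ], box)[1, ]
        u <- dh / sqrt(sum(dh * dh))
        cosang <- (da[near, , drop = FALSE] %*% u)[, 1] / rda[near]
      } else {
        ## hydrogen vertex: deviation of the D-H...A angle from linearity
        ## below angle_max, i.e. cos(D-H-A) < -cos(angle_max)
        hd <- min_image_disp(pos[d, , drop = FALSE], pos[h, ], box)[1, ]
        ha <- min_image_disp(pos[acc[near], , drop = FALSE], pos[h, ], box)
        cos_dha <- (ha %*% hd)[, 1] /
          (sqrt(rowSums(ha * ha)) * sqrt(sum(hd * hd)))
        cosang <- -cos_dha
      }
      count <- count + sum(cosang > cosmax)
    }
  }
  count
}

#' Nonbonded interaction scheme
#'
#' Truncated Coulomb and Lennard-Jones with minimum image, arithmetic-mean
#' sigma / geometric-mean epsilon combining rules, and bonded exclusions
#' (1-2 and 1-3 excluded, 1-4 included unscaled). An optional switching
#' window smoothly truncates the LJ term between \code{r_on} and the
#' cutoff. \code{cutoff = Inf} gives a direct no-cutoff sum (used for the
#' point-charge electrostatics checks).
#'
#' @param cutoff cutoff radius in Angstrom (default 12)
#' @param lj_switch optional \code{c(r_on, r_off)}; \code{r_off} must equal
#'   the cutoff
#' @return object of class \code{"nonbonded_scheme"}
#' @export
nonbonded_scheme <- function(cutoff = 12, lj_switch = NULL) {
  if (!is.null(lj_switch)) {
    if (length(lj_switch) != 2 || lj_switch[1] >= lj_switch[2])
      stop("lj_switch must be c(r_on, r_off) with r_on < r_off")
    if (abs(lj_switch[2] - cutoff) > 1e-9)
      stop("switching r_off must equal the cutoff")
  }
  structure(list(cutoff = cutoff, lj_switch = lj_switch),
            class = "nonbonded_scheme")
}

## CHARMM-style switching function on [r_on, r_off]
switch_factor <- function(r, r_on, r_off) {
  s <- rep(1, length(r))
  mid <- r > r_on & r < r_off
  s[r >= r_off] <- 0
  ro2 <- r_off^2; rn2 <- r_on^2; r2 <- r[mid]^2
  s[mid] <- (ro2 - r2)^2 * (ro2 + 2 * r2 - 3 * rn2) / (ro2 - rn2)^3
  s
}

## 1-2 and 1-3 excluded pairs as a two-column matrix (i < j)
excluded_pairs <- function(topo) {
  b <- topo$bonds
  if (!nrow(b)) return(matrix(integer(0), ncol = 2))
  p12 <- b
  adj <- split(c(b[, 2], b[, 1]), c(b[, 1], b[, 2]))
  p13 <- list()
  for (ctr in names(adj)) {
    nb <- adj[[ctr]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(sort(nb), 2)
      p13[[ctr]] <- t(cmb)
    }
  }
  out <- rbind(p12, do.call(rbind, p13))
  out <- t(apply(out, 1, sort))
  unique(out)
}

#' Group-pair nonbonded interaction energy of a frame
#'
#' Sum over unordered atom pairs (i in A, j in B, i != j; pairs inside the
#' intersection counted once) of the truncated Coulomb energy
#' \eqn{k_C q_i q_j / r} and the Lennard-Jones energy
#' \eqn{4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]}, with minimum-image
#' distances and bonded 1-2/1-3 pairs skipped. The Coulomb constant is
#' derived from CODATA physical constants (about 332.06 kcal/mol A e^-2).
#'
#' @param fr frame
#' @param topo topology (charges and LJ parameters)
#' @param selA,selB atom-index selections
#' @param scheme \code{\link{nonbonded_scheme}}
#' @return object of class \code{"energy_breakdown"} with \code{coulomb},
#'   \code{lennard_jones} and \code{total} in kcal/mol
#' @export
pair_interaction_energy <- function(fr, topo, selA, selB,
                                    scheme = nonbonded_scheme()) {
  if (is.finite(scheme$cutoff) && scheme$cutoff >= min(fr$box) / 2)
    stop("cutoff (", scheme$cutoff,
         " A) must be below half the shortest box edge (",
         min(fr$box) / 2, " A)")
  pr <- unordered_cross_pairs(selA, selB)
  if (!nrow(pr))
    return(energy_breakdown(0, 0))
  excl <- excluded_pairs(topo)
  if (nrow(excl)) {
    key <- paste(pr[, 1], pr[, 2])
    pr <- pr[!key %in% paste(excl[, 1], excl[, 2]), , drop = FALSE]
  }
  if (!nrow(pr)) return(energy_breakdown(0, 0))
  a <- topo$atoms
  d <- fr$positions[pr[, 1], , drop = FALSE] -
       fr$positions[pr[, 2], , drop = FALSE]
  for (k in 1:3) d[, k] <- d[, k] - fr$box[k] * round(d[, k] / fr$box[k])
  r <- sqrt(rowSums(d * d))
  keep <- r < scheme$cutoff
  r <- r[keep]; pr <- pr[keep, , drop = FALSE]
  if (!length(r)) return(energy_breakdown(0, 0))

  qq <- a$charge[pr[, 1]] * a$charge[pr[, 2]]
  ecoul <- .const$k_coulomb_kcal * sum(qq / r)

  eps <- sqrt(a$lj_epsilon[pr[, 1]] * a$lj_epsilon[pr[, 2]])
  sig <- (a$lj_sigma[pr[, 1]] + a$lj_sigma[pr[, 2]]) / 2
  sr6 <- (sig / r)^6
  elj_pair <- 4 * eps * (sr6^2 - sr6)
  if (!is.null(scheme$lj_switch))
    elj_pair <- elj_pair *
      switch_factor(r, scheme$lj_switch[1], scheme$lj_switch[2])
  energy_breakdown(ecoul, sum(elj_pair))
}

## unordered pairs spanning A x B with i != j, intersection pairs once
unordered_cross_pairs <- function(selA, selB) {
  selA <- unique(as.integer(selA)); selB <- unique(as.integer(selB))
  i <- rep(selA, each = length(selB))
  j <- rep(selB, times = length(selA))
  keep <- i != j
  pr <- cbind(pmin(i[keep], j[keep]), pmax(i[keep], j[keep]))
  unique(pr)
}

energy_breakdown <- function(coulomb, lj) {
  structure(list(coulomb = coulomb, lennard_jones = lj,
                 total = coulomb + lj),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(
    "Nonbonded energy: total %.4f kcal/mol (Coulomb %.4f, LJ %.4f)\n",
    x$total, x$coulomb, x$lennard_jones))
  invisible(x)
}

#' Per-frame energy series and window statistics for group pairs
#'
#' Evaluates \code{\link{pair_interaction_energy}} on every frame of the
#' window for each requested selection pair and reports the per-frame
#' series plus mean and standard deviation. Symmetric in the pair order.
#'
#' @param traj trajectory
#' @param topo topology
#' @param pairs named list; each element a list of two selections
#'   \code{list(A, B)}
#' @param scheme \code{\link{nonbonded_scheme}}
#' @param window time window
#' @return named list per pair: data.frame \code{series} (time, coulomb,
#'   lennard_jones, total) and \code{mean}/\code{sd} of the total
#' @export
energy_series <- function(traj, topo, pairs, scheme = nonbonded_scheme(),
                          window = NULL) {
  traj <- window_frames(traj, window)
  out <- list()
  for (nm in names(pairs)) {
    sA <- pairs[[nm]][[1]]; sB <- pairs[[nm]][[2]]
    rows <- lapply(traj$frames, function(fr) {
      e <- pair_interaction_energy(fr, topo, sA, sB, scheme)
      data.frame(time = fr$time, coulomb = e$coulomb,
                 lennard_jones = e$lennard_jones, total = e$total)
    })
    series <- do.call(rbind, rows)
    out[[nm]] <- list(series = series, mean = mean(series$total),
                      sd = stats::sd(series$total),
                      mean_coulomb = mean(series$coulomb),
                      mean_lj = mean(series$lennard_jones))
  }
  out
}
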