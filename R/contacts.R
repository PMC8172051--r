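# Pairwise distance machinery. All distances are Euclidean in nm; when a
# box is supplied the minimum-image convention is applied per (orthorhombic)
# dimension.

pair_dists <- function(A, B, box = NULL) {
  dx <- outer(A[, 1], B[, 1], "-")
  dy <- outer(A[, 2], B[, 2], "-")
  dz <- outer(A[, 3], B[, 3], "-")
  if (!is.null(box)) {
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    dz <- dz - box[3] * round(dz / box[3])
  }
  sqrt(dx * dx + dy * dy + dz * dz)
}

#' Minimum distance between two selections in one frame
#'
#' Distance of closest approach: the minimum over all particle pairs of
#' the Euclidean (minimum-image if `box` is given) distance.
#'
#' @param frame n_particles x 3 coordinate matrix (nm)
#' @param selA,selB particle index vectors (non-empty)
#' @param box orthorhombic box lengths (nm) or NULL for non-periodic
#' @return minimum distance (nm)
#' @export
min_distance <- function(frame, selA, selB, box = NULL) {
  if (length(selA) == 0 || length(selB) == 0) stop("empty selection")
  min(pair_dists(frame[selA, , drop = FALSE], frame[selB, , drop = FALSE], box))
}

# Per-frame minimum distance between two particle index sets, vectorized
# over frames. For small selections the loop runs over particle pairs
# (each a length-n_frames vector op); otherwise over frames.
min_dist_frames <- function(traj, idxA, idxB, periodic = TRUE) {
  if (length(idxA) == 0 || length(idxB) == 0) stop("empty selection")
  nf <- n_frames(traj)
  box <- if (periodic) traj$box else NULL
  if (is.matrix(box) || length(idxA) * length(idxB) > 2048) {
    out <- numeric(nf)
    for (i in seq_len(nf)) {
      b <- if (periodic) frame_box(traj, i) else NULL
      out[i] <- min_distance(frame_coords(traj, i), idxA, idxB, b)
    }
    return(out)
  }
  m <- rep(Inf, nf)
  cx <- traj$coords
  for (a in idxA) {
    dx <- cx[, idxB, 1, drop = FALSE] - cx[, a, 1]
    dy <- cx[, idxB, 2, drop = FALSE] - cx[, a, 2]
    dz <- cx[, idxB, 3, drop = FALSE] - cx[, a, 3]
    if (!is.null(box)) {
      dx <- dx - box[1] * round(dx / box[1])
      dy <- dy - box[2] * round(dy / box[2])
      dz <- dz - box[3] * round(dz / box[3])
    }
    d <- sqrt(dx * dx + dy * dy + dz * dz)
    dim(d) <- c(nf, length(idxB))
    rmin <- d[cbind(seq_len(nf), max.col(-d, ties.method = "first"))]
    m <- pmin(m, rmin)
  }
  m
}

# Mass-weighted centre of mass of a particle set, per frame (n_frames x 3).
com_frames <- function(traj, idx) {
  w <- traj$topology$atoms$mass[idx]
  w <- w / sum(w)
  out <- matrix(0, n_frames(traj), 3)
  for (k in 1:3) {
    m <- traj$coords[, idx, k, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    out[, k] <- m %*% w
  }
  out
}

# Side-chain particle indices of one residue; falls back to all beads of
# the residue when it has no side-chain particle (e.g. one-bead glycine).
sidechain_idx <- function(top, res, chain = NULL) {
  at <- top$atoms
  keep <- at$resid == res
  if (!is.null(chain)) keep <- keep & at$chain == chain
  sc <- which(keep & !(at$elety %in% backbone_names()))
  if (length(sc) > 0) sc else which(keep)
}

#' Per-frame distance trace between two selections
#'
#' `metric = "min_pairwise"` gives the distance of closest approach per
#' frame; `metric = "sidechain_com"` the distance between the mass-weighted
#' centres of mass of the two selections (pass side-chain selections to get
#' the side-chain COM distance).
#'
#' @param traj a `trajectory`
#' @param selA,selB particle index vectors
#' @param metric "min_pairwise" or "sidechain_com"
#' @param periodic apply minimum image using the trajectory box
#' @return object of class `distance_trace`: numeric vector (nm) with
#'   `times`, `metric` and `provenance` attributes
#' @export
distance_trace <- function(traj, selA, selB,
                           metric = c("min_pairwise", "sidechain_com"),
                           periodic = TRUE) {
  metric <- match.arg(metric)
  if (length(selA) == 0 || length(selB) == 0) stop("empty selection")
  if (metric == "min_pairwise") {
    v <- min_dist_frames(traj, selA, selB, periodic = periodic)
  } else {
    a <- com_frames(traj, selA)
    b <- com_frames(traj, selB)
    dd <- a - b
    box <- if (periodic) traj$box else NULL
    if (!is.null(box) && !is.matrix(box))
      for (k in 1:3) dd[, k] <- dd[, k] - box[k] * round(dd[, k] / box[k])
    v <- sqrt(rowSums(dd * dd))
  }
  structure(v, class = "distance_trace", times = traj$times, metric = metric,
            provenance = paste0(attr(selA, "provenance"), " vs ",
                                attr(selB, "provenance")))
}

#' Contact indicator
#'
#' TRUE where the distance is within the cutoff. The boundary is
#' inclusive: a distance exactly equal to the cutoff counts as a contact.
#'
#' @param trace numeric distance vector (nm)
#' @param cutoff contact cutoff (nm), > 0
#' @export
contact_indicator <- function(trace, cutoff) {
  stopifnot(cutoff > 0)
  as.logical(unclass(trace) <= cutoff)
}

# Residue -> particle-index list for a residue group.
residue_particles <- function(top, resids, chain = NULL) {
  at <- top$atoms
  out <- lapply(resids, function(r) {
    keep <- at$resid == r
    if (!is.null(chain)) keep <- keep & at$chain == chain
    which(keep)
  })
  if (any(lengths(out) == 0))
    stop("residues not in topology: ",
         paste(resids[lengths(out) == 0], collapse = ", "))
  names(out) <- resids
  out
}

resolve_window <- function(nf, window) {
  if (is.null(window)) return(seq_len(nf))
  window <- as.integer(window)
  if (length(window) == 0) stop("zero-length frame window")
  if (any(window < 1 | window > nf)) stop("frame window out of range")
  window
}

#' Residue-pair contact-probability map
#'
#' For every residue pair the fraction of frames in which the two
#' residues' minimum inter-particle distance is within the cutoff is
#' computed per replicate (normalizing by that replicate's frame count),
#' then averaged over replicates with equal weight. For `residues_a ==
#' residues_b` (intra-molecular) the map is symmetric with diagonal fixed
#' to 1 by convention.
#'
#' @param trajs a `trajectory` or list of replicate trajectories sharing
#'   one topology
#' @param residues_a,residues_b residue index vectors
#' @param cutoff contact cutoff (nm); 0.6 by default (0.5 is the other
#'   commonly used value — always recorded in the result)
#' @param chain_a,chain_b optional chain restriction per group
#' @param window frame indices to include (NULL = all)
#' @param periodic minimum-image convention; default: on for
#'   inter-molecular maps (different chains), off for intra
#' @return matrix of class `contact_map` with `cutoff`, `n_frames`,
#'   `n_replicates` attributes
#' @export
contact_probability_map <- function(trajs, residues_a, residues_b,
                                    cutoff = 0.6, chain_a = NULL, chain_b = NULL,
                                    window = NULL, periodic = NULL) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  if (length(trajs) < 1) stop("need at least one replicate")
  stopifnot(cutoff > 0)
  intra <- identical(as.integer(residues_a), as.integer(residues_b)) &&
    identical(chain_a, chain_b)
  if (is.null(periodic)) periodic <- !intra
  na <- length(residues_a); nb <- length(residues_b)
  acc <- matrix(0, na, nb, dimnames = list(residues_a, residues_b))
  tot_frames <- 0L
  for (traj in trajs) {
    w <- resolve_window(n_frames(traj), window)
    tw <- subset_frames(traj, w)
    tot_frames <- tot_frames + length(w)
    pa <- residue_particles(traj$topology, residues_a, chain_a)
    pb <- residue_particles(traj$topology, residues_b, chain_b)
    p <- matrix(0, na, nb)
    for (i in seq_len(na)) {
      jmax <- if (intra) i else nb
      for (j in seq_len(jmax)) {
        if (intra && i == j) { p[i, j] <- 1; next }
        d <- min_dist_frames(tw, pa[[i]], pb[[j]], periodic = periodic)
        p[i, j] <- mean(d <= cutoff)
        if (intra) p[j, i] <- p[i, j]
      }
    }
    acc <- acc + p
  }
  structure(acc / length(trajs), class = c("contact_map", "matrix"),
            cutoff = cutoff, n_frames = tot_frames,
            n_replicates = length(trajs), intra = intra)
}

#' Composite apo/bound contact matrix
#'
#' Places one symmetric map in the strict upper triangle and another in
#' the strict lower triangle, diagonal fixed to 1 — the standard composite
#' display of two conditions in one matrix.
#'
#' @param map_upper,map_lower symmetric `contact_map`s with identical labels
#' @export
composite_map <- function(map_upper, map_lower) {
  if (!identical(dimnames(map_upper), dimnames(map_lower)))
    stop("composite_map: label mismatch")
  if (nrow(map_upper) != ncol(map_upper) ||
      !isTRUE(all.equal(unclass(map_upper), t(unclass(map_upper)))) ||
      !isTRUE(all.equal(unclass(map_lower), t(unclass(map_lower)))))
    stop("composite_map: maps must be symmetric")
  out <- matrix(1, nrow(map_upper), ncol(map_upper),
                dimnames = dimnames(map_upper))
  up <- upper.tri(out)
  out[up] <- unclass(map_upper)[up]
  lo <- lower.tri(out)
  out[lo] <- unclass(map_lower)[lo]
  out
}

#' Per-residue partner-contact profile
#'
#' For each residue of group A, the fraction of frames in which its
#' minimum distance to ANY particle of group B is within the cutoff
#' (a union over partner residues, not a sum), replicate-averaged.
#'
#' @inheritParams contact_probability_map
#' @return named numeric vector over `residues_a`
#' @export
per_residue_partner_profile <- function(trajs, residues_a, residues_b,
                                        cutoff = 0.6, chain_a = NULL,
                                        chain_b = NULL, window = NULL,
                                        periodic = TRUE) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  if (length(trajs) < 1) stop("need at least one replicate")
  if (length(residues_b) == 0) stop("empty partner group")
  acc <- stats::setNames(numeric(length(residues_a)), residues_a)
  for (traj in trajs) {
    w <- resolve_window(n_frames(traj), window)
    tw <- subset_frames(traj, w)
    pa <- residue_particles(traj$topology, residues_a, chain_a)
    pb <- unlist(residue_particles(traj$topology, residues_b, chain_b),
                 use.names = FALSE)
    for (i in seq_along(residues_a)) {
      d <- min_dist_frames(tw, pa[[i]], pb, periodic = periodic)
      acc[i] <- acc[i] + mean(d <= cutoff)
    }
  }
  acc / length(trajs)
}

#' Normalized histogram of a residue-pair side-chain COM distance
#'
#' Pools frames over all replicates; bins are half-open `[edge, edge+bin)`
#' with origin 0; bin masses are counts divided by the total frame count
#' and sum to 1.
#'
#' @param trajs a `trajectory` or list of replicates
#' @param res_i,res_j residue indices
#' @param bin bin width (nm), > 0
#' @param chain optional chain of the residues
#' @param periodic minimum-image convention (default off: intra-molecular)
#' @return data.frame with `bin_lower`, `bin_center`, `density`
#' @export
pair_distance_histogram <- function(trajs, res_i, res_j, bin = 0.1,
                                    chain = NULL, periodic = FALSE) {
  stopifnot(bin > 0)
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  d <- unlist(lapply(trajs, function(traj) {
    a <- sidechain_idx(traj$topology, res_i, chain)
    b <- sidechain_idx(traj$topology, res_j, chain)
    unclass(distance_trace(traj, a, b, metric = "sidechain_com",
                           periodic = periodic))
  }))
  k <- floor(d / bin)   # half-open bins [k*bin, (k+1)*bin)
  tab <- table(k)
  kk <- as.integer(names(tab))
  data.frame(bin_lower = kk * bin,
             bin_center = (kk + 0.5) * bin,
             density = as.numeric(tab) / length(d))
}
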