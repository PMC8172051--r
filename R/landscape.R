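check_fit_selection <- function(coords) {
  if (nrow(coords) < 3) stop("fit selection needs >= 3 particles")
  cc <- sweep(coords, 2, colMeans(coords))
  s <- svd(cc, nu = 0, nv = 0)$d
  if (length(s) < 2 || s[2] < 1e-10)
    stop("degenerate fit selection (collinear or coincident particles)")
  invisible(TRUE)
}

#' Least-squares rigid-body superposition
#'
#' Optimal rotation + translation (no reflection) of a mobile frame onto
#' a reference over a fit selection; the transform is applied to the whole
#' mobile frame.
#'
#' @param mobile,reference n_particles x 3 coordinate matrices (nm)
#' @param fit_sel particle indices used for the fit (>= 3, non-collinear)
#' @return transformed copy of `mobile`
#' @export
superpose <- function(mobile, reference, fit_sel = seq_len(nrow(mobile))) {
  stopifnot(nrow(mobile) == nrow(reference))
  check_fit_selection(mobile[fit_sel, , drop = FALSE])
  check_fit_selection(reference[fit_sel, , drop = FALSE])
  inds <- bio3d::atom2xyz(fit_sel)
  # rot.lsq can produce sqrt(<0 by rounding) NaN warnings on
  # near-degenerate eigenvalues; the returned rotation is unaffected
  out <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(reference)),
                   mobile = as.numeric(t(mobile)),
                   fixed.inds = inds, mobile.inds = inds))
  matrix(out, ncol = 3, byrow = TRUE)
}

#' RMSD after superposition
#'
#' Root-mean-square deviation over `rmsd_sel` after least-squares
#' superposition on `fit_sel`. For the disordered-tail landscape the
#' default fits on the same backbone selection whose RMSD is measured,
#' so the value reports internal conformation only.
#'
#' @param frame,reference n_particles x 3 coordinate matrices (nm)
#' @param rmsd_sel particle indices entering the RMSD
#' @param fit_sel particle indices used for the superposition
#' @return RMSD (nm)
#' @export
backbone_rmsd <- function(frame, reference, rmsd_sel, fit_sel = rmsd_sel) {
  if (length(rmsd_sel) == 0) stop("empty selection")
  fitted <- superpose(frame, reference, fit_sel)
  dd <- fitted[rmsd_sel, , drop = FALSE] - reference[rmsd_sel, , drop = FALSE]
  sqrt(mean(rowSums(dd * dd)))
}

#' Per-frame RMSD trace against a reference
#' @param traj a `trajectory`
#' @param reference n_particles x 3 reference frame (nm)
#' @inheritParams backbone_rmsd
#' @export
rmsd_trace <- function(traj, reference, rmsd_sel, fit_sel = rmsd_sel) {
  vapply(seq_len(n_frames(traj)), function(i)
    backbone_rmsd(frame_coords(traj, i), reference, rmsd_sel, fit_sel),
    numeric(1))
}

#' Radius of gyration
#'
#' Mass-weighted RMS distance of a selection from its centre of mass:
#' sqrt( sum m_i |r_i - r_com|^2 / sum m_i ).
#'
#' @param frame n_particles x 3 coordinate matrix (nm)
#' @param sel particle indices
#' @param mass per-particle masses for `sel` (default: equal weights)
#' @return Rg (nm)
#' @export
radius_of_gyration <- function(frame, sel = seq_len(nrow(frame)), mass = NULL) {
  if (length(sel) == 0) stop("empty selection")
  x <- frame[sel, , drop = FALSE]
  if (is.null(mass)) mass <- rep(1, length(sel))
  w <- mass / sum(mass)
  com <- colSums(x * w)
  dd <- sweep(x, 2, com)
  sqrt(sum(w * rowSums(dd * dd)))
}

#' Per-frame radius of gyration of a selection
#' @param traj a `trajectory`
#' @param sel particle indices
#' @param mass_weighted use topology masses (default TRUE)
#' @export
rg_trace <- function(traj, sel, mass_weighted = TRUE) {
  m <- if (mass_weighted) traj$topology$atoms$mass[sel] else NULL
  vapply(seq_len(n_frames(traj)), function(i)
    radius_of_gyration(frame_coords(traj, i), sel, m), numeric(1))
}

# All-pairs RMSD matrix over the frames of a trajectory.
pairwise_rmsd <- function(traj, rmsd_sel, fit_sel = rmsd_sel) {
  n <- n_frames(traj)
  frames <- lapply(seq_len(n), function(i) frame_coords(traj, i))
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    M[i, j] <- M[j, i] <- backbone_rmsd(frames[[i]], frames[[j]],
                                        rmsd_sel, fit_sel)
  M
}

#' GROMOS (Daura) conformational clustering
#'
#' Greedy neighbour-count clustering on the pairwise RMSD matrix:
#' repeatedly, the frame with the most neighbours (pairwise RMSD within
#' the cutoff, among unassigned frames) becomes a cluster centre and is
#' removed together with its neighbours. Ties in neighbour count are
#' broken toward the lowest frame index, making the result deterministic.
#'
#' @param traj a `trajectory` (frames to cluster)
#' @param cutoff RMSD cutoff (nm), > 0
#' @param rmsd_sel,fit_sel selections for the pairwise RMSD
#' @param rmsd_matrix optional precomputed pairwise RMSD matrix
#' @return object of class `cluster_assignment`: `labels` (per-frame
#'   cluster id, 1 = largest), `clusters` (list of `center`, `members`,
#'   `population`), `cutoff`
#' @export
gromos_cluster <- function(traj, cutoff, rmsd_sel, fit_sel = rmsd_sel,
                           rmsd_matrix = NULL) {
  stopifnot(cutoff > 0)
  n <- if (inherits(traj, "trajectory")) n_frames(traj) else nrow(rmsd_matrix)
  if (is.null(rmsd_matrix)) rmsd_matrix <- pairwise_rmsd(traj, rmsd_sel, fit_sel)
  adj <- rmsd_matrix <= cutoff
  diag(adj) <- TRUE
  labels <- integer(n)
  clusters <- list()
  remaining <- seq_len(n)
  k <- 0L
  while (length(remaining) > 0) {
    counts <- rowSums(adj[remaining, remaining, drop = FALSE])
    center <- remaining[which.max(counts)]   # first max = lowest frame index
    members <- remaining[adj[remaining, center]]
    k <- k + 1L
    labels[members] <- k
    clusters[[k]] <- list(center = center, members = members,
                          population = length(members) / n)
    remaining <- setdiff(remaining, members)
  }
  structure(list(labels = labels, clusters = clusters, cutoff = cutoff),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("GROMOS clustering, cutoff %.3g nm: %d clusters\n",
              x$cutoff, length(x$clusters)))
  for (i in seq_len(min(5, length(x$clusters))))
    cat(sprintf("  cluster %d: %d frames (%.1f%%), center frame %d\n", i,
                length(x$clusters[[i]]$members),
                100 * x$clusters[[i]]$population, x$clusters[[i]]$center))
  invisible(x)
}

#' Average structure of the top cluster
#'
#' Reference extraction: every member of the highest-population cluster
#' is superposed onto the cluster centre, then coordinates are averaged.
#'
#' @param assignment a `cluster_assignment`
#' @param traj the clustered `trajectory`
#' @param fit_sel selection used for the superposition
#' @return n_particles x 3 reference frame with a `provenance` attribute
#' @export
reference_from_top_cluster <- function(assignment, traj, fit_sel) {
  cl <- assignment$clusters[[1]]
  center <- frame_coords(traj, cl$center)
  acc <- 0
  for (m in cl$members)
    acc <- acc + superpose(frame_coords(traj, m), center, fit_sel)
  ref <- acc / length(cl$members)
  attr(ref, "provenance") <- sprintf(
    "average of top cluster (%d members, center frame %d, cutoff %.3g nm)",
    length(cl$members), cl$center, assignment$cutoff)
  ref
}

# Half-open binning [k*bin, (k+1)*bin), origin 0.
bin_index <- function(x, bin) as.integer(floor(x / bin)) + 1L

#' 2D population-density landscape
#'
#' Projects each frame onto (backbone RMSD to a reference, side-chain COM
#' distance of a residue pair), bins on a half-open 0.1 nm grid,
#' normalizes per replicate, averages the grids over replicates, and
#' renormalizes. The result is a population density summing to 1.
#'
#' @param trajs a `trajectory` or list of replicates
#' @param reference n_particles x 3 reference frame (nm)
#' @param rmsd_sel,fit_sel selections for the RMSD coordinate
#' @param pair length-2 residue index vector for the distance coordinate
#'   (side-chain centres of mass)
#' @param bin bin width (nm) for both axes, default 0.1
#' @param chain chain of the pair residues
#' @param periodic minimum-image for the pair distance (default off)
#' @return object of class `landscape_density`: matrix (RMSD bins x
#'   distance bins) with `rmsd_centers`, `dist_centers`, `bin` attributes
#' @export
landscape <- function(trajs, reference, rmsd_sel, pair, fit_sel = rmsd_sel,
                      bin = 0.1, chain = NULL, periodic = FALSE) {
  stopifnot(bin > 0, length(pair) == 2)
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  proj <- lapply(trajs, function(traj) {
    r <- rmsd_trace(traj, reference, rmsd_sel, fit_sel)
    a <- sidechain_idx(traj$topology, pair[1], chain)
    b <- sidechain_idx(traj$topology, pair[2], chain)
    d <- unclass(distance_trace(traj, a, b, metric = "sidechain_com",
                                periodic = periodic))
    cbind(r, d)
  })
  nr <- max(vapply(proj, function(p) max(bin_index(p[, 1], bin)), 1L))
  nd <- max(vapply(proj, function(p) max(bin_index(p[, 2], bin)), 1L))
  acc <- matrix(0, nr, nd)
  for (p in proj) {
    g <- matrix(0, nr, nd)
    ij <- cbind(bin_index(p[, 1], bin), bin_index(p[, 2], bin))
    for (row in seq_len(nrow(ij))) g[ij[row, 1], ij[row, 2]] <- g[ij[row, 1], ij[row, 2]] + 1
    acc <- acc + g / nrow(p)
  }
  dens <- acc / sum(acc)
  structure(dens, class = c("landscape_density", "matrix"), bin = bin,
            rmsd_centers = (seq_len(nr) - 0.5) * bin,
            dist_centers = (seq_len(nd) - 0.5) * bin,
            n_replicates = length(trajs))
}

#' Local maxima of a landscape density
#'
#' Bins strictly greater than every neighbour within a Chebyshev radius
#' of `min_sep` bins, ranked by density. A flat grid has no strict maxima.
#'
#' @param ld a `landscape_density`
#' @param min_sep neighbourhood radius in bins (default 1)
#' @return data.frame with `rmsd_center`, `dist_center`, `density`
#' @export
local_maxima <- function(ld, min_sep = 1) {
  m <- unclass(ld)
  nr <- nrow(m); nd <- ncol(m)
  out <- list()
  for (i in seq_len(nr)) for (j in seq_len(nd)) {
    v <- m[i, j]
    if (v <= 0) next
    nb <- m[max(1, i - min_sep):min(nr, i + min_sep),
            max(1, j - min_sep):min(nd, j + min_sep)]
    if (sum(nb >= v) == 1)   # only the bin itself ties its own value
      out[[length(out) + 1]] <- c(i, j, v)
  }
  if (length(out) == 0)
    return(data.frame(rmsd_center = numeric(0), dist_center = numeric(0),
                      density = numeric(0)))
  o <- do.call(rbind, out)
  res <- data.frame(rmsd_center = attr(ld, "rmsd_centers")[o[, 1]],
                    dist_center = attr(ld, "dist_centers")[o[, 2]],
                    density = o[, 3])
  res[order(-res$density), , drop = FALSE]
}
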