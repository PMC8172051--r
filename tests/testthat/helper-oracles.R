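# Independent brute-force oracles and tiny fixture builders. These are
# deliberately naive re-implementations (plain loops, no shared code with
# the package internals) used to freeze expected values.

# Toy topology: n_res residues on one chain, beads per residue named
# BB (+ SC1, SC2, ... for extra beads).
toy_topology <- function(n_res, beads_per_res = 1, chain = "A") {
  elety <- unlist(lapply(seq_len(beads_per_res), function(b)
    if (b == 1) "BB" else paste0("SC", b - 1)))
  topology(data.frame(
    eleno = seq_len(n_res * beads_per_res),
    elety = rep(elety, n_res),
    resid = rep(seq_len(n_res), each = beads_per_res),
    resname = "ALA", chain = chain, mass = 72))
}

# Trajectory with explicit per-frame coordinates (list of n x 3 matrices).
toy_trajectory <- function(frames, top, box = NULL, dt = 1) {
  nf <- length(frames)
  co <- array(NA_real_, dim = c(nf, nrow(frames[[1]]), 3))
  for (i in seq_len(nf)) co[i, , ] <- frames[[i]]
  trajectory(co, dt * (seq_len(nf) - 1), top, box = box)
}

random_frames <- function(nf, np, scale = 2) {
  lapply(seq_len(nf), function(i) matrix(stats::runif(np * 3, 0, scale), np, 3))
}

# Minimum-image distance by explicit enumeration of the 27 periodic images.
oracle_min_image_dist <- function(a, b, box) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- sqrt(sum((a - (b + c(ix, iy, iz) * box))^2))
    if (d < best) best <- d
  }
  best
}

# Contact-probability map by triple loop over replicates, frames, pairs.
oracle_contact_map <- function(trajs, res_a, res_b, cutoff, chain_a = NULL,
                               chain_b = NULL) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  intra <- identical(res_a, res_b) && identical(chain_a, chain_b)
  acc <- matrix(0, length(res_a), length(res_b))
  for (traj in trajs) {
    at <- traj$topology$atoms
    part <- function(r, ch) {
      k <- at$resid == r
      if (!is.null(ch)) k <- k & at$chain == ch
      which(k)
    }
    p <- matrix(0, length(res_a), length(res_b))
    for (ia in seq_along(res_a)) for (ib in seq_along(res_b)) {
      if (intra && res_a[ia] == res_b[ib]) { p[ia, ib] <- 1; next }
      pa <- part(res_a[ia], chain_a); pb <- part(res_b[ib], chain_b)
      hit <- 0
      for (f in seq_len(n_frames(traj))) {
        fc <- frame_coords(traj, f)
        dmin <- Inf
        for (x in pa) for (y in pb) {
          d <- sqrt(sum((fc[x, ] - fc[y, ])^2))
          if (d < dmin) dmin <- d
        }
        if (dmin <= cutoff) hit <- hit + 1
      }
      p[ia, ib] <- hit / n_frames(traj)
    }
    acc <- acc + p
  }
  acc / length(trajs)
}

# GROMOS/Daura clustering by a naive scan re-done from the definition:
# recompute every frame's neighbour count at each round.
oracle_gromos <- function(M, cutoff) {
  n <- nrow(M)
  unassigned <- rep(TRUE, n)
  labels <- integer(n)
  centers <- integer(0)
  k <- 0L
  while (any(unassigned)) {
    best <- -1; best_i <- NA
    for (i in which(unassigned)) {
      cnt <- 0
      for (j in which(unassigned)) if (M[i, j] <= cutoff) cnt <- cnt + 1
      if (cnt > best) { best <- cnt; best_i <- i }   # first max = lowest index
    }
    k <- k + 1L
    centers[k] <- best_i
    for (j in which(unassigned)) if (M[best_i, j] <= cutoff) {
      labels[j] <- k
      unassigned[j] <- FALSE
    }
  }
  list(labels = labels, centers = centers)
}

# Earliest persistent-suffix frame by exhaustive suffix scan.
oracle_binding_frame <- function(v, cutoff) {
  for (i in seq_along(v)) if (all(v[i:length(v)] <= cutoff)) return(i)
  NULL
}

# Random rigid motion (proper rotation + translation).
random_rigid <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
    3, 3, byrow = TRUE)
  list(R = R, t = stats::rnorm(3, 0, 2))
}
apply_rigid <- function(x, rt) sweep(x %*% t(rt$R), 2, rt$t, "+")

# Deterministic rank-decorrelated permutation of 1..n (multiplicative
# shuffle by a unit coprime to n).
decorrelating_permutation <- function(n, mult = 13) {
  order((seq_len(n) * mult) %% n + 1e-9 * seq_len(n))
}
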