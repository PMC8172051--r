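test_that("superposition recovers rigid motions exactly", {
  set.seed(41)
  ref <- matrix(runif(30), 10, 3)
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)  # 90 deg
  mob <- ref %*% t(Rz)
  fitted <- superpose(mob, ref)
  expect_lt(sqrt(mean(rowSums((fitted - ref)^2))), 1e-9)

  id <- superpose(ref, ref)
  expect_lt(max(abs(id - ref)), 1e-9)

  # fitted RMSD never exceeds unfitted RMSD
  for (k in 1:20) {
    a <- matrix(runif(30), 10, 3); b <- matrix(runif(30), 10, 3)
    r_fit <- backbone_rmsd(a, b, 1:10)
    r_raw <- sqrt(mean(rowSums((a - b)^2)))
    expect_lte(r_fit, r_raw + 1e-12)
  }
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "degenerate")
})

test_that("RMSD has its closed-form values and rigid-motion invariance", {
  set.seed(43)
  ref <- matrix(runif(30, 0, 2), 10, 3)
  expect_equal(backbone_rmsd(ref, ref, 1:10), 0, tolerance = 1e-9)

  # displace two measured particles by 0.2 each; fit on the other eight
  mob <- ref
  mob[9, ] <- mob[9, ] + c(0.2, 0, 0)
  mob[10, ] <- mob[10, ] + c(0, 0.2, 0)
  expect_equal(backbone_rmsd(mob, ref, rmsd_sel = 9:10, fit_sel = 1:8), 0.2,
               tolerance = 1e-9)

  for (k in 1:10) {
    rt <- random_rigid()
    expect_equal(backbone_rmsd(apply_rigid(mob, rt), ref, 1:10),
                 backbone_rmsd(mob, ref, 1:10), tolerance = 1e-9)
  }
})

test_that("radius of gyration matches closed forms and is invariant", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  two <- rbind(c(0, 0, 0), c(0, 0, 1.4))
  expect_equal(radius_of_gyration(two), 0.7)   # d/2 for equal masses
  # mass weighting shifts the COM toward the heavy particle
  expect_equal(radius_of_gyration(two, mass = c(3, 1)),
               sqrt(0.75 * 0.35^2 + 0.25 * 1.05^2))
  set.seed(47)
  x <- matrix(runif(24), 8, 3)
  for (k in 1:10) {
    rt <- random_rigid()
    expect_equal(radius_of_gyration(apply_rigid(x, rt)),
                 radius_of_gyration(x), tolerance = 1e-12)
  }
})

test_that("GROMOS clustering handles degenerate and well-separated cases", {
  top <- toy_topology(4)
  base <- matrix(runif(12), 4, 3)
  same <- toy_trajectory(replicate(5, base, simplify = FALSE), top)
  cl <- gromos_cluster(same, 0.1, 1:4)
  expect_equal(length(cl$clusters), 1)
  expect_equal(cl$clusters[[1]]$center, 1)   # lowest-index tie-break
  expect_equal(cl$clusters[[1]]$population, 1)

  # two tight groups of sizes 3 and 2 with distinct internal structure
  # (a rigid offset alone would superpose away)
  set.seed(53)
  other <- base
  other[1, ] <- other[1, ] + c(2, 0, 0)
  g1 <- lapply(1:3, function(i) base + matrix(rnorm(12, 0, 0.005), 4, 3))
  g2 <- lapply(1:2, function(i) other + matrix(rnorm(12, 0, 0.005), 4, 3))
  tr <- toy_trajectory(c(g1[1], g2[1], g1[2:3], g2[2]), top)
  cl2 <- gromos_cluster(tr, 0.2, 1:4)
  expect_equal(lengths(lapply(cl2$clusters, `[[`, "members")), c(3, 2))
  expect_equal(sort(cl2$clusters[[1]]$members), c(1, 3, 4))
  expect_equal(sum(vapply(cl2$clusters, `[[`, 1, "population")), 1)
})

test_that("GROMOS clustering agrees exactly with the naive oracle", {
  set.seed(59)
  top <- toy_topology(5)
  tr <- toy_trajectory(random_frames(20, 5, scale = 1), top)
  M <- pairwise_rmsd(tr, 1:5)
  for (cut in c(0.15, 0.3, 0.6)) {
    cl <- gromos_cluster(tr, cut, 1:5, rmsd_matrix = M)
    o <- oracle_gromos(M, cut)
    expect_equal(cl$labels, o$labels)
    expect_equal(vapply(cl$clusters, `[[`, 1L, "center"), o$centers)
  }
  # every frame in exactly one cluster; first center maximal
  cl <- gromos_cluster(tr, 0.3, 1:5, rmsd_matrix = M)
  expect_true(all(cl$labels >= 1))
  counts <- rowSums(M <= 0.3)
  expect_gte(length(cl$clusters[[1]]$members), max(counts))
  # raising the cutoff never increases the cluster count
  ncl <- vapply(c(0.1, 0.2, 0.4, 0.8),
                function(ct) length(gromos_cluster(tr, ct, 1:5,
                                                   rmsd_matrix = M)$clusters), 1L)
  expect_true(all(diff(ncl) <= 0))
})

test_that("the top-cluster reference is the superposed member average", {
  top <- toy_topology(4)
  base <- matrix(runif(12, 0, 2), 4, 3)
  same <- toy_trajectory(replicate(4, base, simplify = FALSE), top)
  cl <- gromos_cluster(same, 0.1, 1:4)
  ref <- reference_from_top_cluster(cl, same, 1:4)
  expect_equal(unname(ref[, ]), unname(base), tolerance = 1e-9)

  # averaging reduces the mean RMSD to members relative to any single member
  set.seed(61)
  frames <- lapply(1:6, function(i) base + matrix(rnorm(12, 0, 0.1), 4, 3))
  tr <- toy_trajectory(frames, top)
  cl2 <- gromos_cluster(tr, 1.0, 1:4)
  ref2 <- reference_from_top_cluster(cl2, tr, 1:4)
  to_ref <- mean(vapply(frames, function(f) backbone_rmsd(f, ref2, 1:4), 1))
  to_member <- mean(vapply(frames, function(f)
    backbone_rmsd(f, frames[[1]], 1:4), 1))
  expect_lt(to_ref, to_member)
})

test_that("landscapes are normalized densities on a half-open grid", {
  ens <- generate_ensemble(synthetic_spec(n_replicates = 2, n_frames = 200,
                                          tau = 20, planted_contacts = NULL,
                                          seed = 17))
  top <- ens$trajectories[[1]]$topology
  bb <- select_particles(top, resid = 1:37, part = "backbone", chain = "A")
  ref <- frame_coords(ens$trajectories[[1]], 1)
  ld <- landscape(ens$trajectories, ref, bb, pair = c(1, 26), chain = "A")
  expect_equal(sum(ld), 1, tolerance = 1e-9)
  expect_true(all(unclass(ld) >= 0))

  # all frames at one point occupy a single bin with density 1
  one <- subset_frames(ens$trajectories[[1]], rep(1, 1))
  co <- one$coords[rep(1, 5), , , drop = FALSE]
  same <- trajectory(co, 0:4, top)
  ld1 <- landscape(same, frame_coords(same, 1), bb, pair = c(1, 26), chain = "A")
  expect_equal(sum(unclass(ld1) > 0), 1)
  expect_equal(max(ld1), 1)

  # concatenating identical replicates leaves the landscape unchanged
  ld2 <- landscape(list(ens$trajectories[[1]], ens$trajectories[[1]]),
                   ref, bb, pair = c(1, 26), chain = "A")
  ld_single <- landscape(ens$trajectories[[1]], ref, bb, pair = c(1, 26),
                         chain = "A")
  expect_equal(unclass(ld2), unclass(ld_single), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("local maxima are strict neighbourhood peaks", {
  g <- matrix(0, 5, 5)
  g[2, 2] <- 0.6; g[4, 5] <- 0.4
  ld <- structure(g / sum(g), class = c("landscape_density", "matrix"),
                  bin = 0.1, rmsd_centers = (1:5 - 0.5) * 0.1,
                  dist_centers = (1:5 - 0.5) * 0.1)
  mx <- local_maxima(ld)
  expect_equal(nrow(mx), 2)
  expect_equal(mx$rmsd_center, c(0.15, 0.35))

  flat <- structure(matrix(1 / 25, 5, 5),
                    class = c("landscape_density", "matrix"), bin = 0.1,
                    rmsd_centers = (1:5 - 0.5) * 0.1,
                    dist_centers = (1:5 - 0.5) * 0.1)
  expect_equal(nrow(local_maxima(flat)), 0)

  single <- structure(matrix(c(1, rep(0, 8)), 3, 3),
                      class = c("landscape_density", "matrix"), bin = 0.1,
                      rmsd_centers = (1:3 - 0.5) * 0.1,
                      dist_centers = (1:3 - 0.5) * 0.1)
  expect_equal(nrow(local_maxima(single)), 1)
})
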