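test_that("min_distance matches brute force and the minimum-image oracle", {
  fr <- rbind(c(0, 0, 0), c(0, 0, 2), c(0, 0, 3))
  expect_equal(min_distance(rbind(c(0, 0, 0), c(0, 0, 1)), 1, 2), 1.0)
  expect_equal(min_distance(fr, 1:2, 3), 1.0)  # min over all pairs

  box <- c(10, 10, 10)
  fr2 <- rbind(c(0.5, 0, 0), c(9.5, 0, 0))
  expect_equal(min_distance(fr2, 1, 2, box = box), 1.0)

  set.seed(42)
  for (k in 1:25) {
    a <- runif(3, 0, 10); b <- runif(3, 0, 10)
    expect_equal(min_distance(rbind(a, b), 1, 2, box = box),
                 oracle_min_image_dist(a, b, box), tolerance = 1e-12)
  }
  expect_error(min_distance(fr, integer(0), 1), "empty selection")
})

test_that("min_distance is symmetric and rigid-motion invariant", {
  set.seed(7)
  for (k in 1:20) {
    fr <- matrix(runif(30), 10, 3)
    a <- 1:4; b <- 5:10
    expect_identical(min_distance(fr, a, b), min_distance(fr, b, a))
    rt <- random_rigid()
    expect_equal(min_distance(apply_rigid(fr, rt), a, b),
                 min_distance(fr, a, b), tolerance = 1e-9)
  }
})

test_that("distance traces follow the frames and the chosen metric", {
  top <- toy_topology(2, beads_per_res = 2)
  fr <- rbind(c(0, 0, 0), c(0, 0, 0.1), c(2, 0, 0), c(2, 0, 0.1))
  tr <- toy_trajectory(list(fr, fr, fr), top)
  v <- distance_trace(tr, 1:2, 3:4)
  expect_equal(as.numeric(v), rep(2, 3))   # constant for identical frames

  # COM metric between two one-bead side chains
  sc1 <- select(top, "side chain of residue 1")
  sc2 <- select(top, "side chain of residue 2")
  vc <- distance_trace(tr, sc1, sc2, metric = "sidechain_com")
  expect_equal(as.numeric(vc), rep(2, 3))

  # min distance never exceeds the COM distance plus the largest
  # bead-to-COM offset of either set
  set.seed(3)
  top2 <- toy_topology(2, beads_per_res = 3)
  frs <- random_frames(20, 6)
  tr2 <- toy_trajectory(frs, top2)
  vmin <- distance_trace(tr2, 1:3, 4:6)
  vcom <- distance_trace(tr2, 1:3, 4:6, metric = "sidechain_com")
  maxoff <- vapply(frs, function(fr) {
    off <- function(i) max(sqrt(rowSums(sweep(fr[i, ], 2,
                                              colMeans(fr[i, ]))^2)))
    max(off(1:3), off(4:6))
  }, numeric(1))
  expect_true(all(vmin <= vcom + maxoff + 1e-12))
})

test_that("contact indicator uses an inclusive cutoff boundary", {
  expect_equal(contact_indicator(c(0.3, 0.7, 0.5, 0.9), 0.6),
               c(TRUE, FALSE, TRUE, FALSE))
  expect_true(contact_indicator(0.6, 0.6))
  expect_length(contact_indicator(numeric(0), 0.6), 0)
})

test_that("contact probabilities are per-replicate fractions averaged equally", {
  top <- toy_topology(2)
  near <- rbind(c(0, 0, 0), c(0.4, 0, 0))
  far <- rbind(c(0, 0, 0), c(2, 0, 0))
  tr <- toy_trajectory(list(near, far, near, far), top)
  m <- contact_probability_map(tr, 1:2, 1:2, cutoff = 0.6)
  expect_equal(m[1, 2], 0.5)   # contact in 2 of 4 frames
  expect_equal(m[1, 1], 1)     # diagonal convention
  expect_equal(unclass(m), t(unclass(m)))

  # replicates of different length average unweighted: 0.2 and 0.4 -> 0.3
  r1 <- toy_trajectory(c(list(near), replicate(4, far, simplify = FALSE)), top)
  r2 <- toy_trajectory(c(replicate(4, near, simplify = FALSE),
                         replicate(6, far, simplify = FALSE)), top)
  m2 <- contact_probability_map(list(r1, r2), 1:2, 1:2, cutoff = 0.6)
  expect_equal(m2[1, 2], 0.3)

  all_far <- toy_trajectory(list(far, far), top)
  m3 <- contact_probability_map(all_far, 1:2, 1:2, cutoff = 0.6)
  expect_equal(unclass(m3), matrix(c(1, 0, 0, 1), 2, 2), ignore_attr = TRUE)
  expect_error(contact_probability_map(tr, 1:2, 1:2, window = integer(0)),
               "zero-length")
})

test_that("contact map matches the brute-force oracle exactly", {
  set.seed(11)
  top <- toy_topology(6, beads_per_res = 2)
  trajs <- lapply(1:2, function(r)
    toy_trajectory(random_frames(30, 12, scale = 1.5), top))
  m <- contact_probability_map(trajs, 1:6, 1:6, cutoff = 0.6)
  o <- oracle_contact_map(trajs, 1:6, 1:6, 0.6)
  expect_equal(unclass(m), o, ignore_attr = TRUE)
})

test_that("enlarging the cutoff never decreases a contact probability", {
  set.seed(19)
  top <- toy_topology(5, beads_per_res = 2)
  tr <- toy_trajectory(random_frames(40, 10, scale = 1.2), top)
  m1 <- contact_probability_map(tr, 1:5, 1:5, cutoff = 0.4)
  m2 <- contact_probability_map(tr, 1:5, 1:5, cutoff = 0.7)
  expect_true(all(unclass(m2) >= unclass(m1)))
})

test_that("composite maps combine upper and lower triangles", {
  top <- toy_topology(3)
  set.seed(5)
  t1 <- toy_trajectory(random_frames(10, 3, 1), top)
  t2 <- toy_trajectory(random_frames(10, 3, 1), top)
  a <- contact_probability_map(t1, 1:3, 1:3, cutoff = 0.6)
  b <- contact_probability_map(t2, 1:3, 1:3, cutoff = 0.6)
  comp <- composite_map(a, b)
  expect_equal(comp[1, 2], a[1, 2])
  expect_equal(comp[2, 1], b[1, 2])
  expect_equal(diag(comp), c(`1` = 1, `2` = 1, `3` = 1))
  same <- composite_map(a, a)
  expect_equal(same, t(same))
  dimnames(b) <- list(c("4", "5", "6"), c("4", "5", "6"))
  expect_error(composite_map(a, b), "label mismatch")
})

test_that("partner profiles take the union of frames over partners", {
  # residue 1 contacts partner r2 in frames 1,2 and partner r3 in frames
  # 2,3 of 4: union probability 3/4, not the 4/4 a sum would give
  top <- toy_topology(3)
  mk <- function(d2, d3) rbind(c(0, 0, 0), c(d2, 0, 0), c(0, d3, 0))
  frames <- list(mk(0.4, 2), mk(0.4, 0.4), mk(2, 0.4), mk(2, 2))
  tr <- toy_trajectory(frames, top)
  p <- per_residue_partner_profile(tr, 1, 2:3, cutoff = 0.6)
  expect_equal(as.numeric(p["1"]), 3 / 4)

  # profile dominates every pairwise probability
  set.seed(23)
  tr2 <- toy_trajectory(random_frames(30, 3, 1.2), toy_topology(3))
  p2 <- per_residue_partner_profile(tr2, 1, 2:3, cutoff = 0.6)
  m <- contact_probability_map(tr2, 1, 2:3, cutoff = 0.6, periodic = FALSE)
  expect_gte(as.numeric(p2["1"]) + 1e-12, max(unclass(m)))

  expect_error(per_residue_partner_profile(tr, 1, integer(0)), "empty partner")

  # permanent contact with any of several partners gives probability 1
  allnear <- toy_trajectory(replicate(5, mk(0.3, 0.3), simplify = FALSE), top)
  expect_equal(as.numeric(per_residue_partner_profile(allnear, 1, 2:3,
                                                      cutoff = 0.6)["1"]), 1)
})

test_that("pair distance histograms are normalized half-open counts", {
  top <- toy_topology(2, beads_per_res = 2)
  at <- function(d) rbind(c(0, 0, 0), c(0, 0, 0.25), c(d, 0, 0), c(d, 0, 0.25))
  tr <- toy_trajectory(replicate(6, at(1.05), simplify = FALSE), top)
  h <- pair_distance_histogram(tr, 1, 2, bin = 0.1)
  expect_equal(nrow(h), 1)
  expect_equal(h$bin_lower, 1.0)
  expect_equal(h$density, 1)

  tr2 <- toy_trajectory(c(replicate(3, at(1.05), simplify = FALSE),
                          replicate(3, at(1.15), simplify = FALSE)), top)
  h2 <- pair_distance_histogram(tr2, 1, 2, bin = 0.1)
  expect_equal(h2$density, c(0.5, 0.5))
  expect_equal(sum(h2$density), 1, tolerance = 1e-12)
})
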