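test_that("strict binding detection finds the persistent-suffix start", {
  v <- c(1.2, 0.4, 0.8, 0.4, 0.3, 0.45)
  ev <- detect_time_of_binding(v, cutoff = 0.5)
  expect_equal(ev$frame, 4)   # frames 4..6 all within cutoff, frame 3 is not
  expect_null(detect_time_of_binding(c(0.9, 0.8, 0.7), cutoff = 0.5))
  expect_equal(detect_time_of_binding(c(0.3, 0.2, 0.4), cutoff = 0.5)$frame, 1)
  expect_error(detect_time_of_binding(numeric(0)), "empty trace")
})

test_that("strict detection agrees with the exhaustive suffix-scan oracle", {
  set.seed(31)
  for (k in 1:60) {
    n <- sample(1:50, 1)
    v <- runif(n, 0, 1)
    ev <- detect_time_of_binding(v, cutoff = 0.5)
    o <- oracle_binding_frame(v, 0.5)
    if (is.null(o)) expect_null(ev) else expect_equal(ev$frame, o)
  }
})

test_that("tolerant criterion reduces to strict at zero tolerance and forgives short spikes", {
  set.seed(33)
  for (k in 1:40) {
    v <- runif(sample(2:40, 1), 0, 1)
    s <- detect_time_of_binding(v, cutoff = 0.5)
    t0 <- detect_time_of_binding(v, cutoff = 0.5, criterion = "tolerant",
                                 max_unbound_frames = 0,
                                 dissociation_cutoff = 0.5)
    if (is.null(s)) expect_null(t0) else expect_equal(t0$frame, s$frame)
  }
  # an isolated 0.55 spike after binding is forgiven, a 3-frame one is not
  v <- c(0.9, 0.3, 0.55, 0.3, 0.3)
  expect_equal(detect_time_of_binding(v, criterion = "tolerant",
                                      max_unbound_frames = 2)$frame, 2)
  v2 <- c(0.9, 0.3, 0.55, 0.55, 0.55, 0.3, 0.3)
  expect_equal(detect_time_of_binding(v2, criterion = "tolerant",
                                      max_unbound_frames = 2)$frame, 6)
})

test_that("bound/unbound segments tile the trace", {
  seg <- binding_unbinding_segments(c(0.4, 0.4, 0.9, 0.4), cutoff = 0.5)
  expect_equal(seg$state, c("bound", "unbound", "bound"))
  expect_equal(seg$start, c(1, 3, 4))
  expect_equal(seg$end, c(2, 3, 4))

  one <- binding_unbinding_segments(rep(0.3, 7), cutoff = 0.5)
  expect_equal(nrow(one), 1)

  set.seed(37)
  for (k in 1:20) {
    v <- runif(sample(2:60, 1))
    s <- binding_unbinding_segments(v, 0.5)
    ind <- v <= 0.5
    expect_equal(nrow(s), sum(diff(ind) != 0) + 1)   # transitions + 1
    rebuilt <- unlist(Map(function(st, a, b) rep(st == "bound", b - a + 1),
                          s$state, s$start, s$end))
    expect_equal(unname(rebuilt), ind)               # tiles reconstruct it
  }
})

test_that("alignment at binding is pure re-indexing truncated to common span", {
  tr1 <- c(1, 1, 0.3, 0.31, 0.32, 0.33)   # binds at frame 3
  tr2 <- c(1, 1, 1, 1, 1, 0.4, 0.41, 0.42)  # binds at frame 6
  evs <- list(detect_time_of_binding(tr1), detect_time_of_binding(tr2))
  al <- align_at_binding(list(tr1, tr2), evs)
  expect_equal(ncol(al$aligned), 3)   # min(4, 3) post-binding frames
  expect_equal(al$aligned[1, ], tr1[3:5])
  expect_equal(al$aligned[2, ], tr2[6:8])
  expect_equal(al$times, c(0, 1, 2))

  single <- align_at_binding(list(tr1), evs[1])
  expect_equal(single$mean, tr1[3:6])

  expect_warning(al2 <- align_at_binding(list(tr1, c(1, 1, 1)),
                                         list(evs[[1]], NULL)), "excluded")
  expect_equal(al2$n_excluded, 1)
  expect_error(align_at_binding(list(c(1, 1)), list(NULL)), "no replicate")
})

test_that("membrane association counts frames within the cutoff", {
  top <- toy_topology(2, chain = "A")
  mem_at <- data.frame(eleno = 3:4, elety = "PO4", resid = 1:2,
                       resname = "POP", chain = "M", mass = 72)
  top2 <- topology(rbind(top$atoms, mem_at))
  near <- rbind(c(0, 0, 0.3), c(0.35, 0, 0.3), c(0, 0, 0), c(0.35, 0, 0))
  far <- rbind(c(0, 0, 1.0), c(0.35, 0, 1.0), c(0, 0, 0), c(0.35, 0, 0))
  mem <- select(top2, "name PO4")

  tr <- toy_trajectory(replicate(4, near, simplify = FALSE), top2)
  expect_equal(membrane_association_trace(tr, 1:2, mem, chain = "A")$bound_fraction, 1)

  tr2 <- toy_trajectory(list(near, far, near, far), top2)
  r <- membrane_association_trace(tr2, 1:2, mem, chain = "A")
  expect_equal(r$bound_fraction, 0.5)
  expect_equal(as.numeric(r$trace), c(0.3, 1, 0.3, 1))

  # cutoff 0 counts exact touches only
  touch <- rbind(c(0, 0, 0), c(0.35, 0, 0.3), c(0, 0, 0), c(0.35, 0, 0))
  tr3 <- toy_trajectory(list(touch, near), top2)
  expect_equal(membrane_association_trace(tr3, 1:2, mem, cutoff = 0,
                                          chain = "A")$bound_fraction, 0.5)
})

test_that("domain profiles keep the planted ligand at its target domain", {
  ens <- generate_ensemble(synthetic_spec(n_replicates = 3, n_frames = 300,
                                          tau = 40, seed = 13))
  trajs <- ens$trajectories
  top <- trajs[[1]]$topology
  dm <- synthetic_domain_map(top)
  lig <- unlist(lapply(101:115, function(r)
    which(top$atoms$resid == r & top$atoms$chain == "B")))
  tail_sel <- select(top, "residues 1-37 of chain A")
  events <- lapply(seq_along(trajs), function(r)
    detect_time_of_binding(min_dist_frames(trajs[[r]], lig, tail_sel),
                           times = trajs[[r]]$times, replicate = r))
  rec <- domain_map(dm$groups[c("n_terminal", "ecl1", "ecl2", "ecl3", "lumen")],
                    chain = dm$chain)
  prof <- domain_distance_profile(trajs, lig, rec, events,
                                  windows = c(first = 50, last = 50),
                                  receptor_chain = "A")
  first <- prof$windows$first
  # ligand is restrained to the tail: n_terminal row at the bound distance,
  # every other domain clearly farther at all times
  expect_true(all(first["n_terminal", ] < 0.45))
  expect_true(all(first[c("ecl1", "ecl2", "ecl3", "lumen"), ] >
                    max(first["n_terminal", ])))
  # the domain on the far side of the core is never approached
  expect_true(all(prof$full["ecl1", ] > 0.5))
  expect_error(domain_distance_profile(trajs, lig, rec, events,
                                       windows = c(first = 5000),
                                       receptor_chain = "A"),
               "exceeds the common post-binding span")
})
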