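test_that("ensembles are bit-identical under the same seed", {
  sp <- synthetic_spec(n_replicates = 2, n_frames = 120, tau = 30, seed = 9)
  e1 <- generate_ensemble(sp)
  e2 <- generate_ensemble(sp)
  expect_identical(e1$trajectories[[1]]$coords, e2$trajectories[[1]]$coords)
  expect_identical(e1$trajectories[[2]]$coords, e2$trajectories[[2]]$coords)
  e3 <- generate_ensemble(synthetic_spec(n_replicates = 2, n_frames = 120,
                                         tau = 30, seed = 10))
  expect_false(identical(e1$trajectories[[1]]$coords,
                         e3$trajectories[[1]]$coords))
})

test_that("infeasible specs fail at generation time, not silently", {
  expect_error(synthetic_spec(tau = 6000, n_frames = 5000), "tau")
  expect_error(synthetic_spec(bound_mean = 0.48, bound_sd = 0.02),
               "cutoff margin")
  expect_error(synthetic_spec(contact_dist = 0.65), "margin below")
  expect_error(synthetic_spec(planted_contacts = data.frame(i = 1, j = 26, p = 1.2)),
               "in \\[0,1\\]")
  expect_error(synthetic_spec(modes = c("I+V" = 0.5)), "sum to 1")
  expect_error(synthetic_spec(modes = c("I+X" = 1)), "elements I..V")
  expect_error(synthetic_spec(occupancies = c(0.5, 0.4)), "occupancies")
  expect_error(synthetic_spec(shift = list(alpha = -1, beta = 0)),
               "non-negative")
})

test_that("planted binding frames and contacts are recovered", {
  sp <- synthetic_spec(n_replicates = 3, n_frames = 400,
                       tau = c(50, 120, 200), seed = 21)
  ens <- generate_ensemble(sp)
  top <- ens$trajectories[[1]]$topology
  tail_sel <- select(top, "residues 1-37 of chain A")
  lig_sel <- select(top, "chain B")
  for (r in 1:3) {
    tr <- min_dist_frames(ens$trajectories[[r]], lig_sel, tail_sel)
    ev <- detect_time_of_binding(tr, cutoff = 0.5)
    expect_equal(ev$frame, sp$tau[r])
    # ground truth records what was planted
    expect_equal(ens$ground_truth$replicates[[r]]$tau, sp$tau[r])
  }
  # planted contact frequencies recorded per replicate match a recount
  cm <- contact_probability_map(ens$trajectories[[1]], 1, 26, cutoff = 0.6,
                                chain_a = "A", chain_b = "A")
  expect_equal(cm[1, 1], ens$ground_truth$replicates[[1]]$contact_realized,
               tolerance = 1e-12)
})

test_that("state occupancies and membrane association track the planted chain", {
  sp <- synthetic_spec(n_replicates = 1, n_frames = 3000, tau = 100, seed = 33)
  ens <- generate_ensemble(sp)
  tr <- ens$trajectories[[1]]
  states <- ens$ground_truth$replicates[[1]]$states
  # stationary occupancy of the membrane-bound state is 0.6
  expect_equal(mean(states == 1), 0.6, tolerance = 0.12)
  mem <- select(tr$topology, "name PO4")
  ma <- membrane_association_trace(tr, sp$membrane_residues, mem, chain = "A")
  # distal residues touch the membrane exactly in membrane-bound frames
  expect_equal(ma$bound_fraction, mean(states == 1), tolerance = 0.02)
})

test_that("generated trajectories feed every module without special-casing", {
  sp <- synthetic_spec(n_replicates = 2, n_frames = 150, tau = 30, seed = 27)
  ens <- generate_ensemble(sp)
  top <- ens$trajectories[[1]]$topology
  bb <- select_particles(top, resid = 1:37, part = "backbone", chain = "A")
  ref <- frame_coords(ens$trajectories[[1]], 1)
  expect_s3_class(ens$trajectories[[1]], "trajectory")
  expect_no_error({
    rmsd_trace(subset_frames(ens$trajectories[[1]], 1:10), ref, bb)
    rg_trace(ens$trajectories[[1]], bb)
    landscape(ens$trajectories, ref, bb, pair = c(1, 26), chain = "A")
    enumerate_modes(ens$trajectories, synthetic_element_selections(top),
                    select(top, "residues 1-37 of chain A"), cutoff = 0.5)
  })
  f <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(ens$ground_truth, f)
  expect_true(jsonlite::validate(paste(readLines(f), collapse = "")))
})

test_that("shift generators plant contact- and conformation-driven CSPs", {
  set.seed(97)
  contact <- runif(37)
  conf <- runif(37)
  # contact-only, zero noise: CSP is an exact monotone image of contacts
  sp <- synthetic_spec(seed = 15, shift = list(alpha = 0.2, beta = 0,
                                               noise_h = 0, noise_n = 0,
                                               n_replicates = 2))
  tb <- generate_shift_tables(sp, contact, conf)
  prof <- csp_profile(tb$apo, tb$bound)
  cc <- contact_csp_concordance(stats::setNames(contact, 1:37), prof)
  expect_equal(cc$rank_correlation, 1)
  expect_error(generate_shift_tables(sp, contact[1:5], conf), "length")

  # noise-only: the mean+1sd rule flags about the Gaussian upper tail
  sp0 <- synthetic_spec(seed = 15, shift = list(alpha = 0, beta = 0,
                                                noise_h = 0.01, noise_n = 0.05,
                                                n_replicates = 1))
  fracs <- vapply(1:30, function(k) {
    spk <- synthetic_spec(seed = 100 + k,
                          shift = list(alpha = 0, beta = 0, noise_h = 0.01,
                                       noise_n = 0.05, n_replicates = 1))
    tbk <- generate_shift_tables(spk, contact, conf)
    pk <- csp_profile(tbk$apo, tbk$bound)
    hk <- threshold_residues(pk)
    length(hk) / sum(!is.na(pk$csp))
  }, numeric(1))
  # folded-normal upper tail above mean+sd is ~0.12-0.20 for these sizes
  expect_gt(mean(fracs), 0.05)
  expect_lt(mean(fracs), 0.30)
})
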