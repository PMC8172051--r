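default_run_config <- function() {
  list(
    output_dir = "idrbind_run",
    seed = 1,
    synthetic = list(n_replicates = 3, n_frames = 1200, tau = 100),
    write_trajectories = FALSE,
    contacts = list(cutoff = 0.6, histogram_bin = 0.1),
    binding = list(cutoff = 0.5, criterion = "strict",
                   max_unbound_frames = 0, windows = list(first = 100, last = 100)),
    landscape = list(bin = 0.1, cluster_cutoff = 0.1, cluster_max_frames = 120,
                     pair = c(1, 26)),
    modes = list(cutoff = 0.5, top_k = 5),
    csp = list(rule = "mean_sd", k = 1, top_k = 10)
  )
}

merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    if (!key %in% names(base))
      stop("unknown config key: ", path, key)
    if (is.list(base[[key]]) && is.list(user[[key]]) &&
        !is.null(names(base[[key]]))) {
      base[[key]] <- merge_config(base[[key]], user[[key]],
                                  paste0(path, key, "."))
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates simulate -> contacts -> binding -> landscape -> modes ->
#' csp on a synthetic ensemble, writing each stage's TSV outputs before
#' the next stage starts and a machine-readable run manifest (all
#' parameters, including defaults, plus seeds and stage status) at the
#' end. Reruns with the same config produce identical numeric outputs.
#'
#' @param config a config list or path to a YAML file; unknown keys are
#'   rejected. See `default_run_config` in the package sources for the
#'   full schema.
#' @return invisible list of in-memory stage results
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_config(config)
  cfg <- merge_config(default_run_config(), config)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "idrbind",
                   version = as.character(utils::packageVersion("idrbind")),
                   config = cfg, stages = list())
  res <- list()

  # -- simulate ------------------------------------------------------------
  run_stage("simulate", {
    spec <- do.call(synthetic_spec, c(cfg$synthetic, list(seed = cfg$seed)))
    ens <- generate_ensemble(spec)
    write_ground_truth(ens$ground_truth, file.path(out, "ground_truth.json"))
    if (isTRUE(cfg$write_trajectories))
      for (r in seq_along(ens$trajectories))
        write_trajectory(ens$trajectories[[r]],
                         file.path(out, sprintf("replicate_%02d.pdb", r)))
    res$spec <- spec
    res$ens <- ens
  })
  trajs <- res$ens$trajectories
  top <- trajs[[1]]$topology
  nt <- res$spec$tail_length
  dm <- synthetic_domain_map(top, nt)
  tail_res <- dm$groups$n_terminal
  lig_sel <- unlist(residue_particles(top, 101:115, "B"), use.names = FALSE)
  manifest$stages$simulate <- list(status = "ok",
                                   n_replicates = length(trajs),
                                   n_frames = n_frames(trajs[[1]]))

  # -- binding (events are needed to window the contact stage) -------------
  run_stage("binding", {
    tail_sel <- unlist(residue_particles(top, tail_res, "A"), use.names = FALSE)
    traces <- lapply(trajs, function(tr)
      min_dist_frames(tr, lig_sel, tail_sel, periodic = TRUE))
    events <- lapply(seq_along(traces), function(r)
      detect_time_of_binding(traces[[r]], cutoff = cfg$binding$cutoff,
                             criterion = cfg$binding$criterion,
                             max_unbound_frames = cfg$binding$max_unbound_frames,
                             times = trajs[[r]]$times, replicate = r))
    ev_df <- do.call(rbind, lapply(events, function(e)
      if (is.null(e)) NULL else
        data.frame(replicate = e$replicate, frame = e$frame, time_ns = e$time)))
    write_table(ev_df, file.path(out, "binding_events.tsv"))
    win <- unlist(cfg$binding$windows)
    prof <- domain_distance_profile(
      trajs, lig_sel, domain_map(dm$groups[c("n_terminal", "ecl1", "ecl2",
                                             "ecl3", "lumen")],
                                 chain = dm$chain),
      events, windows = win, receptor_chain = "A")
    for (w in names(prof$windows))
      write_matrix(prof$windows[[w]],
                   file.path(out, paste0("domain_profile_", w, ".tsv")))
    res$events <- events
    res$traces <- traces
    res$domain_profile <- prof
  })
  manifest$stages$binding <- list(
    status = "ok",
    n_bound = sum(!vapply(res$events, is.null, TRUE)),
    binding_frames = vapply(res$events, function(e)
      if (is.null(e)) NA_integer_ else e$frame, 1L))

  # -- contacts ------------------------------------------------------------
  run_stage("contacts", {
    pre_win <- seq_len(max(2, min(vapply(res$events, function(e)
      if (is.null(e)) n_frames(trajs[[1]]) else e$frame, 1L)) - 1L))
    apo_map <- contact_probability_map(trajs, tail_res, tail_res,
                                       cutoff = cfg$contacts$cutoff,
                                       chain_a = "A", chain_b = "A",
                                       window = pre_win)
    bound_maps <- lapply(seq_along(trajs), function(r) {
      e <- res$events[[r]]
      if (is.null(e)) return(NULL)
      contact_probability_map(trajs[[r]], tail_res, tail_res,
                              cutoff = cfg$contacts$cutoff,
                              chain_a = "A", chain_b = "A",
                              window = e$frame:n_frames(trajs[[r]]))
    })
    bound_maps <- Filter(Negate(is.null), bound_maps)
    bound_map <- Reduce(`+`, lapply(bound_maps, unclass)) / length(bound_maps)
    comp <- composite_map(
      structure(unclass(apo_map), dimnames = dimnames(apo_map)),
      structure(bound_map, dimnames = dimnames(apo_map)))
    write_matrix(comp, file.path(out, "contact_map_composite.tsv"))
    profile <- per_residue_partner_profile(trajs, tail_res, 101:115,
                                           cutoff = cfg$contacts$cutoff,
                                           chain_a = "A", chain_b = "B")
    write_table(data.frame(resid = tail_res, contact_probability = profile),
                file.path(out, "tail_ligand_contact_profile.tsv"))
    pr <- cfg$landscape$pair
    hist <- pair_distance_histogram(trajs, pr[1], pr[2],
                                    bin = cfg$contacts$histogram_bin,
                                    chain = "A")
    write_table(hist, file.path(out, "pair_distance_histogram.tsv"))
    res$contact_profile <- profile
    res$composite_map <- comp
  })
  manifest$stages$contacts <- list(status = "ok",
                                   cutoff = cfg$contacts$cutoff)

  # -- landscape -----------------------------------------------------------
  run_stage("landscape", {
    nsub <- min(cfg$landscape$cluster_max_frames, n_frames(trajs[[1]]))
    sub <- subset_frames(trajs[[1]],
                         unique(round(seq(1, n_frames(trajs[[1]]),
                                          length.out = nsub))))
    bb <- select_particles(top, resid = tail_res, part = "backbone",
                           chain = "A")
    cl <- gromos_cluster(sub, cfg$landscape$cluster_cutoff, bb)
    write_table(data.frame(frame = seq_len(n_frames(sub)),
                           cluster = cl$labels),
                file.path(out, "cluster_assignment.tsv"))
    ref <- reference_from_top_cluster(cl, sub, bb)
    ld <- landscape(trajs, ref, bb, pair = cfg$landscape$pair,
                    bin = cfg$landscape$bin, chain = "A")
    grid <- expand.grid(rmsd_bin = attr(ld, "rmsd_centers"),
                        dist_bin = attr(ld, "dist_centers"))
    grid$density <- as.numeric(unclass(ld))
    write_table(grid[grid$density > 0, ], file.path(out, "landscape_grid.tsv"))
    mx <- local_maxima(ld)
    write_table(mx, file.path(out, "landscape_maxima.tsv"))
    res$clusters <- cl
    res$landscape <- ld
    res$maxima <- mx
  })
  manifest$stages$landscape <- list(status = "ok",
                                    n_clusters = length(res$clusters$clusters),
                                    n_maxima = nrow(res$maxima))

  # -- modes ---------------------------------------------------------------
  run_stage("modes", {
    els <- synthetic_element_selections(top)
    tail_sel <- unlist(residue_particles(top, tail_res, "A"), use.names = FALSE)
    mt <- enumerate_modes(trajs, els, tail_sel, cutoff = cfg$modes$cutoff,
                          events = res$events, top_k = cfg$modes$top_k)
    write_table(as.data.frame(mt), file.path(out, "binding_modes.tsv"))
    rk <- residue_interaction_ranking(trajs, 101:115, tail_res,
                                      cutoff = cfg$contacts$cutoff,
                                      k = cfg$csp$top_k,
                                      ligand_chain = "B", receptor_chain = "A")
    write_table(rk, file.path(out, "ligand_residue_ranking.tsv"))
    res$mode_table <- mt
  })
  manifest$stages$modes <- list(status = "ok",
                                top_mode = res$mode_table$fingerprint[1],
                                top_population = res$mode_table$population[1])

  # -- csp -----------------------------------------------------------------
  run_stage("csp", {
    # conformational-change score: per-residue backbone fluctuation
    rmsf <- vapply(tail_res, function(rr) {
      b <- select_particles(top, resid = rr, part = "backbone", chain = "A")
      x <- trajs[[1]]$coords[, b[1], , drop = FALSE]
      dim(x) <- dim(x)[c(1, 3)]
      sqrt(mean(rowSums(sweep(x, 2, colMeans(x))^2)))
    }, numeric(1))
    conf <- rmsf / max(rmsf)
    tabs <- generate_shift_tables(res$spec, res$contact_profile, conf)
    csptab <- csp_profile(tabs$apo, tabs$bound)
    write_table(as.data.frame(csptab), file.path(out, "csp_table.tsv"))
    hot <- threshold_residues(csptab, rule = cfg$csp$rule, k = cfg$csp$k)
    conc <- contact_csp_concordance(
      stats::setNames(res$contact_profile, tail_res), csptab,
      k = cfg$csp$top_k)
    write_table(conc$discordant, file.path(out, "contact_csp_concordance.tsv"))
    res$csp <- csptab
    res$concordance <- conc
    res$hotspots <- hot
  })
  manifest$stages$csp <- list(status = "ok",
                              hotspot_cutoff = attr(res$hotspots, "cutoff"),
                              hotspots = as.integer(res$hotspots),
                              rank_correlation = res$concordance$rank_correlation)

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
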