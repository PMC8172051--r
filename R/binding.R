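#' Detect the time of stable binding
#'
#' The time of binding (t = 0) is the earliest frame of a ligand-receptor
#' contact stretch (distance within `cutoff`) that persists to the end of
#' the trace. Under the strict criterion no later frame may exceed the
#' cutoff. The tolerant criterion allows excursions above a separate
#' `dissociation_cutoff` lasting at most `max_unbound_frames` consecutive
#' frames; with `max_unbound_frames = 0` and `dissociation_cutoff = cutoff`
#' it reduces exactly to strict.
#'
#' Absence of binding is a valid result (NULL), not an error.
#'
#' @param trace numeric minimum-distance trace (nm); a `distance_trace`
#'   carries its own times, otherwise supply `times`
#' @param cutoff binding-regime distance cutoff (nm), default 0.5
#' @param criterion "strict" or "tolerant"
#' @param max_unbound_frames tolerant mode: longest permitted consecutive
#'   excursion (frames)
#' @param dissociation_cutoff tolerant mode: distance above which a frame
#'   counts as an excursion (defaults to `cutoff`)
#' @param times frame times (ns); default from the trace or 0,1,2,...
#' @param replicate replicate id recorded on the event
#' @return object of class `binding_event` (fields `frame` 1-based,
#'   `time` ns, `cutoff`, `criterion`, `replicate`), or NULL
#' @export
detect_time_of_binding <- function(trace, cutoff = 0.5,
                                   criterion = c("strict", "tolerant"),
                                   max_unbound_frames = 0,
                                   dissociation_cutoff = cutoff,
                                   times = NULL, replicate = NA) {
  criterion <- match.arg(criterion)
  v <- as.numeric(trace)
  if (length(v) == 0) stop("empty trace")
  if (is.null(times)) times <- attr(trace, "times")
  if (is.null(times)) times <- seq_along(v) - 1
  inb <- v <= cutoff
  if (criterion == "strict") {
    # earliest i with all frames from i on within the cutoff
    out_last <- if (any(!inb)) max(which(!inb)) else 0L
    frame <- out_last + 1L
    if (frame > length(v)) return(NULL)
  } else {
    stopifnot(max_unbound_frames >= 0)
    exc <- v > dissociation_cutoff
    r <- rle(exc)
    ends <- cumsum(r$lengths)
    long <- which(r$values & r$lengths > max_unbound_frames)
    # no real dissociation may occur at/after the binding frame
    earliest_ok <- if (length(long) > 0) ends[max(long)] + 1L else 1L
    cand <- which(inb & seq_along(v) >= earliest_ok)
    if (length(cand) == 0) return(NULL)
    frame <- cand[1]
  }
  structure(list(frame = frame, time = times[frame], cutoff = cutoff,
                 criterion = criterion, replicate = replicate,
                 max_unbound_frames = if (criterion == "tolerant") max_unbound_frames else NULL,
                 dissociation_cutoff = if (criterion == "tolerant") dissociation_cutoff else NULL),
            class = "binding_event")
}

#' @export
print.binding_event <- function(x, ...) {
  cat(sprintf("binding event: frame %d (t = %.4g ns), cutoff %.3g nm, %s\n",
              x$frame, x$time, x$cutoff, x$criterion))
  invisible(x)
}

#' Bound/unbound run segmentation
#'
#' Maximal alternating bound/unbound runs covering every frame;
#' concatenating the segments reconstructs the contact indicator.
#'
#' @param trace numeric distance trace (nm)
#' @param cutoff distance cutoff (nm)
#' @return data.frame with `state` ("bound"/"unbound"), `start`, `end`
#'   (1-based inclusive frame indices)
#' @export
binding_unbinding_segments <- function(trace, cutoff = 0.5) {
  v <- as.numeric(trace)
  if (length(v) == 0) stop("empty trace")
  r <- rle(v <= cutoff)
  end <- cumsum(r$lengths)
  data.frame(state = ifelse(r$values, "bound", "unbound"),
             start = c(1L, utils::head(end, -1) + 1L), end = end,
             stringsAsFactors = FALSE)
}

#' Align replicate traces at their binding frames
#'
#' Re-indexes each trace so its binding frame becomes t = 0 and truncates
#' the ensemble to the shortest post-binding length before averaging
#' (pure re-indexing: per-frame values are unchanged). Replicates without
#' a binding event are excluded and counted.
#'
#' @param traces list of numeric traces (one per replicate)
#' @param events list of `binding_event`s (NULL entries allowed)
#' @param dt frame spacing (ns) for the aligned time axis
#' @return list with `aligned` (replicates x common-length matrix, row
#'   names = included replicate indices), `times` (ns since binding),
#'   `mean` trace, `n_excluded`
#' @export
align_at_binding <- function(traces, events, dt = 1) {
  stopifnot(length(traces) == length(events))
  has <- !vapply(events, is.null, TRUE)
  if (!any(has)) stop("no replicate has a binding event")
  n_excluded <- sum(!has)
  if (n_excluded > 0)
    warning(n_excluded, " replicate(s) without a binding event excluded")
  idx <- which(has)
  spans <- vapply(idx, function(i) length(traces[[i]]) - events[[i]]$frame + 1L, 1L)
  common <- min(spans)
  aligned <- t(vapply(idx, function(i) {
    f <- events[[i]]$frame
    as.numeric(traces[[i]])[f:(f + common - 1L)]
  }, numeric(common)))
  rownames(aligned) <- idx
  list(aligned = aligned, times = dt * (seq_len(common) - 1),
       mean = colMeans(aligned), n_excluded = n_excluded)
}

#' Domain-wise ligand-approach profile, aligned at binding
#'
#' For every receptor domain, the replicate-averaged minimum distance
#' between the ligand and the domain as a function of time since binding.
#' Each replicate is aligned at its own binding event; the ensemble is
#' truncated to the shortest common post-binding span; then the requested
#' windows (first/last `w` ns) are cut out.
#'
#' @param trajs list of replicate trajectories
#' @param ligand_sel particle selection of the ligand (per shared topology)
#' @param domains a `domain_map` of receptor domains (residue groups)
#' @param events list of `binding_event`s, one per replicate (NULL allowed)
#' @param windows named numeric vector of window lengths in ns, e.g.
#'   `c(first = 100, last = 100)`
#' @param receptor_chain chain holding the receptor residues
#' @param periodic minimum-image convention for the ligand-domain distance
#' @return object of class `domain_profile`: list of one matrix
#'   (domain x aligned time, nm) per window plus the full aligned matrix
#' @export
domain_distance_profile <- function(trajs, ligand_sel, domains, events,
                                    windows = c(first = 100, last = 100),
                                    receptor_chain = NULL, periodic = TRUE) {
  stopifnot(inherits(domains, "domain_map"))
  dn <- names(domains$groups)
  per_domain <- lapply(dn, function(g) {
    ch <- receptor_chain
    if (!is.null(domains$chain) && g %in% names(domains$chain))
      ch <- domains$chain[[g]]
    traces <- lapply(trajs, function(traj) {
      dsel <- unlist(residue_particles(traj$topology, domains$groups[[g]], ch),
                     use.names = FALSE)
      min_dist_frames(traj, ligand_sel, dsel, periodic = periodic)
    })
    suppressWarnings(align_at_binding(traces, events,
                                      dt = trajs[[1]]$times[2] - trajs[[1]]$times[1]))
  })
  names(per_domain) <- dn
  times <- per_domain[[1]]$times
  full <- t(vapply(per_domain, function(a) a$mean, numeric(length(times))))
  colnames(full) <- times
  span <- max(times)
  out <- list()
  for (w in names(windows)) {
    if (windows[[w]] > span + (times[2] - times[1]))
      stop("window '", w, "' (", windows[[w]],
           " ns) exceeds the common post-binding span of ", span, " ns")
    keep <- if (w == "last") times > span - windows[[w]] else times < windows[[w]]
    out[[w]] <- full[, keep, drop = FALSE]
  }
  structure(list(windows = out, full = full, times = times,
                 n_excluded = per_domain[[1]]$n_excluded),
            class = "domain_profile")
}

#' Membrane association of a residue range
#'
#' Per-frame minimum distance between a residue range (e.g. the distal
#' tail, residues 1-10) and a membrane selection (e.g. lipid headgroup
#' beads), plus the fraction of frames within the association cutoff
#' (~0.4 nm indicates membrane binding).
#'
#' @param traj a `trajectory`
#' @param residue_range residue indices of the tail segment
#' @param membrane_sel particle selection of the membrane
#' @param cutoff association cutoff (nm), default 0.4
#' @param chain chain of the residue range
#' @param periodic minimum-image convention
#' @return list with `trace` (a `distance_trace`) and `bound_fraction`
#' @export
membrane_association_trace <- function(traj, residue_range, membrane_sel,
                                       cutoff = 0.4, chain = NULL,
                                       periodic = TRUE) {
  if (length(membrane_sel) == 0) stop("empty membrane selection")
  sel <- unlist(residue_particles(traj$topology, residue_range, chain),
                use.names = FALSE)
  v <- min_dist_frames(traj, sel, membrane_sel, periodic = periodic)
  trace <- structure(v, class = "distance_trace", times = traj$times,
                     metric = "min_pairwise",
                     provenance = "residue range vs membrane")
  list(trace = trace, bound_fraction = mean(v <= cutoff))
}
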