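#' Ligand-element contact fingerprint of one frame
#'
#' For each ligand structural element (I: N-domain, II-IV: beta strands,
#' V: alpha helix) TRUE iff the element's minimum distance to the receptor
#' group is within the cutoff. An all-FALSE fingerprint marks an unbound
#' frame (attribute `bound = FALSE`).
#'
#' @param frame n_particles x 3 coordinate matrix (nm)
#' @param element_sels named list of particle-index vectors, one per
#'   disjoint element
#' @param receptor_sel particle indices of the receptor group
#' @param cutoff contact cutoff (nm)
#' @param box orthorhombic box (nm) or NULL
#' @return named logical vector over elements with a `bound` attribute
#' @export
frame_fingerprint <- function(frame, element_sels, receptor_sel, cutoff,
                              box = NULL) {
  if (length(receptor_sel) == 0) stop("empty receptor group")
  if (anyDuplicated(unlist(element_sels)))
    stop("ligand elements must be disjoint")
  fp <- vapply(element_sels, function(sel)
    min_distance(frame, sel, receptor_sel, box) <= cutoff, TRUE)
  attr(fp, "bound") <- any(fp)
  fp
}

fingerprint_string <- function(fp) paste(names(fp)[fp], collapse = "+")

# Per-frame element indicators for a whole trajectory (frames x elements).
element_indicators <- function(traj, element_sels, receptor_sel, cutoff,
                               periodic = TRUE) {
  m <- vapply(element_sels, function(sel)
    min_dist_frames(traj, sel, receptor_sel, periodic = periodic) <= cutoff,
    logical(n_frames(traj)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  m
}

#' Enumerate binding modes by element fingerprint
#'
#' A binding mode is a distinct element fingerprint. Frames before each
#' replicate's binding event are excluded; populations are the fraction of
#' bound frames carrying the fingerprint, computed within replicate and
#' then averaged over replicates. Modes are ranked by decreasing
#' population (top mode = rank 1).
#'
#' @param trajs a `trajectory` or list of replicates
#' @param element_sels named list of particle-index vectors (disjoint
#'   ligand elements, e.g. I..V)
#' @param receptor_sel particle indices of the receptor group (shared
#'   topology)
#' @param cutoff contact cutoff (nm)
#' @param events optional list of `binding_event`s per replicate; frames
#'   before the event are excluded, replicates without events skipped
#' @param periodic minimum-image convention
#' @param top_k number of modes reported (default 5); NULL = all
#' @return data.frame of class `binding_mode_table`: one row per mode
#'   with element flags, `fingerprint`, `population`, `rank`
#' @export
enumerate_modes <- function(trajs, element_sels, receptor_sel, cutoff = 0.5,
                            events = NULL, periodic = TRUE, top_k = 5) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  per_rep <- list()
  for (r in seq_along(trajs)) {
    traj <- trajs[[r]]
    if (!is.null(events)) {
      if (is.null(events[[r]])) next
      traj <- subset_frames(traj, events[[r]]$frame:n_frames(traj))
    }
    ind <- element_indicators(traj, element_sels, receptor_sel, cutoff,
                              periodic)
    bound <- rowSums(ind) > 0
    if (!any(bound)) next
    keys <- apply(ind[bound, , drop = FALSE] + 0L, 1, paste, collapse = "")
    per_rep[[length(per_rep) + 1]] <- table(keys) / sum(bound)
  }
  if (length(per_rep) == 0) stop("no bound frames")
  all_keys <- sort(unique(unlist(lapply(per_rep, names))))
  pm <- vapply(per_rep, function(tb) {
    v <- stats::setNames(numeric(length(all_keys)), all_keys)
    v[names(tb)] <- as.numeric(tb)
    v
  }, numeric(length(all_keys)))
  pop <- rowMeans(matrix(pm, nrow = length(all_keys),
                         dimnames = list(all_keys, NULL)))
  flags <- t(vapply(all_keys, function(k)
    as.integer(strsplit(k, "")[[1]]) == 1L, logical(length(element_sels))))
  colnames(flags) <- names(element_sels)
  fp_str <- apply(flags, 1, function(f)
    paste(names(element_sels)[f], collapse = "+"))
  o <- order(-pop, all_keys)
  out <- data.frame(fingerprint = fp_str[o], flags[o, , drop = FALSE],
                    population = pop[o], rank = seq_along(o),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(top_k)) out <- out[seq_len(min(top_k, nrow(out))), , drop = FALSE]
  attr(out, "cutoff") <- cutoff
  attr(out, "n_replicates") <- length(per_rep)
  class(out) <- c("binding_mode_table", "data.frame")
  out
}

#' Rank ligand residues by receptor-contact probability
#'
#' Ligand residues sorted by their per-residue partner-contact
#' probability with the receptor group (union over receptor residues),
#' ties broken by residue index.
#'
#' @param trajs a `trajectory` or list of replicates
#' @param ligand_residues residue indices of the ligand
#' @param receptor_residues residue indices of the receptor group
#' @param cutoff contact cutoff (nm)
#' @param k number of top residues returned (k > residue count gives the
#'   full ranking)
#' @param ligand_chain,receptor_chain chain restrictions
#' @param periodic minimum-image convention
#' @return data.frame with `resid`, `probability`, `rank`
#' @export
residue_interaction_ranking <- function(trajs, ligand_residues,
                                        receptor_residues, cutoff = 0.6,
                                        k = 10, ligand_chain = NULL,
                                        receptor_chain = NULL,
                                        periodic = TRUE) {
  p <- per_residue_partner_profile(trajs, ligand_residues, receptor_residues,
                                   cutoff = cutoff, chain_a = ligand_chain,
                                   chain_b = receptor_chain,
                                   periodic = periodic)
  o <- order(-p, ligand_residues)
  out <- data.frame(resid = ligand_residues[o], probability = as.numeric(p[o]),
                    rank = seq_along(o))
  out[seq_len(min(k, nrow(out))), , drop = FALSE]
}
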