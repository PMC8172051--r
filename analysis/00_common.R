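# Shared study conditions for the analysis scripts. Every script
# regenerates the replicate ensemble deterministically from this spec, so
# the scripts can be run independently and in any order.

library(idrbind)

STUDY_SEED <- 20
results_dir <- function() {
  d <- file.path("results")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

# Study ensemble: 6 replicates x 2000 frames (1 ns spacing), binding
# planted at frame 150, intra-tail contact (1,26) at 0.7, two-state tail
# (membrane-bound 0.6 / receptor-contacted 0.4), mode frequencies
# 0.4/0.3/0.2/0.1 for I+V, I+II+V, I+IV+V, I.
study_spec <- function() {
  synthetic_spec(n_replicates = 6, n_frames = 2000, tau = 150,
                 seed = STUDY_SEED)
}

study_ensemble <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_ensemble(study_spec())
    cache
  }
})

study_selections <- function(top) {
  list(tail_res = 1:37,
       tail = select(top, "residues 1-37 of chain A"),
       tail_bb = select_particles(top, resid = 1:37, part = "backbone",
                                  chain = "A"),
       lig = select(top, "chain B"),
       lig_res = 101:115,
       mem = select(top, "name PO4"),
       domains = synthetic_domain_map(top),
       elements = synthetic_element_selections(top))
}

study_events <- function(ens, sel) {
  lapply(seq_along(ens$trajectories), function(r)
    detect_time_of_binding(
      distance_trace(ens$trajectories[[r]], sel$lig, sel$tail),
      cutoff = 0.5, replicate = r))
}
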