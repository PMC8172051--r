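#!/usr/bin/env Rscript
# Generate the synthetic replicate ensemble that stands in for the
# undeposited coarse-grain trajectories, and record its ground truth:
# per-replicate binding frames, state sequences, planted contact and
# mode frequencies, and the two conformational-state centroids.

source(file.path("analysis", "00_common.R"))
out <- results_dir()

ens <- study_ensemble()
gt <- ens$ground_truth

write_ground_truth(gt, file.path(out, "ground_truth.json"))
write_trajectory(subset_frames(ens$trajectories[[1]],
                               seq(1, 2000, by = 20)),
                 file.path(out, "replicate_01_every20.pdb"))

cat(sprintf("generated %d replicates x %d frames (seed %d)\n",
            length(ens$trajectories), n_frames(ens$trajectories[[1]]),
            STUDY_SEED))
cat(sprintf("planted binding frame: %d; planted contact (1,26) p=0.7, realized %.3f (mean)\n",
            gt$replicates[[1]]$tau,
            mean(vapply(gt$replicates, function(x) x$contact_realized, 1))))
cat(sprintf("state centroids (RMSD nm, Met1-Asp26 nm): membrane (%.2f, %.2f), receptor (%.2f, %.2f)\n",
            gt$state_centroids$membrane["rmsd"], gt$state_centroids$membrane["dist"],
            gt$state_centroids$receptor["rmsd"], gt$state_centroids$receptor["dist"]))
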