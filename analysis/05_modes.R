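#!/usr/bin/env Rscript
# Fingerprint ligand binding poses by which structural elements (I:
# N-domain, II-IV: beta strands, V: alpha helix) contact the tail, rank
# modes by population, and rank ligand residues by contact probability.

source(file.path("analysis", "00_common.R"))
out <- results_dir()

ens <- study_ensemble()
trajs <- ens$trajectories
sel <- study_selections(trajs[[1]]$topology)
events <- study_events(ens, sel)

mt <- enumerate_modes(trajs, sel$elements, sel$tail, cutoff = 0.5,
                      events = events, top_k = 5)
write_table(as.data.frame(mt), file.path(out, "binding_modes.tsv"))
cat("binding modes (planted frequencies 0.40 I+V, 0.30 I+II+V, 0.20 I+IV+V, 0.10 I):\n")
print(mt[, c("rank", "fingerprint", "population")])

rk <- residue_interaction_ranking(trajs, sel$lig_res, sel$tail_res,
                                  cutoff = 0.6, k = 10,
                                  ligand_chain = "B", receptor_chain = "A")
write_table(rk, file.path(out, "ligand_residue_ranking.tsv"))
cat("top ligand residues by tail-contact probability:\n")
print(head(rk, 5))
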