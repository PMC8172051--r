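# idrbind

Trajectory analysis of ligand binding at an intrinsically disordered
receptor tail.

Chemokine receptors such as CXCR1 recognize their ligands in two steps,
and the first step happens at an intrinsically disordered N-terminal
region that crystallography and NMR cannot resolve. Microsecond
coarse-grain MD ensembles can sample this process, but turning forty
replicate trajectories into statements about binding, conformational
restriction and NMR observables requires a specific analysis stack.
`idrbind` implements that stack for R, for structural-bioinformatics
users who have replicate trajectories (or want statistically faithful
synthetic ones) of a membrane-anchored receptor with a flexible tail and
a diffusing protein ligand.

## What it computes

* **Contact probability maps.** A residue pair is in contact when its
  minimum inter-particle distance d ≤ c (default c = 0.6 nm,
  minimum-image aware). P(contact) is the per-replicate frame fraction,
  averaged over replicates; intra/inter maps, composite apo/bound
  matrices, per-residue partner profiles (union over partners) and
  side-chain COM distance histograms.
* **Binding kinetics.** Time of binding t = 0 is the earliest frame of a
  contact stretch (c = 0.5 nm) that remains undissociated to the end of
  the trajectory, with strict and bounded-excursion (tolerant)
  criteria; bound/unbound segmentation, alignment of replicates at
  t = 0, domain-wise ligand approach profiles, membrane association.
* **Conformational landscapes.** GROMOS (Daura) clustering on pairwise
  backbone RMSD with deterministic lowest-index tie-breaks, top-cluster
  average reference, and 2D population densities over (backbone RMSD,
  Met1–Asp26 side-chain distance) on 0.1 nm bins, with strict local
  maxima as cluster readout.
* **Binding modes.** Boolean fingerprints over ligand structural
  elements (I: N-domain, II–IV: β-strands, V: α-helix), mode populations
  over bound frames, ligand-residue contact ranking.
* **Chemical shift perturbation.** Δδ = sqrt((Δδ_H² + (Δδ_N/5)²)/2)
  from apo/bound amide shift tables (replicate-averaged within state,
  then differenced), proline-aware, with hotspot thresholds and
  contact–CSP concordance statistics (Spearman ρ, top-k Jaccard,
  discordance flags).
* **Synthetic ensembles.** A generator that plants binding frames,
  intra-tail contacts, two-state tail dynamics, mode frequencies,
  membrane association and shift perturbations — with full ground truth
  recorded — so every stage above has a parameter-recovery test.

## Worked example

```r
library(idrbind)

spec <- synthetic_spec(n_replicates = 3, n_frames = 800, tau = 120, seed = 42)
ens  <- generate_ensemble(spec)
top  <- ens$trajectories[[1]]$topology

tail_sel <- select(top, "residues 1-37 of chain A")
ligand   <- select(top, "chain B")

events <- lapply(seq_along(ens$trajectories), function(r)
  detect_time_of_binding(
    distance_trace(ens$trajectories[[r]], ligand, tail_sel),
    cutoff = 0.5, replicate = r))
sapply(events, function(e) e$frame)
#> [1] 120 120 120

cm <- contact_probability_map(ens$trajectories, 1, 26, cutoff = 0.6,
                              chain_a = "A", chain_b = "A")
round(cm[1, 1], 3)
#> [1] 0.703

mt <- enumerate_modes(ens$trajectories, synthetic_element_selections(top),
                      tail_sel, cutoff = 0.5, events = events)
mt[, c("rank", "fingerprint", "population")]
#>   rank fingerprint population
#> 1    1         I+V 0.38864415
#> 2    2      I+II+V 0.30983847
#> 3    3      I+IV+V 0.20704846
#> 4    4           I 0.09446892
```

The three replicates bind at exactly the planted frame 120; the
Met1–Asp26 contact planted at probability 0.7 is estimated at 0.703; and
the four planted binding modes come back in order with populations
within ~0.01 of their planted frequencies (0.4, 0.3, 0.2, 0.1). The
`I+V` top mode is the pattern in which the ligand's N-domain and α-helix
carry the interface.

## The analysis workflow

`analysis/` contains the numbered study scripts, each a thin driver over
the package that prints what it found and writes tables under
`results/`:

```
Rscript analysis/01_simulate.R    # ensemble + ground truth
Rscript analysis/02_contacts.R    # composite contact map, profiles, histogram
Rscript analysis/03_binding.R     # events, domain profiles, membrane association
Rscript analysis/04_landscape.R   # clustering, reference, 2D landscape, maxima
Rscript analysis/05_modes.R       # mode table, ligand residue ranking
Rscript analysis/06_csp.R         # CSP table, hotspots, concordance
```

Scripts are independent (each regenerates the ensemble from the recorded
seed) and deterministic. `run_pipeline()` runs the same stages from one
YAML config with a machine-readable manifest.

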