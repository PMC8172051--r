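# Synthetic replicate ensembles with planted, machine-readable ground
# truth. The generator is deliberately minimal physics: a static receptor
# core (ring of beads) carrying a flexible two-bead-per-residue tail that
# hops between two conformational templates (membrane-bound vs
# receptor-contacted) by a two-state Markov chain, a planar slab of lipid
# headgroup beads, and a rigid five-element ligand that diffuses until a
# planted binding frame and stays bound with controlled distance noise.
# Every planted quantity is recorded so each analysis stage has a
# parameter-recovery test.

# Human CXCR1 N-terminal sequence, residues 1-37 (UniProt P25024):
# gives Met1/Asp26 as the landscape pair and prolines at 7, 21, 22, 29.
TAIL_SEQ_DEFAULT <- "MSNITDPQMWDFDDLNFTGMPPADEDYSPCMLETETL"

#' Specification of a synthetic ensemble
#'
#' Defaults are the study conditions used throughout the package's tests:
#' 10 replicates of 5000 frames at 1 ns spacing, a 37-residue tail,
#' binding planted at frame 100 with bound-state distance 0.35 +/- 0.02 nm,
#' an intra-tail contact (1,26) at probability 0.7, two tail states with
#' occupancies 0.6 (membrane-bound) / 0.4 (receptor-contacted), and mode
#' fingerprint frequencies 0.4/0.3/0.2/0.1 for I+V, I+II+V, I+IV+V, I.
#'
#' @param n_replicates number of replicate trajectories
#' @param n_frames frames per replicate
#' @param dt frame spacing (ns)
#' @param tail_length tail residues (default 37)
#' @param sequence one-letter tail sequence (recycled/truncated to
#'   `tail_length`)
#' @param tau planted binding frame (1-based; scalar or per replicate)
#' @param bound_mean,bound_sd bound-state ligand-tail minimum distance
#'   mean and noise sd (nm)
#' @param spike_prob,spike_value fraction of post-binding frames raised
#'   to `spike_value` nm (transient excursions; default none)
#' @param dip_prob fraction of pre-binding frames dipping into the
#'   binding regime (transient binding-unbinding events)
#' @param planted_contacts data.frame with columns `i`, `j`, `p`
#'   (intra-tail residue pairs realized at per-frame probability `p`),
#'   or NULL
#' @param contact_dist realized distance of a planted contact (nm)
#' @param occupancies length-2 named vector (membrane, receptor) summing
#'   to 1
#' @param dwell_mean mean state dwell time (frames)
#' @param modes named frequencies of planted fingerprints, names like
#'   "I+V"; must sum to 1
#' @param membrane_residues tail residues attracted to the membrane in
#'   the membrane-bound state
#' @param shift list: `alpha` (ppm per unit contact probability), `beta`
#'   (ppm per unit conformational score), `noise_h`, `noise_n` (ppm),
#'   `n_replicates`
#' @param seed master seed; all per-replicate streams derive from it
#' @return object of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_replicates = 10, n_frames = 5000, dt = 1,
                           tail_length = 37, sequence = TAIL_SEQ_DEFAULT,
                           tau = 100, bound_mean = 0.35, bound_sd = 0.02,
                           spike_prob = 0, spike_value = 0.55,
                           dip_prob = 0.02,
                           planted_contacts = data.frame(i = 1, j = 26, p = 0.7),
                           contact_dist = 0.45,
                           occupancies = c(membrane = 0.6, receptor = 0.4),
                           dwell_mean = 25,
                           modes = c("I+V" = 0.4, "I+II+V" = 0.3,
                                     "I+IV+V" = 0.2, "I" = 0.1),
                           membrane_residues = 1:10,
                           shift = list(alpha = 0.2, beta = 0.1,
                                        noise_h = 0.01, noise_n = 0.05,
                                        n_replicates = 5),
                           seed = 1) {
  stopifnot(n_replicates >= 1, n_frames >= 2, dt > 0, tail_length >= 10)
  tau <- rep(as.integer(tau), length.out = n_replicates)
  if (any(tau < 2 | tau >= n_frames))
    stop("infeasible spec: tau must lie in [2, n_frames)")
  if (bound_mean + 4 * bound_sd >= 0.5)
    stop("infeasible spec: bound-state noise exceeds the binding-cutoff margin")
  if (!is.null(planted_contacts)) {
    stopifnot(all(c("i", "j", "p") %in% names(planted_contacts)))
    if (any(planted_contacts$p < 0 | planted_contacts$p > 1))
      stop("planted contact probabilities must be in [0,1]")
    if (contact_dist >= 0.6)
      stop("infeasible spec: contact_dist must leave a margin below the 0.6 nm cutoff")
    if (any(abs(planted_contacts$i - planted_contacts$j) < 3))
      stop("planted contact pairs must be sequence-separated (|i-j| >= 3)")
    if (any(planted_contacts$i > tail_length | planted_contacts$j > tail_length))
      stop("planted contact residues outside the tail")
  }
  stopifnot(length(occupancies) == 2, abs(sum(occupancies) - 1) < 1e-9,
            all(occupancies > 0), dwell_mean >= 1)
  if (abs(sum(modes) - 1) > 1e-9 || any(modes < 0))
    stop("mode frequencies must be non-negative and sum to 1")
  for (m in names(modes)) {
    els <- strsplit(m, "+", fixed = TRUE)[[1]]
    if (length(els) == 0 || !all(els %in% c("I", "II", "III", "IV", "V")))
      stop("mode fingerprint '", m, "' must name elements I..V (at least one)")
  }
  if (any(unlist(shift[c("alpha", "beta")]) < 0))
    stop("shift-generator weights must be non-negative")
  seq1 <- strsplit(sequence, "")[[1]]
  seq1 <- rep(seq1, length.out = tail_length)
  structure(list(n_replicates = n_replicates, n_frames = n_frames, dt = dt,
                 tail_length = tail_length, sequence = seq1, tau = tau,
                 bound_mean = bound_mean, bound_sd = bound_sd,
                 spike_prob = spike_prob, spike_value = spike_value,
                 dip_prob = dip_prob, planted_contacts = planted_contacts,
                 contact_dist = contact_dist, occupancies = occupancies,
                 dwell_mean = dwell_mean, modes = modes,
                 membrane_residues = membrane_residues, shift = shift,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

replicate_seed <- function(master, r, stream = 0L) {
  (as.integer(master) %% 100003L) * 10007L + 101L * as.integer(r) + stream
}

# ---- geometry ------------------------------------------------------------

ELEMENT_NAMES <- c("I", "II", "III", "IV", "V")
ELEMENT_ANCHORS <- c(I = 12L, II = 14L, III = 16L, IV = 18L, V = 10L)

# Builds the static topology and the two tail templates. Layout (nm):
# membrane plane z = 1, receptor core ring at z = 3 centred on (10,10),
# tail attached at the core edge; ligand approaches from -y.
synthetic_geometry <- function(spec) {
  nt <- spec$tail_length
  aa3 <- vapply(spec$sequence, function(a) bio3d::aa123(a), "")
  # tail: BB + SC1 per residue, chain A
  tail_at <- data.frame(
    eleno = seq_len(2 * nt),
    elety = rep(c("BB", "SC1"), nt),
    resid = rep(seq_len(nt), each = 2),
    resname = rep(aa3, each = 2),
    chain = "A", mass = 72, stringsAsFactors = FALSE)
  # receptor core: 16 beads on a ring, residues nt+1 .. nt+16, chain A
  n_core <- 16L
  core_res <- nt + seq_len(n_core)
  ang <- 2 * pi * (seq_len(n_core) - 1) / n_core
  core_xyz <- cbind(10 + 1.2 * cos(ang), 10 + 1.2 * sin(ang), 3.0)
  core_at <- data.frame(eleno = 2 * nt + seq_len(n_core), elety = "BB",
                        resid = core_res, resname = "COR", chain = "A",
                        mass = 72, stringsAsFactors = FALSE)
  # membrane: one fine row under the tail path plus two sparse rows
  mx <- seq(-4.9, 2.0, by = 0.35)
  sx <- seq(-4.9, 9.8, by = 1.05)
  mem_xyz <- rbind(cbind(mx, 10, 1.0), cbind(sx, 9.3, 1.0), cbind(sx, 10.7, 1.0))
  n_mem <- nrow(mem_xyz)
  mem_at <- data.frame(eleno = 2 * nt + n_core + seq_len(n_mem),
                       elety = "PO4", resid = seq_len(n_mem),
                       resname = "POP", chain = "M", mass = 72,
                       stringsAsFactors = FALSE)
  # ligand: 5 elements x 3 one-bead residues, chain B, residues 101..115
  lig_res <- 100L + seq_len(15L)
  lig_at <- data.frame(eleno = 2 * nt + n_core + n_mem + seq_len(15L),
                       elety = "BB", resid = lig_res, resname = "LIG",
                       chain = "B", mass = 72, stringsAsFactors = FALSE)
  top <- topology(rbind(tail_at, core_at, mem_at, lig_at))

  # tail templates (rows follow tail_at order: BB,SC per residue)
  sc_off <- c(0, 0, 0.25)
  template <- function(bb) {
    m <- matrix(NA_real_, 2 * nt, 3)
    m[seq(1, 2 * nt, 2), ] <- bb
    m[seq(2, 2 * nt, 2), ] <- sweep(bb, 2, sc_off, "+")
    m
  }
  i <- seq_len(nt)
  # membrane-bound: straight line toward -x, distal residues dipping to
  # the membrane plane
  zM <- rep(3.0, nt)
  nm_res <- spec$membrane_residues
  zM[nm_res] <- 1.3
  ramp <- setdiff(seq(max(nm_res) + 1, min(nt, max(nm_res) + 10)), nm_res)
  if (length(ramp) > 0)
    zM[ramp] <- seq(1.3, 3.0, length.out = length(ramp) + 2)[-c(1, length(ramp) + 2)]
  bbM <- cbind(8.45 - 0.35 * (nt - i), 10, zM)
  # receptor-contacted: hairpin on top of the core
  half <- ceiling(nt / 2)
  xR <- ifelse(i <= half, 6.1 + 0.35 * i, 6.1 + 0.35 * (nt + 1 - i))
  yR <- ifelse(i <= half, 9.75, 10.25)
  bbR <- cbind(xR, yR, 3.4)
  list(topology = top, n_tail_atoms = 2 * nt,
       tail_templates = list(membrane = template(bbM), receptor = template(bbR)),
       core_xyz = core_xyz, mem_xyz = mem_xyz,
       tail_idx = seq_len(2 * nt),
       core_idx = 2 * nt + seq_len(n_core),
       mem_idx = 2 * nt + n_core + seq_len(n_mem),
       lig_idx = 2 * nt + n_core + n_mem + seq_len(15L),
       lig_res = lig_res)
}

#' Domain map of the synthetic system
#'
#' Receptor domains (n_terminal, ecl1-3, lumen) and ligand structural
#' elements I-V for a topology produced by [generate_ensemble()].
#'
#' @param top the synthetic `topology`
#' @param tail_length tail residues (default 37)
#' @export
synthetic_domain_map <- function(top, tail_length = 37) {
  nt <- tail_length
  domain_map(list(n_terminal = 1:nt,
                  ecl1 = nt + 1:4, ecl2 = nt + 5:8, ecl3 = nt + 9:12,
                  lumen = nt + 13:16,
                  I = 101:103, II = 104:106, III = 107:109,
                  IV = 110:112, V = 113:115),
             top = top,
             chain = c(n_terminal = "A", ecl1 = "A", ecl2 = "A",
                       ecl3 = "A", lumen = "A", I = "B", II = "B",
                       III = "B", IV = "B", V = "B"))
}

#' Ligand-element particle selections of the synthetic system
#' @param top the synthetic `topology`
#' @export
synthetic_element_selections <- function(top) {
  dm <- synthetic_domain_map(top)
  sel <- lapply(ELEMENT_NAMES, function(e)
    unlist(residue_particles(top, dm$groups[[e]], "B"), use.names = FALSE))
  names(sel) <- ELEMENT_NAMES
  sel
}

# Two-state Markov chain with stationary distribution = occupancies and
# dwell times proportional to occupancy (mean dwell = dwell_mean).
simulate_states <- function(nf, occ, dwell_mean) {
  q <- pmin(1, 1 / (2 * dwell_mean * occ))   # leave probabilities
  s <- integer(nf)
  s[1] <- sample.int(2, 1, prob = occ)
  u <- stats::runif(nf)
  for (t in 2:nf) s[t] <- if (u[t] < q[s[t - 1]]) 3L - s[t - 1] else s[t - 1]
  s
}

#' Generate a synthetic replicate ensemble
#'
#' Deterministic given the spec's master seed (per-replicate streams are
#' derived from it and recorded). Returns valid trajectories for every
#' other module with no special-casing, plus the planted ground truth.
#'
#' @param spec a `synthetic_spec`
#' @return list with `trajectories` (list of `trajectory`) and
#'   `ground_truth` (class `ground_truth`)
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  geom <- synthetic_geometry(spec)
  top <- geom$topology
  nt <- spec$tail_length
  nf <- spec$n_frames
  np <- n_particles(top)
  mode_els <- lapply(names(spec$modes), function(m)
    ELEMENT_NAMES %in% strsplit(m, "+", fixed = TRUE)[[1]])
  # planted (RMSD, pair-distance) state centroids from the pure templates,
  # referenced to the majority-state template
  bb_rows <- seq(1, 2 * nt, 2)
  major <- which.max(spec$occupancies)
  ref_bb <- geom$tail_templates[[major]]
  pr <- c(1L, if (nt >= 26) 26L else nt)
  centroids <- lapply(1:2, function(s) {
    tm <- geom$tail_templates[[s]]
    r <- backbone_rmsd(tm, ref_bb, bb_rows)
    d <- sqrt(sum((tm[2 * pr[2], ] - tm[2 * pr[1], ])^2))
    c(rmsd = r, dist = d)
  })
  names(centroids) <- names(geom$tail_templates)

  trajs <- vector("list", spec$n_replicates)
  gt_rep <- vector("list", spec$n_replicates)
  for (r in seq_len(spec$n_replicates)) {
    sd_r <- replicate_seed(spec$seed, r)
    set.seed(sd_r)
    tau <- spec$tau[r]
    states <- simulate_states(nf, spec$occupancies, spec$dwell_mean)
    coords <- array(NA_real_, dim = c(nf, np, 3))
    # tail: template of the frame's state + jitter
    for (s in 1:2) {
      idx <- which(states == s)
      if (length(idx) == 0) next
      tm <- geom$tail_templates[[s]]
      for (k in 1:3)
        coords[idx, geom$tail_idx, k] <-
          matrix(tm[, k], length(idx), 2 * nt, byrow = TRUE)
    }
    coords[, geom$tail_idx, ] <- coords[, geom$tail_idx, ] +
      stats::rnorm(nf * 2 * nt * 3, 0, 0.02)
    # static core + membrane
    for (k in 1:3) {
      coords[, geom$core_idx, k] <- matrix(geom$core_xyz[, k], nf,
                                           length(geom$core_idx), byrow = TRUE)
      coords[, geom$mem_idx, k] <- matrix(geom$mem_xyz[, k], nf,
                                          length(geom$mem_idx), byrow = TRUE)
    }
    # planted intra-tail contacts: place the j side-chain bead at
    # contact_dist from the i side chain (toward -x, away from residue i+1)
    contact_real <- NULL
    if (!is.null(spec$planted_contacts)) {
      contact_real <- numeric(nrow(spec$planted_contacts))
      for (pc in seq_len(nrow(spec$planted_contacts))) {
        i <- spec$planted_contacts$i[pc]
        j <- spec$planted_contacts$j[pc]
        on <- stats::runif(nf) < spec$planted_contacts$p[pc]
        sc_i <- geom$tail_idx[2 * i]
        sc_j <- geom$tail_idx[2 * j]
        coords[on, sc_j, 1] <- coords[on, sc_i, 1] - spec$contact_dist
        coords[on, sc_j, 2] <- coords[on, sc_i, 2]
        coords[on, sc_j, 3] <- coords[on, sc_i, 3]
        contact_real[pc] <- mean(on)
      }
    }
    # ligand-tail minimum distance per frame
    d <- numeric(nf)
    pre <- seq_len(tau - 1)
    d[pre] <- stats::runif(tau - 1, 0.7, 3.0)
    dip <- pre[stats::runif(tau - 1) < spec$dip_prob & pre < tau - 2]
    d[dip] <- 0.4
    d[tau - 1] <- max(d[tau - 1], 0.8)   # binding must start exactly at tau
    post <- tau:nf
    d[post] <- pmax(0.2, stats::rnorm(length(post), spec$bound_mean, spec$bound_sd))
    spike <- post[stats::runif(length(post)) < spec$spike_prob]
    d[spike] <- spec$spike_value
    # per-frame mode fingerprints (iid draws from the planted frequencies)
    mode_id <- integer(nf)
    mode_id[post] <- sample.int(length(spec$modes), length(post),
                                replace = TRUE, prob = spec$modes)
    fp <- matrix(FALSE, nf, 5)
    for (m in seq_along(spec$modes)) {
      sel <- which(mode_id == m)
      if (length(sel) > 0)
        fp[sel, ] <- matrix(mode_els[[m]], length(sel), 5, byrow = TRUE)
    }
    # element placement: each element hangs below (-y) its anchor residue
    first_true <- apply(fp, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
    for (e in 1:5) {
      anchor_bb <- geom$tail_idx[2 * ELEMENT_ANCHORS[e] - 1]
      ax <- coords[, anchor_bb, 1]
      ay <- coords[, anchor_bb, 2]
      az <- coords[, anchor_bb, 3]
      # per-frame stand-off of this element from its anchor
      de <- rep(2.0, nf)                       # not in contact
      de[fp[, e]] <- 0.45                      # contacting, secondary
      lead <- which(fp[, e] & first_true == e)  # carries the planted distance
      de[lead] <- d[lead]
      if (length(spike) > 0) de[intersect(spike, which(fp[, e]))] <- spec$spike_value
      de[pre] <- d[pre] + 0.3 * (e != 1)       # pre-binding: rigid block below res 12
      anchor12 <- geom$tail_idx[2 * ELEMENT_ANCHORS[1] - 1]
      for (k in 1:3) {
        b <- geom$lig_idx[3 * (e - 1) + k]
        post_y <- ay - de - 0.3 * (k - 1)
        coords[, b, 1] <- ax
        coords[, b, 2] <- post_y
        coords[, b, 3] <- az
        # pre-binding the whole ligand rides below the element-I anchor
        coords[pre, b, 1] <- coords[pre, anchor12, 1] + 0.3 * (e - 1)
        coords[pre, b, 2] <- coords[pre, anchor12, 2] - de[pre] - 0.3 * (k - 1)
        coords[pre, b, 3] <- coords[pre, anchor12, 3]
      }
    }
    trajs[[r]] <- trajectory(coords, spec$dt * (seq_len(nf) - 1), top)
    gt_rep[[r]] <- list(replicate = r, seed = sd_r, tau = tau,
                        tau_time = spec$dt * (tau - 1),
                        states = states,
                        occupancy_realized = mean(states == 1),
                        contact_realized = contact_real,
                        mode_realized = as.numeric(
                          table(factor(mode_id[post],
                                       levels = seq_along(spec$modes))) /
                            length(post)))
  }
  gt <- structure(list(spec = spec, replicates = gt_rep,
                       state_centroids = centroids,
                       element_anchors = ELEMENT_ANCHORS,
                       ligand_contact_residues =
                         100L + c(1L, 4L, 7L, 10L, 13L)[
                           vapply(seq_len(5), function(e)
                             any(vapply(mode_els, `[`, TRUE, e) &
                                   spec$modes > 0), TRUE)]),
                  class = "ground_truth")
  list(trajectories = trajs, ground_truth = gt)
}

#' Write ground truth to a JSON file
#' @param gt a `ground_truth`
#' @param path output path
#' @export
write_ground_truth <- function(gt, path) {
  out <- gt
  out$spec <- unclass(out$spec)
  out$replicates <- lapply(out$replicates, function(x) {
    x$states <- NULL  # bulky; occupancy_realized summarizes it
    x
  })
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Generate apo/bound amide shift tables with planted perturbations
#'
#' Apo shifts are typical backbone-amide baselines (1H about 8.3 ppm,
#' 15N about 120 ppm) plus Gaussian noise; bound shifts add a contact
#' term `alpha * contact(i)` and a conformational term `beta * conf(i)`
#' to the proton, and five times that to the nitrogen (so both nuclei
#' contribute equally after the 1/5 weighting). Prolines are emitted
#' amide-less.
#'
#' @param spec a `synthetic_spec` (uses its `shift` block, sequence, seed)
#' @param contact_profile per-tail-residue contact score in [0,1]
#' @param conf_profile per-tail-residue conformational-change score
#' @return list with `apo`, `bound` (lists of `shift_table`) and
#'   `ground_truth` (planted perturbation per residue, hotspot set)
#' @export
generate_shift_tables <- function(spec, contact_profile, conf_profile) {
  stopifnot(inherits(spec, "synthetic_spec"))
  nt <- spec$tail_length
  stopifnot(length(contact_profile) == nt, length(conf_profile) == nt)
  sh <- spec$shift
  if (sh$alpha < 0 || sh$beta < 0) stop("shift weights must be non-negative")
  pert <- sh$alpha * contact_profile + sh$beta * conf_profile
  aa3 <- vapply(spec$sequence, function(a) bio3d::aa123(a), "")
  nrep <- if (is.null(sh$n_replicates)) 5L else sh$n_replicates
  make <- function(state, r) {
    set.seed(replicate_seed(spec$seed, r,
                            stream = if (state == "apo") 7000L else 8000L))
    h <- 8.3 + stats::rnorm(nt, 0, sh$noise_h)
    n <- 120 + stats::rnorm(nt, 0, sh$noise_n)
    if (state == "bound") {
      h <- h + pert
      n <- n + 5 * pert
    }
    shift_table(seq_len(nt), aa3, h, n, state = state, replicate = r)
  }
  apo <- lapply(seq_len(nrep), function(r) make("apo", r))
  bound <- lapply(seq_len(nrep), function(r) make("bound", r))
  hot <- which(pert > mean(pert) + stats::sd(pert))
  list(apo = apo, bound = bound,
       ground_truth = list(perturbation = pert, hotspots = hot,
                           alpha = sh$alpha, beta = sh$beta))
}
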