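#' Particle topology
#'
#' A topology holds the static composition of the system: one row per
#' particle (atom or coarse-grain bead) with its name, residue assignment,
#' chain and mass. Residue indices are 1-based and must be non-decreasing
#' within a chain; every particle belongs to exactly one residue.
#'
#' @param atoms data.frame with columns `eleno` (particle id), `elety`
#'   (particle name), `resid` (1-based residue index), `resname`,
#'   `chain`, `mass` (amu). `mass` defaults to 72 amu (a typical
#'   coarse-grain bead) when absent.
#' @return An object of class `topology`.
#' @export
topology <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  req <- c("eleno", "elety", "resid", "resname", "chain")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    stop("topology: missing columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$mass)) atoms$mass <- rep(72, nrow(atoms))
  if (nrow(atoms) == 0) stop("topology: no particles")
  if (anyDuplicated(atoms$eleno))
    stop("topology: duplicated particle id (eleno)")
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("topology: masses must be > 0")
  if (any(atoms$resid < 1)) stop("topology: residue indices must be >= 1")
  for (ch in unique(atoms$chain)) {
    r <- atoms$resid[atoms$chain == ch]
    if (is.unsorted(r)) stop("topology: residue indices not non-decreasing in chain ", ch)
  }
  structure(list(atoms = atoms), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d particles, %d residues, chains: %s\n",
              n_particles(x), n_residues(x),
              paste(unique(x$atoms$chain), collapse = " ")))
  invisible(x)
}

#' @rdname topology
#' @param top a `topology`
#' @export
n_particles <- function(top) nrow(top$atoms)

#' @rdname topology
#' @export
n_residues <- function(top) {
  nrow(unique(top$atoms[, c("chain", "resid")]))
}

# Particle name classes: the backbone/side-chain split is by name
# convention (coarse-grain BB bead, or atomistic N/CA/C/O), configurable
# via options(idrbind.backbone_names=).
backbone_names <- function() {
  getOption("idrbind.backbone_names", c("BB", "CA", "N", "C", "O"))
}

#' Select particles
#'
#' Deterministic particle selection from a topology. Two entry points are
#' provided: `select_particles()` takes structured arguments;
#' `select()` parses a small expression language used in configs, e.g.
#' `"residues 1-10"`, `"backbone of residues 1-37"`,
#' `"side chain of residue 26"`, `"chain B"`, `"name PO4"`,
#' `"residues 1-10 of chain A"`.
#'
#' An empty result is always an error, never a silent empty selection.
#'
#' @param top a `topology`
#' @param resid residue indices to keep (NULL = all)
#' @param part one of "all", "backbone", "sidechain"
#' @param chain chain id to restrict to (NULL = all)
#' @param name particle names to keep (NULL = all)
#' @param provenance description string recorded on the selection
#' @return Integer vector of particle row indices, class `selection`,
#'   with a `provenance` attribute.
#' @export
select_particles <- function(top, resid = NULL, part = c("all", "backbone", "sidechain"),
                             chain = NULL, name = NULL, provenance = NULL) {
  stopifnot(inherits(top, "topology"))
  part <- match.arg(part)
  at <- top$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resid)) {
    avail <- unique(at$resid[keep])
    bad <- setdiff(resid, avail)
    if (length(bad) > 0)
      stop("select: residues not in topology", if (!is.null(chain)) paste0(" (chain ", chain, ")"),
           ": ", paste(utils::head(bad, 10), collapse = ", "))
    keep <- keep & at$resid %in% resid
  }
  if (part == "backbone") keep <- keep & at$elety %in% backbone_names()
  if (part == "sidechain") keep <- keep & !(at$elety %in% backbone_names())
  if (!is.null(name)) keep <- keep & at$elety %in% name
  idx <- which(keep)
  if (length(idx) == 0) stop("select: empty selection")
  if (is.null(provenance)) {
    provenance <- paste0(
      if (part != "all") paste0(part, " of ") else "",
      if (!is.null(resid)) paste0("residues ", paste(range(resid), collapse = "-")) else "all residues",
      if (!is.null(chain)) paste0(" of chain ", paste(chain, collapse = ",")) else "",
      if (!is.null(name)) paste0(" name ", paste(name, collapse = ",")) else "")
  }
  structure(idx, class = "selection", provenance = provenance)
}

parse_resid_spec <- function(s) {
  # "1-10" or "1,3,5-7"
  parts <- strsplit(gsub("\\s", "", s), ",")[[1]]
  out <- integer(0)
  for (p in parts) {
    if (grepl("^[0-9]+[-–][0-9]+$", p)) {
      ab <- as.integer(strsplit(p, "[-–]")[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else if (grepl("^[0-9]+$", p)) {
      out <- c(out, as.integer(p))
    } else stop("select: cannot parse residue spec '", s, "'")
  }
  out
}

#' @rdname select_particles
#' @param expression selection expression (see Details)
#' @export
select <- function(top, expression) {
  expr <- trimws(tolower(expression))
  part <- "all"
  if (grepl("^backbone of ", expr)) {
    part <- "backbone"; expr <- sub("^backbone of ", "", expr)
  } else if (grepl("^(side ?chain) of ", expr)) {
    part <- "sidechain"; expr <- sub("^(side ?chain) of ", "", expr)
  }
  chain <- NULL
  m <- regmatches(expr, regexec("^(.*) of chain ([a-z0-9])$", expr))[[1]]
  if (length(m) == 3) {
    expr <- trimws(m[2]); chain <- toupper(m[3])
  }
  if (grepl("^residues? ", expr)) {
    resid <- parse_resid_spec(sub("^residues? ", "", expr))
    select_particles(top, resid = resid, part = part, chain = chain,
                     provenance = expression)
  } else if (grepl("^chain ", expr)) {
    select_particles(top, part = part, chain = toupper(sub("^chain ", "", expr)),
                     provenance = expression)
  } else if (grepl("^name ", expr)) {
    nm <- toupper(strsplit(gsub("\\s", "", sub("^name ", "", expr)), ",")[[1]])
    select_particles(top, part = part, chain = chain, name = nm,
                     provenance = expression)
  } else stop("select: cannot parse expression '", expression, "'")
}

#' Named residue groups (domain map)
#'
#' Maps group names (receptor domains such as `n_terminal`, `ecl1`..`ecl3`,
#' `lumen`; ligand structural elements `I`..`V`) to ordered residue-index
#' sets. Groups must be non-empty; when a topology is supplied the indices
#' are checked against it; groups listed in `disjoint` (default: the ligand
#' elements) must not overlap.
#'
#' @param groups named list of integer vectors
#' @param top optional `topology` to validate residues against
#' @param chain optional named character vector: chain each group lives on
#' @param disjoint character vector of group names required to be pairwise
#'   disjoint
#' @return object of class `domain_map`
#' @export
domain_map <- function(groups, top = NULL, chain = NULL,
                       disjoint = intersect(names(groups), c("I", "II", "III", "IV", "V"))) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("domain_map: all groups must be named")
  for (g in names(groups)) {
    groups[[g]] <- as.integer(groups[[g]])
    if (length(groups[[g]]) == 0) stop("domain_map: group '", g, "' is empty")
  }
  if (!is.null(top)) {
    for (g in names(groups)) {
      ch <- if (!is.null(chain) && g %in% names(chain)) chain[[g]] else NULL
      at <- top$atoms
      avail <- if (is.null(ch)) unique(at$resid) else unique(at$resid[at$chain == ch])
      bad <- setdiff(groups[[g]], avail)
      if (length(bad) > 0)
        stop("domain_map: group '", g, "' has residues not in topology: ",
             paste(utils::head(bad, 10), collapse = ", "))
    }
  }
  if (length(disjoint) > 1) {
    all_r <- unlist(groups[disjoint])
    if (anyDuplicated(all_r))
      stop("domain_map: groups ", paste(disjoint, collapse = ","), " must be disjoint")
  }
  structure(list(groups = groups, chain = chain), class = "domain_map")
}

#' @export
print.domain_map <- function(x, ...) {
  for (g in names(x$groups))
    cat(sprintf("%-12s %s\n", g, paste(range(x$groups[[g]]), collapse = "-")))
  invisible(x)
}
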