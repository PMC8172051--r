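#' @importFrom bio3d read.pdb read.dcd write.pdb
NULL

# Mass lookup by particle name. Coarse-grain beads (BB, SC*) get the
# standard 72 amu bead mass; atomistic names fall back to the element
# implied by the first letter.
guess_mass <- function(elety) {
  el <- toupper(elety)
  m <- rep(72, length(el))
  atomistic <- !(el %in% "BB" | grepl("^SC", el))
  first <- substr(gsub("[^A-Z]", "", el[atomistic]), 1, 1)
  tbl <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974)
  mm <- tbl[first]
  mm[is.na(mm)] <- 12.011
  m[atomistic] <- mm
  m
}

#' Read a structure file
#'
#' Reads a PDB or GRO file into a topology plus first-frame coordinates.
#' Coordinates are converted to nm on ingestion (PDB is stored in
#' Angstrom; GRO is already nm).
#'
#' @param path file path
#' @param format "auto" (by extension), "pdb" or "gro"
#' @return list with elements `topology` and `coords`
#'   (n_particles x 3 matrix, nm), and `box` (length-3 nm vector or NULL)
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", gro = "gro",
                     stop("unsupported structure format: .", ext))
  }
  if (format == "pdb") read_structure_pdb(path) else read_structure_gro(path)
}

read_structure_pdb <- function(path) {
  # validation (duplicate serials, empty records) is re-done explicitly
  # below, with line-level messages bio3d does not give
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), ]
  if (nrow(at) == 0) stop("parse error: no ATOM records in ", path)
  if (anyDuplicated(at$eleno)) {
    d <- at$eleno[duplicated(at$eleno)][1]
    stop("parse error in ", path, ": duplicated atom serial ", d)
  }
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  top <- topology(data.frame(eleno = at$eleno, elety = at$elety,
                             resid = at$resno, resname = at$resid,
                             chain = chain, mass = guess_mass(at$elety),
                             stringsAsFactors = FALSE))
  coords <- cbind(at$x, at$y, at$z) * 0.1   # Angstrom -> nm
  list(topology = top, coords = coords, box = NULL)
}

read_structure_gro <- function(path) {
  ln <- readLines(path)
  if (length(ln) < 3) stop("parse error: truncated GRO file ", path)
  nat <- suppressWarnings(as.integer(trimws(ln[2])))
  if (is.na(nat) || nat < 1) stop("parse error in ", path, " line 2: bad atom count")
  if (length(ln) < 2 + nat + 1) stop("parse error: GRO file shorter than declared atom count")
  body <- ln[3:(2 + nat)]
  num <- function(s, i) {
    v <- suppressWarnings(as.numeric(substr(s, 21 + (i - 1) * 8, 20 + i * 8)))
    v
  }
  resid <- suppressWarnings(as.integer(substr(body, 1, 5)))
  resname <- trimws(substr(body, 6, 10))
  elety <- trimws(substr(body, 11, 15))
  eleno <- suppressWarnings(as.integer(substr(body, 16, 20)))
  x <- num(body, 1); y <- num(body, 2); z <- num(body, 3)
  bad <- which(is.na(resid) | is.na(eleno) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0)
    stop("parse error in ", path, " line ", 2 + bad[1], ": malformed GRO atom record")
  box <- suppressWarnings(as.numeric(strsplit(trimws(ln[3 + nat]), "\\s+")[[1]]))
  if (length(box) > 3 && any(box[4:length(box)] != 0))
    stop("triclinic boxes are not supported")
  box <- box[1:3]
  top <- topology(data.frame(eleno = eleno, elety = elety, resid = resid,
                             resname = resname, chain = "A",
                             mass = guess_mass(elety), stringsAsFactors = FALSE))
  list(topology = top, coords = cbind(x, y, z), box = if (all(box > 0)) box else NULL)
}

#' Read a trajectory file
#'
#' Supports multi-model PDB and DCD. XTC is not supported and raises an
#' explicit error. Frame times are synthesized from `dt` (ns) and `time0`
#' since neither format carries reliable time stamps.
#'
#' @param path file path
#' @param top the `topology` of the system
#' @param format "auto", "pdb" (multi-model) or "dcd"
#' @param dt frame spacing (ns) used to synthesize times
#' @param time0 time of the first frame (ns)
#' @param box optional box lengths (nm) to attach
#' @return a `trajectory`
#' @export
read_trajectory <- function(path, top, format = c("auto", "pdb", "dcd", "xtc"),
                            dt = 1, time0 = 0, box = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", dcd = "dcd", xtc = "xtc",
                     stop("unsupported trajectory format: .", ext))
  }
  if (format == "xtc")
    stop("unsupported trajectory format: xtc (use DCD or multi-model PDB)")
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz * 0.1
  } else {
    xyz <- bio3d::read.dcd(path, verbose = FALSE) * 0.1
  }
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  if (nf == 0) stop("empty trajectory: ", path)
  np <- ncol(xyz) / 3
  if (np != n_particles(top))
    stop("particle count mismatch: file has ", np, ", topology has ",
         n_particles(top))
  coords <- array(NA_real_, dim = c(nf, np, 3))
  coords[, , 1] <- xyz[, seq(1, 3 * np, 3), drop = FALSE]
  coords[, , 2] <- xyz[, seq(2, 3 * np, 3), drop = FALSE]
  coords[, , 3] <- xyz[, seq(3, 3 * np, 3), drop = FALSE]
  trajectory(coords, time0 + dt * (seq_len(nf) - 1), top, box = box)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj a `trajectory`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path) {
  at <- traj$topology$atoms
  nf <- n_frames(traj)
  np <- nrow(at)
  xyz <- matrix(NA_real_, nf, 3 * np)
  xyz[, seq(1, 3 * np, 3)] <- traj$coords[, , 1]
  xyz[, seq(2, 3 * np, 3)] <- traj$coords[, , 2]
  xyz[, seq(3, 3 * np, 3)] <- traj$coords[, , 3]
  bio3d::write.pdb(file = path, xyz = xyz * 10, resno = at$resid,
                   resid = at$resname, eleno = at$eleno, elety = at$elety,
                   chain = at$chain)
  invisible(path)
}

#' Write / read a labelled numeric matrix as TSV
#'
#' Tab-separated text with a header row of column labels and a first
#' column of row labels. Values are written with `digits` significant
#' digits (default 6) and round-trip within that precision.
#'
#' @param mat numeric matrix
#' @param path output path
#' @param row_labels,col_labels label vectors; default from dimnames
#' @param digits significant digits retained
#' @export
write_matrix <- function(mat, path, row_labels = rownames(mat),
                         col_labels = colnames(mat), digits = 6) {
  mat <- as.matrix(mat)
  if (is.null(row_labels)) row_labels <- seq_len(nrow(mat))
  if (is.null(col_labels)) col_labels <- seq_len(ncol(mat))
  if (length(row_labels) != nrow(mat) || length(col_labels) != ncol(mat))
    stop("write_matrix: label/shape mismatch")
  out <- cbind(label = as.character(row_labels),
               matrix(format(signif(mat, digits), trim = TRUE, digits = digits),
                      nrow(mat), ncol(mat)))
  colnames(out) <- c("label", as.character(col_labels))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write uniform records as TSV
#'
#' @param records data.frame (or coercible) of uniform records
#' @param path output path
#' @export
write_table <- function(records, path) {
  lens <- vapply(records, length, 1L)
  if (length(unique(lens)) > 1) stop("write_table: ragged input")
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a structured run configuration (YAML)
#' @param path YAML file path
#' @export
read_config <- function(path) yaml::read_yaml(path)
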