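#' Trajectory container
#'
#' Ordered frames of 3D coordinates in nm with per-frame times in ns and an
#' (optional) orthorhombic periodic box. Coordinates are stored as an array
#' of dimension `n_frames x n_particles x 3`. Frames are indexed 1-based.
#'
#' @param coords numeric array `n_frames x n_particles x 3` (nm)
#' @param times numeric vector of frame times (ns), strictly increasing
#' @param top the `topology` the coordinates refer to
#' @param box orthorhombic box lengths (nm): length-3 vector, or
#'   `n_frames x 3` matrix, or NULL for a non-periodic system
#' @return object of class `trajectory`
#' @export
trajectory <- function(coords, times, top, box = NULL) {
  stopifnot(inherits(top, "topology"))
  d <- dim(coords)
  if (length(d) != 3 || d[3] != 3)
    stop("trajectory: coords must be n_frames x n_particles x 3")
  if (d[1] == 0) stop("empty trajectory")
  if (d[2] != n_particles(top))
    stop("trajectory: particle count mismatch (coords ", d[2],
         ", topology ", n_particles(top), ")")
  if (length(times) != d[1]) stop("trajectory: times length != n_frames")
  if (any(diff(times) <= 0)) stop("trajectory: times must be strictly increasing")
  if (!is.null(box)) {
    if (is.matrix(box)) {
      if (nrow(box) != d[1] || ncol(box) != 3)
        stop("trajectory: box matrix must be n_frames x 3")
    } else if (length(box) != 3) {
      stop("trajectory: box must be length-3 (orthorhombic) or n_frames x 3")
    }
    if (any(box <= 0)) stop("trajectory: box lengths must be > 0")
  }
  structure(list(coords = coords, times = as.numeric(times), box = box,
                 topology = top),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d particles, t = %.4g..%.4g ns%s\n",
              n_frames(x), dim(x$coords)[2], x$times[1],
              x$times[n_frames(x)],
              if (is.null(x$box)) "" else " (periodic)"))
  invisible(x)
}

#' @rdname trajectory
#' @param traj a `trajectory`
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame as an n_particles x 3 coordinate matrix
#' @param traj a `trajectory`
#' @param i frame index (1-based)
#' @export
frame_coords <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stop("frame index out of range")
  m <- traj$coords[i, , , drop = FALSE]
  dim(m) <- dim(m)[2:3]
  m
}

# Box lengths for frame i (or NULL).
frame_box <- function(traj, i) {
  if (is.null(traj$box)) return(NULL)
  if (is.matrix(traj$box)) traj$box[i, ] else traj$box
}

#' Subset frames of a trajectory
#' @param traj a `trajectory`
#' @param frames integer vector of frame indices to keep (in order)
#' @export
subset_frames <- function(traj, frames) {
  if (length(frames) == 0) stop("zero-length frame window")
  if (any(frames < 1 | frames > n_frames(traj))) stop("frame window out of range")
  box <- traj$box
  if (is.matrix(box)) box <- box[frames, , drop = FALSE]
  trajectory(traj$coords[frames, , , drop = FALSE], traj$times[frames],
             traj$topology, box)
}
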