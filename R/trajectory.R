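#' Coarse-grained trajectory
#'
#' Ordered frames of bead positions (nm) with per-frame orthorhombic box
#' lengths (nm) and timestamps (ns). Frame times must be strictly
#' increasing with constant spacing.
#'
#' @param positions Numeric array of dim `(n_frames, n_beads, 3)`, nm.
#' @param box Numeric matrix `(n_frames, 3)` of box lengths, nm.
#' @param times Numeric vector of frame times, ns.
#' @return A `cg_trajectory`.
#' @keywords internal
new_cg_trajectory <- function(positions, box, times) {
  stopifnot(length(dim(positions)) == 3L, dim(positions)[3L] == 3L)
  nf <- dim(positions)[1L]
  stopifnot(nrow(box) == nf, length(times) == nf)
  if (!all(is.finite(positions))) {
    stop("non-finite coordinates in trajectory", call. = FALSE)
  }
  if (any(box <= 0)) stop("box lengths must be positive", call. = FALSE)
  dt <- NA_real_
  if (nf > 1L) {
    steps <- diff(times)
    if (any(steps <= 0)) {
      stop("frame times must be strictly increasing", call. = FALSE)
    }
    if (max(steps) - min(steps) > 1e-6 * max(steps)) {
      stop("frame spacing is not constant", call. = FALSE)
    }
    dt <- steps[1L]
  }
  structure(
    list(positions = positions, box = box, times = times,
         frame_interval = dt),
    class = "cg_trajectory"
  )
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("<cg_trajectory> ", n_frames(x), " frames x ", dim(x$positions)[2L],
      " beads, dt = ", x$frame_interval, " ns, t = [",
      x$times[1L], ", ", x$times[n_frames(x)], "] ns\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory A `cg_trajectory`.
#' @export
n_frames <- function(trajectory) dim(trajectory$positions)[1L]

#' Positions of one frame
#' @param trajectory A `cg_trajectory`.
#' @param frame 1-based frame number.
#' @return An `n_beads x 3` matrix, nm.
#' @export
frame_positions <- function(trajectory, frame) {
  trajectory$positions[frame, , , drop = FALSE][1L, , ]
}

#' Read a trajectory
#'
#' Native support covers concatenated GRO frames and multi-MODEL PDB. Any
#' other (e.g. binary XTC/TRR/DCD) format can be admitted through the
#' `reader` plug-in contract: a function `f(path)` returning a list of
#' frames, each a list with elements `time` (ns, may be `NA`), `positions`
#' (an `n_beads x 3` matrix in nm) and `box` (3 box lengths in nm).
#'
#' Frames whose time is missing (PDB, untagged GRO titles) are assigned
#' `0, dt, 2*dt, ...`.
#'
#' @param path Path to the trajectory file.
#' @param topology The matching `cg_topology`; the per-frame bead count must
#'   equal its bead count.
#' @param format `"gro"`, `"pdb"`, or `"auto"` (extension-based). Ignored
#'   when `reader` is given.
#' @param dt Fallback frame interval (ns) when the file stores no times.
#' @param reader Optional plug-in reader function (see above).
#' @return A `cg_trajectory`.
#' @export
read_trajectory <- function(path, topology, format = c("auto", "gro", "pdb"),
                            dt = 1, reader = NULL) {
  if (is.null(reader)) {
    format <- resolve_format(match.arg(format), path)
    parsed <- switch(format,
      gro = parse_gro_file(path),
      pdb = parse_pdb_file(path)
    )
    frames <- parsed$frames
  } else {
    frames <- reader(path)
  }
  nb <- n_beads(topology)
  nf <- length(frames)
  for (f in seq_len(nf)) {
    nb_f <- nrow(frames[[f]]$positions)
    if (nb_f != nb) {
      stop("structural error in frame ", f, ": ", nb_f,
           " beads found, topology declares ", nb, call. = FALSE)
    }
  }
  pos <- array(NA_real_, dim = c(nf, nb, 3L))
  box <- matrix(NA_real_, nf, 3L)
  times <- vapply(frames, function(fr) fr$time %||% NA_real_, numeric(1L))
  for (f in seq_len(nf)) {
    pos[f, , ] <- frames[[f]]$positions
    bx <- frames[[f]]$box
    if (is.null(bx)) stop("frame ", f, " carries no box", call. = FALSE)
    box[f, ] <- bx
  }
  if (anyNA(times)) times <- (seq_len(nf) - 1L) * dt
  new_cg_trajectory(pos, box, times)
}

#' Write a system to GRO or PDB
#'
#' Output files round-trip through [read_topology()] / [read_trajectory()]
#' within the format's coordinate precision (GRO: 3 decimals in nm; PDB:
#' 3 decimals in Angstrom).
#'
#' @param topology A `cg_topology`.
#' @param trajectory A `cg_trajectory` over the same beads.
#' @param path Output file path.
#' @param format `"gro"` or `"pdb"` (default: from the extension).
#' @return `path`, invisibly.
#' @export
write_system <- function(topology, trajectory, path,
                         format = c("auto", "gro", "pdb")) {
  format <- resolve_format(match.arg(format), path)
  if (n_frames(trajectory) < 1L) {
    stop("trajectory has no frames", call. = FALSE)
  }
  if (dim(trajectory$positions)[2L] != n_beads(topology)) {
    stop("trajectory bead count does not match topology", call. = FALSE)
  }
  switch(format,
    gro = write_gro_file(topology, trajectory, path),
    pdb = write_pdb_file(topology, trajectory, path)
  )
  invisible(path)
}
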