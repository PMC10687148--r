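#' Construct a single trajectory frame
#'
#' A frame holds the particle positions of one configuration together with
#' the cubic periodic box edge. Coordinates are stored as read (possibly
#' unwrapped); consumers wrap on demand with [wrap_positions()].
#'
#' @param positions Numeric matrix with one row per atom site and three
#'   columns (x, y, z), in nm.
#' @param box_edge Cubic box edge length L in nm; must be positive. Only
#'   cubic boxes are supported.
#' @param time Frame time in ps (optional, default 0).
#' @return An object of class `fluct_frame`.
#' @export
frame <- function(positions, box_edge, time = 0) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L)
    stop("positions must be an n x 3 matrix of coordinates in nm")
  if (!is.numeric(box_edge) || length(box_edge) != 1L || !is.finite(box_edge) ||
      box_edge <= 0)
    stop("box_edge must be a single positive number (nm)")
  storage.mode(positions) <- "double"
  dimnames(positions) <- NULL
  structure(
    list(positions = positions, box_edge = as.numeric(box_edge),
         time = as.numeric(time)),
    class = "fluct_frame"
  )
}

#' Construct a hydroxyl-site topology
#'
#' Maps each molecule to the atom-site indices of its hydroxyl oxygen
#' (the donor/acceptor site) and hydroxyl hydrogen. Analysis of
#' single-hydroxyl molecules (monohydroxy alcohols) assumes exactly one O
#' and one H site per molecule.
#'
#' @param o_index Integer vector: per-molecule site index of the hydroxyl O.
#' @param h_index Integer vector: per-molecule site index of the hydroxyl H,
#'   same length as `o_index`.
#' @return An object of class `fluct_topology` with `n_molecules` field.
#' @export
topology <- function(o_index, h_index) {
  o_index <- as.integer(o_index)
  h_index <- as.integer(h_index)
  if (length(o_index) != length(h_index))
    stop("o_index and h_index must have one entry per molecule")
  if (length(o_index) < 1L) stop("topology needs at least one molecule")
  all_idx <- c(o_index, h_index)
  if (anyNA(all_idx) || any(all_idx < 1L))
    stop("site indices must be positive integers")
  if (anyDuplicated(all_idx))
    stop("site indices must be unique: each site belongs to one molecule role")
  structure(
    list(o_index = o_index, h_index = h_index,
         n_molecules = length(o_index)),
    class = "fluct_topology"
  )
}

#' Construct a trajectory
#'
#' An ordered sequence of frames sharing a topology, with thermodynamic
#' metadata (temperature, pressure) used by the compressibility estimators.
#'
#' @param frames List of [frame()] objects; at least one.
#' @param topology A [topology()] object, or NULL if no hydroxyl map is
#'   needed (pair-structure analysis on all sites).
#' @param temperature Temperature in K (metadata; required by the
#'   compressibility conversions).
#' @param pressure Pressure in bar (metadata).
#' @return An object of class `fluct_trajectory`.
#' @export
trajectory <- function(frames, topology = NULL, temperature = NA_real_,
                       pressure = NA_real_) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("a trajectory needs at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "fluct_frame")))
    stop("frames must be a list of fluct_frame objects")
  n_sites <- vapply(frames, function(f) nrow(f$positions), integer(1))
  if (length(unique(n_sites)) != 1L)
    stop("inconsistent atom counts across frames")
  if (!is.null(topology)) {
    stopifnot(inherits(topology, "fluct_topology"))
    if (max(c(topology$o_index, topology$h_index)) > n_sites[1])
      stop("topology site indices exceed the frame site count")
  }
  structure(
    list(frames = frames, topology = topology,
         temperature = as.numeric(temperature),
         pressure = as.numeric(pressure)),
    class = "fluct_trajectory"
  )
}

#' @export
print.fluct_trajectory <- function(x, ...) {
  n <- length(x$frames)
  cat(sprintf("fluct_trajectory: %d frame%s, %d sites, box L = %.4g nm\n",
              n, if (n == 1) "" else "s", nrow(x$frames[[1]]$positions),
              x$frames[[1]]$box_edge))
  if (!is.null(x$topology))
    cat(sprintf("  topology: %d molecules (hydroxyl O/H sites)\n",
                x$topology$n_molecules))
  if (is.finite(x$temperature))
    cat(sprintf("  T = %g K, P = %g bar\n", x$temperature, x$pressure))
  invisible(x)
}

#' Wrap coordinates into the primary box [0, L)
#'
#' @param x Numeric matrix (or vector) of coordinates in nm.
#' @param L Cubic box edge in nm.
#' @return Coordinates wrapped component-wise into [0, L).
#' @export
wrap_positions <- function(x, L) {
  if (L <= 0) stop("L must be positive")
  x - L * floor(x / L)
}

#' Minimum-image displacement under cubic periodic boundary conditions
#'
#' Returns the displacement r2 - r1 mapped to the nearest periodic image,
#' i.e. each component in [-L/2, L/2), so its norm is at most sqrt(3) L / 2.
#' Accepts single coordinates or matrices of matching shape.
#'
#' @param r1,r2 Numeric length-3 vectors (or n x 3 matrices) in nm.
#' @param L Cubic box edge in nm, positive.
#' @return Displacement(s) with every component in [-L/2, L/2).
#' @export
minimum_image_displacement <- function(r1, r2, L) {
  if (L <= 0) stop("L must be positive")
  d <- r2 - r1
  d - L * floor(d / L + 0.5)
}

#' Extract per-frame hydroxyl-oxygen coordinates
#'
#' Oxygen positions define molecule location throughout the package
#' (density, subvolume counting, S(k)), matching O-based pair analysis.
#'
#' @param traj A [trajectory()].
#' @return List of n_molecules x 3 matrices, one per frame.
#' @export
oxygen_positions <- function(traj) {
  stopifnot(inherits(traj, "fluct_trajectory"))
  if (is.null(traj$topology))
    return(lapply(traj$frames, function(f) f$positions))
  idx <- traj$topology$o_index
  lapply(traj$frames, function(f) f$positions[idx, , drop = FALSE])
}
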