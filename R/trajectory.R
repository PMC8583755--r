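# Trajectory container: per-frame chain coordinates, optional ion
# coordinates, cubic box, and (for synthetic ensembles) the true generator
# state per frame.

#' Construct a trajectory object
#'
#' Holds per-frame Cartesian coordinates (nm) of a GAG chain, optional ion
#' coordinates, the cubic box edge, and optional per-frame generator state
#' labels (synthetic ensembles only). The chain is stored whole (never
#' wrapped across periodic images); minimum-image distances are applied only
#' where ions are involved.
#'
#' @param coords Either an n_atoms x 3 matrix (single frame) or an
#'   n_atoms x 3 x n_frames array, in nm.
#' @param topology The [gag_topology()] the coordinates belong to.
#' @param box Cubic box edge length (nm), or `NA` for a non-periodic system.
#' @param ions Optional ion coordinates: n_ions x 3 matrix or
#'   n_ions x 3 x n_frames array (nm).
#' @param state Optional integer vector of true generator state labels, one
#'   per frame.
#' @return An object of class `gag_trajectory`.
#' @export
gag_trajectory <- function(coords, topology, box = NA_real_, ions = NULL,
                           state = NULL) {
  stopifnot(inherits(topology, "gag_topology"))
  if (is.matrix(coords)) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2L] == 3L)
  if (dim(coords)[1L] != nrow(topology$atoms)) {
    stop("coords has ", dim(coords)[1L], " atoms but the topology has ",
         nrow(topology$atoms), call. = FALSE)
  }
  if (!all(is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  if (!is.na(box)) .assert_positive(box, "box")
  if (!is.null(ions)) {
    if (is.matrix(ions)) ions <- array(ions, c(dim(ions), dim(coords)[3L]))
    stopifnot(length(dim(ions)) == 3L, dim(ions)[3L] == dim(coords)[3L])
  }
  if (!is.null(state)) stopifnot(length(state) == dim(coords)[3L])
  structure(list(coords = coords, topology = topology, box = box,
                 ions = ions, state = state),
            class = "gag_trajectory")
}

#' Number of frames in a trajectory
#' @param traj A [gag_trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "gag_trajectory"))
  dim(traj$coords)[3L]
}

#' Extract one frame's chain coordinates
#' @param traj A [gag_trajectory()].
#' @param i Frame index (1-based).
#' @return An n_atoms x 3 matrix (nm).
#' @export
frame_coords <- function(traj, i) {
  stopifnot(inherits(traj, "gag_trajectory"))
  traj$coords[, , i, drop = TRUE]
}

#' @export
print.gag_trajectory <- function(x, ...) {
  cat("<gag_trajectory> ", x$topology$gag_kind, ": ", n_frames(x),
      " frames, ", dim(x$coords)[1L], " chain atoms",
      if (!is.null(x$ions)) paste0(", ", dim(x$ions)[1L], " ions"),
      if (!is.na(x$box)) paste0(", box ", x$box, " nm"),
      "\n", sep = "")
  invisible(x)
}

# subset frames, keeping ions/state aligned
.subset_frames <- function(traj, idx) {
  gag_trajectory(traj$coords[, , idx, drop = FALSE], traj$topology,
                 box = traj$box,
                 ions = if (!is.null(traj$ions)) traj$ions[, , idx, drop = FALSE],
                 state = traj$state[idx])
}
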