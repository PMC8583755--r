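# Neighbour-count RMSD clustering: all-vs-all fitted RMSD matrix, the greedy
# largest-neighbourhood extraction, and the cluster-count convergence curve.

#' All-vs-all fitted RMSD matrix
#'
#' Entry (i, j) is the least-squares superposed RMSD between frames i and j
#' over the selected atoms. The full matrix is O(frames^2); beyond
#' `max_frames` frames an explicit `chunked = TRUE` is required as a memory
#' guard.
#'
#' @param traj A [gag_trajectory()].
#' @param selection Atom indices (default: all chain atoms).
#' @param max_frames Frame-count guard (default 2000).
#' @param chunked Set `TRUE` to accept frame counts above `max_frames`.
#' @return A symmetric n_frames x n_frames matrix (nm) with zero diagonal.
#' @export
pairwise_rmsd_matrix <- function(traj, selection = NULL, max_frames = 2000L,
                                 chunked = FALSE) {
  stopifnot(inherits(traj, "gag_trajectory"))
  nf <- n_frames(traj)
  if (nf < 2L) stop("at least two frames required", call. = FALSE)
  if (nf > max_frames && !chunked) {
    stop(nf, " frames exceed max_frames = ", max_frames,
         "; pass chunked = TRUE to proceed", call. = FALSE)
  }
  sel <- selection %||% seq_len(dim(traj$coords)[1L])
  centred <- lapply(seq_len(nf), function(i) {
    x <- traj$coords[sel, , i]
    sweep(x, 2L, colMeans(x))
  })
  sq <- vapply(centred, function(x) sum(x^2), numeric(1L))
  n_at <- length(sel)
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    xi <- centred[[i]]
    for (j in (i + 1L):nf) {
      s <- svd(crossprod(xi, centred[[j]]))
      sig <- s$d
      if (det(s$u) * det(s$v) < 0) sig[3L] <- -sig[3L]
      msd <- (sq[i] + sq[j] - 2 * sum(sig)) / n_at
      m[i, j] <- m[j, i] <- sqrt(max(msd, 0))
    }
  }
  m
}

#' Greedy neighbour-count clustering of an RMSD matrix
#'
#' Repeatedly counts, among the frames not yet assigned, each frame's
#' neighbours within `cutoff` (a frame is its own neighbour), takes the frame
#' with the largest count as a cluster centre, assigns it together with its
#' neighbours to a new cluster, removes them from the pool, and iterates
#' until every frame is assigned. Ties on the neighbour count go to the
#' lowest frame index.
#'
#' @param rmsd_matrix Square symmetric matrix (nm), e.g. from
#'   [pairwise_rmsd_matrix()].
#' @param cutoff Neighbour cutoff (nm); membership uses `<= cutoff`.
#' @return A `gag_cluster_result`: list with `assignments` (tibble `frame`,
#'   `cluster`, `is_center`), `centers` (frame index per cluster), `sizes`,
#'   `n_clusters` and `cutoff`.
#' @export
daura_cluster <- function(rmsd_matrix, cutoff) {
  m <- as.matrix(rmsd_matrix)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-9) {
    stop("rmsd_matrix must be square and symmetric", call. = FALSE)
  }
  .assert_positive(cutoff, "cutoff")
  n <- nrow(m)
  adj <- m <= cutoff
  remaining <- rep(TRUE, n)
  cluster <- integer(n)
  centers <- integer(0L)
  k <- 0L
  while (any(remaining)) {
    k <- k + 1L
    counts <- colSums(adj[remaining, , drop = FALSE])
    counts[!remaining] <- -1L
    center <- which.max(counts)  # lowest index on ties
    members <- which(remaining & adj[, center])
    cluster[members] <- k
    centers[k] <- center
    remaining[members] <- FALSE
  }
  sizes <- tabulate(cluster, k)
  structure(list(
    assignments = tibble::tibble(frame = seq_len(n), cluster = cluster,
                                 is_center = seq_len(n) %in% centers),
    centers = centers, sizes = sizes, n_clusters = k, cutoff = cutoff),
    class = "gag_cluster_result")
}

#' @export
print.gag_cluster_result <- function(x, ...) {
  cat("<gag_cluster_result> ", x$n_clusters, " clusters at cutoff ",
      x$cutoff, " nm; sizes: ", paste(x$sizes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname daura_cluster
#' @param x A `gag_cluster_result`.
#' @param ... Unused.
#' @method tidy gag_cluster_result
#' @export
tidy.gag_cluster_result <- function(x, ...) x$assignments

#' Evolution of the cluster count with trajectory length
#'
#' For each checkpoint t, runs the neighbour-count clustering on the leading
#' t x t block of the RMSD matrix and records the number of clusters — the
#' convergence diagnostic: a flattening curve indicates that the trajectory
#' stopped discovering new conformations.
#'
#' @param rmsd_matrix Square symmetric RMSD matrix (nm).
#' @param cutoff Neighbour cutoff (nm).
#' @param checkpoints Strictly increasing frame counts to evaluate.
#' @return A `gag_cluster_evolution` tibble with columns `checkpoint`,
#'   `n_clusters`.
#' @export
cluster_count_evolution <- function(rmsd_matrix, cutoff, checkpoints) {
  if (length(checkpoints) == 0L) stop("empty checkpoint list", call. = FALSE)
  n <- nrow(as.matrix(rmsd_matrix))
  checkpoints <- as.integer(checkpoints)
  if (any(checkpoints < 2L | checkpoints > n) ||
      any(diff(checkpoints) <= 0L)) {
    stop("checkpoints must be strictly increasing and within [2, n_frames]",
         call. = FALSE)
  }
  counts <- vapply(checkpoints, function(t) {
    daura_cluster(rmsd_matrix[seq_len(t), seq_len(t), drop = FALSE],
                  cutoff)$n_clusters
  }, integer(1L))
  out <- tibble::tibble(checkpoint = checkpoints, n_clusters = counts)
  class(out) <- c("gag_cluster_evolution", class(out))
  out
}
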