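# Free-energy-landscape pipeline: state-vector assembly, PCA, the
# probability-based free-energy surface, k-means state segregation with
# elbow selection, and representative-structure retrieval.

#' Assemble the state matrix from per-frame features
#'
#' Column-binds the four state-vector features (dihedral offsets of both
#' linkage classes, end-to-end distance, hydrogen-bond count) in a fixed,
#' recorded order. With `standardize = TRUE` (the default) each column is
#' z-scored and the centring/scaling parameters are stored; zero-variance
#' columns keep scale 1 so constant features pass through harmlessly.
#'
#' @param features Tibble from [compute_features()] (or any data frame
#'   containing the feature columns).
#' @param columns Feature columns, in order.
#' @param standardize Z-score the columns (recommended: the features have
#'   incommensurate units, and without scaling the largest-variance column
#'   dominates the PCA).
#' @return A `gag_state_matrix`: numeric matrix with attributes `center`,
#'   `scale` and `standardized`.
#' @export
assemble_state_matrix <- function(features,
                                  columns = c("d_offset_l1", "d_offset_l2",
                                              "r_ee", "n_hb"),
                                  standardize = TRUE) {
  missing_cols <- setdiff(columns, names(features))
  if (length(missing_cols) > 0L) {
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(features[columns])
  if (anyNA(m)) stop("state matrix contains undefined entries", call. = FALSE)
  ctr <- colMeans(m)
  scl <- apply(m, 2L, stats::sd)
  scl[scl < 1e-12] <- 1
  if (standardize) m <- sweep(sweep(m, 2L, ctr), 2L, scl, "/")
  structure(m, center = ctr, scale = scl, standardized = standardize,
            class = c("gag_state_matrix", class(m)))
}

#' Undo the standardization of a state matrix
#' @param m A `gag_state_matrix`.
#' @return The matrix on the original feature scales.
#' @export
destandardize <- function(m) {
  stopifnot(inherits(m, "gag_state_matrix"))
  if (!attr(m, "standardized")) return(unclass(m))
  sweep(sweep(unclass(m), 2L, attr(m, "scale"), "*"), 2L, attr(m, "center"), "+")
}

#' Principal component analysis of the state matrix
#'
#' Eigen-decomposition of the feature covariance; scores are the centred
#' data projected on the top `k_pc` eigenvectors. Rank-deficient input is
#' handled by reporting zero-variance components rather than failing.
#'
#' @param m A `gag_state_matrix` (or plain numeric matrix).
#' @param k_pc Number of components to retain (default 2).
#' @return A `gag_pca`: list with `scores` (tibble `frame`, `PC1`, ...),
#'   `loadings` (columns orthonormal), `explained` (all variance fractions,
#'   non-increasing) and `k_pc`.
#' @export
principal_components <- function(m, k_pc = 2L) {
  x <- unclass(m)
  if (nrow(x) <= ncol(x)) {
    stop("need more frames than features for a meaningful PCA", call. = FALSE)
  }
  k_pc <- as.integer(k_pc)
  stopifnot(k_pc >= 1L, k_pc <= ncol(x))
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  scores <- tibble::as_tibble(p$x[, seq_len(k_pc), drop = FALSE])
  scores <- dplyr::bind_cols(tibble::tibble(frame = seq_len(nrow(x))), scores)
  structure(list(scores = scores,
                 loadings = p$rotation[, seq_len(k_pc), drop = FALSE],
                 explained = ev / sum(ev),
                 k_pc = k_pc),
            class = "gag_pca")
}

#' @export
print.gag_pca <- function(x, ...) {
  cat("<gag_pca> ", nrow(x$scores), " frames, ", x$k_pc,
      " components; explained variance: ",
      paste(sprintf("%.1f%%", 100 * x$explained[seq_len(x$k_pc)]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname principal_components
#' @param x A `gag_pca`.
#' @param ... Unused.
#' @method tidy gag_pca
#' @export
tidy.gag_pca <- function(x, ...) {
  tibble::tibble(feature = rep(rownames(x$loadings), x$k_pc),
                 component = rep(colnames(x$loadings), each = nrow(x$loadings)),
                 loading = as.vector(x$loadings))
}

#' @rdname principal_components
#' @method glance gag_pca
#' @export
glance.gag_pca <- function(x, ...) {
  tibble::tibble(k_pc = x$k_pc,
                 var_pc1 = x$explained[1L],
                 var_pc2 = if (length(x$explained) > 1L) x$explained[2L] else NA_real_,
                 var_retained = sum(x$explained[seq_len(x$k_pc)]))
}

#' Free-energy surface over the first two principal components
#'
#' Bins the (PC1, PC2) scores on a regular 2-D grid, normalizes the
#' histogram to a probability P per bin, and converts to a relative free
#' energy dG = -kB T ln(P / Pmax), so the maximal-probability bin sits at
#' dG = 0 and all occupied bins have dG >= 0. Empty bins carry `NA` (their
#' free energy is undefined, not zero or infinite in exports).
#'
#' @param projection A `gag_pca` with at least two components.
#' @param bins Number of bins per axis (default 50).
#' @param temperature Temperature in kelvin (default 300).
#' @param pad Fractional padding of the score extent (default 0.05).
#' @return A `gag_fes` tibble with columns `pc1`, `pc2` (bin centres), `p`,
#'   `dg_kbt`, `dg_kjmol`; attributes record the bin edges and temperature.
#' @export
free_energy_surface <- function(projection, bins = 50L, temperature = 300,
                                pad = 0.05) {
  stopifnot(inherits(projection, "gag_pca"), projection$k_pc >= 2L)
  .assert_positive(temperature, "temperature")
  s1 <- projection$scores$PC1
  s2 <- projection$scores$PC2
  span <- function(v) {
    r <- range(v)
    w <- diff(r)
    if (w < 1e-12) w <- 1
    r + c(-1, 1) * pad * w
  }
  e1 <- seq(span(s1)[1L], span(s1)[2L], length.out = bins + 1L)
  e2 <- seq(span(s2)[1L], span(s2)[2L], length.out = bins + 1L)
  i1 <- pmin(pmax(findInterval(s1, e1, rightmost.closed = TRUE), 1L), bins)
  i2 <- pmin(pmax(findInterval(s2, e2, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(0, bins, bins)
  for (k in seq_along(i1)) counts[i1[k], i2[k]] <- counts[i1[k], i2[k]] + 1
  p <- counts / length(s1)
  pmax_ <- max(p)
  dg <- matrix(NA_real_, bins, bins)
  occ <- p > 0
  dg[occ] <- -log(p[occ] / pmax_)
  out <- tidyr::expand_grid(
    pc1 = (e1[-1L] + e1[-(bins + 1L)]) / 2,
    pc2 = (e2[-1L] + e2[-(bins + 1L)]) / 2)
  # expand_grid varies the last column fastest; counts[i1, i2] indexes rows
  # by pc1, so flatten with pc2 fastest.
  out$p <- as.vector(t(p))
  out$dg_kbt <- as.vector(t(dg))
  out$dg_kjmol <- out$dg_kbt * .KB_KJMOL * temperature
  attr(out, "edges_pc1") <- e1
  attr(out, "edges_pc2") <- e2
  attr(out, "temperature") <- temperature
  class(out) <- c("gag_fes", class(out))
  stopifnot(abs(sum(out$p) - 1) < 1e-9,
            min(out$dg_kbt, na.rm = TRUE) == 0,
            all(out$dg_kbt >= 0, na.rm = TRUE))
  out
}

#' K-means segregation of the PC projection with elbow selection
#'
#' Runs k-means (Hartigan-Wong, multi-restart with a fixed seed) for each
#' candidate k, records the inertia (total within-cluster sum of squares),
#' and selects k at the largest second difference of the inertia curve
#' relative to the local inertia (a scale-invariant elbow; ties go to the
#' smaller k). To keep the inertia curve non-increasing the k-th run
#' also tries a nested start seeded from the (k-1)-solution's centres plus
#' the worst-fit point, keeping whichever solution is better.
#'
#' @param projection A `gag_pca`.
#' @param k_range Candidate cluster counts (default 1:8).
#' @param seed Integer seed for the restarts.
#' @param nstart Random restarts per k (default 10).
#' @return A `gag_states`: list with `labels` (per frame), `k` (selected),
#'   `centers` (selected-k centres in PC space), `inertia` (tibble `k`,
#'   `inertia`), `populations`, and `selection` (rule trace).
#' @export
kmeans_with_elbow <- function(projection, k_range = 1:8, seed = 1L,
                              nstart = 10L) {
  stopifnot(inherits(projection, "gag_pca"))
  x <- as.matrix(projection$scores[, -1L, drop = FALSE])
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0L || any(k_range < 1L) || any(k_range > nrow(x))) {
    stop("k_range must be non-empty and within [1, n_frames]", call. = FALSE)
  }
  fits <- vector("list", length(k_range))
  prev <- NULL
  set.seed(as.integer(seed))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- suppressWarnings(stats::kmeans(x, centers = k, nstart = nstart,
                                          iter.max = 100L))
    if (!is.null(prev) && k > nrow(prev$centers)) {
      # nested start: previous centres plus the worst-fit point
      d2 <- rowSums((x - prev$centers[prev$cluster, , drop = FALSE])^2)
      extra <- x[which.max(d2), , drop = FALSE]
      start <- unique(rbind(prev$centers, extra))
      if (nrow(start) == k) {
        fit2 <- suppressWarnings(stats::kmeans(x, centers = start,
                                               iter.max = 100L))
        if (fit2$tot.withinss < fit$tot.withinss) fit <- fit2
      }
    }
    fits[[i]] <- fit
    prev <- fit
  }
  inertia <- vapply(fits, `[[`, numeric(1L), "tot.withinss")
  sel_i <- if (length(k_range) >= 3L) {
    # scale-invariant elbow: second difference of the inertia curve relative
    # to the local inertia, largest where the decrease flattens abruptly
    d2 <- diff(diff(inertia)) / pmax(inertia[2:(length(inertia) - 1L)],
                                     1e-12 * inertia[1L])
    which.max(d2) + 1L  # ties -> smaller k via which.max
  } else {
    length(k_range)
  }
  best <- fits[[sel_i]]
  structure(list(
    labels = best$cluster,
    k = k_range[sel_i],
    centers = best$centers,
    inertia = tibble::tibble(k = k_range, inertia = inertia),
    populations = as.vector(table(factor(best$cluster,
                                         levels = seq_len(k_range[sel_i])))) /
      nrow(x),
    selection = list(rule = "largest relative second difference of inertia",
                     k_range = k_range, selected = k_range[sel_i])),
    class = "gag_states")
}

#' @export
print.gag_states <- function(x, ...) {
  cat("<gag_states> k = ", x$k, " (", x$selection$rule, "); populations: ",
      paste(sprintf("%.1f%%", 100 * x$populations), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @rdname kmeans_with_elbow
#' @param x A `gag_states`.
#' @param ... Unused.
#' @method tidy gag_states
#' @export
tidy.gag_states <- function(x, ...) {
  tibble::tibble(state = seq_len(x$k),
                 population = x$populations,
                 center_pc1 = x$centers[, 1L],
                 center_pc2 = if (ncol(x$centers) > 1L) x$centers[, 2L] else NA_real_)
}

#' @rdname kmeans_with_elbow
#' @method glance gag_states
#' @export
glance.gag_states <- function(x, ...) {
  tibble::tibble(k = x$k, inertia = x$inertia$inertia[x$inertia$k == x$k],
                 n_frames = length(x$labels))
}

# circular mean (degrees) and circular standard error of the mean
.circ_mean_se <- function(deg) {
  rad <- deg * .DEG
  m <- atan2(mean(sin(rad)), mean(cos(rad))) / .DEG
  dev <- .wrap_deg(deg - m)
  se <- stats::sd(dev) / sqrt(length(dev))
  c(mean = m, se = se)
}

#' Representative structures per conformational state
#'
#' For each k-means state, picks the member frame closest (Euclidean, in PC
#' space) to the state's centre, and summarises the state: population,
#' end-to-end distance and hydrogen-bond count (mean +/- standard error),
#' and circular mean (phi, psi) per linkage class. Empty states are omitted.
#'
#' @param clustering A `gag_states` from [kmeans_with_elbow()].
#' @param projection The `gag_pca` the clustering was run on.
#' @param traj The underlying [gag_trajectory()].
#' @param features Optional feature tibble from [compute_features()]; if
#'   absent, end-to-end distances are computed and `n_hb` is reported as NA.
#' @return A `gag_state_report` tibble: one row per state with columns
#'   `state`, `population`, `centroid_frame`, `r_ee`, `r_ee_se`, `n_hb`,
#'   `n_hb_se`, `phi_l1`, `psi_l1`, `phi_l2`, `psi_l2` and their `_se`
#'   columns.
#' @export
representative_frames <- function(clustering, projection, traj,
                                  features = NULL) {
  stopifnot(inherits(clustering, "gag_states"), inherits(projection, "gag_pca"),
            inherits(traj, "gag_trajectory"))
  labels <- clustering$labels
  if (length(labels) != n_frames(traj)) {
    stop("labels do not cover all frames", call. = FALSE)
  }
  x <- as.matrix(projection$scores[, -1L, drop = FALSE])
  dih <- glycosidic_dihedrals(traj)
  ree <- if (!is.null(features)) features$r_ee else
    end_to_end_distance(traj)$r_ee
  nhb <- if (!is.null(features) && "n_hb" %in% names(features))
    features$n_hb else rep(NA_real_, length(labels))

  rows <- lapply(seq_len(clustering$k), function(s) {
    members <- which(labels == s)
    if (length(members) == 0L) return(NULL)
    d2 <- rowSums((x[members, , drop = FALSE] -
                     matrix(clustering$centers[s, ], length(members),
                            ncol(x), byrow = TRUE))^2)
    cen <- members[which.min(d2)]
    tor <- function(cls, col) {
      v <- dih[dih$linkage_class == cls & dih$frame %in% members, ][[col]]
      if (length(v) == 0L) return(c(mean = NA_real_, se = NA_real_))
      .circ_mean_se(v)
    }
    p1 <- tor("Linkage1", "phi"); s1 <- tor("Linkage1", "psi")
    p2 <- tor("Linkage2", "phi"); s2 <- tor("Linkage2", "psi")
    nh <- nhb[members]
    tibble::tibble(
      state = s,
      population = length(members) / length(labels),
      centroid_frame = cen,
      r_ee = mean(ree[members]),
      r_ee_se = stats::sd(ree[members]) / sqrt(length(members)),
      n_hb = mean(nh),
      n_hb_se = stats::sd(nh) / sqrt(length(members)),
      phi_l1 = p1[["mean"]], phi_l1_se = p1[["se"]],
      psi_l1 = s1[["mean"]], psi_l1_se = s1[["se"]],
      phi_l2 = p2[["mean"]], phi_l2_se = p2[["se"]],
      psi_l2 = s2[["mean"]], psi_l2_se = s2[["se"]])
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("gag_state_report", class(out))
  out
}
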