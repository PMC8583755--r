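# Per-frame structural and interaction observables: fitted RMSD, end-to-end
# distance, residue contact maps, glycosidic torsions and the collective
# dihedral-offset descriptor, geometric hydrogen bonds, cation RDFs and
# proximal-ion counts.

#' Least-squares fitted RMSD to a reference frame
#'
#' Each frame is rigid-body superposed (Kabsch, non-mass-weighted) onto the
#' reference over the selected atoms before the RMSD is taken. By default the
#' whole chain is used for both fitting and measurement.
#'
#' @param traj A [gag_trajectory()].
#' @param reference n_atoms x 3 reference coordinates (nm), e.g. from
#'   [build_extended_chain()].
#' @param selection Atom indices used for fit and RMSD (default: all).
#' @return A tibble with columns `frame`, `rmsd` (nm).
#' @export
fit_and_rmsd <- function(traj, reference, selection = NULL) {
  stopifnot(inherits(traj, "gag_trajectory"), is.matrix(reference))
  sel <- selection %||% seq_len(dim(traj$coords)[1L])
  if (length(sel) == 0L) stop("empty atom selection", call. = FALSE)
  if (nrow(reference) != dim(traj$coords)[1L]) {
    stop("atom-count mismatch: reference has ", nrow(reference),
         " atoms, trajectory has ", dim(traj$coords)[1L], call. = FALSE)
  }
  refsel <- reference[sel, , drop = FALSE]
  r <- vapply(seq_len(n_frames(traj)), function(i) {
    .fitted_rmsd(traj$coords[sel, , i], refsel)
  }, numeric(1L))
  tibble::tibble(frame = seq_len(n_frames(traj)), rmsd = r)
}

#' End-to-end distance
#'
#' Euclidean distance between the C1 atom of the starting (reducing-end)
#' residue and the C4 atom of the terminal residue, per frame. No periodic
#' wrapping is applied: the chain is kept whole.
#'
#' @param traj A [gag_trajectory()].
#' @param topology Defaults to the trajectory's own topology.
#' @return A tibble with columns `frame`, `r_ee` (nm).
#' @export
end_to_end_distance <- function(traj, topology = traj$topology) {
  stopifnot(inherits(traj, "gag_trajectory"))
  ep <- topology$ree_endpoints
  if (any(ep > dim(traj$coords)[1L])) {
    stop("end-to-end endpoint atoms missing from trajectory", call. = FALSE)
  }
  d <- traj$coords[ep[1L], , ] - traj$coords[ep[2L], , ]
  if (is.null(dim(d))) d <- matrix(d, nrow = 3L)
  tibble::tibble(frame = seq_len(n_frames(traj)), r_ee = sqrt(colSums(d^2)))
}

#' Residue-residue contact probability map
#'
#' Two residues are in contact in a frame when the minimum distance between
#' any pair of their atoms is at most `cutoff` (boundary inclusive).
#' Probabilities are frame averages. The diagonal and first off-diagonal are
#' computed but flagged `masked`, since self- and within-disaccharide
#' contacts are conventionally hidden in display.
#'
#' @param traj A [gag_trajectory()].
#' @param topology Defaults to the trajectory's own topology.
#' @param cutoff Contact distance cutoff (nm), default 0.4.
#' @return A `gag_contact_map`: tibble with columns `residue_a`, `residue_b`,
#'   `probability`, `masked`; the symmetric probability matrix is attached as
#'   attribute `"matrix"`.
#' @export
contact_probability_map <- function(traj, topology = traj$topology,
                                    cutoff = 0.4) {
  stopifnot(inherits(traj, "gag_trajectory"))
  .assert_positive(cutoff, "cutoff")
  nf <- n_frames(traj)
  res <- topology$atoms$residue
  n_res <- max(res)
  prob <- matrix(0, n_res, n_res)
  idx <- split(seq_along(res), res)
  for (i in seq_len(nf)) {
    xyz <- traj$coords[, , i]
    for (a in seq_len(n_res)) {
      pa <- xyz[idx[[a]], , drop = FALSE]
      for (b in a:n_res) {
        pb <- xyz[idx[[b]], , drop = FALSE]
        d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
        if (min(d2) <= cutoff^2 + 1e-12) {
          prob[a, b] <- prob[a, b] + 1
          if (a != b) prob[b, a] <- prob[b, a] + 1
        }
      }
    }
  }
  prob <- prob / nf
  out <- tidyr::expand_grid(residue_a = seq_len(n_res),
                            residue_b = seq_len(n_res))
  out$probability <- prob[cbind(out$residue_a, out$residue_b)]
  out$masked <- abs(out$residue_a - out$residue_b) <= 1L
  attr(out, "matrix") <- prob
  attr(out, "cutoff") <- cutoff
  class(out) <- c("gag_contact_map", class(out))
  out
}

#' Glycosidic phi/psi torsions per frame and linkage
#'
#' Signed torsions in (-180, 180] degrees over each linkage's phi quadruple
#' (ring oxygen, anomeric carbon, bridge oxygen, acceptor carbon) and psi
#' quadruple (anomeric carbon, bridge oxygen, acceptor carbon, preceding
#' acceptor carbon). Degenerate colinear geometry yields `NA`.
#'
#' @param traj A [gag_trajectory()].
#' @param topology Defaults to the trajectory's own topology.
#' @return A tibble with columns `frame`, `linkage`, `linkage_class`, `phi`,
#'   `psi` (degrees).
#' @export
glycosidic_dihedrals <- function(traj, topology = traj$topology) {
  stopifnot(inherits(traj, "gag_trajectory"))
  nf <- n_frames(traj)
  lk <- topology$linkages
  per_link <- function(quads) {
    lapply(quads, function(q) {
      .dihedral_frames(traj$coords[q[1L], , , drop = TRUE],
                       traj$coords[q[2L], , , drop = TRUE],
                       traj$coords[q[3L], , , drop = TRUE],
                       traj$coords[q[4L], , , drop = TRUE])
    })
  }
  # single-frame arrays drop to vectors; re-shape to 3 x nf
  if (nf == 1L) {
    per_link <- function(quads) {
      lapply(quads, function(q) {
        xyz <- traj$coords[, , 1L]
        dihedral_angle(xyz[q[1L], ], xyz[q[2L], ], xyz[q[3L], ], xyz[q[4L], ])
      })
    }
  }
  phi <- per_link(lk$phi_atoms)
  psi <- per_link(lk$psi_atoms)
  tibble::tibble(
    frame = rep(seq_len(nf), nrow(lk)),
    linkage = rep(lk$linkage, each = nf),
    linkage_class = rep(lk$linkage_class, each = nf),
    phi = unlist(phi), psi = unlist(psi))
}

#' Collective dihedral-offset descriptor
#'
#' For the N linkages of one class, averages the cosine closeness of (phi,
#' psi) to the reference torsions:
#' D = (1/N) sum_i [(1 + cos(phi_i - phi_ref)) + (1 + cos(psi_i - psi_ref))] / 2.
#' The per-linkage sum of the two cosine terms is divided by two so that a
#' conformation exactly at the reference scores 2 and the range is [0, 2]
#' (2 = fully extended; smaller values indicate deviation from linearity).
#'
#' @param dihedrals Tibble from [glycosidic_dihedrals()].
#' @param reference Tibble from [reference_torsions()].
#' @param linkage_class `"Linkage1"` or `"Linkage2"`.
#' @return A tibble with columns `frame`, `d_offset`.
#' @export
dihedral_offset <- function(dihedrals, reference,
                            linkage_class = c("Linkage1", "Linkage2")) {
  linkage_class <- match.arg(linkage_class)
  d <- dihedrals[dihedrals$linkage_class == linkage_class, ]
  if (nrow(d) == 0L) {
    stop("no linkages of class ", linkage_class, call. = FALSE)
  }
  r <- reference[match(d$linkage, reference$linkage), ]
  if (anyNA(r$phi_ref)) stop("reference does not cover all linkages", call. = FALSE)
  term <- ((1 + cos((d$phi - r$phi_ref) * .DEG)) +
           (1 + cos((d$psi - r$psi_ref) * .DEG))) / 2
  out <- tibble::tibble(frame = d$frame, term = term)
  out <- dplyr::summarise(dplyr::group_by(out, .data$frame),
                          d_offset = mean(.data$term), .groups = "drop")
  names(out) <- c("frame", "d_offset")
  out
}

#' Hydroxyl/amine donor-hydrogen pairs of the chain
#'
#' @param topology A [gag_topology()].
#' @return A tibble with columns `donor`, `hydrogen` (atom indices), matched
#'   by name within each residue (O2/HO2, O3/HO3, O4/HO4, O6/HO6, N2/HN2).
#' @export
donor_hydrogens <- function(topology) {
  at <- topology$atoms
  h <- at[at$element == "H", ]
  parent <- sub("^H", "", h$name)
  donor <- vapply(seq_len(nrow(h)), function(i) {
    j <- which(at$residue == h$residue[i] & at$name == parent[i])
    if (length(j) != 1L) NA_integer_ else j
  }, integer(1L))
  tibble::tibble(donor = donor, hydrogen = h$atom)[!is.na(donor), ]
}

#' Count geometric hydrogen bonds per frame
#'
#' A donor-acceptor pair is counted when the donor-acceptor distance is
#' strictly below `dist_cutoff` and the deviation of the D->H direction from
#' the D->A direction is below `angle_cutoff` degrees (the
#' deviation-from-linearity convention for the "donor-H-acceptor angle").
#'
#' @param traj A [gag_trajectory()].
#' @param donors Tibble with columns `donor`, `hydrogen` (atom indices);
#'   default: all chain hydroxyl/amine donors.
#' @param acceptors Either atom indices into the chain, or external acceptor
#'   positions: an m x 3 matrix (shared by all frames) or m x 3 x n_frames
#'   array, e.g. from [place_hbond_probes()].
#' @param dist_cutoff Donor-acceptor distance cutoff (nm), strict `<`.
#' @param angle_cutoff Angular deviation cutoff (degrees), strict `<`.
#' @return A tibble with columns `frame`, `n_hb`.
#' @export
count_hbonds <- function(traj, donors = donor_hydrogens(traj$topology),
                         acceptors, dist_cutoff = 0.35, angle_cutoff = 30) {
  stopifnot(inherits(traj, "gag_trajectory"))
  .assert_positive(dist_cutoff, "dist_cutoff")
  .assert_positive(angle_cutoff, "angle_cutoff")
  if (anyNA(donors$hydrogen) || nrow(donors) == 0L) {
    stop("every donor must carry a hydrogen", call. = FALSE)
  }
  nf <- n_frames(traj)
  external <- !(is.numeric(acceptors) && is.null(dim(acceptors)))
  if (external && is.matrix(acceptors)) {
    acceptors <- array(acceptors, c(dim(acceptors), nf))
  }
  n_hb <- integer(nf)
  for (i in seq_len(nf)) {
    xyz <- traj$coords[, , i]
    acc <- if (external) acceptors[, , i, drop = TRUE] else
      xyz[acceptors, , drop = FALSE]
    if (is.null(dim(acc))) acc <- matrix(acc, ncol = 3L)
    cnt <- 0L
    for (k in seq_len(nrow(donors))) {
      d <- xyz[donors$donor[k], ]
      h <- xyz[donors$hydrogen[k], ]
      da <- sweep(acc, 2L, d)
      dist <- .row_norms(da)
      u_dh <- .unit(h - d)
      cosang <- (da %*% u_dh) / pmax(dist, 1e-12)
      hit <- dist < dist_cutoff & dist > 1e-9 &
        acos(pmax(-1, pmin(1, cosang))) / .DEG < angle_cutoff
      cnt <- cnt + sum(hit)
    }
    n_hb[i] <- cnt
  }
  tibble::tibble(frame = seq_len(nf), n_hb = n_hb)
}

#' Cation radial distribution function around anionic groups
#'
#' Computes g(r) between the trajectory's ions and each oxygen group
#' (minimum-image distances in the cubic box), normalizes by the ideal-gas
#' shell count at the bulk ion density (n_ions / box volume), averages over
#' frames, and then averages the per-group profiles.
#'
#' @param traj A [gag_trajectory()] carrying ions and a box.
#' @param groups List of atom index vectors, e.g.
#'   `traj$topology$carboxylate_oxygens` (the default) or
#'   `$sulphate_oxygens`.
#' @param bin_width Radial bin width (nm).
#' @param r_max Maximal radius (nm); must not exceed half the box edge.
#' @return A `gag_rdf`: tibble with columns `r` (bin centres, nm), `g`.
#' @export
radial_distribution <- function(traj,
                                groups = traj$topology$carboxylate_oxygens,
                                bin_width = 0.002, r_max = 1.2) {
  stopifnot(inherits(traj, "gag_trajectory"))
  if (is.null(traj$ions) || dim(traj$ions)[1L] == 0L) {
    stop("trajectory carries no ions", call. = FALSE)
  }
  if (is.na(traj$box)) stop("periodic box required for RDFs", call. = FALSE)
  if (r_max > traj$box / 2) {
    stop("bin range exceeds half the box edge", call. = FALSE)
  }
  if (length(groups) == 0L) stop("at least one atom group required", call. = FALSE)
  .assert_positive(bin_width, "bin_width")

  nf <- n_frames(traj)
  n_ions <- dim(traj$ions)[1L]
  rho <- n_ions / traj$box^3
  edges <- seq(0, r_max, by = bin_width)
  nb <- length(edges) - 1L
  centers <- edges[-1L] - bin_width / 2
  shell_vol <- 4 / 3 * pi * (edges[-1L]^3 - edges[-(nb + 1L)]^3)

  g_groups <- vapply(groups, function(gidx) {
    counts <- numeric(nb)
    for (i in seq_len(nf)) {
      ref <- matrix(traj$coords[gidx, , i], ncol = 3L)
      ion <- traj$ions[, , i, drop = TRUE]
      if (is.null(dim(ion))) ion <- matrix(ion, ncol = 3L)
      for (a in seq_len(nrow(ref))) {
        d <- sweep(ion, 2L, ref[a, ])
        d <- .min_image(d, traj$box)
        r <- .row_norms(d)
        counts <- counts + tabulate(findInterval(r[r < r_max], edges,
                                                 left.open = TRUE), nb)
      }
    }
    counts / (nf * length(gidx)) / (rho * shell_vol)
  }, numeric(nb))

  out <- tibble::tibble(r = centers, g = rowMeans(g_groups))
  attr(out, "bin_width") <- bin_width
  attr(out, "n_groups") <- length(groups)
  class(out) <- c("gag_rdf", class(out))
  out
}

#' Ions proximal to the chain
#'
#' Number of ions whose minimum-image distance to any chain atom is at most
#' `cutoff`, per frame.
#'
#' @param traj A [gag_trajectory()] carrying ions.
#' @param cutoff Proximity cutoff (nm), default 0.5.
#' @return A tibble with columns `frame`, `n_proximal`.
#' @export
proximal_ion_count <- function(traj, cutoff = 0.5) {
  stopifnot(inherits(traj, "gag_trajectory"))
  .assert_positive(cutoff, "cutoff")
  nf <- n_frames(traj)
  if (is.null(traj$ions)) {
    return(tibble::tibble(frame = seq_len(nf), n_proximal = 0L))
  }
  cnt <- integer(nf)
  for (i in seq_len(nf)) {
    xyz <- traj$coords[, , i]
    ion <- traj$ions[, , i, drop = TRUE]
    if (is.null(dim(ion))) ion <- matrix(ion, ncol = 3L)
    near <- logical(nrow(ion))
    for (k in seq_len(nrow(ion))) {
      d <- sweep(xyz, 2L, ion[k, ])
      if (!is.na(traj$box)) d <- .min_image(d, traj$box)
      near[k] <- min(rowSums(d^2)) <= cutoff^2 + 1e-12
    }
    cnt[i] <- sum(near)
  }
  tibble::tibble(frame = seq_len(nf), n_proximal = cnt)
}

#' Assemble the per-frame feature table
#'
#' Computes the state-vector features (dihedral offsets of both linkage
#' classes, end-to-end distance, hydrogen-bond count) together with the
#' auxiliary fitted RMSD and, when ions are present, the proximal-ion count.
#' Without explicit water, `n_hb` counts hydrogen bonds to the supplied
#' acceptor probes and is zero when none are given.
#'
#' @param traj A [gag_trajectory()].
#' @param reference Reference frame for RMSD; defaults to the extended chain.
#' @param torsion_reference Reference torsions for the dihedral offsets.
#' @param hbond_acceptors Optional external acceptor positions passed to
#'   [count_hbonds()]; `NULL` gives `n_hb = 0`.
#' @param ion_cutoff Proximity cutoff (nm) for the ion count.
#' @return A tibble with one row per frame: `frame`, `d_offset_l1`,
#'   `d_offset_l2`, `r_ee`, `n_hb`, `rmsd` and, with ions, `n_proximal`.
#' @export
compute_features <- function(traj,
                             reference = build_extended_chain(traj$topology),
                             torsion_reference = reference_torsions(traj$topology),
                             hbond_acceptors = NULL, ion_cutoff = 0.5) {
  stopifnot(inherits(traj, "gag_trajectory"))
  dih <- glycosidic_dihedrals(traj)
  d1 <- dihedral_offset(dih, torsion_reference, "Linkage1")
  has_l2 <- any(traj$topology$linkages$linkage_class == "Linkage2")
  d2 <- if (has_l2) dihedral_offset(dih, torsion_reference, "Linkage2") else
    tibble::tibble(frame = d1$frame, d_offset = NA_real_)
  ree <- end_to_end_distance(traj)
  nhb <- if (is.null(hbond_acceptors)) {
    tibble::tibble(frame = d1$frame, n_hb = 0L)
  } else {
    count_hbonds(traj, acceptors = hbond_acceptors)
  }
  rms <- fit_and_rmsd(traj, reference)
  out <- tibble::tibble(frame = d1$frame,
                        d_offset_l1 = d1$d_offset,
                        d_offset_l2 = d2$d_offset,
                        r_ee = ree$r_ee,
                        n_hb = nhb$n_hb,
                        rmsd = rms$rmsd)
  if (!is.null(traj$ions)) {
    out$n_proximal <- proximal_ion_count(traj, cutoff = ion_cutoff)$n_proximal
  }
  out
}
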