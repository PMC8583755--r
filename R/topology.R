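# GAG chain chemistry: residue templates in an idealized 4C1 chair, linkage
# bookkeeping (Linkage1/Linkage2 with their phi/psi atom quadruples), anionic
# group atom sets, and the internal-coordinate chain builder.

.GAG_KINDS <- c("HA", "H6S", "C4S", "C6S")

# Amino-sugar residue code per GAG (GlcUA is "GU" in all of them).
.AMINO_CODE <- c(HA = "GlN", H6S = "aGlN", C4S = "GaN4", C6S = "GaN6")

#' Idealized geometry parameter set
#'
#' Bond lengths (nm) and angles (degrees) used for the rigid pyranose chair
#' templates and the glycosidic junctions. Ring pucker is fixed: every ring is
#' a symmetric 4C1-like chair; puckering dynamics are outside the scope of
#' this package.
#'
#' @param ring_bond Ring bond length (uniform over C-C and C-O ring bonds).
#' @param ring_pucker Half-amplitude of the chair's alternating out-of-plane
#'   displacement.
#' @param co_bond Exocyclic and glycosidic C-O bond length.
#' @param glyc_angle C-O-C angle at the glycosidic bridge oxygen.
#' @param tet_angle Tetrahedral angle used for sp3 substituents.
#' @return A named list of geometry parameters.
#' @export
gag_geometry <- function(ring_bond = 0.152, ring_pucker = 0.025,
                         co_bond = 0.142, glyc_angle = 117,
                         tet_angle = 109.47, beta_chir = 1) {
  list(ring_bond = ring_bond, ring_pucker = ring_pucker, co_bond = co_bond,
       glyc_angle = glyc_angle, tet_angle = tet_angle, beta_chir = beta_chir,
       oh_bond = 0.096, cc_bond = 0.152, cox_bond = 0.125,
       cn_bond = 0.147, nh_bond = 0.101, os_bond = 0.160, so_bond = 0.144)
}

.element_of <- function(name) {
  ifelse(substr(name, 1L, 1L) == "H", "H",
         substr(gsub("[0-9]", "", name), 1L, 1L))
}

# Rigid residue template in a local frame. Returns atom names and an m x 3
# coordinate matrix (nm). `drop_h` removes the hydroxyl hydrogen of the
# acceptor-site oxygen when the site carries a glycosidic bond.
.residue_template <- function(code, geom = gag_geometry()) {
  ring_names <- c("O5", "C1", "C2", "C3", "C4", "C5")
  q <- geom$ring_pucker
  r <- sqrt(geom$ring_bond^2 - 4 * q^2)
  k <- 0:5
  ring <- cbind(r * cos(k * pi / 3), r * sin(k * pi / 3), q * (-1)^k)
  rownames(ring) <- ring_names

  pos <- lapply(seq_len(6L), function(i) ring[i, ])
  names(pos) <- ring_names

  # equatorial / axial unit directions at each ring atom
  subdir <- function(at, which = c("eq", "ax")) {
    i <- match(at, ring_names)
    u1 <- .unit(ring[(i - 2L) %% 6L + 1L, ] - ring[i, ])
    u2 <- .unit(ring[i %% 6L + 1L, ] - ring[i, ])
    v1 <- .solve_direction(u1, u2, geom$tet_angle, geom$tet_angle, +1)
    v2 <- .solve_direction(u1, u2, geom$tet_angle, geom$tet_angle, -1)
    ax_first <- abs(v1[3L]) >= abs(v2[3L])
    which <- match.arg(which)
    if (which == "ax") (if (ax_first) v1 else v2) else (if (ax_first) v2 else v1)
  }
  add_sub <- function(name, parent, bond, which) {
    pos[[name]] <<- pos[[parent]] + bond * subdir(parent, which)
  }
  add_nerf <- function(name, a, b, c, bond, angle, torsion) {
    pos[[name]] <<- .place_atom(pos[[a]], pos[[b]], pos[[c]], bond, angle, torsion)
  }

  galacto <- code %in% c("GaN4", "GaN6")
  # position-2 substituent: carboxyl sugars carry a hydroxyl, amino sugars N
  if (code == "GU") {
    add_sub("O2", "C2", geom$co_bond, "eq")
    add_nerf("HO2", "C1", "C2", "O2", geom$oh_bond, geom$tet_angle, 180)
  } else {
    add_sub("N2", "C2", geom$cn_bond, "eq")
    add_nerf("HN2", "C1", "C2", "N2", geom$nh_bond, geom$tet_angle, 180)
  }
  add_sub("O3", "C3", geom$co_bond, "eq")
  add_nerf("HO3", "C2", "C3", "O3", geom$oh_bond, geom$tet_angle, 180)
  add_sub("O4", "C4", geom$co_bond, if (galacto) "ax" else "eq")
  add_sub("C6", "C5", geom$cc_bond, "eq")

  if (code == "GU") {
    # carboxylate: planar COO- on C6 (which is the carboxyl carbon)
    add_nerf("O6A", "C4", "C5", "C6", geom$cox_bond, 120, 0)
    add_nerf("O6B", "C4", "C5", "C6", geom$cox_bond, 120, 180)
    add_nerf("HO4", "C3", "C4", "O4", geom$oh_bond, geom$tet_angle, 180)
  } else {
    add_nerf("O6", "C4", "C5", "C6", geom$co_bond, geom$tet_angle, 180)
    if (code %in% c("aGlN", "GaN6")) {
      add_nerf("S", "C5", "C6", "O6", geom$os_bond, geom$glyc_angle, 180)
      add_nerf("O1S", "C6", "O6", "S", geom$so_bond, geom$tet_angle, 60)
      add_nerf("O2S", "C6", "O6", "S", geom$so_bond, geom$tet_angle, 180)
      add_nerf("O3S", "C6", "O6", "S", geom$so_bond, geom$tet_angle, 300)
    } else {
      add_nerf("HO6", "C5", "C6", "O6", geom$oh_bond, geom$tet_angle, 180)
    }
    if (code == "GaN4") {
      add_nerf("S", "C3", "C4", "O4", geom$os_bond, geom$glyc_angle, 180)
      add_nerf("O1S", "C4", "O4", "S", geom$so_bond, geom$tet_angle, 60)
      add_nerf("O2S", "C4", "O4", "S", geom$so_bond, geom$tet_angle, 180)
      add_nerf("O3S", "C4", "O4", "S", geom$so_bond, geom$tet_angle, 300)
    } else {
      add_nerf("HO4", "C3", "C4", "O4", geom$oh_bond, geom$tet_angle, 180)
    }
  }

  xyz <- do.call(rbind, pos)
  list(names = names(pos), xyz = xyz)
}

#' Build a GAG chain topology
#'
#' Encodes a repeating-disaccharide glycosaminoglycan chain: residue sequence,
#' glycosidic linkages with their phi/psi dihedral atom quadruples, anionic
#' group atom sets, and the end-to-end endpoint atoms (C1 of the starting,
#' reducing-end residue and C4 of the terminal residue). Residue 1 is the
#' reducing end; linkage j joins the C1 of residue j+1 to the bridge oxygen
#' of residue j. Odd-numbered linkages are Linkage1 (amino sugar 1->4 GlcUA),
#' even-numbered ones Linkage2, so a chain of n disaccharides carries n
#' Linkage1 and n-1 Linkage2 bonds.
#'
#' The four supported chains are hyaluronic acid (`"HA"`, unsulphated),
#' heparan-6-sulphate (`"H6S"`, alpha Linkage1, both linkages 1->4),
#' chondroitin-4-sulphate (`"C4S"`) and chondroitin-6-sulphate (`"C6S"`).
#' Sulphated chains carry one OSO3- per amino sugar, and every GlcUA carries
#' one COO-, so the formal charge is -(n) for HA and -(2n) for the sulphated
#' chains at n disaccharides.
#'
#' @param gag_kind One of `"HA"`, `"H6S"`, `"C4S"`, `"C6S"`.
#' @param n_disaccharides Number of repeating disaccharide units (>= 1).
#' @param geometry Geometry parameter set from [gag_geometry()].
#' @return An object of class `gag_topology`: a list with elements `gag_kind`,
#'   `n_disaccharides`, `residues` and `atoms` (tibbles), `linkages` (tibble
#'   with phi/psi atom index quadruples as list-columns), `carboxylate_oxygens`
#'   and `sulphate_oxygens` (lists of atom index vectors), `ree_endpoints`
#'   (length-2 atom index vector) and `formal_charge`.
#' @examples
#' top <- gag_topology("HA", 5)
#' table(top$linkages$linkage_class)
#' @export
gag_topology <- function(gag_kind, n_disaccharides = 5,
                         geometry = gag_geometry()) {
  if (length(gag_kind) != 1L || !gag_kind %in% .GAG_KINDS) {
    stop("unknown gag_kind ", deparse(gag_kind), "; valid codes are: ",
         paste(.GAG_KINDS, collapse = ", "), call. = FALSE)
  }
  n_disaccharides <- as.integer(n_disaccharides)
  if (is.na(n_disaccharides) || n_disaccharides < 1L) {
    stop("n_disaccharides must be a positive integer", call. = FALSE)
  }

  n_res <- 2L * n_disaccharides
  amino <- .AMINO_CODE[[gag_kind]]
  codes <- ifelse(seq_len(n_res) %% 2L == 1L, "GU", amino)

  n_link <- n_res - 1L
  link_class <- ifelse(seq_len(n_link) %% 2L == 1L, "Linkage1", "Linkage2")
  # bridge oxygen on the acceptor residue: O4 for 1->4, O3 for 1->3 links
  bridge <- ifelse(link_class == "Linkage1", "O4",
                   if (gag_kind == "H6S") "O4" else "O3")
  anomer <- ifelse(link_class == "Linkage1" & gag_kind == "H6S",
                   "alpha", "beta")

  templates <- list(GU = .residue_template("GU", geometry))
  templates[[amino]] <- .residue_template(amino, geometry)

  # assemble atoms, dropping the hydroxyl H of each occupied acceptor site
  res_atoms <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    tpl <- templates[[codes[i]]]
    keep <- rep(TRUE, length(tpl$names))
    if (i < n_res) {  # residue i accepts linkage i at its bridge oxygen
      keep[tpl$names == paste0("H", bridge[i])] <- FALSE
    }
    res_atoms[[i]] <- list(names = tpl$names[keep], xyz = tpl$xyz[keep, , drop = FALSE])
  }
  counts <- vapply(res_atoms, function(x) length(x$names), integer(1L))
  offset <- cumsum(c(0L, counts[-n_res]))

  atoms <- tibble::tibble(
    atom = seq_len(sum(counts)),
    name = unlist(lapply(res_atoms, `[[`, "names")),
    residue = rep(seq_len(n_res), counts),
    code = rep(codes, counts)
  )
  atoms$element <- .element_of(atoms$name)

  idx <- function(res, name) {
    j <- match(name, res_atoms[[res]]$names)
    if (is.na(j)) stop("atom ", name, " missing in residue ", res, call. = FALSE)
    offset[res] + j
  }

  phi_atoms <- vector("list", n_link)
  psi_atoms <- vector("list", n_link)
  for (j in seq_len(n_link)) {
    don <- j + 1L
    acc <- j
    ob <- bridge[j]
    cb <- sub("O", "C", ob)                        # C4 or C3
    cp <- paste0("C", as.integer(sub("O", "", ob)) - 1L)  # C3 or C2
    phi_atoms[[j]] <- c(idx(don, "O5"), idx(don, "C1"), idx(acc, ob), idx(acc, cb))
    psi_atoms[[j]] <- c(idx(don, "C1"), idx(acc, ob), idx(acc, cb), idx(acc, cp))
  }

  linkages <- tibble::tibble(
    linkage = seq_len(n_link),
    linkage_class = link_class,
    donor_residue = seq_len(n_link) + 1L,
    acceptor_residue = seq_len(n_link),
    bridge_oxygen = bridge,
    anomer = anomer,
    phi_atoms = phi_atoms,
    psi_atoms = psi_atoms
  )

  carbox <- lapply(which(codes == "GU"), function(i) c(idx(i, "O6A"), idx(i, "O6B")))
  sulph <- if (gag_kind == "HA") list() else
    lapply(which(codes == amino), function(i) c(idx(i, "O1S"), idx(i, "O2S"), idx(i, "O3S")))

  structure(list(
    gag_kind = gag_kind,
    n_disaccharides = n_disaccharides,
    geometry = geometry,
    residues = tibble::tibble(residue = seq_len(n_res), code = codes),
    atoms = atoms,
    linkages = linkages,
    carboxylate_oxygens = carbox,
    sulphate_oxygens = sulph,
    ree_endpoints = c(idx(1L, "C1"), idx(n_res, "C4")),
    formal_charge = -(length(carbox) + length(sulph)),
    .residue_geometry = lapply(seq_len(n_res), function(i) {
      list(names = res_atoms[[i]]$names, xyz = res_atoms[[i]]$xyz,
           global = offset[i] + seq_along(res_atoms[[i]]$names))
    })
  ), class = "gag_topology")
}

#' @export
print.gag_topology <- function(x, ...) {
  cat("<gag_topology> ", x$gag_kind, ": ", x$n_disaccharides,
      " disaccharides, ", nrow(x$atoms), " atoms, ",
      sum(x$linkages$linkage_class == "Linkage1"), " Linkage1 + ",
      sum(x$linkages$linkage_class == "Linkage2"), " Linkage2 linkages, ",
      "formal charge ", x$formal_charge, "\n", sep = "")
  invisible(x)
}

# Reference (phi, psi) per GAG and linkage class (degrees).
#
# "idealized_extended": torsions that maximize the end-to-end distance of the
# rigid-chair chain model; frozen once from a one-time optimization of the
# default gag_geometry(). They define "fully extended" for this package and
# give Ree = 4.88 nm (HA/C4S/C6S) and 4.76 nm (H6S) for penta-disaccharides.
#
# "force_field_start": typical starting-structure torsions of extended GAG
# chains built with an all-atom carbohydrate force field, provided for
# comparison with atomistic trajectories.
.REF_TORSIONS <- list(
  idealized_extended = list(
    HA  = list(Linkage1 = c(67.90, -120.10), Linkage2 = c(120.45, -173.07)),
    H6S = list(Linkage1 = c(-99.23, -29.11), Linkage2 = c(120.24, -119.76)),
    C4S = list(Linkage1 = c(67.90, -120.10), Linkage2 = c(120.45, -173.07)),
    C6S = list(Linkage1 = c(67.90, -120.10), Linkage2 = c(120.45, -173.07))
  ),
  force_field_start = list(
    HA  = list(Linkage1 = c(-132.1, -146.1), Linkage2 = c(-93.4, 76.1)),
    H6S = list(Linkage1 = c(-111.6, 87.2),   Linkage2 = c(45.6, 64.3)),
    C4S = list(Linkage1 = c(-139.4, -146.9), Linkage2 = c(-102.8, 91.1)),
    C6S = list(Linkage1 = c(-120.8, -156.3), Linkage2 = c(-106.6, 87.4))
  )
)

#' Reference glycosidic torsions of the fully extended chain
#'
#' Per-linkage (phi_ref, psi_ref) in degrees, as present in the fully
#' extended starting structure. These anchor the dihedral-offset descriptor:
#' a conformation at exactly these torsions scores the maximal offset value
#' of 2. The default `"idealized_extended"` set contains the torsions that
#' maximize the end-to-end distance of the package's rigid-chair chain model;
#' `"force_field_start"` holds typical extended-chain starting torsions from
#' all-atom carbohydrate force-field models, for comparison with atomistic
#' trajectories.
#'
#' @param topology A [gag_topology()].
#' @param source Which reference set to use (ignored when `phi_psi` is given).
#' @param phi_psi Optional override: named list with `Linkage1` and `Linkage2`
#'   entries, each `c(phi, psi)` in degrees.
#' @return A tibble with columns `linkage`, `linkage_class`, `phi_ref`,
#'   `psi_ref`.
#' @export
reference_torsions <- function(topology,
                               source = c("idealized_extended", "force_field_start"),
                               phi_psi = NULL) {
  stopifnot(inherits(topology, "gag_topology"))
  source <- match.arg(source)
  tab <- phi_psi %||% .REF_TORSIONS[[source]][[topology$gag_kind]]
  cls <- topology$linkages$linkage_class
  tibble::tibble(
    linkage = topology$linkages$linkage,
    linkage_class = cls,
    phi_ref = vapply(cls, function(k) tab[[k]][1L], numeric(1L),
                     USE.NAMES = FALSE),
    psi_ref = vapply(cls, function(k) tab[[k]][2L], numeric(1L),
                     USE.NAMES = FALSE)
  )
}

# Build Cartesian coordinates (n_atoms x 3, nm) from per-linkage torsions.
# phi_psi: n_linkages x 2 matrix in degrees.
.build_chain <- function(topology, phi_psi) {
  geom <- topology$geometry
  rg <- topology$.residue_geometry
  n_res <- nrow(topology$residues)
  coords <- matrix(NA_real_, nrow(topology$atoms), 3L)
  coords[rg[[1L]]$global, ] <- rg[[1L]]$xyz

  for (j in seq_len(nrow(topology$linkages))) {
    lk <- topology$linkages[j, ]
    acc <- rg[[lk$acceptor_residue]]
    don <- rg[[lk$donor_residue]]
    ob <- lk$bridge_oxygen
    cb <- sub("O", "C", ob)
    cp <- paste0("C", as.integer(sub("O", "", ob)) - 1L)
    p_ob <- coords[acc$global[match(ob, acc$names)], ]
    p_cb <- coords[acc$global[match(cb, acc$names)], ]
    p_cp <- coords[acc$global[match(cp, acc$names)], ]

    # psi places the donor anomeric carbon, phi the donor ring oxygen
    p_c1 <- .place_atom(p_cp, p_cb, p_ob, geom$co_bond, geom$glyc_angle,
                        phi_psi[j, 2L])
    i_c1 <- match("C1", don$names)
    i_o5 <- match("O5", don$names)
    i_c2 <- match("C2", don$names)
    b_c1o5 <- .vnorm(don$xyz[i_o5, ] - don$xyz[i_c1, ])
    b_c1c2 <- .vnorm(don$xyz[i_c2, ] - don$xyz[i_c1, ])
    gamma1 <- acos(sum(.unit(don$xyz[i_o5, ] - don$xyz[i_c1, ]) *
                       .unit(don$xyz[i_c2, ] - don$xyz[i_c1, ]))) / .DEG
    p_o5 <- .place_atom(p_cb, p_ob, p_c1, b_c1o5, geom$tet_angle,
                        phi_psi[j, 1L])
    chir <- if (lk$anomer == "beta") geom$beta_chir else -geom$beta_chir
    v_c2 <- .solve_direction(.unit(p_o5 - p_c1), .unit(p_ob - p_c1),
                             gamma1, geom$tet_angle, chir)
    p_c2 <- p_c1 + b_c1c2 * v_c2

    fit <- .kabsch(don$xyz[c(i_c1, i_o5, i_c2), ], rbind(p_c1, p_o5, p_c2))
    coords[don$global, ] <- .apply_kabsch(fit, don$xyz)
  }
  coords
}

#' Build the idealized fully extended chain
#'
#' Places every residue on the rigid chair template and sets each glycosidic
#' (phi, psi) to the reference torsions, giving a reproducible, maximally
#' extended single-frame structure. The construction is fully deterministic:
#' identical inputs give bit-identical coordinates.
#'
#' @param topology A [gag_topology()].
#' @param reference Reference torsions tibble from [reference_torsions()].
#' @return An n_atoms x 3 coordinate matrix (nm) with the atom-name vector as
#'   rownames.
#' @examples
#' top <- gag_topology("HA", 5)
#' xyz <- build_extended_chain(top)
#' @export
build_extended_chain <- function(topology, reference = reference_torsions(topology)) {
  stopifnot(inherits(topology, "gag_topology"))
  if (nrow(reference) != nrow(topology$linkages)) {
    stop("reference must contain one row per linkage", call. = FALSE)
  }
  xyz <- .build_chain(topology, cbind(reference$phi_ref, reference$psi_ref))
  rownames(xyz) <- topology$atoms$name
  xyz
}
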