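# Standard-format readers/writers, pipeline configuration and the
# end-to-end orchestration: simulate -> features -> clustering -> FES.
# Internally all coordinates are nm; the PDB boundary converts to/from
# Angstrom. Atom and frame indices are 1-based in R; the topology sidecar
# JSON uses 0-based atom indices alongside 1-based PDB serials.

.ION_RESID <- "SOD"

# PDB resName is a 3-character column; map the package's residue codes to
# 3-char aliases at the format boundary.
.PDB_RESID <- c(GU = "GCU", GlN = "NAG", aGlN = "NGS", GaN4 = "G4S",
                GaN6 = "G6S")

#' Export a topology as PDB plus a JSON sidecar
#'
#' Writes the idealized extended structure as a single-MODEL PDB (Angstrom)
#' and a machine-readable sidecar listing the linkage dihedral quadruples and
#' anionic-group atom indices (0-based in the sidecar; PDB serials 1-based).
#'
#' @param topology A [gag_topology()].
#' @param pdb_path Output PDB path.
#' @param sidecar_path Output JSON path (default: `pdb_path` + ".json").
#' @return Invisibly, the sidecar list.
#' @export
export_topology <- function(topology, pdb_path,
                            sidecar_path = paste0(pdb_path, ".json")) {
  stopifnot(inherits(topology, "gag_topology"))
  xyz <- build_extended_chain(topology)
  at <- topology$atoms
  bio3d::write.pdb(file = pdb_path,
                   xyz = as.vector(t(xyz)) * 10,
                   resno = at$residue, resid = unname(.PDB_RESID[at$code]),
                   elety = at$name)
  side <- list(
    gag_kind = topology$gag_kind,
    n_disaccharides = topology$n_disaccharides,
    linkages = lapply(seq_len(nrow(topology$linkages)), function(j) list(
      linkage = j,
      linkage_class = topology$linkages$linkage_class[j],
      phi_atoms = topology$linkages$phi_atoms[[j]] - 1L,
      psi_atoms = topology$linkages$psi_atoms[[j]] - 1L)),
    carboxylate_oxygens = lapply(topology$carboxylate_oxygens, function(v) v - 1L),
    sulphate_oxygens = lapply(topology$sulphate_oxygens, function(v) v - 1L),
    ree_endpoints = topology$ree_endpoints - 1L,
    formal_charge = topology$formal_charge)
  jsonlite::write_json(side, sidecar_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(side)
}

#' Write a trajectory as a multi-model PDB with a manifest
#'
#' Chain atoms and (if present) ions are written per frame as PDB MODELs in
#' Angstrom; ions appear as `SOD` residues after the chain. A JSON manifest
#' alongside records the topology identity, box and frame count, since the
#' PDB format itself does not carry the cubic box used for minimum-image
#' distances.
#'
#' @param traj A [gag_trajectory()].
#' @param path Output PDB path.
#' @param manifest_path JSON manifest path (default: `path` + ".json").
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path, manifest_path = paste0(path, ".json")) {
  stopifnot(inherits(traj, "gag_trajectory"))
  nf <- n_frames(traj)
  at <- traj$topology$atoms
  n_ions <- if (is.null(traj$ions)) 0L else dim(traj$ions)[1L]
  xyz <- t(vapply(seq_len(nf), function(i) {
    m <- traj$coords[, , i]
    if (n_ions > 0L) m <- rbind(m, matrix(traj$ions[, , i], n_ions, 3L))
    as.vector(t(m)) * 10
  }, numeric(3L * (nrow(at) + n_ions))))
  resno <- c(at$residue, max(at$residue) + seq_len(n_ions))
  resid <- c(unname(.PDB_RESID[at$code]), rep(.ION_RESID, n_ions))
  elety <- c(at$name, rep(.ION_RESID, n_ions))
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, resid = resid,
                   elety = elety)
  jsonlite::write_json(list(
    gag_kind = traj$topology$gag_kind,
    n_disaccharides = traj$topology$n_disaccharides,
    n_frames = nf, n_ions = n_ions, box = traj$box,
    units = "nm in package, Angstrom in PDB"),
    manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a trajectory from a multi-model PDB
#'
#' Coordinates are returned in nm regardless of the source's Angstrom
#' convention. Ion records (`SOD` residues) are split off into the ion set.
#' The cubic box is taken from the JSON manifest when present.
#'
#' @param path Multi-model PDB path.
#' @param topology The expected [gag_topology()]; atom count and names are
#'   validated against the file.
#' @param manifest_path Manifest JSON path (default: `path` + ".json"); if
#'   missing, the box is `NA`.
#' @return A [gag_trajectory()].
#' @export
read_trajectory <- function(path, topology,
                            manifest_path = paste0(path, ".json")) {
  stopifnot(inherits(topology, "gag_topology"))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  is_ion <- pdb$atom$resid == .ION_RESID
  n_chain <- sum(!is_ion)
  if (n_chain != nrow(topology$atoms)) {
    stop("atom-count mismatch in ", path, ": file has ", n_chain,
         " chain atoms, topology has ", nrow(topology$atoms), call. = FALSE)
  }
  if (!all(trimws(pdb$atom$elety[!is_ion]) == topology$atoms$name)) {
    stop("atom names in ", path, " do not match the topology", call. = FALSE)
  }
  xyz <- pdb$xyz / 10
  nf <- nrow(xyz)
  n_at <- ncol(xyz) / 3L
  all_coords <- array(NA_real_, c(n_at, 3L, nf))
  for (i in seq_len(nf)) all_coords[, , i] <- matrix(xyz[i, ], n_at, 3L, byrow = TRUE)
  box <- NA_real_
  if (file.exists(manifest_path)) {
    man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    box <- man$box %||% NA_real_
    if (!is.null(man$n_frames) && man$n_frames != nf) {
      stop("truncated trajectory ", path, ": manifest declares ",
           man$n_frames, " frames, last complete frame read is ", nf,
           call. = FALSE)
    }
  }
  gag_trajectory(all_coords[!is_ion, , , drop = FALSE], topology, box = box,
                 ions = if (any(is_ion)) all_coords[is_ion, , , drop = FALSE])
}

#' Pipeline configuration
#'
#' Bundles every tunable of the simulate -> features -> clustering -> FES
#' pipeline, with the conventional defaults: 0.4 nm contact cutoff,
#' 0.35 nm / 30 degree hydrogen-bond criterion, 0.5 nm ion-proximity cutoff,
#' RMSD clustering cutoffs {0.3, 0.4, 0.5} nm and T = 300 K. The
#' configuration round-trips losslessly through YAML
#' ([write_config()] / [read_config()]).
#'
#' @param gag_kind GAG code.
#' @param output_dir Directory the pipeline writes into.
#' @param n_disaccharides,n_frames,seed Ensemble size and seed.
#' @param weights,concentration Two-state mixture parameters.
#' @param n_ions Cation count; `NULL` means exactly charge-neutralizing.
#' @param box Cubic box edge (nm).
#' @param contact_cutoff,hbond_dist,hbond_angle,ion_cutoff Feature cutoffs.
#' @param rmsd_cutoffs RMSD clustering cutoffs (nm).
#' @param cluster_max_frames Leading frames used for the all-vs-all RMSD
#'   clustering stage.
#' @param temperature Temperature (K) for the free-energy conversion.
#' @param fes_bins FES bins per axis.
#' @param k_range,kmeans_nstart K-means candidates and restarts.
#' @return A `gag_config` list.
#' @export
gag_pipeline_config <- function(gag_kind = "HA", output_dir,
                                n_disaccharides = 5L, n_frames = 1000L,
                                seed = 1L, weights = c(0.7, 0.3),
                                concentration = 20, n_ions = NULL, box = 6.8,
                                contact_cutoff = 0.4, hbond_dist = 0.35,
                                hbond_angle = 30, ion_cutoff = 0.5,
                                rmsd_cutoffs = c(0.3, 0.4, 0.5),
                                cluster_max_frames = 300L, temperature = 300,
                                fes_bins = 50L, k_range = 1:8,
                                kmeans_nstart = 10L) {
  cfg <- list(gag_kind = gag_kind, output_dir = output_dir,
              n_disaccharides = as.integer(n_disaccharides),
              n_frames = as.integer(n_frames), seed = as.integer(seed),
              weights = weights, concentration = concentration,
              n_ions = n_ions, box = box,
              contact_cutoff = contact_cutoff, hbond_dist = hbond_dist,
              hbond_angle = hbond_angle, ion_cutoff = ion_cutoff,
              rmsd_cutoffs = rmsd_cutoffs,
              cluster_max_frames = as.integer(cluster_max_frames),
              temperature = temperature, fes_bins = as.integer(fes_bins),
              k_range = as.integer(k_range),
              kmeans_nstart = as.integer(kmeans_nstart))
  class(cfg) <- "gag_config"
  validate_config(cfg)
  cfg
}

#' @rdname gag_pipeline_config
#' @param config A `gag_config`.
#' @export
validate_config <- function(config) {
  if (!config$gag_kind %in% .GAG_KINDS) {
    stop("unknown gag_kind ", deparse(config$gag_kind), "; valid codes are: ",
         paste(.GAG_KINDS, collapse = ", "), call. = FALSE)
  }
  cuts <- c(contact_cutoff = config$contact_cutoff,
            hbond_dist = config$hbond_dist, hbond_angle = config$hbond_angle,
            ion_cutoff = config$ion_cutoff, box = config$box,
            temperature = config$temperature, config$rmsd_cutoffs)
  bad <- names(cuts)[!is.finite(cuts) | cuts <= 0]
  if (length(bad) > 0L) {
    stop("cutoffs must be positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(config$weights <= 0)) stop("weights must be positive", call. = FALSE)
  invisible(config)
}

#' @rdname gag_pipeline_config
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname gag_pipeline_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$k_range <- as.integer(cfg$k_range)
  class(cfg) <- "gag_config"
  validate_config(cfg)
  cfg
}

.write_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) a trajectory, computes the feature table, runs the
#' neighbour-count RMSD clustering at each configured cutoff, builds the
#' PCA / free-energy-surface / k-means stage, and writes every artifact as
#' CSV/JSON into `config$output_dir` together with a provenance manifest
#' (configuration, its hash, and the full output list). Reruns with an
#' identical configuration produce byte-identical outputs. A stage failure
#' aborts with the stage name; artifacts of completed stages are preserved.
#'
#' @param config A `gag_config` from [gag_pipeline_config()] or a YAML path.
#' @param traj Optional pre-existing [gag_trajectory()]; by default a
#'   two-state synthetic ensemble is generated from the configuration.
#' @return Invisibly, a list with the in-memory results of each stage.
#' @export
run_gag_pipeline <- function(config, traj = NULL) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out_files <- character(0L)
  emit <- function(x, name) {
    p <- file.path(config$output_dir, name)
    .write_csv(x, p)
    out_files <<- c(out_files, name)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  top <- gag_topology(config$gag_kind, config$n_disaccharides)

  traj <- stage("simulate", {
    if (is.null(traj)) {
      n_ions <- config$n_ions %||% -top$formal_charge
      im <- if (n_ions > 0L) {
        ion_model("uniform_bulk", n_ions = n_ions, box = config$box)
      }
      sample_ensemble(two_state_spec(top, n_frames = config$n_frames,
                                     seed = config$seed,
                                     weights = config$weights,
                                     concentration = config$concentration,
                                     ion_model = im))
    } else traj
  })

  feats <- stage("features", {
    f <- compute_features(traj, ion_cutoff = config$ion_cutoff)
    emit(f, "features.csv")
    jsonlite::write_json(list(
      contact_cutoff_nm = config$contact_cutoff,
      hbond_dist_nm = config$hbond_dist, hbond_angle_deg = config$hbond_angle,
      ion_cutoff_nm = config$ion_cutoff,
      d_offset_normalization = "per-linkage cosine pair averaged: reference scores 2, range [0, 2]",
      distances = "nm", angles = "degrees"),
      file.path(config$output_dir, "features_conventions.json"),
      auto_unbox = TRUE, pretty = TRUE)
    out_files <- c(out_files, "features_conventions.json")
    cmap <- contact_probability_map(traj, cutoff = config$contact_cutoff)
    emit(as.data.frame(cmap[, c("residue_a", "residue_b", "probability",
                                "masked")]), "contact_map.csv")
    list(features = f, contact_map = cmap)
  })

  clust <- stage("cluster", {
    n_sub <- min(n_frames(traj), config$cluster_max_frames)
    sub <- .subset_frames(traj, seq_len(n_sub))
    m <- pairwise_rmsd_matrix(sub)
    checkpoints <- unique(round(seq(max(2L, n_sub %/% 10L), n_sub,
                                    length.out = 10L)))
    res <- lapply(config$rmsd_cutoffs, function(cut) {
      cl <- daura_cluster(m, cut)
      ev <- cluster_count_evolution(m, cut, checkpoints)
      list(cutoff = cut, clusters = cl, evolution = ev)
    })
    assign_tab <- dplyr::bind_rows(lapply(res, function(r) {
      dplyr::mutate(r$clusters$assignments, cutoff = r$cutoff)
    }))
    emit(assign_tab, "cluster_assignments.csv")
    evo_tab <- dplyr::bind_rows(lapply(res, function(r) {
      dplyr::mutate(r$evolution, cutoff = r$cutoff)
    }))
    emit(evo_tab, "cluster_evolution.csv")
    res
  })

  fes <- stage("fes", {
    sm <- assemble_state_matrix(feats$features)
    pca <- principal_components(sm, k_pc = 2L)
    surf <- free_energy_surface(pca, bins = config$fes_bins,
                                temperature = config$temperature)
    emit(as.data.frame(surf), "fes_grid.csv")
    states <- kmeans_with_elbow(pca, k_range = config$k_range,
                                seed = config$seed,
                                nstart = config$kmeans_nstart)
    emit(tibble::tibble(frame = seq_along(states$labels),
                        state = states$labels), "state_labels.csv")
    emit(states$inertia, "kmeans_inertia.csv")
    report <- representative_frames(states, pca, traj,
                                    features = feats$features)
    emit(as.data.frame(report), "state_report.csv")
    jsonlite::write_json(list(
      loadings = apply(pca$loadings, 2L, stats::setNames,
                       rownames(pca$loadings), simplify = FALSE),
      explained_variance = pca$explained,
      standardized = TRUE),
      file.path(config$output_dir, "pca.json"), auto_unbox = TRUE,
      pretty = TRUE, digits = NA)
    out_files <- c(out_files, "pca.json")
    list(pca = pca, surface = surf, states = states, report = report)
  })

  rdf <- NULL
  if (!is.null(traj$ions) && dim(traj$ions)[1L] > 0L) {
    rdf <- stage("rdf", {
      r <- radial_distribution(traj, bin_width = 0.02)
      emit(as.data.frame(r), "rdf_carboxylate.csv")
      if (length(traj$topology$sulphate_oxygens) > 0L) {
        rs <- radial_distribution(traj, groups = traj$topology$sulphate_oxygens,
                                  bin_width = 0.02)
        emit(as.data.frame(rs), "rdf_sulphate.csv")
      }
      r
    })
  }

  # the hash and echoed config cover the scientific configuration only, not
  # the output location, so reruns into different directories compare equal
  cfg_echo <- unclass(config)
  cfg_echo$output_dir <- NULL
  manifest <- list(config = cfg_echo,
                   config_hash = rlang::hash(cfg_echo),
                   outputs = c(out_files, "manifest.json"))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(trajectory = traj, features = feats$features,
                 contact_map = feats$contact_map, clustering = clust,
                 fes = fes, rdf = rdf,
                 manifest = file.path(config$output_dir, "manifest.json")))
}
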