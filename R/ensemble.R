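# Synthetic conformational ensembles with known statistical structure.
#
# Frames are drawn from a mixture of conformational states. Each state holds
# per-linkage-class mean torsions and an angular concentration; per frame,
# every linkage's (phi, psi) is sampled independently from a von Mises
# distribution around the state means and the chain is rebuilt on the rigid
# chair geometry. Optional monovalent cations are placed either uniformly in
# the box or on shells around chosen target atoms, giving analytic
# expectations for the radial-distribution and proximal-ion features.

#' Define a conformational state of the torsion mixture
#'
#' @param mean Named list with `Linkage1` and `Linkage2` entries, each
#'   `c(phi, psi)` in degrees: the state's mean torsions per linkage class.
#' @param concentration Von Mises concentration kappa (dimensionless, >= 0;
#'   0 is uniform on the circle, large values approach a delta).
#' @param weight Positive mixture weight (normalized across states).
#' @return An object of class `gag_state_spec`.
#' @export
conformational_state <- function(mean, concentration = 20, weight = 1) {
  stopifnot(is.list(mean), all(c("Linkage1", "Linkage2") %in% names(mean)) ||
              "Linkage1" %in% names(mean))
  if (!is.numeric(concentration) || any(concentration < 0) ||
      any(!is.finite(concentration))) {
    stop("concentration must be finite and >= 0", call. = FALSE)
  }
  .assert_positive(weight, "weight")
  structure(list(mean = mean, concentration = concentration, weight = weight),
            class = "gag_state_spec")
}

#' Define an ion placement model
#'
#' @param mode `"uniform_bulk"` (positions i.i.d. uniform in the box) or
#'   `"shell"` (positions uniform on a thin radial shell around randomly
#'   chosen target atoms).
#' @param n_ions Number of cations (>= 0).
#' @param box Cubic box edge (nm); the default mirrors a solvated
#'   penta-disaccharide setup.
#' @param target_atoms Atom indices the shells are centred on (shell mode).
#' @param shell_radius,shell_width Shell centre radius and radial width (nm).
#' @return An object of class `gag_ion_model`.
#' @export
ion_model <- function(mode = c("uniform_bulk", "shell"), n_ions, box = 6.8,
                      target_atoms = NULL, shell_radius = 0.25,
                      shell_width = 0.02) {
  mode <- match.arg(mode)
  n_ions <- as.integer(n_ions)
  stopifnot(!is.na(n_ions), n_ions >= 0L)
  .assert_positive(box, "box")
  if (mode == "shell") {
    if (is.null(target_atoms) || length(target_atoms) == 0L) {
      stop("shell mode requires target_atoms", call. = FALSE)
    }
    .assert_positive(shell_radius, "shell_radius")
    if (shell_radius + shell_width / 2 > box / 2) {
      stop("shell radius exceeds half the box edge: periodic-image ambiguity",
           call. = FALSE)
    }
  }
  structure(list(mode = mode, n_ions = n_ions, box = box,
                 target_atoms = target_atoms, shell_radius = shell_radius,
                 shell_width = shell_width),
            class = "gag_ion_model")
}

#' Specify a synthetic ensemble
#'
#' @param topology A [gag_topology()].
#' @param states List of [conformational_state()] objects (mixture
#'   components). Weights are normalized to sum to one.
#' @param n_frames Number of frames to draw (>= 1).
#' @param seed Integer seed; identical specs give bit-identical trajectories.
#' @param ion_model Optional [ion_model()].
#' @return An object of class `gag_ensemble_spec`.
#' @export
ensemble_spec <- function(topology, states, n_frames = 1000L, seed = 1L,
                          ion_model = NULL) {
  stopifnot(inherits(topology, "gag_topology"))
  if (inherits(states, "gag_state_spec")) states <- list(states)
  stopifnot(length(states) >= 1L,
            all(vapply(states, inherits, logical(1L), "gag_state_spec")))
  w <- vapply(states, `[[`, numeric(1L), "weight")
  if (any(w <= 0) || sum(w) <= 0) {
    stop("state weights must be positive", call. = FALSE)
  }
  n_frames <- as.integer(n_frames)
  stopifnot(!is.na(n_frames), n_frames >= 1L)
  if (!is.null(ion_model)) stopifnot(inherits(ion_model, "gag_ion_model"))
  structure(list(topology = topology, states = states,
                 weights = w / sum(w), n_frames = n_frames,
                 seed = as.integer(seed), ion_model = ion_model),
            class = "gag_ensemble_spec")
}

#' Two-state extended/compact ensemble specification
#'
#' The stock study conditions for the synthetic generator: a 70/30 mixture of
#' an extended state (means at the reference torsions, limited wobble) and a
#' compact state whose Linkage2 psi is rotated far from the reference (with a
#' smaller Linkage1 shift), emulating the extended-versus-kinked regimes seen
#' in atomistic GAG ensembles where Linkage1 stays close to linear while
#' Linkage2 splits into two populations.
#'
#' @param topology A [gag_topology()].
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @param weights Length-2 positive mixture weights (extended, compact).
#' @param concentration Von Mises kappa shared by both states.
#' @param ion_model Optional [ion_model()].
#' @return A [ensemble_spec()].
#' @export
two_state_spec <- function(topology, n_frames = 5000L, seed = 1L,
                           weights = c(0.7, 0.3), concentration = 20,
                           ion_model = NULL) {
  ref <- reference_torsions(topology)
  m <- function(cls) {
    r <- ref[match(cls, ref$linkage_class), ]
    c(r$phi_ref, r$psi_ref)
  }
  extended <- conformational_state(
    mean = list(Linkage1 = m("Linkage1"), Linkage2 = m("Linkage2")),
    concentration = concentration, weight = weights[1L])
  compact <- conformational_state(
    mean = list(Linkage1 = m("Linkage1") + c(0, -40),
                Linkage2 = m("Linkage2") + c(-30, -120)),
    concentration = concentration, weight = weights[2L])
  ensemble_spec(topology, list(extended, compact), n_frames = n_frames,
                seed = seed, ion_model = ion_model)
}

# Von Mises sampler (Best & Fisher 1979 rejection scheme), mean in degrees.
.rvonmises <- function(n, mean_deg, kappa) {
  if (n == 0L) return(numeric(0L))
  if (kappa < 1e-8) return(.wrap_deg(runif(n, -180, 180) + mean_deg))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    u2 <- stats::runif(m)
    u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0L) {
      theta <- sign(u3[ok] - 0.5) * acos(pmax(-1, pmin(1, f[ok])))
      out[got + seq_len(k)] <- theta
      got <- got + k
    }
  }
  .wrap_deg(out / .DEG + mean_deg)
}

# wrap degrees into (-180, 180]
.wrap_deg <- function(x) {
  y <- x - 360 * round(x / 360)
  y[y <= -180] <- y[y <= -180] + 360
  y
}

#' Sample a synthetic trajectory from a mixture specification
#'
#' Draws each frame's state from the mixture weights, samples every linkage's
#' (phi, psi) independently from a von Mises distribution around that state's
#' class means, and rebuilds Cartesian coordinates on the idealized chair
#' geometry. Each frame is centred in the box. The sampled torsions are kept
#' in the `sampled_torsions` attribute so downstream measurements can be
#' validated against the generator's ground truth.
#'
#' @param spec A [ensemble_spec()].
#' @return A [gag_trajectory()] with per-frame `state` labels.
#' @examples
#' top <- gag_topology("HA", 2)
#' traj <- sample_ensemble(two_state_spec(top, n_frames = 10))
#' @export
sample_ensemble <- function(spec) {
  stopifnot(inherits(spec, "gag_ensemble_spec"))
  top <- spec$topology
  n <- spec$n_frames
  n_link <- nrow(top$linkages)
  cls <- top$linkages$linkage_class
  box <- if (!is.null(spec$ion_model)) spec$ion_model$box else 6.8

  set.seed(spec$seed)
  state <- sample.int(length(spec$states), n, replace = TRUE,
                      prob = spec$weights)

  phi <- matrix(NA_real_, n, n_link)
  psi <- matrix(NA_real_, n, n_link)
  for (s in seq_along(spec$states)) {
    st <- spec$states[[s]]
    rows <- which(state == s)
    if (length(rows) == 0L) next
    for (j in seq_len(n_link)) {
      mu <- st$mean[[cls[j]]]
      kap <- if (length(st$concentration) > 1L) st$concentration[[cls[j]]] else st$concentration
      phi[rows, j] <- .rvonmises(length(rows), mu[1L], kap)
      psi[rows, j] <- .rvonmises(length(rows), mu[2L], kap)
    }
  }

  coords <- array(NA_real_, c(nrow(top$atoms), 3L, n))
  for (i in seq_len(n)) {
    xyz <- .build_chain(top, cbind(phi[i, ], psi[i, ]))
    coords[, , i] <- sweep(xyz, 2L, colMeans(xyz) - box / 2, "-")
  }

  ions <- NULL
  if (!is.null(spec$ion_model) && spec$ion_model$n_ions > 0L) {
    ions <- array(NA_real_, c(spec$ion_model$n_ions, 3L, n))
    for (i in seq_len(n)) {
      ions[, , i] <- place_ions(coords[, , i], spec$ion_model, seed = NULL)
    }
  }

  traj <- gag_trajectory(coords, top, box = box, ions = ions, state = state)
  attr(traj, "sampled_torsions") <- tibble::tibble(
    frame = rep(seq_len(n), n_link),
    linkage = rep(seq_len(n_link), each = n),
    phi = as.vector(phi), psi = as.vector(psi))
  traj
}

#' Place ions around a single frame
#'
#' `uniform_bulk` draws positions i.i.d. uniform in the cubic box;
#' `shell` places each ion at a uniformly random direction and a radius
#' uniform in `shell_radius` +/- `shell_width`/2 around a randomly chosen
#' target atom, then wraps into the box.
#'
#' @param frame n_atoms x 3 coordinate matrix (nm).
#' @param model A [ion_model()].
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return n_ions x 3 matrix of ion coordinates (nm).
#' @export
place_ions <- function(frame, model, seed = NULL) {
  stopifnot(inherits(model, "gag_ion_model"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- model$n_ions
  if (n == 0L) return(matrix(numeric(0L), 0L, 3L))
  if (model$mode == "uniform_bulk") {
    return(matrix(stats::runif(3L * n, 0, model$box), n, 3L))
  }
  targets <- model$target_atoms
  pick <- targets[sample.int(length(targets), n, replace = TRUE)]
  u <- stats::rnorm(3L * n)
  dir <- matrix(u, n, 3L) / .row_norms(matrix(u, n, 3L))
  rad <- model$shell_radius + (stats::runif(n) - 0.5) * model$shell_width
  pos <- frame[pick, , drop = FALSE] + dir * rad
  pos %% model$box
}

#' Deterministic hydrogen-bond probe placement
#'
#' Places pseudo-water acceptor probes relative to chosen chain donors so the
#' geometric hydrogen-bond criterion can be exercised without simulating
#' solvent: each probe sits at `distance` from its donor, at `angle_dev`
#' degrees off the donor's D-H direction.
#'
#' @param frame n_atoms x 3 coordinate matrix (nm).
#' @param donors Tibble with columns `donor` and `hydrogen` (atom indices),
#'   e.g. from [donor_hydrogens()].
#' @param distance Donor-probe distance (nm).
#' @param angle_dev Deviation (degrees) of the D->probe direction from the
#'   D->H direction.
#' @return n_donors x 3 matrix of probe positions (nm).
#' @export
place_hbond_probes <- function(frame, donors, distance = 0.30, angle_dev = 0) {
  stopifnot(is.data.frame(donors), all(c("donor", "hydrogen") %in% names(donors)))
  out <- matrix(NA_real_, nrow(donors), 3L)
  for (i in seq_len(nrow(donors))) {
    d <- frame[donors$donor[i], ]
    h <- frame[donors$hydrogen[i], ]
    u <- .unit(h - d)
    # any fixed perpendicular for the off-axis rotation
    ref <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- .unit(.cross3(u, ref))
    v <- cos(angle_dev * .DEG) * u + sin(angle_dev * .DEG) * perp
    out[i, ] <- d + distance * v
  }
  out
}
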