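test_that("torsion measurement agrees with planar references and bio3d", {
  p <- list(c(0, 0.1, 0), c(0, 0, 0), c(0.15, 0, 0), c(0.15, 0.1, 0))
  expect_equal(dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]]), 0)
  expect_equal(abs(dihedral_angle(p[[1]], p[[2]], p[[3]],
                                  c(0.15, -0.1, 0))), 180)
  set.seed(1)
  for (i in 1:20) {
    q <- matrix(rnorm(12), 4, 3)
    mine <- dihedral_angle(q[1, ], q[2, ], q[3, ], q[4, ])
    ref <- bio3d::torsion.xyz(as.vector(t(q)), atm.inc = 4)
    expect_equal(mine, as.numeric(ref), tolerance = 1e-6)
  }
})

test_that("fitted RMSD vanishes for identical and rigidly moved frames", {
  top <- gag_topology("HA", 2)
  xyz <- build_extended_chain(top)
  set.seed(2)
  rot <- random_rotation()
  moved <- xyz %*% t(rot) + matrix(c(1, -2, 0.5), nrow(xyz), 3, byrow = TRUE)
  traj <- traj_from_frames(list(xyz, moved), top)
  r <- fit_and_rmsd(traj, xyz)
  expect_equal(r$rmsd[1], 0, tolerance = 1e-12)
  expect_equal(r$rmsd[2], 0, tolerance = 1e-6)
})

test_that("fitted RMSD matches the quaternion oracle on random frames", {
  set.seed(3)
  for (n_at in c(3, 10, 40)) {
    x <- matrix(rnorm(n_at * 3), n_at, 3)
    y <- x + matrix(rnorm(n_at * 3, sd = 0.2), n_at, 3)
    expect_equal(gagscape:::.fitted_rmsd(x, y), oracle_quaternion_rmsd(x, y),
                 tolerance = 1e-8)
  }
})

test_that("RMSD rejects an atom-count mismatch", {
  top <- gag_topology("HA", 2)
  traj <- tiny_traj(top, n = 2)
  expect_error(fit_and_rmsd(traj, matrix(0, 5, 3)), "mismatch")
})

test_that("end-to-end distance follows Euclid and is isometry-invariant", {
  top <- gag_topology("HA", 1)
  xyz <- build_extended_chain(top)
  xyz[top$ree_endpoints[1], ] <- c(0, 0, 0)
  xyz[top$ree_endpoints[2], ] <- c(3, 4, 0)
  traj <- traj_from_frames(list(xyz), top)
  expect_equal(end_to_end_distance(traj)$r_ee, 5)

  set.seed(4)
  moved <- xyz %*% t(random_rotation()) + 2.5
  expect_equal(end_to_end_distance(traj_from_frames(list(moved), top))$r_ee, 5,
               tolerance = 1e-9)
})

test_that("contacts are boundary-inclusive at the cutoff", {
  top <- gag_topology("HA", 2)
  xyz <- build_extended_chain(top)
  at <- top$atoms
  # move residue 4 so its closest atom to residue 1 sits at exactly 0.4 nm
  i1 <- which(at$residue == 1)
  i4 <- which(at$residue == 4)
  d <- as.matrix(dist(xyz))[i1, i4]
  hit <- which(d == min(d), arr.ind = TRUE)[1, ]
  a <- i1[hit[1]]
  b <- i4[hit[2]]
  u <- (xyz[b, ] - xyz[a, ]) / sqrt(sum((xyz[b, ] - xyz[a, ])^2))
  shift <- (xyz[a, ] + 0.4 * u) - xyz[b, ]
  xyz2 <- xyz
  xyz2[i4, ] <- sweep(xyz[i4, ], 2, -shift)
  # other residues pushed far away so only the engineered pair can touch
  cm <- contact_probability_map(traj_from_frames(list(xyz2), top), top, 0.4)
  m <- attr(cm, "matrix")
  expect_equal(m[1, 4], 1)
  expect_true(isSymmetric(m))
})

test_that("an extended single frame has no non-adjacent contacts", {
  top <- ha5()
  cm <- contact_probability_map(
    traj_from_frames(list(build_extended_chain(top)), top), top)
  tab <- cm[!cm$masked, ]
  expect_true(all(tab$probability == 0))
  expect_true(all(cm$probability >= 0 & cm$probability <= 1))
})

test_that("contact probabilities equal a brute-force distance scan", {
  top <- gag_topology("HA", 2)
  set.seed(5)
  frames <- lapply(1:10, function(i) {
    build_extended_chain(top) + matrix(rnorm(nrow(top$atoms) * 3, sd = 0.12),
                                       nrow(top$atoms), 3)
  })
  traj <- traj_from_frames(frames, top)
  cm <- attr(contact_probability_map(traj, top, 0.4), "matrix")
  res <- top$atoms$residue
  for (a in 1:4) for (b in 1:4) {
    hits <- vapply(frames, function(f) {
      min(as.matrix(dist(f))[res == a, res == b]) <= 0.4
    }, logical(1))
    expect_equal(cm[a, b], mean(hits))
  }
})

test_that("the dihedral offset matches hand evaluations and stays in [0, 2]", {
  top <- gag_topology("HA", 1)  # single Linkage1
  ref <- reference_torsions(top)
  fake_dih <- function(phi, psi) {
    tibble::tibble(frame = 1L, linkage = 1L, linkage_class = "Linkage1",
                   phi = phi, psi = psi)
  }
  at_ref <- fake_dih(ref$phi_ref, ref$psi_ref)
  expect_equal(dihedral_offset(at_ref, ref, "Linkage1")$d_offset, 2)
  anti <- fake_dih(ref$phi_ref + 180, ref$psi_ref - 180)
  expect_equal(dihedral_offset(anti, ref, "Linkage1")$d_offset, 0,
               tolerance = 1e-12)
  # single linkage, phi off by 90, psi at reference: ((1+0) + (1+1)) / 2
  quarter <- fake_dih(ref$phi_ref + 90, ref$psi_ref)
  expect_equal(dihedral_offset(quarter, ref, "Linkage1")$d_offset, 1.5)
  expect_error(dihedral_offset(at_ref, ref, "Linkage2"), "no linkages")

  set.seed(6)
  rand <- tibble::tibble(frame = rep(1:50, 1), linkage = 1L,
                         linkage_class = "Linkage1",
                         phi = runif(50, -180, 180),
                         psi = runif(50, -180, 180))
  d <- dihedral_offset(rand, ref, "Linkage1")$d_offset
  expect_true(all(d >= 0 & d <= 2))
})

test_that("hydrogen-bond counting honours both geometric criteria", {
  top <- gag_topology("HA", 1)
  xyz <- build_extended_chain(top)
  don <- donor_hydrogens(top)[1, ]
  traj <- traj_from_frames(list(xyz), top)

  probe_at <- function(dist, ang) place_hbond_probes(xyz, don, dist, ang)
  expect_equal(count_hbonds(traj, don, probe_at(0.30, 0))$n_hb, 1)
  expect_equal(count_hbonds(traj, don, probe_at(0.36, 0))$n_hb, 0)
  expect_equal(count_hbonds(traj, don, probe_at(0.35, 0))$n_hb, 0)  # strict <
  expect_equal(count_hbonds(traj, don, probe_at(0.30, 29.9))$n_hb, 1)
  expect_equal(count_hbonds(traj, don, probe_at(0.30, 31))$n_hb, 0)
  expect_error(count_hbonds(traj, tibble::tibble(donor = 1L,
                                                 hydrogen = NA_integer_),
                            probe_at(0.3, 0)), "hydrogen")
})

test_that("hydrogen-bond counts equal the exhaustive pair oracle", {
  top <- gag_topology("HA", 2)
  xyz <- build_extended_chain(top)
  don <- donor_hydrogens(top)
  set.seed(7)
  # probes around each donor with mixed distances/angles straddling both
  # criteria, plus far-off decoys
  probes <- do.call(rbind, lapply(seq_len(nrow(don)), function(i) {
    rbind(place_hbond_probes(xyz, don[i, ], runif(1, 0.2, 0.45),
                             runif(1, 0, 60)),
          place_hbond_probes(xyz, don[i, ], runif(1, 0.2, 0.45),
                             runif(1, 0, 60)),
          xyz[don$donor[i], ] + rnorm(3, sd = 1))
  }))
  traj <- traj_from_frames(list(xyz), top)
  mine <- count_hbonds(traj, don, probes)$n_hb
  orc <- oracle_hbond_count(xyz, don$donor, don$hydrogen, probes)
  expect_gt(orc, 0)  # fixture exercises the criteria
  expect_equal(mine, orc)

  # seven engineered probes of which exactly four satisfy both criteria
  d1 <- don[rep(1, 7), ]
  dists <- c(0.30, 0.34, 0.20, 0.33, 0.36, 0.40, 0.30)
  angs <- c(0, 10, 25, 29, 0, 5, 45)
  pr <- do.call(rbind, lapply(1:7, function(i) {
    place_hbond_probes(xyz, d1[i, ], dists[i], angs[i])
  }))
  expect_equal(count_hbonds(traj, don[1, ], pr)$n_hb, 4)
  expect_equal(oracle_hbond_count(xyz, don$donor[1], don$hydrogen[1], pr), 4)
})

test_that("an ideal-gas ion field has g(r) = 1 within sampling error", {
  top <- gag_topology("HA", 1)
  im <- ion_model("uniform_bulk", n_ions = 1000, box = 6.8)
  traj <- tiny_traj(top, n = 40, seed = 10, ion_model = im)
  rdf <- radial_distribution(traj, bin_width = 0.05, r_max = 1.2)
  n_expected <- 1000 / 6.8^3 * 4 / 3 * pi *
    (rdf$r + 0.025)^3 - 1000 / 6.8^3 * 4 / 3 * pi * (rdf$r - 0.025)^3
  counts <- rdf$g * n_expected * 40 * 2  # frames x carboxylate oxygens
  se <- sqrt(pmax(counts, 1)) / (n_expected * 40 * 2)
  off <- abs(rdf$g - 1) > 3 * se
  expect_true(all(!off[rdf$r > 0.3]))
})

test_that("shell-placed ions put the g(r) peak in the contact-pair window", {
  top <- gag_topology("HA", 2)
  ref <- build_extended_chain(top)
  targets <- unlist(top$carboxylate_oxygens)
  im <- ion_model("shell", n_ions = 400, box = 6.8, target_atoms = targets,
                  shell_radius = 0.25, shell_width = 0.02)
  traj <- tiny_traj(top, n = 10, seed = 11, ion_model = im)
  rdf <- radial_distribution(traj, bin_width = 0.02, r_max = 1.0)
  peak <- rdf$r[which.max(rdf$g)]
  expect_gte(peak, 0.2)
  expect_lte(peak, 0.3)
})

test_that("a two-ion hand histogram matches the RDF normalization", {
  top <- gag_topology("HA", 1)
  xyz <- build_extended_chain(top)
  box <- 6
  xyz <- sweep(xyz, 2, colMeans(xyz) - box / 2)
  target <- top$carboxylate_oxygens[[1]][1]
  p0 <- xyz[target, ]
  ions <- rbind(p0 + c(0.31, 0, 0), p0 + c(0, 0.72, 0))
  traj <- gag_trajectory(xyz, top, box = box, ions = ions)
  rdf <- radial_distribution(traj, groups = list(target), bin_width = 0.1,
                             r_max = 1.0)
  rho <- 2 / box^3
  shell <- function(lo, hi) 4 / 3 * pi * (hi^3 - lo^3)
  expected <- rep(0, 10)
  expected[4] <- 1 / (rho * shell(0.3, 0.4))
  expected[8] <- 1 / (rho * shell(0.7, 0.8))
  expect_equal(rdf$g, expected)
})

test_that("RDF guards its preconditions", {
  top <- gag_topology("HA", 1)
  traj <- tiny_traj(top, n = 2)
  expect_error(radial_distribution(traj), "no ions")
  im <- ion_model("uniform_bulk", n_ions = 10, box = 4)
  traj2 <- tiny_traj(top, n = 2, ion_model = im)
  expect_error(radial_distribution(traj2, r_max = 2.5), "half the box")
})

test_that("proximal-ion counts match direct distance checks", {
  top <- gag_topology("HA", 1)
  xyz <- build_extended_chain(top)
  box <- 8
  xyz <- sweep(xyz, 2, colMeans(xyz) - box / 2)
  u <- xyz[1, ] - colMeans(xyz)  # outward direction so atom 1 stays nearest
  u <- u / sqrt(sum(u^2))
  near <- function(dist) xyz[1, ] + dist * u
  dmin <- function(p) min(sqrt(rowSums(sweep(xyz, 2, p)^2)))
  ions <- rbind(near(0.3), near(0.45), near(0.6))
  # verify the engineered distances before asserting the count
  d <- apply(ions, 1, dmin)
  expect_equal(proximal_ion_count(gag_trajectory(xyz, top, box = box,
                                                 ions = ions))$n_proximal,
               sum(d <= 0.5))
  expect_equal(sum(d <= 0.5), 2)

  far <- matrix(rep(xyz[1, ] + c(2.5, 2.5, 0), 4), 4, 3, byrow = TRUE)
  expect_equal(proximal_ion_count(gag_trajectory(xyz, top, box = box,
                                                 ions = far))$n_proximal, 0)
})

test_that("distance features are invariant under a global rigid motion", {
  top <- gag_topology("HA", 2)
  traj <- tiny_traj(top, n = 3, seed = 12)
  set.seed(13)
  rot <- random_rotation()
  shift <- c(0.3, -1, 2)
  moved <- traj
  for (i in 1:3) {
    moved$coords[, , i] <- traj$coords[, , i] %*% t(rot) +
      matrix(shift, nrow(top$atoms), 3, byrow = TRUE)
  }
  expect_equal(end_to_end_distance(moved)$r_ee,
               end_to_end_distance(traj)$r_ee, tolerance = 1e-9)
  expect_equal(attr(contact_probability_map(moved, top), "matrix"),
               attr(contact_probability_map(traj, top), "matrix"))
  d0 <- glycosidic_dihedrals(traj)
  d1 <- glycosidic_dihedrals(moved)
  expect_equal(d0$phi, d1$phi, tolerance = 1e-9)
})
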