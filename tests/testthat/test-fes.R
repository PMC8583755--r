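fake_features <- function(n = 100, seed = 1) {
  set.seed(seed)
  tibble::tibble(frame = seq_len(n),
                 d_offset_l1 = runif(n, 1.5, 2),
                 d_offset_l2 = runif(n, 0.5, 2),
                 r_ee = rnorm(n, 4, 0.4),
                 n_hb = rpois(n, 80))
}

test_that("the state matrix keeps column order and standardizes exactly", {
  f <- fake_features(100)
  m <- assemble_state_matrix(f)
  expect_equal(colnames(m), c("d_offset_l1", "d_offset_l2", "r_ee", "n_hb"))
  expect_equal(dim(m), c(100L, 4L))
  expect_true(all(abs(colMeans(m)) < 1e-10))
  expect_true(all(abs(apply(m, 2, sd) - 1) < 1e-10))
  back <- destandardize(m)
  expect_equal(back, unname(as.matrix(f[, -1])), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("constant feature columns pass through standardization", {
  f <- fake_features(50)
  f$n_hb <- 0L
  m <- assemble_state_matrix(f)
  expect_true(all(m[, "n_hb"] == 0))
  expect_false(anyNA(m))
})

test_that("mismatched or undefined features are rejected", {
  f <- fake_features(10)
  expect_error(assemble_state_matrix(f[, 1:3]), "missing feature columns")
  f$r_ee[3] <- NA
  expect_error(assemble_state_matrix(f), "undefined")
})

test_that("PCA matches an independent eigendecomposition on a hand matrix", {
  set.seed(2)
  x <- matrix(rnorm(20), 5, 4,
              dimnames = list(NULL, c("d_offset_l1", "d_offset_l2",
                                      "r_ee", "n_hb")))
  p <- principal_components(x, k_pc = 2)
  ev <- eigen(cov(x), symmetric = TRUE)
  expect_equal(p$explained, ev$values / sum(ev$values), tolerance = 1e-8)
  # loadings match up to sign
  for (j in 1:2) {
    expect_equal(abs(sum(p$loadings[, j] * ev$vectors[, j])), 1,
                 tolerance = 1e-8)
  }
})

test_that("PCA scores are decorrelated and loadings orthonormal", {
  f <- fake_features(200, seed = 3)
  p <- principal_components(assemble_state_matrix(f), k_pc = 4)
  s <- as.matrix(p$scores[, -1])
  cv <- cov(s)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  expect_equal(crossprod(p$loadings), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(p$explained) <= 1e-12))
})

test_that("variance concentrated in one column gives a rank-1 projection", {
  n <- 50
  x <- cbind(d_offset_l1 = rep(1.8, n), d_offset_l2 = rep(1.2, n),
             r_ee = seq(3, 5, length.out = n), n_hb = rep(80, n))
  p <- principal_components(x, k_pc = 2)
  expect_equal(p$explained[1], 1, tolerance = 1e-12)
})

test_that("the free-energy surface obeys its normalization invariants", {
  f <- fake_features(500, seed = 4)
  p <- principal_components(assemble_state_matrix(f))
  surf <- free_energy_surface(p, bins = 30)
  expect_equal(sum(surf$p), 1, tolerance = 1e-9)
  expect_equal(min(surf$dg_kbt, na.rm = TRUE), 0)
  expect_true(all(surf$dg_kbt >= 0, na.rm = TRUE))
  expect_true(all(is.na(surf$dg_kbt[surf$p == 0])))
  expect_error(free_energy_surface(p, temperature = -5), "positive")
})

test_that("a probability of Pmax/e costs exactly one kBT (2.494 kJ/mol)", {
  # engineered scores: bin A holds e times the frames of bin B
  n_a <- 136
  n_b <- 50  # 136/50 = 2.72 = e to within the bin resolution of the test
  scores <- tibble::tibble(frame = 1:(n_a + n_b),
                           PC1 = c(rep(-1, n_a), rep(1, n_b)),
                           PC2 = 0)
  p <- structure(list(scores = scores, loadings = diag(2),
                      explained = c(1, 0), k_pc = 2L), class = "gag_pca")
  surf <- free_energy_surface(p, bins = 2, temperature = 300)
  occ <- surf[surf$p > 0, ]
  expect_equal(occ$dg_kbt[occ$p == min(occ$p)],
               -log(n_b / n_a), tolerance = 1e-12)
  expect_equal(-log(1 / exp(1)), 1)  # the target contrast
  # at exactly Pmax/e the cost is 1 kBT = 2.494 kJ/mol at 300 K
  expect_equal(1 * 0.008314462618 * 300, 2.494, tolerance = 1e-3)
  expect_equal(occ$dg_kjmol, occ$dg_kbt * 0.008314462618 * 300)
})

test_that("delta and uniform occupancies give flat surfaces", {
  scores <- tibble::tibble(frame = 1:40, PC1 = 0.5, PC2 = -0.2)
  p <- structure(list(scores = scores, loadings = diag(2),
                      explained = c(1, 0), k_pc = 2L), class = "gag_pca")
  surf <- free_energy_surface(p, bins = 10)
  expect_equal(sum(surf$p > 0), 1)
  expect_equal(surf$dg_kbt[surf$p > 0], 0)

  g <- expand.grid(x = 1:6, y = 1:6)
  scores2 <- tibble::tibble(frame = 1:36, PC1 = g$x, PC2 = g$y)
  p2 <- structure(list(scores = scores2, loadings = diag(2),
                       explained = c(0.5, 0.5), k_pc = 2L),
                  class = "gag_pca")
  surf2 <- free_energy_surface(p2, bins = 6, pad = 0.01)
  expect_true(all(surf2$dg_kbt[surf2$p > 0] == 0))
})

test_that("k-means recovers four well-separated blobs and selects k = 4", {
  set.seed(5)
  centers <- rbind(c(-5, -5), c(-5, 5), c(5, -5), c(5, 5))
  truth <- rep(1:4, each = 100)
  pts <- centers[truth, ] + matrix(rnorm(800, sd = 0.4), 400, 2)
  p <- structure(list(scores = tibble::tibble(frame = 1:400,
                                              PC1 = pts[, 1], PC2 = pts[, 2]),
                      loadings = diag(2), explained = c(0.5, 0.5), k_pc = 2L),
                 class = "gag_pca")
  st <- kmeans_with_elbow(p, k_range = 1:8, seed = 6)
  expect_equal(st$k, 4)
  tab <- table(st$labels, truth)
  expect_gte(sum(apply(tab, 2, max)) / 400, 0.99)
  expect_true(all(diff(st$inertia$inertia) <= 1e-9))
  expect_equal(sum(st$populations), 1)
})

test_that("k = 1 inertia equals the total centred sum of squares", {
  f <- fake_features(80, seed = 7)
  p <- principal_components(assemble_state_matrix(f))
  st <- kmeans_with_elbow(p, k_range = 1:4, seed = 8)
  x <- as.matrix(p$scores[, -1])
  tss <- sum(scale(x, scale = FALSE)^2)
  expect_equal(st$inertia$inertia[st$inertia$k == 1], tss, tolerance = 1e-9)
})

test_that("state clustering is reproducible under a fixed seed", {
  f <- fake_features(150, seed = 9)
  p <- principal_components(assemble_state_matrix(f))
  s1 <- kmeans_with_elbow(p, k_range = 1:5, seed = 10)
  s2 <- kmeans_with_elbow(p, k_range = 1:5, seed = 10)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$inertia, s2$inertia)
})

test_that("representative frames minimize the PC distance to their centre", {
  top <- gag_topology("HA", 2)
  traj <- sample_ensemble(two_state_spec(top, n_frames = 120, seed = 11))
  f <- compute_features(traj)
  p <- principal_components(assemble_state_matrix(f))
  st <- kmeans_with_elbow(p, k_range = 1:4, seed = 12)
  rep_tab <- representative_frames(st, p, traj, features = f)
  x <- as.matrix(p$scores[, -1])
  for (r in seq_len(nrow(rep_tab))) {
    s <- rep_tab$state[r]
    members <- which(st$labels == s)
    d2 <- rowSums((x[members, , drop = FALSE] -
                     matrix(st$centers[s, ], length(members), 2,
                            byrow = TRUE))^2)
    expect_equal(rep_tab$centroid_frame[r], members[which.min(d2)])
  }
  expect_equal(sum(rep_tab$population), 1)

  # a centroid of a single-member cluster is that member
  one <- which(tabulate(st$labels) == 1)
  if (length(one) > 0) {
    expect_equal(rep_tab$centroid_frame[rep_tab$state == one[1]],
                 which(st$labels == one[1]))
  }
})

test_that("each centroid carries its cluster's majority generator state", {
  top <- gag_topology("HA", 3)
  traj <- sample_ensemble(two_state_spec(top, n_frames = 300, seed = 13))
  f <- compute_features(traj)
  p <- principal_components(assemble_state_matrix(f))
  st <- kmeans_with_elbow(p, k_range = 2, seed = 14)
  rep_tab <- representative_frames(st, p, traj, features = f)
  for (r in seq_len(nrow(rep_tab))) {
    members <- which(st$labels == rep_tab$state[r])
    majority <- as.integer(names(which.max(table(traj$state[members]))))
    expect_equal(traj$state[rep_tab$centroid_frame[r]], majority)
  }
})
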