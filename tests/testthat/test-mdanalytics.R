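test_that("Kabsch superposition removes rigid motion exactly", {
  set.seed(1)
  A <- matrix(rnorm(30), 10)
  fit <- kabsch_superpose(A, A)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  th <- pi / 2
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  B <- A %*% t(R) + matrix(c(1, -2, 3), 10, 3, byrow = TRUE)
  expect_equal(kabsch_superpose(B, A)$rmsd, 0, tolerance = 1e-12)
  expect_error(kabsch_superpose(A, A[1:5, ]), "identical dimensions")
  expect_error(kabsch_superpose(A, A, weights = rep(0, 10)),
               "not all zero")
})

test_that("Kabsch rotations are proper even for reflection-prone inputs", {
  set.seed(4)
  for (rep in 1:20) {
    A <- matrix(rnorm(15), 5)
    B <- -A + matrix(rnorm(15, 0, 0.1), 5)  # mirrored target
    expect_equal(det(kabsch_superpose(A, B)$rotation), 1, tolerance = 1e-9)
  }
})

test_that("Kabsch RMSD equals the quaternion-eigenvalue oracle", {
  set.seed(2024)
  for (rep in 1:100) {
    n <- sample(4:30, 1)
    A <- matrix(rnorm(3 * n), n)
    B <- matrix(rnorm(3 * n), n)
    expect_equal(kabsch_superpose(A, B)$rmsd, quaternion_rmsd(A, B),
                 tolerance = 1e-9)
  }
})

test_that("RMSD series distinguishes rigid motion from real deviation", {
  g <- gen_trajectory(n_atoms = 20, n_frames = 30, sigma = 0,
                      rigid_motions = TRUE, seed = 5)
  fit <- rmsd_series(g$traj, fit = TRUE)
  expect_lt(max(fit$values), 1e-8)
  nofit <- rmsd_series(g$traj, fit = FALSE)
  expect_gt(mean(nofit$values), 0.1)
  expect_true(all(fit$values <= nofit$values + 1e-12))
  expect_error(rmsd_series(g$traj, selection = integer(0)), "empty")
})

test_that("RMSD mean matches the closed-form noise expectation", {
  sigma <- 0.2
  g <- gen_trajectory(n_atoms = 50, n_frames = 2000, sigma = sigma,
                      seed = 17)
  s <- rmsd_series(g$traj, reference = g$reference, fit = FALSE)
  expect_equal(s$mean, sigma * sqrt(3), tolerance = 0.05)
  sf <- rmsd_series(g$traj, reference = g$reference, fit = TRUE)
  expect_true(all(sf$values <= s$values + 1e-12))
})

test_that("RMSD and Rg are invariant under a global rigid motion", {
  g <- gen_trajectory(n_atoms = 15, n_frames = 10, sigma = 0.3, seed = 8)
  set.seed(9)
  qrR <- qr(matrix(rnorm(9), 3)); R <- qr.Q(qrR)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  co2 <- g$traj$coords
  for (f in 1:10)
    co2[f, , ] <- matrix(co2[f, , ], ncol = 3) %*% t(R) +
      matrix(c(5, -3, 2), 15, 3, byrow = TRUE)
  t2 <- trajectory(co2, g$traj$topology, g$traj$times)
  expect_equal(rmsd_series(t2)$values, rmsd_series(g$traj)$values,
               tolerance = 1e-8)
  expect_equal(rg_series(t2)$values, rg_series(g$traj)$values,
               tolerance = 1e-8)
})

test_that("RMSF is zero for static input and recovers planted amplitudes", {
  co <- array(rep(matrix(runif(60), 20), each = 5), c(5, 20, 3))
  static <- trajectory(co, simple_topology(20))
  expect_lt(max(rmsf(static)), 1e-10)
  g <- gen_trajectory(n_atoms = 30, n_frames = 4000,
                      sigma = seq(0.1, 0.5, length.out = 30), seed = 42)
  rec <- rmsf(g$traj, fit = FALSE)
  expect_lt(max(abs(rec - g$sigma * sqrt(3)) / (g$sigma * sqrt(3))), 0.05)
  expect_warning(
    rmsf(trajectory(co[1, , , drop = FALSE], simple_topology(20))),
    "single-frame")
})

test_that("per-residue RMSF averages over each residue's atoms", {
  g <- gen_trajectory(n_atoms = 10, n_frames = 200, sigma = 0.2, seed = 6)
  atomic <- rmsf(g$traj, fit = FALSE)
  res <- rmsf(g$traj, fit = FALSE, by_residue = TRUE)
  expect_equal(unname(res["1"]), mean(atomic[1:5]))
  expect_equal(unname(res["2"]), mean(atomic[6:10]))
})

test_that("radius of gyration matches closed forms and the pairwise oracle", {
  # points on a sphere of radius R about the COM
  set.seed(12)
  dirs <- matrix(rnorm(90), 30); dirs <- dirs / sqrt(rowSums(dirs^2))
  sph <- rbind(5 * dirs, -5 * dirs)  # antipodal pairs keep COM at 0
  expect_equal(radius_of_gyration(sph), 5)
  two <- rbind(c(0, 0, 0), c(4, 0, 0))
  expect_equal(radius_of_gyration(two), 2)
  co <- matrix(runif(300, 0, 15), 100)
  m <- runif(100, 1, 16)
  expect_equal(radius_of_gyration(co, m), rg_pairwise_oracle(co, m),
               tolerance = 1e-10)
  expect_error(radius_of_gyration(two, c(0, 0)), "total mass")
})

test_that("Shrake-Rupley reproduces analytic sphere and cap areas", {
  s1 <- sasa_shrake_rupley(matrix(0, 1, 3), 1.7)
  expect_equal(s1$total, 4 * pi * 3.1^2, tolerance = 1e-10)
  # far apart: additivity
  far <- sasa_shrake_rupley(rbind(c(0, 0, 0), c(50, 0, 0)), c(1.7, 1.5))
  expect_equal(far$total, 4 * pi * 3.1^2 + 4 * pi * 2.9^2,
               tolerance = 1e-10)
  # overlapping pair vs the analytic two-sphere cap formula, 2% at 960
  R1 <- 1.7 + 1.4; R2 <- 1.5 + 1.4; d <- 2.4
  s2 <- sasa_shrake_rupley(rbind(c(0, 0, 0), c(d, 0, 0)), c(1.7, 1.5))
  exact <- two_sphere_sasa_oracle(R1, R2, d)
  expect_equal(s2$per_atom, exact, tolerance = 0.02)
})

test_that("SASA decreases monotonically on approach and converges in points", {
  rad <- c(1.7, 1.7)
  dists <- c(7, 5, 4, 3, 2, 1)
  tot <- sapply(dists, function(d)
    sasa_shrake_rupley(rbind(c(0, 0, 0), c(d, 0, 0)), rad)$total)
  expect_true(all(diff(tot) <= 1e-9))
  set.seed(3)
  co <- matrix(runif(30, 0, 6), 10)
  r10 <- runif(10, 1.2, 1.9)
  e1 <- abs(sasa_shrake_rupley(co, r10, n_points = 240)$total -
              sasa_shrake_rupley(co, r10, n_points = 3840)$total)
  e2 <- abs(sasa_shrake_rupley(co, r10, n_points = 960)$total -
              sasa_shrake_rupley(co, r10, n_points = 3840)$total)
  expect_lt(e2, e1 + 1e-9)
  expect_error(sasa_shrake_rupley(co, r10, n_points = 6), ">= 12")
})

test_that("crafted hydrogen-bond geometries count as specified", {
  ok <- make_hbond_frame(2.9, 10)
  tr <- trajectory(array(ok$coords, c(1, 3, 3)), ok$topology)
  s <- hbond_count_series(tr, donor_selection = 1:2,
                          acceptor_selection = 3)
  expect_equal(s$values, 1)
  far <- make_hbond_frame(4.0, 10)
  tr2 <- trajectory(array(far$coords, c(1, 3, 3)), far$topology)
  expect_equal(hbond_count_series(tr2, 1:2, 3)$values, 0)
  bent <- make_hbond_frame(2.9, 45)
  tr3 <- trajectory(array(bent$coords, c(1, 3, 3)), bent$topology)
  expect_equal(hbond_count_series(tr3, 1:2, 3)$values, 0)
  expect_equal(hbond_count_series(tr3, 1:2, 3,
                                  hbond_criteria(3.5, 60))$values, 1)
})

test_that("hydrogen-bond counts equal the all-pairs oracle on random frames", {
  set.seed(77)
  n <- 60
  roles <- rep(c("donor-heavy", "hydrogen", "acceptor"), each = 20)
  top <- data.frame(atom_name = sprintf("X%d", 1:n),
                    residue_id = rep(1:2, each = 30),
                    mass = 12, vdw_radius = 1.5,
                    hbond_role = roles,
                    hydrogen_parent = c(rep(NA, 20), 1:20, rep(NA, 20)),
                    stringsAsFactors = FALSE)
  for (rep_ in 1:5) {
    co <- matrix(runif(3 * n, 0, 12), n)
    # hydrogens placed 1 A from their parent donors
    dirh <- matrix(rnorm(60), 20); dirh <- dirh / sqrt(rowSums(dirh^2))
    co[21:40, ] <- co[1:20, ] + dirh
    tr <- trajectory(array(co, c(1, n, 3)), top)
    mine <- hbond_count_series(tr, donor_selection = 1:40,
                               acceptor_selection = 41:60)$values
    oracle <- hbond_all_pairs_oracle(co, top, 1:40, 41:60)
    expect_equal(mine, as.numeric(oracle))
  }
})

test_that("PCA captures planted one-dimensional motion", {
  set.seed(31)
  n <- 25
  ref <- matrix(runif(3 * n, 0, 10), n)
  axis <- c(1, 0, 0)
  co <- array(0, c(300, n, 3))
  for (f in 1:300)
    co[f, , ] <- ref + matrix(rnorm(1, 0, 1.5) * axis, n, 3, byrow = TRUE) +
      matrix(rnorm(3 * n, 0, 0.01), n)
  tr <- trajectory(co, simple_topology(n))
  p <- pca_trajectory(tr, fit = FALSE)
  expect_gt(p$eigenvalues[1] / sum(p$eigenvalues), 0.99)
  expect_equal(sum(p$eigenvalues), p$trace, tolerance = 1e-10)
  expect_lt(max(abs(colMeans(p$projections))), 1e-10)
  expect_equal(t(p$vectors) %*% p$vectors, diag(2), tolerance = 1e-10)
  expect_error(pca_trajectory(trajectory(co[1, , , drop = FALSE],
                                         simple_topology(n))),
               "at least 2")
})

test_that("PCA eigen decomposition reconstructs centered coordinates", {
  g <- gen_trajectory(n_atoms = 8, n_frames = 40, sigma = 0.3, seed = 21)
  p <- pca_trajectory(g$traj, fit = FALSE, n_components = 2)
  X <- t(sapply(1:40, function(f)
    as.vector(t(matrix(g$traj$coords[f, , ], ncol = 3))))) / 10
  Xc <- sweep(X, 2, colMeans(X))
  proj_all <- Xc %*% p$all_vectors
  expect_equal(unname(proj_all %*% t(p$all_vectors)), unname(Xc),
               tolerance = 1e-8)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_true(all(p$eigenvalues >= 0))
})

test_that("free-energy landscape normalizes and masks as specified", {
  one <- fel(matrix(c(0.5, 0.5), 1, 2), n_bins = 8)
  expect_equal(sum(one$probability), 1)
  expect_equal(min(one$G, na.rm = TRUE), 0)
  expect_equal(sum(!is.na(one$G)), 1L)
  # uniform occupancy: every occupied bin at G = 0
  grid <- as.matrix(expand.grid(x = (1:4 - 0.5) / 4, y = (1:4 - 0.5) / 4))
  u <- fel(grid, n_bins = 4)
  expect_true(all(abs(u$G[!is.na(u$G)]) < 1e-12))
  expect_equal(sum(u$probability), 1)
  expect_error(fel(grid, n_bins = 0), ">= 1")
})

test_that("two-state occupancies give the closed-form basin depth", {
  p <- gen_two_state_projections(n_frames = 50000, p1 = 0.8, p2 = 0.2,
                                 seed = 1)
  f <- fel(p$projections, n_bins = 32)
  g_major <- min(f$G[f$x_edges[-1] < 0, ], na.rm = TRUE)
  g_minor <- min(f$G[f$x_edges[-1] > 0, ], na.rm = TRUE)
  expect_equal(g_minor - g_major, f$kT * log(4),
               tolerance = 0.2 * f$kT / (f$kT * log(4)))
  expect_equal(f$kT, 2.494, tolerance = 1e-3)
})

test_that("equilibrium window verdicts match a direct scan", {
  const <- md_ser <- structure(list(times = 1:200, values = rep(3, 200),
                                    label = "", mean = 3, sd = 0),
                               class = "md_series")
  v <- equilibrium_window(const, t_start = 100)
  expect_true(v$equilibrated)
  expect_equal(v$violation_fraction, 0)
  spike <- const
  spike$values[150] <- 3 * 1.2
  expect_false(equilibrium_window(spike, t_start = 100)$equilibrated)
  # AR(1) series vs brute-force scan
  set.seed(55)
  x <- numeric(300)
  for (t in 2:300) x[t] <- 0.9 * x[t - 1] + rnorm(1, 0, 0.3)
  ser <- structure(list(times = 1:300, values = 10 + x, label = "",
                        mean = mean(10 + x), sd = sd(x)),
                   class = "md_series")
  v2 <- equilibrium_window(ser, t_start = 100, band = 0.05)
  win <- ser$values[ser$times > 100]
  direct <- abs(win - mean(win)) > 0.05 * abs(mean(win))
  expect_equal(v2$equilibrated, !any(direct))
  expect_equal(v2$violation_fraction, mean(direct))
  expect_error(equilibrium_window(ser, t_start = 400), "beyond")
})
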