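# Independent oracles used across the suite.  These deliberately take
# different computational routes than the package implementations.

# Quaternion-eigenvalue RMSD oracle: the optimal superposition RMSD is
# sqrt((Ga + Gb - 2*lambda_max) / N) where lambda_max is the largest
# eigenvalue of the 4x4 quaternion key matrix of the correlation matrix.
quaternion_rmsd <- function(mobile, reference) {
  N <- nrow(mobile)
  A <- scale(mobile, scale = FALSE)
  B <- scale(reference, scale = FALSE)
  Ga <- sum(A^2); Gb <- sum(B^2)
  M <- t(A) %*% B
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (Ga + Gb - 2 * lam) / N))
}

# Generic shoelace polygon area from explicit vertex coordinates.
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Radar polygon area from explicitly constructed vertices.
radar_area_vertex_oracle <- function(radii) {
  n <- length(radii)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  shoelace_area(radii * cos(ang), radii * sin(ang))
}

# Brute-force competition rank counter.
competition_rank_oracle <- function(values) {
  out <- integer(length(values))
  for (i in seq_along(values)) {
    better <- 0L
    for (j in seq_along(values)) if (values[j] < values[i]) better <- better + 1L
    out[i] <- 1L + better
  }
  out
}

# Naive double-loop radius of gyration (pairwise form):
# Rg^2 = sum_{i<j} m_i m_j d_ij^2 / M^2
rg_pairwise_oracle <- function(coords, masses) {
  M <- sum(masses)
  s <- 0
  n <- nrow(coords)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + masses[i] * masses[j] * sum((coords[i, ] - coords[j, ])^2)
  sqrt(s / M^2)
}

# Analytic exposed area of two overlapping probe-inflated spheres.
two_sphere_sasa_oracle <- function(R1, R2, d) {
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  x2 <- (d^2 + R2^2 - R1^2) / (2 * d)
  c(2 * pi * R1 * (R1 + x1), 2 * pi * R2 * (R2 + x2))
}

# Exhaustive all-pairs hydrogen-bond counter for one frame, written as a
# flat enumeration over every (hydrogen, acceptor) combination.
hbond_all_pairs_oracle <- function(coords, topology, donor_sel,
                                   acceptor_sel, max_dist = 3.5,
                                   max_angle = 30) {
  hyd <- which(topology$hbond_role == "hydrogen")
  acc <- intersect(acceptor_sel, which(topology$hbond_role == "acceptor"))
  don <- intersect(donor_sel, which(topology$hbond_role == "donor-heavy"))
  count <- 0L
  if (length(hyd) == 0L || length(acc) == 0L) return(count)
  grid <- expand.grid(h = hyd, a = acc)
  for (k in seq_len(nrow(grid))) {
    h <- grid$h[k]; a <- grid$a[k]
    d <- topology$hydrogen_parent[h]
    if (is.na(d) || !(d %in% don) || a == d) next
    v_da <- coords[a, ] - coords[d, ]
    v_dh <- coords[h, ] - coords[d, ]
    dist <- sqrt(sum(v_da^2))
    ang <- acos(max(-1, min(1, sum(v_dh * v_da) /
                              (sqrt(sum(v_dh^2)) * dist)))) * 180 / pi
    if (dist <= max_dist && ang <= max_angle) count <- count + 1L
  }
  count
}

# Place a donor-H...acceptor triple with a given D...A distance and
# H-D...A angle, for crafted-geometry tests.
make_hbond_frame <- function(da_dist, hda_angle_deg) {
  ang <- hda_angle_deg * pi / 180
  coords <- rbind(
    c(0, 0, 0),                                  # donor heavy
    c(cos(ang), sin(ang), 0),                    # hydrogen (1 A from D)
    c(da_dist, 0, 0))                            # acceptor
  topology <- data.frame(
    atom_name = c("N1", "H1", "O1"),
    residue_id = c(1L, 1L, 2L),
    mass = c(14.007, 1.008, 15.999),
    vdw_radius = c(1.55, 1.1, 1.52),
    hbond_role = c("donor-heavy", "hydrogen", "acceptor"),
    hydrogen_parent = c(NA, 1L, NA),
    stringsAsFactors = FALSE)
  list(coords = coords, topology = topology)
}

# Minimal valid topology for n generic atoms.
simple_topology <- function(n, role = "none") {
  data.frame(atom_name = sprintf("C%d", seq_len(n)),
             residue_id = seq_len(n),
             mass = 12.011, vdw_radius = 1.7,
             hbond_role = role, hydrogen_parent = NA_integer_,
             stringsAsFactors = FALSE)
}
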