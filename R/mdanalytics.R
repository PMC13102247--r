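#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the weighted RMSD
#' between two point sets, via SVD of the weighted covariance matrix with
#' the usual sign correction so reflections are excluded.
#'
#' @param mobile,reference numeric `N x 3` coordinate matrices (Angstrom).
#' @param weights non-negative per-atom weights, not all zero (default
#'   uniform).
#' @return list with `rotation` (3x3, determinant +1), `translation`
#'   (length 3; the fitted mobile is `mobile %*% t(R) + translation`),
#'   `rmsd` (weighted, Angstrom) and `fitted` (the transformed mobile).
#' @export
kabsch_superpose <- function(mobile, reference,
                             weights = rep(1, nrow(mobile))) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("mobile and reference must have identical dimensions",
         call. = FALSE)
  if (ncol(mobile) != 3L) stop("coordinates must be N x 3", call. = FALSE)
  if (any(weights < 0) || sum(weights) == 0)
    stop("weights must be non-negative and not all zero", call. = FALSE)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  A <- sweep(mobile, 2L, cm)
  B <- sweep(reference, 2L, cr)
  H <- t(A * w) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted <- A %*% t(R)
  fitted <- sweep(fitted, 2L, cr, "+")
  rmsd <- sqrt(sum(w * rowSums((fitted - reference)^2)))
  list(rotation = R, translation = cr - as.vector(R %*% cm),
       rmsd = rmsd, fitted = fitted)
}

#' Per-frame RMSD time series
#'
#' RMSD of each frame from a reference structure over a selection, after
#' optional Kabsch superposition (`fit = TRUE`, the default).  A summary
#' mean and SD over frames is attached.
#'
#' @param traj a [trajectory()].
#' @param reference frame index into `traj` (default 1) or an explicit
#'   `N x 3` matrix over the selected atoms.
#' @param selection integer vector of atom indices (default all atoms).
#' @param fit superpose each frame onto the reference before measuring.
#' @return object of class `md_series`: list with `times` (ns, or frame
#'   index), `values` (Angstrom), `label`, `mean`, `sd`.
#' @export
rmsd_series <- function(traj, reference = 1L, selection = NULL,
                        fit = TRUE) {
  selection <- selection %||% seq_len(n_atoms(traj))
  if (length(selection) == 0L) stop("empty selection", call. = FALSE)
  ref <- if (is.matrix(reference)) reference
         else frame_coords(traj, reference)[selection, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    m <- frame_coords(traj, f)[selection, , drop = FALSE]
    if (fit) kabsch_superpose(m, ref)$rmsd
    else sqrt(mean(rowSums((m - ref)^2)))
  }, numeric(1))
  md_series(vals, traj$times, "RMSD (A)")
}

md_series <- function(values, times = NULL, label = "") {
  structure(list(times = times %||% seq_along(values),
                 values = values, label = label,
                 mean = mean(values),
                 sd = if (length(values) > 1L) stats::sd(values) else 0),
            class = "md_series")
}

#' @export
print.md_series <- function(x, ...) {
  cat(sprintf("md_series %s: n = %d, mean = %.4f +/- %.4f\n",
              x$label, length(x$values), x$mean, x$sd))
  invisible(x)
}

#' Per-atom root-mean-square fluctuation
#'
#' After superposing every frame onto the mean structure (one fit-to-first,
#' recompute-mean, refit iteration), computes
#' `RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2)`.  Optionally aggregates to
#' per-residue values by averaging over each residue's selected atoms.
#'
#' @param traj a [trajectory()].
#' @param selection atom indices (default all).
#' @param fit superpose frames before measuring (default TRUE).
#' @param by_residue return one value per residue instead of per atom.
#' @return numeric vector of RMSF values (Angstrom), named by atom index
#'   or residue id.
#' @export
rmsf <- function(traj, selection = NULL, fit = TRUE, by_residue = FALSE) {
  selection <- selection %||% seq_len(n_atoms(traj))
  if (length(selection) == 0L) stop("empty selection", call. = FALSE)
  nf <- n_frames(traj)
  if (nf < 2L)
    warning("single-frame trajectory: RMSF is identically zero")
  frames <- lapply(seq_len(nf), function(f)
    frame_coords(traj, f)[selection, , drop = FALSE])
  if (fit && nf > 1L) {
    ref <- frames[[1L]]
    frames <- lapply(frames, function(m) kabsch_superpose(m, ref)$fitted)
    mean_struct <- Reduce(`+`, frames) / nf
    frames <- lapply(frames, function(m)
      kabsch_superpose(m, mean_struct)$fitted)
  }
  mean_struct <- Reduce(`+`, frames) / nf
  dev2 <- Reduce(`+`, lapply(frames, function(m)
    rowSums((m - mean_struct)^2))) / nf
  vals <- sqrt(dev2)
  names(vals) <- selection
  if (by_residue) {
    res <- traj$topology$residue_id[selection]
    vals <- tapply(vals, res, mean)
    vals <- stats::setNames(as.numeric(vals), names(vals))
  }
  vals
}

#' Radius of gyration of one frame
#'
#' `Rg = sqrt( sum_i m_i |r_i - r_COM|^2 / sum_i m_i )`, the mass-weighted
#' RMS distance of atoms from their center of mass.
#'
#' @param coords `N x 3` coordinate matrix (Angstrom).
#' @param masses per-atom masses (amu), total > 0.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(coords, masses = rep(1, nrow(coords))) {
  coords <- as.matrix(coords)
  if (length(masses) != nrow(coords))
    stop("masses length must match atom count", call. = FALSE)
  M <- sum(masses)
  if (M <= 0) stop("total mass must be > 0", call. = FALSE)
  com <- colSums(coords * masses) / M
  sqrt(sum(masses * rowSums(sweep(coords, 2L, com)^2)) / M)
}

#' Rg time series over a trajectory
#'
#' @param traj a [trajectory()]; masses come from the topology.
#' @param selection atom indices (default all).
#' @return an `md_series` in Angstrom.
#' @export
rg_series <- function(traj, selection = NULL) {
  selection <- selection %||% seq_len(n_atoms(traj))
  if (length(selection) == 0L) stop("empty selection", call. = FALSE)
  masses <- traj$topology$mass[selection]
  vals <- vapply(seq_len(n_frames(traj)), function(f)
    radius_of_gyration(frame_coords(traj, f)[selection, , drop = FALSE],
                       masses), numeric(1))
  md_series(vals, traj$times, "Rg (A)")
}

# Deterministic Fibonacci lattice of n points on the unit sphere.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1L)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Samples a deterministic Fibonacci lattice of `n_points` on each atom's
#' probe-inflated sphere (radius `r_i + probe`) and counts points not
#' buried inside any neighbor's inflated sphere; the per-atom SASA is the
#' accessible fraction times the sphere area.  The point set is
#' deterministic, so results are bit-reproducible.
#'
#' @param coords `N x 3` coordinates (Angstrom).
#' @param vdw_radii per-atom van der Waals radii (Angstrom, > 0).
#' @param probe probe radius, Angstrom (default 1.4, water).
#' @param n_points sphere sample points per atom (default 960, >= 12).
#' @return list with `total` (Angstrom^2), `total_nm2` (nm^2) and
#'   `per_atom` (Angstrom^2).
#' @export
sasa_shrake_rupley <- function(coords, vdw_radii, probe = 1.4,
                               n_points = 960L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (length(vdw_radii) != n)
    stop("vdw_radii length must match atom count", call. = FALSE)
  if (any(vdw_radii <= 0)) stop("radii must be > 0", call. = FALSE)
  if (n_points < 12L) stop("n_points must be >= 12", call. = FALSE)
  sphere <- fibonacci_sphere(n_points)
  R <- vdw_radii + probe
  per_atom <- numeric(n)
  # neighbor prefilter: only atoms within R_i + R_j can bury points
  d2 <- as.matrix(stats::dist(coords))^2
  for (i in seq_len(n)) {
    pts <- sweep(sphere * R[i], 2L, coords[i, ], "+")
    nbr <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    acc <- rep(TRUE, n_points)
    for (j in nbr) {
      dx <- sweep(pts, 2L, coords[j, ])
      acc <- acc & (rowSums(dx^2) >= R[j]^2)
      if (!any(acc)) break
    }
    per_atom[i] <- sum(acc) / n_points * 4 * pi * R[i]^2
  }
  list(total = sum(per_atom), total_nm2 = sum(per_atom) / 100,
       per_atom = per_atom)
}

#' SASA time series over a trajectory
#'
#' @param traj a [trajectory()]; radii come from the topology.
#' @param selection atom indices (default all).
#' @param probe,n_points see [sasa_shrake_rupley()].
#' @param units `"nm2"` (default, as commonly reported) or `"A2"`.
#' @return an `md_series`.
#' @export
sasa_series <- function(traj, selection = NULL, probe = 1.4,
                        n_points = 960L, units = c("nm2", "A2")) {
  units <- match.arg(units)
  selection <- selection %||% seq_len(n_atoms(traj))
  if (length(selection) == 0L) stop("empty selection", call. = FALSE)
  radii <- traj$topology$vdw_radius[selection]
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    s <- sasa_shrake_rupley(frame_coords(traj, f)[selection, , drop = FALSE],
                            radii, probe, n_points)
    if (units == "nm2") s$total_nm2 else s$total
  }, numeric(1))
  md_series(vals, traj$times, paste0("SASA (", units, ")"))
}

#' Geometric hydrogen-bond criteria
#'
#' Defaults follow the common GROMACS convention: donor-acceptor distance
#' at most 3.5 Angstrom and hydrogen-donor-acceptor angle at most 30
#' degrees.
#'
#' @param max_da_dist maximum D...A distance, Angstrom (> 0).
#' @param max_hda_angle maximum H-D...A angle, degrees (0, 180].
#' @return list of criteria.
#' @export
hbond_criteria <- function(max_da_dist = 3.5, max_hda_angle = 30) {
  if (max_da_dist <= 0) stop("distance cutoff must be > 0", call. = FALSE)
  if (max_hda_angle <= 0 || max_hda_angle > 180)
    stop("angle cutoff must be in (0, 180]", call. = FALSE)
  list(max_da_dist = max_da_dist, max_hda_angle = max_hda_angle)
}

# H-bond count for one frame given donor-heavy, hydrogen and acceptor
# indices; roles and hydrogen parents come from the topology.
hbond_count_frame <- function(coords, topology, donors, acceptors,
                              criteria) {
  hyd <- which(topology$hbond_role == "hydrogen" &
                 topology$hydrogen_parent %in% donors)
  count <- 0L
  for (h in hyd) {
    d <- topology$hydrogen_parent[h]
    for (a in acceptors) {
      if (a == d) next
      v_da <- coords[a, ] - coords[d, ]
      dist_da <- sqrt(sum(v_da^2))
      if (dist_da > criteria$max_da_dist) next
      v_dh <- coords[h, ] - coords[d, ]
      cosang <- sum(v_dh * v_da) /
        (sqrt(sum(v_dh^2)) * dist_da)
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang <= criteria$max_hda_angle) count <- count + 1L
    }
  }
  count
}

#' Hydrogen-bond count time series
#'
#' Per frame, counts (donor-H, acceptor) pairs meeting the geometric
#' criteria where the donor heavy atom belongs to `donor_selection` and
#' the acceptor to `acceptor_selection` (e.g. ligand donors vs protein
#' acceptors).  Roles and hydrogen parents must be annotated in the
#' topology.
#'
#' @param traj a [trajectory()].
#' @param donor_selection atom indices eligible as donor heavy atoms.
#' @param acceptor_selection atom indices eligible as acceptors.
#' @param criteria a [hbond_criteria()].
#' @return an `md_series` of integer counts.
#' @export
hbond_count_series <- function(traj, donor_selection, acceptor_selection,
                               criteria = hbond_criteria()) {
  top <- traj$topology
  if (!all(c("hbond_role", "hydrogen_parent") %in% names(top)))
    stop("topology lacks hbond role annotations", call. = FALSE)
  donors <- intersect(donor_selection,
                      which(top$hbond_role == "donor-heavy"))
  acceptors <- intersect(acceptor_selection,
                         which(top$hbond_role == "acceptor"))
  vals <- vapply(seq_len(n_frames(traj)), function(f)
    hbond_count_frame(frame_coords(traj, f), top, donors, acceptors,
                      criteria), integer(1))
  md_series(as.numeric(vals), traj$times, "H-bonds (count)")
}

#' Cartesian principal component analysis of a trajectory
#'
#' Frames are superposed to the mean structure (fit to the first frame,
#' recompute the mean, refit once), the `3N`-dimensional coordinate
#' covariance is eigendecomposed, and per-frame projections onto the
#' leading components are reported in nm (coordinates / 10 from
#' Angstrom).  The covariance is mass-unweighted.
#'
#' @param traj a [trajectory()].
#' @param selection atom indices (default all).
#' @param fit superpose frames first (default TRUE).
#' @param n_components number of projection columns to return (default 2).
#' @return object of class `md_pca`: `eigenvalues` (nm^2, descending),
#'   `vectors` (3N x n_components, orthonormal), `mean_structure`
#'   (Angstrom), `projections` (frames x n_components, nm), `ranges`
#'   (per-PC min/max, nm), `trace` (nm^2).
#' @export
pca_trajectory <- function(traj, selection = NULL, fit = TRUE,
                           n_components = 2L) {
  selection <- selection %||% seq_len(n_atoms(traj))
  if (length(selection) == 0L) stop("empty selection", call. = FALSE)
  nf <- n_frames(traj)
  if (nf < 2L) stop("PCA needs at least 2 frames", call. = FALSE)
  frames <- lapply(seq_len(nf), function(f)
    frame_coords(traj, f)[selection, , drop = FALSE])
  if (fit) {
    ref <- frames[[1L]]
    frames <- lapply(frames, function(m) kabsch_superpose(m, ref)$fitted)
    mean_struct <- Reduce(`+`, frames) / nf
    frames <- lapply(frames, function(m)
      kabsch_superpose(m, mean_struct)$fitted)
  }
  mean_struct <- Reduce(`+`, frames) / nf
  X <- t(vapply(frames, function(m) as.vector(t(m - mean_struct)),
                numeric(3L * length(selection)))) / 10  # Angstrom -> nm
  C <- stats::cov(X) * (nf - 1) / nf  # population covariance over frames
  eig <- eigen(C, symmetric = TRUE)
  nc <- min(n_components, ncol(eig$vectors))
  proj <- X %*% eig$vectors[, seq_len(nc), drop = FALSE]
  ranges <- apply(proj, 2L, range)
  structure(list(eigenvalues = pmax(eig$values, 0),
                 vectors = eig$vectors[, seq_len(nc), drop = FALSE],
                 all_vectors = eig$vectors,
                 mean_structure = mean_struct,
                 projections = proj,
                 ranges = ranges,
                 trace = sum(diag(C))),
            class = "md_pca")
}

#' @export
print.md_pca <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  cat(sprintf("md_pca: PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * x$eigenvalues[1L] / tot,
              100 * x$eigenvalues[2L] / tot))
  invisible(x)
}

#' Free-energy landscape by Boltzmann inversion
#'
#' Bins the per-frame (PC1, PC2) projections into a 2-D histogram and maps
#' occupancy probabilities to free energies
#' `G_b = -kB T ln(P_b / P_max)`, so the most occupied bin has G = 0 and
#' empty bins are masked (NA).  At 300 K, `kB T = 2.494 kJ/mol`.
#'
#' @param projections two-column matrix (or data.frame) of PC1/PC2 values
#'   per frame, in nm.
#' @param n_bins bins per axis (default 32).
#' @param temperature Kelvin (default 300).
#' @param units `"kJ/mol"` (default) or `"kT"`.
#' @return object of class `md_fel`: `x_edges`, `y_edges`, `probability`
#'   (bins x bins, sums to 1 over occupied bins), `G` (same shape, NA in
#'   empty bins, min 0), `kT` (kJ/mol), `units`.
#' @export
fel <- function(projections, n_bins = 32L, temperature = 300,
                units = c("kJ/mol", "kT")) {
  units <- match.arg(units)
  projections <- as.matrix(projections)
  if (nrow(projections) < 1L) stop("need at least one frame", call. = FALSE)
  if (n_bins < 1L) stop("n_bins must be >= 1", call. = FALSE)
  kT <- 0.0083144621 * temperature  # kJ/mol
  rng <- function(v) {
    r <- range(v)
    if (r[1L] == r[2L]) r + c(-0.5, 0.5) else r
  }
  xe <- seq(rng(projections[, 1L])[1L], rng(projections[, 1L])[2L],
            length.out = n_bins + 1L)
  ye <- seq(rng(projections[, 2L])[1L], rng(projections[, 2L])[2L],
            length.out = n_bins + 1L)
  ix <- pmin(pmax(findInterval(projections[, 1L], xe,
                               rightmost.closed = TRUE), 1L), n_bins)
  iy <- pmin(pmax(findInterval(projections[, 2L], ye,
                               rightmost.closed = TRUE), 1L), n_bins)
  counts <- matrix(0, n_bins, n_bins)
  for (k in seq_len(nrow(projections)))
    counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
  P <- counts / sum(counts)
  G <- matrix(NA_real_, n_bins, n_bins)
  occ <- P > 0
  scale <- if (units == "kT") 1 else kT
  G[occ] <- -scale * log(P[occ] / max(P))
  structure(list(x_edges = xe, y_edges = ye, probability = P, G = G,
                 kT = kT, units = units, temperature = temperature),
            class = "md_fel")
}

#' Equilibrium-window verdict for a structural time series
#'
#' Tests whether, after `t_start`, a series stays within a relative band
#' of its post-`t_start` mean — the working definition of an equilibrated
#' structural parameter (default: after 100 ns, within +/- 10% of the
#' window mean).
#'
#' @param series an `md_series` with times in ns.
#' @param t_start window start (ns, default 100).
#' @param band allowed relative deviation from the window mean
#'   (default 0.10).
#' @return list with `equilibrated` (logical), `window_mean`, `window_sd`,
#'   `violation_fraction` and `n_window`.
#' @export
equilibrium_window <- function(series, t_start = 100, band = 0.10) {
  idx <- which(series$times > t_start)
  if (length(idx) == 0L)
    stop("series does not extend beyond t_start = ", t_start, call. = FALSE)
  v <- series$values[idx]
  m <- mean(v)
  viol <- abs(v - m) > band * abs(m)
  list(equilibrated = !any(viol),
       window_mean = m,
       window_sd = if (length(v) > 1L) stats::sd(v) else 0,
       violation_fraction = mean(viol),
       n_window = length(v))
}
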