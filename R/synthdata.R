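#' Generate a synthetic docking score table with planted binders
#'
#' Emulates the statistical structure of a multi-program docking campaign:
#' each compound has a latent affinity, every program observes it plus
#' independent Gaussian noise scaled so any two program columns correlate
#' at `rho`, and a subset of "true binders" is shifted by a fixed effect.
#' This is a stand-in noise model for pipeline testing, not a claim about
#' real docking error structure.
#'
#' @param n_compounds number of compounds.
#' @param n_programs number of score columns (default 7).
#' @param rho target inter-program score correlation in [0, 1].
#' @param n_binders number of planted strong binders.
#' @param effect binder shift in kcal/mol (negative = stronger binding,
#'   default -3).
#' @param latent_mean,latent_sd latent affinity distribution (kcal/mol;
#'   defaults -6.5 and 0.8, the score spread typical of a pre-filtered
#'   hit list).
#' @param seed RNG seed; the generator is a pure function of its
#'   arguments.
#' @return list with `table` (a [score_table()]) and `binders` (character
#'   ids of the planted binders).
#' @export
gen_score_table <- function(n_compounds = 100L, n_programs = 7L,
                            rho = 0.8, n_binders = 5L, effect = -3,
                            latent_mean = -6.5, latent_sd = 0.8,
                            seed = 1L) {
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]", call. = FALSE)
  if (n_binders > n_compounds)
    stop("more binders than compounds", call. = FALSE)
  with_seed(seed, {
    ids <- sprintf("CMP%04d", seq_len(n_compounds))
    latent <- stats::rnorm(n_compounds, latent_mean, latent_sd)
    binders <- sample(ids, n_binders)
    latent[ids %in% binders] <- latent[ids %in% binders] + effect
    # score_j = latent + noise; cor(two programs) = var_l / (var_l + var_n)
    noise_sd <- if (rho == 1) 0 else latent_sd * sqrt((1 - rho) / rho)
    vals <- vapply(seq_len(n_programs), function(j)
      latent + stats::rnorm(n_compounds, 0, noise_sd),
      numeric(n_compounds))
    vals <- matrix(vals, nrow = n_compounds,
                   dimnames = list(NULL, sprintf("PROG%d",
                                                 seq_len(n_programs))))
    list(table = score_table(vals, compound_ids = ids),
         binders = binders)
  })
}

# Random proper rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3L))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

#' Generate a synthetic harmonic trajectory with known fluctuations
#'
#' Frames are the reference structure plus iid Gaussian displacement with
#' per-atom amplitude `sigma_i` on each coordinate (so the expected RMSF
#' of atom i is `sigma_i * sqrt(3)`), optionally composed with a random
#' global rigid motion per frame.  A topology sidecar with masses, radii
#' and hydrogen-bond roles is emitted alongside.
#'
#' @param n_atoms atoms per frame.
#' @param n_frames frames.
#' @param sigma per-atom displacement amplitude (Angstrom), scalar or
#'   length `n_atoms`.
#' @param rigid_motions apply a random rotation + translation to every
#'   frame (default FALSE).
#' @param frame_interval_ns spacing of the time grid (default 0.01 ns =
#'   10 ps).
#' @param box_size extent of the random reference structure (Angstrom).
#' @param seed RNG seed.
#' @return list with `traj` (a [trajectory()]), `sigma` (per-atom ground
#'   truth), `reference` (N x 3) and `rg_reference`.
#' @export
gen_trajectory <- function(n_atoms = 50L, n_frames = 1000L, sigma = 0.2,
                           rigid_motions = FALSE,
                           frame_interval_ns = 0.01,
                           box_size = 20, seed = 1L) {
  sigma <- rep_len(sigma, n_atoms)
  if (any(sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  with_seed(seed, {
    ref <- matrix(stats::runif(n_atoms * 3L, 0, box_size), ncol = 3L)
    coords <- array(0, dim = c(n_frames, n_atoms, 3L))
    for (f in seq_len(n_frames)) {
      disp <- matrix(stats::rnorm(n_atoms * 3L, 0, sigma), ncol = 3L)
      m <- ref + disp
      if (rigid_motions) {
        R <- random_rotation()
        tr <- stats::runif(3L, -5, 5)
        m <- m %*% t(R) + matrix(tr, n_atoms, 3L, byrow = TRUE)
      }
      coords[f, , ] <- m
    }
    roles <- rep(c("donor-heavy", "hydrogen", "acceptor", "none"),
                 length.out = n_atoms)
    top <- data.frame(
      atom_name = sprintf("C%d", seq_len(n_atoms)),
      residue_id = ((seq_len(n_atoms) - 1L) %/% 5L) + 1L,
      mass = 12.011,
      vdw_radius = 1.7,
      hbond_role = roles,
      hydrogen_parent = ifelse(roles == "hydrogen",
                               pmax(1L, seq_len(n_atoms) - 1L),
                               NA_integer_),
      stringsAsFactors = FALSE
    )
    times <- seq_len(n_frames) * frame_interval_ns
    list(traj = trajectory(coords, top, times = times),
         sigma = sigma, reference = ref,
         rg_reference = radius_of_gyration(ref, top$mass))
  })
}

#' Generate two-state (PC1, PC2) projection samples
#'
#' A mixture of two Gaussian clusters with stated occupancies, the test
#' harness for free-energy-landscape basin depths: the expected free
#' energy difference between the basin minima is `kB T ln(p1 / p2)`.
#'
#' @param n_frames samples.
#' @param p1,p2 state occupancies, must sum to 1.
#' @param centers 2 x 2 matrix of state centers (rows = states, nm).
#' @param spread within-state SD (nm).
#' @param seed RNG seed.
#' @return list with `projections` (n x 2 matrix) and `state` (1/2 labels).
#' @export
gen_two_state_projections <- function(n_frames = 20000L, p1 = 0.8,
                                      p2 = 0.2,
                                      centers = rbind(c(-1, 0), c(1, 0)),
                                      spread = 0.15, seed = 1L) {
  if (p1 <= 0 || p2 <= 0 || abs(p1 + p2 - 1) > 1e-12)
    stop("occupancies must be positive and sum to 1", call. = FALSE)
  with_seed(seed, {
    state <- sample(1:2, n_frames, replace = TRUE, prob = c(p1, p2))
    proj <- centers[state, , drop = FALSE] +
      matrix(stats::rnorm(2L * n_frames, 0, spread), ncol = 2L)
    list(projections = proj, state = state)
  })
}

#' Generate synthetic MM-PBSA component records
#'
#' Draws per-term means around supplied true components with Gaussian
#' noise, and computes the stated totals by the same additivity and
#' quadrature rules the bookkeeping validates — so generated tables
#' always pass [validate_components_table()] until corrupted.
#'
#' @param true_components data.frame with `compound_id` and
#'   `<term>_mean`/`<term>_sd` columns for the four terms.
#' @param noise_sd SD of the perturbation added to each term mean
#'   (kJ/mol, default 0 = exact copy).
#' @param seed RNG seed.
#' @return data.frame in the [read_energy_components()] schema including
#'   stated totals.
#' @export
gen_mmpbsa <- function(true_components, noise_sd = 0, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  terms <- c("vdw", "elec", "polar_solv", "sasa")
  with_seed(seed, {
    out <- true_components
    for (term in terms) {
      mcol <- paste0(term, "_mean")
      out[[mcol]] <- out[[mcol]] +
        stats::rnorm(nrow(out), 0, noise_sd)
    }
    m <- sapply(terms, function(t) out[[paste0(t, "_mean")]])
    s <- sapply(terms, function(t) out[[paste0(t, "_sd")]])
    m <- matrix(m, nrow = nrow(out)); s <- matrix(s, nrow = nrow(out))
    out$total_mean <- rowSums(m)
    out$total_sd <- sqrt(rowSums(s^2))
    out
  })
}
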