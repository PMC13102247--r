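#' Conceptual-DFT global reactivity descriptors
#'
#' Koopmans-type descriptors from frontier-orbital energies:
#' \describe{
#'   \item{gap}{`E_LUMO - E_HOMO`, chemical-stability proxy}
#'   \item{IP, EA}{ionization potential `-E_HOMO`, electron affinity
#'     `-E_LUMO`}
#'   \item{chi}{electronegativity `(IP + EA) / 2`}
#'   \item{mu}{chemical potential `-chi`}
#'   \item{eta}{global hardness `(IP - EA) / 2`}
#'   \item{sigma}{global softness `1 / eta`}
#'   \item{omega}{electrophilicity index `chi^2 / (2 * eta)`}
#' }
#' `sign_mode = "published"` flips the printed signs of chi and mu
#' (electronegativity reported negative, chemical potential positive), a
#' convention some published tables use; magnitudes are identical in both
#' modes.  A degenerate gap (`E_HOMO == E_LUMO`) leaves `sigma` and
#' `omega` as `Inf` rather than silently dropping the record.
#'
#' @param E_HOMO,E_LUMO frontier-orbital energies (same units; values are
#'   reported in the units of the input and never rescaled).
#' @param sign_mode `"standard"` or `"published"`.
#' @param dipole optional dipole moment (Debye), passed through.
#' @param compound_id optional identifier, passed through.
#' @return data.frame with one row per input and the columns above.
#' @export
compute_descriptors <- function(E_HOMO, E_LUMO,
                                sign_mode = c("standard", "published"),
                                dipole = NA_real_,
                                compound_id = NULL) {
  sign_mode <- match.arg(sign_mode)
  if (any(!is.finite(E_HOMO)) || any(!is.finite(E_LUMO)))
    stop("orbital energies must be finite", call. = FALSE)
  if (any(E_HOMO > E_LUMO))
    stop("E_HOMO must not exceed E_LUMO", call. = FALSE)
  IP <- -E_HOMO
  EA <- -E_LUMO
  chi <- (IP + EA) / 2
  mu <- -chi
  eta <- (IP - EA) / 2
  sigma <- ifelse(eta > 0, 1 / eta, Inf)
  omega <- ifelse(eta > 0, chi^2 / (2 * eta), Inf)
  if (sign_mode == "published") {
    tmp <- chi
    chi <- -abs(tmp)
    mu <- abs(tmp)
  }
  out <- data.frame(
    compound_id = compound_id %||% rep(NA_character_, length(E_HOMO)),
    E_HOMO = E_HOMO, E_LUMO = E_LUMO,
    gap = E_LUMO - E_HOMO, IP = IP, EA = EA,
    chi = chi, mu = mu, eta = eta, sigma = sigma, omega = omega,
    dipole = rep_len(dipole, length(E_HOMO)),
    sign_mode = rep_len(sign_mode, length(E_HOMO)),
    stringsAsFactors = FALSE
  )
  out
}

#' Descriptor table for a set of orbital records
#'
#' Vectorized [compute_descriptors()] over the rows of an orbital-record
#' data.frame (see [read_orbitals()]); input order is preserved.
#'
#' @param records data.frame with `compound_id`, `E_HOMO`, `E_LUMO` and
#'   optional `dipole`.
#' @param sign_mode see [compute_descriptors()].
#' @return data.frame of descriptors, one row per record.
#' @export
descriptor_table <- function(records, sign_mode = "standard") {
  if (nrow(records) == 0L)
    return(compute_descriptors(numeric(0), numeric(0),
                               sign_mode = sign_mode))
  compute_descriptors(records$E_HOMO, records$E_LUMO,
                      sign_mode = sign_mode,
                      dipole = records$dipole %||% NA_real_,
                      compound_id = records$compound_id)
}
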