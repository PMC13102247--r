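#' Combine MM-PBSA energy components
#'
#' Total binding energy is the exact sum of the four term means (van der
#' Waals, electrostatic, polar solvation, SASA); its SD is the quadrature
#' combination `sqrt(sum of squared term SDs)` of the per-term SDs, the
#' propagation rule for independent uncertainties.  When the record
#' carries a stated total, the result is validated against it.
#'
#' @param record one-row data.frame in the [read_energy_components()]
#'   schema (or a list with the same fields).
#' @param tol agreement tolerance against a stated total, kJ/mol
#'   (default 0.002, half a unit in the last printed digit).
#' @return list with `compound_id`, `total_mean`, `total_sd` (kJ/mol),
#'   `shares` (per-term fraction of the absolute total), and when a stated
#'   total is present `stated_total_mean`, `stated_total_sd`,
#'   `valid_mean`, `valid_sd`.
#' @export
combine_components <- function(record, tol = 0.002) {
  terms <- c("vdw", "elec", "polar_solv", "sasa")
  for (term in terms) {
    if (is.null(record[[paste0(term, "_mean")]]) ||
        is.na(record[[paste0(term, "_mean")]]))
      stop("missing MM-PBSA term: ", term, call. = FALSE)
  }
  means <- vapply(terms, function(t) record[[paste0(t, "_mean")]],
                  numeric(1))
  sds <- vapply(terms, function(t) record[[paste0(t, "_sd")]] %||% 0,
                numeric(1))
  if (any(sds < 0, na.rm = TRUE))
    stop("negative SD", call. = FALSE)
  total <- sum(means)
  total_sd <- sqrt(sum(sds^2))
  out <- list(compound_id = record$compound_id %||% NA_character_,
              total_mean = total, total_sd = total_sd,
              term_means = means, term_sds = sds,
              shares = abs(means) / sum(abs(means)))
  if (!is.null(record$total_mean) && !is.na(record$total_mean)) {
    out$stated_total_mean <- record$total_mean
    out$stated_total_sd <- record$total_sd
    out$valid_mean <- abs(total - record$total_mean) <= tol
    out$valid_sd <- if (is.null(record$total_sd) || is.na(record$total_sd))
      NA else abs(total_sd - record$total_sd) <= tol
  }
  out
}

#' Validate a table of MM-PBSA component records
#'
#' Runs [combine_components()] on every row and reports, per compound,
#' the recomputed total and whether it agrees with the stated total
#' (mean additivity and quadrature SD, each within `tol`).
#'
#' @param records data.frame from [read_energy_components()].
#' @param tol kJ/mol tolerance (default 0.002).
#' @return data.frame with one row per record: `compound_id`,
#'   `total_mean`, `total_sd`, `stated_total_mean`, `stated_total_sd`,
#'   `valid_mean`, `valid_sd`, `valid` (both checks, NA-safe).
#' @export
validate_components_table <- function(records, tol = 0.002) {
  if (nrow(records) == 0L)
    return(data.frame(compound_id = character(0), total_mean = numeric(0),
                      total_sd = numeric(0),
                      stated_total_mean = numeric(0),
                      stated_total_sd = numeric(0),
                      valid_mean = logical(0), valid_sd = logical(0),
                      valid = logical(0)))
  rows <- lapply(seq_len(nrow(records)), function(i) {
    r <- combine_components(records[i, , drop = FALSE], tol = tol)
    data.frame(compound_id = r$compound_id,
               total_mean = r$total_mean, total_sd = r$total_sd,
               stated_total_mean = r$stated_total_mean %||% NA_real_,
               stated_total_sd = r$stated_total_sd %||% NA_real_,
               valid_mean = r$valid_mean %||% NA,
               valid_sd = r$valid_sd %||% NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$valid <- out$valid_mean & (is.na(out$valid_sd) | out$valid_sd)
  out
}
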