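#' Default stability criteria thresholds
#'
#' The hard screen applied before scoring: average RMSD below 3.5
#' Angstrom, average RMSF below 1.65 Angstrom, and MM-PBSA binding energy
#' below -60 kJ/mol.  All comparisons are strict (a metric exactly at a
#' threshold fails).
#'
#' @return named list of thresholds.
#' @export
default_criteria <- function() {
  list(rmsd_max = 3.5, rmsf_max = 1.65, binding_max = -60)
}

#' Apply hard stability criteria to candidate metrics
#'
#' @param metrics data.frame with one row per candidate and columns
#'   `compound_id`, `rmsd_mean` (Angstrom), `rmsf_mean` (Angstrom),
#'   `binding_energy` (kJ/mol); other columns pass through.
#' @param thresholds list as from [default_criteria()].
#' @return data.frame with logical columns `rmsd_pass`, `rmsf_pass`,
#'   `binding_pass` and `all_pass`.
#' @export
apply_criteria <- function(metrics, thresholds = default_criteria()) {
  out <- data.frame(compound_id = metrics$compound_id,
                    stringsAsFactors = FALSE)
  out$rmsd_pass <- metrics$rmsd_mean < thresholds$rmsd_max
  out$rmsf_pass <- metrics$rmsf_mean < thresholds$rmsf_max
  out$binding_pass <- metrics$binding_energy < thresholds$binding_max
  out$all_pass <- out$rmsd_pass & out$rmsf_pass & out$binding_pass
  out
}

#' Min-max sub-score on a 0-10 scale
#'
#' Linear map of a raw metric across candidates onto [0, 10] with the best
#' value (per orientation) mapped to 10 and the worst to 0.  When all
#' values are identical the map is degenerate and every candidate gets the
#' midpoint 5.
#'
#' @param values numeric vector across candidates (no NAs).
#' @param orientation `"lower_is_better"` or `"higher_is_better"`.
#' @return numeric vector on [0, 10].
#' @export
subscore <- function(values, orientation = c("lower_is_better",
                                             "higher_is_better")) {
  orientation <- match.arg(orientation)
  if (anyNA(values)) stop("NA in sub-score input", call. = FALSE)
  rng <- range(values)
  if (rng[1L] == rng[2L]) return(rep(5, length(values)))
  s <- (values - rng[1L]) / (rng[2L] - rng[1L]) * 10
  if (orientation == "lower_is_better") 10 - s else s
}

#' Default stability-score weights
#'
#' RMSD consistency 25%, RMSF 25%, binding energy 30%, hydrogen-bond
#' stability 20%.
#'
#' @return named numeric vector summing to 1.
#' @export
default_weights <- function() {
  c(rmsd = 0.25, rmsf = 0.25, binding = 0.30, hbond = 0.20)
}

#' Weighted stability score and priority tiers
#'
#' Combines four sub-scores — RMSD consistency (the SD of the RMSD series
#' by default, selectable to the mean via `rmsd_metric`), mean RMSF,
#' MM-PBSA binding energy, and hydrogen-bond stability — into a composite
#' on [0, 10] by the weighted sum, then assigns priority tiers by
#' composite cut-offs (defaults: HIGH >= 8, MEDIUM >= 7, else LOW).
#'
#' Hydrogen-bond stability is quantified as
#' `10 * (1 - coefficient of variation of the count series)`, clipped to
#' [0, 10], so sustained bonding with little variability scores high; if
#' the metrics table carries no `hbond_cv` column the hbond weight is
#' dropped and the remaining weights renormalized.
#'
#' @param metrics data.frame with `compound_id`, `rmsd_mean`, `rmsd_sd`,
#'   `rmsf_mean`, `binding_energy` and optionally `hbond_cv` columns.
#' @param weights named vector (`rmsd`, `rmsf`, `binding`, `hbond`)
#'   summing to 1 (tolerance 1e-9).
#' @param tiers named list of lower composite cut-offs for `HIGH` and
#'   `MEDIUM`.
#' @param rmsd_metric `"sd"` (consistency, default) or `"mean"`.
#' @return data.frame ordered by descending composite: sub-score columns,
#'   `composite` and `tier`.
#' @export
stability_score <- function(metrics, weights = default_weights(),
                            tiers = list(HIGH = 8, MEDIUM = 7),
                            rmsd_metric = c("sd", "mean")) {
  rmsd_metric <- match.arg(rmsd_metric)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1", call. = FALSE)
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  n <- nrow(metrics)
  if (n < 1L) stop("no candidates", call. = FALSE)
  rmsd_raw <- if (rmsd_metric == "sd") metrics$rmsd_sd else
    metrics$rmsd_mean
  sub <- data.frame(
    compound_id = metrics$compound_id,
    rmsd_sub = subscore(rmsd_raw, "lower_is_better"),
    rmsf_sub = subscore(metrics$rmsf_mean, "lower_is_better"),
    binding_sub = subscore(metrics$binding_energy, "lower_is_better"),
    stringsAsFactors = FALSE
  )
  w <- weights
  if (!is.null(metrics$hbond_cv) && !anyNA(metrics$hbond_cv)) {
    sub$hbond_sub <- pmin(10, pmax(0, 10 * (1 - metrics$hbond_cv)))
  } else {
    w <- w[names(w) != "hbond"]
    w <- w / sum(w)
  }
  comp <- w[["rmsd"]] * sub$rmsd_sub + w[["rmsf"]] * sub$rmsf_sub +
    w[["binding"]] * sub$binding_sub
  if (!is.null(sub$hbond_sub)) comp <- comp + w[["hbond"]] * sub$hbond_sub
  sub$composite <- comp
  sub$tier <- ifelse(comp >= tiers$HIGH, "HIGH",
                     ifelse(comp >= tiers$MEDIUM, "MEDIUM", "LOW"))
  sub[order(-sub$composite, sub$compound_id), , drop = FALSE]
}

#' Default funnel configuration
#'
#' All tunables of the end-to-end prioritization in one list: the hit
#' filter (program column, cutoff, strictness), consensus size `k`,
#' descriptor sign mode, criteria thresholds, stability weights and tier
#' cut-offs.
#'
#' @return nested list of settings.
#' @export
default_funnel_config <- function() {
  list(
    filter = list(column = "ADT", cutoff = -6.0, strict = TRUE),
    consensus = list(k = 6L),
    reactivity = list(sign_mode = "standard"),
    criteria = default_criteria(),
    stability = list(weights = as.list(default_weights()),
                     tiers = list(HIGH = 8, MEDIUM = 7),
                     rmsd_metric = "sd")
  )
}

#' Read a funnel configuration file
#'
#' YAML key-value file with the same structure as
#' [default_funnel_config()]; missing keys fall back to the defaults.
#'
#' @param path YAML file.
#' @return nested list of settings.
#' @export
read_funnel_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_funnel_config(), user)
}

#' Run the full prioritization funnel
#'
#' Orchestrates the pipeline in study order: threshold filter on the
#' docking table, radar-area consensus selection of the top `k`,
#' reactivity-descriptor annotation of the selected compounds, the hard
#' criteria screen, and the weighted stability ranking.  Every stage's
#' intermediate is returned, with provenance (axis order, thresholds,
#' weights, config digest) alongside.
#'
#' @param score_table a [score_table()] of docking scores.
#' @param orbital_records data.frame from [read_orbitals()], or NULL to
#'   skip descriptor annotation.
#' @param metrics data.frame of per-candidate MD/energy metrics (see
#'   [stability_score()]), or NULL to stop after the consensus stage.
#' @param config nested list as from [default_funnel_config()].
#' @return object of class `funnel_result` with elements `filtered`,
#'   `rank_matrix`, `consensus`, `descriptors`, `criteria`, `ranking` and
#'   `provenance`.
#' @export
run_funnel <- function(score_table, orbital_records = NULL, metrics = NULL,
                       config = default_funnel_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  filtered <- stage("filter", {
    validate_score_table(score_table)
    filter_by_threshold(score_table, config$filter$column,
                        config$filter$cutoff, config$filter$strict)
  })
  rank_matrix <- stage("consensus", build_rank_matrix(filtered))
  consensus <- stage("consensus",
                     consensus_select(rank_matrix, config$consensus$k))
  descriptors <- NULL
  if (!is.null(orbital_records)) {
    descriptors <- stage("reactivity", {
      sel <- orbital_records[
        orbital_records$compound_id %in% consensus$selected, , drop = FALSE]
      descriptor_table(sel, sign_mode = config$reactivity$sign_mode)
    })
  }
  criteria <- NULL; ranking <- NULL
  if (!is.null(metrics)) {
    criteria <- stage("criteria", apply_criteria(metrics, config$criteria))
    ranking <- stage("stability", stability_score(
      metrics, weights = unlist(config$stability$weights),
      tiers = config$stability$tiers,
      rmsd_metric = config$stability$rmsd_metric))
  }
  prov <- list(
    axis_order = consensus$program_names,
    filter = config$filter,
    k = config$consensus$k,
    thresholds = config$criteria,
    weights = unlist(config$stability$weights),
    config_digest = fnv1a(paste(deparse(config), collapse = ""))
  )
  structure(list(filtered = filtered, rank_matrix = rank_matrix,
                 consensus = consensus, descriptors = descriptors,
                 criteria = criteria, ranking = ranking,
                 provenance = prov),
            class = "funnel_result")
}

#' @export
print.funnel_result <- function(x, ...) {
  cat("funnel_result\n")
  cat("  filtered compounds:", length(x$filtered$compound_ids), "\n")
  cat("  consensus top-", x$consensus$k, ": ",
      paste(x$consensus$selected, collapse = ", "), "\n", sep = "")
  if (!is.null(x$ranking)) {
    cat("  stability ranking:\n")
    print(x$ranking, row.names = FALSE)
  }
  invisible(x)
}
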