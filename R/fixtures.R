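#' Path to a packaged fixture
#'
#' The package ships the published tables of the source screening study as
#' plain CSV fixtures: the seven-program docking score table, the
#' published per-program rank matrix, the frontier-orbital energies with
#' derived reactivity descriptors, the MM-PBSA component table, and the
#' MD observable summaries.
#'
#' @param name one of `"docking_scores"`, `"docking_ranks_published"`,
#'   `"frontier_orbitals"`, `"reactivity_published"`,
#'   `"mmpbsa_components"`, `"md_summaries_published"`.
#' @return file path inside the installed package.
#' @export
lf_fixture <- function(name = c("docking_scores", "docking_ranks_published",
                                "frontier_orbitals", "reactivity_published",
                                "mmpbsa_components",
                                "md_summaries_published")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, ".csv"), package = "leadfunnel",
              mustWork = TRUE)
}

#' Load the packaged docking score table
#' @return a [score_table()] (32 compounds x 7 programs, all columns
#'   minimized scores).
#' @export
fixture_docking_scores <- function() {
  read_score_table(lf_fixture("docking_scores"))
}

#' Load the published per-program rank matrix
#' @return integer matrix with compound ids as rownames.
#' @export
fixture_published_ranks <- function() {
  df <- utils::read.csv(lf_fixture("docking_ranks_published"),
                        check.names = FALSE)
  m <- as.matrix(df[, -1L])
  storage.mode(m) <- "integer"
  rownames(m) <- df$compound_id
  m
}

#' Load the packaged frontier-orbital records
#' @return data.frame as from [read_orbitals()].
#' @export
fixture_orbitals <- function() {
  read_orbitals(lf_fixture("frontier_orbitals"))
}

#' Load the published reactivity descriptor values
#' @return data.frame of the printed descriptor rows.
#' @export
fixture_reactivity_published <- function() {
  utils::read.csv(lf_fixture("reactivity_published"), check.names = FALSE)
}

#' Load the packaged MM-PBSA component table
#' @return data.frame as from [read_energy_components()].
#' @export
fixture_mmpbsa <- function() {
  read_energy_components(lf_fixture("mmpbsa_components"))
}

#' Load the published MD observable summaries
#'
#' Per-candidate mean and SD of RMSD, RMSF (Angstrom), radius of gyration
#' (Angstrom) and SASA (nm^2) as printed in the study, joined with the
#' MM-PBSA binding energies for the triage stage.
#'
#' @return data.frame with one row per MD candidate including a
#'   `binding_energy` column (kJ/mol).
#' @export
fixture_md_summaries <- function() {
  md <- utils::read.csv(lf_fixture("md_summaries_published"),
                        check.names = FALSE)
  en <- validate_components_table(fixture_mmpbsa())
  md$binding_energy <- en$total_mean[match(md$compound_id,
                                           en$compound_id)]
  md
}
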