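#' Construct a docking score table
#'
#' A `score_table` holds one row per compound and one column per docking
#' program, together with a per-column orientation flag saying whether
#' smaller values mean stronger predicted binding (the usual case for
#' docking energies in kcal/mol and for PLANTS-style scores, both of which
#' are minimized).
#'
#' @param values numeric matrix, compounds x programs.
#' @param compound_ids character vector of unique compound identifiers
#'   (defaults to `rownames(values)`).
#' @param program_names character vector of unique program labels
#'   (defaults to `colnames(values)`); the column order is preserved and
#'   later defines the radar axes of the consensus stage.
#' @param orientation `"lower_is_better"` or `"higher_is_better"`, recycled
#'   per column.
#' @return An object of class `score_table`.
#' @seealso [read_score_table()], [build_rank_matrix()]
#' @export
score_table <- function(values, compound_ids = rownames(values),
                        program_names = colnames(values),
                        orientation = "lower_is_better") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(compound_ids) || is.null(program_names))
    stop("compound_ids and program_names are required", call. = FALSE)
  orientation <- rep_len(orientation, ncol(values))
  obj <- structure(list(
    compound_ids = as.character(compound_ids),
    program_names = as.character(program_names),
    values = unname(values),
    orientation = orientation
  ), class = "score_table")
  validate_score_table(obj)
}

validate_score_table <- function(x) {
  stopifnot(inherits(x, "score_table"))
  if (nrow(x$values) == 0L) stop("score table has no rows", call. = FALSE)
  dup <- x$compound_ids[duplicated(x$compound_ids)]
  if (length(dup) > 0L)
    stop("duplicate compound_id: ", dup[1L], call. = FALSE)
  dupp <- x$program_names[duplicated(x$program_names)]
  if (length(dupp) > 0L)
    stop("duplicate program name: ", dupp[1L], call. = FALSE)
  if (nrow(x$values) != length(x$compound_ids) ||
      ncol(x$values) != length(x$program_names))
    stop("matrix dimensions do not match id/label counts", call. = FALSE)
  if (!all(is.finite(x$values)))
    stop("score table contains non-finite entries", call. = FALSE)
  if (!all(x$orientation %in% c("lower_is_better", "higher_is_better")))
    stop("orientation must be lower_is_better or higher_is_better",
         call. = FALSE)
  x
}

#' @export
print.score_table <- function(x, ...) {
  cat("score_table:", length(x$compound_ids), "compounds x",
      length(x$program_names), "programs\n")
  cat("programs:", paste(x$program_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.score_table <- function(x, ...) {
  df <- data.frame(compound_id = x$compound_ids, x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-1L] <- x$program_names
  df
}

#' Read a docking score table from CSV
#'
#' Expects a header row whose first column is `compound_id`, followed by one
#' numeric column per docking program.  Unicode minus signs (as they appear
#' in publisher tables) are normalized to ASCII on read.
#'
#' @param path path to a CSV file (or a connection).
#' @param orientation per-column orientation flags, recycled; default treats
#'   every program as a minimized score.
#' @return A [score_table()].
#' @export
read_score_table <- function(path, orientation = "lower_is_better") {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L)
    stop("expected a compound-id column plus at least one program column",
         call. = FALSE)
  if (nrow(df) == 0L) stop("score table body is empty", call. = FALSE)
  ids <- trimws(df[[1L]])
  vals <- vapply(names(df)[-1L], function(cn)
    parse_numeric_strict(df[[cn]], cn, id_hint = ids),
    numeric(nrow(df)))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(NULL, names(df)[-1L]))
  score_table(vals, compound_ids = ids, program_names = names(df)[-1L],
              orientation = orientation)
}

#' Write a docking score table to CSV
#'
#' Inverse of [read_score_table()]; round-trips exactly at full double
#' precision.
#'
#' @param x a [score_table()].
#' @param path output path.
#' @export
write_score_table <- function(x, path) {
  validate_score_table(x)
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read frontier-orbital energies
#'
#' Reads a CSV with columns `compound_id`, `E_HOMO`, `E_LUMO` and optional
#' `dipole` (Debye).  Energies are taken in the units of the source table
#' and not rescaled.
#'
#' @param path CSV path.
#' @return data.frame with one validated record per compound.
#' @export
read_orbitals <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("compound_id", "E_HOMO", "E_LUMO")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  out <- data.frame(
    compound_id = trimws(df$compound_id),
    E_HOMO = parse_numeric_strict(df$E_HOMO, "E_HOMO", df$compound_id),
    E_LUMO = parse_numeric_strict(df$E_LUMO, "E_LUMO", df$compound_id),
    stringsAsFactors = FALSE
  )
  out$dipole <- if ("dipole" %in% names(df))
    parse_numeric_strict(df$dipole, "dipole", df$compound_id) else NA_real_
  bad <- which(out$E_HOMO > out$E_LUMO)
  if (length(bad) > 0L)
    stop("E_HOMO > E_LUMO for ", out$compound_id[bad[1L]], call. = FALSE)
  if (!all(is.finite(out$E_HOMO)) || !all(is.finite(out$E_LUMO)))
    stop("orbital energies must be finite", call. = FALSE)
  out
}

#' Read MM-PBSA energy components
#'
#' Accepts either split columns (`vdw_mean`, `vdw_sd`, ..., optional
#' `total_mean`/`total_sd`) or "a ± b" cells in columns `vdw`, `elec`,
#' `polar_solv`, `sasa` and optional `total`.  All values in kJ/mol.
#'
#' @param path CSV path.
#' @return data.frame of validated component records, one per compound,
#'   with columns `<term>_mean`/`<term>_sd` for the four terms and, when
#'   stated in the source, `total_mean`/`total_sd`.
#' @export
read_energy_components <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!"compound_id" %in% names(df))
    stop("missing column(s): compound_id", call. = FALSE)
  terms <- c("vdw", "elec", "polar_solv", "sasa")
  out <- data.frame(compound_id = trimws(df$compound_id),
                    stringsAsFactors = FALSE)
  grab <- function(term) {
    mcol <- paste0(term, "_mean"); scol <- paste0(term, "_sd")
    if (all(c(mcol, scol) %in% names(df))) {
      cbind(parse_numeric_strict(df[[mcol]], mcol, df$compound_id),
            parse_numeric_strict(df[[scol]], scol, df$compound_id))
    } else if (term %in% names(df)) {
      parse_pm(df[[term]])
    } else {
      stop("missing MM-PBSA term: ", term, call. = FALSE)
    }
  }
  for (term in terms) {
    ms <- grab(term)
    out[[paste0(term, "_mean")]] <- ms[, 1L]
    out[[paste0(term, "_sd")]] <- ms[, 2L]
    if (any(ms[, 2L] < 0, na.rm = TRUE))
      stop("negative SD in term ", term, call. = FALSE)
  }
  if (all(c("total_mean", "total_sd") %in% names(df))) {
    out$total_mean <- parse_numeric_strict(df$total_mean, "total_mean",
                                           df$compound_id)
    out$total_sd <- parse_numeric_strict(df$total_sd, "total_sd",
                                         df$compound_id)
  } else if ("total" %in% names(df)) {
    ms <- parse_pm(df$total)
    out$total_mean <- ms[, 1L]; out$total_sd <- ms[, 2L]
  }
  if (!is.null(out$total_sd) && any(out$total_sd < 0, na.rm = TRUE))
    stop("negative SD in stated total", call. = FALSE)
  out
}

#' Extract the best pose score from Vina-family output
#'
#' Scans a PDBQT or log stream for `REMARK VINA RESULT:` records and returns
#' the energy of the first (best) pose in kcal/mol.
#'
#' @param path path to a PDBQT/log file, or a character vector of lines.
#' @return numeric scalar, kcal/mol.
#' @export
read_vina_pdbqt_score <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
           else as.character(path)
  hits <- grep("REMARK VINA RESULT:", lines, value = TRUE)
  if (length(hits) == 0L) stop("no score record found", call. = FALSE)
  fields <- strsplit(trimws(sub(".*REMARK VINA RESULT:", "", hits[1L])),
                     "\\s+")[[1L]]
  as.numeric(fields[1L])
}

#' Read a topology sidecar
#'
#' The sidecar is a CSV with columns `atom_name`, `residue_id`, `mass`
#' (amu), `vdw_radius` (Angstrom), `hbond_role` (one of `donor-heavy`,
#' `acceptor`, `hydrogen`, `none`) and `hydrogen_parent` (1-based index of
#' the bonded heavy atom, required for every hydrogen, NA otherwise).
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_topology <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  need <- c("atom_name", "residue_id", "mass", "vdw_radius", "hbond_role",
            "hydrogen_parent")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("topology missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(df$mass <= 0)) stop("masses must be > 0", call. = FALSE)
  if (any(df$vdw_radius <= 0)) stop("radii must be > 0", call. = FALSE)
  ok <- c("donor-heavy", "acceptor", "hydrogen", "none")
  if (!all(df$hbond_role %in% ok))
    stop("unknown hbond_role value", call. = FALSE)
  h <- which(df$hbond_role == "hydrogen")
  if (any(is.na(df$hydrogen_parent[h])))
    stop("hydrogen_parent required for every hydrogen atom", call. = FALSE)
  df
}

#' Construct a trajectory object
#'
#' @param coords numeric array of dimension `n_frames x n_atoms x 3`, in
#'   Angstrom.
#' @param topology data.frame as returned by [read_topology()].
#' @param times optional per-frame timestamps in ns, strictly increasing.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(coords, topology, times = NULL) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3L] == 3L)
  if (dim(coords)[2L] != nrow(topology))
    stop("topology covers ", nrow(topology), " atoms but frames have ",
         dim(coords)[2L], call. = FALSE)
  if (!is.null(times)) {
    if (length(times) != dim(coords)[1L])
      stop("times length must equal n_frames", call. = FALSE)
    if (any(diff(times) <= 0))
      stop("times must be strictly increasing", call. = FALSE)
  }
  structure(list(coords = coords, topology = topology, times = times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", dim(x$coords)[1L], "frames,", dim(x$coords)[2L],
      "atoms\n")
  if (!is.null(x$times))
    cat("time span:", x$times[1L], "-", x$times[length(x$times)], "ns\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1L]
n_atoms <- function(traj) dim(traj$coords)[2L]
frame_coords <- function(traj, i) {
  matrix(traj$coords[i, , ], ncol = 3L)
}

#' Read a coordinate trajectory
#'
#' Supports multi-model PDB (`MODEL`/`ENDMDL` blocks with fixed-column
#' `ATOM`/`HETATM` records; a file without `MODEL` records is a single
#' frame) and plain XYZ (count line, comment line, `element x y z`).
#' Coordinates are interpreted in Angstrom unless `scale` says otherwise
#' (e.g. `scale = 10` for nm input).  The topology sidecar must cover all
#' atoms; atom membership, masses and hydrogen-bond roles come exclusively
#' from it.
#'
#' @param path coordinate file.
#' @param topology path to topology sidecar CSV, or a data.frame.
#' @param format `"auto"` (by extension), `"pdb"` or `"xyz"`.
#' @param times optional per-frame timestamps (ns).
#' @param scale multiplier applied to coordinates on read (default 1 = file
#'   already in Angstrom).
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, topology, format = c("auto", "pdb", "xyz"),
                            times = NULL, scale = 1) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xyz")) "xyz" else "pdb"
  }
  top <- if (is.character(topology)) read_topology(topology) else topology
  frames <- unname(switch(format,
    pdb = parse_multimodel_pdb(readLines(path)),
    xyz = parse_xyz(readLines(path))))
  n <- vapply(frames, nrow, integer(1))
  if (length(unique(n)) != 1L) {
    bad <- which(n != n[1L])[1L]
    stop("frame ", bad, ": expected ", n[1L], " atoms, found ", n[bad],
         call. = FALSE)
  }
  coords <- array(0, dim = c(length(frames), n[1L], 3L))
  for (i in seq_along(frames)) coords[i, , ] <- frames[[i]] * scale
  trajectory(coords, top, times = times)
}

parse_multimodel_pdb <- function(lines) {
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_breaks <- cumsum(trimws(rec) == "MODEL")
  if (max(model_breaks) == 0L) model_breaks <- rep(1L, length(lines))
  grp <- model_breaks[is_atom]
  if (sum(is_atom) == 0L) stop("no ATOM records found", call. = FALSE)
  atoms <- lines[is_atom]
  xyz <- cbind(as.numeric(substr(atoms, 31L, 38L)),
               as.numeric(substr(atoms, 39L, 46L)),
               as.numeric(substr(atoms, 47L, 54L)))
  lapply(split.data.frame(xyz, grp), function(m) unname(as.matrix(m)))
}

parse_xyz <- function(lines) {
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "") { i <- i + 1L; next }
    cnt <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(cnt)) stop("bad XYZ count line at line ", i, call. = FALSE)
    body <- lines[(i + 2L):(i + 1L + cnt)]
    if (length(body) < cnt || anyNA(body))
      stop("frame ", length(frames) + 1L, ": expected ", cnt, " atoms",
           call. = FALSE)
    toks <- strsplit(trimws(body), "\\s+")
    if (any(lengths(toks) < 4L))
      stop("frame ", length(frames) + 1L, ": malformed XYZ atom line",
           call. = FALSE)
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + cnt
  }
  if (length(frames) == 0L) stop("no XYZ frames found", call. = FALSE)
  frames
}

#' Write a trajectory as multi-model PDB
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @export
write_trajectory_pdb <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  top <- traj$topology
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    m <- frame_coords(traj, f)
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(nrow(m)), substr(top$atom_name, 1L, 4L), "UNK",
      top$residue_id, m[, 1L], m[, 2L], m[, 3L]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a trajectory as plain XYZ
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @export
write_trajectory_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  top <- traj$topology
  el <- sub("[0-9].*$", "", top$atom_name)
  for (f in seq_len(n_frames(traj))) {
    writeLines(as.character(n_atoms(traj)), con)
    writeLines(paste("frame", f), con)
    m <- frame_coords(traj, f)
    writeLines(sprintf("%-2s %14.8f %14.8f %14.8f", el,
                       m[, 1L], m[, 2L], m[, 3L]), con)
  }
  invisible(path)
}

#' Write a topology sidecar CSV
#' @param topology data.frame in the [read_topology()] schema.
#' @param path output path.
#' @export
write_topology <- function(topology, path) {
  utils::write.csv(topology, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
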