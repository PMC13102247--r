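#' Competition ("min") ranking of one score column
#'
#' Assigns rank 1 to the best value under the column's orientation; tied
#' values all share the smallest rank they could occupy and the next
#' distinct value's rank skips the tied count (so two values tied at rank
#' 23 are followed by rank 25).  This is the tie policy consistent with
#' published rank-by-rank consensus tables.
#'
#' @param values finite numeric vector.
#' @param orientation `"lower_is_better"` (docking energies) or
#'   `"higher_is_better"`.
#' @return integer vector of ranks, same length as `values`.
#' @export
rank_column <- function(values, orientation = "lower_is_better") {
  if (anyNA(values) || !all(is.finite(values)))
    stop("values must be finite (no NaN/NA)", call. = FALSE)
  v <- if (identical(orientation, "higher_is_better")) -values else values
  # competition rank: 1 + number of strictly better values
  vapply(v, function(x) 1L + sum(v < x), integer(1))
}

#' Build the per-program rank matrix of a score table
#'
#' Applies [rank_column()] to every column of a [score_table()] under that
#' column's orientation.  The column order of the input is preserved and
#' later defines the radar axes, so it is part of the result's provenance.
#'
#' @param table a [score_table()].
#' @return object of class `rank_matrix`: integer matrix `ranks`
#'   (compounds x programs) plus `compound_ids` and `program_names`.
#' @export
build_rank_matrix <- function(table) {
  validate_score_table(table)
  ranks <- vapply(seq_along(table$program_names), function(j)
    rank_column(table$values[, j], table$orientation[j]),
    integer(length(table$compound_ids)))
  ranks <- matrix(ranks, nrow = length(table$compound_ids))
  structure(list(compound_ids = table$compound_ids,
                 program_names = table$program_names,
                 ranks = ranks),
            class = "rank_matrix")
}

#' @export
print.rank_matrix <- function(x, ...) {
  cat("rank_matrix:", length(x$compound_ids), "compounds x",
      length(x$program_names), "programs (1 = best)\n")
  invisible(x)
}

#' @export
as.data.frame.rank_matrix <- function(x, ...) {
  df <- data.frame(compound_id = x$compound_ids, x$ranks,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-1L] <- x$program_names
  df
}

#' Area of a radar (spider) polygon
#'
#' Places radius `r_j` at angle `2*pi*j/n` for the `n` axes in `axis_order`
#' and returns the shoelace area of the closed polygon.  For equal angular
#' spacing this reduces to `0.5 * sin(2*pi/n) * sum_j r_j * r_{j+1}`
#' (cyclic), which is the consensus statistic: smaller area means the
#' compound sits closer to the center (ranks near 1) on all axes.
#'
#' @param ranks positive numeric vector, length >= 3 (one radius per axis).
#' @param axis_order permutation of `seq_along(ranks)` giving the axis
#'   arrangement; the area is invariant under cyclic rotations of this
#'   order but not under arbitrary permutations.
#' @return polygon area (dimensionless when radii are ranks).
#' @export
radar_area <- function(ranks, axis_order = seq_along(ranks)) {
  n <- length(ranks)
  if (n < 3L) stop("radar area undefined for fewer than 3 axes",
                   call. = FALSE)
  if (any(!is.finite(ranks)) || any(ranks <= 0))
    stop("all radii must be positive and finite", call. = FALSE)
  if (!setequal(axis_order, seq_len(n)))
    stop("axis_order must be a permutation of the axes", call. = FALSE)
  r <- ranks[axis_order]
  0.5 * sin(2 * pi / n) * sum(r * r[c(2:n, 1L)])
}

#' Radar-polygon-area consensus selection
#'
#' Computes each compound's radar area from its per-program ranks, orders
#' compounds by ascending area (smaller = better consensus performance) and
#' returns the top `k`.  Ties on area are broken by mean rank, then by
#' compound id, so the ordering is fully deterministic.
#'
#' @param rank_matrix a [build_rank_matrix()] result.
#' @param k number of compounds to select.
#' @param axis_order axis arrangement passed to [radar_area()].
#' @return object of class `consensus_result`: a data.frame `table` with
#'   columns `compound_id`, `radar_area`, `mean_rank`, `final_rank`,
#'   `selected`, plus the `axis_order` and program names used.
#' @export
consensus_select <- function(rank_matrix, k,
                             axis_order = seq_along(rank_matrix$program_names)) {
  stopifnot(inherits(rank_matrix, "rank_matrix"))
  n <- length(rank_matrix$compound_ids)
  if (k <= 0L) stop("k must be positive", call. = FALSE)
  if (k > n) stop("k = ", k, " exceeds the ", n, " compounds available",
                  call. = FALSE)
  areas <- apply(rank_matrix$ranks, 1L, radar_area, axis_order = axis_order)
  mean_ranks <- rowMeans(rank_matrix$ranks)
  ord <- order(areas, mean_ranks, rank_matrix$compound_ids)
  tab <- data.frame(
    compound_id = rank_matrix$compound_ids[ord],
    radar_area = areas[ord],
    mean_rank = mean_ranks[ord],
    final_rank = seq_len(n),
    selected = seq_len(n) <= k,
    stringsAsFactors = FALSE
  )
  structure(list(table = tab,
                 selected = tab$compound_id[tab$selected],
                 k = k,
                 axis_order = axis_order,
                 program_names = rank_matrix$program_names[axis_order]),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus_result: top", x$k, "by radar area",
      "(axes:", paste(x$program_names, collapse = ", "), ")\n")
  print(utils::head(x$table, x$k), row.names = FALSE)
  invisible(x)
}

#' Filter a score table on one program's values
#'
#' Retains compounds whose score in `column` is below `cutoff` (strictly by
#' default, matching "binding energy less than" wording; `strict = FALSE`
#' switches to `<=`).
#'
#' @param table a [score_table()].
#' @param column program name to filter on.
#' @param cutoff energy cutoff (same units as the column).
#' @param strict use `<` (default) rather than `<=`.
#' @return the filtered [score_table()]; may have zero rows, in which case
#'   a plain empty subset marker is returned since a valid score table
#'   requires at least one row.
#' @export
filter_by_threshold <- function(table, column, cutoff, strict = TRUE) {
  validate_score_table(table)
  j <- match(column, table$program_names)
  if (is.na(j)) stop("unknown column: ", column, call. = FALSE)
  keep <- if (strict) table$values[, j] < cutoff else
    table$values[, j] <= cutoff
  if (!any(keep)) {
    return(structure(list(compound_ids = character(0),
                          program_names = table$program_names,
                          values = table$values[0, , drop = FALSE],
                          orientation = table$orientation),
                     class = "score_table"))
  }
  score_table(table$values[keep, , drop = FALSE],
              compound_ids = table$compound_ids[keep],
              program_names = table$program_names,
              orientation = table$orientation)
}

#' Baseline consensus orderings
#'
#' Mean-rank and rank-sum aggregations, provided as comparison baselines
#' for the radar-area method.  Both produce identical orderings (rank sum
#' is `n_programs` times the mean rank); ties are broken by compound id.
#'
#' @param rank_matrix a [build_rank_matrix()] result.
#' @param method `"mean_rank"` or `"rank_sum"`.
#' @return data.frame with `compound_id`, `score` (the aggregate) and
#'   `final_rank`, ordered best first.
#' @export
consensus_alternatives <- function(rank_matrix,
                                   method = c("mean_rank", "rank_sum")) {
  stopifnot(inherits(rank_matrix, "rank_matrix"))
  method <- match.arg(method)
  agg <- switch(method,
                mean_rank = rowMeans(rank_matrix$ranks),
                rank_sum = rowSums(rank_matrix$ranks))
  ord <- order(agg, rank_matrix$compound_ids)
  data.frame(compound_id = rank_matrix$compound_ids[ord],
             score = agg[ord],
             final_rank = seq_along(ord),
             stringsAsFactors = FALSE)
}
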