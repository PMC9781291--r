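# Group-level analysis: per-100-cells transmission histograms across the
# cultures of an experimental group, binned shares, rank-sum comparisons.

#' Per-cell transmission counts of a compressed graph
#'
#' A cell's transfer count is its in-degree plus out-degree on the
#' transmission graph — the total number of calcium-signal transmissions it
#' took part in.
#'
#' @inheritParams compressed_edge_count
#' @return A tibble with columns `cell_id` and `transfers` (one row per
#'   cell, including cells with zero transfers).
#' @export
per_cell_transfers <- function(cg) {
  deg <- degree_centrality(cg)
  tibble::tibble(cell_id = deg$cell_id,
                 transfers = deg$indegree + deg$outdegree)
}

#' Assemble one culture's cell records for group analysis
#'
#' Convenience wrapper tagging [per_cell_transfers()] with culture and group
#' identifiers so that several cultures can be row-bound into the input of
#' [group_histogram()] and [bin_shares()].
#'
#' @inheritParams compressed_edge_count
#' @param culture_id Culture identifier.
#' @param group Group label.
#' @return A tibble with columns `culture_id`, `group`, `cell_id`,
#'   `transfers`.
#' @export
culture_cells <- function(cg, culture_id, group) {
  dplyr::bind_cols(
    tibble::tibble(culture_id = rep(culture_id, cg$n_cells),
                   group = rep(group, cg$n_cells)),
    per_cell_transfers(cg))
}

#' Group histogram of per-cell transmission counts, per 100 cells
#'
#' Pools the cells of all cultures in each group and reports, for each
#' transfer count i = 1..`max_transfers`, the number of cells with exactly i
#' transfers per hundred cells of the group:
#' \eqn{n_i = (100 / n_g) \sum_k \sum_j [count_{jk} = i]},
#' where \eqn{n_g} is the group's total cell count across its K cultures.
#' Pooling across cultures happens before normalisation — the histogram is a
#' group portrait, not an average of per-culture histograms. Cells with zero
#' transfers contribute to \eqn{n_g} but to no bar, so the bars sum to at
#' most 100. Counts above `max_transfers` fall outside the histogram (they
#' are retained by the binned ">40" share of [bin_shares()]).
#'
#' @param cells Data frame with one row per cell: columns `group` and
#'   `transfers` (and typically `culture_id`); see [culture_cells()].
#' @param max_transfers Largest transfer count shown; default 50.
#' @return A tibble with columns `group`, `i` (1..`max_transfers`), `n_i`.
#' @export
group_histogram <- function(cells, max_transfers = 50L) {
  cells <- tibble::as_tibble(cells)
  stopifnot(all(c("group", "transfers") %in% names(cells)))
  if (!nrow(cells)) stop("no cells supplied (n_g = 0).", call. = FALSE)
  cells |>
    dplyr::group_by(.data$group) |>
    dplyr::reframe(
      i = seq_len(max_transfers),
      n_i = 100 * tabulate(.data$transfers[.data$transfers >= 1L &
                                             .data$transfers <= max_transfers],
                           nbins = max_transfers) / dplyr::n())
}

transfer_bins <- function() {
  tibble::tibble(bin = factor(c("2-4", "5-10", "11-24", "25-40", ">40"),
                              levels = c("2-4", "5-10", "11-24", "25-40",
                                         ">40")),
                 lo = c(2, 5, 11, 25, 41), hi = c(4, 10, 24, 40, Inf))
}

#' Per-culture shares of cells by transmission interval
#'
#' For each culture, the percentage of its cells whose transfer count falls
#' in each of the closed intervals 2–4, 5–10, 11–24, 25–40, and more than
#' 40. Counts of 0 and 1 fall in no interval. The culture — not the cell —
#' is the statistical unit fed into [compare_groups()].
#'
#' @param cells Data frame with one row per cell: columns `culture_id`,
#'   `transfers`, and optionally `group` (carried through).
#' @return A tibble with columns `culture_id` (and `group` if supplied),
#'   `bin`, `share` (percent of the culture's cells).
#' @export
bin_shares <- function(cells) {
  cells <- tibble::as_tibble(cells)
  stopifnot(all(c("culture_id", "transfers") %in% names(cells)))
  bins <- transfer_bins()
  keys <- intersect(c("culture_id", "group"), names(cells))
  cells |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::reframe(
      bin = bins$bin,
      share = purrr::map2_dbl(bins$lo, bins$hi, function(lo, hi) {
        100 * sum(.data$transfers >= lo & .data$transfers <= hi) / dplyr::n()
      }))
}

#' Per-culture share of cells above a transfer count
#'
#' Percentage of each culture's cells with strictly more than `threshold`
#' transfers, labelled `">threshold"` in a `bin` column so the result feeds
#' [compare_groups()] directly. The share of cells with more than five
#' transmissions is the classic contrast between synchronised
#' neuron-containing cultures and asynchronous monoastrocytic ones.
#'
#' @inheritParams bin_shares
#' @param threshold Count that must be exceeded; default 5.
#' @return A tibble with `culture_id` (and `group` if supplied), `bin`,
#'   `share`.
#' @export
share_above <- function(cells, threshold = 5) {
  cells <- tibble::as_tibble(cells)
  stopifnot(all(c("culture_id", "transfers") %in% names(cells)))
  keys <- intersect(c("culture_id", "group"), names(cells))
  cells |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      bin = paste0(">", threshold),
      share = 100 * mean(.data$transfers > threshold),
      .groups = "drop")
}

#' Pairwise group comparison of binned shares
#'
#' Two-sided Mann–Whitney–Wilcoxon rank-sum tests on the per-culture shares
#' of a chosen transmission interval, for every pair of groups, with
#' Holm–Bonferroni correction across the pairs. The exact null distribution
#' is used when both groups have at most `exact_max` cultures and the shares
#' are tie-free; otherwise the normal approximation with tie correction.
#'
#' @param shares Output of [bin_shares()] (must include a `group` column),
#'   or any data frame with `group`, `bin`, `share`.
#' @param bin Interval label to test, e.g. `"5-10"`; one of the levels of
#'   `shares$bin`.
#' @param alpha Significance level for the `significant` flag; default 0.05.
#' @param exact_max Largest per-group size for the exact null; default 10.
#' @return A tibble with columns `group1`, `group2`, `n1`, `n2`,
#'   `statistic`, `p_value`, `p_adj`, `significant`.
#' @export
compare_groups <- function(shares, bin, alpha = 0.05, exact_max = 10L) {
  shares <- tibble::as_tibble(shares)
  stopifnot(all(c("group", "bin", "share") %in% names(shares)))
  if (!bin %in% as.character(shares$bin)) {
    stop("`bin` not found in `shares`: ", bin, call. = FALSE)
  }
  x <- dplyr::filter(shares, as.character(.data$bin) == !!bin)
  groups <- unique(as.character(x$group))
  if (length(groups) < 2L) {
    stop("need at least two groups to compare.", call. = FALSE)
  }
  sizes <- table(as.character(x$group))
  if (any(sizes < 2L)) {
    stop("every group needs at least two cultures; too few in: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  pairs <- utils::combn(groups, 2L)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    g1 <- pairs[1L, p]; g2 <- pairs[2L, p]
    s1 <- x$share[x$group == g1]; s2 <- x$share[x$group == g2]
    exact <- length(s1) <= exact_max && length(s2) <= exact_max &&
      !any(duplicated(c(s1, s2)))
    wt <- suppressWarnings(
      stats::wilcox.test(s1, s2, alternative = "two.sided", exact = exact,
                         correct = TRUE))
    p <- wt$p.value
    if (is.nan(p)) p <- 1  # all shares identical: no evidence of difference
    tibble::tibble(group1 = g1, group2 = g2,
                   n1 = length(s1), n2 = length(s2),
                   statistic = unname(wt$statistic), p_value = p)
  })
  res$p_adj <- stats::p.adjust(res$p_value, method = "holm")
  res$significant <- res$p_adj < alpha
  res
}
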