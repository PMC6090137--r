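rank_levels <- c("unassigned", "order", "genus", "species")

#' Taxonomic rank from a sequence-similarity hit
#'
#' Identity-threshold banding for rDNA similarity searches: hits covering
#' less than 94% of the query length are discarded (`unassigned`);
#' otherwise identity of 98--100% supports a presumed species, 94--97% the
#' genus, and 80--93% the order. Fractional identities falling between the
#' printed integer bands are resolved with half-open intervals `[94, 98)`
#' and `[80, 94)`, so the map is total; identity below 80% is `unassigned`.
#'
#' @param identity_pct,coverage_pct Percent identity and query coverage,
#'   each in `[0, 100]`; vectorised.
#' @return Character vector in
#'   `{"species", "genus", "order", "unassigned"}`.
#' @examples
#' assign_rank(c(99, 95, 85, 99), c(100, 96, 95, 90))
#' @export
assign_rank <- function(identity_pct, coverage_pct) {
  if (length(identity_pct) != length(coverage_pct)) {
    abort("`identity_pct` and `coverage_pct` must have equal length.")
  }
  vals <- c(identity_pct, coverage_pct)
  if (anyNA(vals) || any(vals < 0 | vals > 100)) {
    abort("Percentages must lie in [0, 100].")
  }
  dplyr::case_when(
    coverage_pct < 94 ~ "unassigned",
    identity_pct >= 98 ~ "species",
    identity_pct >= 94 ~ "genus",
    identity_pct >= 80 ~ "order",
    .default = "unassigned"
  )
}

#' Lowest common rank of conflicting hits
#'
#' When several acceptable hits disagree, the assignment falls back to the
#' least specific rank among them (order < genus < species); any
#' `unassigned` hit makes the whole set unassigned. The operation is
#' idempotent and independent of hit order.
#'
#' @param ranks Nonempty character vector of ranks as returned by
#'   [assign_rank()].
#' @return A single rank.
#' @examples
#' lowest_common_rank(c("species", "genus"))
#' @export
lowest_common_rank <- function(ranks) {
  if (length(ranks) == 0) abort("`ranks` must be nonempty.")
  idx <- match(ranks, rank_levels)
  if (anyNA(idx)) {
    abort(paste0("Unknown rank(s): ",
                 paste(unique(ranks[is.na(idx)]), collapse = ", ")))
  }
  rank_levels[min(idx)]
}

#' Assign ranks to a table of similarity hits
#'
#' Tabular wrapper: adds a `rank` column from the identity/coverage rule
#' and, optionally grouped by a query identifier, resolves conflicting hits
#' to their lowest common rank.
#'
#' @param hits Tibble with columns `identity` and `coverage` (percent), and
#'   optionally a query id column named by `by`.
#' @param by Optional grouping column for conflict resolution.
#' @return `hits` with a `rank` column; if `by` is given, one row per query
#'   with the consensus `rank`.
#' @export
assign_rank_table <- function(hits, by = NULL) {
  stopifnot(all(c("identity", "coverage") %in% names(hits)))
  out <- dplyr::mutate(hits, rank = assign_rank(.data$identity, .data$coverage))
  if (is.null(by)) return(out)
  out |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(n_hits = dplyr::n(),
                     rank = lowest_common_rank(.data$rank), .groups = "drop")
}
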