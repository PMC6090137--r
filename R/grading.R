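# The printed strength scale for one sign family (patterns of 0/1 over the
# three observation days). Negative patterns mirror it exactly.
positive_grade_map <- function() {
  tibble::tribble(
    ~d3, ~d5, ~d7, ~grade, ~label,
    1L, 1L, 1L, 6L, "strong induction",
    0L, 1L, 1L, 5L, "induction",
    0L, 0L, 1L, 4L, "mild induction",
    1L, 0L, 1L, 4L, "mild induction",
    1L, 1L, 0L, 3L, "acceleration",
    0L, 1L, 0L, 2L, "acceleration",
    1L, 0L, 0L, 1L, "acceleration"
  )
}

negative_label <- function(label) {
  c("strong induction" = "strong inhibition",
    "induction" = "inhibition",
    "mild induction" = "mild inhibition",
    "acceleration" = "retardation")[label]
}

#' The full pattern-to-grade rule table
#'
#' All 27 possible day-3/5/7 significance patterns with their grade and
#' label: the 14 printed monotone rows (7 induction families and their
#' mirror-image inhibitions), the all-zero pattern (grade 0, `"none"`), and
#' the 6 mixed-sign patterns, which the scale does not define and which are
#' graded 0 with `mixed = TRUE` so they stay auditable.
#'
#' @return Tibble with columns `d3`, `d5`, `d7`, `grade`, `label`, `mixed`.
#' @examples
#' grade_rules()
#' @export
grade_rules <- function() {
  pos <- positive_grade_map()
  neg <- dplyr::mutate(pos,
                       dplyr::across(c("d3", "d5", "d7", "grade"), ~ -.x),
                       label = unname(negative_label(.data$label)))
  printed <- dplyr::bind_rows(pos, neg) |> dplyr::mutate(mixed = FALSE)
  all27 <- tidyr::expand_grid(d3 = -1:1, d5 = -1:1, d7 = -1:1) |>
    dplyr::mutate(dplyr::across(dplyr::everything(), as.integer))
  rest <- dplyr::anti_join(all27, printed, by = c("d3", "d5", "d7")) |>
    dplyr::mutate(
      grade = 0L,
      mixed = !(.data$d3 == 0 & .data$d5 == 0 & .data$d7 == 0),
      label = ifelse(.data$mixed, "mixed", "none")
    )
  dplyr::bind_rows(printed, rest) |>
    dplyr::arrange(dplyr::desc(.data$grade), dplyr::desc(.data$d3),
                   dplyr::desc(.data$d5), dplyr::desc(.data$d7))
}

#' Grade a day-wise significance pattern
#'
#' Maps the ordered triplet of signed significance calls at days 3, 5 and 7
#' to the signed interaction strength in `[-6, +6]`: e.g. significant
#' induction on all three days is a strong induction (+6), induction on days
#' 5 and 7 only an induction (+5), repression on all three days a strong
#' inhibition (-6). The map is a lookup of the printed scale, not a weighted
#' sum -- (0,0,1) and (1,0,1) both grade 4. Patterns mixing +1 and -1 are
#' outside the scale and grade 0 with `mixed = TRUE` (and a warning).
#'
#' @param d3 Either the day-3 calls (vectorised, with `d5` and `d7`), or a
#'   single length-3 pattern `c(d3, d5, d7)` when `d5`/`d7` are missing.
#' @param d5,d7 Day-5 and day-7 calls; entries must be in `{-1, 0, 1}`.
#' @param quiet Suppress the mixed-pattern warning.
#' @return Tibble with columns `d3`, `d5`, `d7`, `grade`, `label`, `mixed`.
#' @examples
#' grade_pattern(c(1, 1, 1))
#' grade_pattern(d3 = c(0, 0), d5 = c(1, -1), d7 = c(1, -1))
#' @export
grade_pattern <- function(d3, d5, d7, quiet = FALSE) {
  if (missing(d5) && missing(d7)) {
    if (length(d3) != 3) {
      abort("A single pattern must have exactly 3 entries (days 3, 5, 7).")
    }
    d5 <- d3[2]; d7 <- d3[3]; d3 <- d3[1]
  }
  pat <- tibble::tibble(d3 = d3, d5 = d5, d7 = d7)
  vals <- unlist(pat)
  if (anyNA(vals) || !all(vals %in% c(-1, 0, 1))) {
    abort("Pattern entries must be -1, 0 or +1.")
  }
  pat <- dplyr::mutate(pat, dplyr::across(dplyr::everything(), as.integer))
  out <- dplyr::left_join(pat, grade_rules(), by = c("d3", "d5", "d7"))
  if (!quiet && any(out$mixed)) {
    warn(paste0(sum(out$mixed), " mixed-sign pattern(s) graded 0; ",
                "the strength scale does not define them."))
  }
  out
}

#' Grade all interaction time series
#'
#' Collapses per-day comparison results into one graded interaction per
#' (focal, partner, medium) key. Each key must contribute exactly one
#' comparison per configured day; keys with a missing day or a missing
#' monoculture control are kept with status `"incomplete"` and an `NA`
#' grade, never silently dropped.
#'
#' @param comparisons Output of [compare_growth()].
#' @param days The three observation days (default `c(3, 5, 7)`).
#' @return Tibble keyed by (`focal`, `kingdom`, `partner`, `medium`) with the
#'   per-day calls `d3`, `d5`, `d7`, the `grade`, `label`, `mixed` flag and
#'   `status`.
#' @examples
#' cfg <- fbi_sim_config(noise_cv = 0, seed = 1)
#' simulate_areas(cfg) |> compare_growth() |> grade_interactions()
#' @export
grade_interactions <- function(comparisons, days = c(3, 5, 7)) {
  if (length(days) != 3) {
    abort("The strength scale is defined for exactly 3 observation days.")
  }
  key <- c("focal", "kingdom", "partner", "medium")
  if (anyDuplicated(comparisons[c(key, "day")])) {
    abort("Duplicate day within a (focal, partner, medium) key.")
  }
  unknown_days <- setdiff(unique(comparisons$day), days)
  if (length(unknown_days)) {
    abort(paste0("Comparisons contain unconfigured days: ",
                 paste(unknown_days, collapse = ", ")))
  }

  wide <- comparisons |>
    dplyr::mutate(day = paste0("d", .data$day)) |>
    tidyr::pivot_wider(id_cols = dplyr::all_of(key),
                       names_from = "day", values_from = "sign_call")
  for (col in paste0("d", days)) {
    if (!col %in% names(wide)) wide[[col]] <- NA_integer_
  }
  day_cols <- paste0("d", days)
  calls <- as.matrix(wide[day_cols])
  complete <- !apply(is.na(calls), 1, any)

  graded <- wide[c(key, day_cols)]
  names(graded)[names(graded) %in% day_cols] <- c("d3", "d5", "d7")
  graded$grade <- NA_integer_
  graded$label <- NA_character_
  graded$mixed <- NA
  if (any(complete)) {
    g <- grade_pattern(graded$d3[complete], graded$d5[complete],
                       graded$d7[complete], quiet = TRUE)
    graded$grade[complete] <- g$grade
    graded$label[complete] <- g$label
    graded$mixed[complete] <- g$mixed
  }
  graded$status <- ifelse(complete, "ok", "incomplete")
  if (any(graded$mixed, na.rm = TRUE)) {
    warn(paste0(sum(graded$mixed, na.rm = TRUE),
                " mixed-sign pattern(s) graded 0."))
  }
  dplyr::arrange(graded, .data$medium, .data$focal, .data$partner)
}
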