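# Vectorised Welch machinery shared by welch_t_test() and compare_growth().
# Degenerate cases (both samples with zero variance) are resolved by the
# means rather than erroring: equal means -> t = 0, p = 1; unequal means ->
# p = 0 with an infinite statistic. Both are flagged.
welch_stats <- function(mx, vx, nx, my, vy, ny) {
  se2 <- vx / nx + vy / ny
  diff <- mx - my
  degenerate <- se2 == 0
  t <- ifelse(degenerate,
              ifelse(diff == 0, 0, sign(diff) * Inf),
              diff / sqrt(se2))
  dof <- ifelse(degenerate, NA_real_,
                se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1)))
  p <- ifelse(degenerate,
              ifelse(diff == 0, 1, 0),
              2 * pt(-abs(t), dof))
  tibble::tibble(t_statistic = t, dof = dof, p_value = p,
                 mean_diff = diff, degenerate = degenerate)
}

#' Welch's two-sample t-test
#'
#' Two-tailed t-test with unequal variances (Welch--Satterthwaite degrees of
#' freedom), the comparison applied to every co-culture vs monoculture cell
#' of the bioassay. Both samples constant and equal gives `t = 0, p = 1`;
#' both constant and unequal gives `p = 0`; either case is flagged
#' `degenerate`.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @return One-row tibble: `t_statistic`, `dof`, `p_value`, `mean_diff`
#'   (`mean(x) - mean(y)`), `n_x`, `n_y`, `degenerate`.
#' @examples
#' welch_t_test(c(10, 11, 12), c(20, 21, 22))
#' @export
welch_t_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) abort("Samples must not contain NA.")
  if (length(x) < 2 || length(y) < 2) {
    abort("Each sample needs at least 2 values.")
  }
  out <- welch_stats(mean(x), var(x), length(x), mean(y), var(y), length(y))
  dplyr::mutate(out, n_x = length(x), n_y = length(y),
                .after = "mean_diff")
}

#' Signed significance call
#'
#' Collapses a test result to one of `-1`, `0`, `+1`: `+1` when the
#' co-culture mean is significantly larger than the control (an induction of
#' growth), `-1` when significantly smaller (a repression), `0` otherwise.
#' Significance is strict: `p < alpha`.
#'
#' @param p_value P-value(s) in `[0, 1]`.
#' @param mean_diff Mean difference(s), co-culture minus monoculture.
#' @param alpha Significance threshold (default 0.05).
#' @return Integer vector in `{-1, 0, 1}`.
#' @examples
#' significance_call(c(0.01, 0.2, 0.05), c(3.2, -3.2, 1))
#' @export
significance_call <- function(p_value, mean_diff, alpha = 0.05) {
  if (any(p_value < 0 | p_value > 1, na.rm = TRUE)) {
    abort("`p_value` must lie in [0, 1].")
  }
  out <- integer(length(p_value))
  sig <- !is.na(p_value) & p_value < alpha & !is.na(mean_diff) & mean_diff != 0
  out[sig] <- sign(mean_diff[sig])
  out[is.na(p_value) | is.na(mean_diff)] <- NA
  as.integer(out)
}

#' Compare every co-culture cell to its monoculture control
#'
#' For each (focal, partner, medium, day) cell, tests the co-culture colony
#' areas against the focal strain's monoculture areas on the same medium and
#' day with [welch_t_test()], and attaches the signed significance call.
#' Effects are tested in both directions: each unordered strain pair yields
#' one comparison with the fungus focal and one with the bacterium focal. A
#' cell whose monoculture control is absent is reported with status
#' `"missing_control"` rather than dropped.
#'
#' @param records Long-format area tibble ([simulate_areas()] /
#'   [read_area_csv()]).
#' @param alpha Significance threshold for the sign call.
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()]; default `"none"`, matching an uncorrected per-test
#'   threshold. When enabled, sign calls use the adjusted p-values.
#' @return Tibble with one row per comparison: identifiers, sample sizes,
#'   `t_statistic`, `dof`, `p_value` (adjusted if requested), `mean_diff`,
#'   `sign_call`, `degenerate`, `status`.
#' @examples
#' cfg <- fbi_sim_config(seed = 7)
#' comparisons <- simulate_areas(cfg) |> compare_growth()
#' dplyr::count(comparisons, sign_call)
#' @export
compare_growth <- function(records, alpha = 0.05, p_adjust = "none") {
  validate_area_records(records)

  mono <- records |>
    dplyr::filter(is.na(.data$partner)) |>
    dplyr::group_by(.data$focal, .data$medium, .data$day) |>
    dplyr::summarise(m_mono = mean(.data$area), v_mono = var(.data$area),
                     n_mono = dplyr::n(), .groups = "drop")

  co <- records |>
    dplyr::filter(!is.na(.data$partner)) |>
    dplyr::group_by(.data$focal, .data$kingdom, .data$partner,
                    .data$medium, .data$day) |>
    dplyr::summarise(m_co = mean(.data$area), v_co = var(.data$area),
                     n_co = dplyr::n(), .groups = "drop")

  if (any(co$n_co < 2)) abort("Each co-culture cell needs >= 2 replicates.")

  joined <- dplyr::left_join(co, mono, by = c("focal", "medium", "day"))
  missing <- is.na(joined$m_mono)
  if (any(!missing & joined$n_mono < 2)) {
    abort("Each monoculture control needs >= 2 replicates.")
  }

  stats <- welch_stats(joined$m_co, joined$v_co, joined$n_co,
                       joined$m_mono, joined$v_mono, joined$n_mono)
  out <- dplyr::bind_cols(
    joined[c("focal", "kingdom", "partner", "medium", "day", "n_co", "n_mono")],
    stats
  )
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out$status <- ifelse(missing, "missing_control", "ok")
  out$n_mono[missing] <- 0L
  out$sign_call <- significance_call(out$p_value, out$mean_diff, alpha)
  dplyr::arrange(out, .data$medium, .data$focal, .data$partner, .data$day)
}
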