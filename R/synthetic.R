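#' Default strain roster
#'
#' The bioassay design crosses four filamentous fungi (`F1`--`F4`) with five
#' bacterial strains (`B1`--`B5`), the roster used throughout the package
#' defaults. Every cross-kingdom ordered pair is a potential directed
#' interaction, so each direction of a network has 4 x 5 = 20 possible links.
#'
#' @param n_fungi,n_bacteria Number of fungal / bacterial strains.
#' @return A tibble with columns `strain` (label) and `kingdom`
#'   (`"fungus"` or `"bacterium"`), in fixed roster order.
#' @examples
#' fbi_strains()
#' @export
fbi_strains <- function(n_fungi = 4, n_bacteria = 5) {
  stopifnot(n_fungi >= 1, n_bacteria >= 1)
  tibble::tibble(
    strain = c(paste0("F", seq_len(n_fungi)), paste0("B", seq_len(n_bacteria))),
    kingdom = c(rep("fungus", n_fungi), rep("bacterium", n_bacteria))
  )
}

#' Specify a planted interaction effect
#'
#' An effect changes the expected colony area of `focal` when grown next to
#' `partner` on `medium`, from `onset_day` onwards, by a fractional
#' `magnitude` (+0.5 = 50% larger than the monoculture baseline). Effects are
#' direction-specific: an effect on the focal organism implies nothing about
#' the partner. With the default three observation days, onset at day 3
#' plants the full (1,1,1) significance pattern, onset at day 5 plants
#' (0,1,1), and onset at day 7 plants (0,0,1).
#'
#' @param focal Strain whose colony area is affected.
#' @param partner Co-cultured strain causing the effect (other kingdom).
#' @param medium Medium label the effect applies to.
#' @param onset_day First day the effect is expressed.
#' @param magnitude Fractional change in expected area; must be > -1.
#' @return One-row tibble; rows from several calls can be combined with
#'   [dplyr::bind_rows()] and passed to [fbi_sim_config()].
#' @examples
#' fbi_effect("B1", partner = "F1", medium = "MM", onset_day = 3, magnitude = 0.5)
#' @export
fbi_effect <- function(focal, partner, medium, onset_day = 3, magnitude = 0.5) {
  if (any(magnitude <= -1)) {
    abort("`magnitude` must be > -1 (areas stay positive).")
  }
  tibble::tibble(
    focal = focal, partner = partner, medium = medium,
    onset_day = onset_day, magnitude = magnitude
  )
}

#' Plant the same effect on every cross-kingdom pair of one medium
#'
#' Convenience wrapper used for calibration and recovery scenarios, e.g. a
#' stress-gradient setting where every interaction on the low-nutrient medium
#' is induced and every interaction on the rich medium is repressed.
#'
#' @param strains Strain roster as from [fbi_strains()].
#' @param medium Medium label.
#' @param magnitude Fractional effect applied to every pair.
#' @param onset_day First day the effect is expressed.
#' @param direction Which directed effects to plant: effects of fungi on
#'   bacteria, of bacteria on fungi, or both.
#' @return Tibble of effect rows (one per directed pair).
#' @export
fbi_uniform_effects <- function(strains, medium, magnitude, onset_day = 3,
                                direction = c("both", "fungi_to_bacteria",
                                              "bacteria_to_fungi")) {
  direction <- match.arg(direction)
  fungi <- strains$strain[strains$kingdom == "fungus"]
  bacteria <- strains$strain[strains$kingdom == "bacterium"]
  f2b <- tidyr::expand_grid(focal = bacteria, partner = fungi)
  b2f <- tidyr::expand_grid(focal = fungi, partner = bacteria)
  pairs <- switch(direction,
    both = dplyr::bind_rows(f2b, b2f),
    fungi_to_bacteria = f2b,
    bacteria_to_fungi = b2f
  )
  dplyr::mutate(pairs, medium = medium, onset_day = onset_day,
                magnitude = magnitude)
}

default_baselines <- function(strains, days) {
  # Linear-in-day expected areas; fungal colonies expand much faster than
  # bacterial ones on plates.
  slope <- ifelse(strains$kingdom == "fungus", 40, 15)
  tidyr::expand_grid(
    dplyr::mutate(strains, .slope = slope)[c("strain", ".slope")],
    day = days
  ) |>
    dplyr::mutate(baseline = .data$.slope * .data$day) |>
    dplyr::select("strain", "day", "baseline")
}

#' Configuration for the synthetic colony-area generator
#'
#' Bundles and validates everything [simulate_areas()] needs. The defaults
#' mirror the bioassay design: 4 fungi x 5 bacteria, four media, colonies
#' photographed at 72, 120 and 168 h (days 3, 5, 7), three replicates.
#'
#' @param strains Roster tibble (`strain`, `kingdom`); see [fbi_strains()].
#' @param media Character vector of medium labels.
#' @param days Ordered observation days.
#' @param n_replicates Replicate plates per condition (>= 2).
#' @param baseline_area Tibble (`strain`, `day`, `baseline`) of expected
#'   monoculture areas (mm^2); must be positive and non-decreasing over days.
#'   Default: linear growth, 40 mm^2/day for fungi and 15 mm^2/day for
#'   bacteria.
#' @param noise_cv Coefficient of variation of multiplicative replicate
#'   noise (>= 0).
#' @param effects Tibble of planted effects ([fbi_effect()] rows), or `NULL`.
#' @param seed Integer RNG seed.
#' @return A validated list of class `fbi_sim_config`.
#' @export
fbi_sim_config <- function(strains = fbi_strains(),
                           media = c("CP", "LB", "MM", "PDA"),
                           days = c(3, 5, 7),
                           n_replicates = 3,
                           baseline_area = NULL,
                           noise_cv = 0.1,
                           effects = NULL,
                           seed = 1L) {
  stopifnot(is.data.frame(strains), all(c("strain", "kingdom") %in% names(strains)))
  if (anyDuplicated(strains$strain)) abort("Strain labels must be unique.")
  if (!all(strains$kingdom %in% c("fungus", "bacterium"))) {
    abort("`kingdom` must be 'fungus' or 'bacterium'.")
  }
  if (n_replicates < 2) abort("`n_replicates` must be >= 2.")
  if (noise_cv < 0) abort("`noise_cv` must be >= 0.")
  if (is.unsorted(days, strictly = TRUE)) abort("`days` must be strictly increasing.")

  baseline_area <- baseline_area %||% default_baselines(strains, days)
  need <- tidyr::expand_grid(strain = strains$strain, day = days)
  got <- dplyr::semi_join(need, baseline_area, by = c("strain", "day"))
  if (nrow(got) < nrow(need)) abort("`baseline_area` must cover every strain x day.")
  if (any(baseline_area$baseline <= 0)) abort("Baseline areas must be positive.")
  dec <- baseline_area |>
    dplyr::arrange(.data$strain, .data$day) |>
    dplyr::group_by(.data$strain) |>
    dplyr::summarise(ok = !is.unsorted(.data$baseline), .groups = "drop")
  if (!all(dec$ok)) abort("Baseline areas must be non-decreasing over days.")

  if (!is.null(effects) && nrow(effects) > 0) {
    stopifnot(all(c("focal", "partner", "medium", "onset_day", "magnitude") %in%
                    names(effects)))
    if (anyDuplicated(effects[c("focal", "partner", "medium")])) {
      abort("Duplicate effect for the same (focal, partner, medium).")
    }
    if (any(effects$magnitude <= -1)) abort("Effect magnitudes must be > -1.")
    kng <- setNames(strains$kingdom, strains$strain)
    if (any(is.na(kng[effects$focal])) || any(is.na(kng[effects$partner]))) {
      abort("Effects refer to strains outside the roster.")
    }
    if (any(kng[effects$focal] == kng[effects$partner])) {
      abort("Effects must be cross-kingdom (focal and partner in different kingdoms).")
    }
    live <- !is.na(effects$onset_day)
    if (any(live & !(effects$onset_day %in% days))) {
      abort("`onset_day` must be one of the configured days (or NA for no effect).")
    }
  }

  structure(
    list(strains = tibble::as_tibble(strains), media = media, days = days,
         n_replicates = as.integer(n_replicates),
         baseline_area = tibble::as_tibble(baseline_area),
         noise_cv = noise_cv,
         effects = if (is.null(effects)) fbi_effect(character(), character(), character())[0, ]
                   else tibble::as_tibble(effects),
         seed = as.integer(seed)),
    class = "fbi_sim_config"
  )
}

#' Simulate a colony-area bioassay dataset
#'
#' Generates the long-format table the analysis pipeline consumes: one row
#' per focal organism x medium x day x replicate, in monoculture (no
#' partner) and in co-culture with every strain of the other kingdom. The
#' expected co-culture area is `baseline * (1 + magnitude)` from the
#' matching effect's onset day onwards and equals the monoculture baseline
#' otherwise; replicate noise is multiplicative lognormal, parameterised by
#' its coefficient of variation and scaled to leave the expectation
#' untouched. Identical configurations (including seed) reproduce the table
#' exactly.
#'
#' @param config An [fbi_sim_config()] object.
#' @return Tibble with columns `focal`, `kingdom`, `partner` (`NA` for
#'   monoculture controls), `medium`, `day`, `replicate`, `area`.
#' @examples
#' cfg <- fbi_sim_config(noise_cv = 0, seed = 42)
#' areas <- simulate_areas(cfg)
#' dplyr::count(areas, is.na(partner))
#' @export
simulate_areas <- function(config) {
  stopifnot(inherits(config, "fbi_sim_config"))
  strains <- config$strains
  kng <- setNames(strains$kingdom, strains$strain)

  partners_of <- function(strain) {
    strains$strain[strains$kingdom != kng[[strain]]]
  }
  pairs <- purrr::map_dfr(strains$strain, function(s) {
    tibble::tibble(focal = s, partner = c(NA_character_, partners_of(s)))
  })

  grid <- tidyr::expand_grid(
    pairs,
    medium = config$media,
    day = config$days,
    replicate = seq_len(config$n_replicates)
  ) |>
    dplyr::mutate(kingdom = unname(kng[.data$focal])) |>
    dplyr::arrange(.data$focal, !is.na(.data$partner), .data$partner,
                   .data$medium, .data$day, .data$replicate)

  grid <- dplyr::left_join(grid, config$baseline_area,
                           by = c(focal = "strain", "day"))

  eff <- config$effects
  if (nrow(eff) > 0) {
    grid <- grid |>
      dplyr::left_join(eff, by = c("focal", "partner", "medium")) |>
      dplyr::mutate(
        active = !is.na(.data$onset_day) & .data$day >= .data$onset_day,
        expected = .data$baseline *
          (1 + dplyr::if_else(.data$active, .data$magnitude, 0, missing = 0))
      )
  } else {
    grid <- dplyr::mutate(grid, expected = .data$baseline)
  }

  cv <- config$noise_cv
  mult <- if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    local_seed(config$seed, exp(rnorm(nrow(grid), -sdlog^2 / 2, sdlog)))
  } else {
    rep(1, nrow(grid))
  }

  grid |>
    dplyr::mutate(area = .data$expected * mult) |>
    dplyr::select("focal", "kingdom", "partner", "medium", "day",
                  "replicate", "area")
}

#' Read and write the canonical colony-area CSV
#'
#' The canonical file is a plain CSV with columns `focal, kingdom, partner,
#' medium, day, replicate, area`; monoculture controls have an empty
#' `partner` field. `write_area_csv()` prepends `#`-comment header lines
#' recording the seed, which `read_area_csv()` skips.
#'
#' @param records Area tibble as produced by [simulate_areas()].
#' @param path File path.
#' @param seed Optional seed to record in the header comment.
#' @return `read_area_csv()` returns the area tibble; `write_area_csv()`
#'   returns `path` invisibly.
#' @export
write_area_csv <- function(records, path, seed = NULL) {
  header <- paste0("# fbinet colony areas",
                   if (!is.null(seed)) paste0("; seed=", seed) else "")
  writeLines(header, path)
  readr::write_csv(records, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_area_csv
#' @export
read_area_csv <- function(path) {
  out <- readr::read_csv(
    path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      focal = readr::col_character(), kingdom = readr::col_character(),
      partner = readr::col_character(), medium = readr::col_character(),
      day = readr::col_double(), replicate = readr::col_integer(),
      area = readr::col_double()
    )
  )
  validate_area_records(out)
  out
}

validate_area_records <- function(records) {
  need <- c("focal", "kingdom", "partner", "medium", "day", "replicate", "area")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    abort(paste0("Area table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (any(records$area <= 0, na.rm = TRUE)) {
    bad <- which(records$area <= 0)
    abort(paste0("Areas must be positive; offending rows: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  key <- records[c("focal", "partner", "medium", "day", "replicate")]
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))
    abort(paste0("Duplicate (focal, partner, medium, day, replicate) rows: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  invisible(records)
}
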