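#' Assay configuration: detection limits and below-LOD substitution
#'
#' Lower limits of detection per hormone (insulin 12 pg/mL, leptin 11 pg/mL,
#' adiponectin 5 ng/mL) and the fraction of the LOD substituted for
#' non-detectable values (default one half).
#'
#' @param lod Named numeric vector of detection limits, in assay units.
#' @param substitution_factor Fraction of the LOD used for below-LOD values,
#'   in `(0, 1]`.
#' @return An object of class `assay_config`.
#' @export
assay_config <- function(lod = c(insulin = 12, leptin = 11, adiponectin = 5),
                         substitution_factor = 0.5) {
  if (any(lod <= 0)) stop("all LODs must be > 0", call. = FALSE)
  if (substitution_factor <= 0 || substitution_factor > 1) {
    stop("substitution_factor must lie in (0, 1]", call. = FALSE)
  }
  structure(list(lod = lod, substitution_factor = substitution_factor),
            class = "assay_config")
}

#' Adiposity categorisation thresholds
#'
#' Overweight is BMI at or above `bmi_cut` (default 25 kg/m^2); excessive fat
#' mass is FMI strictly above `fmi_cut` (default 9). Note the asymmetry: the
#' BMI bound is closed (25 is overweight) while the FMI bound is open (9 is
#' normal).
#'
#' @param bmi_cut,fmi_cut Positive thresholds.
#' @return An object of class `adiposity_thresholds`.
#' @export
adiposity_thresholds <- function(bmi_cut = 25, fmi_cut = 9) {
  if (bmi_cut <= 0 || fmi_cut <= 0) stop("thresholds must be > 0", call. = FALSE)
  structure(list(bmi_cut = bmi_cut, fmi_cut = fmi_cut),
            class = "adiposity_thresholds")
}

#' Milk macronutrient energy factors (kcal/g)
#'
#' @param carbohydrate,protein,fat kcal per gram; defaults 4, 4 and 9.
#' @return An object of class `energy_factors`.
#' @export
energy_factors <- function(carbohydrate = 4, protein = 4, fat = 9) {
  if (any(c(carbohydrate, protein, fat) <= 0)) {
    stop("energy factors must be > 0", call. = FALSE)
  }
  structure(list(carbohydrate = carbohydrate, protein = protein, fat = fat),
            class = "energy_factors")
}

#' Substitute below-LOD hormone values at a fraction of the detection limit
#'
#' Non-detectable concentrations (`NA` with `below_lod = TRUE`, or any `NA`
#' when no flag is supplied) are replaced by
#' `substitution_factor * LOD` of the hormone; detectable values pass through
#' unchanged. Idempotent: substituted values are at the LOD fraction already
#' and are not altered by a second pass.
#'
#' @param value Numeric vector of concentrations; `NA` marks non-detectable.
#' @param hormone One of the hormones named in `cfg$lod`.
#' @param cfg An [assay_config()].
#' @param below_lod Optional logical vector flagging non-detectable entries;
#'   defaults to `is.na(value)`.
#' @return Numeric vector with below-LOD entries substituted.
#' @examples
#' impute_below_lod(c(NA, 90), "leptin", assay_config())  # 5.5, 90
#' @export
impute_below_lod <- function(value, hormone, cfg = assay_config(),
                             below_lod = NULL) {
  if (!hormone %in% names(cfg$lod)) {
    stop(sprintf("no LOD configured for hormone '%s'", hormone), call. = FALSE)
  }
  if (any(value < 0, na.rm = TRUE)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  if (is.null(below_lod)) below_lod <- is.na(value)
  below_lod <- !is.na(below_lod) & below_lod & is.na(value)
  value[below_lod] <- cfg$substitution_factor * cfg$lod[[hormone]]
  value
}

#' Body-composition indices from mass and height
#'
#' BMI, fat-mass index and fat-free-mass index: each mass (kg) divided by
#' squared height (m).
#'
#' @param weight_kg,fm_kg,ffm_kg Masses in kg (`NA` allowed).
#' @param height_m Height in metres, strictly positive.
#' @return A tibble with columns `bmi`, `fmi`, `ffmi`.
#' @examples
#' compute_indices(67.3, 1.69)          # BMI 23.56
#' @export
compute_indices <- function(weight_kg, height_m, fm_kg = NA_real_,
                            ffm_kg = NA_real_) {
  if (any(height_m <= 0, na.rm = TRUE)) {
    stop("height must be > 0", call. = FALSE)
  }
  if (any(c(weight_kg, fm_kg, ffm_kg) < 0, na.rm = TRUE)) {
    stop("masses must be >= 0", call. = FALSE)
  }
  tibble::tibble(bmi = weight_kg / height_m^2,
                 fmi = fm_kg / height_m^2,
                 ffmi = ffm_kg / height_m^2)
}

#' Categorise maternal adiposity
#'
#' @param bmi,fmi Numeric vectors (kg/m^2), `NA` allowed.
#' @param th An [adiposity_thresholds()].
#' @return A tibble with factors `bmi_group` (`normal`/`overweight`) and
#'   `fmi_group` (`normal`/`excessive`), plus 0/1 indicators `bmi_high`,
#'   `fmi_high` convenient as numeric exposures.
#' @examples
#' categorize_adiposity(c(22.5, 25), c(9, 9.1))
#' @export
categorize_adiposity <- function(bmi, fmi, th = adiposity_thresholds()) {
  if (any(c(bmi, fmi) < 0, na.rm = TRUE)) stop("inputs must be >= 0", call. = FALSE)
  bmi_high <- as.numeric(bmi >= th$bmi_cut)
  fmi_high <- as.numeric(fmi > th$fmi_cut)
  tibble::tibble(
    bmi_group = factor(ifelse(bmi_high == 1, "overweight", "normal"),
                       levels = c("normal", "overweight")),
    fmi_group = factor(ifelse(fmi_high == 1, "excessive", "normal"),
                       levels = c("normal", "excessive")),
    bmi_high = bmi_high, fmi_high = fmi_high
  )
}

#' Milk energy concentration from macronutrients
#'
#' `energy = 9 * fat + 4 * protein + 4 * carbohydrate` (kcal/L for g/L
#' inputs), with configurable factors.
#'
#' @param fat_g_per_l,protein_g_per_l,carb_g_per_l Macronutrient
#'   concentrations in g/L, non-negative.
#' @param ef An [energy_factors()].
#' @return Energy concentration, kcal/L.
#' @examples
#' compute_energy(40, 11, 68)  # 676
#' @export
compute_energy <- function(fat_g_per_l, protein_g_per_l, carb_g_per_l,
                           ef = energy_factors()) {
  if (any(c(fat_g_per_l, protein_g_per_l, carb_g_per_l) < 0, na.rm = TRUE)) {
    stop("macronutrient concentrations must be >= 0", call. = FALSE)
  }
  ef$fat * fat_g_per_l + ef$protein * protein_g_per_l +
    ef$carbohydrate * carb_g_per_l
}

#' Add visit-centred infant age
#'
#' Centres infant age within each visit: `centered_age = age - mean(age at
#' that visit)`, so the per-visit mean of the new column is zero. (The
#' opposite sign convention, mean minus age, gives identical fits with
#' flipped coefficient sign.)
#'
#' @param visit_table Data frame with `visit` and `infant_age_months`.
#' @return The input as a tibble with a `centered_age` column.
#' @export
center_age <- function(visit_table) {
  stopifnot(all(c("visit", "infant_age_months") %in% names(visit_table)))
  if (nrow(visit_table) == 0) stop("no rows to centre", call. = FALSE)
  visit_table |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$visit) |>
    dplyr::mutate(centered_age = .data$infant_age_months -
                    mean(.data$infant_age_months, na.rm = TRUE)) |>
    dplyr::ungroup()
}

#' Map postpartum age to the study visit window
#'
#' Colostrum within 72 h of birth is V1; then V2 = 1.0-3.49, V3 = 3.5-5.99
#' and V4 = 6.0-8.5 months (half-open at the inner boundaries, so 3.49
#' belongs to V2 and 3.5 to V3). Ages outside every window return
#' `"unassigned"`.
#'
#' @param postpartum_months Numeric vector of ages in months (>= 0).
#' @return Character vector of labels `V1`/`V2`/`V3`/`V4`/`unassigned`.
#' @examples
#' assign_visit_window(c(0.05, 3.49, 3.5, 7.1, 10))
#' @export
assign_visit_window <- function(postpartum_months) {
  if (any(postpartum_months < 0, na.rm = TRUE)) {
    stop("postpartum_months must be >= 0", call. = FALSE)
  }
  v1_max <- 72 / 24 / 30.44  # 72 h in months
  dplyr::case_when(
    is.na(postpartum_months) ~ NA_character_,
    postpartum_months <= v1_max ~ "V1",
    postpartum_months >= 1.0 & postpartum_months < 3.5 ~ "V2",
    postpartum_months >= 3.5 & postpartum_months < 6.0 ~ "V3",
    postpartum_months >= 6.0 & postpartum_months <= 8.5 ~ "V4",
    TRUE ~ "unassigned"
  )
}

#' Preprocess a visit table into analysis-ready variables
#'
#' Applies half-LOD substitution to every hormone column using its
#' `*_below_lod` flag, adds natural-log hormone columns, adiposity groups and
#' 0/1 indicators, and the visit-centred age. Flags are retained so
#' sensitivity analyses can drop rather than substitute.
#'
#' @param visit_table Tibble from [generate_cohort()] or read from CSV.
#' @param cfg An [assay_config()].
#' @param th An [adiposity_thresholds()].
#' @return The analysis-ready tibble.
#' @export
preprocess_visits <- function(visit_table, cfg = assay_config(),
                              th = adiposity_thresholds()) {
  tbl <- tibble::as_tibble(visit_table)
  hormones <- names(cfg$lod)
  for (comp in c("milk", "mplasma", "iplasma")) {
    for (h in hormones) {
      col <- paste0(comp, "_", h)
      if (!col %in% names(tbl)) next
      flag <- paste0(col, "_below_lod")
      fl <- if (flag %in% names(tbl)) tbl[[flag]] else NULL
      tbl[[col]] <- impute_below_lod(tbl[[col]], h, cfg, below_lod = fl)
      logcol <- paste0("log_", col)
      tbl[[logcol]] <- ifelse(!is.na(tbl[[col]]) & tbl[[col]] > 0,
                              log(tbl[[col]]), NA_real_)
    }
  }
  if (all(c("bmi", "fmi") %in% names(tbl))) {
    grp <- categorize_adiposity(tbl$bmi, tbl$fmi, th)
    tbl <- dplyr::bind_cols(tbl, grp)
  }
  center_age(tbl)
}
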