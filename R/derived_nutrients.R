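nutrient_cols <- function() {
  c("energy_kj", "protein_g", "fibre_g", "phosphorus_mg", "potassium_mg",
    "magnesium_mg", "calcium_mg", "sodium_mg", "sat_fat_g", "poly_fat_g",
    "alcohol_g")
}

check_profile <- function(p) {
  miss <- setdiff(nutrient_cols(), names(p))
  if (length(miss)) stop("nutrient profile missing column(s): ",
                         paste(miss, collapse = ", "))
  invisible(p)
}

#' Potential renal acid load (PRAL)
#'
#' Estimates the diet's acid load in mEq/d from the established linear
#' formula: 0.49 x protein (g/d) + 0.037 x phosphorus (mg/d) - 0.021 x
#' potassium (mg/d) - 0.026 x magnesium (mg/d) - 0.013 x calcium (mg/d).
#' "Phosphate" in the formula is dietary phosphorus in mg/d, the convention
#' of the original formulation. Negative values indicate an alkalizing diet.
#'
#' @param p data.frame of daily nutrient profiles (one row per
#'   participant-day or per participant mean) with the columns of
#'   `nutrient_cols()`, or at least the five inputs.
#' @return numeric vector, mEq/d.
#' @examples
#' pral(data.frame(protein_g = 80, phosphorus_mg = 1400, potassium_mg = 3000,
#'                 magnesium_mg = 320, calcium_mg = 900))  # 7.98
#' @export
pral <- function(p) {
  0.49 * p$protein_g + 0.037 * p$phosphorus_mg - 0.021 * p$potassium_mg -
    0.026 * p$magnesium_mg - 0.013 * p$calcium_mg
}

#' Protein-to-fibre ratio
#'
#' Total dietary protein (g/d) divided by total dietary fibre (g/d). Recalls
#' with fibre below `min_fibre` g/d produce NA with a warning rather than a
#' numerically absurd or infinite ratio; such records are excluded from ratio
#' summaries.
#'
#' @param p nutrient profile data.frame with protein_g and fibre_g.
#' @param min_fibre guard threshold in g/d (default 0.1).
#' @return numeric vector.
#' @export
protein_fibre_ratio <- function(p, min_fibre = 0.1) {
  bad <- !is.finite(p$fibre_g) | p$fibre_g < min_fibre
  if (all(bad)) stop("protein-to-fibre ratio undefined: fibre below ",
                     min_fibre, " g/d for every record")
  out <- p$protein_g / p$fibre_g
  if (any(bad)) {
    warning(sum(bad), " record(s) with fibre < ", min_fibre,
            " g/d flagged NA in protein-to-fibre ratio")
    out[bad] <- NA_real_
  }
  out
}

#' Mean of two daily nutrient profiles
#'
#' Field-wise mean of the two 24-h recall days, mirroring the two-day
#' averaging of food-group intakes.
#'
#' @param day1,day2 nutrient profile data.frames with a participant_id
#'   column, one row per participant, identically ordered.
#' @return data.frame of the same shape with averaged nutrient columns.
#' @export
mean_profile <- function(day1, day2) {
  check_profile(day1); check_profile(day2)
  if (!identical(as.character(day1$participant_id),
                 as.character(day2$participant_id)))
    stop("day profiles are not aligned: participant ids differ")
  out <- day1
  for (cl in nutrient_cols()) out[[cl]] <- (day1[[cl]] + day2[[cl]]) / 2
  out
}
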