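#' Scoring-unit layout
#'
#' The 46 scoring units (23 groups x 2 contexts) in their canonical column
#' order, used by every intake matrix in the package.
#'
#' @return data.frame with columns unit (e.g. "g01.core"), group_id, context.
#' @export
unit_layout <- function() {
  grid <- expand.grid(context = contexts(), group_id = seq_len(23L),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("group_id", "context")]
  grid$unit <- sprintf("g%02d.%s", grid$group_id, grid$context)
  rownames(grid) <- NULL
  grid[, c("unit", "group_id", "context")]
}

empty_intake_matrix <- function(participant_ids) {
  u <- unit_layout()
  m <- matrix(0, nrow = length(participant_ids), ncol = nrow(u),
              dimnames = list(as.character(participant_ids), u$unit))
  class(m) <- c("intake_matrix", class(m))
  m
}

#' Validate a food-composition table
#'
#' The table maps each 8-digit food code to its per-ingredient decomposition:
#' one row per (food_code, group_id) with the mass fraction of the food
#' contributed by that group, plus the food's core/discretionary context.
#' Context belongs to the parent product: a fruit fraction inside a
#' discretionary cake stays fruit, counted in the discretionary context.
#'
#' @param composition data.frame with columns food_code, context, group_id,
#'   fraction.
#' @param tol tolerance on each food's fraction sum (default 1e-9).
#' @return the table, invisibly, after validation.
#' @export
validate_composition <- function(composition, tol = 1e-9) {
  need <- c("food_code", "context", "group_id", "fraction")
  if (!all(need %in% names(composition)))
    stop("composition table must have columns: ", paste(need, collapse = ", "))
  if (!all(composition$context %in% contexts()))
    stop("composition context must be 'core' or 'discretionary'")
  if (any(composition$fraction < 0 | composition$fraction > 1))
    stop("composition fractions must lie in [0, 1]")
  if (!all(composition$group_id %in% seq_len(23L)))
    stop("composition group_id must be in 1..23")
  sums <- tapply(composition$fraction, composition$food_code, sum)
  bad <- names(sums)[abs(sums - 1) > tol]
  if (length(bad))
    stop("composition fractions do not sum to 1 for food code(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  nctx <- tapply(composition$context, composition$food_code,
                 function(x) length(unique(x)))
  if (any(nctx > 1))
    stop("food code(s) with conflicting context: ",
         paste(utils::head(names(nctx)[nctx > 1], 5L), collapse = ", "))
  invisible(composition)
}

#' Decompose food records into group-by-context gram intakes
#'
#' Multi-ingredient foods, beverages and mixed dishes are split into their
#' per-group gram contributions: the entry for (group g, context c) is the sum
#' over records with context c of \code{grams * fraction(g)}. Total mass is
#' conserved.
#'
#' @param records data.frame of consumed foods with columns food_code and
#'   grams; may carry participant_id and day columns, which are ignored here.
#' @param composition a validated food-composition table
#'   ([validate_composition()]).
#' @return a 1 x 46 intake matrix (one row, canonical unit columns).
#' @examples
#' comp <- data.frame(food_code = "10000001", context = "core",
#'                    group_id = 2, fraction = 1)
#' decompose_foods(data.frame(food_code = "10000001", grams = 100), comp)
#' @export
decompose_foods <- function(records, composition) {
  validate_composition(composition)
  m <- empty_intake_matrix("1")
  if (is.null(records) || nrow(records) == 0L) return(m)
  if (any(records$grams < 0)) stop("negative grams in food records")
  unknown <- setdiff(records$food_code, composition$food_code)
  if (length(unknown))
    stop("food code(s) missing from composition table: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  x <- merge(records[, c("food_code", "grams")], composition, by = "food_code")
  x$contrib <- x$grams * x$fraction
  key <- sprintf("g%02d.%s", x$group_id, x$context)
  agg <- tapply(x$contrib, key, sum)
  m[1L, names(agg)] <- agg
  m
}

#' Average two recall days of an intake matrix
#'
#' @param day1,day2 intake matrices with identical row (participant) names.
#' @return the entry-wise mean, same shape.
#' @export
average_days <- function(day1, day2) {
  if (!identical(dim(day1), dim(day2)) ||
      !identical(rownames(day1), rownames(day2)))
    stop("day matrices are not aligned: participant ids differ")
  out <- (day1 + day2) / 2
  class(out) <- class(day1)
  out
}

#' Build per-day and two-day-mean intake matrices for a whole cohort
#'
#' Applies [decompose_foods()] to every (participant, day) in a long recall
#' table and averages the two days, the exposure substrate of the indices.
#'
#' @param recalls data.frame with columns participant_id, day (1 or 2),
#'   food_code, grams.
#' @param composition food-composition table.
#' @return list with elements day1, day2 and mean, each an n x 46 intake
#'   matrix with participants as rows.
#' @export
cohort_intakes <- function(recalls, composition) {
  validate_composition(composition)
  if (any(recalls$grams < 0)) stop("negative grams in food records")
  if (!all(recalls$day %in% c(1L, 2L))) stop("day must be 1 or 2")
  unknown <- setdiff(recalls$food_code, composition$food_code)
  if (length(unknown))
    stop("food code(s) missing from composition table: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  ids <- as.character(sort(unique(recalls$participant_id)))
  x <- merge(recalls, composition, by = "food_code")
  x$contrib <- x$grams * x$fraction
  x$unit <- sprintf("g%02d.%s", x$group_id, x$context)

  one_day <- function(d) {
    m <- empty_intake_matrix(ids)
    xd <- x[x$day == d, , drop = FALSE]
    if (nrow(xd)) {
      agg <- tapply(xd$contrib,
                    list(as.character(xd$participant_id), xd$unit), sum)
      agg[is.na(agg)] <- 0
      m[rownames(agg), colnames(agg)] <- agg
    }
    m
  }
  day1 <- one_day(1L)
  day2 <- one_day(2L)
  list(day1 = day1, day2 = day2, mean = average_days(day1, day2))
}
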