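#' Food-group taxonomy for the plant-based diet indices
#'
#' The indices operate on 23 food groups classified as healthy plant (7),
#' unhealthy plant (5) or animal (11), each consumed in one of two contexts:
#' \emph{core} (foods from the five recommended food groups of the Australian
#' Dietary Guidelines) or \emph{discretionary} (energy-dense, nutrient-poor
#' products). A (group, context) pair is one \emph{scoring unit}.
#'
#' Two of the eleven animal group labels are placeholders ("organ meats",
#' "animal-based sauces and stocks"): the classification scheme in the source
#' food-composition database names nine animal groups explicitly and the
#' remaining two are configurable. Only the total of 23 groups and the 7/5
#' plant split are structural.
#'
#' @param names_animal_extra character(2), labels for the two configurable
#'   animal groups.
#' @return A data.frame with columns \code{group_id} (1-23), \code{name} and
#'   \code{category} (factor: healthy_plant, unhealthy_plant, animal).
#' @examples
#' fg <- food_groups()
#' table(fg$category)
#' @export
food_groups <- function(names_animal_extra = c("organ meats",
                                               "animal-based sauces and stocks")) {
  stopifnot(length(names_animal_extra) == 2L)
  healthy <- c("whole grains", "fruits", "vegetables", "nuts and seeds",
               "legumes", "unsaturated plant oils and spreads", "tea and coffee")
  unhealthy <- c("refined grains", "fruit juices", "saturated plant fats",
                 "sugars and syrups", "miscellaneous plant products")
  animal <- c("animal fats", "low-fat dairy", "moderate-fat dairy",
              "high-fat dairy", "eggs", "fish and seafood",
              "processed or non-lean red meat and poultry",
              "unprocessed lean red meat and poultry",
              "miscellaneous animal items", names_animal_extra)
  df <- data.frame(
    group_id = seq_len(23L),
    name = c(healthy, unhealthy, animal),
    category = factor(rep(c("healthy_plant", "unhealthy_plant", "animal"),
                          times = c(7L, 5L, 11L)),
                      levels = c("healthy_plant", "unhealthy_plant", "animal")),
    stringsAsFactors = FALSE
  )
  class(df) <- c("food_group_table", "data.frame")
  df
}

#' The two consumption contexts
#' @return character(2): "core", "discretionary".
#' @export
contexts <- function() c("core", "discretionary")

#' Scoring matrix for the three plant-based diet indices
#'
#' Each index assigns every scoring unit an orientation and a weight:
#' \describe{
#'   \item{PDI}{all plant units positive, all animal units reverse, all
#'     weights 1 (46 units; totals in [46, 230]).}
#'   \item{hPDI}{healthy-plant units positive with weight 2 in core and 1 in
#'     discretionary (so a top-quintile healthy plant food scores 10 from core
#'     foods, 5 from discretionary foods); unhealthy-plant and animal units
#'     reverse with weight 1 (53 weight units; totals in [53, 265]).}
#'   \item{uPDI}{unhealthy-plant units positive with weight 2 in discretionary
#'     and 1 in core; healthy-plant and animal units reverse with weight 1
#'     (51 weight units; totals in [51, 255]).}
#' }
#' A positive unit contributes \code{weight * s} where s in 1..5 is the
#' quintile score; a reverse unit contributes \code{weight * (6 - s)}.
#'
#' @param groups a food-group table from [food_groups()].
#' @return data.frame with columns index, group_id, category, context,
#'   orientation ("positive"/"reverse") and weight (1 or 2).
#' @examples
#' sm <- scoring_matrix()
#' # total weight per index: 46, 53, 51
#' tapply(sm$weight, sm$index, sum)
#' @export
scoring_matrix <- function(groups = food_groups()) {
  grid <- expand.grid(group_id = groups$group_id, context = contexts(),
                      index = c("PDI", "hPDI", "uPDI"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$category <- as.character(groups$category)[grid$group_id]
  plant <- grid$category != "animal"

  orientation <- ifelse(plant, "positive", "reverse")
  weight <- rep(1L, nrow(grid))

  h <- grid$index == "hPDI"
  orientation[h & grid$category != "healthy_plant"] <- "reverse"
  weight[h & grid$category == "healthy_plant" & grid$context == "core"] <- 2L

  u <- grid$index == "uPDI"
  orientation[u & grid$category != "unhealthy_plant"] <- "reverse"
  weight[u & grid$category == "unhealthy_plant" &
           grid$context == "discretionary"] <- 2L

  out <- data.frame(index = grid$index, group_id = grid$group_id,
                    category = grid$category, context = grid$context,
                    orientation = orientation, weight = weight,
                    stringsAsFactors = FALSE)
  class(out) <- c("scoring_matrix", "data.frame")
  out
}

#' Theoretical score ranges implied by a scoring matrix
#'
#' Minimum = sum of unit weights (every unit at its worst oriented quintile
#' score of 1); maximum = 5 times that.
#'
#' @param sm a scoring matrix from [scoring_matrix()].
#' @return data.frame with index, min, max.
#' @export
score_ranges <- function(sm = scoring_matrix()) {
  w <- tapply(sm$weight, sm$index, sum)
  data.frame(index = names(w), min = as.integer(w), max = as.integer(5L * w),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write / read a scoring matrix as CSV (audit trail)
#' @param sm scoring matrix.
#' @param path file path.
#' @return `read_scoring_matrix` returns the scoring matrix data.frame.
#' @export
write_scoring_matrix <- function(sm, path) {
  utils::write.csv(as.data.frame(sm), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scoring_matrix
#' @export
read_scoring_matrix <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("scoring_matrix", "data.frame")
  out
}
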