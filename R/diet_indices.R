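#' Weighted quantile, inverse-ECDF "lower" type
#'
#' Returns, for each probability p, the smallest observed value x such that
#' the weighted ECDF at x is at least p. This definition is exactly
#' reproducible (no interpolation), invariant to rescaling of the weights,
#' and with equal weights coincides with the unweighted lower empirical
#' quantile.
#'
#' @param x numeric values.
#' @param w positive weights, same length as x.
#' @param probs probabilities in (0, 1].
#' @return numeric vector of quantiles.
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(is.finite(x)), all(is.finite(w)))
  if (any(w < 0) || sum(w) <= 0) stop("weights must be non-negative with positive sum")
  o <- order(x)
  xs <- x[o]
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) xs[which(cw >= p - 1e-12)[1L]], numeric(1))
}

#' Quintile cutpoints of the weighted consumption distribution
#'
#' For every scoring unit, the four cut values are the survey-weighted
#' 20/40/60/80 percentiles of grams/day over the analysis sample, zeros
#' included. They are computed once, on the post-exclusion sample. Units
#' where a quintile of the weighted mass sits at zero get zero cuts there;
#' the tie rule in [assign_unit_scores()] then sends all zero consumers to
#' the lowest quintile.
#'
#' @param intakes n x 46 intake matrix (two-day means).
#' @param weights survey calibration weights (length n, positive).
#' @return 4 x 46 matrix of non-decreasing cut values (rows p20, p40, p60,
#'   p80), class "quintile_cutpoints".
#' @export
compute_cutpoints <- function(intakes, weights) {
  if (nrow(intakes) < 5L)
    stop("at least 5 participants are required to form quintiles")
  if (length(weights) != nrow(intakes)) stop("weights are not aligned with intakes")
  if (any(weights <= 0)) stop("calibration weights must be positive")
  cuts <- apply(intakes, 2L, weighted_quantile, w = weights,
                probs = c(0.2, 0.4, 0.6, 0.8))
  rownames(cuts) <- c("p20", "p40", "p60", "p80")
  class(cuts) <- c("quintile_cutpoints", class(cuts))
  cuts
}

#' Quintile membership and unit scores
#'
#' Quintile bins are half-open upwards: intake <= p20 is Q1, p20 < intake <=
#' p40 is Q2, ..., intake > p80 is Q5; a value equal to a cut takes the lower
#' quintile. A positive unit contributes \code{weight * s}; a reverse unit
#' \code{weight * (6 - s)}.
#'
#' @param intake numeric vector of grams/day for one unit.
#' @param cuts the unit's four non-decreasing cut values.
#' @return `quintile_of` returns integers 1-5.
#' @export
quintile_of <- function(intake, cuts) {
  stopifnot(length(cuts) == 4L, !is.unsorted(cuts))
  1L + (intake > cuts[1L]) + (intake > cuts[2L]) +
    (intake > cuts[3L]) + (intake > cuts[4L])
}

#' @rdname quintile_of
#' @param orientation "positive" or "reverse".
#' @param weight unit weight (1 or 2).
#' @return `assign_unit_scores` returns integer unit scores
#'   (weight x oriented quintile score).
#' @export
assign_unit_scores <- function(intake, cuts, orientation, weight = 1L) {
  s <- quintile_of(intake, cuts)
  if (orientation == "reverse") s <- 6L - s
  else if (orientation != "positive") stop("unknown orientation: ", orientation)
  as.integer(weight) * s
}

#' Score a cohort on the three plant-based diet indices
#'
#' Sums the 46/53/51 weighted unit scores per participant for the overall
#' PDI, the hPDI and the uPDI.
#'
#' @param intakes n x 46 intake matrix of two-day mean grams/day.
#' @param cuts cutpoints from [compute_cutpoints()], computed on the sample
#'   containing these participants.
#' @param sm scoring matrix ([scoring_matrix()]).
#' @return data.frame with participant_id, pdi, hpdi, updi (integers within
#'   the theoretical ranges 46-230, 53-265, 51-255).
#' @export
score_cohort <- function(intakes, cuts, sm = scoring_matrix()) {
  if (!identical(colnames(intakes), colnames(cuts)))
    stop("intake matrix and cutpoints use different unit layouts")
  if (any(is.na(intakes))) stop("intake matrix has missing entries")
  n <- nrow(intakes)
  units <- unit_layout()
  # quintile of every participant for every unit, n x 46
  q <- vapply(seq_len(nrow(units)),
              function(j) quintile_of(intakes[, j], cuts[, j]),
              integer(n))
  if (n == 1L) q <- matrix(q, nrow = 1L)
  totals <- sapply(c("PDI", "hPDI", "uPDI"), function(ix) {
    smx <- sm[sm$index == ix, ]
    key <- sprintf("g%02d.%s", smx$group_id, smx$context)
    j <- match(key, units$unit)
    oriented <- q[, j, drop = FALSE]
    rev <- smx$orientation == "reverse"
    oriented[, rev] <- 6L - oriented[, rev, drop = FALSE]
    as.integer(oriented %*% smx$weight)
  })
  if (n == 1L) totals <- matrix(totals, nrow = 1L,
                                dimnames = list(NULL, c("PDI", "hPDI", "uPDI")))
  data.frame(participant_id = rownames(intakes),
             pdi = totals[, "PDI"], hpdi = totals[, "hPDI"],
             updi = totals[, "uPDI"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Weighted quintile of a total index score
#'
#' Quintile membership (1-5) of each participant's total score within the
#' weighted distribution of the analysis sample, used for Table-1-style
#' summaries and trend tests.
#'
#' @param score numeric vector of index totals.
#' @param weights survey weights.
#' @return integer vector in 1..5.
#' @export
score_quintile <- function(score, weights) {
  cuts <- weighted_quantile(score, weights, c(0.2, 0.4, 0.6, 0.8))
  quintile_of(score, cuts)
}

#' Cohort placing one participant at a theoretical score extreme
#'
#' Builds a 10-participant, equal-weight cohort in which participant 1 sits
#' in the best- or worst-scoring quintile of every scoring unit of the given
#' index: units the index scores positively get intake 100 g/d against a
#' background of 1-9 g/d (top quintile) or 0 g/d (bottom quintile), and
#' reverse-scored units the opposite. Scoring participant 1 with the engine
#' then realises the index's theoretical maximum or minimum (PDI 230/46,
#' hPDI 265/53, uPDI 255/51).
#'
#' @param index "PDI", "hPDI" or "uPDI".
#' @param extreme "max" or "min".
#' @param sm scoring matrix.
#' @return list with `intakes` (10 x 46 matrix, participant "X" first) and
#'   `weights` (equal).
#' @export
extreme_intake_cohort <- function(index = c("PDI", "hPDI", "uPDI"),
                                  extreme = c("max", "min"),
                                  sm = scoring_matrix()) {
  index <- match.arg(index)
  extreme <- match.arg(extreme)
  u <- unit_layout()
  m <- empty_intake_matrix(c("X", sprintf("B%d", 1:9)))
  m[2:10, ] <- matrix(rep(1:9, ncol(m)), nrow = 9L)
  smx <- sm[sm$index == index, ]
  key <- sprintf("g%02d.%s", smx$group_id, smx$context)
  want_high <- (smx$orientation == "positive") == (extreme == "max")
  m[1L, match(key, u$unit)] <- ifelse(want_high, 100, 0)
  list(intakes = m, weights = rep(1, 10L))
}
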