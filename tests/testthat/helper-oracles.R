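# Independent brute-force oracles, written as plain loops so they share no
# code path with the implementation.

# lower-type weighted quantile by expanding integer weights
brute_weighted_quantile <- function(x, w_int, p) {
  expanded <- sort(rep(x, times = w_int))
  expanded[ceiling(p * length(expanded))]
}

# quintile cuts + membership by explicit weighted ECDF loop
brute_quintile <- function(x_all, w, x) {
  o <- order(x_all)
  xs <- x_all[o]; ws <- w[o]
  tot <- sum(ws)
  cuts <- numeric(4)
  for (k in 1:4) {
    acc <- 0
    for (i in seq_along(xs)) {
      acc <- acc + ws[i]
      if (acc / tot >= k / 5 - 1e-12) { cuts[k] <- xs[i]; break }
    }
  }
  q <- 1L
  for (k in 1:4) if (x > cuts[k]) q <- q + 1L
  q
}

# full index totals by enumerating every scoring-matrix row
brute_scores <- function(intakes, weights, sm) {
  u <- plantdex::unit_layout()
  n <- nrow(intakes)
  out <- matrix(0L, n, 3, dimnames = list(rownames(intakes),
                                          c("PDI", "hPDI", "uPDI")))
  for (i in seq_len(n)) {
    for (r in seq_len(nrow(sm))) {
      col <- sprintf("g%02d.%s", sm$group_id[r], sm$context[r])
      q <- brute_quintile(intakes[, col], weights, intakes[i, col])
      s <- if (sm$orientation[r] == "reverse") 6L - q else q
      out[i, sm$index[r]] <- out[i, sm$index[r]] + sm$weight[r] * s
    }
  }
  out
}

# replicate-rule jackknife se of a weighted mean by naive loop
naive_repwt_se <- function(x, weight, rep_weights, variance_factor) {
  theta <- sum(weight * x) / sum(weight)
  ss <- 0
  for (r in seq_len(ncol(rep_weights))) {
    wr <- rep_weights[, r]
    ss <- ss + (sum(wr * x) / sum(wr) - theta)^2
  }
  sqrt(variance_factor * ss)
}

# small equal-weight design with degenerate replicates (all equal to main)
degenerate_design <- function(n, weight = rep(1, n), R = 4) {
  survey_design(sprintf("P%d", seq_len(n)), weight,
                matrix(weight, n, R))
}

# delete-a-group jackknife design with lognormal weights
dagjk_design <- function(n, R = 60, seed = 1) {
  set.seed(seed)
  w <- rlnorm(n, log(100), 0.3)
  grp <- ((seq_len(n) - 1L) %% R) + 1L
  repw <- outer(seq_len(n), seq_len(R),
                function(i, r) ifelse(grp[i] == r, 0, w[i] * R / (R - 1)))
  survey_design(sprintf("P%d", seq_len(n)), w, repw)
}

small_cohort <- function(n = 80, seed = 42, ...) {
  generate_cohort(generator_config(n = n, seed = seed, ...))
}
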