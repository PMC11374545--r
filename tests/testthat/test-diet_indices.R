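test_that("scoring matrix reproduces the printed structure of all three indices", {
  sm <- scoring_matrix()
  expect_equal(nrow(sm), 3L * 46L)
  w <- tapply(sm$weight, sm$index, sum)
  expect_equal(as.integer(w[c("PDI", "hPDI", "uPDI")]), c(46L, 53L, 51L))
  pdi <- sm[sm$index == "PDI", ]
  expect_true(all(pdi$weight == 1L))
  expect_true(all(pdi$orientation[pdi$category != "animal"] == "positive"))
  expect_true(all(pdi$orientation[pdi$category == "animal"] == "reverse"))
  h <- sm[sm$index == "hPDI" & sm$category == "healthy_plant", ]
  expect_equal(h$weight[h$context == "core"], rep(2L, 7))
  expect_equal(h$weight[h$context == "discretionary"], rep(1L, 7))
  rng <- score_ranges(sm)
  expect_equal(rng$min[match(c("PDI", "hPDI", "uPDI"), rng$index)],
               c(46L, 53L, 51L))
  expect_equal(rng$max[match(c("PDI", "hPDI", "uPDI"), rng$index)],
               c(230L, 265L, 255L))
})

test_that("scoring-matrix CSV round-trips", {
  f <- tempfile(fileext = ".csv")
  write_scoring_matrix(scoring_matrix(), f)
  expect_equal(read_scoring_matrix(f), scoring_matrix(),
               ignore_attr = TRUE)
})

test_that("weighted quantiles match the expanded-weights oracle", {
  set.seed(3)
  for (rep in 1:20) {
    x <- round(runif(15, 0, 100), 1)
    w <- sample(1:5, 15, replace = TRUE)
    for (p in c(0.2, 0.4, 0.6, 0.8))
      expect_equal(weighted_quantile(x, w, p),
                   brute_weighted_quantile(x, w, p))
  }
})

test_that("cutpoints on 1..100 with equal weights are the 20/40/60/80 percentiles", {
  m <- empty_intake_matrix(as.character(1:100))
  m[, "g01.core"] <- 1:100
  cuts <- compute_cutpoints(m, rep(1, 100))
  expect_equal(unname(cuts[, "g01.core"]), c(20, 40, 60, 80))
  expect_equal(unname(quintile_of(50, cuts[, "g01.core"])), 3L)
})

test_that("degenerate all-zero units give zero cuts and universal Q1", {
  m <- empty_intake_matrix(as.character(1:10))
  cuts <- compute_cutpoints(m, rep(1, 10))
  expect_true(all(cuts == 0))
  expect_true(all(quintile_of(m[, 1], cuts[, 1]) == 1L))
})

test_that("cutpoints are invariant to rescaling the weights", {
  set.seed(5)
  m <- empty_intake_matrix(as.character(1:30))
  m[] <- rexp(length(m), 1 / 40)
  w <- runif(30, 0.5, 3)
  expect_equal(compute_cutpoints(m, w), compute_cutpoints(m, 10 * w))
})

test_that("fewer than 5 participants is a sample-size error", {
  m <- empty_intake_matrix(as.character(1:4))
  expect_error(compute_cutpoints(m, rep(1, 4)), "5 participants")
})

test_that("unit scores follow orientation and weight, with reversal symmetry", {
  cuts <- c(10, 20, 30, 40)
  expect_equal(assign_unit_scores(45, cuts, "positive", 1L), 5L)
  expect_equal(assign_unit_scores(45, cuts, "positive", 2L), 10L)
  expect_equal(assign_unit_scores(45, cuts, "reverse", 1L), 1L)
  expect_equal(assign_unit_scores(5, cuts, "positive", 2L), 2L)
  for (x in c(5, 10, 15, 25, 35, 50))  # ties take the lower quintile
    expect_equal(assign_unit_scores(x, cuts, "positive") +
                   assign_unit_scores(x, cuts, "reverse"), 6L)
  expect_equal(assign_unit_scores(10, cuts, "positive"), 1L)
  expect_equal(assign_unit_scores(20, cuts, "positive"), 2L)
})

test_that("index totals match the brute-force enumeration oracle on small cohorts", {
  sm <- scoring_matrix()
  set.seed(11)
  for (rep in 1:3) {
    n <- sample(6:20, 1)
    m <- empty_intake_matrix(sprintf("p%d", 1:n))
    m[] <- rexp(length(m), 1 / 30) * rbinom(length(m), 1, 0.7)
    w <- runif(n, 0.5, 4)
    cuts <- compute_cutpoints(m, w)
    got <- score_cohort(m, cuts, sm)
    want <- brute_scores(m, w, sm)
    expect_equal(got$pdi, unname(want[, "PDI"]))
    expect_equal(got$hpdi, unname(want[, "hPDI"]))
    expect_equal(got$updi, unname(want[, "uPDI"]))
  }
})

test_that("scores stay within theoretical ranges on random cohorts", {
  co <- small_cohort(n = 60, seed = 9)
  s <- co$true_scores
  expect_true(all(s$pdi >= 46 & s$pdi <= 230))
  expect_true(all(s$hpdi >= 53 & s$hpdi <= 265))
  expect_true(all(s$updi >= 51 & s$updi <= 255))
})

test_that("raising a healthy core intake never lowers hPDI nor raises uPDI", {
  co <- small_cohort(n = 50, seed = 2)
  m <- co$intakes$mean
  cuts <- compute_cutpoints(m, co$design$weight)
  base <- score_cohort(m, cuts)
  m2 <- m
  m2[7, "g02.core"] <- m2[7, "g02.core"] + 500  # fruits, core
  bumped <- score_cohort(m2, cuts)              # cutpoints held fixed
  expect_gte(bumped$hpdi[7], base$hpdi[7])
  expect_lte(bumped$updi[7], base$updi[7])
  expect_equal(bumped$hpdi[-7], base$hpdi[-7])
})

test_that("quintile assignment is invariant under increasing transforms of a unit", {
  set.seed(13)
  m <- empty_intake_matrix(sprintf("p%d", 1:25))
  m[] <- rexp(length(m), 1 / 30) * rbinom(length(m), 1, 0.6)
  w <- runif(25, 0.5, 3)
  q0 <- quintile_of(m[, "g05.core"],
                    compute_cutpoints(m, w)[, "g05.core"])
  m[, "g05.core"] <- m[, "g05.core"]^3  # strictly increasing on [0, Inf)
  q1 <- quintile_of(m[, "g05.core"],
                    compute_cutpoints(m, w)[, "g05.core"])
  expect_equal(q0, q1)
})

test_that("extreme cohorts realise every theoretical bound", {
  want <- list(PDI = c(46, 230), hPDI = c(53, 265), uPDI = c(51, 255))
  col <- c(PDI = "pdi", hPDI = "hpdi", uPDI = "updi")
  for (ix in names(want)) {
    for (k in 1:2) {
      cc <- extreme_intake_cohort(ix, c("min", "max")[k])
      s <- score_cohort(cc$intakes, compute_cutpoints(cc$intakes, cc$weights))
      expect_equal(s[[col[[ix]]]][1], want[[ix]][k])
    }
  }
})
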