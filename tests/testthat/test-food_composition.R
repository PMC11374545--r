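test_that("taxonomy has 23 groups with the 7/5/11 category split", {
  fg <- food_groups()
  expect_equal(nrow(fg), 23L)
  expect_equal(as.vector(table(fg$category)[c("healthy_plant",
                                              "unhealthy_plant", "animal")]),
               c(7L, 5L, 11L))
  expect_setequal(c("whole grains", "fruits", "vegetables", "nuts and seeds",
                    "legumes"),
                  intersect(fg$name[fg$category == "healthy_plant"],
                            c("whole grains", "fruits", "vegetables",
                              "nuts and seeds", "legumes")))
})

test_that("single-ingredient foods decompose to their own group", {
  comp <- data.frame(food_code = "10100001", context = "core",
                     group_id = 2L, fraction = 1)
  m <- decompose_foods(data.frame(food_code = "10100001", grams = 100), comp)
  expect_equal(unname(m[1, "g02.core"]), 100)
  expect_equal(sum(m), 100)
})

test_that("a mixed discretionary cake splits into ingredient groups in the parent context", {
  comp <- default_composition()
  rec <- data.frame(food_code = "20000001", grams = 200)
  m <- decompose_foods(rec, comp)
  expect_equal(unname(m[1, "g08.discretionary"]), 100)   # refined grains
  expect_equal(unname(m[1, "g11.discretionary"]), 50)    # sugars and syrups
  expect_equal(unname(m[1, "g17.discretionary"]), 30)    # eggs
  expect_equal(unname(m[1, "g02.discretionary"]), 20)    # fruit, kept in the
  expect_equal(unname(m[1, "g02.core"]), 0)              # cake's context
  expect_equal(sum(m), 200)
})

test_that("empty record list gives an all-zero matrix", {
  m <- decompose_foods(data.frame(food_code = character(), grams = numeric()),
                       default_composition())
  expect_true(all(m == 0))
  expect_equal(dim(m), c(1L, 46L))
})

test_that("composition errors name the offending food code", {
  bad <- data.frame(food_code = "99999999", context = "core",
                    group_id = c(1L, 2L), fraction = c(0.5, 0.4))
  expect_error(validate_composition(bad), "99999999")
  expect_error(decompose_foods(data.frame(food_code = "10100001", grams = -5),
                               default_composition()),
               "negative grams")
})

test_that("decomposition conserves mass and is additive over record lists", {
  comp <- default_composition()
  set.seed(7)
  for (rep in 1:10) {
    codes <- sample(comp$food_code, 12, replace = TRUE)
    grams <- round(runif(12, 0, 400), 2)
    rec <- data.frame(food_code = codes, grams = grams)
    m <- decompose_foods(rec, comp)
    expect_equal(sum(m), sum(grams), tolerance = 1e-10)
    half <- sample(12, 6)
    m1 <- decompose_foods(rec[half, ], comp)
    m2 <- decompose_foods(rec[-half, ], comp)
    expect_equal(m1 + m2, m, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("two-day averaging is the entry-wise mean, symmetric and idempotent", {
  set.seed(1)
  m1 <- empty_intake_matrix(c("a", "b"))
  m2 <- empty_intake_matrix(c("a", "b"))
  m1[] <- runif(length(m1), 0, 50)
  m2[] <- runif(length(m2), 0, 50)
  expect_equal(average_days(m1, m1), m1)
  expect_equal(average_days(m1, m2), average_days(m2, m1))
  z <- m1; z[] <- 0
  expect_equal(average_days(z, m2), m2 / 2, ignore_attr = TRUE)
  m3 <- empty_intake_matrix(c("a", "c"))
  expect_error(average_days(m1, m3), "participant ids")
})

test_that("cohort_intakes reproduces per-participant decomposition and day means", {
  comp <- default_composition()
  recalls <- data.frame(
    participant_id = c("p1", "p1", "p1", "p2", "p2"),
    day = c(1L, 1L, 2L, 1L, 2L),
    food_code = c("10110000", "20000001", "10110000", "10220000", "10220000"),
    grams = c(100, 200, 50, 80, 40))
  ci <- cohort_intakes(recalls, comp)
  expect_equal(unname(ci$day1["p1", "g01.core"]), 100)
  expect_equal(unname(ci$day1["p1", "g08.discretionary"]), 100)
  expect_equal(unname(ci$mean["p1", "g01.core"]), 75)
  expect_equal(unname(ci$mean["p2", "g02.discretionary"]), 60)
  expect_equal(sum(ci$day1) + sum(ci$day2), sum(recalls$grams))
})
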