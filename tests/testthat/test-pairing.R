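test_that("mean absolute pair difference is plain arithmetic", {
  expect_equal(
    mean_abs_pair_diff(tibble::tibble(male_age = c(7, 7), female_age = c(7, 7))),
    0
  )
  expect_equal(
    mean_abs_pair_diff(tibble::tibble(male_age = c(10, 20), female_age = c(12, 15))),
    3.5
  )
  withr::with_seed(131, {
    p <- tibble::tibble(male_age = sample(4:37, 21, TRUE), female_age = sample(4:37, 21, TRUE))
    acc <- 0
    for (i in 1:21) acc <- acc + abs(p$male_age[i] - p$female_age[i])
    expect_equal(mean_abs_pair_diff(p), acc / 21)
  })
  expect_error(mean_abs_pair_diff(tibble::tibble(male_age = numeric(0), female_age = numeric(0))), "at least one")
})

test_that("the randomization null is reproducible and degenerate-safe", {
  p <- tibble::tibble(male_age = c(10, 10, 10), female_age = c(10, 10, 10))
  r <- random_pairing_null(p, n_sim = 200, seed = 5)
  expect_equal(r$observed, 0)
  expect_equal(c(r$conf_low, r$conf_high), c(0, 0))
  expect_equal(r$verdict, "inside")

  p2 <- tibble::tibble(male_age = c(4, 12, 30), female_age = c(5, 13, 28))
  a <- random_pairing_null(p2, n_sim = 500, seed = 7)
  b <- random_pairing_null(p2, n_sim = 500, seed = 7)
  expect_identical(a$null_draws, b$null_draws)
  expect_lte(a$conf_low, a$conf_high)
  expect_warning(random_pairing_null(p2, n_sim = 50, seed = 1), "unstable")
  expect_error(random_pairing_null(p2[1, ], seed = 1), "two pairs")
})

test_that("three-pair null draws come from the exhaustive re-pairing distribution", {
  m <- c(1, 5, 9)
  f <- c(2, 3, 10)
  perms <- list(
    c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)
  )
  vals <- vapply(perms, function(pm) mean(abs(m - f[pm])), numeric(1))
  r <- random_pairing_null(
    tibble::tibble(male_age = m, female_age = f),
    n_sim = 6000, seed = 3
  )
  # every simulated value is one of the 3! enumerated ones ...
  expect_true(all(r$null_draws %in% vals))
  # ... with frequencies converging to uniform (4 SE band)
  freq <- table(factor(r$null_draws, levels = sort(unique(vals))))
  expected <- 6000 * as.vector(table(factor(vals, levels = sort(unique(vals))))) / 6
  expect_true(all(abs(freq - expected) < 4 * sqrt(6000 * (1 / 6) * (5 / 6))))
  # CI from the enumerated distribution brackets the simulated CI
  expect_gte(r$conf_low, min(vals))
  expect_lte(r$conf_high, max(vals))
})

test_that("strong assortment is detected as outside-low", {
  withr::with_seed(141, {
    ages <- sort(sample(4:37, 21))
    p <- tibble::tibble(
      male_age = ages,
      female_age = ages + sample(c(-1, 0, 1), 21, TRUE)
    )
    r <- random_pairing_null(p, n_sim = 1000, seed = 9)
    expect_equal(r$verdict, "outside-low")
    expect_lt(r$observed, r$conf_low)
  })
})

test_that("the null distribution is invariant to which sex is permuted", {
  withr::with_seed(151, {
    p <- tibble::tibble(
      male_age = sample(4:37, 21, TRUE),
      female_age = sample(4:37, 21, TRUE)
    )
    a <- random_pairing_null(p, n_sim = 4000, seed = 11)
    b <- random_pairing_null(
      dplyr::rename(p, male_age = "female_age", female_age = "male_age"),
      n_sim = 4000, seed = 12
    )
    expect_equal(a$observed, b$observed)
    expect_equal(mean(a$null_draws), mean(b$null_draws), tolerance = 0.02)
    expect_equal(a$conf_low, b$conf_low, tolerance = 0.35)
    expect_equal(a$conf_high, b$conf_high, tolerance = 0.35)
  })
})

test_that("predicted complexity for pairs is a pure function of age", {
  withr::with_seed(161, {
    n <- 100
    age <- runif(n, 4, 37)
    d <- tibble::tibble(age = age, age2 = age^2, date = runif(n, 0, 151))
    std <- standardize_predictors(d)
    # concave quadratic peaking at z(age) = 0, i.e. at the mean age
    std$sdc <- 50 + 10 * std$age - 30 * std$age2 + 20 * std$date + rnorm(n)
    avg <- model_average(model_selection(std, "sdc", terms = c("age", "age2", "date")))

    pairs <- tibble::tibble(
      male_id = c("m1", "m2"), male_age = c(20, 20),
      female_id = c("f1", "f2"), female_age = c(20, 33)
    )
    pp <- predicted_sdc_for_pairs(pairs, avg)
    # equal ages -> equal predicted scores
    expect_equal(pp$male_sdc_pred[1], pp$female_sdc_pred[1])
    expect_equal(pp$male_sdc_pred, rep(pp$male_sdc_pred[1], 2))

    # a symmetric quadratic makes distant ages display alike:
    # find the age pair straddling the peak with equal predictions
    grid <- predict_response(avg, tibble::tibble(age = seq(4, 37, 0.1), date = 94))
    peak <- grid$age[which.max(grid$.pred)]
    young <- peak - 10
    old <- peak + 10
    pq <- predicted_sdc_for_pairs(
      tibble::tibble(male_age = young, female_age = old), avg
    )
    expect_lt(
      abs(pq$male_sdc_pred - pq$female_sdc_pred),
      0.02 * abs(pq$male_sdc_pred)
    )
    expect_error(
      predicted_sdc_for_pairs(tibble::tibble(male_age = NA, female_age = 5), avg),
      "missing"
    )
  })
})
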