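# minimal hand-built candidate object accepted by model_average()
fake_candidate <- function(coef, vcov, label, n = 50,
                           model = data.frame(x = c(0, 1))) {
  structure(
    list(
      coef = coef, vcov = vcov, label = label, family = "gaussian",
      fit = list(model = model), n = n, terms = setdiff(names(coef), "(Intercept)")
    ),
    class = "sdc_candidate"
  )
}

test_that("averaging a single model returns its own coefficients and SEs", {
  withr::with_seed(41, {
    d <- tibble::tibble(x = rnorm(40))
    d$y <- 1 + 0.5 * d$x + rnorm(40)
    fit <- fit_candidate(d, "y", "x")
    avg <- model_average(list(fit), weights = 1)
    expect_equal(
      avg$coefficients$estimate,
      unname(fit$coef)
    )
    expect_equal(
      avg$coefficients$se,
      unname(sqrt(diag(fit$vcov))),
      tolerance = 1e-10
    )
    expect_equal(avg$coefficients$sum_of_weights, c(1, 1))
  })
})

test_that("a term absent from some models shrinks by the zero method", {
  m1 <- fake_candidate(
    c("(Intercept)" = 0, x = 2.0),
    matrix(0, 2, 2, dimnames = list(c("(Intercept)", "x"), c("(Intercept)", "x"))),
    "x"
  )
  m2 <- fake_candidate(
    c("(Intercept)" = 0),
    matrix(0, 1, 1, dimnames = list("(Intercept)", "(Intercept)")),
    "1"
  )
  avg <- model_average(list(m1, m2), weights = c(0.6, 0.4))
  x_row <- avg$coefficients[avg$coefficients$term == "x", ]
  expect_equal(x_row$estimate, 1.2) # 0.6 * 2 + 0.4 * 0
  expect_equal(x_row$sum_of_weights, 0.6)
})

test_that("a three-model fixture matches the spreadsheet computation", {
  # weights 0.5 / 0.3 / 0.2; term x in models 1 and 2; term z only in model 3
  mk <- function(terms, beta, var, label) {
    nm <- c("(Intercept)", terms)
    v <- diag(c(0.04, var), nrow = length(nm))
    dimnames(v) <- list(nm, nm)
    fake_candidate(setNames(c(1, beta), nm), v, label)
  }
  m1 <- mk("x", 3.0, 0.25, "x")
  m2 <- mk("x", 2.0, 0.16, "x ")
  m3 <- mk("z", -1.0, 0.09, "z")
  avg <- model_average(list(m1, m2, m3), weights = c(0.5, 0.3, 0.2))

  # estimate(x) = .5*3 + .3*2 + .2*0 = 2.1
  # SE(x) = .5*sqrt(.25 + (3-2.1)^2) + .3*sqrt(.16 + (2-2.1)^2) + .2*sqrt(0 + 2.1^2)
  co <- avg$coefficients
  x <- co[co$term == "x", ]
  expect_equal(x$estimate, 2.1)
  se_x <- 0.5 * sqrt(0.25 + 0.81) + 0.3 * sqrt(0.16 + 0.01) + 0.2 * 2.1
  expect_equal(x$se, se_x, tolerance = 1e-12)
  expect_equal(x$conf_low, 2.1 - stats::qnorm(0.975) * se_x, tolerance = 1e-10)
  expect_equal(x$sum_of_weights, 0.8)

  z <- co[co$term == "z", ]
  expect_equal(z$estimate, 0.2 * -1)
  expect_equal(z$sum_of_weights, 0.2)
  # intercept present everywhere: plain weighted mean, importance 1
  ic <- co[co$term == "(Intercept)", ]
  expect_equal(ic$estimate, 1)
  expect_equal(ic$sum_of_weights, 1)
})

test_that("splitting a model's weight across a duplicate leaves the average unchanged", {
  m1 <- fake_candidate(
    c("(Intercept)" = 1, x = 2),
    matrix(c(0.01, 0, 0, 0.04), 2, 2,
      dimnames = list(c("(Intercept)", "x"), c("(Intercept)", "x"))
    ),
    "x"
  )
  m2 <- fake_candidate(
    c("(Intercept)" = 0.5),
    matrix(0.02, dimnames = list("(Intercept)", "(Intercept)")),
    "1"
  )
  a <- model_average(list(m1, m2), weights = c(0.6, 0.4))
  b <- model_average(list(m1, m1, m2), weights = c(0.3, 0.3, 0.4))
  expect_equal(a$coefficients$estimate, b$coefficients$estimate)
  expect_equal(a$coefficients$se, b$coefficients$se)
})

test_that("predictions are the dot product, inverse-linked and extrapolation-flagged", {
  withr::with_seed(51, {
    n <- 100
    age <- runif(n, 4, 37)
    d <- tibble::tibble(age = age, age2 = age^2)
    std <- standardize_predictors(d)
    std$y <- 10 + 4 * std$age - 6 * std$age2 + rnorm(n, 0, 0.1)
    sel <- model_selection(std, "y", terms = c("age", "age2"))
    avg <- model_average(sel)

    # hand-computed linear combination at three ages
    rec <- scaling_record(std)
    co <- setNames(avg$coefficients$estimate, avg$coefficients$term)
    ages <- c(6, 20, 34)
    za <- (ages - rec$center[rec$term == "age"]) / rec$scale[rec$term == "age"]
    za2 <- (ages^2 - rec$center[rec$term == "age2"]) / rec$scale[rec$term == "age2"]
    by_hand <- co[["(Intercept)"]] + co[["age"]] * za + co[["age2"]] * za2
    pred <- predict_response(avg, tibble::tibble(age = ages))
    expect_equal(pred$.pred, unname(by_hand), tolerance = 1e-10)
    expect_false(any(pred$.extrapolated))
    # outside the fitted age range is flagged but still returned
    out <- predict_response(avg, tibble::tibble(age = 60))
    expect_true(out$.extrapolated)

    # all slopes zero -> flat curve at the intercept
    flat <- fake_candidate(
      c("(Intercept)" = 7),
      matrix(0.1, dimnames = list("(Intercept)", "(Intercept)")),
      "1"
    )
    favg <- model_average(list(flat), weights = 1)
    expect_equal(
      predict_response(favg, tibble::tibble(x = c(0, 1, 99)))$.pred,
      rep(7, 3)
    )
  })
})

test_that("a fitted concave quadratic peaks where calculus says it should", {
  withr::with_seed(61, {
    x <- runif(400, -3, 3)
    d <- tibble::tibble(x = x, x2 = x^2)
    # do not standardize: peak of b1*x + b2*x^2 sits at -b1 / (2 b2)
    d$y <- 2 + 1.5 * d$x - 0.5 * d$x2 + rnorm(400, 0, 0.05)
    fit <- fit_candidate(d, "y", c("x", "x2"))
    grid <- tibble::tibble(x = seq(-3, 3, by = 0.001))
    grid$x2 <- grid$x^2
    pred <- predict_response(fit, grid)
    expect_equal(
      grid$x[which.max(pred$.pred)],
      -unname(fit$coef[["x"]]) / (2 * unname(fit$coef[["x2"]])),
      tolerance = 1e-2
    )
  })
})

test_that("binomial averages return probabilities", {
  withr::with_seed(71, {
    n <- 120
    d <- tibble::tibble(x = rnorm(n))
    d$y <- rbinom(n, 1, plogis(-1 + 2 * d$x))
    sel <- model_selection(d, "y", terms = "x", family = "binomial")
    avg <- model_average(sel)
    p <- predict_response(avg, tibble::tibble(x = c(-2, 0, 2)))$.pred
    expect_true(all(p >= 0 & p <= 1))
    expect_true(p[3] > p[1])
  })
})
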