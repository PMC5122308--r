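test_that("individual generation honors the design and is deterministic", {
  ind <- generate_individuals(seed = 1)
  expect_equal(nrow(ind), 100)
  expect_equal(sum(ind$sex == "F"), 50)
  expect_true(all(ind$age >= 4 & ind$age <= 37))
  expect_true(all(ind$date >= 0 & ind$date <= 151))
  expect_true(all(ind$group_size >= 9 & ind$group_size <= 130))
  expect_equal(sum(ind$year == 2L), 56)
  expect_identical(ind, generate_individuals(seed = 1))
  expect_false(identical(ind, generate_individuals(seed = 2)))

  # quality collapses to q0 when every coefficient is silenced
  cfg0 <- sdc_generator_config(
    q_age = 0, q_age2 = 0, q_date = 0, sigma_q = 0, q0 = 1.25
  )
  expect_equal(generate_individuals(cfg0, seed = 3)$quality, rep(1.25, 100))
  expect_error(sdc_generator_config(age_range = c(10, 4)), "low <= high")
  expect_error(sdc_generator_config(assortment = 2), "\\[0, 1\\]")
})

test_that("sequence generation spans the switching extremes", {
  # s = 0: the bird never changes posture
  cfg_still <- sdc_generator_config(s0 = 0, beta_s = 0)
  seq0 <- generate_sequence(1, cfg_still, seed = 5)
  expect_equal(versatility(seq0$posture), 0)
  expect_equal(richness(seq0$posture), 1)

  # s = 1 with a two-posture accessible set: strict alternation
  cfg_alt <- sdc_generator_config(s0 = 1, beta_s = 0, beta_m = 0)
  seq1 <- generate_sequence(1, cfg_alt, seed = 6)
  expect_equal(richness(seq1$posture), 2)
  expect_equal(versatility(seq1$posture), nrow(seq1) - 1)

  # valid sequences: sorted times inside the window
  s <- generate_sequence(1.2, seed = 7)
  expect_false(is.unsorted(s$t, strictly = TRUE))
  expect_true(all(s$t >= 0 & s$t < 300))
})

test_that("expected change count matches the analytic Markov rate", {
  cfg <- sdc_generator_config(event_rate = 20)
  q <- 1.0
  s_q <- plogis(qlogis(cfg$s0) + cfg$beta_s * q)
  sims <- withr::with_seed(171, {
    vapply(1:2000, function(i) {
      p <- generate_sequence(q, cfg, seed = sample.int(1e8, 1))$posture
      c(changes = scan_changes(p), events = length(p))
    }, numeric(2))
  })
  # E[changes] = (E[events] - 1) * s(q); compare within 3 SE
  expected <- cfg$event_rate * s_q
  se <- sd(sims["changes", ]) / sqrt(2000)
  expect_lt(abs(mean(sims["changes", ]) - expected), 3 * se + 0.05)
})

test_that("scores from the default generator respect the structural bounds", {
  st <- generate_study(seed = 23)
  expect_true(all(st$scores$richness >= 1 & st$scores$richness <= 9))
  expect_true(all(st$scores$versatility >= 0))
  expect_identical(st$scores$sdc, st$scores$richness * st$scores$versatility)
  # most sequences fall in the field-observed score ranges
  frac <- mean(
    st$scores$richness >= 2 & st$scores$richness <= 8 &
      st$scores$versatility >= 2 & st$scores$versatility <= 17
  )
  expect_gt(frac, 0.8)
})

test_that("breeding status follows the logistic link on standardized sdc", {
  st <- generate_study(seed = 29)
  expect_equal(nrow(st$breeding), 56)
  # gamma1 = 0 makes prevalence depend only on gamma0
  cfg0 <- sdc_generator_config(gamma1 = 0, gamma0 = 0, n_breeding_cohort = 100)
  counts <- withr::with_seed(181, {
    vapply(1:40, function(i) {
      sc <- tibble::tibble(
        subject_id = as.character(1:100), sdc = rnorm(100, 50, 20),
        year = 2L
      )
      mean(generate_breeding(sc, cfg0, seed = sample.int(1e8, 1))$breeder)
    }, numeric(1))
  })
  expect_equal(mean(counts), 0.5, tolerance = 0.03)

  # large gamma1 separates breeders by sdc rank almost perfectly
  cfgL <- sdc_generator_config(gamma1 = 50, n_breeding_cohort = 100)
  sc <- tibble::tibble(
    subject_id = as.character(1:100), sdc = 1:100, year = 2L
  )
  b <- generate_breeding(sc, cfgL, seed = 31)
  top <- sc$sdc[match(b$subject_id[b$breeder], sc$subject_id)]
  bot <- sc$sdc[match(b$subject_id[!b$breeder], sc$subject_id)]
  expect_gt(min(top), max(bot) - 10)
})

test_that("logistic regression recovers the breeding link parameters", {
  cfg <- sdc_generator_config(n_breeding_cohort = 500, n_individuals = 500)
  hits <- withr::with_seed(191, {
    vapply(1:30, function(i) {
      sc <- tibble::tibble(
        subject_id = as.character(1:500),
        sdc = rnorm(500, 50, 20), year = 2L
      )
      b <- generate_breeding(sc, cfg, seed = sample.int(1e8, 1))
      z <- (sc$sdc - mean(sc$sdc)) / (2 * sd(sc$sdc))
      fit <- glm(b$breeder ~ z, family = binomial)
      ci0 <- coef(fit)[1] + c(-2, 2) * sqrt(vcov(fit)[1, 1])
      ci1 <- coef(fit)[2] + c(-2, 2) * sqrt(vcov(fit)[2, 2])
      (cfg$gamma0 >= ci0[1] && cfg$gamma0 <= ci0[2]) +
        (cfg$gamma1 >= ci1[1] && cfg$gamma1 <= ci1[2])
    }, numeric(1))
  })
  # ~95% coverage per parameter over 30 replicates
  expect_gt(mean(hits), 2 * 0.8)
})

test_that("pair generation spans random to perfectly assorted mating", {
  ind <- generate_individuals(seed = 37)
  cfg1 <- sdc_generator_config(assortment = 1)
  p1 <- generate_pairs(ind, cfg1, seed = 41)
  expect_equal(nrow(p1), 21)
  expect_equal(anyDuplicated(c(p1$male_id, p1$female_id)), 0)

  # rank matching minimizes the mean quality difference over all matchings:
  # compare against 2000 random rematchings of the same individuals
  qm <- function(a) 0.16 * a - 0.004 * a^2
  obs <- mean(abs(qm(p1$male_age) - qm(p1$female_age)))
  rnd <- withr::with_seed(43, {
    vapply(1:2000, function(i) {
      mean(abs(qm(p1$male_age) - qm(sample(p1$female_age))))
    }, numeric(1))
  })
  expect_lte(obs, min(rnd) + 1e-12)

  expect_error(
    generate_pairs(ind[1:10, ], cfg1, seed = 1),
    "at least 21"
  )
})

test_that("whole studies regenerate bit-identically from (config, seed)", {
  a <- generate_study(seed = 47)
  b <- generate_study(seed = 47)
  expect_identical(a$individuals, b$individuals)
  expect_identical(a$events, b$events)
  expect_identical(a$scores, b$scores)
  expect_identical(a$breeding, b$breeding)
  expect_identical(a$pairs, b$pairs)
  # all cross-references resolve
  expect_true(all(a$events$subject_id %in% a$individuals$subject_id))
  expect_true(all(a$breeding$subject_id %in% a$individuals$subject_id))
  expect_true(all(
    c(a$pairs$male_id, a$pairs$female_id) %in% a$individuals$subject_id
  ))
})

test_that("replicate-mean sdc by age is concave with an interior peak", {
  means <- withr::with_seed(201, {
    reps <- purrr::map(1:6, function(i) {
      st <- generate_study(seed = sample.int(1e8, 1))
      st$scores[, c("age", "sdc")]
    })
    purrr::list_rbind(reps) |>
      dplyr::group_by(.data$age) |>
      dplyr::summarise(m = mean(.data$sdc), .groups = "drop")
  })
  quad <- lm(m ~ age + I(age^2), data = means)
  expect_lt(coef(quad)[["I(age^2)"]], 0)
  peak <- -coef(quad)[["age"]] / (2 * coef(quad)[["I(age^2)"]])
  expect_gt(peak, 10)
  expect_lt(peak, 30)
})
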