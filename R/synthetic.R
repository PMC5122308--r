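#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic cohort: sample sizes, the latent
#' quality model, the Markov display-sequence model, the breeding link
#' and the pair-formation model. Defaults emulate a single field season
#' of communal-display focal sampling: 100 focal individuals (50
#' females, 50 males) aged 4-37, observed from November to March
#' (day 0 = Nov 1), display groups of 9-130 birds, five-minute windows.
#'
#' Latent quality is `q = q0 + q_age*age + q_age2*age^2 + q_date*date +
#' Normal(0, sigma_q)`; the default coefficients put the age peak at 20
#' years (early-life improvement followed by senescence) and a positive
#' season trend. Sequences are first-order Markov chains over the
#' nine-posture repertoire: event count ~ 1 + Poisson(`event_rate`);
#' at each step the bird switches posture with probability
#' `plogis(qlogis(s0) + beta_s*q)` and draws the new posture uniformly
#' from an accessible set of size `clamp(2 + round(beta_m*q), 2, 9)`, so
#' higher-quality birds switch more often among more postures — the
#' simplest mechanism making richness and versatility rise jointly with
#' quality. Breeding status is Bernoulli with
#' `logit p = gamma0 + gamma1 * SDC_std` over a 56-bird focal-year
#' cohort, and pairs form by rank-matching on age-predicted quality with
#' Gaussian rank jitter controlled by `assortment` (0 = random mating,
#' 1 = perfect rank matching).
#'
#' @param n_individuals Cohort size (split `prop_female` female).
#' @param prop_female Proportion of females (default 0.5).
#' @param age_range,date_range,group_size_range,hour_range Inclusive
#'   sampling ranges (ages and dates integer-valued; hour decimal).
#' @param window_length Observation window, seconds.
#' @param event_rate Mean number of logged events per window minus 1.
#' @param q0,q_age,q_age2,q_date,sigma_q Latent quality model.
#' @param s0,beta_s,beta_m Sequence model: baseline switch probability
#'   and the quality slopes of switching and accessible-set size.
#' @param gamma0,gamma1 Breeding link (logit scale, SDC standardized by
#'   two SDs).
#' @param n_breeding_cohort Individuals with assessable breeding status
#'   (the focal-year subset).
#' @param n_pairs Number of both-ringed pairs.
#' @param assortment Pairing assortment strength in `[0, 1]`.
#' @param repertoire Display repertoire (default the built-in nine
#'   postures).
#' @return A list of class `sdc_generator_config`.
#' @export
sdc_generator_config <- function(n_individuals = 100,
                                 prop_female = 0.5,
                                 age_range = c(4, 37),
                                 date_range = c(0, 151),
                                 group_size_range = c(9, 130),
                                 hour_range = c(8, 17),
                                 window_length = 300,
                                 event_rate = 30,
                                 q0 = 0, q_age = 0.16, q_age2 = -0.004,
                                 q_date = 0.004, sigma_q = 0.25,
                                 s0 = 0.08, beta_s = 1.1, beta_m = 2.5,
                                 gamma0 = -1.33, gamma1 = 1.42,
                                 n_breeding_cohort = 56,
                                 n_pairs = 21,
                                 assortment = 0,
                                 repertoire = default_repertoire()) {
  cfg <- list(
    n_individuals = n_individuals, prop_female = prop_female,
    age_range = age_range, date_range = date_range,
    group_size_range = group_size_range, hour_range = hour_range,
    window_length = window_length, event_rate = event_rate,
    q0 = q0, q_age = q_age, q_age2 = q_age2, q_date = q_date,
    sigma_q = sigma_q,
    s0 = s0, beta_s = beta_s, beta_m = beta_m,
    gamma0 = gamma0, gamma1 = gamma1,
    n_breeding_cohort = n_breeding_cohort,
    n_pairs = n_pairs, assortment = assortment,
    repertoire = repertoire
  )
  if (n_individuals < 2 || prop_female < 0 || prop_female > 1) {
    abort("Invalid cohort specification.")
  }
  if (any(diff(age_range) < 0) || any(diff(date_range) < 0) ||
      any(diff(group_size_range) < 0) || any(diff(hour_range) < 0)) {
    abort("Ranges must be (low, high) with low <= high.")
  }
  if (assortment < 0 || assortment > 1) {
    abort("`assortment` must lie in [0, 1].")
  }
  if (s0 < 0 || s0 > 1) {
    abort("`s0` is a probability.")
  }
  structure(cfg, class = c("sdc_generator_config", "list"))
}

# age/date component of quality without the noise; used for pairing scores
quality_mean <- function(config, age, date = 0) {
  config$q0 + config$q_age * age + config$q_age2 * age^2 +
    config$q_date * date
}

#' Generate a synthetic focal cohort
#'
#' Draws individual metadata (id, sex, age, date, hour, group size,
#' year) and the latent quality score driving display behavior. The
#' focal-year breeding cohort (`n_breeding_cohort` individuals) is
#' labelled year 2, everyone else year 1.
#'
#' @param config An [sdc_generator_config()].
#' @param seed Integer seed (all generators are deterministic given the
#'   seed and restore the global RNG state).
#' @return A tibble with one row per individual: `subject_id`, `sex`
#'   (`"F"`/`"M"`), `sex01` (F = 0, M = 1), `age`, `date`, `hour`,
#'   `group_size`, `year`, `quality`.
#' @export
generate_individuals <- function(config = sdc_generator_config(), seed = 1) {
  n <- config$n_individuals
  n_f <- round(n * config$prop_female)
  withr::with_seed(seed, {
    sex <- c(rep("F", n_f), rep("M", n - n_f))
    id <- sprintf("%s%03d", sex, c(seq_len(n_f), seq_len(n - n_f)))
    age <- sample(config$age_range[1]:config$age_range[2], n, replace = TRUE)
    date <- sample(config$date_range[1]:config$date_range[2], n, replace = TRUE)
    hour <- round(runif(n, config$hour_range[1], config$hour_range[2]), 2)
    group_size <- sample(
      config$group_size_range[1]:config$group_size_range[2], n,
      replace = TRUE
    )
    year <- rep(1L, n)
    year[sample.int(n, min(config$n_breeding_cohort, n))] <- 2L
    quality <- quality_mean(config, age, date) + rnorm(n, 0, config$sigma_q)
    tibble::tibble(
      subject_id = id, sex = sex, sex01 = as.integer(sex == "M"),
      age = age, date = date, hour = hour,
      group_size = group_size, year = year, quality = quality
    )
  })
}

generate_sequence_impl <- function(subject_id, quality, config) {
  labels <- config$repertoire$label
  n_events <- rpois(1, config$event_rate) + 1
  t <- sort(runif(n_events, 0, config$window_length))
  s <- plogis(qlogis(config$s0) + config$beta_s * quality)
  m <- max(2, min(length(labels), 2 + round(config$beta_m * quality)))
  accessible <- sample(labels, m)
  p <- character(n_events)
  p[1] <- sample(accessible, 1)
  if (n_events > 1) {
    switch_here <- runif(n_events - 1) < s
    for (i in 2:n_events) {
      p[i] <- if (switch_here[i - 1]) {
        sample(setdiff(accessible, p[i - 1]), 1)
      } else {
        p[i - 1]
      }
    }
  }
  tibble::tibble(
    subject_id = subject_id, t = t, posture = p,
    span = config$window_length
  )
}

#' Generate one synthetic display sequence
#'
#' @inheritParams generate_individuals
#' @param subject_id Id stored in the result.
#' @param quality Latent quality of the displaying individual.
#' @return A sequence tibble (see [behavior_sequence()]).
#' @export
generate_sequence <- function(quality, config = sdc_generator_config(),
                              seed = 1, subject_id = "sim") {
  withr::with_seed(seed, generate_sequence_impl(subject_id, quality, config))
}

#' Generate display sequences for a whole cohort
#'
#' @inheritParams generate_individuals
#' @param individuals Tibble from [generate_individuals()].
#' @return A long event tibble covering all individuals.
#' @export
generate_sequences <- function(individuals,
                               config = sdc_generator_config(), seed = 1) {
  withr::with_seed(seed, {
    purrr::map2(
      individuals$subject_id, individuals$quality,
      function(id, q) generate_sequence_impl(id, q, config)
    ) |>
      purrr::list_rbind()
  })
}

#' Generate breeding status from display complexity
#'
#' Within the focal-year cohort (year 2), breeding is Bernoulli with
#' `logit p = gamma0 + gamma1 * z(SDC)`, SDC standardized by two sample
#' SDs within the cohort so that `gamma1` is on the same scale as a
#' two-SD-standardized regression coefficient.
#'
#' @inheritParams generate_individuals
#' @param scores Score table from [score_sequences()] including a `year`
#'   column (as produced when metadata is joined).
#' @return Tibble `subject_id`, `breeder` (logical) for the cohort only.
#' @export
generate_breeding <- function(scores, config = sdc_generator_config(),
                              seed = 1) {
  cohort <- if ("year" %in% names(scores)) {
    scores[scores$year == 2L, ]
  } else {
    scores
  }
  if (nrow(cohort) == 0) {
    abort("No focal-year cohort to assign breeding status in.")
  }
  z <- if (sd(cohort$sdc) > 0) {
    (cohort$sdc - mean(cohort$sdc)) / (2 * sd(cohort$sdc))
  } else {
    rep(0, nrow(cohort))
  }
  withr::with_seed(seed, {
    p <- plogis(config$gamma0 + config$gamma1 * z)
    tibble::tibble(
      subject_id = cohort$subject_id,
      breeder = rbinom(nrow(cohort), 1, p) == 1
    )
  })
}

#' Generate mated pairs with tunable assortment
#'
#' Samples `n_pairs` males and `n_pairs` females and mates them by
#' rank-matching on age-predicted quality with Gaussian rank jitter:
#' at `assortment = 1` ranks match exactly (which minimizes the mean
#' absolute difference over all matchings); at `assortment = 0` mating
#' is uniformly random; in between, jitter SD is
#' `n_pairs * (1 - assortment) / assortment` rank units.
#'
#' @inheritParams generate_sequences
#' @return Tibble `male_id`, `male_age`, `female_id`, `female_age`.
#' @export
generate_pairs <- function(individuals, config = sdc_generator_config(),
                           seed = 1) {
  males <- individuals[individuals$sex == "M", ]
  females <- individuals[individuals$sex == "F", ]
  n <- config$n_pairs
  if (nrow(males) < n || nrow(females) < n) {
    abort(paste0("Need at least ", n, " individuals of each sex."))
  }
  rho <- config$assortment
  withr::with_seed(seed, {
    males <- males[sample.int(nrow(males), n), ]
    females <- females[sample.int(nrow(females), n), ]
    score_m <- quality_mean(config, males$age)
    score_f <- quality_mean(config, females$age)
    if (rho == 0) {
      ord_m <- seq_len(n)
      ord_f <- sample.int(n)
    } else {
      jitter_sd <- n * (1 - rho) / rho
      ord_m <- order(rank(score_m, ties.method = "first") + rnorm(n, 0, jitter_sd))
      ord_f <- order(rank(score_f, ties.method = "first") + rnorm(n, 0, jitter_sd))
    }
    tibble::tibble(
      male_id = males$subject_id[ord_m],
      male_age = males$age[ord_m],
      female_id = females$subject_id[ord_f],
      female_age = females$age[ord_f]
    )
  })
}

#' Generate a complete synthetic study
#'
#' One call produces every table the analysis pipeline consumes:
#' metadata with latent quality, event sequences, SDC scores, breeding
#' status for the focal-year cohort, and mated pairs. Regeneration from
#' the same `(config, seed)` is bit-identical.
#'
#' @inheritParams generate_individuals
#' @param mode Versatility definition used for the bundled scores.
#' @return A list of class `sdc_study`: `individuals`, `events`,
#'   `scores`, `breeding`, `pairs`, `config`, `seed`.
#' @examples
#' study <- generate_study(seed = 42)
#' dplyr::count(study$scores, .data$sex)
#' @export
generate_study <- function(config = sdc_generator_config(), seed = 1,
                           mode = c("change-count", "distinct-ordered")) {
  mode <- match.arg(mode)
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, 4))
  individuals <- generate_individuals(config, seed = seeds[1])
  events <- generate_sequences(individuals, config, seed = seeds[2])
  scores <- score_sequences(
    events, individuals,
    repertoire = config$repertoire, mode = mode
  )
  breeding <- generate_breeding(scores, config, seed = seeds[3])
  pairs <- generate_pairs(individuals, config, seed = seeds[4])
  structure(
    list(
      individuals = individuals, events = events, scores = scores,
      breeding = breeding, pairs = pairs, config = config, seed = seed
    ),
    class = "sdc_study"
  )
}

#' @export
print.sdc_study <- function(x, ...) {
  cat(
    "<synthetic display study: ", nrow(x$individuals), " individuals, ",
    nrow(x$events), " events, ", nrow(x$breeding),
    " with breeding status, ", nrow(x$pairs), " pairs, seed ", x$seed,
    ">\n",
    sep = ""
  )
  invisible(x)
}
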