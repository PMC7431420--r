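test_that("population generation honours sex ratio, pairing and the seed", {
  cfg <- population_config(n_individuals = 10, sex_ratio_male = 0.5,
                           pair_fraction = 1, seed = 1)
  r <- generate_population(cfg)
  expect_equal(sum(r$sex == "M"), 5L)
  expect_equal(sum(r$sex == "F"), 5L)
  # perfect matching: 5 male-female pairs, nobody in two pairs
  expect_true(all(!is.na(r$partner_id)))
  expect_identical(r$partner_id[match(r$partner_id, r$individual_id)],
                   r$individual_id)
  expect_true(all(r$sex[match(r$partner_id, r$individual_id)] !=
                    r$sex))
  # identical config + seed: byte-identical roster
  expect_identical(generate_population(cfg), r)
  # invalid configs rejected
  expect_error(population_config(n_individuals = 1), "at least 2")
  expect_error(population_config(sex_ratio_male = 1.4), "\\[0, 1\\]")
  expect_error(survey_design(period_length_min = 5), "10 minutes")
})

test_that("sightings respect detection, ringing and period uniqueness", {
  cfg <- population_config(n_individuals = 30, n_years = 1, seed = 2)
  r <- generate_population(cfg)

  empty <- generate_sightings(r, survey_design(detection_prob = 0), cfg)
  expect_equal(nrow(empty), 0L)

  s <- generate_sightings(r, survey_design(detection_prob = 0.3), cfg)
  # only ringed birds in surveyed habitats appear
  expect_true(all(s$individual_id %in%
                    r$individual_id[r$ringed &
                                      r$habitat %in% c("saltmarsh",
                                                       "grassland")]))
  # at most one row per bird per period
  expect_false(anyDuplicated(s[, c("individual_id", "period_id")]) > 0)
  expect_true(all(is.finite(s$x) & is.finite(s$y)))
})

test_that("pair-bond attraction co-locates partners at the stated rate", {
  cfg <- population_config(n_individuals = 30, n_years = 2,
                           pair_fraction = 1, pair_bond_attraction = 1,
                           seed = 3)
  r <- generate_population(cfg)
  des <- survey_design(detection_prob = 0.6, surveys_per_year = 10,
                       periods_per_survey = 6)

  shared_dist <- function(s, roster) {
    pairs <- roster[roster$sex == "M" & !is.na(roster$partner_id), ]
    out <- numeric()
    for (p in unique(s$period_id)) {
      sp <- s[s$period_id == p, ]
      i <- match(pairs$individual_id, sp$individual_id)
      j <- match(pairs$partner_id, sp$individual_id)
      ok <- !is.na(i) & !is.na(j)
      out <- c(out, sqrt((sp$x[i[ok]] - sp$x[j[ok]])^2 +
                           (sp$y[i[ok]] - sp$y[j[ok]])^2))
    }
    out
  }

  # q = 1: every co-detected pair within the chain distance
  s1 <- generate_sightings(r, des, cfg)
  d1 <- shared_dist(s1, r)
  expect_gt(length(d1), 50)
  expect_true(all(d1 <= 20))

  # q = 0.8: co-location fraction within the binomial 99% interval
  s2 <- generate_sightings(r, des, cfg, pair_attraction = 0.8)
  d2 <- shared_dist(s2, r)
  n <- length(d2)
  expect_gt(n, 200)
  frac <- mean(d2 <= 20)
  half <- qnorm(0.995) * sqrt(0.8 * 0.2 / n)
  expect_gt(frac, 0.8 - half - 0.02)  # small allowance for chance
  expect_lt(frac, 0.8 + half + 0.02)  # co-location at 0 attraction
})

test_that("nest generation honours dates, habitats and success probability", {
  cfg <- population_config(n_individuals = 60, n_years = 3,
                           habitat_fidelity = 1, seed = 4)
  r <- generate_population(cfg)

  # all successful when success probability is 1
  n1 <- generate_nests(r, cfg, ground_truth(nest_success_prob = 1))
  expect_true(all(n1$success))
  expect_true(all(n1$laid_date < n1$incubation_end))

  # coordinates inside the stated habitat rectangle
  hb <- cfg$habitats[match(n1$habitat, cfg$habitats$habitat), ]
  expect_true(all(n1$x >= hb$xmin & n1$x <= hb$xmax &
                    n1$y >= hb$ymin & n1$y <= hb$ymax))

  # each pair has at most one nest per year
  expect_false(anyDuplicated(n1[, c("male_id", "year")]) > 0)

  # full habitat fidelity plus certain staying: consecutive-year nests in
  # the same habitat throughout
  tr <- ground_truth(dispersal_stay_prob_by_success =
                       c(fail = 1, success = 1))
  n2 <- generate_nests(r, cfg, tr)
  d <- dispersal_records(n2)
  expect_true(all(d$stayed_same_habitat))
})

test_that("dispersal stay probabilities are recovered by a logistic fit", {
  cfg <- population_config(n_individuals = 500, n_years = 4, seed = 5)
  r <- generate_population(cfg)
  tr <- ground_truth(nest_success_prob = 0.5,
                     dispersal_stay_prob_by_success =
                       c(fail = 0.6, success = 0.9))
  nests <- generate_nests(r, cfg, tr)
  d <- dispersal_records(nests)
  expect_gt(nrow(d), 300)
  fit <- glm(stayed_same_habitat ~ prev_success, family = binomial(),
             data = d)
  true_lor <- log((0.9 / 0.1) / (0.6 / 0.4))
  expect_lt(abs(unname(coef(fit)["prev_successTRUE"]) - true_lor), 0.3)
})

test_that("simulation is reproducible table-for-table and emulates sparsity", {
  cfg <- population_config(seed = 6)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$sightings, s2$sightings)
  expect_identical(s1$nests, s2$nests)
  expect_identical(s1$roster, s2$roster)

  # networks built from the default configuration are sparse
  pd <- prepare_analysis_data(s1)
  dens <- sapply(pd$networks, network_density)
  expect_true(all(dens < 0.05))

  # true_sri_effect = 0 disables the pair-bond co-location process
  s0 <- simulate_dataset(population_config(n_individuals = 20, n_years = 1,
                                           seed = 7),
                         survey_design(detection_prob = 0.4),
                         ground_truth(true_sri_effect = 0))
  expect_s3_class(s0, "plover_simulation")
})
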