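#' Default habitat map: three rectangular habitat blocks
#'
#' Axis-aligned, non-overlapping rectangles standing in for the three
#' habitat types of the study system (saltmarsh, grassland, semi-desert).
#' Non-breeding resighting surveys cover only saltmarsh and grassland;
#' breeding occurs in all three. Real polygon maps can be supplied as
#' GeoJSON via [read_habitats_geojson()].
#'
#' @return data.frame with `habitat`, `xmin`, `xmax`, `ymin`, `ymax`,
#'   `surveyed`.
#' @export
default_habitats <- function() {
  data.frame(
    habitat = c("saltmarsh", "grassland", "semi-desert"),
    xmin = c(0, 1200, 2400), xmax = c(1000, 2200, 3400),
    ymin = c(0, 0, 0), ymax = c(1000, 1000, 1000),
    surveyed = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Synthetic population configuration
#'
#' Parameters of the simulated colour-ringed population. Defaults emulate
#' the study system: about 80% of adults ringed, a near-even adult sex
#' ratio, most adults in socially monogamous pairs, strong habitat
#' fidelity, and home ranges small relative to habitat extent so that
#' chance co-occurrence within the 20 m chain distance is rare.
#'
#' @param n_individuals number of adults (>= 2).
#' @param sex_ratio_male proportion of males.
#' @param n_years number of study years.
#' @param habitats habitat rectangles, see [default_habitats()].
#' @param ringed_fraction proportion of adults colour-ringed.
#' @param pair_fraction proportion of the limiting sex that is pair-bonded.
#' @param pair_bond_attraction probability q that a bonded pair co-locates
#'   within the chain distance when both are detected in a sampling period.
#' @param habitat_fidelity probability a pair's first nest is in the
#'   female's home habitat.
#' @param home_range_sd SD (m) of isotropic Gaussian scatter of sightings
#'   around an individual's home-range centre.
#' @param patch_prob probability a detected bird is at one of its habitual
#'   communal patches (roost/foraging site) rather than scattered around
#'   its home-range centre; patches generate the baseline chance
#'   associations of the population.
#' @param n_patches number of communal patches per habitat per year.
#' @param patch_jitter SD (m) of scatter around a patch centre.
#' @param first_year first calendar year of the simulation.
#' @param seed integer seed driving all per-year/per-stage substreams.
#' @return object of class `population_config`.
#' @export
population_config <- function(n_individuals = 120, sex_ratio_male = 0.5,
                              n_years = 4, habitats = default_habitats(),
                              ringed_fraction = 0.8, pair_fraction = 0.9,
                              pair_bond_attraction = 0.8,
                              habitat_fidelity = 0.9, home_range_sd = 30,
                              patch_prob = 0.45, n_patches = 8,
                              patch_jitter = 6,
                              first_year = 2015, seed = 42) {
  probs <- c(sex_ratio_male, ringed_fraction, pair_fraction,
             pair_bond_attraction, habitat_fidelity, patch_prob)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all proportions/probabilities must lie in [0, 1]")
  }
  if (n_individuals < 2) stop("n_individuals must be at least 2")
  if (n_years < 1) stop("n_years must be at least 1")
  stopifnot(all(habitats$xmin < habitats$xmax),
            all(habitats$ymin < habitats$ymax))
  if (.rectangles_overlap(habitats)) stop("habitat rectangles must not overlap")
  structure(list(n_individuals = as.integer(n_individuals),
                 sex_ratio_male = sex_ratio_male,
                 n_years = as.integer(n_years), habitats = habitats,
                 ringed_fraction = ringed_fraction,
                 pair_fraction = pair_fraction,
                 pair_bond_attraction = pair_bond_attraction,
                 habitat_fidelity = habitat_fidelity,
                 home_range_sd = home_range_sd,
                 patch_prob = patch_prob,
                 n_patches = as.integer(n_patches),
                 patch_jitter = patch_jitter,
                 first_year = as.integer(first_year),
                 seed = as.integer(seed)),
            class = "population_config")
}

.rectangles_overlap <- function(h) {
  n <- nrow(h)
  if (n < 2L) return(FALSE)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (h$xmin[i] < h$xmax[j] && h$xmin[j] < h$xmax[i] &&
        h$ymin[i] < h$ymax[j] && h$ymin[j] < h$ymax[i]) return(TRUE)
  }
  FALSE
}

#' Non-breeding survey design
#'
#' Survey effort for the resighting programme. Sampling periods are fixed
#' at 10 minutes — the time window within which detected individuals are
#' eligible for association. Surveys run from mid January to late July;
#' the breeding season starts 1 August, and surveys within
#' `exclusion_days` of it are excluded from pre-breeding networks.
#'
#' @param surveys_per_year survey days per year.
#' @param periods_per_survey 10-min sampling periods per survey day.
#' @param period_length_min period length, fixed at 10 minutes.
#' @param detection_prob per-period detection probability of an eligible
#'   (ringed, surveyed-habitat) bird.
#' @param season_start_month,season_start_day breeding-season start.
#' @param exclusion_days pre-season exclusion window (default 14).
#' @return object of class `survey_design`.
#' @export
survey_design <- function(surveys_per_year = 20, periods_per_survey = 8,
                          period_length_min = 10, detection_prob = 0.08,
                          season_start_month = 8, season_start_day = 1,
                          exclusion_days = 14) {
  if (period_length_min != 10) {
    stop("sampling periods are fixed at 10 minutes")
  }
  if (exclusion_days < 0) stop("exclusion_days must be non-negative")
  if (detection_prob < 0 || detection_prob > 1) {
    stop("detection_prob must lie in [0, 1]")
  }
  structure(list(surveys_per_year = as.integer(surveys_per_year),
                 periods_per_survey = as.integer(periods_per_survey),
                 period_length_min = 10L,
                 detection_prob = detection_prob,
                 season_start_month = as.integer(season_start_month),
                 season_start_day = as.integer(season_start_day),
                 exclusion_days = as.integer(exclusion_days)),
            class = "survey_design")
}

#' Ground truth for parameter-recovery experiments
#'
#' Known effect sizes baked into the generated data. Stay probabilities by
#' previous nest fate default to the regime reported for the study system
#' (about 0.89 after success, 0.67 after failure). `true_sri_effect`
#' controls the pair-bond co-location process: `NULL` uses the population
#' config's `pair_bond_attraction` directly; a number e maps to
#' co-location probability q = 1 - exp(-e), so e = 0 switches the process
#' off entirely and the pairing-versus-SRI null is exactly true.
#'
#' @param true_sri_effect pair-bond effect strength, or NULL (see above).
#' @param nest_success_prob probability a nest hatches at least one egg.
#' @param dispersal_stay_prob_by_success named probabilities
#'   `c(fail = , success = )` of staying in the same habitat.
#' @param breed_prob probability a bonded pair nests in a given year.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(true_sri_effect = NULL, nest_success_prob = 0.6,
                         dispersal_stay_prob_by_success =
                           c(fail = 0.667, success = 0.891),
                         breed_prob = 0.85) {
  probs <- c(nest_success_prob, dispersal_stay_prob_by_success, breed_prob)
  if (any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  stopifnot(all(c("fail", "success") %in%
                  names(dispersal_stay_prob_by_success)))
  structure(list(true_sri_effect = true_sri_effect,
                 nest_success_prob = nest_success_prob,
                 dispersal_stay_prob_by_success =
                   dispersal_stay_prob_by_success,
                 breed_prob = breed_prob,
                 true_pairs = NULL),
            class = "ground_truth")
}

# deterministic substream seeds derived from the global seed
.substream <- function(seed, key) {
  as.integer((as.double(seed) * 48271 + key * 1299709) %% 2147483647)
}

.pick_point <- function(h, n) {
  data.frame(x = runif(n, h$xmin, h$xmax), y = runif(n, h$ymin, h$ymax))
}

.habitat_at <- function(habitats, x, y) {
  out <- rep(NA_character_, length(x))
  for (i in seq_len(nrow(habitats))) {
    inside <- x >= habitats$xmin[i] & x <= habitats$xmax[i] &
      y >= habitats$ymin[i] & y <= habitats$ymax[i]
    out[inside & is.na(out)] <- habitats$habitat[i]
  }
  out
}

#' Generate a synthetic population roster
#'
#' Assigns sexes (matching the sex ratio up to rounding), ring status,
#' home habitats, home-range centres, and pair bonds. Partners are drawn
#' uniformly at random between the sexes, independently of habitat and
#' space, so that pairing carries no built-in association with social or
#' spatial structure beyond what the pair-bond co-location process adds.
#'
#' @param config a [population_config()].
#' @return data.frame roster: `individual_id`, `sex`, `ringed`, `habitat`,
#'   `cx`, `cy`, `partner_id`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  set.seed(.substream(config$seed, 1L))
  n <- config$n_individuals
  n_m <- round(n * config$sex_ratio_male)
  sex <- sample(c(rep("M", n_m), rep("F", n - n_m)))
  ringed <- sample(seq_len(n) <= round(n * config$ringed_fraction))
  habitat <- sample(config$habitats$habitat, n, replace = TRUE)
  centres <- do.call(rbind, lapply(seq_len(n), function(i) {
    .pick_point(config$habitats[config$habitats$habitat == habitat[i], ], 1L)
  }))
  roster <- data.frame(
    individual_id = sprintf("B%03d", seq_len(n)),
    sex = sex, ringed = ringed, habitat = habitat,
    cx = centres$x, cy = centres$y,
    partner_id = NA_character_, stringsAsFactors = FALSE
  )
  males <- sample(roster$individual_id[roster$sex == "M"])
  females <- sample(roster$individual_id[roster$sex == "F"])
  n_pairs <- floor(min(length(males), length(females)) *
                     config$pair_fraction)
  if (n_pairs > 0L) {
    m <- males[seq_len(n_pairs)]; f <- females[seq_len(n_pairs)]
    roster$partner_id[match(m, roster$individual_id)] <- f
    roster$partner_id[match(f, roster$individual_id)] <- m
  }
  roster
}

#' Generate synthetic non-breeding sightings
#'
#' For each year, survey day and 10-min sampling period, each ringed bird
#' whose home habitat is surveyed is detected independently with the
#' design's detection probability. A detected bird is either at one of
#' its two habitual communal patches (probability `patch_prob`; patches
#' are shared sites that create chance associations and multi-bird
#' groups) or scattered isotropically around its home-range centre. When
#' both members of a bonded pair are detected in the same period, with
#' probability q (the pair-bond attraction) the female is placed within
#' the chain distance of the male; q = 0 makes pair bonds invisible in
#' the sighting stream.
#'
#' @param roster from [generate_population()].
#' @param design a [survey_design()].
#' @param config the [population_config()] used for the roster.
#' @param pair_attraction override of the co-location probability q
#'   (default `config$pair_bond_attraction`).
#' @return sightings data.frame (`individual_id`, `sex`, `date`,
#'   `period_id`, `x`, `y`, `habitat`, `year`).
#' @export
generate_sightings <- function(roster, design, config,
                               pair_attraction = NULL) {
  stopifnot(nrow(roster) > 0L)
  q <- pair_attraction %||% config$pair_bond_attraction
  surveyed <- config$habitats$habitat[config$habitats$surveyed]
  eligible <- roster[roster$ringed & roster$habitat %in% surveyed, ]
  rows <- list()
  for (yi in seq_len(config$n_years)) {
    year <- config$first_year + yi - 1L
    set.seed(.substream(config$seed, 100L + yi))
    # communal patches for this year, and each bird's two habitual patches
    patches <- do.call(rbind, lapply(surveyed, function(hb) {
      h <- config$habitats[config$habitats$habitat == hb, ]
      cbind(.pick_point(h, config$n_patches))
    }))
    if (nrow(eligible) > 0L && nrow(patches) > 0L) {
      pd2 <- outer(eligible$cx, patches$x, "-")^2 +
        outer(eligible$cy, patches$y, "-")^2
      my_patches <- t(apply(pd2, 1L, function(d)
        order(d)[seq_len(min(2L, length(d)))]))
    }
    dates <- as.Date(sprintf("%d-01-15", year)) +
      round(seq(0, 190, length.out = design$surveys_per_year))
    for (s in seq_len(design$surveys_per_year)) {
      for (p in seq_len(design$periods_per_survey)) {
        det_i <- which(runif(nrow(eligible)) < design$detection_prob)
        if (length(det_i) == 0L) next
        det <- eligible[det_i, , drop = FALSE]
        n <- nrow(det)
        at_patch <- runif(n) < config$patch_prob
        pk <- my_patches[det_i, , drop = FALSE]
        patch_pick <- pk[cbind(seq_len(n), sample(c(1L, 2L), n,
                                                  replace = TRUE))]
        x <- ifelse(at_patch,
                    rnorm(n, patches$x[patch_pick], config$patch_jitter),
                    rnorm(n, det$cx, config$home_range_sd))
        y <- ifelse(at_patch,
                    rnorm(n, patches$y[patch_pick], config$patch_jitter),
                    rnorm(n, det$cy, config$home_range_sd))
        # pair-bond co-location: pull the female to the male's position
        if (q > 0 && n > 1L) {
          is_m <- det$sex == "M" & !is.na(det$partner_id) &
            det$partner_id %in% det$individual_id
          for (i in which(is_m)) {
            j <- match(det$partner_id[i], det$individual_id)
            if (runif(1) < q) {
              r <- 10 * sqrt(runif(1)); a <- runif(1, 0, 2 * pi)
              x[j] <- x[i] + r * cos(a)
              y[j] <- y[i] + r * sin(a)
            }
          }
        }
        hab <- .habitat_at(config$habitats, x, y)
        hab[is.na(hab)] <- det$habitat[is.na(hab)]
        rows[[length(rows) + 1L]] <- data.frame(
          individual_id = det$individual_id, sex = det$sex,
          date = dates[s],
          period_id = sprintf("%d-S%02d-P%02d", year, s, p),
          x = x, y = y, habitat = hab, year = year,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(individual_id = character(), sex = character(),
                      date = as.Date(character()), period_id = character(),
                      x = numeric(), y = numeric(), habitat = character(),
                      year = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate synthetic nesting records across years
#'
#' Bonded pairs nest in a given year with probability `breed_prob`. A
#' pair's first nest is placed in the female's home habitat with
#' probability `habitat_fidelity` (otherwise a random other habitat);
#' subsequent-year nests stay in the previous habitat with the
#' ground-truth stay probability given the previous attempt's fate,
#' otherwise move to a random different habitat. Nest coordinates are
#' uniform within the chosen habitat rectangle; clutches are laid around
#' mid September (breeding Aug-Dec) and incubated for 26 days; success is
#' Bernoulli with the ground-truth hatching probability.
#'
#' @param roster from [generate_population()].
#' @param config the [population_config()].
#' @param truth a [ground_truth()].
#' @return nests data.frame (`nest_id`, `male_id`, `female_id`, `x`, `y`,
#'   `habitat`, `laid_date`, `incubation_end`, `success`, `year`).
#' @export
generate_nests <- function(roster, config, truth = ground_truth()) {
  pairs <- roster[roster$sex == "M" & !is.na(roster$partner_id), ]
  if (nrow(pairs) == 0L) stop("roster contains no pair bonds")
  set.seed(.substream(config$seed, 200L))
  habs <- config$habitats$habitat
  stay <- truth$dispersal_stay_prob_by_success
  # initial habitat choice: female's home habitat with prob habitat_fidelity
  f_hab <- roster$habitat[match(pairs$partner_id, roster$individual_id)]
  cur_hab <- ifelse(runif(nrow(pairs)) < config$habitat_fidelity, f_hab,
                    vapply(f_hab, function(h)
                      sample(setdiff(habs, h), 1L), character(1)))
  prev_success <- rep(NA, nrow(pairs))
  bred_prev <- rep(FALSE, nrow(pairs))
  out <- list()
  nid <- 0L
  for (yi in seq_len(config$n_years)) {
    year <- config$first_year + yi - 1L
    set.seed(.substream(config$seed, 300L + yi))
    breeds <- runif(nrow(pairs)) < truth$breed_prob
    for (i in which(breeds)) {
      if (bred_prev[i]) {
        p_stay <- if (isTRUE(prev_success[i])) stay[["success"]]
                  else stay[["fail"]]
        if (runif(1) >= p_stay) {
          cur_hab[i] <- sample(setdiff(habs, cur_hab[i]), 1L)
        }
      }
      h <- config$habitats[config$habitats$habitat == cur_hab[i], ]
      pt <- .pick_point(h, 1L)
      laid <- as.Date(sprintf("%d-09-15", year)) +
        max(-45, min(75, round(rnorm(1, 0, 20))))
      nid <- nid + 1L
      out[[nid]] <- data.frame(
        nest_id = sprintf("N%04d", nid),
        male_id = pairs$individual_id[i],
        female_id = pairs$partner_id[i],
        x = pt$x, y = pt$y, habitat = cur_hab[i],
        laid_date = laid, incubation_end = laid + 26,
        success = runif(1) < truth$nest_success_prob,
        year = year, stringsAsFactors = FALSE
      )
      prev_success[i] <- out[[nid]]$success
    }
    bred_prev <- breeds
  }
  nests <- do.call(rbind, out)
  rownames(nests) <- NULL
  nests
}

#' Simulate a complete multi-year dataset
#'
#' Runs [generate_population()], [generate_sightings()] and
#' [generate_nests()] under one global seed and returns the bundle the
#' analysis pipeline consumes, including season-start dates and the
#' realised ground truth (with `true_pairs` filled in).
#'
#' @param config a [population_config()].
#' @param design a [survey_design()].
#' @param truth a [ground_truth()]; its `true_sri_effect`, when non-NULL,
#'   overrides the config's pair-bond attraction via q = 1 - exp(-effect).
#' @return object of class `plover_simulation`: list with `roster`,
#'   `sightings`, `nests`, `season_start`, `habitats`, `truth`, `config`,
#'   `design`.
#' @export
simulate_dataset <- function(config = population_config(),
                             design = survey_design(),
                             truth = ground_truth()) {
  q <- if (!is.null(truth$true_sri_effect)) {
    1 - exp(-max(0, truth$true_sri_effect))
  } else config$pair_bond_attraction
  roster <- generate_population(config)
  sightings <- generate_sightings(roster, design, config,
                                  pair_attraction = q)
  nests <- generate_nests(roster, config, truth)
  years <- config$first_year + seq_len(config$n_years) - 1L
  season_start <- data.frame(
    year = years,
    season_start = as.Date(sprintf("%d-%02d-%02d", years,
                                   design$season_start_month,
                                   design$season_start_day))
  )
  truth$true_pairs <- data.frame(
    male_id = roster$individual_id[roster$sex == "M" &
                                     !is.na(roster$partner_id)],
    female_id = roster$partner_id[roster$sex == "M" &
                                    !is.na(roster$partner_id)],
    stringsAsFactors = FALSE
  )
  structure(list(roster = roster, sightings = sightings, nests = nests,
                 season_start = season_start, habitats = config$habitats,
                 truth = truth, config = config, design = design),
            class = "plover_simulation")
}

#' @export
print.plover_simulation <- function(x, ...) {
  cat(sprintf(
    "plover_simulation: %d birds, %d years, %d sightings, %d nests\n",
    nrow(x$roster), x$config$n_years, nrow(x$sightings), nrow(x$nests)))
  invisible(x)
}
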