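#' Prepare the shared analysis data bundle
#'
#' Deduplicates sightings, restricts them to the pre-breeding window,
#' groups every sampling period with the chain rule, builds per-year
#' networks, and derives the breeding-pairs table from the nests. All
#' analysis builders and randomisation schemes operate on this bundle.
#'
#' @param x a `plover_simulation`, or a list with `sightings`, `nests`,
#'   `season_start` (data.frame year/season_start).
#' @param exclusion_days pre-season exclusion window (14; sensitivity 30).
#' @param drop_may also drop May sightings (sensitivity variant).
#' @param chain_distance chain-rule threshold in metres.
#' @param radius neighbourhood radius in metres.
#' @return object of class `plover_data`.
#' @export
prepare_analysis_data <- function(x, exclusion_days = 14, drop_may = FALSE,
                                  chain_distance = 20, radius = 100) {
  sightings <- deduplicate_sightings(x$sightings)
  pre <- filter_prebreeding(sightings, x$season_start,
                            exclusion_days = exclusion_days,
                            drop_may = drop_may)
  groups_by_year <- lapply(split(pre, pre$year), assign_groups_all,
                           chain_distance = chain_distance)
  nests <- x$nests
  pairs <- unique(nests[, c("male_id", "female_id", "year", "habitat")])
  structure(list(
    sightings = sightings, prebreeding = pre,
    groups_by_year = groups_by_year,
    networks = .networks_from_groups(groups_by_year),
    nests = nests, pairs = pairs, radius = radius,
    exclusion_days = exclusion_days, drop_may = drop_may,
    chain_distance = chain_distance
  ), class = "plover_data")
}

.networks_from_groups <- function(groups_by_year) {
  out <- lapply(names(groups_by_year), function(y) {
    network_from_groups(groups_by_year[[y]], year = as.integer(y))
  })
  names(out) <- names(groups_by_year)
  out
}

.networks <- function(pd) {
  pd$networks %||% .networks_from_groups(pd$groups_by_year)
}

# ---- analysis dataset builders ------------------------------------------

#' Per-individual sociality dataset (sex differences in network metrics)
#' @param pd a `plover_data` bundle.
#' @return data.frame of node metrics across years.
#' @export
build_sociality_data <- function(pd) {
  nets <- .networks(pd)
  out <- do.call(rbind, lapply(nets, function(nw) {
    cbind(node_metrics(nw), year = nw$year)
  }))
  out$year <- factor(out$year)
  rownames(out) <- NULL
  out
}

#' Male-by-female dyad dataset for the pairing analysis
#'
#' For each year with both network and breeding data, every combination of
#' males and females that have pre-breeding social information and bred
#' that year, with the dyad's SRI and whether they were an actual breeding
#' pair.
#'
#' @param pd a `plover_data` bundle.
#' @return data.frame `year`, `male_id`, `female_id`, `sri`, `paired`.
#' @export
build_pairing_data <- function(pd) {
  nets <- .networks(pd)
  out <- list()
  for (y in names(nets)) {
    nw <- nets[[y]]
    py <- pd$pairs[pd$pairs$year == as.integer(y), ]
    if (nrow(py) == 0L) next
    males <- intersect(unique(py$male_id), nw$nodes$individual_id)
    females <- intersect(unique(py$female_id), nw$nodes$individual_id)
    if (length(males) == 0L || length(females) == 0L) next
    grid <- expand.grid(male_id = males, female_id = females,
                        stringsAsFactors = FALSE)
    grid$sri <- nw$sri[cbind(grid$male_id, grid$female_id)]
    grid$paired <- paste(grid$male_id, grid$female_id) %in%
      paste(py$male_id, py$female_id)
    grid$year <- factor(y)
    out[[y]] <- grid
  }
  if (length(out) == 0L) {
    stop("no year has both pre-breeding network and breeding data")
  }
  res <- do.call(rbind, out)
  res$year <- factor(res$year)
  rownames(res) <- NULL
  res
}

#' Per-nest dataset: success, pair SRI and spatial/temporal context
#' @param pd a `plover_data` bundle.
#' @param require_sri keep only nests whose pair has social information.
#' @return data.frame from [focal_context()] plus `sri`.
#' @export
build_nest_success_data <- function(pd, require_sri = FALSE) {
  ctx <- focal_context(pd$nests, radius = pd$radius)
  nets <- .networks(pd)
  ctx$sri <- NA_real_
  for (y in names(nets)) {
    nw <- nets[[y]]
    i <- which(ctx$year == as.integer(y) &
                 ctx$male_id %in% nw$nodes$individual_id &
                 ctx$female_id %in% nw$nodes$individual_id)
    if (length(i) > 0L) {
      ctx$sri[i] <- nw$sri[cbind(ctx$male_id[i], ctx$female_id[i])]
    }
  }
  if (require_sri) ctx <- ctx[!is.na(ctx$sri), , drop = FALSE]
  ctx$year <- factor(ctx$year)
  rownames(ctx) <- NULL
  ctx
}

#' Per-individual breeding-synchrony dataset
#'
#' One row per nest member with social information: the nest's count of
#' temporally overlapping nests and mean distance to them, alongside the
#' individual's pre-breeding degree and strength.
#'
#' @param pd a `plover_data` bundle.
#' @return data.frame.
#' @export
build_synchrony_data <- function(pd) {
  ctx <- focal_context(pd$nests, radius = pd$radius)
  nets <- .networks(pd)
  long <- rbind(
    data.frame(individual_id = ctx$male_id, ctx, stringsAsFactors = FALSE),
    data.frame(individual_id = ctx$female_id, ctx, stringsAsFactors = FALSE)
  )
  long$degree <- NA_integer_; long$strength <- NA_real_
  for (y in names(nets)) {
    nm <- node_metrics(nets[[y]])
    i <- which(long$year == as.integer(y) &
                 long$individual_id %in% nm$individual_id)
    if (length(i) > 0L) {
      j <- match(long$individual_id[i], nm$individual_id)
      long$degree[i] <- nm$degree[j]
      long$strength[i] <- nm$strength[j]
    }
  }
  long <- long[!is.na(long$degree), , drop = FALSE]
  long$year <- factor(long$year)
  rownames(long) <- NULL
  long
}

#' Dyadic social-association versus breeding-structure dataset
#'
#' All same-year dyads of nesting individuals with social information,
#' excluding actual breeding pairs: the dyad's SRI against whether their
#' (first) nests overlapped in incubation and the distance between them.
#'
#' @param pd a `plover_data` bundle.
#' @return data.frame `year`, `id_a`, `id_b`, `nest_a`, `nest_b`, `sri`,
#'   `overlaps`, `distance_m`, `habitat` (of the focal nest).
#' @export
build_dyad_breeding_data <- function(pd) {
  nets <- .networks(pd)
  nests <- pd$nests[order(pd$nests$year, as.Date(pd$nests$laid_date)), ]
  out <- list()
  for (y in names(nets)) {
    nw <- nets[[y]]
    ny <- nests[nests$year == as.integer(y), ]
    if (nrow(ny) == 0L) next
    # first nest per breeding individual that year
    long <- rbind(data.frame(id = ny$male_id, ny, stringsAsFactors = FALSE),
                  data.frame(id = ny$female_id, ny, stringsAsFactors = FALSE))
    long <- long[!duplicated(long$id), ]
    long <- long[long$id %in% nw$nodes$individual_id, ]
    if (nrow(long) < 2L) next
    idx <- t(utils::combn(nrow(long), 2L))
    a <- idx[, 1L]; b <- idx[, 2L]
    d <- data.frame(
      year = factor(y), id_a = long$id[a], id_b = long$id[b],
      nest_a = long$nest_id[a], nest_b = long$nest_id[b],
      sri = nw$sri[cbind(long$id[a], long$id[b])],
      overlaps = incubation_overlap(long$laid_date[a],
                                    long$incubation_end[a],
                                    long$laid_date[b],
                                    long$incubation_end[b]),
      distance_m = nest_distance(long$x[a], long$y[a],
                                 long$x[b], long$y[b]),
      habitat = long$habitat[a],
      stringsAsFactors = FALSE
    )
    # drop actual breeding pairs and same-nest dyads
    py <- pd$pairs[pd$pairs$year == as.integer(y), ]
    pk <- c(paste(py$male_id, py$female_id), paste(py$female_id, py$male_id))
    d <- d[!(paste(d$id_a, d$id_b) %in% pk) & d$nest_a != d$nest_b, ]
    out[[y]] <- d
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no dyadic breeding data available")
  res$year <- factor(res$year)
  rownames(res) <- NULL
  res
}

#' Dispersal dataset (consecutive-year transitions)
#' @param pd a `plover_data` bundle.
#' @param first_only keep only each individual's first transition.
#' @param require_neighbours keep only transitions whose previous nest had
#'   concurrent neighbours within the radius.
#' @return data.frame from [dispersal_records()].
#' @export
build_dispersal_data <- function(pd, first_only = FALSE,
                                 require_neighbours = FALSE) {
  d <- dispersal_records(pd$nests, radius = pd$radius,
                         first_only = first_only)
  if (require_neighbours) {
    d <- d[!is.na(d$prev_prop_neighbours_successful), , drop = FALSE]
  }
  d$year_from <- factor(d$year_from)
  d$distance_m1 <- d$distance_m + 1  # log-link offset for zero distances
  rownames(d) <- NULL
  d
}

# ---- the analysis registry ----------------------------------------------

#' The registered analysis suite
#'
#' Returns the full set of analyses linking pre-breeding sociality,
#' breeding structure and dispersal, each entry pairing a model
#' specification with its dataset builder, its randomisation null scheme
#' (`datastream`, `mate`, `mate_habitat`, `nest`, or `none` for plain
#' likelihood-ratio inference) and, where applicable, the reduced model of
#' the focal likelihood-ratio test. Reference levels of year and habitat
#' factors are alphabetical/numeric-order defaults.
#'
#' @return named list of analysis entries.
#' @export
analysis_registry <- function() {
  e <- function(id, description, builder, spec, null_scheme,
                builder_args = list()) {
    list(id = id, description = description, builder = builder,
         builder_args = builder_args, spec = spec,
         null_scheme = null_scheme)
  }
  list(
    A1_degree = e("A1_degree",
      "sex difference in node degree (datastream null)",
      build_sociality_data,
      model_spec("A1_degree", degree ~ sex + year + (1 | individual_id),
                 family = "poisson", focal_term = "sex"),
      "datastream"),
    A1_strength = e("A1_strength",
      "sex difference in node strength (datastream null)",
      build_sociality_data,
      model_spec("A1_strength", strength ~ sex + year + (1 | individual_id),
                 family = "gaussian", focal_term = "sex"),
      "datastream"),
    A1_prop_male = e("A1_prop_male",
      "sex difference in proportion of male associates (datastream null)",
      function(pd) {
        d <- build_sociality_data(pd)
        d[d$degree > 0L, , drop = FALSE]
      },
      model_spec("A1_prop_male",
                 cbind(n_male_associates, degree - n_male_associates) ~
                   sex + year + (1 | individual_id),
                 family = "binomial", focal_term = "sex"),
      "datastream"),
    A2 = e("A2",
      "pair formation ~ pre-breeding SRI (mate-identity null)",
      build_pairing_data,
      model_spec("A2", paired ~ sri + year + (1 | male_id) + (1 | female_id),
                 family = "binomial", focal_term = "sri",
                 data_filter = "all male x female combinations with social and breeding data"),
      "mate"),
    A2_habitat = e("A2_habitat",
      "pair formation ~ SRI, habitat-constrained mate null",
      build_pairing_data,
      model_spec("A2_habitat",
                 paired ~ sri + year + (1 | male_id) + (1 | female_id),
                 family = "binomial", focal_term = "sri",
                 data_filter = "pairs with recorded nest locations"),
      "mate_habitat"),
    A3 = e("A3",
      "nest success ~ pair SRI (LRT)",
      build_nest_success_data,
      model_spec("A3", success ~ sri + year + (1 | male_id) + (1 | female_id),
                 family = "binomial", focal_term = "sri",
                 data_filter = "nests whose pair has social information"),
      "none", builder_args = list(require_sri = TRUE)),
    A3_glm = e("A3_glm",
      "nest success ~ pair SRI + habitat (GLM, first records)",
      function(pd) {
        d <- build_nest_success_data(pd, require_sri = TRUE)
        d <- d[order(d$year, d$julian_laid), ]
        d[!duplicated(paste(d$male_id, d$female_id)), , drop = FALSE]
      },
      model_spec("A3_glm", success ~ sri + habitat,
                 family = "binomial", focal_term = "sri"),
      "none"),
    A4_degree = e("A4_degree",
      "number of concurrent nests ~ degree (nest null)",
      build_synchrony_data,
      model_spec("A4_degree",
                 n_overlapping ~ degree + year + (1 | individual_id) +
                   (1 | nest_id),
                 family = "poisson", focal_term = "degree"),
      "nest"),
    A4_strength = e("A4_strength",
      "number of concurrent nests ~ strength (nest null)",
      build_synchrony_data,
      model_spec("A4_strength",
                 n_overlapping ~ strength + year + (1 | individual_id) +
                   (1 | nest_id),
                 family = "poisson", focal_term = "strength"),
      "nest"),
    A5_degree = e("A5_degree",
      "mean distance to concurrent nests ~ degree (nest null)",
      function(pd) {
        d <- build_synchrony_data(pd)
        d[!is.na(d$mean_dist_overlapping), , drop = FALSE]
      },
      model_spec("A5_degree",
                 mean_dist_overlapping ~ degree + year +
                   (1 | individual_id) + (1 | nest_id),
                 family = "gaussian", link = "log", focal_term = "degree"),
      "nest"),
    A5_strength = e("A5_strength",
      "mean distance to concurrent nests ~ strength (nest null)",
      function(pd) {
        d <- build_synchrony_data(pd)
        d[!is.na(d$mean_dist_overlapping), , drop = FALSE]
      },
      model_spec("A5_strength",
                 mean_dist_overlapping ~ strength + year +
                   (1 | individual_id) + (1 | nest_id),
                 family = "gaussian", link = "log", focal_term = "strength"),
      "nest"),
    A6_overlap = e("A6_overlap",
      "dyad nest concurrency ~ SRI (nest null)",
      build_dyad_breeding_data,
      model_spec("A6_overlap",
                 overlaps ~ sri + habitat + year + (1 | id_a) + (1 | id_b),
                 family = "binomial", focal_term = "sri"),
      "nest"),
    A6_distance = e("A6_distance",
      "dyad nest distance ~ SRI (nest null)",
      build_dyad_breeding_data,
      model_spec("A6_distance",
                 distance_m ~ sri + habitat + year + (1 | id_a) + (1 | id_b),
                 family = "gaussian", link = "log", focal_term = "sri"),
      "nest"),
    A7 = e("A7",
      "nest success ~ breeding structure + habitat + laying date (LRT, VIF)",
      build_nest_success_data,
      model_spec("A7",
                 success ~ n_overlapping + mean_dist_overlapping +
                   min_dist_overlapping + habitat + julian_std +
                   I(julian_std^2) + (1 | year),
                 family = "binomial", focal_term = "n_overlapping"),
      "none"),
    A8 = e("A8",
      "nest success ~ concurrent nests within 100 m (LRT)",
      build_nest_success_data,
      model_spec("A8",
                 success ~ n_within_radius + habitat + julian_std +
                   I(julian_std^2) + (1 | year),
                 family = "binomial", focal_term = "n_within_radius"),
      "none"),
    A9 = e("A9",
      "habitat fidelity ~ previous nest success (LRT)",
      build_dispersal_data,
      model_spec("A9",
                 stayed_same_habitat ~ prev_success + prev_habitat +
                   (1 | individual_id) + (1 | year_from),
                 family = "binomial", focal_term = "prev_success"),
      "none"),
    A10 = e("A10",
      "dispersal distance ~ previous nest success (LRT)",
      build_dispersal_data,
      model_spec("A10",
                 distance_m1 ~ prev_success + prev_habitat +
                   (1 | individual_id) + (1 | year_from),
                 family = "gaussian", link = "log",
                 focal_term = "prev_success"),
      "none"),
    A11 = e("A11",
      "dispersal distance ~ neighbour success (GLM, first records)",
      build_dispersal_data,
      model_spec("A11",
                 distance_m1 ~ prev_success +
                   prev_prop_neighbours_successful + prev_habitat,
                 family = "gaussian", link = "log",
                 focal_term = "prev_prop_neighbours_successful"),
      "none",
      builder_args = list(first_only = TRUE, require_neighbours = TRUE))
  )
}

.drop_focal <- function(spec) {
  reduced_formula <- update(spec$formula,
                            paste(". ~ . -", spec$focal_term))
  out <- spec
  out$name <- paste0(spec$name, "_reduced")
  out$formula <- reduced_formula
  out
}

# fast logistic permutation path: covariates fixed, response re-derived
.fast_binomial_stat <- function(X, focal_col) {
  function(y) {
    fit <- suppressWarnings(
      glm.fit(X, y, family = binomial(), control = list(maxit = 50)))
    as.numeric(fit$coefficients[focal_col])
  }
}

#' Run one registered analysis end-to-end
#'
#' Builds the analysis dataset, fits the model (maximum likelihood), runs
#' the focal-term likelihood-ratio test, computes VIFs where the model has
#' at least two fixed terms, and — for analyses with a randomisation null —
#' recomputes the focal coefficient on `n_perm` randomised datasets and
#' reports the two-tailed permutation p-value.
#'
#' @param id analysis id, a name of [analysis_registry()].
#' @param pd a `plover_data` bundle from [prepare_analysis_data()].
#' @param n_perm number of randomisations (ignored for `none` schemes).
#' @param seed integer seed for the randomisations.
#' @param mixed fit random effects in the observed model.
#' @param mixed_null fit random effects inside permutation replicates;
#'   the default FALSE uses the documented fixed-effects GLM fallback for
#'   speed and robustness of the null distribution.
#' @param method two-tailed p-value rule, see [pvalue_two_tailed()].
#' @return object of class `analysis_result`.
#' @export
run_analysis <- function(id, pd, n_perm = 1000, seed = 1, mixed = TRUE,
                         mixed_null = FALSE,
                         method = c("doubled", "deviation")) {
  method <- match.arg(method)
  reg <- analysis_registry()
  if (!id %in% names(reg)) {
    stop("unknown analysis id '", id, "'; see names(analysis_registry())")
  }
  entry <- reg[[id]]
  builder <- function(pd_) {
    do.call(entry$builder, c(list(pd_), entry$builder_args))
  }
  ds <- builder(pd)
  vars <- intersect(all.vars(lme4::nobars(entry$spec$formula)), names(ds))
  ds <- ds[complete.cases(ds[, vars, drop = FALSE]), , drop = FALSE]
  fit <- fit_model(entry$spec, ds, mixed = mixed)
  reduced_fit <- fit_model(.drop_focal(entry$spec), ds, mixed = mixed)
  lrt_res <- lrt(fit, reduced_fit)
  vif <- tryCatch(compute_vif(entry$spec$formula, ds),
                  error = function(e) NULL)
  perm <- NULL
  if (entry$null_scheme != "none" && n_perm > 0) {
    perm <- .run_null(entry, pd, builder, n_perm, seed, mixed_null, method)
  }
  structure(list(id = id, description = entry$description,
                 spec = entry$spec, fit = fit, lrt = lrt_res, vif = vif,
                 perm = perm, n_obs = fit$n_obs),
            class = "analysis_result")
}

.run_null <- function(entry, pd, builder, n_perm, seed, mixed_null, method) {
  scheme <- entry$null_scheme
  spec <- entry$spec
  if (scheme %in% c("mate", "mate_habitat") && !mixed_null) {
    # covariates are invariant under mate randomisation: permute the pair
    # table, re-derive the response, refit on a fixed design matrix
    ds <- builder(pd)
    fixed <- lme4::nobars(spec$formula)
    X <- model.matrix(fixed, ds)
    focal_col <- grep(paste0("^", spec$focal_term), colnames(X))[1L]
    stat <- .fast_binomial_stat(X, focal_col)
    key <- paste(ds$male_id, ds$female_id, as.character(ds$year))
    stratum <- if (scheme == "mate") "year" else c("year", "habitat")
    statistic_fn <- function(pairs) {
      y <- as.numeric(key %in% paste(pairs$male_id, pairs$female_id,
                                     as.character(pairs$year)))
      stat(y)
    }
    randomiser <- function(pairs) mate_randomise(pairs, stratum = stratum)
    return(run_permutation_test(statistic_fn, randomiser, pd$pairs,
                                n_perm = n_perm, seed = seed,
                                method = method,
                                statistic_name = spec$focal_term))
  }
  randomiser <- switch(scheme,
    datastream = function(pd_) {
      pd_$groups_by_year <- lapply(pd_$groups_by_year, datastream_randomise)
      pd_$networks <- NULL
      pd_
    },
    mate = function(pd_) {
      pd_$pairs <- mate_randomise(pd_$pairs, stratum = "year")
      pd_
    },
    mate_habitat = function(pd_) {
      pd_$pairs <- mate_randomise(pd_$pairs, stratum = c("year", "habitat"))
      pd_
    },
    nest = function(pd_) {
      pd_$nests <- nest_randomise(pd_$nests,
                                  stratum = c("year", "habitat"))
      pd_
    },
    stop("unknown null scheme: ", scheme))
  statistic_fn <- function(pd_) {
    focal_estimate(fit_model(spec, builder(pd_), mixed = mixed_null))
  }
  run_permutation_test(statistic_fn, randomiser, pd, n_perm = n_perm,
                       seed = seed, method = method,
                       statistic_name = spec$focal_term)
}

#' @export
print.analysis_result <- function(x, ...) {
  cat(sprintf("analysis %s: %s\n", x$id, x$description))
  cat(sprintf("  n = %d, focal %s = %.4g, LRT chi-sq = %.3f (df %d), p = %.4g\n",
              x$n_obs, x$spec$focal_term, focal_estimate(x$fit),
              x$lrt$chi_sq, x$lrt$df, x$lrt$p))
  if (!is.null(x$perm)) {
    cat(sprintf("  permutation p (two-tailed, %d randomisations) = %.4g\n",
                x$perm$n_perm, x$perm$p_two_tailed))
  }
  invisible(x)
}
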