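#' Do two incubation intervals overlap?
#'
#' Nests are considered concurrent when the closed intervals from clutch
#' laying to the end of incubation share at least one calendar day.
#' Vectorised over all four arguments.
#'
#' @param laid_a,end_a,laid_b,end_b Dates (or anything coercible).
#' @return logical vector.
#' @export
incubation_overlap <- function(laid_a, end_a, laid_b, end_b) {
  laid_a <- as.Date(laid_a); end_a <- as.Date(end_a)
  laid_b <- as.Date(laid_b); end_b <- as.Date(end_b)
  if (any(laid_a > end_a, na.rm = TRUE) || any(laid_b > end_b, na.rm = TRUE)) {
    stop("laid date after incubation end")
  }
  laid_a <= end_b & laid_b <= end_a
}

#' Euclidean distance between nests, in metres
#'
#' Coordinates are planar metres (projected); missing coordinates give NA,
#' flagged for downstream exclusion.
#'
#' @param x1,y1,x2,y2 numeric vectors of coordinates.
#' @return numeric vector of distances.
#' @export
nest_distance <- function(x1, y1, x2, y2) {
  sqrt((x1 - x2)^2 + (y1 - y2)^2)
}

#' Breeding-network dyads: temporal overlap and distance between nests
#'
#' All within-year pairs of nests with their concurrency flag and pairwise
#' Euclidean distance.
#'
#' @param nests nests table (see package overview for columns).
#' @return data.frame `year`, `nest_a`, `nest_b`, `overlaps`, `distance_m`.
#' @export
breeding_dyads <- function(nests) {
  pieces <- lapply(split(nests, nests$year), function(ny) {
    n <- nrow(ny)
    if (n < 2L) return(NULL)
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    a <- idx[, 1L]; b <- idx[, 2L]
    data.frame(
      year = ny$year[1L],
      nest_a = ny$nest_id[a],
      nest_b = ny$nest_id[b],
      overlaps = incubation_overlap(ny$laid_date[a], ny$incubation_end[a],
                                    ny$laid_date[b], ny$incubation_end[b]),
      distance_m = nest_distance(ny$x[a], ny$y[a], ny$x[b], ny$y[b]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Temporal and spatial context of each focal nest
#'
#' For every nest, counts the other nests of the same year whose incubation
#' overlaps it, the mean and minimum distance to those concurrent nests,
#' how many of them lie within `radius` metres (boundary inclusive), and
#' the proportion of those within-radius concurrent neighbours that were
#' successful. Nests belonging to either member of the focal pair are never
#' counted as neighbours. Julian laying date (day of year) is returned raw
#' and variance-standardised over the returned table.
#'
#' @param nests nests table.
#' @param radius neighbourhood radius in metres (default 100).
#' @return data.frame, one row per nest, with columns `nest_id`, `year`,
#'   `habitat`, `success`, `male_id`, `female_id`, `n_overlapping`,
#'   `mean_dist_overlapping`, `min_dist_overlapping`, `n_within_radius`,
#'   `prop_neighbours_successful`, `julian_laid`, `julian_std`.
#' @export
focal_context <- function(nests, radius = 100) {
  pieces <- lapply(split(nests, nests$year), function(ny) {
    n <- nrow(ny)
    res <- data.frame(
      nest_id = ny$nest_id, year = ny$year, habitat = ny$habitat,
      success = ny$success, male_id = ny$male_id, female_id = ny$female_id,
      n_overlapping = 0L,
      mean_dist_overlapping = NA_real_, min_dist_overlapping = NA_real_,
      n_within_radius = 0L, prop_neighbours_successful = NA_real_,
      julian_laid = as.integer(format(as.Date(ny$laid_date), "%j")),
      stringsAsFactors = FALSE
    )
    if (n >= 2L) {
      for (i in seq_len(n)) {
        other <- setdiff(seq_len(n), i)
        # exclude the focal pair's own other nests (either member)
        own <- ny$male_id[other] %in% c(ny$male_id[i], ny$female_id[i]) |
          ny$female_id[other] %in% c(ny$male_id[i], ny$female_id[i])
        other <- other[!own]
        if (length(other) == 0L) next
        ov <- other[incubation_overlap(ny$laid_date[i], ny$incubation_end[i],
                                       ny$laid_date[other],
                                       ny$incubation_end[other])]
        res$n_overlapping[i] <- length(ov)
        if (length(ov) > 0L) {
          d <- nest_distance(ny$x[i], ny$y[i], ny$x[ov], ny$y[ov])
          res$mean_dist_overlapping[i] <- mean(d)
          res$min_dist_overlapping[i] <- min(d)
          near <- ov[d <= radius]
          res$n_within_radius[i] <- length(near)
          if (length(near) > 0L) {
            res$prop_neighbours_successful[i] <- mean(ny$success[near])
          }
        }
      }
    }
    res
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  mu <- mean(out$julian_laid, na.rm = TRUE)
  sdev <- sd(out$julian_laid, na.rm = TRUE)
  out$julian_std <- if (isTRUE(sdev > 0)) (out$julian_laid - mu) / sdev else 0
  out
}

#' Between-year breeding dispersal records
#'
#' For every individual (male or female) breeding in two consecutive years,
#' one record per year-to-year transition: fate and habitat of the previous
#' attempt, whether the bird stayed in the same habitat, the distance
#' between the two nest locations, and the proportion of the previous
#' nest's concurrent neighbours within `radius` m that were successful.
#' Where an individual has several nests in a year its earliest-laid nest
#' is used; `first_only = TRUE` additionally keeps just the first
#' transition per individual, as used in the fixed-effects analyses.
#'
#' @param nests nests table.
#' @param radius neighbourhood radius in metres for the neighbour-success
#'   covariate (default 100).
#' @param first_only keep only each individual's first transition.
#' @return data.frame with one row per (individual, consecutive-year
#'   transition); non-consecutive gaps are skipped and counted in the
#'   `n_skipped_nonconsecutive` attribute.
#' @export
dispersal_records <- function(nests, radius = 100, first_only = FALSE) {
  ctx <- focal_context(nests, radius = radius)
  long <- rbind(
    data.frame(individual_id = nests$male_id, nests,
               stringsAsFactors = FALSE),
    data.frame(individual_id = nests$female_id, nests,
               stringsAsFactors = FALSE)
  )
  long <- long[order(long$individual_id, long$year,
                     as.Date(long$laid_date)), ]
  first_per_year <- long[!duplicated(long[, c("individual_id", "year")]), ]
  n_skipped <- 0L
  recs <- lapply(split(first_per_year, first_per_year$individual_id),
                 function(h) {
    if (nrow(h) < 2L) return(NULL)
    h <- h[order(h$year), ]
    step <- diff(h$year)
    n_skipped <<- n_skipped + sum(step > 1L)
    i <- which(step == 1L)
    if (length(i) == 0L) return(NULL)
    data.frame(
      individual_id = h$individual_id[1L],
      year_from = h$year[i], year_to = h$year[i + 1L],
      prev_success = h$success[i],
      prev_habitat = h$habitat[i], next_habitat = h$habitat[i + 1L],
      stayed_same_habitat = h$habitat[i] == h$habitat[i + 1L],
      distance_m = nest_distance(h$x[i], h$y[i], h$x[i + 1L], h$y[i + 1L]),
      prev_prop_neighbours_successful =
        ctx$prop_neighbours_successful[match(h$nest_id[i], ctx$nest_id)],
      prev_n_within_radius =
        ctx$n_within_radius[match(h$nest_id[i], ctx$nest_id)],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    out <- data.frame(individual_id = character(), year_from = integer(),
                      year_to = integer(), prev_success = logical(),
                      prev_habitat = character(), next_habitat = character(),
                      stayed_same_habitat = logical(), distance_m = numeric(),
                      prev_prop_neighbours_successful = numeric(),
                      prev_n_within_radius = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  if (first_only && nrow(out) > 0L) {
    out <- out[order(out$individual_id, out$year_from), ]
    out <- out[!duplicated(out$individual_id), ]
    rownames(out) <- NULL
  }
  attr(out, "n_skipped_nonconsecutive") <- n_skipped
  out
}
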