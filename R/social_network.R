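#' Collapse repeat sightings of a bird within a sampling period
#'
#' Association inference operates on one position per individual per 10-min
#' sampling period. Repeat detections of the same bird within a period are
#' collapsed to their mean coordinate; all other fields are taken from the
#' first record. Conflicting sex records for a single colour-ring id are a
#' data error and are rejected.
#'
#' @param sightings data.frame with at least `individual_id`, `sex`,
#'   `period_id`, `x`, `y`.
#' @return data.frame with one row per (individual, period).
#' @export
deduplicate_sightings <- function(sightings) {
  stopifnot(is.data.frame(sightings))
  sx <- unique(sightings[, c("individual_id", "sex")])
  bad <- unique(sx$individual_id[duplicated(sx$individual_id)])
  if (length(bad) > 0L) {
    stop("conflicting sex records for individual(s): ",
         paste(bad, collapse = ", "))
  }
  key <- paste(sightings$individual_id, sightings$period_id, sep = "\r")
  if (!anyDuplicated(key)) {
    return(sightings)
  }
  keep <- !duplicated(key)
  out <- sightings[keep, , drop = FALSE]
  out$x <- as.numeric(tapply(sightings$x, key, mean)[key[keep]])
  out$y <- as.numeric(tapply(sightings$y, key, mean)[key[keep]])
  rownames(out) <- NULL
  out
}

#' Restrict sightings to the pre-breeding window
#'
#' Keeps sightings recorded strictly more than `exclusion_days` days before
#' the start of that year's breeding season, so that early breeding
#' behaviour does not leak into pre-breeding social networks. The default
#' window of 14 days can be widened to 30 days, and May can additionally be
#' dropped entirely, as sensitivity variants.
#'
#' @param sightings data.frame with `date` (Date) and `year` columns.
#' @param season_start Date vector named by year (or a data.frame with
#'   columns `year`, `season_start`) giving each breeding-season start.
#' @param exclusion_days non-negative integer; sightings within this many
#'   days before season start are excluded (default 14; sensitivity 30).
#' @param drop_may if TRUE also drop all May sightings.
#' @return filtered data.frame.
#' @export
filter_prebreeding <- function(sightings, season_start, exclusion_days = 14,
                               drop_may = FALSE) {
  stopifnot(exclusion_days >= 0)
  if (is.data.frame(season_start)) {
    season_start <- setNames(as.Date(season_start$season_start),
                             season_start$year)
  }
  yrs <- as.character(sightings$year)
  missing_yr <- setdiff(unique(yrs), names(season_start))
  if (length(missing_yr) > 0L) {
    stop("no season_start given for year(s): ",
         paste(missing_yr, collapse = ", "))
  }
  cutoff <- as.Date(season_start[yrs]) - exclusion_days
  keep <- as.Date(sightings$date) < cutoff
  if (drop_may) {
    keep <- keep & format(as.Date(sightings$date), "%m") != "05"
  }
  out <- sightings[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chain-rule grouping of one sampling period
#'
#' Partitions the individuals sighted in a single 10-min sampling period
#' into gambit-of-the-group flocks: two birds are in the same group when
#' they are connected by a chain of inter-individual distances each at most
#' `chain_distance` metres (boundary inclusive). Groups are the connected
#' components of the thresholded distance graph.
#'
#' @param period_sightings data.frame of sightings sharing one `period_id`.
#' @param chain_distance chain threshold in metres (default 20).
#' @return the input with a `group` column (integer component label within
#'   the period).
#' @export
assign_groups <- function(period_sightings, chain_distance = 20) {
  pid <- unique(period_sightings$period_id)
  if (length(pid) != 1L) {
    stop("assign_groups() expects sightings from exactly one sampling period")
  }
  n <- nrow(period_sightings)
  out <- period_sightings
  if (n <= 1L) {
    out$group <- rep(1L, n)
    return(out)
  }
  d <- as.matrix(dist(cbind(period_sightings$x, period_sightings$y)))
  adj <- d <= chain_distance
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  out$group <- as.integer(igraph::components(g)$membership)
  out
}

#' Chain-rule grouping of every sampling period in a sightings table
#'
#' Applies [assign_groups()] period by period and returns a long
#' group-membership table with globally unique group labels
#' (`period_id:component`).
#'
#' @inheritParams assign_groups
#' @param sightings deduplicated sightings (one row per bird per period).
#' @return data.frame with columns `period_id`, `individual_id`, `sex`,
#'   `group` (character, unique across periods) plus `year` if present.
#' @export
assign_groups_all <- function(sightings, chain_distance = 20) {
  keep <- intersect(c("period_id", "individual_id", "sex", "year"),
                    names(sightings))
  pieces <- lapply(split(sightings, sightings$period_id), function(p) {
    p <- assign_groups(p, chain_distance)
    p$group <- paste0(p$period_id[1L], ":", p$group)
    p[, c(keep, "group")]
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Simple ratio index for one dyad
#'
#' Counts, over all sampling periods, x = periods with both birds in the
#' same group, y_AB = periods with both observed but in different groups,
#' and y_A, y_B = periods with only one of the two observed, and returns
#' SRI = x / (x + y_AB + y_A + y_B). A dyad never observed has SRI 0.
#'
#' @param groups long group-membership table from [assign_groups_all()].
#' @param id_a,id_b individual ids.
#' @return SRI in \[0, 1\].
#' @export
compute_sri <- function(groups, id_a, id_b) {
  ga <- groups[groups$individual_id == id_a, c("period_id", "group")]
  gb <- groups[groups$individual_id == id_b, c("period_id", "group")]
  both <- merge(ga, gb, by = "period_id")
  x <- sum(both$group.x == both$group.y)
  y_ab <- nrow(both) - x
  y_a <- nrow(ga) - nrow(both)
  y_b <- nrow(gb) - nrow(both)
  denom <- x + y_ab + y_a + y_b
  if (denom == 0L) 0 else x / denom
}

#' Simple ratio index matrix over all dyads
#'
#' Matrix-algebra form of [compute_sri()]: with P the period-by-individual
#' presence matrix and G the group-by-individual incidence matrix,
#' co-membership counts are t(G) G, both-seen counts are t(P) P, and the
#' SRI denominator for a dyad is the number of periods in which at least
#' one member was observed.
#'
#' @param groups long group-membership table from [assign_groups_all()].
#' @param ids optional character vector fixing the node set and order
#'   (defaults to the sorted ids present in `groups`).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
sri_matrix <- function(groups, ids = NULL) {
  if (is.null(ids)) ids <- sort(unique(groups$individual_id))
  ind <- factor(groups$individual_id, levels = ids)
  P <- pmin(unclass(table(groups$period_id, ind)), 1L)
  G <- pmin(unclass(table(groups$group, ind)), 1L)
  X <- crossprod(G)           # same-group periods
  B <- crossprod(P)           # both-observed periods
  n_seen <- diag(B)
  denom <- outer(n_seen, n_seen, "+") - B
  S <- ifelse(denom > 0, X / denom, 0)
  diag(S) <- 0
  dimnames(S) <- list(ids, ids)
  S
}

#' Build a pre-breeding social network for one year
#'
#' Nodes are all individuals sighted at least once in the year's
#' (pre-breeding-filtered) sightings; edges are SRI weights from
#' gambit-of-the-group chain-rule grouping of each 10-min sampling period.
#'
#' @param sightings deduplicated sightings, already restricted to the
#'   pre-breeding window (see [filter_prebreeding()]).
#' @param year year to build the network for.
#' @param chain_distance chain threshold in metres (default 20).
#' @return an object of class `plover_network`: list with `year`, `nodes`
#'   (data.frame id, sex), `sri` (matrix), `groups` (long membership
#'   table) and `sampling_periods` (count).
#' @export
build_network <- function(sightings, year, chain_distance = 20) {
  s <- sightings[sightings$year == year, , drop = FALSE]
  if (nrow(s) == 0L) stop("no sightings for year ", year)
  groups <- assign_groups_all(s, chain_distance)
  network_from_groups(groups, year = year)
}

#' Assemble a network from an existing group-membership table
#'
#' Used both by [build_network()] and by data-stream randomisations, where
#' group sizes and sighting patterns are fixed and only identities move.
#'
#' @param groups long group-membership table (one year's periods).
#' @param year year label for the network.
#' @return `plover_network` object.
#' @export
network_from_groups <- function(groups, year = NA) {
  ids <- sort(unique(groups$individual_id))
  sex <- groups$sex[match(ids, groups$individual_id)]
  S <- sri_matrix(groups, ids)
  structure(list(
    year = year,
    nodes = data.frame(individual_id = ids, sex = sex,
                       stringsAsFactors = FALSE),
    sri = S,
    groups = groups,
    sampling_periods = length(unique(groups$period_id))
  ), class = "plover_network")
}

#' @export
print.plover_network <- function(x, ...) {
  ne <- sum(x$sri[upper.tri(x$sri)] > 0)
  cat(sprintf(
    "plover_network (year %s): %d nodes, %d SRI>0 edges, %d periods, density %.4f\n",
    x$year, nrow(x$nodes), ne, x$sampling_periods, network_density(x)))
  invisible(x)
}

#' Network density over SRI>0 edges
#'
#' @param network `plover_network`.
#' @return realised non-zero edges divided by possible edges,
#'   2 E / (n (n - 1)); NA for fewer than two nodes.
#' @export
network_density <- function(network) {
  n <- nrow(network$nodes)
  if (n < 2L) return(NA_real_)
  e <- sum(network$sri[upper.tri(network$sri)] > 0)
  2 * e / (n * (n - 1))
}

#' Edge list of a network
#'
#' @param network `plover_network`.
#' @param positive_only keep only SRI > 0 edges (default TRUE).
#' @return data.frame `id_a`, `id_b`, `sri`.
#' @export
network_edges <- function(network, positive_only = TRUE) {
  S <- network$sri
  ut <- which(upper.tri(S), arr.ind = TRUE)
  out <- data.frame(id_a = rownames(S)[ut[, 1L]],
                    id_b = colnames(S)[ut[, 2L]],
                    sri = S[ut], stringsAsFactors = FALSE)
  if (positive_only) out <- out[out$sri > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-node social metrics
#'
#' Degree is the number of associates with SRI > 0, strength the sum of
#' incident SRI weights, and `prop_male_associates` the proportion of a
#' node's associates that are male (NA for isolated nodes).
#'
#' @param network `plover_network`.
#' @return data.frame with `individual_id`, `sex`, `degree`, `strength`,
#'   `n_male_associates`, `prop_male_associates`.
#' @export
node_metrics <- function(network) {
  S <- network$sri
  pos <- S > 0
  deg <- rowSums(pos)
  male <- network$nodes$sex == "M"
  n_male <- as.integer(pos %*% male)
  data.frame(
    individual_id = network$nodes$individual_id,
    sex = network$nodes$sex,
    degree = as.integer(deg),
    strength = rowSums(S),
    n_male_associates = n_male,
    prop_male_associates = ifelse(deg > 0, n_male / deg, NA_real_),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
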