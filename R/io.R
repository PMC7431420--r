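#' Read a sightings CSV
#'
#' UTF-8, comma-separated, header row, ISO-8601 dates. Columns:
#' `individual_id`, `sex`, `date`, `period_id`, `x`, `y`, `habitat`,
#' `year`.
#'
#' @param path file path.
#' @return sightings data.frame with `date` parsed to Date.
#' @export
read_sightings <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.sighting_cols, names(d))
  if (length(miss) > 0L) {
    stop("sightings file missing column(s): ", paste(miss, collapse = ", "))
  }
  d$date <- as.Date(d$date)
  d
}

#' Read a nests CSV
#'
#' Columns: `nest_id`, `male_id`, `female_id`, `x`, `y`, `habitat`,
#' `laid_date`, `incubation_end`, `success`, `year`.
#'
#' @param path file path.
#' @return nests data.frame with dates parsed and `success` logical.
#' @export
read_nests <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.nest_cols, names(d))
  if (length(miss) > 0L) {
    stop("nests file missing column(s): ", paste(miss, collapse = ", "))
  }
  d$laid_date <- as.Date(d$laid_date)
  d$incubation_end <- as.Date(d$incubation_end)
  d$success <- as.logical(d$success)
  d
}

#' Write a table as CSV (UTF-8, ISO dates, no row names)
#' @param x data.frame.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_table_csv <- function(x, path) {
  for (cl in names(x)) if (inherits(x[[cl]], "Date")) {
    x[[cl]] <- format(x[[cl]], "%Y-%m-%d")
  }
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write habitat rectangles as a GeoJSON FeatureCollection
#' @param habitats habitat table, see [default_habitats()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_habitats_geojson <- function(habitats, path) {
  features <- lapply(seq_len(nrow(habitats)), function(i) {
    h <- habitats[i, ]
    ring <- list(c(h$xmin, h$ymin), c(h$xmax, h$ymin), c(h$xmax, h$ymax),
                 c(h$xmin, h$ymax), c(h$xmin, h$ymin))
    list(type = "Feature",
         properties = list(habitat = h$habitat,
                           surveyed = isTRUE(h$surveyed)),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read habitat polygons from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon features with a `habitat`
#' property (and optional `surveyed`). Returns the bounding-box habitat
#' table used throughout, with the exact rings kept in the `polygons`
#' attribute for point-in-polygon queries.
#'
#' @param path GeoJSON file path.
#' @return habitat data.frame with `polygons` attribute (named list of
#'   two-column coordinate matrices).
#' @export
read_habitats_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  if (!identical(g$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection")
  }
  rows <- list(); polys <- list()
  for (f in g$features) {
    if (!identical(f$geometry$type, "Polygon")) {
      stop("only Polygon features are supported")
    }
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1L]],
                                  function(p) c(p[[1L]], p[[2L]])))
    hab <- f$properties$habitat
    polys[[hab]] <- ring
    rows[[hab]] <- data.frame(
      habitat = hab,
      xmin = min(ring[, 1L]), xmax = max(ring[, 1L]),
      ymin = min(ring[, 2L]), ymax = max(ring[, 2L]),
      surveyed = isTRUE(f$properties$surveyed),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "polygons") <- polys
  out
}

#' Point-in-polygon test (ray casting, boundary-tolerant)
#' @param px,py point coordinates (vectors).
#' @param ring two-column matrix of polygon vertices (closed or open ring).
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, ring) {
  n <- nrow(ring)
  if (all(ring[1L, ] == ring[n, ])) { ring <- ring[-n, , drop = FALSE]; n <- n - 1L }
  vapply(seq_along(px), function(k) {
    x <- px[k]; y <- py[k]
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- ring[i, 1L]; yi <- ring[i, 2L]
      xj <- ring[j, 1L]; yj <- ring[j, 2L]
      # on-edge points count as inside
      if ((x - xi)^2 + (y - yi)^2 == 0) return(TRUE)
      if ((yi > y) != (yj > y) &&
          x < (xj - xi) * (y - yi) / (yj - yi) + xi) {
        inside <- !inside
      }
      j <- i
    }
    inside
  }, logical(1))
}

#' Which habitat polygon contains each point?
#' @param habitats habitat table (with optional `polygons` attribute from
#'   [read_habitats_geojson()]).
#' @param x,y coordinates.
#' @return character vector of habitat labels (NA outside all habitats).
#' @export
habitat_of_point <- function(habitats, x, y) {
  polys <- attr(habitats, "polygons")
  if (is.null(polys)) return(.habitat_at(habitats, x, y))
  out <- rep(NA_character_, length(x))
  for (hab in names(polys)) {
    hit <- point_in_polygon(x, y, polys[[hab]])
    out[hit & is.na(out)] <- hab
  }
  out
}

#' Export a network as GraphML
#' @param network `plover_network`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  g <- igraph::graph_from_adjacency_matrix(network$sri, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$sex <- network$nodes$sex[match(igraph::V(g)$name,
                                              network$nodes$individual_id)]
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
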