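## Plain-text I/O: GeoJSON geography, CSV tables, JSON sidecars.

#' Write area polygons as a GeoJSON FeatureCollection
#'
#' One feature per area with property `area_id`; additional per-area
#' properties may be joined from a data.frame.
#'
#' @param features list of `(area_id, ring)` features (see
#'   [adjacency_from_polygons()]).
#' @param path output file.
#' @param properties optional data.frame keyed by `area_id` whose remaining
#'   columns become feature properties.
#' @export
write_geojson <- function(features, path, properties = NULL) {
  feats <- lapply(features, function(f) {
    props <- list(area_id = as.character(f$area_id))
    if (!is.null(properties)) {
      row <- properties[properties$area_id == f$area_id, , drop = FALSE]
      if (nrow(row) == 1L)
        for (nm in setdiff(names(row), "area_id")) props[[nm]] <- row[[nm]]
    }
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(unname(apply(f$ring, 1, c,
                                                         simplify = FALSE)))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GeoJSON FeatureCollection of area polygons
#'
#' @param path GeoJSON file with Polygon features carrying an `area_id`
#'   property.
#' @return list of features `(area_id, ring, properties)` suitable for
#'   [adjacency_from_polygons()].
#' @export
read_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  stop_if(!identical(g$type, "FeatureCollection"), "not a FeatureCollection")
  lapply(g$features, function(f) {
    stop_if(!identical(f$geometry$type, "Polygon"),
            "only Polygon geometries supported")
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) as.numeric(unlist(p))))
    list(area_id = as.character(f$properties$area_id), ring = ring,
         properties = f$properties)
  })
}

#' Write an adjacency structure as a two-column edge list CSV
#'
#' @param adj a [adjacency_structure()].
#' @param path output file (columns `from`, `to`, one row per unordered
#'   pair).
#' @export
write_adjacency <- function(adj, path) {
  e <- adjacency_edges(adj)
  utils::write.csv(data.frame(from = adj$ids[e[, 1]], to = adj$ids[e[, 2]]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an edge-list CSV into an adjacency structure
#'
#' @param path CSV with columns `from`, `to`.
#' @param ids optional full id set (to retain isolated areas).
#' @return a [adjacency_structure()].
#' @export
read_adjacency <- function(path, ids = NULL) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- ids %||% sort(unique(c(e$from, e$to)))
  nb <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) nb[[i]] <- integer()
  fi <- match(e$from, ids); ti <- match(e$to, ids)
  stop_if(anyNA(fi) || anyNA(ti), "edge references an unknown area id")
  for (r in seq_len(nrow(e))) {
    nb[[fi[r]]] <- c(nb[[fi[r]]], ti[r])
    nb[[ti[r]]] <- c(nb[[ti[r]]], fi[r])
  }
  adjacency_structure(ids, unname(nb))
}

#' Read episode records from CSV
#'
#' @param path CSV with columns `person_id`, `event_date` (ISO dates),
#'   `sex`, `age`, `area_id`, `method` (possibly `";"`-separated labels).
#'   Empty `area_id` is read as missing.
#' @return data.frame of episode records.
#' @export
read_episodes <- function(path) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(area_id = "character"))
  r$event_date <- as.Date(r$event_date)
  r$area_id[!is.na(r$area_id) & r$area_id == ""] <- NA_character_
  r
}
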