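#' Write a raster to an Esri ASCII grid (.asc)
#'
#' Plain-text interchange raster: six-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows top to bottom. `NA`
#' cells are written as the grid's nodata sentinel. Values round-trip
#' bit-exactly at the precision of `format`'s 17 significant digits.
#'
#' @param raster an [acc_raster()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path) {
  g <- raster$grid
  v <- raster$values
  v[!is.finite(v)] <- g$nodata
  hdr <- c(sprintf("ncols %d", g$n_cols),
           sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %.10g", g$origin_x),
           sprintf("yllcorner %.10g", g$origin_y),
           sprintf("cellsize %.10g", g$cell_size),
           sprintf("NODATA_value %.10g", g$nodata))
  body <- apply(v, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an Esri ASCII grid (.asc)
#'
#' @param path input file path.
#' @param layer layer name for the returned raster.
#' @return an [acc_raster()] with nodata cells as `NA`.
#' @export
read_ascii_grid <- function(path, layer = "layer") {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  g <- grid_spec(n_rows = val("nrows"), n_cols = val("ncols"),
                 cell_size = val("cellsize"), origin_x = val("xllcorner"),
                 origin_y = val("yllcorner"), nodata = val("NODATA_value"))
  nums <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(nums, nrow = g$n_rows, ncol = g$n_cols, byrow = TRUE)
  m[m == g$nodata] <- NA
  acc_raster(g, m, layer = layer)
}

geojson_feature <- function(geometry, properties) {
  list(type = "Feature", geometry = geometry, properties = properties)
}

write_geojson <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' Write a road network to GeoJSON
#'
#' One LineString feature per segment with properties `road_class` and
#' `segment_id`.
#' @param roads a `road_network` (see [road_network()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roads_geojson <- function(roads, path) {
  feats <- lapply(roads$segments, function(s) {
    geojson_feature(
      list(type = "LineString",
           coordinates = lapply(seq_len(nrow(s$coords)),
                                function(i) unname(s$coords[i, ]))),
      list(road_class = s$road_class, segment_id = s$segment_id))
  })
  write_geojson(feats, path)
}

#' Read a road network from GeoJSON
#' @param path GeoJSON file of LineString features with `road_class` and
#'   `segment_id` properties.
#' @return a `road_network`.
#' @export
read_roads_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  segs <- lapply(fc$features, function(f) {
    coords <- do.call(rbind, lapply(f$geometry$coordinates,
                                    function(p) as.numeric(unlist(p))))
    list(coords = coords,
         road_class = f$properties$road_class,
         segment_id = as.integer(f$properties$segment_id))
  })
  road_network(segs)
}

#' Write a facility registry to GeoJSON
#' @param registry a `facility_registry` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_facilities_geojson <- function(registry, path) {
  feats <- lapply(seq_len(nrow(registry)), function(i) {
    geojson_feature(
      list(type = "Point",
           coordinates = c(registry$x[i], registry$y[i])),
      list(level = registry$level[i], sector = registry$sector[i],
           facility_id = registry$facility_id[i]))
  })
  write_geojson(feats, path)
}

#' Read a facility registry from GeoJSON
#' @param path GeoJSON of Point features with `level`, `sector`,
#'   `facility_id` properties.
#' @return a `facility_registry`.
#' @export
read_facilities_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  rows <- lapply(fc$features, function(f) {
    data.frame(x = as.numeric(f$geometry$coordinates[[1]]),
               y = as.numeric(f$geometry$coordinates[[2]]),
               level = f$properties$level, sector = f$properties$sector,
               facility_id = as.integer(f$properties$facility_id))
  })
  facility_registry(do.call(rbind, rows))
}

#' Write RWI sample points to GeoJSON
#' @param rwi data.frame with `x`, `y`, `rwi`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rwi_geojson <- function(rwi, path) {
  feats <- lapply(seq_len(nrow(rwi)), function(i) {
    geojson_feature(list(type = "Point", coordinates = c(rwi$x[i], rwi$y[i])),
                    list(rwi = rwi$rwi[i]))
  })
  write_geojson(feats, path)
}

#' Read RWI sample points from GeoJSON
#' @param path GeoJSON of Point features with an `rwi` property.
#' @return data.frame with `x`, `y`, `rwi`.
#' @export
read_rwi_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  do.call(rbind, lapply(fc$features, function(f) {
    data.frame(x = as.numeric(f$geometry$coordinates[[1]]),
               y = as.numeric(f$geometry$coordinates[[2]]),
               rwi = as.numeric(f$properties$rwi))
  }))
}

#' Write zone polygons to GeoJSON
#' @param zones a `zone_set` (see [zone_set()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_zones_geojson <- function(zones, path) {
  feats <- lapply(zones$zones, function(z) {
    ring <- z$ring
    if (!all(ring[1, ] == ring[nrow(ring), ]))
      ring <- rbind(ring, ring[1, , drop = FALSE])
    geojson_feature(
      list(type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)),
                                     function(i) unname(ring[i, ])))),
      list(zone_id = z$zone_id, zone_level = z$zone_level))
  })
  write_geojson(feats, path)
}

#' Read zone polygons from GeoJSON
#' @param path GeoJSON of Polygon features with `zone_id` and `zone_level`.
#' @return a `zone_set`.
#' @export
read_zones_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  zs <- lapply(fc$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) as.numeric(unlist(p))))
    list(ring = ring, zone_id = f$properties$zone_id,
         zone_level = f$properties$zone_level)
  })
  zone_set(zs)
}

#' Write trajectories to long-form CSV (trip_id, x, y, t)
#' @param trajectories list of trajectory data.frames (`x`, `y`, `t` with a
#'   `trip_id` column or attribute).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(trajectories, path) {
  long <- do.call(rbind, lapply(trajectories, function(tr) {
    data.frame(trip_id = if (!is.null(tr$trip_id)) tr$trip_id
               else attr(tr, "trip_id"),
               x = tr$x, y = tr$y, t = tr$t)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read trajectories from long-form CSV
#' @param path CSV with columns trip_id, x, y, t.
#' @return list of per-trip data.frames ordered by t.
#' @export
read_trajectories_csv <- function(path) {
  long <- utils::read.csv(path)
  lapply(split(long, long$trip_id), function(d) d[order(d$t), , drop = FALSE])
}

#' Write a speed table to CSV
#' @param table a `speed_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_speed_table_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a speed table from CSV
#' @param path CSV with columns class_kind, class, mean, min, max, sd, n.
#' @return a `speed_table`.
#' @export
read_speed_table_csv <- function(path) {
  speed_table(utils::read.csv(path))
}
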