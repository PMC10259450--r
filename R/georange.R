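# Occurrence records -> grid ranges, island membership, range overlap and
# asymmetry, and the allopatric/sympatric call.

#' Load and validate occurrence records
#'
#' Required columns: `species`, `lon`, `lat`. Optional: `island_id` (explicit
#' island membership, overrides polygon lookup), `flank` (mountain-flank
#' label, used for the different-slopes rule), `habitat` (`"paramo"` or
#' `"forest"`). Exact duplicate records are dropped.
#'
#' @param x a CSV file path or a data.frame.
#' @return a validated `occurrences` data.frame.
#' @export
load_occurrences <- function(x) {
  df <- if (is.data.frame(x)) x else
    utils::read.csv(x, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort("missing columns: ", paste(miss, collapse = ", "))
  df$species <- as.character(df$species)
  if (any(is.na(df$species) | df$species == ""))
    abort("empty species field in occurrence table")
  df$lon <- suppressWarnings(as.numeric(df$lon))
  df$lat <- suppressWarnings(as.numeric(df$lat))
  if (any(is.na(df$lon)) || any(is.na(df$lat)))
    abort("unparseable coordinates in occurrence table")
  if (any(df$lon < -180 | df$lon > 180))
    abort("longitude out of range [-180, 180]")
  if (any(df$lat < -90 | df$lat > 90))
    abort("latitude out of range [-90, 90]")
  for (opt in c("island_id", "flank", "habitat"))
    if (!opt %in% names(df)) df[[opt]] <- NA_character_
  df <- df[, c("species", "lon", "lat", "island_id", "flank", "habitat")]
  df <- unique(df)
  rownames(df) <- NULL
  class(df) <- c("occurrences", "data.frame")
  df
}

#' Define a rasterisation grid
#'
#' Cells are half-open intervals `[x, x + s)` on each axis, tiled from an
#' integer-degree anchored origin, so a point exactly on a cell edge falls in
#' the higher-index cell and results are bit-stable.
#'
#' @param cell_size cell edge in decimal degrees (the study sizes are 0.05
#'   and 0.1).
#' @param origin length-2 numeric, grid origin (lon, lat); default `c(0, 0)`.
#' @return a `grid_spec` object.
#' @export
grid_spec <- function(cell_size, origin = c(0, 0)) {
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    abort("cell_size must be a single positive number")
  structure(list(cell_size = cell_size, origin = origin),
            class = "grid_spec")
}

#' Rasterise one species' occurrences onto a grid
#'
#' @param occs an `occurrences` table.
#' @param species species name present in `occs`.
#' @param grid a [grid_spec()].
#' @return a `grid_range`: species, grid, and the set of occupied cell
#'   indices (duplicate occurrences in one cell collapse).
#' @export
rasterize <- function(occs, species, grid) {
  rec <- occs[occs$species == species, , drop = FALSE]
  if (nrow(rec) == 0) abort("unknown species: ", species)
  cx <- floor((rec$lon - grid$origin[1]) / grid$cell_size)
  cy <- floor((rec$lat - grid$origin[2]) / grid$cell_size)
  cells <- unique(data.frame(cell_x = cx, cell_y = cy))
  rownames(cells) <- NULL
  structure(list(species = species, grid = grid, cells = cells),
            class = "grid_range")
}

#' Number of occupied cells in a grid range
#' @param gr a `grid_range`.
#' @return integer cell count (the range-size measure).
#' @export
range_size <- function(gr) nrow(gr$cells)

cell_keys <- function(gr) paste(gr$cells$cell_x, gr$cells$cell_y)

check_same_grid <- function(ga, gb) {
  if (!isTRUE(all.equal(ga$grid$cell_size, gb$grid$cell_size)) ||
      !isTRUE(all.equal(ga$grid$origin, gb$grid$origin)))
    abort("grid ranges use different grid specifications")
}

#' Range overlap between two sister species
#'
#' Cells occupied by both species divided by the cell count of the
#' smaller-ranged species. 0 means full allopatry; 1 means the
#' smaller-ranged sister occurs solely within its sister's range.
#'
#' @param ga,gb `grid_range` objects on the same grid.
#' @return overlap in `[0, 1]`; symmetric.
#' @export
range_overlap <- function(ga, gb) {
  check_same_grid(ga, gb)
  shared <- length(intersect(cell_keys(ga), cell_keys(gb)))
  shared / min(range_size(ga), range_size(gb))
}

#' Range asymmetry between two sister species
#'
#' Cell count of the larger-ranged sister divided by that of the smaller.
#'
#' @param ga,gb `grid_range` objects on the same grid.
#' @return asymmetry ratio `>= 1`; symmetric.
#' @export
range_asymmetry <- function(ga, gb) {
  check_same_grid(ga, gb)
  a <- range_size(ga); b <- range_size(gb)
  max(a, b) / min(a, b)
}

## ---- islands -------------------------------------------------------------

#' Build an island map from polygons
#'
#' @param polygons named list of polygons; each a 2-column matrix (lon, lat)
#'   of vertices (closed implicitly). Names are island ids.
#' @param bioregion optional character vector, one label per island.
#' @return an `island_map`.
#' @export
island_map <- function(polygons, bioregion = NULL) {
  ids <- names(polygons)
  if (is.null(ids) || anyDuplicated(ids))
    abort("island polygons must carry unique ids")
  for (p in polygons) {
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3)
      abort("each polygon must be a matrix of >= 3 (lon, lat) vertices")
    if (any(!is.finite(p))) abort("invalid polygon geometry")
  }
  if (!is.null(bioregion) && length(bioregion) != length(polygons))
    abort("bioregion labels must match polygon count")
  structure(list(polygons = polygons, bioregion = bioregion),
            class = "island_map")
}

#' Read an island map from GeoJSON
#'
#' Expects a FeatureCollection of (single-ring) Polygon features with an
#' `id` property and optionally a `bioregion` property.
#'
#' @param path GeoJSON file.
#' @return an `island_map`.
#' @export
read_islands <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) abort("not a GeoJSON FeatureCollection")
  polys <- list(); bior <- character()
  for (f in gj$features) {
    if (!identical(f$geometry$type, "Polygon"))
      abort("only Polygon features are supported")
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    # drop the GeoJSON closing vertex (first == last)
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), ]
    id <- as.character(f$properties$id)
    polys[[id]] <- m
    bior <- c(bior, if (!is.null(f$properties$bioregion))
      as.character(f$properties$bioregion) else NA_character_)
  }
  island_map(polys, if (all(is.na(bior))) NULL else bior)
}

#' Write an island map as GeoJSON
#' @param islands an `island_map`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_islands <- function(islands, path) {
  feats <- lapply(seq_along(islands$polygons), function(i) {
    m <- islands$polygons[[i]]
    ring <- lapply(seq_len(nrow(m)), function(r) list(m[r, 1], m[r, 2]))
    ring[[length(ring) + 1]] <- ring[[1]]
    props <- list(id = names(islands$polygons)[i])
    if (!is.null(islands$bioregion))
      props$bioregion <- islands$bioregion[i]
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Even-odd ray-casting point-in-polygon, boundary-inclusive: points on a
# polygon edge or vertex count as inside (island margins hold occurrences).
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    # boundary check: point on segment (i, j)
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    if (abs(cross) < 1e-12 &&
        px >= min(xi, xj) - 1e-12 && px <= max(xi, xj) + 1e-12 &&
        py >= min(yi, yj) - 1e-12 && py <= max(yi, yj) + 1e-12)
      return(TRUE)
    if ((yi > py) != (yj > py)) {
      xint <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Assign occurrences to islands
#'
#' Point-in-polygon membership per record (boundary points inside). Records
#' with an explicit `island_id` bypass the polygon lookup. Records falling
#' outside every polygon are flagged; they are excluded from island sets but
#' retained for gridding.
#'
#' @param occs an `occurrences` table.
#' @param islands an `island_map`.
#' @return list with `sets` (named list: species -> character vector of
#'   island ids) and `outside` (row indices of flagged records).
#' @export
assign_islands <- function(occs, islands) {
  ids <- names(islands$polygons)
  rec_island <- character(nrow(occs))
  for (r in seq_len(nrow(occs))) {
    if (!is.na(occs$island_id[r]) && occs$island_id[r] != "") {
      rec_island[r] <- as.character(occs$island_id[r])
      next
    }
    hit <- NA_character_
    for (id in ids) {
      if (point_in_polygon(occs$lon[r], occs$lat[r], islands$polygons[[id]])) {
        hit <- id
        break
      }
    }
    rec_island[r] <- if (is.na(hit)) NA_character_ else hit
  }
  outside <- which(is.na(rec_island))
  sets <- lapply(split(rec_island, occs$species),
                 function(v) sort(unique(v[!is.na(v)])))
  list(sets = sets, outside = outside)
}

#' Score a species pair as allopatric or sympatric from island memberships
#'
#' Sisters sharing at least one island are sympatric; sisters on
#' non-overlapping island sets are allopatric. Exception for forest-belt
#' species below the open-paramo line: when both species carry habitat tag
#' `"forest"` and their mountain-flank labels are disjoint on every island
#' they share, the pair is called allopatric — they inhabit different slopes
#' of the same mountain. A species with no island membership and no flank
#' data yields `"undetermined"`, which the classifier treats as inconclusive.
#'
#' @param sp1,sp2 species names.
#' @param island_sets named list from [assign_islands()]`$sets`.
#' @param occs the `occurrences` table (source of habitat/flank labels).
#' @return one of `"allopatric"`, `"sympatric"`, `"undetermined"`.
#' @export
island_call <- function(sp1, sp2, island_sets, occs) {
  s1 <- island_sets[[sp1]]
  s2 <- island_sets[[sp2]]
  flanks <- function(sp, isl) {
    f <- occs$flank[occs$species == sp]
    i <- occs$island_id[occs$species == sp]
    unique(f[!is.na(f) & (is.na(i) | i == isl | isl == "")])
  }
  habitat <- function(sp) {
    h <- unique(occs$habitat[occs$species == sp])
    h <- h[!is.na(h)]
    if (length(h)) h[1] else NA_character_
  }
  has_flank <- function(sp) any(!is.na(occs$flank[occs$species == sp]))
  if ((is.null(s1) || length(s1) == 0) && !has_flank(sp1))
    return("undetermined")
  if ((is.null(s2) || length(s2) == 0) && !has_flank(sp2))
    return("undetermined")
  shared <- intersect(s1, s2)
  if (length(shared) == 0) return("allopatric")
  # different-slopes exception for forest dwellers
  if (identical(habitat(sp1), "forest") && identical(habitat(sp2), "forest")) {
    disjoint_everywhere <- all(vapply(shared, function(isl) {
      f1 <- flanks(sp1, isl); f2 <- flanks(sp2, isl)
      length(f1) > 0 && length(f2) > 0 && length(intersect(f1, f2)) == 0
    }, TRUE))
    if (disjoint_everywhere) return("allopatric")
  }
  "sympatric"
}

#' Export grid ranges as a BED-like TSV
#' @param ranges list of `grid_range` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_grid_ranges <- function(ranges, path) {
  rows <- do.call(rbind, lapply(ranges, function(g)
    cbind(g$cells, species = g$species)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
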