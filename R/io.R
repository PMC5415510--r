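#' Construct a spatial-unit feature table
#'
#' The clustering substrate: one row per spatial unit (e.g. an HU-12
#' watershed), one column per numeric geospatial variable, each variable
#' tagged with a theme (terrestrial, climate, freshwater, or other).
#' Missing entries are `NA`, never zero.
#'
#' @param values numeric matrix, n units x p variables, with unique non-empty
#'   rownames (unit ids) and unique colnames (variable names). `NA` = missing.
#' @param themes named character vector mapping every variable name to one of
#'   `"terrestrial"`, `"climate"`, `"freshwater"`, `"other"`; variables not
#'   named default to `"other"`.
#' @param area optional positive numeric vector of unit areas (ha).
#' @return an object of class `unit_table` with elements `unit_id`, `values`,
#'   `themes` and optionally `area`.
#' @export
unit_table <- function(values, themes = NULL, area = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  ids <- rownames(values)
  abort_if(is.null(ids) || anyNA(ids) || any(!nzchar(ids)),
           "unit ids must be non-empty rownames of `values`")
  dup <- unique(ids[duplicated(ids)])
  abort_if(length(dup) > 0,
           "duplicate unit ids: ", paste(dup, collapse = ", "))
  vars <- colnames(values)
  if (is.null(vars)) {
    vars <- paste0("v", seq_len(ncol(values)))
    colnames(values) <- vars
  }
  abort_if(anyDuplicated(vars) > 0,
           "variable names must be unique colnames of `values`")
  abort_if(nrow(values) < 2, "need at least 2 spatial units")
  abort_if(ncol(values) < 1, "need at least 1 variable")
  th <- setNames(rep("other", length(vars)), vars)
  if (!is.null(themes)) {
    bad <- setdiff(names(themes), vars)
    abort_if(length(bad) > 0,
             "theme map names unknown variables: ", paste(bad, collapse = ", "))
    legal <- c("terrestrial", "climate", "freshwater", "other")
    abort_if(!all(themes %in% legal),
             "themes must be one of: ", paste(legal, collapse = ", "))
    th[names(themes)] <- themes
  }
  if (!is.null(area)) {
    abort_if(length(area) != nrow(values) || any(area <= 0, na.rm = TRUE),
             "`area` must be positive, one value per unit")
  }
  structure(list(unit_id = ids, values = values, themes = th, area = area),
            class = "unit_table")
}

#' @export
print.unit_table <- function(x, ...) {
  cat(sprintf("<unit_table> %d units x %d variables\n",
              nrow(x$values), ncol(x$values)))
  cat("  themes:", paste(sprintf("%s=%d", names(table(x$themes)),
                                 table(x$themes)), collapse = ", "), "\n")
  nm <- sum(is.na(x$values))
  if (nm > 0) cat(sprintf("  missing entries: %d\n", nm))
  invisible(x)
}

#' @export
dim.unit_table <- function(x) dim(x$values)

#' Read a spatial-unit feature table from CSV
#'
#' Expects a header row; the first column is the unit identifier, the
#' remaining columns are numeric (empty string = missing). An optional theme
#' map CSV with columns `variable,theme` assigns each variable to a theme;
#' variables absent from the map default to `"other"`.
#'
#' @param path path to the feature CSV.
#' @param theme_map optional path to a `variable,theme` CSV.
#' @return a [unit_table()].
#' @export
read_unit_table <- function(path, theme_map = NULL) {
  raw <- read.csv(path, check.names = FALSE, colClasses = "character",
                  na.strings = "")
  abort_if(ncol(raw) < 2, "feature CSV needs an id column plus >= 1 variable")
  ids <- raw[[1]]
  vals <- as.matrix(raw[-1])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell at row %d, column '%s' (value '%s')",
                 bad[1, 1], colnames(raw)[-1][bad[1, 2]],
                 vals[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  rownames(num) <- ids
  colnames(num) <- colnames(raw)[-1]
  themes <- NULL
  if (!is.null(theme_map)) {
    tm <- read.csv(theme_map, check.names = FALSE,
                   colClasses = "character")
    abort_if(!all(c("variable", "theme") %in% names(tm)),
             "theme map needs columns 'variable' and 'theme'")
    themes <- setNames(tm$theme, tm$variable)
    themes <- themes[names(themes) %in% colnames(num)]
  }
  unit_table(num, themes = themes)
}

#' Read a spatial adjacency graph from a two-column edge-list CSV
#'
#' Builds the undirected unit-contiguity graph. Duplicate and reversed pairs
#' collapse to a single edge; self-loops and edges naming unknown units are
#' errors; units with no neighbors produce a warning, not an error.
#'
#' @param path path to a CSV whose first two columns are unit-id pairs.
#' @param table a [unit_table()] defining the known unit ids.
#' @return an undirected [igraph::igraph] with one vertex per unit (named by
#'   unit id, in table order).
#' @export
read_adjacency <- function(path, table) {
  ed <- read.csv(path, check.names = FALSE, colClasses = "character")
  abort_if(ncol(ed) < 2, "edge list needs two columns")
  edges_graph(cbind(ed[[1]], ed[[2]]), table$unit_id)
}

edges_graph <- function(pairs, unit_ids) {
  pairs <- as.matrix(pairs)
  abort_if(any(pairs[, 1] == pairs[, 2]),
           "self-loop edge: ",
           paste(unique(pairs[pairs[, 1] == pairs[, 2], 1]), collapse = ", "))
  unknown <- setdiff(unique(c(pairs)), unit_ids)
  abort_if(length(unknown) > 0,
           "edges reference unknown unit ids: ",
           paste(unknown, collapse = ", "))
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs[, 1], to = pairs[, 2]),
    directed = FALSE,
    vertices = data.frame(name = unit_ids))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  iso <- igraph::V(g)$name[igraph::degree(g) == 0]
  if (length(iso) > 0) {
    warning(length(iso), " unit(s) with zero neighbors: ",
            paste(head(iso, 5), collapse = ", "),
            if (length(iso) > 5) ", ..." else "", call. = FALSE)
  }
  g
}

#' Derive unit adjacency from GeoJSON polygons
#'
#' Reads an RFC 7946 FeatureCollection of Polygon/MultiPolygon features and
#' declares two units adjacent when their boundaries share vertices: under the
#' rook rule (default) they must share at least two boundary vertices (a
#' boundary segment of positive length); under the queen rule a single shared
#' vertex (corner contact) suffices. Coordinates are snapped to a tolerance
#' before comparison, so every rook edge is also a queen edge.
#'
#' @param path path to a GeoJSON file.
#' @param rule `"rook"` (default) or `"queen"`.
#' @param id_property name of the feature property holding the unit id.
#' @param snap coordinate snapping tolerance for vertex identity.
#' @return an undirected, named [igraph::igraph].
#' @export
adjacency_from_polygons <- function(path, rule = c("rook", "queen"),
                                    id_property = "id", snap = 1e-8) {
  rule <- match.arg(rule)
  gj <- jsonlite::read_json(path)
  abort_if(!identical(gj$type, "FeatureCollection"),
           "GeoJSON must be a FeatureCollection")
  feats <- gj$features
  abort_if(length(feats) < 1, "no features in GeoJSON")
  ids <- character(length(feats))
  verts <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    id <- f$properties[[id_property]]
    abort_if(is.null(id),
             sprintf("feature %d lacks id property '%s'", i, id_property))
    ids[i] <- as.character(id)
    geom <- f$geometry
    abort_if(is.null(geom) || is.null(geom$type),
             sprintf("feature '%s' has no geometry", ids[i]))
    rings <- switch(geom$type,
      Polygon = geom$coordinates,
      MultiPolygon = do.call(c, geom$coordinates),
      stop(sprintf("feature '%s': unsupported geometry type '%s'",
                   ids[i], geom$type), call. = FALSE))
    xy <- do.call(rbind, lapply(rings, function(r)
      do.call(rbind, lapply(r, function(p) c(as.numeric(p[[1]]),
                                             as.numeric(p[[2]]))))))
    abort_if(is.null(xy) || nrow(xy) < 4 || anyNA(xy),
             sprintf("feature '%s' has invalid geometry", ids[i]))
    verts[[i]] <- unique(paste(round(xy[, 1] / snap), round(xy[, 2] / snap)))
  }
  dup <- unique(ids[duplicated(ids)])
  abort_if(length(dup) > 0, "duplicate feature ids: ",
           paste(dup, collapse = ", "))
  need <- if (rule == "rook") 2L else 1L
  pairs <- NULL
  n <- length(ids)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (length(intersect(verts[[i]], verts[[j]])) >= need)
        pairs <- rbind(pairs, c(ids[i], ids[j]))
    }
  }
  if (is.null(pairs)) {
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = ids)
    warning("no adjacent polygons found", call. = FALSE)
    return(g)
  }
  suppressWarnings(edges_graph(pairs, ids))
}

#' Write a regionalization and reports to an output directory
#'
#' Writes `assignments.csv` (`unit_id,region`), and when supplied:
#' `metrics.json` (cluster-quality report), `importance.csv` (random-forest
#' variable importances), `selection_curve.csv` (SSW-vs-k curves) and
#' `partition.json` (response variance partition). Reading the assignment CSV
#' back with [read_assignments()] reproduces the unit-to-region map exactly.
#'
#' @param regionalization a [regionalization] object.
#' @param out_dir output directory, created if absent.
#' @param quality optional cluster-quality report from
#'   [evaluate_regionalization()].
#' @param importance optional importance table from
#'   [region_variable_importance()].
#' @param curve optional selection curve from [ssw_vs_k_curves()].
#' @param partition optional report from [partition_response_variance()].
#' @return invisibly, the vector of file paths written.
#' @export
export_results <- function(regionalization, out_dir, quality = NULL,
                           importance = NULL, curve = NULL, partition = NULL) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  abort_if(!ok, "cannot create output directory: ", out_dir)
  written <- character(0)
  f <- file.path(out_dir, "assignments.csv")
  write.csv(data.frame(unit_id = regionalization$unit_id,
                       region = regionalization$label),
            f, row.names = FALSE, quote = FALSE)
  written <- c(written, f)
  if (!is.null(quality)) {
    f <- file.path(out_dir, "metrics.json")
    jsonlite::write_json(unclass(quality), f, auto_unbox = TRUE, digits = NA)
    written <- c(written, f)
  }
  if (!is.null(importance)) {
    f <- file.path(out_dir, "importance.csv")
    write.csv(as.data.frame(unclass(importance)[c("variable_name",
                                                  "importance")]),
              f, row.names = FALSE, quote = FALSE)
    written <- c(written, f)
  }
  if (!is.null(curve)) {
    f <- file.path(out_dir, "selection_curve.csv")
    write.csv(selection_curve_frame(curve), f, row.names = FALSE,
              quote = FALSE)
    written <- c(written, f)
  }
  if (!is.null(partition)) {
    f <- file.path(out_dir, "partition.json")
    jsonlite::write_json(unclass(partition), f, auto_unbox = TRUE, digits = NA)
    written <- c(written, f)
  }
  invisible(written)
}

#' Read a region-assignment CSV written by [export_results()]
#'
#' @param path path to a CSV with columns `unit_id,region`.
#' @return a [regionalization] object (provenance records only the file).
#' @export
read_assignments <- function(path) {
  df <- read.csv(path, check.names = FALSE, colClasses = c("character", "integer"))
  abort_if(!all(c("unit_id", "region") %in% names(df)),
           "assignment CSV needs columns 'unit_id' and 'region'")
  regionalization(df$unit_id, df$region,
                  provenance = list(method = "file", path = path))
}

#' Read a point-response table (e.g. lakes) from CSV
#'
#' Columns: `point_id`, `unit_id`, then one numeric column per response
#' (total phosphorus in ug/L, Secchi depth in m, ...). Empty cells are
#' missing responses.
#'
#' @param path path to the CSV.
#' @return a data.frame of class `response_table`.
#' @export
read_responses <- function(path) {
  df <- read.csv(path, check.names = FALSE, na.strings = "")
  abort_if(!all(c("point_id", "unit_id") %in% names(df)),
           "response CSV needs columns 'point_id' and 'unit_id'")
  df$point_id <- as.character(df$point_id)
  df$unit_id <- as.character(df$unit_id)
  dup <- unique(df$point_id[duplicated(df$point_id)])
  abort_if(length(dup) > 0, "duplicate point ids: ",
           paste(head(dup, 5), collapse = ", "))
  class(df) <- c("response_table", "data.frame")
  df
}
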