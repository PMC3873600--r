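# VTK legacy ASCII polydata export/import for tract models, with
# per-vertex scalar arrays (spoke lengths, areas, statistics, cluster
# ids) carried as POINT_DATA FIELD arrays.

#' Write a tract model as VTK legacy ASCII polydata
#'
#' Emits POINTS, POLYGONS, and a POINT_DATA FIELD block containing the
#' model's spoke lengths and vertex areas plus any extra per-vertex
#' scalars supplied. A JSON sidecar (same path with `.json` appended)
#' records provenance: parameters, grid geometry, and a content hash.
#'
#' @param model a `tract_model`.
#' @param path output `.vtk` path.
#' @param scalars named list of extra per-vertex numeric vectors.
#' @param provenance named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_vtk_model <- function(model, path, scalars = list(), provenance = list()) {
  stopifnot(inherits(model, "tract_model"))
  v <- model$vertices; tri <- model$triangles
  arrays <- c(list(spoke_length_plus = model$spoke_lengths[, 1],
                   spoke_length_minus = model$spoke_lengths[, 2],
                   vertex_area = model$vertex_area,
                   normal_x = model$normals[, 1],
                   normal_y = model$normals[, 2],
                   normal_z = model$normals[, 3],
                   spoke_plus_x = model$spokes[, 1, 1],
                   spoke_plus_y = model$spokes[, 2, 1],
                   spoke_plus_z = model$spokes[, 3, 1],
                   spoke_minus_x = model$spokes[, 1, 2],
                   spoke_minus_y = model$spokes[, 2, 2],
                   spoke_minus_z = model$spokes[, 3, 2],
                   vertex_depth = model$vertex_depth),
              scalars)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0",
     "tractfa skeleton model", "ASCII", "DATASET POLYDATA",
     sprintf("POINTS %d float", nrow(v)))
  wl(apply(format(v, digits = 9, trim = TRUE, scientific = FALSE), 1,
           paste, collapse = " "))
  wl(sprintf("POLYGONS %d %d", nrow(tri), 4L * nrow(tri)))
  wl(paste(3L, tri[, 1] - 1L, tri[, 2] - 1L, tri[, 3] - 1L))
  wl(sprintf("POINT_DATA %d", nrow(v)),
     sprintf("FIELD model_data %d", length(arrays)))
  for (nm in names(arrays)) {
    a <- as.numeric(arrays[[nm]])
    if (length(a) != nrow(v))
      abort("write_vtk_model: array '", nm, "' has wrong length")
    wl(sprintf("%s 1 %d float", nm, length(a)))
    wl(paste(format(a, digits = 9, trim = TRUE, scientific = TRUE),
             collapse = " "))
  }
  sidecar <- c(list(format = "tractfa-model",
                    n_vertices = nrow(v), n_triangles = nrow(tri),
                    spacing = model$spacing, origin = model$origin,
                    grid_dims = model$grid_dims, params = model$params),
               provenance)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a tract model written by [write_vtk_model()]
#'
#' @param path `.vtk` path (expects the JSON sidecar alongside).
#' @return a `tract_model`; extra scalar arrays appear in
#'   `$extra_scalars`.
#' @export
read_vtk_model <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  np <- as.integer(strsplit(lines[ip], " +")[[1]][2])
  v <- matrix(scan(text = lines[(ip + 1):(ip + np)], quiet = TRUE),
              ncol = 3, byrow = TRUE)
  it <- grep("^POLYGONS", lines)[1]
  nt <- as.integer(strsplit(lines[it], " +")[[1]][2])
  tri <- matrix(scan(text = lines[(it + 1):(it + nt)], quiet = TRUE),
                ncol = 4, byrow = TRUE)[, 2:4, drop = FALSE] + 1L
  storage.mode(tri) <- "integer"
  ifd <- grep("^FIELD", lines)[1]
  nf <- as.integer(strsplit(lines[ifd], " +")[[1]][3])
  arrays <- list()
  cur <- ifd + 1L
  for (f in seq_len(nf)) {
    hd <- strsplit(trimws(lines[cur]), " +")[[1]]
    nm <- hd[1]; len <- as.integer(hd[3])
    vals <- numeric(0)
    cur <- cur + 1L
    while (length(vals) < len) {
      vals <- c(vals, scan(text = lines[cur], quiet = TRUE))
      cur <- cur + 1L
    }
    arrays[[nm]] <- vals
  }
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path) else list()
  spokes <- array(NA_real_, c(np, 3L, 2L),
                  dimnames = list(NULL, NULL, c("plus", "minus")))
  spokes[, , 1] <- cbind(arrays$spoke_plus_x, arrays$spoke_plus_y,
                         arrays$spoke_plus_z)
  spokes[, , 2] <- cbind(arrays$spoke_minus_x, arrays$spoke_minus_y,
                         arrays$spoke_minus_z)
  core <- c("spoke_length_plus", "spoke_length_minus", "vertex_area",
            "normal_x", "normal_y", "normal_z", "vertex_depth",
            "spoke_plus_x", "spoke_plus_y", "spoke_plus_z",
            "spoke_minus_x", "spoke_minus_y", "spoke_minus_z")
  model <- structure(list(
    vertices = v, triangles = tri, edges = triangle_edges(tri),
    normals = cbind(arrays$normal_x, arrays$normal_y, arrays$normal_z),
    spokes = spokes,
    spoke_lengths = cbind(plus = arrays$spoke_length_plus,
                          minus = arrays$spoke_length_minus),
    vertex_area = arrays$vertex_area,
    vertex_depth = arrays$vertex_depth,
    spacing = as.numeric(unlist(side$spacing %||% c(1, 1, 1))),
    origin = as.numeric(unlist(side$origin %||% c(0, 0, 0))),
    grid_dims = as.integer(unlist(side$grid_dims %||% rep(NA_integer_, 3))),
    params = side$params %||% list(),
    extra_scalars = arrays[setdiff(names(arrays), core)]
  ), class = "tract_model")
  model
}
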