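#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`,
#' and restores the previous state on exit. All stochastic operations in
#' the package route their seeds through this helper so that a fixed seed
#' yields bit-identical output regardless of surrounding RNG use.
#'
#' @param seed integer scalar.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# spawn k child seeds from one parent seed, each < 2^31
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

abort <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' 3-D scalar volume with world geometry
#'
#' Lightweight container pairing a 3-D array with its voxel spacing (mm)
#' and world origin (mm). World coordinates of voxel `(i, j, k)`
#' (1-based) are `origin + (c(i, j, k) - 1) * spacing`; axes are assumed
#' world-aligned.
#'
#' @param data numeric or logical 3-D array.
#' @param spacing positive length-3 numeric, voxel edge lengths in mm.
#' @param origin length-3 numeric, world position of the first voxel
#'   center in mm.
#' @return an object of class `volume3d` with fields `data`, `spacing`,
#'   `origin`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) abort("volume3d: `data` must be a 3-D array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    abort("volume3d: spacing must be positive and finite")
  origin <- rep_len(as.numeric(origin), 3L)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d %dx%dx%d, spacing %s mm, origin %s mm>\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ",")))
  invisible(x)
}

as_volume3d <- function(x) {
  if (inherits(x, "volume3d")) return(x)
  abort("expected a volume3d object")
}

# world coordinates (n x 3) of 1-based voxel index matrix
voxel_to_world <- function(idx, vol) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep(sweep(idx - 1, 2L, vol$spacing, "*"), 2L, vol$origin, "+")
}

# continuous 0-based voxel coordinates of world points (n x 3)
world_to_voxel <- function(pts, vol) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  sweep(sweep(pts, 2L, vol$origin, "-"), 2L, vol$spacing, "/")
}

# shift a 3-D array by `dr` voxels (any integer) along axis `ax`,
# padding with `fill`
shift3d <- function(a, ax, dr, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  n <- d[ax]
  k <- abs(dr)
  if (k >= n) return(out)
  src <- dst <- lapply(d, seq_len)
  if (dr > 0) { dst[[ax]] <- (k + 1):n; src[[ax]] <- 1:(n - k) }
  else        { dst[[ax]] <- 1:(n - k); src[[ax]] <- (k + 1):n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# binary dilation / erosion with the 6-neighbourhood structuring element
dilate6 <- function(mask) {
  out <- mask
  for (ax in 1:3) for (dr in c(-1, 1))
    out <- out | shift3d(mask, ax, dr, FALSE)
  out
}

erode6 <- function(mask) {
  out <- mask
  for (ax in 1:3) for (dr in c(-1, 1))
    out <- out & shift3d(mask, ax, dr, FALSE)
  out
}

# 6-connected component labels of a logical 3-D array (0 = background)
label_components6 <- function(mask) {
  d <- dim(mask)
  n <- prod(d)
  idx <- which(mask)
  if (length(idx) == 0L) return(array(0L, d))
  edges <- grid_edges6(mask)
  lab <- cpp_label_components(n, edges, as.vector(mask))
  out <- array(0L, d)
  out[idx] <- lab[idx]
  out
}

# edge list (E x 2, 1-based linear indices) between 6-adjacent TRUE voxels
grid_edges6 <- function(mask) {
  d <- dim(mask)
  lin <- array(seq_len(prod(d)), d)
  e <- list()
  for (ax in 1:3) {
    sel_a <- sel_b <- lapply(d, seq_len)
    sel_a[[ax]] <- 1:(d[ax] - 1)
    sel_b[[ax]] <- 2:d[ax]
    a <- lin[sel_a[[1]], sel_a[[2]], sel_a[[3]]]
    b <- lin[sel_b[[1]], sel_b[[2]], sel_b[[3]]]
    keep <- mask[a] & mask[b]
    e[[ax]] <- cbind(a[keep], b[keep])
  }
  m <- do.call(rbind, e)
  storage.mode(m) <- "integer"
  m
}

n_components6 <- function(mask) {
  lab <- label_components6(mask)
  length(setdiff(unique(as.vector(lab)), 0L))
}

# md5 of a serialized R object, via a temporary file (tools::md5sum)
object_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tf))
}
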