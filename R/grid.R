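#' Spatial grid specification
#'
#' Defines the regular longitude/latitude lattice shared by every stage of the
#' pipeline. Cells are indexed row-major from the north-west corner (row 1 is
#' the northernmost band); cell centres sit at
#' `lon_min + (col - 0.5) * cell_size` and `lat_max - (row - 0.5) * cell_size`.
#' `total_cells` (TC) counts land cells only.
#'
#' @param lon_min,lon_max,lat_min,lat_max bounding box, decimal degrees.
#' @param cell_size cell edge in degrees (default 0.1).
#' @param land_mask logical matrix (`n_rows` x `n_cols`), `TRUE` on land. If
#'   `NULL`, all cells are land.
#' @return an object of class `grid_spec`.
#' @export
build_grid <- function(lon_min, lon_max, lat_min, lat_max,
                       cell_size = 0.1, land_mask = NULL) {
  if (lon_max <= lon_min || lat_max <= lat_min) {
    stop("inverted bounding box: require lon_min < lon_max and lat_min < lat_max")
  }
  if (cell_size <= 0) stop("cell_size must be positive")
  n_cols <- as.integer(round((lon_max - lon_min) / cell_size))
  n_rows <- as.integer(round((lat_max - lat_min) / cell_size))
  if (n_rows < 1L || n_cols < 1L) stop("bounding box smaller than one cell")
  if (is.null(land_mask)) {
    land_mask <- matrix(TRUE, n_rows, n_cols)
  }
  if (!is.matrix(land_mask) || !identical(dim(land_mask), c(n_rows, n_cols))) {
    stop(sprintf("land mask dimension mismatch: expected %d x %d", n_rows, n_cols))
  }
  storage.mode(land_mask) <- "logical"
  g <- structure(list(
    lon_min = lon_min, lon_max = lon_max,
    lat_min = lat_min, lat_max = lat_max,
    cell_size = cell_size,
    n_rows = n_rows, n_cols = n_cols,
    land_mask = land_mask,
    total_cells = sum(land_mask)
  ), class = "grid_spec")
  if (g$total_cells < 1L) stop("grid has no land cells")
  g
}

#' @exportS3Method base::print
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g deg, %d land cells (TC)\n",
              x$n_rows, x$n_cols, x$cell_size, x$total_cells))
  cat(sprintf("  lon [%g, %g], lat [%g, %g]\n",
              x$lon_min, x$lon_max, x$lat_min, x$lat_max))
  invisible(x)
}

#' Cell-centre coordinates
#'
#' @param grid a `grid_spec`.
#' @param land_only if `TRUE` return land cells only.
#' @return data frame with columns `row`, `col`, `lon`, `lat`.
#' @export
cell_centers <- function(grid, land_only = FALSE) {
  idx <- expand.grid(row = seq_len(grid$n_rows), col = seq_len(grid$n_cols))
  out <- data.frame(
    row = idx$row, col = idx$col,
    lon = grid$lon_min + (idx$col - 0.5) * grid$cell_size,
    lat = grid$lat_max - (idx$row - 0.5) * grid$cell_size
  )
  if (land_only) out <- out[grid$land_mask[cbind(out$row, out$col)], , drop = FALSE]
  out
}

#' Locate points on the grid
#'
#' Cells are half-open: `[lon, lon + cs)` in longitude and `(lat - cs, lat]`
#' in latitude, so each point maps to exactly one cell.
#'
#' @param grid a `grid_spec`.
#' @param lon,lat point coordinates, degrees.
#' @return integer matrix with columns `row`, `col`.
#' @export
locate_cells <- function(grid, lon, lat) {
  col <- floor((lon - grid$lon_min) / grid$cell_size) + 1L
  row <- ceiling((grid$lat_max - lat) / grid$cell_size)
  row[lat == grid$lat_max] <- 1L
  bad <- col < 1L | col > grid$n_cols | row < 1L | row > grid$n_rows
  if (any(bad)) stop(sprintf("%d point(s) fall outside the grid", sum(bad)))
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Rasterize camp locations into a presence grid
#'
#' A land cell is marked present when its centre lies within `buffer_km`
#' great-circle kilometres of at least one (non-excluded) camp. The buffer
#' represents the unit area of land a camp exploits for subsistence; the union
#' over camps is taken, so overlapping buffers are not double-counted, and
#' water cells are never presences.
#'
#' @param camps data frame with columns `lon`, `lat` and optionally `excluded`.
#' @param grid a `grid_spec`.
#' @param buffer_km buffer radius in km (default 20).
#' @return a `presence_grid`: list with `grid`, logical matrix `presence`, and
#'   count `n_presence` (PP).
#' @export
rasterize_presences <- function(camps, grid, buffer_km = 20) {
  if (!is.null(camps$excluded)) camps <- camps[!as.logical(camps$excluded), , drop = FALSE]
  presence <- matrix(FALSE, grid$n_rows, grid$n_cols)
  if (nrow(camps) == 0L) {
    warning("no camps after exclusion filter; presence grid is empty")
    return(new_presence_grid(grid, presence))
  }
  locate_cells(grid, camps$lon, camps$lat)  # errors if any camp outside grid
  cc <- cell_centers(grid, land_only = TRUE)
  hit <- rep(FALSE, nrow(cc))
  for (k in seq_len(nrow(camps))) {
    d <- geosphere::distHaversine(c(camps$lon[k], camps$lat[k]),
                                  cbind(cc$lon, cc$lat), r = 6371000)
    hit <- hit | (d <= buffer_km * 1000)
  }
  presence[cbind(cc$row, cc$col)] <- hit
  new_presence_grid(grid, presence)
}

new_presence_grid <- function(grid, presence) {
  stopifnot(identical(dim(presence), dim(grid$land_mask)))
  presence <- presence & grid$land_mask
  structure(list(grid = grid, presence = presence, n_presence = sum(presence)),
            class = "presence_grid")
}

#' @exportS3Method base::print
print.presence_grid <- function(x, ...) {
  cat(sprintf("presence_grid: %d presence cells (PP) of %d land cells (TC)\n",
              x$n_presence, x$grid$total_cells))
  invisible(x)
}

#' Environmental layer stack across time slices
#'
#' Bundles one or more named environmental rasters per time slice (age in
#' years BP). Emulating the paleoclimate reconstruction the pipeline targets,
#' ages step by 1,000 years up to 21,000 BP and by 2,000 years beyond that,
#' but any strictly increasing age vector is accepted.
#'
#' @param grid a `grid_spec`.
#' @param ages numeric vector of years BP, strictly increasing, `>= 0`.
#' @param slices list (one element per age) of named lists of matrices, each
#'   matrix `n_rows` x `n_cols`.
#' @return an object of class `layer_stack`.
#' @export
layer_stack <- function(grid, ages, slices) {
  ages <- as.numeric(ages)
  if (length(ages) != length(slices)) stop("ages and slices lengths differ")
  if (any(ages < 0)) stop("ages must be non-negative (years BP)")
  if (is.unsorted(ages, strictly = TRUE)) stop("ages must be strictly increasing")
  for (k in seq_along(slices)) {
    nm <- names(slices[[k]])
    if (is.null(nm) || anyDuplicated(nm)) stop("layer names must be unique per slice")
    for (lay in slices[[k]]) {
      if (!identical(dim(lay), dim(grid$land_mask))) {
        stop(sprintf("layer dimension mismatch at age %g", ages[k]))
      }
    }
  }
  structure(list(grid = grid, ages = ages, slices = slices), class = "layer_stack")
}

#' Extract one time slice from a stack
#'
#' @param stack a `layer_stack`.
#' @param age years BP; must match one of `stack$ages` exactly.
#' @return named list of layer matrices.
#' @export
get_slice <- function(stack, age) {
  k <- match(age, stack$ages)
  if (is.na(k)) stop(sprintf("no slice at age %g BP", age))
  stack$slices[[k]]
}

#' Round an age to the nearest available slice
#'
#' Exact midpoints round toward the younger (smaller BP) slice.
#'
#' @param stack a `layer_stack`.
#' @param age_bp years BP.
#' @return the matched slice age, or `NA` if outside the stack's age range
#'   extended by half a step on each end.
#' @export
nearest_slice_age <- function(stack, age_bp) {
  ages <- stack$ages
  vapply(age_bp, function(a) {
    d <- abs(ages - a)
    k <- which(d == min(d))
    k <- k[1L]  # ties: younger slice (ages increasing, first hit is younger)
    half <- if (length(ages) > 1L) max(diff(ages)) / 2 else Inf
    if (d[k] > half) NA_real_ else ages[k]
  }, numeric(1))
}

#' Read a camp table from CSV
#'
#' Expected header: `id,lon,lat,population_size,excluded` (the last two
#' optional).
#'
#' @param path CSV file path.
#' @return data frame of camp records.
#' @export
read_camps <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "lon", "lat")
  if (!all(need %in% names(df))) {
    stop("camps CSV must have columns id, lon, lat")
  }
  if (is.null(df$excluded)) df$excluded <- FALSE
  if (!is.null(df$population_size) && any(df$population_size < 0, na.rm = TRUE)) {
    stop("population_size must be non-negative")
  }
  df
}

#' Serialize / read a layer stack as long-format CSV
#'
#' Plain-text round trip for stacks: columns `age_bp, layer, row, col, value`.
#' Water cells are written as well so the round trip is exact.
#'
#' @param stack a `layer_stack`.
#' @param path output CSV path.
#' @export
write_stack_csv <- function(stack, path) {
  rows <- lapply(seq_along(stack$ages), function(k) {
    sl <- stack$slices[[k]]
    do.call(rbind, lapply(names(sl), function(nm) {
      m <- sl[[nm]]
      data.frame(age_bp = stack$ages[k], layer = nm,
                 row = as.vector(row(m)), col = as.vector(col(m)),
                 value = as.vector(m))
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

#' @rdname write_stack_csv
#' @param grid the `grid_spec` the stack conforms to.
#' @export
read_stack_csv <- function(path, grid) {
  df <- utils::read.csv(path)
  ages <- sort(unique(df$age_bp))
  slices <- lapply(ages, function(a) {
    sub <- df[df$age_bp == a, ]
    sl <- lapply(split(sub, sub$layer), function(s) {
      m <- matrix(NA_real_, grid$n_rows, grid$n_cols)
      m[cbind(s$row, s$col)] <- s$value
      m
    })
    sl
  })
  layer_stack(grid, ages, slices)
}
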