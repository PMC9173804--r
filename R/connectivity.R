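#' Predicted camp count from a presence-cell count
#'
#' The presence raster inflates camp numbers because every cell within the
#' subsistence buffer of a camp is a presence; the observed camp-to-cell
#' ratio converts back. Rounds half-up.
#'
#' @param pp presence-cell count PP_T.
#' @param ratio camps per presence cell (default 0.16).
#' @return integer camp count.
#' @export
expected_camp_count <- function(pp, ratio = 0.16) {
  stopifnot(pp >= 0, ratio >= 0)
  as.integer(floor(pp * ratio + 0.5))
}

#' Randomly place camps on presence cells
#'
#' Uniform sample without replacement of `n` presence cells; reproducible
#' given `seed`.
#'
#' @param presence a `presence_grid`.
#' @param n number of camps.
#' @param seed integer seed.
#' @return a `camp_set`: list with `cells` (linear cell indices into the grid
#'   matrix), `n`, `seed`.
#' @export
place_camps <- function(presence, n, seed = 1) {
  idx <- which(presence$presence)
  if (n > length(idx)) stop("more camps requested than presence cells")
  set.seed(seed)
  cells <- if (n == length(idx)) idx else sample(idx, n)
  structure(list(cells = sort(cells), n = n, seed = seed,
                 grid = presence$grid), class = "camp_set")
}

#' Tobler's hiking function
#'
#' Walking speed as a function of slope (rise over run, signed in the
#' direction of travel): `W = 6 exp(-3.5 |S + 0.05|)` km/h. Maximum speed
#' 6 km/h on a gentle -5% downhill; about 5.04 km/h on the flat; symmetric
#' about S = -0.05, hence direction-dependent on sloped ground.
#'
#' @param slope rise/run, dimensionless; vectorized.
#' @return speed in km/h, in (0, 6\].
#' @export
tobler_speed <- function(slope) {
  6 * exp(-3.5 * abs(slope + 0.05))
}

km_per_deg_lat <- function() pi * 6371 / 180

#' Build the anisotropic travel-time graph over a grid
#'
#' Nodes are traversable cells; directed edges join 8-neighbours, weighted by
#' walking time: horizontal step length (km, E-W steps scaled by cos of
#' latitude) divided by [tobler_speed()] of the elevation grade in the
#' direction of travel. Uphill and downhill edges between the same pair of
#' cells therefore carry different weights. Water cells are impassable by
#' default, or traversable with a fixed crossing penalty (hours) added to
#' every edge entering a water cell.
#'
#' @param grid a `grid_spec`.
#' @param dem elevation matrix, metres.
#' @param water_mask logical matrix, `TRUE` = water.
#' @param water_penalty_hours `Inf` (default) makes water impassable; a
#'   finite value makes each step into a water cell cost that many extra
#'   hours.
#' @return a `travel_graph`: list with the igraph object, the vector of cell
#'   indices present as nodes, and a lookup from cell index to node id.
#' @export
build_travel_graph <- function(grid, dem, water_mask = NULL,
                               water_penalty_hours = Inf) {
  nr <- grid$n_rows; nc <- grid$n_cols
  stopifnot(identical(dim(dem), c(nr, nc)))
  if (is.null(water_mask)) water_mask <- matrix(FALSE, nr, nc)
  passable <- grid$land_mask | (!is.infinite(water_penalty_hours) & water_mask)
  if (is.infinite(water_penalty_hours)) passable <- passable & !water_mask
  cells <- which(passable)
  node_of <- integer(nr * nc)
  node_of[cells] <- seq_along(cells)
  rows <- ((cells - 1L) %% nr) + 1L
  cols <- ((cells - 1L) %/% nr) + 1L
  lat <- grid$lat_max - (rows - 0.5) * grid$cell_size
  kmlat <- km_per_deg_lat() * grid$cell_size
  offsets <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
                   c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (k in seq_len(nrow(offsets))) {
    dr <- offsets[k, 1]; dc <- offsets[k, 2]
    r2 <- rows + dr; c2 <- cols + dc
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    tgt <- (c2[ok] - 1L) * nr + r2[ok]
    ok2 <- node_of[tgt] > 0L
    src_cell <- cells[ok][ok2]; tgt_cell <- tgt[ok2]
    if (!length(src_cell)) next
    mid_lat <- (lat[ok][ok2] + (grid$lat_max - (r2[ok][ok2] - 0.5) * grid$cell_size)) / 2
    dy <- abs(dr) * kmlat
    dx <- abs(dc) * kmlat * cos(mid_lat * pi / 180)
    dist_km <- sqrt(dx^2 + dy^2)
    grade <- (dem[tgt_cell] - dem[src_cell]) / (dist_km * 1000)
    hours <- dist_km / tobler_speed(grade)
    if (!is.infinite(water_penalty_hours)) {
      hours <- hours + water_penalty_hours * water_mask[tgt_cell]
    }
    from <- c(from, node_of[src_cell]); to <- c(to, node_of[tgt_cell])
    w <- c(w, hours)
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  if (igraph::vcount(g) < length(cells)) {
    g <- igraph::add_vertices(g, length(cells) - igraph::vcount(g))
  }
  igraph::E(g)$weight <- w
  structure(list(graph = g, cells = cells, node_of = node_of, grid = grid),
            class = "travel_graph")
}

#' Accumulated walking-time field around a source cell
#'
#' Shortest anisotropic walking time (hours) from the source to every cell,
#' by Dijkstra's algorithm on the travel graph; unreachable and impassable
#' cells are `Inf`. Times beyond `cap_hours` are reported as `Inf` when a cap
#' is given.
#'
#' @param tg a `travel_graph`.
#' @param source_cell linear cell index of the source.
#' @param cap_hours optional cap (default 7); `NULL` for no cap.
#' @return a `travel_time_field`: list with `hours` matrix and `source`.
#' @export
accumulated_cost <- function(tg, source_cell, cap_hours = 7) {
  v <- tg$node_of[source_cell]
  if (v == 0L) stop("source cell is not traversable (water or off-land)")
  d <- as.numeric(igraph::distances(tg$graph, v = v, mode = "out"))
  hours <- matrix(Inf, tg$grid$n_rows, tg$grid$n_cols)
  hours[tg$cells] <- d
  if (!is.null(cap_hours)) hours[hours > cap_hours] <- Inf
  structure(list(hours = hours, source = source_cell, cap = cap_hours),
            class = "travel_time_field")
}

#' Camp connectivity within a walking-time cap
#'
#' For each camp, counts the other camps reachable within `cap_hours` of
#' outbound walking (anisotropic, so A reaching B does not imply B reaching
#' A).
#'
#' @param camps a `camp_set`.
#' @param tg a `travel_graph` over the same grid.
#' @param cap_hours walking-time cap (default 7).
#' @return a `connectivity_result`: data frame with `cell`, `neighbors`;
#'   attributes `mean`, `median`, `max`.
#' @export
count_neighbors <- function(camps, tg, cap_hours = 7) {
  stopifnot(camps$n >= 1)
  nodes <- tg$node_of[camps$cells]
  if (any(nodes == 0L)) stop("some camps sit on non-traversable cells")
  tt <- igraph::distances(tg$graph, v = nodes, to = nodes, mode = "out")
  within <- tt <= cap_hours
  diag(within) <- FALSE
  counts <- rowSums(within)
  out <- data.frame(cell = camps$cells, neighbors = as.integer(counts))
  attr(out, "mean") <- mean(counts)
  attr(out, "median") <- stats::median(counts)
  attr(out, "max") <- max(counts)
  class(out) <- c("connectivity_result", class(out))
  out
}

#' Per-slice connectivity summary across a range series
#'
#' Chains the camp-count rule, random placement and neighbour counting for
#' every time slice of a predicted range series over a fixed landscape.
#'
#' @param model a `niche_model`.
#' @param stack a `layer_stack`.
#' @param tg a `travel_graph` on the same grid.
#' @param tau decision threshold (default the model's).
#' @param ratio camps per presence cell (default 0.16).
#' @param cap_hours walking-time cap (default 7).
#' @param seed integer seed for camp placement.
#' @return data frame with `age_bp`, `pp`, `n_camps`, `mean_neighbors`,
#'   `median_neighbors`, `max_neighbors`.
#' @export
connectivity_series <- function(model, stack, tg, tau = model$tau,
                                ratio = 0.16, cap_hours = 7, seed = 1) {
  rows <- lapply(seq_along(stack$ages), function(k) {
    s <- project_slice(model, stack$slices[[k]], stack$grid, age = stack$ages[k])
    pg <- binarize(s, tau)
    n <- expected_camp_count(pg$n_presence, ratio)
    if (n < 1 || pg$n_presence < 1) {
      return(data.frame(age_bp = stack$ages[k], pp = pg$n_presence, n_camps = n,
                        mean_neighbors = NA_real_, median_neighbors = NA_real_,
                        max_neighbors = NA_real_))
    }
    traversable <- pg$presence & (tg$node_of[seq_along(pg$presence)] > 0L)
    dim(traversable) <- dim(pg$presence)
    pg2 <- new_presence_grid(pg$grid, traversable)
    n <- min(n, pg2$n_presence)
    camps <- place_camps(pg2, n, seed = seed + k)
    cr <- count_neighbors(camps, tg, cap_hours)
    data.frame(age_bp = stack$ages[k], pp = pg$n_presence, n_camps = n,
               mean_neighbors = attr(cr, "mean"),
               median_neighbors = attr(cr, "median"),
               max_neighbors = attr(cr, "max"))
  })
  do.call(rbind, rows)
}
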