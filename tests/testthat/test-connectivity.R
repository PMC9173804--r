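test_that("camp counts follow the ratio rule with half-up rounding", {
  expect_equal(expected_camp_count(100), 16L)
  expect_equal(expected_camp_count(10), 2L)   # round(1.6) up
  expect_equal(expected_camp_count(0), 0L)
  # consistency identity: the observed ratio re-applied returns the camps
  expect_equal(expected_camp_count(4577, 749 / 4577), 749L)
  expect_equal(round(749 / 4577, 2), 0.16)
})

test_that("camp placement is exhaustive at n = PP, seeded, and uniform", {
  w <- shared_world()
  s <- project_slice(w$model, get_slice(w$truth$stack, 0), w$truth$grid)
  pg <- binarize(s, 0.8)
  all_camps <- place_camps(pg, pg$n_presence, seed = 3)
  expect_setequal(all_camps$cells, which(pg$presence))
  expect_identical(place_camps(pg, 10, seed = 7)$cells,
                   place_camps(pg, 10, seed = 7)$cells)
  expect_error(place_camps(pg, pg$n_presence + 1), "more camps")

  # inclusion frequencies within the binomial 99% CI of n/PP
  gg <- equator_grid(5)
  pres <- paleoniche:::new_presence_grid(gg, matrix(TRUE, 5, 5))
  pp <- 25; n <- 5; draws <- 4000
  counts <- integer(pp)
  for (k in seq_len(draws)) {
    cells <- place_camps(pres, n, seed = 10000 + k)$cells
    counts[cells] <- counts[cells] + 1L
  }
  p <- n / pp
  ci <- draws * p + c(-1, 1) * qnorm(0.995) * sqrt(draws * p * (1 - p))
  expect_true(all(counts >= ci[1] & counts <= ci[2]))
})

test_that("Tobler speeds hit the closed form, maximum, and symmetry point", {
  expect_equal(tobler_speed(-0.05), 6)
  expect_equal(tobler_speed(0), 6 * exp(-0.175))
  expect_equal(tobler_speed(-0.15), tobler_speed(0.05))
  s <- seq(-1, 1, by = 0.01)
  expect_true(all(tobler_speed(s) > 0 & tobler_speed(s) <= 6))
})

test_that("flat-terrain travel times respect the octile bound on the closed form", {
  g <- equator_grid(40)
  d <- gen_dem(g, relief_amplitude = 0)
  tg <- build_travel_graph(g, d$dem, d$water)
  src_rc <- c(20, 20)
  src <- (src_rc[2] - 1) * g$n_rows + src_rc[1]
  f <- accumulated_cost(tg, src, cap_hours = NULL)
  cc <- cell_centers(g)
  dist_km <- haversine_km(cc$lon[src], cc$lat[src], cc$lon, cc$lat)
  hrs <- f$hours[cbind(cc$row, cc$col)]
  direct <- dist_km / tobler_speed(0)
  nonzero <- dist_km > 0
  ratio <- hrs[nonzero] / direct[nonzero]
  expect_true(all(ratio >= 1 - 1e-6))         # never faster than straight-line
  expect_true(all(ratio <= 1.082 + 5e-3))     # octile bound (plus lat distortion)
  expect_equal(f$hours[src_rc[1], src_rc[2]], 0)
})

test_that("slopes make travel anisotropic; flat terrain keeps it symmetric", {
  g <- equator_grid(10)
  ramp <- matrix(rep(seq(0, by = 600, length.out = 10), each = 10), 10, 10)
  tg <- build_travel_graph(g, ramp, matrix(FALSE, 10, 10))
  west <- 5 + 2 * 10   # row 5, col 3 (low side)
  east <- 5 + 7 * 10   # row 5, col 8 (high side)
  t_up <- accumulated_cost(tg, west, cap_hours = NULL)$hours[5, 8]
  t_down <- accumulated_cost(tg, east, cap_hours = NULL)$hours[5, 3]
  expect_lt(t_down, t_up)  # descending near the optimum grade beats climbing

  d <- gen_dem(g, relief_amplitude = 0)
  tgf <- build_travel_graph(g, d$dem, d$water)
  a <- 3 + 2 * 10; b <- 8 + 6 * 10
  expect_equal(accumulated_cost(tgf, a, NULL)$hours[8, 7],
               accumulated_cost(tgf, b, NULL)$hours[3, 3], tolerance = 1e-10)
})

test_that("water barriers block movement entirely when impassable", {
  g <- equator_grid(11)
  d <- gen_dem(g, relief_amplitude = 0)
  water <- matrix(FALSE, 11, 11)
  water[4:8, 4:8] <- TRUE
  water[5:7, 5:7] <- FALSE  # island inside a water ring
  tg <- build_travel_graph(g, d$dem, water)
  src <- 6 + 5 * 11  # row 6, col 6: island centre
  f <- accumulated_cost(tg, src, cap_hours = NULL)
  outside <- is.finite(f$hours)
  outside[5:7, 5:7] <- FALSE
  expect_false(any(outside))
  # a finite crossing penalty restores reachability, at a cost
  tg2 <- build_travel_graph(g, d$dem, water, water_penalty_hours = 5)
  f2 <- accumulated_cost(tg2, src, cap_hours = NULL)
  expect_true(all(is.finite(f2$hours)))
  expect_gt(f2$hours[1, 1], 10)  # two water entries en route
})

test_that("neighbor counts match flat-terrain closed forms", {
  g <- equator_grid(30)
  d <- gen_dem(g, relief_amplitude = 0)
  tg <- build_travel_graph(g, d$dem, d$water)
  # two camps two columns (~22 km) apart: 22.2 / 5.037 ~ 4.4 h < 7
  camps <- structure(list(cells = c(15 + 13 * 30, 15 + 15 * 30), n = 2,
                          seed = 1, grid = g), class = "camp_set")
  cr <- count_neighbors(camps, tg, cap_hours = 7)
  expect_equal(cr$neighbors, c(1L, 1L))
  single <- structure(list(cells = 15 + 13 * 30, n = 1, seed = 1, grid = g),
                      class = "camp_set")
  expect_equal(count_neighbors(single, tg)$neighbors, 0L)

  # an impassable river between two camps zeroes both counts
  dr <- gen_dem(g, river = list(orientation = "vertical", at = 15, width = 1))
  tgr <- build_travel_graph(g, dr$dem, dr$water)
  cr2 <- count_neighbors(camps, tgr, cap_hours = 7)
  expect_equal(cr2$neighbors, c(0L, 0L))
})

test_that("travel cost obeys the triangle inequality and cap monotonicity", {
  g <- equator_grid(15)
  d <- gen_dem(g, relief_amplitude = 300, corr_length = 4, seed = 9)
  tg <- build_travel_graph(g, d$dem, d$water)
  set.seed(15)
  cells <- sample(which(g$land_mask), 6)
  tt <- igraph::distances(tg$graph, v = tg$node_of[cells],
                          to = tg$node_of[cells], mode = "out")
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    expect_gte(tt[i, j] + tt[j, k] + 1e-9, tt[i, k])
  }
  camps <- structure(list(cells = cells, n = 6, seed = 1, grid = g),
                     class = "camp_set")
  n3 <- count_neighbors(camps, tg, cap_hours = 3)$neighbors
  n7 <- count_neighbors(camps, tg, cap_hours = 7)$neighbors
  expect_true(all(n7 >= n3))
})

test_that("the per-slice connectivity series chains the whole pipeline", {
  w <- shared_world()
  g <- w$truth$grid
  d <- gen_dem(g, relief_amplitude = 200, seed = 2)
  tg <- build_travel_graph(g, d$dem, d$water)
  st <- layer_stack(g, w$truth$stack$ages[1:3], w$truth$stack$slices[1:3])
  cs <- connectivity_series(w$model, st, tg, ratio = 0.16, seed = 5)
  expect_equal(nrow(cs), 3)
  expect_true(all(cs$n_camps <= cs$pp))
  expect_true(all(cs$mean_neighbors >= 0, na.rm = TRUE))
  expect_true(all(cs$max_neighbors <= cs$n_camps - 1, na.rm = TRUE))
})
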