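toy_sites <- function() {
  data.frame(
    id = sprintf("s%d", 1:6),
    lon = runif(6, 0.2, 4.8), lat = runif(6, -2.3, 2.3),
    age_bp = c(3000, 5000, 7000, 2000, 4000, 6000),
    age_error = c(100, 1200, 200, 150, 90, 300),
    material = c("charcoal", "charcoal", "carbonate", "charcoal", "charcoal", "charcoal"),
    lab_code = c("L1", "L2", "L3", "", "L5", "L6"),
    stratigraphy_ok = TRUE,
    farming_indicators = c("", "", "", "", "iron_metallurgy", ""),
    chronoculture = c("MSA", "MSA", "MSA", "MSA", "LSA", "MSA"),
    has_lithics = TRUE, pottery = FALSE, disputed = FALSE,
    stringsAsFactors = FALSE
  )
}

test_that("date curation applies each removal rule and is idempotent", {
  set.seed(20)
  raw <- toy_sites()
  # rules hit: s2 error > 1000, s3 carbonate, s4 missing lab code,
  # s5 farming indicator -> s1, s6 survive
  cur <- filter_dates(raw)
  expect_setequal(cur$id, c("s1", "s6"))
  removed <- attr(cur, "removed")
  expect_equal(sum(removed), 4)
  expect_true(all(c("carbonate", "error_gt_max", "missing_lab_code",
                    "farming_indicator") %in% names(removed)))
  # idempotent: re-filtering the curated table removes nothing
  cur2 <- filter_dates(cur)
  expect_equal(cur2$id, cur$id)

  # farming chronocultures are excluded even without indicators
  raw$farming_indicators <- ""
  raw$chronoculture[6] <- "EarlyIronAge"
  expect_false("s6" %in% filter_dates(raw)$id)

  # sensitivity subsets
  raw2 <- toy_sites()
  raw2$pottery[1] <- TRUE
  expect_false("s1" %in% filter_dates(raw2, exclude_pottery = TRUE)$id)
  raw2$disputed[6] <- TRUE
  expect_false("s6" %in% filter_dates(raw2, exclude_disputed = TRUE)$id)
  raw2$has_lithics[1] <- FALSE
  expect_false("s1" %in% filter_dates(raw2, lithics_only = TRUE)$id)
})

test_that("deduplication keeps one date per coarse cell and slice", {
  w <- shared_world()
  st <- w$truth$stack
  base <- data.frame(
    id = c("a", "b", "c", "d"),
    lon = c(1.02, 1.08, 1.03, 3.5),    # a, b, c share a 0.5-deg cell
    lat = c(0.52, 0.58, 0.53, -1.2),
    age_bp = c(3000, 3100, 4000, 3000),  # a, b same slice; c next slice
    age_error = c(200, 100, 150, 80),
    stringsAsFactors = FALSE
  )
  dd <- dedupe_sites(base, st)
  # b beats a (smaller error) within the shared cell and slice; c and d kept
  expect_setequal(dd$id, c("b", "c", "d"))
  expect_equal(dd$slice_age[dd$id == "c"], 4000)
  # ties on error go to the earliest id
  base2 <- base
  base2$age_error <- c(100, 100, 150, 80)
  expect_true("a" %in% dedupe_sites(base2, st)$id)
})

test_that("expected site counts follow E_T = N_T * PP_T / TC", {
  expect_equal(expected_sites(7, 100, 100), 7)
  expect_equal(expected_sites(7, 0, 100), 0)
  expect_equal(expected_sites(10, 3628, 36277), 10 * 3628 / 36277)
  expect_error(expected_sites(5, 200, 100))
})

test_that("chi-square goodness of fit matches hand arithmetic", {
  expect_equal(chi_square_gof(23, 23, 118)$statistic, 0)
  # O=42, E=23, n=118: 19^2/23 + 19^2/95
  res <- chi_square_gof(42, 23, 118)
  expect_equal(res$statistic, 19^2 / 23 + 19^2 / 95)
  expect_equal(res$statistic, 19.496, tolerance = 1e-4)
  expect_equal(res$df, 1L)
  # doubling the deviation and both expecteds doubles the statistic
  expect_equal(chi_square_gof(84, 46, 236)$statistic, 2 * res$statistic)
  expect_error(chi_square_gof(5, 0, 10))
})

test_that("observed counts hit both degenerate extremes", {
  w <- shared_world()
  st <- w$truth$stack
  sites <- gen_archaeo_sites(w$truth, 40, mode = "signal", p_suit = 1,
                             suit_threshold = 0.5)
  # tau = 0 marks every land cell present -> O = n
  oc <- observed_count(sites, w$model, st, tau = 0)
  expect_equal(oc$O, oc$n)
  # tau = 1 leaves (almost surely) nothing present -> O = 0
  oc0 <- observed_count(sites, w$model, st, tau = 1)
  expect_equal(oc0$O, 0)
})

test_that("a time-constant landscape makes the permutation distribution degenerate", {
  w <- shared_world()
  g <- w$truth$grid
  env0 <- get_slice(w$truth$stack, 0)
  st_const <- layer_stack(g, c(0, 1000, 2000), rep(list(env0), 3))
  set.seed(21)
  sites <- data.frame(
    id = sprintf("s%d", 1:30),
    lon = runif(30, g$lon_min + 0.1, g$lon_max - 0.1),
    lat = runif(30, g$lat_min + 0.1, g$lat_max - 0.1),
    age_bp = sample(c(0, 1000, 2000), 30, replace = TRUE),
    age_error = 100, stringsAsFactors = FALSE
  )
  vr <- permute_dates(sites, w$model, st_const, w$model$tau,
                      n_perm = 50, seed = 2)
  expect_equal(sd(vr$perm_counts), 0)
  expect_equal(unique(vr$perm_counts), vr$O)
  expect_equal(vr$p_perm, 1)  # every permutation ties the observed count
})

test_that("planted date-suitability signal beats its permutation mean", {
  w <- shared_world()
  hits <- sapply(1:10, function(k) {
    sites <- gen_archaeo_sites(w$truth, 60, mode = "signal", p_suit = 0.8,
                               seed = 3000 + k)
    vr <- permute_dates(sites, w$model, w$truth$stack, w$model$tau,
                        n_perm = 60, seed = k)
    vr$O > vr$perm_mean
  })
  expect_gte(mean(hits), 0.9)
})

test_that("permutation counts and E agree with direct enumeration on a toy grid", {
  w <- shared_world()
  st <- w$truth$stack
  sites <- gen_archaeo_sites(w$truth, 25, mode = "null", seed = 77)
  vr <- permute_dates(sites, w$model, st, w$model$tau, n_perm = 30, seed = 9)
  # E equals the sum over slices of N_T * PP_T / TC computed independently
  slice_age <- nearest_slice_age(st, sites$age_bp)
  rc <- locate_cells(st$grid, sites$lon, sites$lat)
  E_direct <- 0
  for (a in sort(unique(slice_age))) {
    pg <- binarize(project_slice(w$model, get_slice(st, a), st$grid), w$model$tau)
    E_direct <- E_direct + sum(slice_age == a) * pg$n_presence / st$grid$total_cells
  }
  expect_equal(vr$E, E_direct, tolerance = 1e-12)
  expect_equal(length(vr$perm_counts), 30)
  expect_true(all(vr$perm_counts >= 0 & vr$perm_counts <= vr$n))
})

test_that("performance-age correlation recovers the closed-form point-biserial", {
  set.seed(22)
  n <- 60
  age <- runif(n, 0, 9000)
  ind <- as.numeric(age < median(age))
  # direct point-biserial formula: (M1 - M0)/s_y * sqrt(n1 n0 / (n (n-1)))
  n1 <- sum(ind); n0 <- n - n1
  r_direct <- (mean(age[ind == 1]) - mean(age[ind == 0])) / sd(age) *
    sqrt(n1 * n0 / (n * (n - 1)))
  expect_equal(cor(ind, age), r_direct, tolerance = 1e-10)
  expect_lt(r_direct, -0.5)

  w <- shared_world()
  sites <- gen_archaeo_sites(w$truth, 50, mode = "null", seed = 5)
  pa <- performance_vs_age(sites, w$model, w$truth$stack, w$model$tau)
  expect_lt(abs(pa$r), 3 / sqrt(50) + 0.15)  # independent by construction
  # constant indicator: undefined, flagged
  expect_warning(
    pa0 <- performance_vs_age(sites, w$model, w$truth$stack, tau = 0),
    "zero variance")
  expect_true(is.na(pa0$r))
})

test_that("the confounder screen flags copies and passes independent layers", {
  w <- shared_world()
  g <- w$truth$grid
  env <- get_slice(w$truth$stack, 0)
  expect_false(confounder_check(env, env$env1, g)$pass)
  expect_equal(confounder_check(env, env$env1, g)$max_abs_r, 1)
  set.seed(23)
  indep <- matrix(rnorm(g$n_rows * g$n_cols), g$n_rows, g$n_cols)
  res <- confounder_check(env, indep, g)
  expect_true(res$pass)
  expect_lt(res$max_abs_r, 0.15)
  # a layer tuned near r = 0.5 still passes
  half <- env$env1 + matrix(rnorm(g$n_rows * g$n_cols, sd = sd(env$env1) * sqrt(3)),
                            g$n_rows, g$n_cols)
  res2 <- confounder_check(env, half, g)
  expect_true(res2$pass)
  expect_gt(res2$max_abs_r, 0.3)
})
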