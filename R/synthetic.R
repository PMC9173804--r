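#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators with the defaults the
#' test-bed landscapes use: a 50 x 50 cell grid, 10 time slices, Gaussian
#' random fields with a 6-cell correlation length, a logistic true
#' suitability over two environmental fields, a wedge-shaped
#' density-suitability envelope with true upper slope 43, archaeological
#' site enrichment p_suit = 0.8, island-model differentiation F = 0.10 and
#' class-wise IBD sharing rates.
#'
#' @param seed integer master seed.
#' @param n_rows,n_cols grid dimensions (cells).
#' @param n_slices number of time slices.
#' @param corr_length spatial autocorrelation length, cells (correlation
#'   falls to 1/e at this lag).
#' @param drift temporal drift magnitude in (0, 1): the innovation weight of
#'   the stationary AR(1) evolution of each field across slices
#'   (`field_k = sqrt(1 - drift^2) * field_(k-1) + drift * innovation`);
#'   0 freezes the climate, 1 makes slices independent. The default 0.6
#'   (consecutive-slice correlation 0.8) lets environments decorrelate over a
#'   few slices, emulating the strong glacial-interglacial turnover of
#'   suitable areas.
#' @param beta0 intercept of the true suitability logit.
#' @param beta coefficients of the true suitability logit on the layers.
#' @param b_true true wedge upper slope, persons per suitability unit.
#' @param a_true small wedge offset, persons.
#' @param p_suit probability a signal-mode site falls in a suitable cell.
#' @param fst_true island-model differentiation F.
#' @param ibd_rates named sharing rates per length class.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_rows = 50, n_cols = 50, n_slices = 10,
                       corr_length = 6, drift = 0.6,
                       beta0 = -1, beta = c(env1 = 2.5, env2 = -1.5),
                       b_true = 43, a_true = 2, p_suit = 0.8,
                       fst_true = 0.10,
                       ibd_rates = c("1-5" = 0.5, "5-10" = 0.3, ">10" = 0.1)) {
  stopifnot(all(ibd_rates >= 0 & ibd_rates <= 1), p_suit >= 0, p_suit <= 1)
  structure(list(seed = seed, n_rows = n_rows, n_cols = n_cols,
                 n_slices = n_slices, corr_length = corr_length,
                 drift = drift, beta0 = beta0, beta = beta, b_true = b_true,
                 a_true = a_true, p_suit = p_suit, fst_true = fst_true,
                 ibd_rates = ibd_rates), class = "sim_config")
}

#' Stationary isotropic Gaussian random field
#'
#' White noise convolved (circularly, via FFT) with a Gaussian kernel whose
#' bandwidth is `corr_length / 2`, giving a field whose correlation function
#' is Gaussian and falls to `1/e` at lag `corr_length` cells. The output is
#' standardized to zero mean and unit variance.
#'
#' @param n_rows,n_cols field dimensions.
#' @param corr_length 1/e correlation lag, cells.
#' @return numeric matrix.
#' @export
gen_gaussian_field <- function(n_rows, n_cols, corr_length) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (corr_length <= 0) return(z)
  sdk <- corr_length / 2
  dr <- pmin(0:(n_rows - 1), n_rows - 0:(n_rows - 1))
  dc <- pmin(0:(n_cols - 1), n_cols - 0:(n_cols - 1))
  kern <- exp(-outer(dr^2, dc^2, "+") / (2 * sdk^2))
  f <- Re(stats::fft(stats::fft(z) * stats::fft(kern), inverse = TRUE))
  (f - mean(f)) / stats::sd(f)
}

#' Synthetic environmental stack with known true suitability
#'
#' Two spatially autocorrelated layers (`env1`, `env2`) evolve across slices
#' as a stationary AR(1) process with innovation weight `cfg$drift`, so
#' consecutive slices are similar but environments decorrelate over a few
#' slices and the suitable area shifts and turns over through time; the true
#' suitability of every slice is the logistic
#' `plogis(beta0 + beta1 * env1 + beta2 * env2)`. Ages follow the
#' paleoclimate convention: 1,000-year steps up to 21,000 BP, 2,000-year
#' steps beyond.
#'
#' @param cfg a `sim_config`.
#' @param land_frac fraction of cells on land (a random smooth mask; 1 = all
#'   land).
#' @return list with `stack` (a `layer_stack`), `true_suit` (list of
#'   matrices per slice), `grid`, and `cfg`.
#' @export
gen_landscape_stack <- function(cfg, land_frac = 1) {
  set.seed(cfg$seed)
  nr <- cfg$n_rows; nc <- cfg$n_cols
  mask <- if (land_frac >= 1) matrix(TRUE, nr, nc) else {
    f <- gen_gaussian_field(nr, nc, cfg$corr_length)
    f >= stats::quantile(f, 1 - land_frac)
  }
  grid <- build_grid(0, nc * 0.1, -nr * 0.1 / 2, nr * 0.1 / 2,
                     cell_size = 0.1, land_mask = mask)
  ages <- slice_ages(cfg$n_slices)
  d <- cfg$drift
  fields <- lapply(names(cfg$beta), function(nm) gen_gaussian_field(nr, nc, cfg$corr_length))
  names(fields) <- names(cfg$beta)
  slices <- vector("list", length(ages))
  for (k in seq_along(ages)) {
    if (k > 1 && d > 0) {
      fields <- lapply(fields, function(f) {
        sqrt(1 - d^2) * f + d * gen_gaussian_field(nr, nc, cfg$corr_length)
      })
    }
    slices[[k]] <- fields
  }
  stack <- layer_stack(grid, ages, slices)
  true_suit <- lapply(slices, function(sl) {
    eta <- cfg$beta0
    for (nm in names(cfg$beta)) eta <- eta + cfg$beta[[nm]] * sl[[nm]]
    stats::plogis(eta)
  })
  list(stack = stack, true_suit = true_suit, grid = grid, cfg = cfg)
}

slice_ages <- function(n_slices) {
  a <- seq(0, by = 1000, length.out = min(n_slices, 22))
  if (n_slices > 22) a <- c(a, seq(23000, by = 2000, length.out = n_slices - 22))
  a[seq_len(n_slices)]
}

#' Synthetic camps with wedge-shaped population sizes
#'
#' Camp cells are sampled (with replacement: several camps can share a cell)
#' proportionally to true suitability over land cells; population sizes are
#' `Uniform(0, a_true + b_true * s)`, so the upper envelope of the
#' size-suitability cloud has slope `b_true` and the relation is
#' heteroscedastic and wedge-shaped, as ethnographic camp sizes are.
#'
#' @param truth output of [gen_landscape_stack()].
#' @param n_camps camp count.
#' @param slice which slice's true suitability to sample from (default 1 =
#'   present).
#' @return data frame of camp records (`id`, `lon`, `lat`,
#'   `population_size`, `excluded`, `suitability`, `cell_row`, `cell_col`).
#' @export
gen_camps <- function(truth, n_camps, slice = 1) {
  stopifnot(n_camps >= 1)
  cfg <- truth$cfg
  set.seed(cfg$seed + 1000L)
  grid <- truth$grid
  s <- truth$true_suit[[slice]]
  land <- which(grid$land_mask)
  cells <- sample(land, n_camps, replace = TRUE, prob = s[land])
  rows <- ((cells - 1L) %% grid$n_rows) + 1L
  cols <- ((cells - 1L) %/% grid$n_rows) + 1L
  jit <- function(n) stats::runif(n, -0.45, 0.45) * grid$cell_size
  suit <- s[cells]
  sizes <- stats::runif(n_camps, 0, cfg$a_true + cfg$b_true * suit)
  data.frame(
    id = sprintf("camp%04d", seq_len(n_camps)),
    lon = grid$lon_min + (cols - 0.5) * grid$cell_size + jit(n_camps),
    lat = grid$lat_max - (rows - 0.5) * grid$cell_size + jit(n_camps),
    population_size = sizes, excluded = FALSE,
    suitability = suit, cell_row = rows, cell_col = cols,
    stringsAsFactors = FALSE
  )
}

#' Synthetic dated archaeological sites
#'
#' Signal mode places each site, with probability `p_suit`, in a cell that is
#' truly suitable (true suitability at or above `suit_threshold`) at the
#' site's own slice, and uniformly over land otherwise; null mode ignores
#' suitability entirely, which makes it the ground truth for type-I
#' calibration of the date-permutation test. Dates are drawn uniformly over
#' the slices; curation fields are filled with clean values (charcoal, lab
#' codes, sound stratigraphy, Stone Age affiliation) so the records pass
#' [filter_dates()] unless perturbed by the caller.
#'
#' @param truth output of [gen_landscape_stack()].
#' @param n_sites site count.
#' @param mode `"signal"` or `"null"`.
#' @param p_suit suitable-cell placement probability (signal mode); defaults
#'   to the config's.
#' @param suit_threshold true-suitability cut defining "suitable" (default
#'   0.5).
#' @param seed seed; defaults to the config's seed + 2000.
#' @return data frame of site records.
#' @export
gen_archaeo_sites <- function(truth, n_sites, mode = c("signal", "null"),
                              p_suit = truth$cfg$p_suit, suit_threshold = 0.5,
                              seed = truth$cfg$seed + 2000L) {
  mode <- match.arg(mode)
  set.seed(seed)
  grid <- truth$grid
  ages <- truth$stack$ages
  land <- which(grid$land_mask)
  slice_idx <- sample.int(length(ages), n_sites, replace = TRUE)
  cells <- integer(n_sites)
  for (i in seq_len(n_sites)) {
    s <- truth$true_suit[[slice_idx[i]]]
    suitable <- land[s[land] >= suit_threshold]
    cells[i] <- if (mode == "signal" && length(suitable) > 0 &&
                    stats::runif(1) < p_suit) {
      if (length(suitable) == 1) suitable else sample(suitable, 1)
    } else {
      sample(land, 1)
    }
  }
  rows <- ((cells - 1L) %% grid$n_rows) + 1L
  cols <- ((cells - 1L) %/% grid$n_rows) + 1L
  data.frame(
    id = sprintf("site%04d", seq_len(n_sites)),
    lon = grid$lon_min + (cols - 0.5) * grid$cell_size,
    lat = grid$lat_max - (rows - 0.5) * grid$cell_size,
    age_bp = ages[slice_idx],
    age_error = round(stats::runif(n_sites, 40, 400)),
    material = "charcoal",
    lab_code = sprintf("LAB-%05d", seq_len(n_sites)),
    stratigraphy_ok = TRUE,
    farming_indicators = "",
    chronoculture = sample(c("MSA", "LSA"), n_sites, replace = TRUE),
    has_lithics = TRUE, pottery = FALSE, disputed = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Synthetic genotypes and IBD segment lists
#'
#' Genotypes follow the Balding-Nichols island model: per site an ancestral
#' frequency `p ~ Uniform(0.1, 0.9)`, population frequencies
#' `Beta(p (1-F)/F, (1-p)(1-F)/F)` at the configured `F`, and binomial
#' dosages. IBD lists are generated dyad-wise per length class: with the
#' configured class sharing rate a cross-population dyad is connected and
#' receives `min_blocks + Poisson(1)` segments of that class, otherwise a
#' below-threshold count (`Poisson(0.3)` capped at `min_blocks - 1`);
#' segment lengths are uniform within the class bounds. The realized
#' sharing probability of each class therefore estimates the configured
#' rate.
#'
#' @param cfg a `sim_config`.
#' @param n_per_pop individuals per population.
#' @param n_pops number of populations (default 2).
#' @param n_sites number of biallelic sites.
#' @return list with `G` (dosage matrix), `pops` (labels), `ibd` (segment
#'   data frame), `cfg`.
#' @export
gen_genotypes_and_ibd <- function(cfg, n_per_pop = 100, n_pops = 2,
                                  n_sites = 5000) {
  set.seed(cfg$seed + 3000L)
  Fst <- cfg$fst_true
  pops <- rep(sprintf("pop%d", seq_len(n_pops)), each = n_per_pop)
  p_anc <- stats::runif(n_sites, 0.1, 0.9)
  G <- matrix(NA_integer_, n_per_pop * n_pops, n_sites)
  for (k in seq_len(n_pops)) {
    pk <- if (Fst > 0) {
      stats::rbeta(n_sites, p_anc * (1 - Fst) / Fst, (1 - p_anc) * (1 - Fst) / Fst)
    } else p_anc
    rows <- which(pops == sprintf("pop%d", k))
    G[rows, ] <- stats::rbinom(length(rows) * n_sites, 2, rep(pk, each = length(rows)))
  }
  rownames(G) <- sprintf("ind%03d", seq_len(nrow(G)))
  ids <- rownames(G)
  bounds <- list("1-5" = c(1, 5), "5-10" = c(5, 10), ">10" = c(10, 25))
  segs <- list()
  for (cl in names(cfg$ibd_rates)) {
    mb <- default_min_blocks(cl)
    rate <- cfg$ibd_rates[[cl]]
    for (i in seq_len(nrow(G) - 1)) {
      for (j in (i + 1):nrow(G)) {
        if (pops[i] == pops[j]) next
        nblocks <- if (stats::runif(1) < rate) {
          mb + stats::rpois(1, 1)
        } else {
          min(stats::rpois(1, 0.3), mb - 1L)
        }
        if (nblocks == 0) next
        len <- stats::runif(nblocks, bounds[[cl]][1], bounds[[cl]][2] - 1e-9)
        st <- stats::runif(nblocks, 0, 200)
        segs[[length(segs) + 1L]] <- data.frame(
          ind_a = ids[i], ind_b = ids[j],
          chrom = as.character(sample.int(22, nblocks, replace = TRUE)),
          start_cm = st, end_cm = st + len, length_cm = len,
          stringsAsFactors = FALSE)
      }
    }
  }
  ibd <- if (length(segs)) do.call(rbind, segs) else
    data.frame(ind_a = character(0), ind_b = character(0), chrom = character(0),
               start_cm = numeric(0), end_cm = numeric(0), length_cm = numeric(0))
  list(G = G, pops = pops, ibd = ibd, cfg = cfg)
}

#' Synthetic digital elevation model and water mask
#'
#' Smooth random relief (a Gaussian random field scaled to
#' `relief_amplitude` metres) with an optional straight river barrier of
#' configurable width; zero amplitude gives a perfectly flat DEM, which is
#' what the closed-form travel-time checks use.
#'
#' @param grid a `grid_spec`.
#' @param relief_amplitude relief standard deviation, metres.
#' @param corr_length relief correlation length, cells.
#' @param river `NULL`, or list with `orientation` (`"vertical"` or
#'   `"horizontal"`), `at` (column or row index), `width` (cells).
#' @param seed integer seed.
#' @return list with `dem` (matrix, metres) and `water` (logical matrix).
#' @export
gen_dem <- function(grid, relief_amplitude = 0, corr_length = 6, river = NULL,
                    seed = 1) {
  set.seed(seed)
  nr <- grid$n_rows; nc <- grid$n_cols
  dem <- if (relief_amplitude > 0) {
    gen_gaussian_field(nr, nc, corr_length) * relief_amplitude
  } else {
    matrix(0, nr, nc)
  }
  water <- matrix(FALSE, nr, nc)
  if (!is.null(river)) {
    span <- river$at + seq_len(river$width) - 1L
    if (identical(river$orientation, "vertical")) {
      water[, span] <- TRUE
    } else {
      water[span, ] <- TRUE
    }
  }
  list(dem = dem, water = water)
}
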