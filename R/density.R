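#' Tukey upper-fence outlier filter for camp population sizes
#'
#' Removes values strictly above `Q3 + 1.5 * (Q3 - Q1)` (upper fence only;
#' small camps are never outliers under this rule). Quartiles use linear
#' interpolation (quantile type 7).
#'
#' @param sizes numeric vector of population sizes.
#' @return list with `retained` (values), `fence` (upper fence), and
#'   `removed` (count).
#' @export
tukey_filter <- function(sizes) {
  if (length(sizes) < 4) {
    warning("fewer than 4 values; no outlier filtering applied")
    return(list(retained = sizes, fence = Inf, removed = 0L))
  }
  q <- stats::quantile(sizes, c(0.25, 0.75), type = 7, names = FALSE)
  fence <- q[2] + 1.5 * (q[2] - q[1])
  keep <- sizes <= fence
  list(retained = sizes[keep], fence = fence, removed = sum(!keep))
}

#' Ordinary least-squares suitability-density regression
#'
#' Fits `density ~ suitability` by OLS and reports the slope with its t-test,
#' quantifying whether cells the niche model scores as more suitable hold
#' larger camp populations.
#'
#' @param suitability suitability values per cell.
#' @param density persons per cell (outliers already removed).
#' @return list with `slope`, `intercept`, `t`, `p`, and the `lm` fit.
#' @export
fit_density_ols <- function(suitability, density) {
  stopifnot(length(suitability) == length(density), length(density) >= 3)
  if (stats::sd(suitability) == 0) stop("suitability has zero variance")
  fit <- stats::lm(density ~ suitability)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["suitability", "Estimate"]),
       intercept = unname(sm["(Intercept)", "Estimate"]),
       t = unname(sm["suitability", "t value"]),
       p = unname(sm["suitability", "Pr(>|t|)"]),
       fit = fit)
}

check_loss <- function(r, q) sum(r * (q - (r < 0)))

#' Linear quantile regression via the MM algorithm
#'
#' Minimizes the asymmetric absolute-deviation (check) loss for a linear
#' model by iteratively reweighted least squares with the standard
#' majorize-minimize surrogate (weights `1/(eps + |r|)`), starting from the
#' OLS fit. For the straight-line models used here this converges to the
#' check-loss optimum to well within the tolerance of the data.
#'
#' @param x covariate vector.
#' @param y response vector.
#' @param q quantile level in (0, 1).
#' @param eps smoothing constant for the surrogate.
#' @param max_iter,tol iteration controls.
#' @return list with `intercept`, `slope`, `loss` (minimized check loss).
#' @export
rq_line <- function(x, y, q, eps = 1e-8, max_iter = 500, tol = 1e-10) {
  stopifnot(q > 0, q < 1, length(x) == length(y))
  X <- cbind(1, x)
  beta <- stats::coef(stats::lm.fit(X, y))
  loss_old <- check_loss(y - X %*% beta, q)
  for (it in seq_len(max_iter)) {
    r <- drop(y - X %*% beta)
    w <- 1 / (eps + abs(r))
    # surrogate normal equations: X'WX b = X'Wy + (2q-1) X'1
    XtW <- t(X * w)
    rhs <- XtW %*% y + (2 * q - 1) * colSums(X)
    beta_new <- tryCatch(solve(XtW %*% X, rhs), error = function(e) beta)
    loss_new <- check_loss(y - X %*% beta_new, q)
    if (loss_new <= loss_old) beta <- drop(beta_new)
    if (abs(loss_old - loss_new) < tol * (1 + loss_old)) break
    loss_old <- min(loss_old, loss_new)
  }
  r <- drop(y - X %*% beta)
  list(intercept = beta[1], slope = beta[2], loss = check_loss(r, q))
}

#' Quantile-regression envelope of the density-suitability wedge
#'
#' Fits a straight-line quantile regression of density on suitability at each
#' requested percentile and reports, per percentile, the slope and the R1
#' goodness-of-fit: `R1 = 1 - V_fit / V_null`, where V is the minimized
#' check loss and the null model is intercept-only (the sample quantile).
#' Under a wedge-shaped (upper-bounded, heteroscedastic) relation the slope
#' grows with the percentile and the top percentiles track the abundance
#' ceiling that suitability imposes.
#'
#' @param suitability,density numeric vectors per cell.
#' @param percentiles percentiles in (0, 100); default the set
#'   50, 55, 60, 65, 70, 75, 80, 90, 95, 99.
#' @return data frame with columns `percentile`, `slope`, `intercept`, `R1`.
#' @export
fit_density_quantiles <- function(suitability, density,
                                  percentiles = c(50, 55, 60, 65, 70, 75, 80, 90, 95, 99)) {
  stopifnot(length(suitability) == length(density), length(density) >= 10)
  if (any(percentiles <= 0 | percentiles >= 100)) {
    stop("percentiles must lie strictly between 0 and 100")
  }
  rows <- lapply(percentiles, function(p) {
    q <- p / 100
    fit <- rq_line(suitability, density, q)
    # null: best constant under check loss = the q-th sample quantile
    qn <- stats::quantile(density, q, type = 1, names = FALSE)
    vnull <- check_loss(density - qn, q)
    r1 <- if (vnull > 0) 1 - fit$loss / vnull else 1
    data.frame(percentile = p, slope = fit$slope, intercept = fit$intercept,
               R1 = r1)
  })
  do.call(rbind, rows)
}

#' Metapopulation size from a suitability map
#'
#' Translates suitability into a potential population size (PPS) per land
#' cell, sums to the gross potential population size (GPPS), and corrects for
#' territoriality: `size = GPPS * GCS / ASA`, with GCS the grid-cell area and
#' ASA the average subsistence area per camp.
#'
#' Anchoring of the PPS line is configurable:
#' \describe{
#'   \item{`centered` (default)}{`PPS_c = max(0, P_bar + b (s_c - s_bar))`,
#'     with `P_bar` the mean observed cell population (after outlier removal)
#'     and `s_bar` the mean suitability of the observed cells, so the line
#'     reproduces the observed mean at the observed mean suitability.}
#'   \item{`intercept`}{`PPS_c = max(0, a + b s_c)` using the fitted OLS
#'     intercept.}
#' }
#'
#' @param suit_map a `suitability_map`, or a numeric vector of suitabilities.
#' @param slope fitted density slope b (persons per suitability unit).
#' @param intercept fitted OLS intercept (used by `anchor = "intercept"`).
#' @param mean_observed_pop mean observed cell population P_bar.
#' @param mean_observed_suit mean suitability of the observed cells s_bar.
#' @param GCS grid-cell area, km^2 (default 123).
#' @param ASA average subsistence area, km^2 (default 1079).
#' @param anchor `"centered"` or `"intercept"`.
#' @return list with `GPPS`, `GCS`, `ASA`, `size`, `anchor`.
#' @export
metapopulation_size <- function(suit_map, slope, intercept = NULL,
                                mean_observed_pop = NULL,
                                mean_observed_suit = NULL,
                                GCS = 123, ASA = 1079,
                                anchor = c("centered", "intercept")) {
  anchor <- match.arg(anchor)
  if (GCS <= 0 || ASA <= 0) stop("GCS and ASA must be positive")
  s <- if (inherits(suit_map, "suitability_map")) {
    suit_map$values[suit_map$grid$land_mask]
  } else {
    as.numeric(suit_map)
  }
  pps <- if (anchor == "centered") {
    if (is.null(mean_observed_pop) || is.null(mean_observed_suit)) {
      stop("centered anchoring needs mean_observed_pop and mean_observed_suit")
    }
    pmax(0, mean_observed_pop + slope * (s - mean_observed_suit))
  } else {
    if (is.null(intercept)) stop("intercept anchoring needs the fitted intercept")
    pmax(0, intercept + slope * s)
  }
  gpps <- sum(pps)
  list(GPPS = gpps, GCS = GCS, ASA = ASA, size = gpps * GCS / ASA,
       anchor = anchor)
}
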