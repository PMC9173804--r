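#' Curate a radiocarbon site table down to reliable hunter-gatherer dates
#'
#' Applies, in order: (1) reliability screening — drop dates on carbonate
#' material (possible reservoir effects), dates with errors above
#' `max_error` years (the resolution of the paleoclimate slices), dates with
#' dubious stratigraphy, and dates missing a laboratory code; (2) farming
#' removal — drop any record with a farming indicator (pearl millet, oil
#' palm, iron metallurgy, pit features) or a farming chronocultural
#' affiliation (Neolithic, Early/Recent Iron Age). What remains is taken to
#' represent hunter-gatherer occupations. Optional stricter subsets: lithics
#' only, excluding disputed dates, excluding pottery-bearing sites.
#'
#' @param sites data frame with columns `id`, `lon`, `lat`, `age_bp`,
#'   `age_error`, `material`, `lab_code`, `stratigraphy_ok`,
#'   `farming_indicators` (comma-separated string or empty), `chronoculture`,
#'   and optionally `has_lithics`, `pottery`, `disputed`.
#' @param max_error maximum admissible dating error, years (default 1000).
#' @param lithics_only keep only records flagged `has_lithics`.
#' @param exclude_disputed drop records flagged `disputed`.
#' @param exclude_pottery drop records flagged `pottery`.
#' @return the curated data frame; attribute `"removed"` tabulates removal
#'   reasons.
#' @export
filter_dates <- function(sites, max_error = 1000, lithics_only = FALSE,
                         exclude_disputed = FALSE, exclude_pottery = FALSE) {
  stopifnot(all(c("age_bp", "age_error", "material", "lab_code",
                  "stratigraphy_ok", "chronoculture") %in% names(sites)))
  if (any(sites$age_bp < 0 | sites$age_error < 0, na.rm = TRUE)) {
    stop("ages and errors must be non-negative")
  }
  farming_cultures <- c("Neolithic", "EarlyIronAge", "RecentIronAge")
  fi <- sites$farming_indicators
  if (is.null(fi)) fi <- rep("", nrow(sites))
  fi[is.na(fi)] <- ""
  reasons <- character(nrow(sites))
  mark <- function(cond, why) {
    hit <- cond & reasons == ""
    reasons[hit] <<- why
  }
  mark(sites$material == "carbonate", "carbonate")
  mark(sites$age_error > max_error, "error_gt_max")
  mark(!sites$stratigraphy_ok, "dubious_stratigraphy")
  mark(is.na(sites$lab_code) | sites$lab_code == "", "missing_lab_code")
  mark(nzchar(fi), "farming_indicator")
  mark(sites$chronoculture %in% farming_cultures, "farming_chronoculture")
  if (lithics_only) mark(!isTRUE_vec(sites$has_lithics), "no_lithics")
  if (exclude_disputed) mark(isTRUE_vec(sites$disputed), "disputed")
  if (exclude_pottery) mark(isTRUE_vec(sites$pottery), "pottery")
  out <- sites[reasons == "", , drop = FALSE]
  attr(out, "removed") <- table(reasons[reasons != ""])
  out
}

isTRUE_vec <- function(x) {
  if (is.null(x)) return(FALSE)
  !is.na(x) & as.logical(x)
}

#' Deduplicate dated sites per coarse cell and time slice
#'
#' Keeps one record per `dedupe_deg` x `dedupe_deg` cell per time slice (the
#' slice each date rounds to), avoiding pseudo-replication from sites with
#' many nearby dates. The representative is the record with the smallest
#' dating error; ties go to the lexicographically earliest id.
#'
#' @param sites curated site data frame (needs `lon`, `lat`, `age_bp`,
#'   `age_error`, `id`).
#' @param stack a `layer_stack` defining the slice ages.
#' @param dedupe_deg coarse cell size, degrees (default 0.5).
#' @return deduplicated data frame with an added `slice_age` column.
#' @export
dedupe_sites <- function(sites, stack, dedupe_deg = 0.5) {
  if (nrow(sites) == 0) return(sites)
  slice_age <- nearest_slice_age(stack, sites$age_bp)
  keep <- !is.na(slice_age)
  if (any(!keep)) {
    message(sprintf("%d site(s) outside the stack's age range excluded", sum(!keep)))
  }
  sites <- sites[keep, , drop = FALSE]
  slice_age <- slice_age[keep]
  cellx <- floor(sites$lon / dedupe_deg)
  celly <- floor(sites$lat / dedupe_deg)
  key <- paste(cellx, celly, slice_age, sep = "|")
  ord <- order(key, sites$age_error, as.character(sites$id))
  sites <- sites[ord, , drop = FALSE]
  slice_age <- slice_age[ord]
  first <- !duplicated(key[ord])
  out <- sites[first, , drop = FALSE]
  out$slice_age <- slice_age[first]
  out[order(as.character(out$id)), , drop = FALSE]
}

#' Expected number of sites on predicted presences at one time slice
#'
#' Under independence of site location and suitability,
#' `E_T = N_T * PP_T / TC`: the dated-site count at slice T times the
#' fraction of the map predicted present.
#'
#' @param n_t sites dated to slice T.
#' @param pp_t predicted presence cells at slice T.
#' @param tc total land cells in the map.
#' @return expected count E_T.
#' @export
expected_sites <- function(n_t, pp_t, tc) {
  stopifnot(tc >= 1, pp_t >= 0, pp_t <= tc, n_t >= 0)
  n_t * pp_t / tc
}

site_presence_indicator <- function(sites, model, stack, tau) {
  grid <- stack$grid
  rc <- locate_cells(grid, sites$lon, sites$lat)
  slice_age <- if (!is.null(sites$slice_age)) sites$slice_age else {
    nearest_slice_age(stack, sites$age_bp)
  }
  pres_by_age <- new.env()
  vapply(seq_len(nrow(sites)), function(i) {
    a <- slice_age[i]
    if (is.na(a)) return(NA)
    key <- as.character(a)
    if (is.null(pres_by_age[[key]])) {
      s <- project_slice(model, get_slice(stack, a), grid, age = a)
      pres_by_age[[key]] <- binarize(s, tau)$presence
    }
    pres_by_age[[key]][rc[i, 1], rc[i, 2]]
  }, logical(1))
}

#' Observed count of sites on predicted presences
#'
#' Counts sites whose map cell is a predicted presence at the slice their own
#' radiocarbon date rounds to. Sites outside the stack's age range are
#' excluded with a message.
#'
#' @param sites site data frame (with `slice_age` from [dedupe_sites()], or
#'   raw `age_bp`).
#' @param model a `niche_model`.
#' @param stack a `layer_stack`.
#' @param tau decision threshold.
#' @return list with `O` (observed count) and `n` (sites evaluated).
#' @export
observed_count <- function(sites, model, stack, tau) {
  ind <- site_presence_indicator(sites, model, stack, tau)
  if (any(is.na(ind))) {
    message(sprintf("%d site(s) outside the stack's age range excluded", sum(is.na(ind))))
  }
  list(O = sum(ind, na.rm = TRUE), n = sum(!is.na(ind)))
}

#' Chi-square goodness of fit for observed vs expected presence counts
#'
#' Two categories (site on a predicted presence, or not) with expecteds
#' `{E, n - E}`: `chi2 = (O-E)^2/E + ((n-O)-(n-E))^2/(n-E)`, df = 1.
#'
#' @param O observed count on presences.
#' @param E expected count on presences.
#' @param n total sites.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square_gof <- function(O, E, n) {
  if (E <= 0 || E >= n) stop("E must lie strictly between 0 and n")
  stat <- (O - E)^2 / E + ((n - O) - (n - E))^2 / (n - E)
  list(statistic = stat, df = 1L, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Permutation test of the date-suitability association
#'
#' Shuffles the multiset of radiocarbon dates across the site locations
#' `n_perm` times (permutation without replacement); for each permutation the
#' number of sites landing on predicted presences at their assigned dates is
#' recomputed. If suitability landscapes genuinely shift through time and
#' sites track them, the observed count with the true dates should exceed the
#' permutation distribution. The empirical p-value uses the
#' `(1 + k) / (1 + n_perm)` estimator.
#'
#' @param sites deduplicated site data frame (with `slice_age`).
#' @param model a `niche_model`.
#' @param stack a `layer_stack`.
#' @param tau decision threshold.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return a `validation_result`: list with `O`, `E`, `n`, `chi_square`,
#'   `perm_counts`, `perm_mean`, `perm_sd`, `p_perm`, `n_perm`, `seed`.
#' @export
permute_dates <- function(sites, model, stack, tau, n_perm = 1000, seed = 1) {
  grid <- stack$grid
  slice_age <- if (!is.null(sites$slice_age)) sites$slice_age else {
    nearest_slice_age(stack, sites$age_bp)
  }
  ok <- !is.na(slice_age)
  sites <- sites[ok, , drop = FALSE]
  slice_age <- slice_age[ok]
  n <- nrow(sites)
  if (length(unique(slice_age)) < 2) {
    warning("fewer than 2 distinct slice dates; permutation distribution is degenerate")
  }
  rc <- locate_cells(grid, sites$lon, sites$lat)
  ages <- sort(unique(slice_age))
  # presence indicator per (site, slice): precompute once, permutations are lookups
  pres <- matrix(FALSE, n, length(ages), dimnames = list(NULL, as.character(ages)))
  pp_t <- integer(length(ages))
  for (j in seq_along(ages)) {
    s <- project_slice(model, get_slice(stack, ages[j]), grid, age = ages[j])
    pg <- binarize(s, tau)
    pp_t[j] <- pg$n_presence
    pres[, j] <- pg$presence[rc]
  }
  slice_col <- match(slice_age, ages)
  O <- sum(pres[cbind(seq_len(n), slice_col)])
  n_t <- tabulate(slice_col, nbins = length(ages))
  E <- sum(expected_sites(n_t, pp_t, grid$total_cells))
  set.seed(seed)
  perm_counts <- permute_presence_counts(pres, slice_col, n_perm)
  structure(list(
    O = O, E = E, n = n,
    chi_square = if (E > 0 && E < n) chi_square_gof(O, E, n) else NULL,
    perm_counts = perm_counts,
    perm_mean = mean(perm_counts), perm_sd = stats::sd(perm_counts),
    p_perm = (1 + sum(perm_counts >= O)) / (n_perm + 1),
    n_perm = n_perm, seed = seed
  ), class = "validation_result")
}

#' Permutation counts from a precomputed presence lookup
#'
#' Inner loop of [permute_dates()]: given the site-by-slice in-presence
#' indicator matrix and the true slice assignment, shuffles the assignment
#' (without replacement) `n_perm` times and returns the in-presence count of
#' each permutation. Exposed so large calibration studies can precompute the
#' indicator once and reuse it across replicates.
#'
#' @param pres logical matrix, sites x slices: is the site's cell a
#'   predicted presence at that slice.
#' @param slice_col integer column index of each site's true slice.
#' @param n_perm number of permutations.
#' @return numeric vector of length `n_perm`.
#' @export
permute_presence_counts <- function(pres, slice_col, n_perm) {
  n <- length(slice_col)
  vapply(seq_len(n_perm), function(k) {
    pc <- slice_col[sample.int(n)]
    sum(pres[cbind(seq_len(n), pc)])
  }, numeric(1))
}

#' @exportS3Method base::print
print.validation_result <- function(x, ...) {
  cat(sprintf("archaeological validation: O = %d, E = %.2f of n = %d sites\n",
              x$O, x$E, x$n))
  if (!is.null(x$chi_square)) {
    cat(sprintf("  chi-square = %.3f (df = 1), p = %.2g\n",
                x$chi_square$statistic, x$chi_square$p))
  }
  cat(sprintf("  permutations: mean %.3f, SD %.3f, empirical p = %.4f (%d perms)\n",
              x$perm_mean, x$perm_sd, x$p_perm, x$n_perm))
  invisible(x)
}

#' Correlation between model performance and site age
#'
#' Point-biserial correlation between the in-presence indicator and the
#' radiocarbon age, checking that the model does not systematically degrade
#' (or improve) for older sites.
#'
#' @inheritParams observed_count
#' @return list with `r`, `t`, `df`, `p`; `r` is `NA` with a warning when the
#'   indicator has zero variance.
#' @export
performance_vs_age <- function(sites, model, stack, tau) {
  ind <- site_presence_indicator(sites, model, stack, tau)
  ok <- !is.na(ind)
  ind <- as.numeric(ind[ok]); age <- sites$age_bp[ok]
  if (length(ind) < 3) stop("need at least 3 usable sites")
  if (stats::sd(ind) == 0 || stats::sd(age) == 0) {
    warning("zero variance in indicator or ages; correlation undefined")
    return(list(r = NA_real_, t = NA_real_, df = length(ind) - 2, p = NA_real_))
  }
  ct <- stats::cor.test(ind, age)
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       df = unname(ct$parameter), p = ct$p.value)
}

#' Screen a confounder layer against the model predictors
#'
#' Pearson correlation, over land cells, of a candidate confounder (soil pH
#' in the motivating analysis) against each predictor layer; passes when no
#' |r| reaches `r_cut`.
#'
#' @param env named list of predictor layer matrices.
#' @param confounder confounder layer matrix.
#' @param grid a `grid_spec`.
#' @param r_cut failure threshold (default 0.7).
#' @return list with `correlations` (named vector), `max_abs_r`, `pass`.
#' @export
confounder_check <- function(env, confounder, grid, r_cut = 0.7) {
  land <- which(grid$land_mask)
  cvec <- confounder[land]
  if (stats::sd(cvec) == 0) stop("confounder layer is constant")
  cors <- vapply(names(env), function(nm) {
    x <- env[[nm]][land]
    if (stats::sd(x) == 0) {
      warning(sprintf("constant predictor layer '%s' skipped", nm))
      return(NA_real_)
    }
    stats::cor(x, cvec)
  }, numeric(1))
  max_abs <- max(abs(cors), na.rm = TRUE)
  list(correlations = cors, max_abs_r = max_abs, pass = max_abs < r_cut)
}

#' Read an archaeological site table from CSV
#'
#' @param path CSV with the site fields used by [filter_dates()].
#' @return data frame.
#' @export
read_sites <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "lon", "lat", "age_bp", "age_error")
  if (!all(need %in% names(df))) {
    stop("sites CSV must have columns id, lon, lat, age_bp, age_error")
  }
  df
}
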