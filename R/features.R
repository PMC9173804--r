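#' Feature basis for the presence/background niche model
#'
#' Expands raw predictors into the six feature classes used by
#' maximum-entropy-style distribution models: linear, quadratic, pairwise
#' product, hinge (forward and reverse), threshold (step), and indicator
#' columns for categorical predictors. Knots for hinge and threshold features
#' sit at interior quantiles (deciles by default) of the training
#' distribution. Numeric predictors are rescaled to [0, 1] on their training
#' range before expansion; the training extremes are kept as the clamp range
#' used when projecting into novel environments.
#'
#' @param train data frame of predictor values (training cases).
#' @param categorical character vector of predictor names to treat as
#'   categorical.
#' @param n_knots number of interior knots per numeric predictor.
#' @param classes feature classes to include.
#' @return a `feature_basis` descriptor.
#' @export
feature_basis <- function(train, categorical = character(0), n_knots = 10,
                          classes = c("linear", "quadratic", "product",
                                      "hinge", "threshold", "categorical")) {
  classes <- match.arg(classes, several.ok = TRUE)
  num_names <- setdiff(names(train), categorical)
  clamp <- lapply(train[num_names], function(x) range(x, na.rm = TRUE))
  knots <- lapply(train[num_names], function(x) {
    qs <- stats::quantile(x, probs = seq_len(n_knots - 1) / n_knots,
                          na.rm = TRUE, type = 7)
    unique(as.numeric(qs))
  })
  levels <- lapply(train[intersect(categorical, names(train))],
                   function(x) sort(unique(x)))
  structure(list(numeric = num_names, categorical = intersect(categorical, names(train)),
                 clamp = clamp, knots = knots, levels = levels,
                 classes = classes),
            class = "feature_basis")
}

#' Evaluate a feature basis on new data
#'
#' @param basis a `feature_basis`.
#' @param newdata data frame holding every predictor the basis names.
#' @param clamp clip numeric predictors into their training range first.
#' @return numeric design matrix (cases x features).
#' @export
expand_features <- function(basis, newdata, clamp = TRUE) {
  for (nm in c(basis$numeric, basis$categorical)) {
    if (is.null(newdata[[nm]])) stop(sprintf("missing predictor layer '%s'", nm))
  }
  n <- nrow(newdata)
  cols <- list()
  for (nm in basis$numeric) {
    x <- as.numeric(newdata[[nm]])
    rng <- basis$clamp[[nm]]
    if (clamp) x <- pmin(pmax(x, rng[1]), rng[2])
    span <- max(rng[2] - rng[1], .Machine$double.eps)
    z <- (x - rng[1]) / span
    if ("linear" %in% basis$classes) cols[[paste0("lin_", nm)]] <- z
    if ("quadratic" %in% basis$classes) cols[[paste0("quad_", nm)]] <- z^2
    kn <- basis$knots[[nm]]
    kz <- (pmin(pmax(kn, rng[1]), rng[2]) - rng[1]) / span
    if ("hinge" %in% basis$classes) {
      for (i in seq_along(kz)) {
        k <- kz[i]
        if (k < 1) cols[[sprintf("hingef_%s_%d", nm, i)]] <- pmax(0, (z - k) / (1 - k))
        if (k > 0) cols[[sprintf("hinger_%s_%d", nm, i)]] <- pmax(0, (k - z) / k)
      }
    }
    if ("threshold" %in% basis$classes) {
      for (i in seq_along(kz)) {
        cols[[sprintf("thr_%s_%d", nm, i)]] <- as.numeric(z >= kz[i])
      }
    }
  }
  if ("product" %in% basis$classes && length(basis$numeric) >= 2) {
    zs <- lapply(basis$numeric, function(nm) {
      x <- as.numeric(newdata[[nm]])
      rng <- basis$clamp[[nm]]
      if (clamp) x <- pmin(pmax(x, rng[1]), rng[2])
      (x - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
    })
    names(zs) <- basis$numeric
    pairs <- utils::combn(basis$numeric, 2, simplify = FALSE)
    for (p in pairs) cols[[paste0("prod_", p[1], "_", p[2])]] <- zs[[p[1]]] * zs[[p[2]]]
  }
  if ("categorical" %in% basis$classes) {
    for (nm in basis$categorical) {
      x <- newdata[[nm]]
      lv <- basis$levels[[nm]]
      unseen <- !(x %in% lv)
      if (any(unseen)) {
        # novel category: clamp to the nearest trained level (numeric codes)
        if (is.numeric(lv)) {
          x[unseen] <- vapply(x[unseen], function(v) lv[which.min(abs(lv - v))],
                              lv[1])
        } else {
          x[unseen] <- lv[1]
        }
        message(sprintf("%d value(s) of '%s' at unseen category levels clamped to nearest trained level",
                        sum(unseen), nm))
      }
      for (l in lv) cols[[paste0("cat_", nm, "_", l)]] <- as.numeric(x == l)
    }
  }
  out <- do.call(cbind, cols)
  if (is.null(out)) out <- matrix(numeric(0), nrow = n, ncol = 0)
  out
}
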