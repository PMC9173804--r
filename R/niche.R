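#' Collinearity screen for candidate predictors
#'
#' Implements the select07 rule: among every pair of numeric predictors whose
#' absolute Pearson correlation reaches `r_cut`, the member with the lower
#' univariate explained deviance (D-squared from a single-predictor binomial
#' GLM against the response) is dropped. Pairs are processed in decreasing
#' |r| and the scan repeats until no offending pair remains. Constant
#' predictors, whose correlation is undefined, are dropped with a warning.
#'
#' @param predictors data frame of numeric candidate predictors (cases x p).
#' @param response binary vector (0/1) per case.
#' @param r_cut correlation threshold (default 0.7).
#' @return character vector of retained predictor names.
#' @export
select07 <- function(predictors, response, r_cut = 0.7) {
  stopifnot(nrow(predictors) >= 2, length(response) == nrow(predictors))
  keep <- names(predictors)
  const <- vapply(predictors, function(x) stats::sd(x) == 0, logical(1))
  if (any(const)) {
    warning(sprintf("dropping constant predictor(s): %s",
                    paste(keep[const], collapse = ", ")))
    keep <- keep[!const]
  }
  d2 <- vapply(keep, function(nm) {
    fit <- stats::glm(response ~ predictors[[nm]], family = stats::binomial())
    1 - fit$deviance / fit$null.deviance
  }, numeric(1))
  repeat {
    if (length(keep) < 2) break
    cm <- abs(stats::cor(predictors[keep]))
    diag(cm) <- 0
    if (max(cm) < r_cut) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    pair <- keep[worst]
    drop <- pair[which.min(d2[pair])]
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Favorability transform
#'
#' Converts a binomial-GLM predicted probability into a prevalence-corrected
#' favorability: `F = (P/(1-P)) / (n1/n0 + P/(1-P))`, where `n1` and `n0` are
#' the training counts of presences and absences. `F = 0.5` exactly when `P`
#' equals the training prevalence `n1/(n1+n0)`, so favorability is comparable
#' across models fitted at different prevalences.
#'
#' @param P predicted probability (vectorized).
#' @param n1,n0 presence and absence counts used in fitting.
#' @return favorability in \[0, 1\], strictly increasing in `P`.
#' @export
favorability <- function(P, n1, n0) {
  if (n1 <= 0 || n0 <= 0) stop("n1 and n0 must be positive")
  out <- numeric(length(P))
  out[P <= 0] <- 0
  out[P >= 1] <- 1
  mid <- P > 0 & P < 1
  odds <- P[mid] / (1 - P[mid])
  out[mid] <- odds / (n1 / n0 + odds)
  out
}

#' Presence/absence decision threshold
#'
#' Chooses the threshold maximizing sensitivity + specificity under the
#' classification rule `score >= tau => presence`. Candidates are the observed
#' scores plus 0 and 1; ties go to the smallest candidate.
#'
#' @param scores_pres scores at presence cases.
#' @param scores_abs scores at absence/background cases.
#' @return the optimal threshold tau.
#' @export
compute_threshold <- function(scores_pres, scores_abs) {
  stopifnot(length(scores_pres) > 0, length(scores_abs) > 0)
  cand <- sort(unique(c(0, scores_pres, scores_abs, 1)))
  ss <- vapply(cand, function(t) {
    mean(scores_pres >= t) + mean(scores_abs < t)
  }, numeric(1))
  cand[which.max(ss)]  # which.max returns the first (smallest) maximizer
}

#' Rank-based AUC (Mann-Whitney statistic)
#'
#' @param scores_pres,scores_abs scores for the two classes.
#' @return AUC in \[0, 1\]; ties counted half.
#' @export
auc_rank <- function(scores_pres, scores_abs) {
  n1 <- length(scores_pres); n0 <- length(scores_abs)
  r <- rank(c(scores_pres, scores_abs))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

confusion_metrics <- function(scores_pres, scores_abs, tau) {
  tp <- sum(scores_pres >= tau); fn <- length(scores_pres) - tp
  tn <- sum(scores_abs < tau);  fp <- length(scores_abs) - tn
  n <- tp + fn + tn + fp
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  list(sensitivity = sens, specificity = spec, TSS = sens + spec - 1,
       kappa = if (pe < 1) (po - pe) / (1 - pe) else 0)
}

#' Fit the environmental niche model
#'
#' Two fitting modes share one surface:
#' \describe{
#'   \item{`maxent_like`}{an L1-penalized logistic regression of presence
#'     cells against a background sample, over the expanded feature basis
#'     (linear, quadratic, product, hinge, threshold, categorical indicator).
#'     The penalty plays the role of maximum-entropy regularization: each
#'     retained feature pays for its weight, which protects projection into
#'     novel climates against overfitting. Output is the logistic-scaled
#'     probability in \[0, 1\].}
#'   \item{`favorability_glm`}{a binomial GLM (linear + quadratic terms) of
#'     presence against all non-presence land cells, followed by the
#'     favorability transform so the output is prevalence-corrected.}
#' }
#' Training predictor extremes are stored as clamp ranges; the decision
#' threshold tau is set by [compute_threshold()] on the training scores.
#'
#' @param presences a `presence_grid`.
#' @param env named list of layer matrices for the training slice.
#' @param mode `"maxent_like"` or `"favorability_glm"`.
#' @param background_n background sample size for `maxent_like` (capped at the
#'   number of available non-presence land cells).
#' @param regularization L1 penalty (glmnet lambda) for `maxent_like`.
#' @param categorical names of categorical layers.
#' @param n_knots hinge/threshold knots per predictor.
#' @param seed integer seed for the background draw.
#' @return a `niche_model`.
#' @export
fit_enm <- function(presences, env, mode = c("maxent_like", "favorability_glm"),
                    background_n = 10000, regularization = 1e-3,
                    categorical = character(0), n_knots = 10, seed = 1) {
  mode <- match.arg(mode)
  grid <- presences$grid
  if (presences$n_presence < 1) stop("need at least one presence cell")
  land <- which(grid$land_mask)
  pres_idx <- which(presences$presence)
  abs_idx <- setdiff(land, pres_idx)
  env_df_at <- function(idx) {
    as.data.frame(lapply(env, function(m) m[idx]))
  }
  if (mode == "maxent_like") {
    set.seed(seed)
    nb <- min(background_n, length(abs_idx))
    if (nb < background_n) {
      warning(sprintf("background_n capped at %d available non-presence land cells", nb))
    }
    bg_idx <- sample(abs_idx, nb)
    train_idx <- c(pres_idx, bg_idx)
    y <- c(rep(1, length(pres_idx)), rep(0, nb))
  } else {
    train_idx <- c(pres_idx, abs_idx)
    y <- c(rep(1, length(pres_idx)), rep(0, length(abs_idx)))
  }
  train <- env_df_at(train_idx)
  if (mode == "maxent_like") {
    basis <- feature_basis(train, categorical = categorical, n_knots = n_knots)
    X <- expand_features(basis, train, clamp = FALSE)
    fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                          lambda = regularization, standardize = FALSE)
    weights <- as.numeric(fit$beta)
    names(weights) <- rownames(fit$beta)
    intercept <- as.numeric(fit$a0)
  } else {
    basis <- feature_basis(train, categorical = categorical,
                           classes = c("linear", "quadratic", "categorical"))
    X <- expand_features(basis, train, clamp = FALSE)
    df <- as.data.frame(X)
    fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
    if (!fit$converged) warning("favorability GLM did not converge (possible separation)")
    cf <- stats::coef(fit)
    intercept <- cf[1]
    weights <- cf[-1]
    weights[is.na(weights)] <- 0
    names(weights) <- colnames(X)
  }
  model <- structure(list(
    mode = mode, basis = basis, weights = weights, intercept = intercept,
    regularization = if (mode == "maxent_like") regularization else 0,
    n1 = sum(y == 1), n0 = sum(y == 0),
    predictor_names = names(env), tau = NA_real_
  ), class = "niche_model")
  scores <- predict_suitability(model, train, clamp = FALSE)
  model$tau <- compute_threshold(scores[y == 1], scores[y == 0])
  model
}

#' Score suitability for a table of predictor values
#'
#' @param model a `niche_model`.
#' @param newdata data frame of predictor values.
#' @param clamp clip predictors into the training clamp range first.
#' @return suitability values in \[0, 1\].
#' @export
predict_suitability <- function(model, newdata, clamp = TRUE) {
  X <- expand_features(model$basis, newdata, clamp = clamp)
  eta <- drop(X %*% model$weights[colnames(X)]) + model$intercept
  P <- stats::plogis(eta)
  if (model$mode == "favorability_glm") {
    favorability(P, model$n1, model$n0)
  } else {
    P
  }
}

#' @exportS3Method base::print
print.niche_model <- function(x, ...) {
  cat(sprintf("niche_model (%s): %d features, %d active; tau = %.3f; n1 = %d, n0 = %d\n",
              x$mode, length(x$weights), sum(x$weights != 0), x$tau, x$n1, x$n0))
  invisible(x)
}

#' Repeated split-sample cross-validation of a niche model
#'
#' Per repetition: draw a random `train_frac` of the cases (cells) for
#' calibration, refit, set the threshold on the calibration scores, then score
#' the held-out cases: rank AUC, Cohen's kappa, sensitivity, specificity and
#' TSS = sensitivity + specificity - 1. Repetitions whose validation fold
#' lacks one of the classes are redrawn.
#'
#' @param cases data frame holding the predictors plus a 0/1 column `y`.
#' @param fit_fun function(train_df) -> list(score = function(newdata) scores).
#'   Defaults to an L1-logistic over the feature basis, mirroring
#'   [fit_enm()]'s `maxent_like` mode on tabular cases.
#' @param train_frac calibration fraction (default 0.8).
#' @param reps number of repetitions (default 500).
#' @param seed integer seed.
#' @return list with mean `AUC`, `kappa`, `sensitivity`, `specificity`, `TSS`
#'   and the number of repetitions.
#' @export
evaluate_cv <- function(cases, fit_fun = NULL, train_frac = 0.8, reps = 500,
                        seed = 1) {
  stopifnot(is.data.frame(cases), "y" %in% names(cases))
  y_all <- cases$y
  preds <- cases[setdiff(names(cases), "y")]
  if (is.null(fit_fun)) {
    fit_fun <- function(train_df) {
      ytr <- train_df$y
      ptr <- train_df[setdiff(names(train_df), "y")]
      basis <- feature_basis(ptr, n_knots = 5)
      X <- expand_features(basis, ptr, clamp = FALSE)
      fit <- glmnet::glmnet(X, ytr, family = "binomial", alpha = 1,
                            lambda = 1e-3, standardize = FALSE)
      w <- as.numeric(fit$beta); a0 <- as.numeric(fit$a0)
      list(score = function(nd) {
        Xn <- expand_features(basis, nd, clamp = TRUE)
        stats::plogis(drop(Xn %*% w) + a0)
      })
    }
  }
  set.seed(seed)
  n <- nrow(cases)
  acc <- matrix(NA_real_, reps, 5,
                dimnames = list(NULL, c("AUC", "kappa", "sensitivity",
                                        "specificity", "TSS")))
  r <- 1
  redraws <- 0
  while (r <= reps) {
    tr <- sample.int(n, round(train_frac * n))
    va <- setdiff(seq_len(n), tr)
    if (length(unique(y_all[va])) < 2 || length(unique(y_all[tr])) < 2) {
      redraws <- redraws + 1
      if (redraws > 100 * reps) stop("cannot draw folds containing both classes")
      next
    }
    m <- fit_fun(cases[tr, , drop = FALSE])
    s_tr <- m$score(preds[tr, , drop = FALSE])
    tau <- compute_threshold(s_tr[y_all[tr] == 1], s_tr[y_all[tr] == 0])
    s_va <- m$score(preds[va, , drop = FALSE])
    sp <- s_va[y_all[va] == 1]; sa <- s_va[y_all[va] == 0]
    cm <- confusion_metrics(sp, sa, tau)
    acc[r, ] <- c(auc_rank(sp, sa), cm$kappa, cm$sensitivity,
                  cm$specificity, cm$TSS)
    r <- r + 1
  }
  out <- as.list(colMeans(acc))
  out$reps <- reps
  out
}

#' Serialize a fitted niche model to JSON
#'
#' @param model a `niche_model`.
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  obj <- list(
    mode = model$mode,
    intercept = model$intercept,
    weights = as.list(model$weights),
    regularization = model$regularization,
    n1 = model$n1, n0 = model$n0, tau = model$tau,
    predictor_names = model$predictor_names,
    basis = list(numeric = model$basis$numeric,
                 categorical = model$basis$categorical,
                 clamp = model$basis$clamp,
                 knots = model$basis$knots,
                 levels = model$basis$levels,
                 classes = model$basis$classes)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  basis <- structure(list(
    numeric = as.character(obj$basis$numeric),
    categorical = as.character(obj$basis$categorical),
    clamp = lapply(obj$basis$clamp, as.numeric),
    knots = lapply(obj$basis$knots, as.numeric),
    levels = obj$basis$levels,
    classes = as.character(obj$basis$classes)
  ), class = "feature_basis")
  w <- unlist(obj$weights)
  structure(list(mode = obj$mode, basis = basis, weights = w,
                 intercept = obj$intercept, regularization = obj$regularization,
                 n1 = obj$n1, n0 = obj$n0,
                 predictor_names = as.character(obj$predictor_names),
                 tau = obj$tau),
            class = "niche_model")
}
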