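# brute-force reference for the select07 rule: repeatedly find the highest
# correlated offending pair and drop its weaker member
select07_oracle <- function(preds, y, r_cut = 0.7) {
  d2 <- sapply(names(preds), function(nm) {
    f <- glm(y ~ preds[[nm]], family = binomial())
    1 - f$deviance / f$null.deviance
  })
  keep <- names(preds)
  repeat {
    pairs <- t(combn(keep, 2))
    rs <- apply(pairs, 1, function(p) abs(cor(preds[[p[1]]], preds[[p[2]]])))
    if (all(rs < r_cut)) break
    p <- pairs[which.max(rs), ]
    keep <- setdiff(keep, p[which.min(d2[p])])
    if (length(keep) < 2) break
  }
  keep
}

test_that("select07 drops the weaker member of correlated pairs", {
  set.seed(5)
  n <- 400
  x1 <- rnorm(n)
  y <- rbinom(n, 1, plogis(2 * x1))
  # x2 is a noisy copy of x1: highly correlated but clearly less informative
  preds <- data.frame(x1 = x1, x2 = x1 + rnorm(n, sd = 0.5))
  kept <- select07(preds, y)
  expect_equal(kept, "x1")

  # mutually uncorrelated set: all retained
  preds2 <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  expect_setequal(select07(preds2, y), c("a", "b", "c"))

  # 5 predictors with planted correlated pairs vs the exhaustive oracle
  x <- replicate(3, rnorm(n))
  preds3 <- data.frame(p1 = x[, 1], p2 = 0.95 * x[, 1] + 0.1 * rnorm(n),
                       p3 = x[, 2], p4 = x[, 3],
                       p5 = 0.9 * x[, 2] + 0.2 * rnorm(n))
  y3 <- rbinom(n, 1, plogis(x[, 1] + 0.5 * x[, 2]))
  expect_setequal(select07(preds3, y3), select07_oracle(preds3, y3))
  cors <- abs(cor(preds3[select07(preds3, y3)]))
  diag(cors) <- 0
  expect_lt(max(cors), 0.7)

  expect_warning(select07(data.frame(k = rep(1, n), x = x1), y), "constant")
})

test_that("favorability maps prevalence to one half and respects limits", {
  expect_equal(favorability(100 / 350, 100, 250), 0.5)
  expect_equal(favorability(0, 10, 10), 0)
  expect_equal(favorability(1, 10, 10), 1)
  # n1/n0 = 0.25, P = 0.5 -> odds 1 -> 1/(0.25 + 1) = 0.8
  expect_equal(favorability(0.5, 25, 100), 0.8)
  p <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(favorability(p, 30, 70)) > 0))
  expect_true(all(favorability(p, 3, 700) >= 0 & favorability(p, 3, 700) <= 1))
  expect_error(favorability(0.5, 0, 10), "positive")
})

test_that("threshold maximizes sensitivity + specificity, ties to smallest", {
  # brute force over candidates
  sp <- c(0.8, 0.9); sa <- c(0.1, 0.2)
  tau <- compute_threshold(sp, sa)
  expect_equal(tau, 0.8)
  expect_equal(mean(sp >= tau) + mean(sa < tau), 2)

  set.seed(1)
  sp2 <- runif(50); sa2 <- runif(70)
  tau2 <- compute_threshold(sp2, sa2)
  cand <- sort(unique(c(0, sp2, sa2, 1)))
  ss <- sapply(cand, function(t) mean(sp2 >= t) + mean(sa2 < t))
  expect_equal(mean(sp2 >= tau2) + mean(sa2 < tau2), max(ss))
  expect_equal(tau2, cand[which.max(ss)])

  # identical score distributions: no skill, best sum is 1
  s <- runif(100)
  expect_equal(max(sapply(c(0, s, 1), function(t) mean(s >= t) + mean(s < t))), 1)
})

test_that("rank AUC agrees with an independent ROC implementation", {
  set.seed(2)
  sp <- rnorm(80, 1); sa <- rnorm(120)
  ref <- suppressMessages(
    pROC::auc(pROC::roc(c(rep(1, 80), rep(0, 120)), c(sp, sa), quiet = TRUE)))
  expect_equal(auc_rank(sp, sa), as.numeric(ref), tolerance = 1e-12)
})

test_that("fitted suitability is monotone in a single informative predictor", {
  w <- shared_world()
  g <- w$truth$grid
  set.seed(3)
  env <- list(env1 = matrix(rnorm(g$n_rows * g$n_cols), g$n_rows, g$n_cols))
  pres <- env$env1 >= quantile(env$env1, 0.8)  # presences at high values only
  pg <- paleoniche:::new_presence_grid(g, pres)
  m <- fit_enm(pg, env, background_n = 1000, seed = 2)
  grid_vals <- seq(min(env$env1), max(env$env1), length.out = 50)
  s <- predict_suitability(m, data.frame(env1 = grid_vals))
  expect_true(all(diff(s) >= -1e-8))
})

test_that("model recovers a known logistic suitability (rank r > 0.9)", {
  w <- shared_world()
  s_fit <- project_slice(w$model, get_slice(w$truth$stack, 0), w$truth$grid)
  land <- w$truth$grid$land_mask
  expect_gt(cor(s_fit$values[land], w$truth$true_suit[[1]][land],
                method = "spearman"), 0.9)
  expect_true(all(s_fit$values[land] >= 0 & s_fit$values[land] <= 1))
})

test_that("infinite regularization shrinks the model to a constant", {
  w <- shared_world()
  m <- fit_enm(w$pg, get_slice(w$truth$stack, 0), background_n = 1000,
               regularization = 1e6, seed = 1)
  expect_true(all(m$weights == 0))
  land <- w$truth$grid$land_mask
  s <- project_slice(m, get_slice(w$truth$stack, 0), w$truth$grid)
  expect_equal(sd(s$values[land]), 0)
})

test_that("favorability-GLM mode outputs prevalence-corrected suitability", {
  w <- shared_world()
  m <- fit_enm(w$pg, get_slice(w$truth$stack, 0), mode = "favorability_glm")
  land <- w$truth$grid$land_mask
  s <- project_slice(m, get_slice(w$truth$stack, 0), w$truth$grid)
  expect_true(all(s$values[land] >= 0 & s$values[land] <= 1))
  # favorability ranks agree with the truth almost as well as the main mode
  expect_gt(cor(s$values[land], w$truth$true_suit[[1]][land],
                method = "spearman"), 0.85)
})

test_that("cross-validation is honest: separable data aces, permuted labels do not", {
  set.seed(4)
  n <- 300
  x <- rep(c(-1, 1), each = n / 2)  # two perfectly separated clusters
  cases_sep <- data.frame(x = x, y = as.numeric(x > 0))
  cv <- evaluate_cv(cases_sep, reps = 20, seed = 1)
  expect_equal(cv$AUC, 1)
  expect_equal(cv$TSS, 1)
  expect_equal(cv$sensitivity + cv$specificity - 1, cv$TSS)

  # labels independent of the predictor: no skill on average
  cases_null <- data.frame(x = rnorm(500), y = rbinom(500, 1, 0.4))
  cv0 <- evaluate_cv(cases_null, reps = 50, seed = 2)
  expect_lt(abs(cv0$AUC - 0.5), 0.05)
  expect_lt(abs(cv0$TSS - 0), 0.1)
})

test_that("confusion metrics satisfy the TSS identity for arbitrary cuts", {
  set.seed(6)
  for (k in 1:20) {
    sp <- runif(30); sa <- runif(40); tau <- runif(1)
    cm <- paleoniche:::confusion_metrics(sp, sa, tau)
    expect_equal(cm$TSS, cm$sensitivity + cm$specificity - 1)
  }
})

test_that("a fitted model round-trips through JSON", {
  w <- shared_world()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(w$model, path)
  m2 <- read_model_json(path)
  nd <- data.frame(env1 = c(-1, 0, 1.5), env2 = c(0.2, -0.3, 2))
  expect_equal(predict_suitability(m2, nd), predict_suitability(w$model, nd),
               tolerance = 1e-12)
  expect_equal(m2$tau, w$model$tau)
})
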