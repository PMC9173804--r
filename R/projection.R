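#' Project a fitted niche model onto a time slice
#'
#' Evaluates the model over every land cell of a slice. With `clamp = TRUE`
#' (the default, and the behaviour used for paleo-projection) each predictor
#' is clipped into its training range first, so the response extrapolates in
#' a horizontal line beyond the most extreme environmental values seen during
#' calibration.
#'
#' @param model a `niche_model`.
#' @param slice named list of layer matrices (one time slice).
#' @param grid the `grid_spec` the slice conforms to.
#' @param age years BP recorded on the output.
#' @param clamp clip predictors to the training range (default `TRUE`).
#' @return a `suitability_map`: list with `grid`, `age`, and matrix `values`
#'   (suitability in \[0, 1\] on land, `NA` on water).
#' @export
project_slice <- function(model, slice, grid, age = 0, clamp = TRUE) {
  missing <- setdiff(c(model$basis$numeric, model$basis$categorical), names(slice))
  if (length(missing)) {
    stop(sprintf("missing predictor layer(s): %s", paste(missing, collapse = ", ")))
  }
  land <- which(grid$land_mask)
  nd <- as.data.frame(lapply(slice[c(model$basis$numeric, model$basis$categorical)],
                             function(m) m[land]))
  vals <- predict_suitability(model, nd, clamp = clamp)
  m <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  m[land] <- vals
  structure(list(grid = grid, age = age, values = m), class = "suitability_map")
}

#' @exportS3Method base::print
print.suitability_map <- function(x, ...) {
  v <- x$values[x$grid$land_mask]
  cat(sprintf("suitability_map @ %g BP: mean %.3f, range [%.3f, %.3f] over %d land cells\n",
              x$age, mean(v), min(v), max(v), length(v)))
  invisible(x)
}

#' Binarize a suitability map at a threshold
#'
#' Presence iff suitability `>= tau`.
#'
#' @param s a `suitability_map`.
#' @param tau threshold in \[0, 1\].
#' @return a `presence_grid`.
#' @export
binarize <- function(s, tau) {
  stopifnot(tau >= 0, tau <= 1)
  pres <- !is.na(s$values) & s$values >= tau
  new_presence_grid(s$grid, pres)
}

#' Predicted range size across time slices
#'
#' Projects the model (clamped) onto every slice of a stack, binarizes at
#' `tau`, and reports the presence-cell count PP_T per slice plus its mean.
#' Slices missing any model predictor are skipped with a message.
#'
#' @param model a `niche_model`.
#' @param stack a `layer_stack`.
#' @param tau decision threshold; defaults to the model's fitted `tau`.
#' @return a `range_series`: data frame with columns `age_bp`, `pp`, plus
#'   attribute `mean_pp`.
#' @export
range_series <- function(model, stack, tau = model$tau) {
  need <- c(model$basis$numeric, model$basis$categorical)
  rows <- lapply(seq_along(stack$ages), function(k) {
    sl <- stack$slices[[k]]
    if (!all(need %in% names(sl))) {
      message(sprintf("slice at %g BP missing layer(s); skipped", stack$ages[k]))
      return(NULL)
    }
    s <- project_slice(model, sl, stack$grid, age = stack$ages[k])
    data.frame(age_bp = stack$ages[k], pp = binarize(s, tau)$n_presence)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no usable slices in stack")
  attr(out, "mean_pp") <- mean(out$pp)
  class(out) <- c("range_series", class(out))
  out
}
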