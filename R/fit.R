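# Penalized least-squares fit of the influence function.
#
# Model: centered log expression of gene i is
#   y_i = sum_j alpha_ij f(d_ij) + eps_i,   f(d) = sum_k c_k B_k(d),
# so y = B c + eps with b_ik = sum_j alpha_ij B_k(d_ij) precomputed.
# Coefficients minimize
#   F(c) = (1/N) ||y - B c||^2 + sigma * c' D c
# with D the second-difference penalty; the minimizer solves the symmetric
# system (B'B / N + sigma D) c = B'y / N exactly, with no iteration.

solve_penalized <- function(B, y, sigma, D) {
  N <- nrow(B)
  A <- crossprod(B) / N + sigma * D
  rhs <- crossprod(B, y) / N
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (!is.null(ch))
    return(drop(backsolve(ch, backsolve(ch, rhs, transpose = TRUE))))
  # a design with no active features (e.g. every site filtered out) has a
  # zero right-hand side: the fit is the zero curve, not an error
  if (max(abs(rhs)) <= 1e-12 * max(1, max(abs(A))))
    return(numeric(ncol(B)))
  if (sigma == 0)
    stopf("penalized system is singular; increase sigma or reduce n_basis")
  # sigma > 0 but the penalty null space overlaps an unidentified data
  # direction (degenerate designs, e.g. all sites sharing one covariate
  # value): the normal equations of the convex objective are consistent, so
  # take the minimum-norm solution
  sv <- svd(A)
  pos <- sv$d > max(dim(A)) * .Machine$double.eps * max(sv$d)
  cf <- drop(sv$v[, pos, drop = FALSE] %*%
               (crossprod(sv$u[, pos, drop = FALSE], rhs) / sv$d[pos]))
  if (max(abs(A %*% cf - rhs)) > 1e-6 * max(1, max(abs(rhs))))
    stopf("penalized system is singular; increase sigma or reduce n_basis")
  cf
}

#' Fit an influence function by penalized least squares
#'
#' Fits the additive binding-influence model: each gene's (centered) log
#' expression is the sum over its associated binding sites of
#' \code{alpha * f(covariate)}, where the influence function \code{f} is a
#' B-spline curve. The coefficients minimize mean squared error plus
#' \code{sigma} times a discrete second-difference roughness penalty, and
#' are obtained by one exact symmetric solve. With \code{sigma = 0} the fit
#' is ordinary least squares. No intercept is fitted: the basal term is
#' assumed removed by response centering (or absent, as in synthetic data).
#'
#' @param x A \code{binding_profiles} object, or a precomputed design
#'   matrix from [design_features()].
#' @param y Numeric response vector (one value per gene/row of the design).
#' @param basis A \code{spline_basis}; defaults to 20 cubic functions over
#'   +/- 100 kb when \code{x} is a profile set.
#' @param sigma Regularization parameter (>= 0). Use [select_sigma()] for a
#'   data-driven choice.
#' @param penalty_order Difference order of the penalty (default 2).
#' @param variant Model variant label stored on the fit: \code{"position"}
#'   (basis over distance) or \code{"conservation"} (basis over the sites'
#'   conservation scores). See [fit_variant_model()] for the uniform model.
#' @param outside Passed to [design_features()].
#' @return An object of class \code{influence_fit} with components
#'   \code{coefficients}, \code{basis}, \code{sigma}, \code{penalty_order},
#'   \code{variant}, \code{fitted.values}, \code{residuals}, \code{mse}.
#' @seealso [influence_curve()], [predict.influence_fit()],
#'   [predict_differential()]
#' @examples
#' spec <- synthetic_spec(n_genes = 300, noise_sd = 0.3)
#' study <- simulate_study(spec, seed = 1)
#' prof <- associate_sites(study$tss, study$sites$tissueA, cutoff = 1e5)
#' fit <- fit_influence(prof, study$expression$tissueA, sigma = 1e-3)
#' print(fit)
#' @export
fit_influence <- function(x, y, basis = NULL, sigma = 1e-3, penalty_order = 2,
                          variant = c("position", "conservation"),
                          outside = "error") {
  variant <- match.arg(variant)
  if (sigma < 0) stopf("sigma must be >= 0")
  if (anyNA(y) || any(!is.finite(y))) stopf("response contains non-finite values")
  if (inherits(x, "binding_profiles")) {
    if (is.null(basis))
      basis <- if (variant == "position") build_basis(-1e5, 1e5, 20) else build_basis(0, 1, 10)
    covariate <- if (variant == "position") "distance" else "conservation"
    B <- design_features(x, basis, covariate = covariate, outside = outside)
  } else {
    B <- as.matrix(x)
    if (is.null(basis)) stopf("basis must be supplied with a precomputed design matrix")
  }
  if (nrow(B) != length(y)) stopf("design has %d rows but response has %d values", nrow(B), length(y))
  if (nrow(B) < 1) stopf("at least one observation is required")
  D <- penalty_matrix(basis, penalty_order)
  cf <- solve_penalized(B, y, sigma, D)
  fitted <- drop(B %*% cf)
  structure(list(coefficients = cf, basis = basis, sigma = sigma,
                 penalty_order = penalty_order, variant = variant,
                 regulator_weights = NULL,
                 fitted.values = fitted, residuals = y - fitted,
                 y = y, mse = mean((y - fitted)^2), n = length(y),
                 call = match.call()),
            class = "influence_fit")
}

#' Select the regularization parameter by held-out error
#'
#' Grid search for \code{sigma}: the design rows are split once into an
#' inner training and validation set; the value minimizing validation MSE
#' is returned.
#'
#' @param B Design matrix.
#' @param y Response vector.
#' @param basis A \code{spline_basis} matching \code{B}.
#' @param candidates Candidate sigma values (default \code{10^(-5..2)}).
#' @param seed Seed for the inner split.
#' @param train_fraction Inner training fraction (default 2/3).
#' @param penalty_order Difference order of the penalty.
#' @return The selected sigma.
#' @export
select_sigma <- function(B, y, basis, candidates = 10^seq(-5, 2), seed = 1,
                         train_fraction = 2/3, penalty_order = 2) {
  n <- nrow(B)
  if (n < 3) stopf("need at least 3 observations to select sigma")
  idx <- with_seed(seed, sample.int(n, round(train_fraction * n)))
  D <- penalty_matrix(basis, penalty_order)
  err <- vapply(candidates, function(s) {
    cf <- tryCatch(solve_penalized(B[idx, , drop = FALSE], y[idx], s, D),
                   error = function(e) NULL)
    if (is.null(cf)) return(Inf)
    mean((y[-idx] - drop(B[-idx, , drop = FALSE] %*% cf))^2)
  }, numeric(1))
  candidates[which.min(err)]
}

#' Evaluate the fitted influence curve
#'
#' @param model An \code{influence_fit}.
#' @param grid Numeric vector of covariate values (bp for the position
#'   model).
#' @return Data frame with columns \code{d} and \code{influence}; points
#'   outside the basis domain evaluate to 0.
#' @export
influence_curve <- function(model, grid) {
  data.frame(d = grid,
             influence = drop(eval_basis(model$basis, grid) %*% model$coefficients))
}

#' Predict expression contributions for binding profiles
#'
#' Computes \code{sum_j alpha_j f(x_j)} per gene: the model's predicted
#' centered log expression. Genes with empty profiles predict 0 (the basal
#' level). With \code{newdata} missing, returns the fitted values.
#'
#' @param object An \code{influence_fit}.
#' @param newdata A \code{binding_profiles} object, or a design matrix.
#' @param ... Unused.
#' @return Named numeric vector of predictions.
#' @export
predict.influence_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  if (inherits(newdata, "binding_profiles") && !is.null(object$regulator_weights)) {
    # fold the per-site regulator weight a(regs) into alpha before the sum
    w <- object$regulator_weights
    rule <- object$weight_combine %||% "mean"
    att <- attributes(newdata)
    newdata <- lapply(newdata, function(e) {
      if (nrow(e)) e$alpha <- e$alpha * combine_weights(w, e$regulators, rule)
      e
    })
    attributes(newdata) <- att
  }
  B <- if (inherits(newdata, "binding_profiles")) {
    variant_design(newdata, object$basis, object$variant)
  } else as.matrix(newdata)
  drop(B %*% object$coefficients)
}

#' Predicted log fold change between two binding configurations
#'
#' Under the assumption that basal expression and degradation rates are
#' shared between conditions, the predicted log fold change of a gene is
#' the difference of its per-condition influence sums.
#'
#' @param model An \code{influence_fit}.
#' @param profiles_a,profiles_b \code{binding_profiles} for the same genes
#'   in conditions a and b (same gene names, same order).
#' @return Named numeric vector of predicted log fold changes (a vs b).
#' @export
predict_differential <- function(model, profiles_a, profiles_b) {
  if (!identical(names(profiles_a), names(profiles_b)))
    stopf("profiles_a and profiles_b must cover the same genes in the same order")
  predict(model, profiles_a) - predict(model, profiles_b)
}

#' @export
print.influence_fit <- function(x, ...) {
  cat(sprintf("influence_fit (%s variant): P = %d basis functions on [%s, %s], sigma = %g\n",
              x$variant, x$basis$n_basis, format(x$basis$domain[1], big.mark = ","),
              format(x$basis$domain[2], big.mark = ","), x$sigma))
  cat(sprintf("  n = %d genes, training MSE = %.4g\n", x$n, x$mse))
  if (!is.null(x$regulator_weights)) {
    cat("  regulator weights:\n")
    print(round(x$regulator_weights, 3))
  }
  invisible(x)
}

#' @export
summary.influence_fit <- function(object, ...) {
  grid <- seq(object$basis$domain[1], object$basis$domain[2], length.out = 401)
  curve <- influence_curve(object, grid)
  peak <- curve$d[which.max(curve$influence)]
  out <- list(fit = object, peak_position = peak,
              peak_influence = max(curve$influence),
              roughness = drop(crossprod(object$coefficients,
                                         penalty_matrix(object$basis, object$penalty_order) %*%
                                           object$coefficients)),
              r_squared = if (stats::var(object$y) > 0) 1 - object$mse / mean((object$y - mean(object$y))^2) else NA_real_)
  class(out) <- "summary.influence_fit"
  out
}

#' @export
print.summary.influence_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  peak influence %.4g at %s bp; roughness c'Dc = %.4g; R^2 = %.3f\n",
              x$peak_influence, format(x$peak_position, big.mark = ","), x$roughness,
              x$r_squared))
  invisible(x)
}

#' @export
coef.influence_fit <- function(object, ...) object$coefficients

#' @export
residuals.influence_fit <- function(object, ...) object$residuals

#' @export
fitted.influence_fit <- function(object, ...) object$fitted.values

#' Plot the fitted influence curve
#'
#' @param x An \code{influence_fit}.
#' @param n Number of grid points.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.influence_fit <- function(x, n = 401, ...) {
  grid <- seq(x$basis$domain[1], x$basis$domain[2], length.out = n)
  cv <- influence_curve(x, grid)
  xlab <- if (x$variant == "conservation") "conservation score" else "signed distance to TSS (bp)"
  graphics::plot(cv$d, cv$influence, type = "l", xlab = xlab,
                 ylab = "influence f", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(cv)
}

#' Simulate responses from a fitted influence model
#'
#' Draws \code{y = prediction + Normal(0, noise_sd)} for the supplied
#' profiles (or the training design when \code{newdata} is missing), with
#' \code{noise_sd} defaulting to the residual standard deviation.
#'
#' @param object An \code{influence_fit}.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed.
#' @param newdata Profiles or design matrix; training design by default.
#' @param noise_sd Noise standard deviation.
#' @param ... Unused.
#' @return A data frame with \code{nsim} columns.
#' @export
simulate.influence_fit <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                                   noise_sd = stats::sd(object$residuals), ...) {
  mu <- if (is.null(newdata)) object$fitted.values else predict(object, newdata)
  draw <- function() mu + stats::rnorm(length(mu), 0, noise_sd)
  sims <- if (is.null(seed)) replicate(nsim, draw())
          else with_seed(seed, replicate(nsim, draw()))
  sims <- matrix(sims, ncol = nsim)
  out <- as.data.frame(sims)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
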