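# Competing and extended model variants: uniform weighting, conservation
# weighting, per-regulator influence weights, affinity weighting.

# Design matrix for a variant. "uniform" ignores position entirely: one
# column holding each gene's total (alpha-weighted) site count.
variant_design <- function(profiles, basis, variant, outside = "error") {
  switch(variant,
    position = design_features(profiles, basis, covariate = "distance", outside = outside),
    conservation = design_features(profiles, basis, covariate = "conservation", outside = outside),
    uniform = matrix(vapply(profiles, function(e) sum(e$alpha), numeric(1)),
                     ncol = 1, dimnames = list(names(profiles), NULL)),
    stopf("unknown variant '%s'", variant))
}

default_basis <- function(variant, cutoff = 1e5, n_basis = 20) {
  switch(variant,
    position = build_basis(-cutoff, cutoff, n_basis),
    conservation = build_basis(0, 1, max(4, min(n_basis, 10))),
    uniform = NULL)
}

#' Fit a model variant
#'
#' One entry point for the three competing models: \code{"position"}
#' (influence as a spline in signed TSS distance), \code{"uniform"} (all
#' binding events weighted equally regardless of position: prediction is a
#' single fitted weight times the gene's site count) and
#' \code{"conservation"} (influence as a spline in the sites' conservation
#' scores). All three use the same penalized least-squares machinery; the
#' uniform model has a single unpenalized coefficient, so its fit equals
#' the closed form \code{w = sum(x*y) / sum(x^2)}.
#'
#' @param profiles A \code{binding_profiles} object.
#' @param y Response vector (one value per gene).
#' @param variant \code{"position"}, \code{"uniform"} or
#'   \code{"conservation"}.
#' @param basis A \code{spline_basis}; a default matching the variant is
#'   built when \code{NULL}. Ignored for \code{"uniform"}.
#' @param sigma Regularization parameter (ignored for \code{"uniform"}).
#' @param penalty_order Difference order of the penalty.
#' @param outside Passed to [design_features()].
#' @return An \code{influence_fit}.
#' @export
fit_variant_model <- function(profiles, y, variant = c("position", "uniform", "conservation"),
                              basis = NULL, sigma = 1e-3, penalty_order = 2,
                              outside = "error") {
  variant <- match.arg(variant)
  if (is.null(basis)) basis <- default_basis(variant, cutoff = attr(profiles, "cutoff") %||% 1e5)
  B <- variant_design(profiles, basis, variant, outside = outside)
  if (nrow(B) != length(y)) stopf("design has %d rows but response has %d values", nrow(B), length(y))
  D <- if (variant == "uniform") matrix(0, 1, 1) else penalty_matrix(basis, penalty_order)
  cf <- solve_penalized(B, y, if (variant == "uniform") 0 else sigma, D)
  fitted <- drop(B %*% cf)
  structure(list(coefficients = cf, basis = basis, sigma = sigma,
                 penalty_order = penalty_order, variant = variant,
                 regulator_weights = NULL,
                 fitted.values = fitted, residuals = y - fitted,
                 y = y, mse = mean((y - fitted)^2), n = length(y),
                 call = match.call()),
            class = "influence_fit")
}

#' @rdname fit_variant_model
#' @export
fit_uniform <- function(profiles, y) fit_variant_model(profiles, y, variant = "uniform")

#' @rdname fit_variant_model
#' @export
fit_conservation_model <- function(profiles, y, basis = NULL, sigma = 1e-3)
  fit_variant_model(profiles, y, variant = "conservation", basis = basis, sigma = sigma)

# Per-entry regulator share matrix for the "mean" combination rule:
# row j has 1/|regs_j| in the columns of the regulators bound at entry j.
regulator_shares <- function(reg_list, regulators) {
  M <- matrix(0, nrow = length(reg_list), ncol = length(regulators),
              dimnames = list(NULL, regulators))
  for (j in seq_along(reg_list)) {
    r <- reg_list[[j]]
    M[j, r] <- 1 / length(r)
  }
  M
}

combine_weights <- function(w, reg_list, combine) {
  lens <- lengths(reg_list)
  if (all(lens == 1L))  # single-label sites: all rules coincide
    return(unname(w[unlist(reg_list, use.names = FALSE)]))
  vapply(reg_list, function(r) {
    switch(combine,
           mean = mean(w[r]),
           product = prod(w[r]),
           max = max(w[r]))
  }, numeric(1))
}

#' Fit per-regulator influence weights
#'
#' Fits the bilinear model \code{y_i = sum_j a(regs_j) * alpha_j * f(d_j)}
#' where \code{a} combines per-regulator weights \code{w_r} over the
#' regulators bound at a site (mean by default) and \code{f} is the spline
#' influence function. Fitting alternates exact coordinate steps: (i) with
#' weights fixed, solve the penalized system for the curve coefficients;
#' (ii) with the curve fixed, solve least squares for the weights. The
#' designated reference regulator's weight is held at 1 throughout, which
#' fixes the scale ambiguity between \code{w} and \code{f} and keeps the
#' objective non-increasing. Weights are clamped to a small positive floor.
#'
#' For \code{combine = "product"} or \code{"max"} the weight step is not a
#' linear problem and is solved numerically (box-constrained BFGS); the
#' returned object records the combination rule used.
#'
#' @param profiles A \code{binding_profiles} object; every entry must carry
#'   at least one regulator label.
#' @param y Response vector.
#' @param basis A \code{spline_basis} (default 20 cubic functions over the
#'   profile cutoff).
#' @param sigma Regularization parameter for the curve step.
#' @param reference Name of the reference regulator (weight fixed at 1).
#' @param max_iter Maximum alternating rounds.
#' @param tol Relative objective-change convergence tolerance.
#' @param combine Multi-regulator combination rule: \code{"mean"}
#'   (default), \code{"product"} or \code{"max"}.
#' @return An object of class \code{regulator_weight_fit}: list with
#'   \code{model} (an \code{influence_fit} carrying the weights),
#'   \code{weights}, \code{iterations}, \code{converged}, \code{objective}
#'   (the non-increasing trace) and \code{combine}.
#' @export
fit_regulator_weights <- function(profiles, y, basis = NULL, sigma = 1e-3,
                                  reference = NULL, max_iter = 50, tol = 1e-9,
                                  combine = c("mean", "product", "max")) {
  combine <- match.arg(combine)
  if (is.null(basis)) basis <- default_basis("position", cutoff = attr(profiles, "cutoff") %||% 1e5)
  sizes <- profile_sizes(profiles)
  gene_idx <- rep(seq_along(profiles), sizes)
  d <- unlist(lapply(profiles, function(e) e$distance), use.names = FALSE)
  alpha <- unlist(lapply(profiles, function(e) e$alpha), use.names = FALSE)
  reg_list <- do.call(c, lapply(profiles, function(e) e$regulators))
  if (any(lengths(reg_list) == 0))
    stopf("every site must carry at least one regulator label")
  regulators <- sort(unique(unlist(reg_list)))
  if (is.null(reference)) reference <- regulators[1]
  if (!reference %in% regulators) stopf("reference regulator '%s' not found", reference)
  others <- setdiff(regulators, reference)

  N <- length(y)
  D <- penalty_matrix(basis, 2)
  Bsite <- eval_basis(basis, d) * alpha      # per-entry basis rows, alpha folded in
  M <- regulator_shares(reg_list, regulators)

  w <- stats::setNames(rep(1, length(regulators)), regulators)
  floor_w <- 1e-6
  # per-entry site weight a(regs); the mean rule is the linear map M %*% w
  site_weights <- function(wts) {
    if (combine == "mean") drop(M %*% wts) else combine_weights(wts, reg_list, combine)
  }
  objective <- function(cf, wts) {
    pred <- numeric(N)
    contrib <- drop(Bsite %*% cf) * site_weights(wts)
    agg <- rowsum(contrib, gene_idx)
    pred[as.integer(rownames(agg))] <- agg
    mean((y - pred)^2) + sigma * drop(crossprod(cf, D %*% cf))
  }

  trace <- numeric(0)
  converged <- FALSE
  cf <- NULL
  for (it in seq_len(max_iter)) {
    ## curve step: penalized solve with weights fixed
    a <- site_weights(w)
    Bg <- matrix(0, nrow = N, ncol = basis$n_basis)
    agg <- rowsum(Bsite * a, gene_idx)
    Bg[as.integer(rownames(agg)), ] <- agg
    cf <- solve_penalized(Bg, y, sigma, D)

    ## weight step: curve fixed, reference weight held at 1
    fj <- drop(Bsite %*% cf)
    obj_it <- NULL
    if (combine == "mean" && length(others)) {
      X <- matrix(0, nrow = N, ncol = length(regulators), dimnames = list(NULL, regulators))
      aggX <- rowsum(M * fj, gene_idx)
      X[as.integer(rownames(aggX)), ] <- aggX
      y_adj <- y - X[, reference]
      Xo <- X[, others, drop = FALSE]
      wo <- tryCatch(drop(solve(crossprod(Xo), crossprod(Xo, y_adj))),
                     error = function(e) w[others])
      w_new <- w
      w_new[others] <- pmax(wo, floor_w)
      # the exact LS step cannot increase the objective; only a clamped
      # step needs the explicit monotonicity check
      if (all(wo >= floor_w) || objective(cf, w_new) <= objective(cf, w))
        w <- w_new
      # with the mean rule, predictions are X %*% w: reuse X for the trace
      obj_it <- mean((y - drop(X %*% w))^2) + sigma * drop(crossprod(cf, D %*% cf))
    } else if (length(others)) {
      obj_o <- function(wo) {
        wt <- w; wt[others] <- wo
        objective(cf, wt)
      }
      opt <- stats::optim(w[others], obj_o, method = "L-BFGS-B",
                          lower = floor_w, upper = Inf)
      wt <- w; wt[others] <- opt$par
      if (objective(cf, wt) <= objective(cf, w)) w <- wt
    }

    trace <- c(trace, obj_it %||% objective(cf, w))
    if (it > 1 && abs(trace[it - 1] - trace[it]) < tol * max(1, abs(trace[it - 1]))) {
      converged <- TRUE
      break
    }
  }
  ## refresh the curve for the final weights
  a <- site_weights(w)
  Bg <- matrix(0, nrow = N, ncol = basis$n_basis)
  agg <- rowsum(Bsite * a, gene_idx)
  Bg[as.integer(rownames(agg)), ] <- agg
  cf <- solve_penalized(Bg, y, sigma, D)
  trace <- c(trace, objective(cf, w))

  fitted <- numeric(N)
  contrib <- drop(Bsite %*% cf) * a
  aggp <- rowsum(contrib, gene_idx)
  fitted[as.integer(rownames(aggp))] <- aggp
  model <- structure(list(coefficients = cf, basis = basis, sigma = sigma,
                          penalty_order = 2, variant = "position",
                          regulator_weights = w, weight_combine = combine,
                          fitted.values = fitted, residuals = y - fitted,
                          y = y, mse = mean((y - fitted)^2), n = N,
                          call = match.call()),
                     class = "influence_fit")
  structure(list(model = model, weights = w, reference = reference,
                 iterations = length(trace) - 1L, converged = converged,
                 objective = trace, combine = combine),
            class = "regulator_weight_fit")
}

#' @export
print.regulator_weight_fit <- function(x, ...) {
  cat(sprintf("regulator_weight_fit: %d regulators (reference '%s' = 1), %d rounds, %s\n",
              length(x$weights), x$reference, x$iterations,
              if (x$converged) "converged" else "not converged"))
  print(round(sort(x$weights, decreasing = TRUE), 3))
  cat(sprintf("  final objective %.6g (combine rule: %s)\n",
              x$objective[length(x$objective)], x$combine))
  invisible(x)
}

#' Reweight site modifiers by ChIP enrichment (affinity)
#'
#' Upweights sites with higher ChIP enrichment ratios: each entry's
#' modifier becomes
#' \code{alpha * (enrichment / median_enrichment)^gamma}, with the median
#' taken over the distinct sites appearing in the profile set (i.e. over
#' the tissue's sites). \code{gamma = 0} leaves the profiles unchanged.
#'
#' @param profiles A \code{binding_profiles} object whose entries carry
#'   enrichment ratios.
#' @param gamma Affinity exponent (default 1).
#' @return The profile set with updated \code{alpha} values.
#' @export
apply_affinity_weights <- function(profiles, gamma = 1) {
  if (gamma == 0) return(profiles)
  ids <- unlist(lapply(profiles, function(e) e$site_id), use.names = FALSE)
  enr <- unlist(lapply(profiles, function(e) e$enrichment), use.names = FALSE)
  if (anyNA(enr)) stopf("site(s) missing enrichment ratio")
  med <- stats::median(enr[!duplicated(ids)])
  out <- lapply(profiles, function(e) {
    e$alpha <- e$alpha * (e$enrichment / med)^gamma
    e
  })
  attributes(out) <- attributes(profiles)
  out
}
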