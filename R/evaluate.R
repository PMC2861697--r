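# Evaluation protocol: repeated train/test splits, bootstrap influence
# bands, permutation controls and paired model comparisons. All
# randomness is driven by explicit seeds derived from one base seed, so
# identical seeds give identical reports.

#' Center and scale expression values
#'
#' Mean-centers and scales by the population standard deviation
#' (\code{sqrt(mean((x - mean(x))^2))}). The transform parameters are
#' attached as attributes \code{center} and \code{scale} for inverse
#' mapping.
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @return The standardized vector.
#' @export
normalize_expression <- function(values) {
  if (length(unique(values)) < 2) stopf("cannot standardize a constant vector")
  ctr <- mean(values)
  scl <- sqrt(mean((values - ctr)^2))
  structure((values - ctr) / scl, center = ctr, scale = scl)
}

#' Random train/test split of genes
#'
#' Assigns \code{round(train_fraction * N)} genes to the training set and
#' the rest to the test set, deterministically for a given seed.
#'
#' @param gene_ids Character vector of gene ids (>= 3).
#' @param train_fraction Training fraction (default 2/3).
#' @param seed Integer seed.
#' @return List with \code{train} and \code{test} id vectors.
#' @export
split_train_test <- function(gene_ids, train_fraction = 2/3, seed = 1) {
  n <- length(gene_ids)
  if (n < 3) stopf("need at least 3 genes to split")
  idx <- with_seed(seed, sample.int(n, round(train_fraction * n)))
  list(train = gene_ids[idx], test = gene_ids[-idx])
}

# ---------------------------------------------------------------------------
# Design assembly shared by all evaluation entry points.
#
# Returns the response and one design matrix per requested variant /
# assignment arm, restricted to bound genes (>= 1 associated site within
# the cutoff in >= 1 analyzed tissue) and, in differential mode, to genes
# flagged differential when the expression table carries that flag.

assemble_design <- function(tss, sites, expression, mode, variant, cutoff,
                            assignment = "multi", n_basis = 20,
                            conserved_only = FALSE, conservation_threshold = NULL,
                            affinity_gamma = NULL, normalize = TRUE,
                            tissues = NULL) {
  assoc <- switch(assignment, multi = associate_sites,
                  nearest = nearest_gene_assignment,
                  stopf("unknown assignment mode '%s'", assignment))
  all_tissues <- names(sites)
  if (is.null(tissues))
    tissues <- if (mode == "absolute") all_tissues[1] else all_tissues[1:2]
  profs <- lapply(tissues, function(t) {
    p <- assoc(tss, sites[[t]], cutoff)
    if (conserved_only) {
      if (is.null(conservation_threshold)) stopf("conserved_only requires a conservation threshold")
      p <- filter_profiles(p, function(e) !is.na(e$conservation) &
                             e$conservation > conservation_threshold)
    }
    if (!is.null(affinity_gamma)) p <- apply_affinity_weights(p, affinity_gamma)
    p
  })
  names(profs) <- tissues

  # bound-gene filter always uses unfiltered multi-gene association so that
  # all arms of a paired comparison (nearest-gene, conserved-only) keep the
  # same gene set
  bound_ref <- lapply(tissues, function(t)
    profile_sizes(associate_sites(tss, sites[[t]], cutoff)) > 0)
  bound <- Reduce(`|`, bound_ref)
  keep <- bound
  if (mode == "differential" && "differential" %in% names(expression)) {
    de <- expression$differential[match(tss$gene_id, expression$gene_id)]
    keep <- keep & !is.na(de) & de
  }
  ord <- match(tss$gene_id, expression$gene_id)
  if (anyNA(ord)) stopf("expression table missing %d gene(s)", sum(is.na(ord)))
  y <- if (mode == "absolute") {
    expression[[tissues[1]]][ord]
  } else {
    expression[[tissues[1]]][ord] - expression[[tissues[2]]][ord]
  }
  keep <- keep & !is.na(y)
  if (!any(keep)) stopf("zero bound genes at cutoff %s", format(cutoff, big.mark = ","))
  y <- y[keep]
  if (normalize) y <- normalize_expression(y)

  basis <- default_basis(variant, cutoff = cutoff, n_basis = n_basis)
  Bs <- lapply(profs, function(p)
    variant_design(p, basis, variant)[keep, , drop = FALSE])
  B <- if (mode == "absolute") Bs[[1]] else Bs[[1]] - Bs[[2]]
  list(B = B, y = as.numeric(y), gene_ids = tss$gene_id[keep], basis = basis,
       tissues = tissues)
}

fit_rows <- function(B, y, idx, sigma, D)
  solve_penalized(B[idx, , drop = FALSE], y[idx], sigma, D)

trial_metrics <- function(pred, obs) {
  c(mse = mean((obs - pred)^2),
    pearson = safe_cor(pred, obs, "pearson"),
    spearman = safe_cor(pred, obs, "spearman"))
}

summarize_trials <- function(trials) {
  stats_for <- function(col) {
    v <- trials[[col]]
    c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE),
      median = stats::median(v, na.rm = TRUE))
  }
  lapply(stats::setNames(nm = setdiff(names(trials), c("trial", "seed"))), stats_for)
}

new_report <- function(trials, config) {
  structure(list(trials = trials, summary = summarize_trials(trials),
                 config = config), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("evaluation_report: %s\n",
              paste(sprintf("%s=%s", names(cfg), vapply(cfg, function(v)
                paste(format(v), collapse = "/"), "")), collapse = ", ")))
  for (m in names(x$summary)) {
    s <- x$summary[[m]]
    cat(sprintf("  %-18s mean %8.4f  sd %7.4f  median %8.4f\n",
                m, s[["mean"]], s[["sd"]], s[["median"]]))
  }
  invisible(x)
}

#' Repeated train/test evaluation of a model variant
#'
#' Runs the evaluation protocol: restrict to bound genes at the given
#' cutoff (and, in differential mode, to flagged differentially expressed
#' genes), standardize the response, then repeatedly split genes 2:1 into
#' training and test sets, fit the variant on the training set and record
#' held-out MSE and Pearson/Spearman correlations.
#'
#' @param tss TSS data frame.
#' @param sites Named list of per-tissue site data frames.
#' @param expression Expression data frame (gene_id, tissue columns,
#'   optional \code{differential} flag).
#' @param mode \code{"absolute"} (first tissue's level) or
#'   \code{"differential"} (first minus second tissue).
#' @param variant Model variant: \code{"position"}, \code{"uniform"} or
#'   \code{"conservation"}.
#' @param cutoff Association cutoff in bp; also the position basis domain.
#' @param n_trials Number of random splits (default 100).
#' @param base_seed Base seed; trial seeds are derived from it.
#' @param sigma Regularization parameter, or \code{"auto"} to select once
#'   by inner held-out error before the trials.
#' @param n_basis Spline basis size for the position model.
#' @param assignment Site-to-gene assignment: \code{"multi"} or
#'   \code{"nearest"}.
#' @param normalize Standardize the response (default TRUE).
#' @param conserved_only Drop sites at or below
#'   \code{conservation_threshold} before fitting.
#' @param conservation_threshold Threshold used when
#'   \code{conserved_only = TRUE}.
#' @param affinity_gamma If non-NULL, apply [apply_affinity_weights()]
#'   with this exponent.
#' @param tissues Tissue subset/order override.
#' @param train_fraction Training fraction (default 2/3).
#' @return An \code{evaluation_report}.
#' @export
run_experiment <- function(tss, sites, expression, mode = c("absolute", "differential"),
                           variant = c("position", "uniform", "conservation"),
                           cutoff = 1e5, n_trials = 100, base_seed = 1,
                           sigma = "auto", n_basis = 20, assignment = "multi",
                           normalize = TRUE, conserved_only = FALSE,
                           conservation_threshold = NULL, affinity_gamma = NULL,
                           tissues = NULL, train_fraction = 2/3) {
  mode <- match.arg(mode); variant <- match.arg(variant)
  dz <- assemble_design(tss, sites, expression, mode, variant, cutoff,
                        assignment = assignment, n_basis = n_basis,
                        conserved_only = conserved_only,
                        conservation_threshold = conservation_threshold,
                        affinity_gamma = affinity_gamma, normalize = normalize,
                        tissues = tissues)
  D <- if (variant == "uniform") matrix(0, 1, 1) else penalty_matrix(dz$basis, 2)
  if (identical(sigma, "auto"))
    sigma <- if (variant == "uniform") 0 else select_sigma(dz$B, dz$y, dz$basis, seed = base_seed)
  seeds <- derive_seeds(base_seed, n_trials)
  n <- length(dz$y)
  rows <- lapply(seq_len(n_trials), function(i) {
    idx <- with_seed(seeds[i], sample.int(n, round(train_fraction * n)))
    cf <- fit_rows(dz$B, dz$y, idx, sigma, D)
    m <- trial_metrics(drop(dz$B[-idx, , drop = FALSE] %*% cf), dz$y[-idx])
    c(trial = i, seed = seeds[i], m)
  })
  trials <- as.data.frame(do.call(rbind, rows))
  new_report(trials, list(mode = mode, variant = variant, cutoff = cutoff,
                          assignment = assignment, sigma = sigma,
                          n_basis = n_basis, n_genes = n,
                          conserved_only = conserved_only,
                          n_trials = n_trials, base_seed = base_seed))
}

#' Permutation control for the evaluation protocol
#'
#' Repeats the train/test protocol with the (standardized) response
#' randomly permuted across genes before each trial, and records alongside
#' each trial the baseline MSE of predicting the training-set mean. Under
#' this null the model should do no better than the baseline.
#'
#' @inheritParams run_experiment
#' @param n_perm Number of permutation trials (default 100).
#' @return An \code{evaluation_report} whose trials carry an extra
#'   \code{baseline_mse} column.
#' @export
permutation_control <- function(tss, sites, expression, mode = c("absolute", "differential"),
                                variant = "position", cutoff = 1e5, n_perm = 100,
                                base_seed = 1, sigma = 1e-3, n_basis = 20,
                                assignment = "multi", normalize = TRUE,
                                tissues = NULL, train_fraction = 2/3) {
  mode <- match.arg(mode)
  dz <- assemble_design(tss, sites, expression, mode, variant, cutoff,
                        assignment = assignment, n_basis = n_basis,
                        normalize = normalize, tissues = tissues)
  D <- if (variant == "uniform") matrix(0, 1, 1) else penalty_matrix(dz$basis, 2)
  n <- length(dz$y)
  perm_seeds <- derive_seeds(base_seed, n_perm, stream = 1L)
  split_seeds <- derive_seeds(base_seed, n_perm, stream = 2L)
  rows <- lapply(seq_len(n_perm), function(i) {
    yp <- with_seed(perm_seeds[i], sample(dz$y))
    idx <- with_seed(split_seeds[i], sample.int(n, round(train_fraction * n)))
    cf <- fit_rows(dz$B, yp, idx, sigma, D)
    m <- trial_metrics(drop(dz$B[-idx, , drop = FALSE] %*% cf), yp[-idx])
    c(trial = i, seed = perm_seeds[i], m,
      baseline_mse = mean((yp[-idx] - mean(yp[idx]))^2))
  })
  trials <- as.data.frame(do.call(rbind, rows))
  new_report(trials, list(mode = mode, variant = variant, cutoff = cutoff,
                          control = "permutation", sigma = sigma,
                          n_genes = n, n_trials = n_perm, base_seed = base_seed))
}

#' Bootstrap confidence band for the influence curve
#'
#' Resamples genes with replacement, refits the position model on each
#' resample and evaluates the fitted influence curve on a distance grid.
#' The band is the pointwise empirical \code{(1 - level)/2} and
#' \code{(1 + level)/2} quantile envelope around the pointwise median.
#' Degenerate resamples (constant response) are skipped and counted.
#'
#' By default the response is \emph{not} standardized, so the fitted curves
#' are on the response's natural scale and directly comparable to a known
#' generating influence function.
#'
#' @inheritParams run_experiment
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param level Band level (default 0.99).
#' @param grid Distance grid (default 1 kb steps over +/- cutoff).
#' @return A \code{bootstrap_band}: list with \code{grid}, \code{median},
#'   \code{lower}, \code{upper}, \code{n_boot}, \code{level},
#'   \code{n_skipped}.
#' @export
bootstrap_influence <- function(tss, sites, expression, mode = c("absolute", "differential"),
                                cutoff = 1e5, n_boot = 1000, level = 0.99,
                                grid = seq(-cutoff, cutoff, by = 1000),
                                base_seed = 1, sigma = 1e-3, n_basis = 20,
                                normalize = FALSE, tissues = NULL) {
  mode <- match.arg(mode)
  if (n_boot < 2) stopf("n_boot must be >= 2")
  dz <- assemble_design(tss, sites, expression, mode, "position", cutoff,
                        n_basis = n_basis, normalize = normalize, tissues = tissues)
  D <- penalty_matrix(dz$basis, 2)
  G <- eval_basis(dz$basis, grid)
  n <- length(dz$y)
  seeds <- derive_seeds(base_seed, n_boot)
  curves <- matrix(NA_real_, nrow = n_boot, ncol = length(grid))
  skipped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- with_seed(seeds[b], sample.int(n, n, replace = TRUE))
    if (length(unique(dz$y[idx])) < 2) { skipped <- skipped + 1L; next }
    cf <- fit_rows(dz$B, dz$y, idx, sigma, D)
    curves[b, ] <- drop(G %*% cf)
  }
  curves <- curves[stats::complete.cases(curves), , drop = FALSE]
  if (!nrow(curves)) stopf("all bootstrap replicates were degenerate")
  qs <- apply(curves, 2, stats::quantile,
              probs = c((1 - level) / 2, 0.5, (1 + level) / 2), names = FALSE)
  structure(list(grid = grid, lower = qs[1, ], median = qs[2, ], upper = qs[3, ],
                 n_boot = n_boot, level = level, n_skipped = skipped,
                 sigma = sigma, cutoff = cutoff),
            class = "bootstrap_band")
}

#' @export
print.bootstrap_band <- function(x, ...) {
  cat(sprintf("bootstrap_band: %d replicates (%d skipped), %.0f%% band on %d grid points\n",
              x$n_boot, x$n_skipped, 100 * x$level, length(x$grid)))
  invisible(x)
}

#' Plot a bootstrap influence band
#' @param x A \code{bootstrap_band}.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bootstrap_band <- function(x, ...) {
  graphics::plot(x$grid, x$median, type = "n", ylim = range(x$lower, x$upper),
                 xlab = "signed distance to TSS (bp)", ylab = "influence f", ...)
  graphics::polygon(c(x$grid, rev(x$grid)), c(x$lower, rev(x$upper)),
                    col = "grey85", border = NA)
  graphics::lines(x$grid, x$median)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

# Paired trials over two prebuilt designs sharing one response. The same
# split is reused in both arms (paired design).
paired_trials <- function(B_a, B_b, y, basis_a, basis_b, variant_a, variant_b,
                          n_trials, base_seed, sigma_a, sigma_b,
                          train_fraction = 2/3, labels = c("a", "b")) {
  D_a <- if (variant_a == "uniform") matrix(0, 1, 1) else penalty_matrix(basis_a, 2)
  D_b <- if (variant_b == "uniform") matrix(0, 1, 1) else penalty_matrix(basis_b, 2)
  n <- length(y)
  seeds <- derive_seeds(base_seed, n_trials)
  rows <- lapply(seq_len(n_trials), function(i) {
    idx <- with_seed(seeds[i], sample.int(n, round(train_fraction * n)))
    cf_a <- fit_rows(B_a, y, idx, sigma_a, D_a)
    cf_b <- fit_rows(B_b, y, idx, sigma_b, D_b)
    mse_a <- mean((y[-idx] - drop(B_a[-idx, , drop = FALSE] %*% cf_a))^2)
    mse_b <- mean((y[-idx] - drop(B_b[-idx, , drop = FALSE] %*% cf_b))^2)
    c(trial = i, seed = seeds[i], mse_a = mse_a, mse_b = mse_b,
      diff = mse_a - mse_b)
  })
  trials <- as.data.frame(do.call(rbind, rows))
  names(trials)[3:5] <- c(paste0("mse_", labels), "diff")
  trials
}

#' Paired comparison of multi-gene vs nearest-gene site assignment
#'
#' Fits the position model under both association modes on identical
#' train/test splits and reports the paired held-out MSE difference
#' (nearest minus multi; positive means multi-gene wins). The gene set is
#' the multi-gene bound set so both arms score the same genes.
#'
#' @inheritParams run_experiment
#' @return An \code{evaluation_report} with per-trial \code{mse_multi},
#'   \code{mse_nearest} and \code{diff = mse_nearest - mse_multi}.
#' @export
compare_assignment_modes <- function(tss, sites, expression,
                                     mode = c("absolute", "differential"),
                                     cutoff = 1e5, n_trials = 100, base_seed = 1,
                                     sigma = 1e-3, n_basis = 20, normalize = TRUE,
                                     tissues = NULL, train_fraction = 2/3) {
  mode <- match.arg(mode)
  dz_m <- assemble_design(tss, sites, expression, mode, "position", cutoff,
                          assignment = "multi", n_basis = n_basis,
                          normalize = normalize, tissues = tissues)
  dz_n <- assemble_design(tss, sites, expression, mode, "position", cutoff,
                          assignment = "nearest", n_basis = n_basis,
                          normalize = normalize, tissues = tissues)
  # the bound filter is identical in both arms (it always uses multi-gene
  # association), so the designs are row-aligned
  stopifnot(identical(dz_m$gene_ids, dz_n$gene_ids))
  trials <- paired_trials(dz_n$B, dz_m$B, dz_m$y, dz_n$basis, dz_m$basis,
                          "position", "position", n_trials, base_seed,
                          sigma, sigma, train_fraction,
                          labels = c("nearest", "multi"))
  trials$diff <- trials$mse_nearest - trials$mse_multi
  new_report(trials, list(mode = mode, comparison = "nearest_vs_multi",
                          cutoff = cutoff, sigma = sigma,
                          n_genes = length(dz_m$y), n_trials = n_trials,
                          base_seed = base_seed))
}

#' Paired comparison of conserved-only vs all-sites fitting
#'
#' Fits the position model once using all associated sites and once using
#' only sites with conservation strictly above the threshold, on identical
#' splits and the same (all-sites bound) gene set. Reports the paired
#' held-out MSE difference (conserved-only minus all-sites; positive means
#' the non-conserved sites carried predictive signal).
#'
#' @inheritParams run_experiment
#' @param threshold Conservation threshold defining "conserved".
#' @return An \code{evaluation_report} with per-trial
#'   \code{mse_conserved}, \code{mse_all} and
#'   \code{diff = mse_conserved - mse_all}.
#' @export
conserved_only_comparison <- function(tss, sites, expression, threshold,
                                      mode = c("absolute", "differential"),
                                      cutoff = 1e5, n_trials = 100, base_seed = 1,
                                      sigma = 1e-3, n_basis = 20, normalize = TRUE,
                                      tissues = NULL, train_fraction = 2/3) {
  mode <- match.arg(mode)
  dz_all <- assemble_design(tss, sites, expression, mode, "position", cutoff,
                            n_basis = n_basis, normalize = normalize,
                            tissues = tissues)
  dz_con <- assemble_design(tss, sites, expression, mode, "position", cutoff,
                            n_basis = n_basis, conserved_only = TRUE,
                            conservation_threshold = threshold,
                            normalize = normalize, tissues = tissues)
  stopifnot(identical(dz_all$gene_ids, dz_con$gene_ids))
  trials <- paired_trials(dz_con$B, dz_all$B, dz_all$y, dz_con$basis, dz_all$basis,
                          "position", "position", n_trials, base_seed,
                          sigma, sigma, train_fraction,
                          labels = c("conserved", "all"))
  trials$diff <- trials$mse_conserved - trials$mse_all
  new_report(trials, list(mode = mode, comparison = "conserved_only_vs_all",
                          threshold = threshold, cutoff = cutoff, sigma = sigma,
                          n_genes = length(dz_all$y), n_trials = n_trials,
                          base_seed = base_seed))
}

#' Paired comparison of two model variants
#'
#' Fits two variants on identical splits and the same gene set and reports
#' the paired held-out MSE difference (\code{variant_a} minus
#' \code{variant_b}).
#'
#' @inheritParams run_experiment
#' @param variant_a,variant_b The two variants to compare.
#' @param sigma_a,sigma_b Regularization for each arm (\code{"auto"}
#'   selects per arm before the trials).
#' @return An \code{evaluation_report}.
#' @export
compare_variants <- function(tss, sites, expression, variant_a, variant_b,
                             mode = c("absolute", "differential"), cutoff = 1e5,
                             n_trials = 100, base_seed = 1, sigma_a = "auto",
                             sigma_b = "auto", n_basis = 20, normalize = TRUE,
                             tissues = NULL, train_fraction = 2/3) {
  mode <- match.arg(mode)
  dz_a <- assemble_design(tss, sites, expression, mode, variant_a, cutoff,
                          n_basis = n_basis, normalize = normalize, tissues = tissues)
  dz_b <- assemble_design(tss, sites, expression, mode, variant_b, cutoff,
                          n_basis = n_basis, normalize = normalize, tissues = tissues)
  stopifnot(identical(dz_a$gene_ids, dz_b$gene_ids))
  pick_sigma <- function(sig, dz, variant) {
    if (!identical(sig, "auto")) return(sig)
    if (variant == "uniform") 0 else select_sigma(dz$B, dz$y, dz$basis, seed = base_seed)
  }
  sa <- pick_sigma(sigma_a, dz_a, variant_a)
  sb <- pick_sigma(sigma_b, dz_b, variant_b)
  trials <- paired_trials(dz_a$B, dz_b$B, dz_a$y, dz_a$basis, dz_b$basis,
                          variant_a, variant_b, n_trials, base_seed, sa, sb,
                          train_fraction, labels = c(variant_a, variant_b))
  new_report(trials, list(mode = mode,
                          comparison = paste(variant_a, "vs", variant_b),
                          cutoff = cutoff, sigma_a = sa, sigma_b = sb,
                          n_genes = length(dz_a$y), n_trials = n_trials,
                          base_seed = base_seed))
}
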