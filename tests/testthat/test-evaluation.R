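test_that("expression normalization centers and scales by population sd", {
  z <- normalize_expression(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(attr(z, "center"), 2)
  expect_equal(attr(z, "scale"), sqrt(2 / 3))
  # idempotent on already-standardized input
  z2 <- normalize_expression(as.numeric(z))
  expect_equal(as.numeric(z2), as.numeric(z), tolerance = 1e-12)
  expect_error(normalize_expression(rep(5, 4)), "constant")
})

test_that("train/test splits are 2:1, disjoint, exhaustive and seeded", {
  ids <- sprintf("g%02d", 1:9)
  sp <- split_train_test(ids, seed = 4)
  expect_length(sp$train, 6L)
  expect_length(sp$test, 3L)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_identical(sp, split_train_test(ids, seed = 4))
  expect_false(identical(sp$train, split_train_test(ids, seed = 5)$train))
  expect_error(split_train_test(ids[1:2]), "at least 3")
})

test_that("expression table reader validates ids and cells", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tliver\tcerebellum\tdifferential",
               "g1\t1.5\t0.2\tTRUE", "g2\t-0.3\t0.9\tFALSE"), f)
  tab <- read_expression_table(f)
  expect_equal(tab$liver, c(1.5, -0.3))
  expect_identical(tab$differential, c(TRUE, FALSE))
  writeLines(c("gene_id\tliver", "g1\t1.0", "g1\t2.0"), f)
  expect_error(read_expression_table(f), "duplicate")
  writeLines(c("gene_id\tliver", "g1\tNaN"), f)
  expect_error(read_expression_table(f), "non-finite")
})

test_that("run_experiment is deterministic and near-perfect on noise-free data", {
  spec <- synthetic_spec(n_genes = 250, noise_sd = 0)
  st <- simulate_study(spec, seed = 97)
  r1 <- run_experiment(st$tss, st$sites, st$expression, mode = "absolute",
                       variant = "position", cutoff = 1e5, n_trials = 8,
                       base_seed = 21, sigma = 1e-6, normalize = FALSE)
  r2 <- run_experiment(st$tss, st$sites, st$expression, mode = "absolute",
                       variant = "position", cutoff = 1e5, n_trials = 8,
                       base_seed = 21, sigma = 1e-6, normalize = FALSE)
  expect_identical(r1$trials, r2$trials)
  expect_true(all(r1$trials$pearson >= 0.999))
  r3 <- run_experiment(st$tss, st$sites, st$expression, mode = "absolute",
                       variant = "position", cutoff = 1e5, n_trials = 8,
                       base_seed = 22, sigma = 1e-6, normalize = FALSE)
  expect_false(identical(r1$trials$seed, r3$trials$seed))
})

test_that("differential mode restricts to flagged genes and uses design differences", {
  st <- small_study(n_genes = 300, seed = 101, tissue_unique_fraction = 0.6)
  rep <- run_experiment(st$tss, st$sites, st$expression, mode = "differential",
                        variant = "position", cutoff = 1e5, n_trials = 5,
                        base_seed = 7, sigma = 1e-3)
  expect_lte(rep$config$n_genes, sum(st$expression$differential))
  expect_true(all(rep$trials$mse >= 0))
  expect_true(all(abs(rep$trials$pearson) <= 1, na.rm = TRUE))
})

test_that("permutation trials carry a train-mean baseline near 1 on standardized y", {
  st <- small_study(n_genes = 400, seed = 103, noise_sd = 0.5)
  pc <- permutation_control(st$tss, st$sites, st$expression, mode = "absolute",
                            cutoff = 1e5, n_perm = 25, base_seed = 17, sigma = 1e-3)
  expect_equal(nrow(pc$trials), 25L)
  expect_equal(mean(pc$trials$baseline_mse), 1, tolerance = 0.1)
  # deterministic given the base seed
  pc2 <- permutation_control(st$tss, st$sites, st$expression, mode = "absolute",
                             cutoff = 1e5, n_perm = 25, base_seed = 17, sigma = 1e-3)
  expect_identical(pc$trials, pc2$trials)
})

test_that("bootstrap bands are ordered, sized and reproducible", {
  st <- small_study(n_genes = 300, seed = 107, noise_sd = 0.5)
  grid <- seq(-1e5, 1e5, by = 5000)
  bb <- bootstrap_influence(st$tss, st$sites, st$expression, cutoff = 1e5,
                            n_boot = 40, level = 0.95, grid = grid,
                            base_seed = 31, sigma = 1e-3)
  expect_true(all(bb$lower <= bb$median + 1e-12))
  expect_true(all(bb$median <= bb$upper + 1e-12))
  expect_length(bb$median, length(grid))
  bb2 <- bootstrap_influence(st$tss, st$sites, st$expression, cutoff = 1e5,
                             n_boot = 40, level = 0.95, grid = grid,
                             base_seed = 31, sigma = 1e-3)
  expect_identical(bb[c("lower", "median", "upper")],
                   bb2[c("lower", "median", "upper")])
  expect_error(bootstrap_influence(st$tss, st$sites, st$expression, n_boot = 1),
               "n_boot")
})

test_that("assignment modes coincide when every site has one candidate gene", {
  # genes spaced farther than twice the cutoff: multi-gene and nearest-gene
  # association are then identical
  spec <- synthetic_spec(n_genes = 60, min_spacing = 250000,
                        chrom_length = 60 * 260000 + 2e5 + 2000,
                        distance_max = 1e5, noise_sd = 0.3)
  st <- simulate_study(spec, seed = 109)
  cm <- compare_assignment_modes(st$tss, st$sites, st$expression,
                                 mode = "absolute", cutoff = 1e5, n_trials = 6,
                                 base_seed = 13, sigma = 1e-3)
  expect_equal(cm$trials$mse_multi, cm$trials$mse_nearest, tolerance = 1e-12)
  expect_equal(cm$trials$diff, numeric(6), tolerance = 1e-12)
})

test_that("conserved-only comparison is a no-op when no sites are removed", {
  st <- small_study(n_genes = 200, seed = 113)
  cc <- conserved_only_comparison(st$tss, st$sites, st$expression,
                                  threshold = -0.01, mode = "absolute",
                                  cutoff = 1e5, n_trials = 5, base_seed = 19,
                                  sigma = 1e-3)
  expect_equal(cc$trials$diff, numeric(5), tolerance = 1e-12)
  # threshold above every score: conserved arm has no features and
  # predictions collapse to 0, so its MSE is ~1 on standardized y
  cc2 <- conserved_only_comparison(st$tss, st$sites, st$expression,
                                   threshold = 1, mode = "absolute",
                                   cutoff = 1e5, n_trials = 5, base_seed = 19,
                                   sigma = 1e-3)
  expect_equal(mean(cc2$trials$mse_conserved), 1, tolerance = 0.15)
})

test_that("held-out accuracy improves with sample size and degrades with noise", {
  cors <- sapply(c(100, 500), function(n) {
    st <- small_study(n_genes = n, seed = 127, noise_sd = 0.5)
    r <- run_experiment(st$tss, st$sites, st$expression, mode = "absolute",
                        variant = "position", cutoff = 1e5, n_trials = 10,
                        base_seed = 3, sigma = 1e-3)
    r$summary$pearson[["mean"]]
  })
  expect_gt(cors[2], cors[1])
  cors_noise <- sapply(c(0.2, 1.5), function(sd) {
    st <- small_study(n_genes = 300, seed = 131, noise_sd = sd)
    r <- run_experiment(st$tss, st$sites, st$expression, mode = "absolute",
                        variant = "position", cutoff = 1e5, n_trials = 10,
                        base_seed = 3, sigma = 1e-3)
    r$summary$pearson[["mean"]]
  })
  expect_gt(cors_noise[1], cors_noise[2])
})
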