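test_that("basis is a partition of unity inside the domain and zero outside", {
  bs <- build_basis(-1e5, 1e5, n_basis = 12)
  x <- seq(-1e5, 1e5, length.out = 101)
  expect_equal(rowSums(eval_basis(bs, x)), rep(1, length(x)), tolerance = 1e-12)
  out <- eval_basis(bs, c(-1e5 - 1, 1e5 + 1, 3e5))
  expect_equal(out, matrix(0, 3, 12))
  expect_error(build_basis(0, 1, n_basis = 3), "n_basis")
  expect_error(build_basis(5, 5, 10), "d_min")
})

test_that("uniform cubic basis takes the 1/6, 4/6, 1/6 values at a central knot", {
  # knots at 0,1,...,10; at interior knot x = 5 the three overlapping cubic
  # B-splines take the classic uniform values (Cox-de Boor by hand)
  bs <- build_basis(0, 10, n_basis = 13)  # 9 interior knots, unit spacing
  v <- drop(eval_basis(bs, 5))
  nz <- which(v > 1e-12)
  expect_length(nz, 3L)
  expect_equal(unname(v[nz]), c(1, 4, 1) / 6, tolerance = 1e-12)
})

test_that("second-difference penalty annihilates constants and lines only", {
  bs <- build_basis(0, 1, n_basis = 9)
  D <- penalty_matrix(bs, 2)
  expect_equal(drop(t(rep(1, 9)) %*% D %*% rep(1, 9)), 0, tolerance = 1e-12)
  lin <- seq_len(9)
  expect_equal(drop(t(lin) %*% D %*% lin), 0, tolerance = 1e-10)
  # explicit hand expansion for an interior unit spike: the three second
  # differences touching it contribute 1^2 + (-2)^2 + 1^2
  spike <- c(0, 0, 0, 1, numeric(5))
  Delta <- diff(diag(9), differences = 2)
  expect_equal(drop(t(spike) %*% D %*% spike), sum((Delta %*% spike)^2))
  expect_equal(drop(t(spike) %*% D %*% spike), 1 + 4 + 1)
  expect_error(penalty_matrix(bs, 9), "order")
})

test_that("design features are additive sums of basis values over sites", {
  bs <- build_basis(-1e4, 1e4, n_basis = 8)
  tss <- make_tss("g1", 50000)
  prof_empty <- associate_sites(tss, make_sites(integer()), cutoff = 1e4)
  expect_equal(design_features(prof_empty, bs),
               matrix(0, 1, 8, dimnames = list("g1", NULL)))

  one <- associate_sites(tss, make_sites(47000), cutoff = 1e4)
  f1 <- design_features(one, bs)
  expect_equal(drop(f1), drop(eval_basis(bs, -3000)))

  two <- associate_sites(tss, make_sites(c(47000, 47000)), cutoff = 1e4)
  expect_equal(design_features(two, bs), 2 * f1)

  # outside-domain handling
  wide <- associate_sites(tss, make_sites(47000), cutoff = 2e4)
  bs_small <- build_basis(-2000, 2000, 6)
  expect_error(design_features(wide, bs_small), "outside")
  expect_equal(design_features(wide, bs_small, outside = "drop"),
               matrix(0, 1, 6, dimnames = list("g1", NULL)))
})

test_that("closed-form penalized fit matches a numerical optimizer", {
  st <- small_study(n_genes = 50, seed = 23, noise_sd = 0.4)
  prof <- associate_sites(st$tss, st$sites$tissueA, cutoff = 1e5)
  bs <- build_basis(-1e5, 1e5, n_basis = 8)
  y <- st$expression$tissueA
  B <- design_features(prof, bs)
  D <- penalty_matrix(bs, 2)
  for (sigma in c(0.5, 0.01)) {
    fit <- fit_influence(prof, y, basis = bs, sigma = sigma)
    obj <- function(cc) mean((y - B %*% cc)^2) + sigma * drop(t(cc) %*% D %*% cc)
    grad <- function(cc) drop(-2 * t(B) %*% (y - B %*% cc) / length(y) + 2 * sigma * D %*% cc)
    opt <- optim(numeric(8), obj, grad, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-15))
    expect_lt(abs(obj(coef(fit)) - opt$value) / abs(opt$value), 1e-6)
    expect_equal(coef(fit), opt$par, tolerance = 1e-4)
  }
})

test_that("with sigma = 0 the fit is ordinary least squares", {
  st <- small_study(n_genes = 60, seed = 31)
  prof <- associate_sites(st$tss, st$sites$tissueA, cutoff = 1e5)
  bs <- build_basis(-1e5, 1e5, n_basis = 8)
  B <- design_features(prof, bs)
  y <- st$expression$tissueA
  fit <- fit_influence(prof, y, basis = bs, sigma = 0)
  ols <- lm.fit(B, y)
  expect_equal(unname(coef(fit)), unname(ols$coefficients), tolerance = 1e-8)
})

test_that("large sigma drives the curve to the penalty null space (a line)", {
  st <- small_study(n_genes = 200, seed = 37)
  prof <- associate_sites(st$tss, st$sites$tissueA, cutoff = 1e5)
  fit <- fit_influence(prof, st$expression$tissueA, sigma = 1e9)
  # null space of the order-2 penalty: coefficient sequences with vanishing
  # second differences
  cf <- coef(fit)
  expect_lt(max(abs(diff(cf, differences = 2))), 1e-6 * max(abs(cf)))
})

test_that("regularization is monotone: training MSE up, roughness down in sigma", {
  st <- small_study(n_genes = 150, seed = 41)
  prof <- associate_sites(st$tss, st$sites$tissueA, cutoff = 1e5)
  y <- st$expression$tissueA
  bs <- build_basis(-1e5, 1e5, 12)
  D <- penalty_matrix(bs, 2)
  sig <- 10^seq(-6, 2)
  fits <- lapply(sig, function(s) fit_influence(prof, y, basis = bs, sigma = s))
  mse <- vapply(fits, function(f) f$mse, numeric(1))
  rough <- vapply(fits, function(f) drop(t(coef(f)) %*% D %*% coef(f)), numeric(1))
  expect_true(all(diff(mse) >= -1e-10))
  expect_true(all(diff(rough) <= 1e-10))
})

test_that("prediction is additive, zero on empty profiles, and curve-consistent", {
  st <- small_study(n_genes = 80, seed = 43)
  prof <- associate_sites(st$tss, st$sites$tissueA, cutoff = 1e5)
  fit <- fit_influence(prof, st$expression$tissueA, sigma = 1e-3)

  tss2 <- make_tss(c("a", "b"), c(5e5, 9e5), chrom = "chrS")
  empty <- associate_sites(tss2, st$sites$tissueA[0, ], cutoff = 1e5)
  expect_equal(unname(predict(fit, empty)), c(0, 0))

  one <- associate_sites(make_tss("a", 5e5, chrom = "chrS"),
                         make_sites(5e5 + 12000, chrom = "chrS", tissue = "tissueA"),
                         cutoff = 1e5)
  pred1 <- predict(fit, one)
  expect_equal(unname(pred1),
               influence_curve(fit, 12000)$influence)
  dup <- one
  dup$a <- rbind(dup$a, dup$a)
  expect_equal(unname(predict(fit, dup)), 2 * unname(pred1))
})

test_that("differential predictions are antisymmetric differences", {
  st <- small_study(n_genes = 100, seed = 47)
  pa <- associate_sites(st$tss, st$sites$tissueA, cutoff = 1e5)
  pb <- associate_sites(st$tss, st$sites$tissueB, cutoff = 1e5)
  fit <- fit_influence(pa, st$expression$tissueA, sigma = 1e-3)
  d_ab <- predict_differential(fit, pa, pb)
  d_ba <- predict_differential(fit, pb, pa)
  expect_equal(d_ab, -d_ba)
  expect_equal(unname(predict_differential(fit, pa, pa)), numeric(length(pa)))
  empty <- lapply(pa, function(e) e[0, , drop = FALSE])
  attributes(empty) <- attributes(pa)
  expect_equal(predict_differential(fit, pa, empty), predict(fit, pa))
})

test_that("influence curve follows the coefficients", {
  bs <- build_basis(-1e4, 1e4, 10)
  m0 <- structure(list(coefficients = numeric(10), basis = bs, variant = "position"),
                  class = "influence_fit")
  grid <- seq(-1e4, 1e4, length.out = 21)
  expect_equal(influence_curve(m0, grid)$influence, numeric(21))
  m1 <- m0; m1$coefficients <- rep(1, 10)
  expect_equal(influence_curve(m1, grid)$influence, rep(1, 21))
  expect_equal(influence_curve(m1, 2e4)$influence, 0)  # outside the domain
})

test_that("fitted curve recovers a known influence function", {
  spec <- synthetic_spec(n_genes = 600, influence_preset = "linear_decay_50kb",
                        noise_sd = 0.5)
  st <- simulate_study(spec, seed = 53)
  prof <- associate_sites(st$tss, st$sites$tissueA, cutoff = 1e5)
  fit <- fit_influence(prof, st$expression$tissueA, sigma = 1e-3)
  grid <- seq(-1e5, 1e5, by = 1000)
  expect_gt(cor(influence_curve(fit, grid)$influence, st$truth$influence(grid)), 0.95)
})

test_that("model JSON round trip restores every field", {
  st <- small_study(n_genes = 60, seed = 59)
  prof <- associate_sites(st$tss, st$sites$tissueA, cutoff = 1e5)
  fit <- fit_influence(prof, st$expression$tissueA, sigma = 0.02)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(fit, f)
  back <- read_model(f)
  expect_equal(back$coefficients, unname(coef(fit)))
  expect_equal(back$basis$knots, fit$basis$knots)
  expect_equal(back$sigma, fit$sigma)
  expect_equal(back$variant, fit$variant)
  grid <- seq(-1e5, 1e5, length.out = 31)
  expect_equal(influence_curve(back, grid), influence_curve(fit, grid))
  # schema mismatch is rejected with the expected version named
  writeLines('{"schema_version":"other/9"}', f)
  expect_error(read_model(f), "regspline-model/1")
})

test_that("singular unpenalized systems advise increasing sigma", {
  tss <- make_tss(c("g1", "g2"), c(50000, 300000))
  prof <- associate_sites(tss, make_sites(c(47000, 297000)), cutoff = 1e4)
  bs <- build_basis(-1e4, 1e4, 8)  # 8 coefficients, 2 observations
  expect_error(fit_influence(prof, c(1, 2), basis = bs, sigma = 0), "sigma")
})
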