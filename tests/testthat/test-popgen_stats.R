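test_that("heterozygosity matrices match hand-enumerated cases", {
  # monomorphic dataset -> all entries zero
  cl <- repeats_one_locus(list(c(10L, 10L), c(10L, 10L),
                               c(10L, 10L), c(10L, 10L)),
                          c("A", "A", "B", "B"))
  H <- heterozygosity_matrix(cl)
  expect_equal(unclass(H), matrix(0, 2, 2, dimnames = list(c("A", "B"),
                                                           c("A", "B"))),
               ignore_attr = TRUE)

  # one population, two distinct alleles (n = 2): unbiased H = 1
  cl2 <- repeats_one_locus(list(c(10L, 12L)), "A")
  expect_equal(unname(diag(unclass(heterozygosity_matrix(cl2)))), 1)
  expect_equal(unname(diag(unclass(
    heterozygosity_matrix(cl2, correction = "plugin")))), 0.5)

  # two populations fixed for different alleles
  cl3 <- repeats_one_locus(list(c(10L, 10L), c(10L, 10L),
                                c(12L, 12L), c(12L, 12L)),
                           c("A", "A", "B", "B"))
  H3 <- unclass(heterozygosity_matrix(cl3))
  expect_equal(unname(diag(H3)), c(0, 0))
  expect_equal(H3["A", "B"], 1)
})

test_that("F_ST follows the heterozygosity-matrix definition", {
  H <- matrix(c(0.5, 0.8, 0.8, 0.7), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  f <- fst_pairwise(H)
  expect_equal(f["A", "B"], 1 - 0.6 / 0.8)
  expect_equal(unname(diag(unclass(f))), c(0, 0))
  # identical populations -> 0; fixed for different alleles -> 1
  Hsame <- matrix(0.6, 2, 2, dimnames = dimnames(H))
  expect_equal(fst_pairwise(Hsame)["A", "B"], 0)
  Hfix <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = dimnames(H))
  expect_equal(fst_pairwise(Hfix)["A", "B"], 1)
  # zero between-H with positive within-H is undefined
  Hbad <- matrix(c(0.5, 0, 0, 0.5), 2, 2, dimnames = dimnames(H))
  expect_true(is.na(fst_pairwise(Hbad)["A", "B"]))
})

test_that("regression recovers exact linear relationships and validates input", {
  x <- c(A = 0, B = 1000, C = 2000, D = 5000, E = 9000)
  y <- setNames(-8.9e-6 * x + 0.8, names(x))
  fit <- suppressWarnings(regress_h_on_covariate(y, x, n_boot = 200, seed = 1,
                                                 unit = "populations"))
  expect_equal(fit$slope, -8.9e-6, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.8, tolerance = 1e-10)
  expect_lt(diff(fit$boot_ci["slope", ]), 1e-12)
  # constant response -> zero slope (perfect-fit warning is expected here)
  y0 <- setNames(rep(0.5, 5), names(x))
  expect_equal(suppressWarnings(
    regress_h_on_covariate(y0, x, n_boot = 50, seed = 1,
                           unit = "populations"))$slope, 0)
  expect_error(regress_h_on_covariate(y, setNames(rep(1, 5), names(x)),
                                      n_boot = 10, unit = "populations"),
               "singular")
  expect_error(regress_h_on_covariate(y[1:2], x[1:2], unit = "populations"),
               "3 populations")
  expect_error(regress_h_on_covariate(y, x[1:4], unit = "populations"),
               "E")
})

test_that("bootstrap runs are bit-reproducible under a fixed seed", {
  set.seed(7)
  x <- setNames(runif(10, 0, 10000), LETTERS[1:10])
  y <- setNames(-5e-6 * x + 0.7 + rnorm(10, 0, 0.02), LETTERS[1:10])
  f1 <- regress_h_on_covariate(y, x, n_boot = 500, seed = 42,
                               unit = "populations")
  f2 <- regress_h_on_covariate(y, x, n_boot = 500, seed = 42,
                               unit = "populations")
  expect_identical(f1$boot_ci, f2$boot_ci)
  f3 <- regress_h_on_covariate(y, x, n_boot = 500, seed = 43,
                               unit = "populations")
  expect_false(identical(f1$boot_ci, f3$boot_ci))
})

test_that("locus-level resampling works from a heterozygosity matrix", {
  cfg <- sim_config(n_populations = 4, samples_per_population = 8,
                    demography = "star",
                    marker_classes = data.frame(label = "di",
                                                motif_length = 2L,
                                                n_loci = 25L, mu = 1.5e-3))
  panel <- simulate_panel(cfg, seed = 2)
  H <- heterozygosity_matrix(truth_dataset(panel))
  x <- setNames(c(0, 2000, 5000, 9000), colnames(H))
  fit <- regress_h_on_covariate(H, x, n_boot = 300, seed = 9, unit = "loci")
  expect_identical(fit$unit, "loci")
  expect_true(fit$boot_ci["slope", 1] <= fit$boot_ci["slope", 2])
  # plain vectors cannot be resampled by locus
  expect_error(regress_h_on_covariate(setNames(diag(unclass(H)), colnames(H)),
                                      x, n_boot = 10, unit = "loci"),
               "per-locus")
})

test_that("slope comparison matches an explicit general-linear-model oracle", {
  set.seed(11)
  x <- setNames(seq(0, 10000, length.out = 20), paste0("p", 1:20))
  ya <- setNames(-8e-6 * x + 0.8 + rnorm(20, 0, 0.01), names(x))
  yb <- setNames(-5e-6 * x + 0.8 + rnorm(20, 0, 0.01), names(x))
  fa <- regress_h_on_covariate(ya, x, n_boot = 20, seed = 1,
                               unit = "populations")
  fb <- regress_h_on_covariate(yb, x, n_boot = 20, seed = 1,
                               unit = "populations")
  res <- compare_slopes(fa, fb)
  # independent oracle: explicit design matrices and RSS-based F
  y <- c(ya, yb); g <- rep(0:1, each = 20); xx <- c(x, x)
  Xf <- cbind(1, xx, g, xx * g)
  Xr <- cbind(1, xx, g)
  rss <- function(X) sum(stats::lsfit(X, y, intercept = FALSE)$residuals^2)
  Fo <- (rss(Xr) - rss(Xf)) / (rss(Xf) / (40 - 4))
  expect_equal(res$F, Fo, tolerance = 1e-8)
  expect_identical(res$df1, 1L)
  expect_identical(res$df2, 36L)
  expect_equal(res$p_value, stats::pf(Fo, 1, 36, lower.tail = FALSE),
               tolerance = 1e-8)

  # identical fits -> F ~ 0, p ~ 1
  same <- compare_slopes(fa, fa)
  expect_lt(same$F, 1e-20)
  expect_gt(same$p_value, 0.999)
  # noiseless slope difference -> overwhelming evidence
  ya0 <- setNames(-8e-6 * x + 0.8, names(x))
  yb0 <- setNames(-5e-6 * x + 0.8, names(x))
  fa0 <- suppressWarnings(regress_h_on_covariate(ya0, x, n_boot = 10, seed = 1,
                                                 unit = "populations"))
  fb0 <- suppressWarnings(regress_h_on_covariate(yb0, x, n_boot = 10, seed = 1,
                                                 unit = "populations"))
  expect_lt(compare_slopes(fa0, fb0)$p_value, 1e-10)
  expect_error(compare_slopes(fa, regress_h_on_covariate(
    ya[1:10], x[1:10], n_boot = 10, seed = 1, unit = "populations")),
    "same covariate")
})

test_that("class combination rarefies before averaging", {
  panel <- simulate_panel(
    sim_config(n_populations = 3, samples_per_population = 12,
               demography = "star", share_genealogies = TRUE,
               marker_classes = data.frame(
                 label = c("di", "tri"), motif_length = c(2L, 3L),
                 n_loci = c(30L, 30L), mu = c(1.5e-3, 0.75e-3))),
    seed = 13)
  cl <- truth_dataset(panel)
  divs <- list(
    di = class_diversity(cl, panel$truth$locus[panel$truth$class == "di"], "di"),
    tri = class_diversity(cl, panel$truth$locus[panel$truth$class == "tri"], "tri"))
  # single class: identical to its own within-H
  expect_equal(combined_heterozygosity(divs["tri"], "tri"),
               setNames(diag(divs$tri$H), divs$tri$populations))
  # two identical classes combine to themselves
  divs_same <- list(a = divs$di, b = divs$di)
  expect_equal(combined_heterozygosity(divs_same, "a", k = c(b = 1)),
               setNames(diag(divs$di$H), divs$di$populations))
  # rarefied combination sits near the slow class, below naive pooling
  k <- fit_rarefaction_factor(divs$di, divs$tri, "heterozygosity")$k
  comb <- combined_heterozygosity(divs, "tri", k = c(di = k))
  naive <- (diag(divs$di$H) + diag(divs$tri$H)) / 2
  expect_true(all(comb < naive))
  expect_equal(mean(comb), mean(diag(divs$tri$H)), tolerance = 0.03)
  # upward combination is refused
  expect_error(combined_heterozygosity(divs, "di", k = c(tri = 2)),
               "infeasible|\\(0, 1\\]")
})
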