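# Heterozygosity matrices, pairwise F_ST, diversity-vs-covariate
# regressions with bootstrap confidence intervals, and slope-equality
# tests.

# Per-population allele-frequency summaries for one locus.
.pop_freqs <- function(alleles) {
  tab <- table(alleles)
  list(p = as.numeric(tab) / sum(tab), levels = as.integer(names(tab)),
       n = length(alleles))
}

#' Within/between-population heterozygosity matrix
#'
#' Diagonal entries hold within-population expected heterozygosity,
#' off-diagonal entries the between-population heterozygosity (probability
#' that one allele from each population differ). Within-population values
#' use, by default, the sample-size-corrected (unbiased) estimator
#' `n/(n-1) * (1 - sum(p^2))` with `n` the number of typed alleles;
#' between-population values are the plug-in cross-product
#' `1 - sum(p_a * p_b)` (unbiased as is, since the two alleles never
#' coincide by sampling). Loci are averaged with equal weight; a locus is
#' skipped for an entry when a population has fewer than two typed alleles
#' there (skips are counted, not imputed).
#'
#' @param cleaned a [clean_dataset()] result with population assignments.
#' @param loci retained locus ids to use (default: all retained).
#' @param correction `"unbiased"` (default) or `"plugin"` for the
#'   within-population entries.
#' @return matrix of class `het_matrix` (populations x populations) with
#'   attributes `n_loci_used` (entry-wise contributing-locus counts),
#'   `by_locus` (within-population H per locus x population, for
#'   locus-resampling bootstraps) and `correction`.
#' @export
heterozygosity_matrix <- function(cleaned, loci = NULL,
                                  correction = c("unbiased", "plugin")) {
  correction <- match.arg(correction)
  stopifnot(inherits(cleaned, "cleaned_dataset"))
  if (is.null(cleaned$populations))
    stop("dataset has no population assignments")
  if (is.null(loci)) loci <- loci_by_motif(cleaned)
  pops <- sort(unique(cleaned$populations))
  P <- length(pops)
  ind_by_pop <- lapply(pops, function(p)
    names(cleaned$populations)[cleaned$populations == p])
  acc <- used <- matrix(0, P, P, dimnames = list(pops, pops))
  by_locus <- matrix(NA_real_, length(loci), P,
                     dimnames = list(loci, pops))
  any_typed <- logical(P)
  for (li in seq_along(loci)) {
    fr <- vector("list", P)
    for (a in seq_len(P)) {
      al <- .locus_alleles(cleaned$repeats, loci[li], ind_by_pop[[a]])
      if (length(al)) any_typed[a] <- TRUE
      if (length(al) >= 2L) fr[[a]] <- .pop_freqs(al)
    }
    for (a in seq_len(P)) {
      if (is.null(fr[[a]])) next
      h <- 1 - sum(fr[[a]]$p^2)
      if (correction == "unbiased")
        h <- h * fr[[a]]$n / (fr[[a]]$n - 1)
      acc[a, a] <- acc[a, a] + h
      used[a, a] <- used[a, a] + 1
      by_locus[li, a] <- h
      if (a < P) for (b in (a + 1L):P) {
        if (is.null(fr[[b]])) next
        common <- intersect(fr[[a]]$levels, fr[[b]]$levels)
        cross <- sum(fr[[a]]$p[match(common, fr[[a]]$levels)] *
                     fr[[b]]$p[match(common, fr[[b]]$levels)])
        acc[a, b] <- acc[a, b] + (1 - cross)
        acc[b, a] <- acc[b, a] + (1 - cross)
        used[a, b] <- used[a, b] + 1
        used[b, a] <- used[b, a] + 1
      }
    }
  }
  if (any(!any_typed))
    stop("population(s) with no typed alleles at any locus: ",
         paste(pops[!any_typed], collapse = ", "))
  H <- acc / used
  H[used == 0] <- NA_real_
  structure(H, n_loci_used = used, by_locus = by_locus,
            correction = correction,
            class = c("het_matrix", "matrix", "array"))
}

#' Pairwise F_ST from a heterozygosity matrix
#'
#' `F_ST(a, b) = 1 - mean(H[a,a], H[b,b]) / H[a,b]`: between-population
#' differentiation normalised by the average within-population diversity.
#' Values are clamped to `[0, 1]` (clamping is recorded in the
#' `n_clamped` attribute). An entry with zero between-population
#' heterozygosity but positive within-H is undefined and returned as `NA`.
#'
#' @param H a [heterozygosity_matrix()] (or any symmetric matrix with
#'   within-H on the diagonal).
#' @return symmetric matrix of pairwise F_ST with zero diagonal.
#' @export
fst_pairwise <- function(H) {
  stopifnot(is.matrix(H), nrow(H) == ncol(H))
  P <- nrow(H)
  Fst <- matrix(0, P, P, dimnames = dimnames(H))
  n_clamped <- 0L
  for (a in seq_len(P)) for (b in seq_len(P)) {
    if (a == b) next
    hw <- mean(c(H[a, a], H[b, b]))
    hb <- H[a, b]
    if (hb == 0) {
      Fst[a, b] <- if (hw == 0) 0 else NA_real_
      next
    }
    f <- 1 - hw / hb
    if (f < 0 || f > 1) n_clamped <- n_clamped + 1L
    Fst[a, b] <- min(1, max(0, f))
  }
  structure(Fst, n_clamped = n_clamped,
            class = c("fst_matrix", "matrix", "array"))
}

#' Regress per-population heterozygosity on a covariate
#'
#' Ordinary least squares of within-population diversity on a
#' per-population covariate (typically distance from sub-Saharan Africa,
#' km), with percentile bootstrap confidence intervals. The default
#' resampling unit is loci — the exchangeable unit when the uncertainty of
#' interest is the marker set — via the per-locus matrix attached to a
#' [heterozygosity_matrix()]; set `unit = "populations"` (or pass plain
#' `h` values without a by-locus matrix) to resample populations instead.
#'
#' @param h named per-population heterozygosity vector, or a
#'   [heterozygosity_matrix()] (its diagonal and by-locus matrix are
#'   used).
#' @param covariate named numeric vector, population -> covariate value;
#'   must cover all populations in `h`.
#' @param n_boot number of bootstrap samples.
#' @param seed RNG seed (bootstrap runs are bit-reproducible given a
#'   seed).
#' @param unit bootstrap resampling unit.
#' @param conf confidence level for the percentile intervals.
#' @return object of class `h_regression`: slope, intercept, their
#'   classical standard errors, percentile `boot_ci` (matrix with rows
#'   intercept/slope), `n_boot`, `seed`, `unit` and the fitted data.
#' @export
regress_h_on_covariate <- function(h, covariate, n_boot = 10000, seed = 1L,
                                   unit = c("loci", "populations"),
                                   conf = 0.95) {
  unit <- match.arg(unit)
  by_locus <- NULL
  if (inherits(h, "het_matrix")) {
    by_locus <- attr(h, "by_locus")
    h <- stats::setNames(diag(unclass(h)), colnames(h))
  }
  pops <- names(h)
  if (length(pops) < 3L) stop("need at least 3 populations to regress")
  missing_cov <- setdiff(pops, names(covariate))
  if (length(missing_cov))
    stop("covariate missing for population(s): ",
         paste(missing_cov, collapse = ", "))
  x <- covariate[pops]
  if (stats::sd(x) == 0)
    stop("singular design: covariate is constant across populations")
  if (unit == "loci" && is.null(by_locus))
    stop("locus-level bootstrap requires a het_matrix with per-locus values; ",
         "use unit = \"populations\" for plain vectors")
  fit <- stats::lm(h ~ x)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, 2L)
  if (unit == "loci") {
    L <- nrow(by_locus)
    for (b in seq_len(n_boot)) {
      hb <- colMeans(by_locus[sample.int(L, L, replace = TRUE), ,
                              drop = FALSE], na.rm = TRUE)
      boot[b, ] <- .ols_coef(x, hb)
    }
  } else {
    n <- length(x)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(x[idx]) == 0) { b_coef <- c(NA, NA) }
      else b_coef <- .ols_coef(x[idx], h[idx])
      boot[b, ] <- b_coef
    }
  }
  alpha <- (1 - conf) / 2
  ci <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE)
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 slope_se = unname(se[2]), intercept_se = unname(se[1]),
                 boot_ci = matrix(t(ci), 2, 2,
                                  dimnames = list(c("intercept", "slope"),
                                                  c("lower", "upper"))),
                 n_boot = n_boot, seed = seed, unit = unit, conf = conf,
                 x = x, y = h, lm = fit),
            class = "h_regression")
}

.ols_coef <- function(x, y) {
  xm <- mean(x); ym <- mean(y)
  b <- sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  c(ym - b * xm, b)
}

#' @export
print.h_regression <- function(x, ...) {
  cat(sprintf("h_regression (%d populations, %s bootstrap, B = %d):\n",
              length(x$x), x$unit, x$n_boot))
  cat(sprintf("  slope     = %.4g +/- %.3g   %.0f%% CI [%.4g, %.4g]\n",
              x$slope, x$slope_se, 100 * x$conf,
              x$boot_ci["slope", 1], x$boot_ci["slope", 2]))
  cat(sprintf("  intercept = %.4g +/- %.3g   %.0f%% CI [%.4g, %.4g]\n",
              x$intercept, x$intercept_se, 100 * x$conf,
              x$boot_ci["intercept", 1], x$boot_ci["intercept", 2]))
  invisible(x)
}

#' @export
coef.h_regression <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' @export
plot.h_regression <- function(x, ..., xlab = "covariate",
                              ylab = "heterozygosity") {
  graphics::plot(x$x, x$y, xlab = xlab, ylab = ylab, ...)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}

#' Test equality of two regression slopes
#'
#' ANCOVA-style interaction test: the two datasets (which must share the
#' same covariate values) are stacked and the slope-difference term tested
#' with an F statistic on `(1, n_a + n_b - 4)` degrees of freedom.
#'
#' @param fit_a,fit_b [regress_h_on_covariate()] results on the same
#'   covariate values.
#' @return list with `F`, `df1`, `df2`, `p_value` and the slope
#'   difference.
#' @export
compare_slopes <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "h_regression"), inherits(fit_b, "h_regression"))
  if (!isTRUE(all.equal(sort(unname(fit_a$x)), sort(unname(fit_b$x)))))
    stop("the two fits must be on the same covariate values")
  dat <- data.frame(y = c(fit_a$y, fit_b$y), x = c(fit_a$x, fit_b$x),
                    g = factor(rep(c("a", "b"),
                                   c(length(fit_a$y), length(fit_b$y)))))
  rss_full <- stats::deviance(stats::lm(y ~ x * g, data = dat))
  rss_red <- stats::deviance(stats::lm(y ~ x + g, data = dat))
  df2 <- nrow(dat) - 4L
  extra <- max(0, rss_red - rss_full)
  f_stat <- if (rss_full > 0) extra / (rss_full / df2)
            else if (extra > 0) Inf else 0
  list(F = f_stat, df1 = 1L, df2 = df2,
       p_value = stats::pf(f_stat, 1, df2, lower.tail = FALSE),
       slope_difference = fit_b$slope - fit_a$slope)
}

#' Combine marker classes at a common mutation rate
#'
#' The correct way of averaging diversity across marker classes with
#' different mutation rates: every class is first rarefied to the target
#' class's rate, then per-population within-heterozygosities are combined
#' with weight proportional to the number of loci (so each locus carries
#' equal weight in the overall metric). Naive pooling without rarefaction
#' mixes scales and inflates the combined heterozygosity.
#'
#' @param divs named list of [class_diversity()] objects over the same
#'   populations.
#' @param rarefy_to name of the target class.
#' @param k named numeric vector of rarefaction factors
#'   `mu_target / mu_class` for every other class (e.g. fitted `k` values
#'   from [fit_rarefaction_factor()]); all must lie in `(0, 1]`.
#' @param nodes quadrature nodes.
#' @return named per-population vector of combined within-population
#'   heterozygosity.
#' @export
combined_heterozygosity <- function(divs, rarefy_to, k = NULL, nodes = 2048) {
  stopifnot(rarefy_to %in% names(divs))
  pops <- divs[[rarefy_to]]$populations
  total <- stats::setNames(numeric(length(pops)), pops)
  weight <- 0
  for (nm in names(divs)) {
    d <- divs[[nm]]
    if (!identical(d$populations, pops))
      stop("all classes must cover the same populations")
    if (nm == rarefy_to) {
      hw <- diag(d$H)
    } else {
      if (is.null(k) || is.null(k[[nm]]))
        stop("no rarefaction factor supplied for class: ", nm)
      ki <- k[[nm]]
      if (is.na(ki) || ki <= 0 || ki > 1)
        stop("infeasible rarefaction direction for class ", nm,
             ": factor must lie in (0, 1]")
      K <- build_kernel(ki, nrow(d$pmfs) - 1L, nodes)
      q <- K %*% d$pmfs
      q[q < 0] <- 0
      q <- sweep(q, 2, colSums(q), "/")
      hw <- numeric(length(pops))
      within_cols <- which(d$pair_i == d$pair_j)
      hw[d$pair_i[within_cols]] <- 1 - q[1, within_cols]
    }
    total <- total + d$n_loci * hw
    weight <- weight + d$n_loci
  }
  total / weight
}
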