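# Mutation rarefaction under the stepwise mutation model (SMM).
#
# The observable is the distribution p(Delta) of absolute differences in
# repeat count between two sampled alleles. Under the SMM with symmetric
# single-step mutations at rate mu per generation, a pair with TMRCA t has
# characteristic function (1 - mu + mu*cos(w))^(2t); averaging over the
# (unknown) genealogy gives p-hat(w) = g((1 - mu*(1 - cos w))) for a
# generating function g of the TMRCA distribution. Because the genealogy is
# independent of the mutation rate, the distribution at a lower rate
# mu' = r*mu is obtained from the observed one by the substitution
# w -> arccos(1 - r*(1 - cos w)) in the characteristic function — an
# implicit thinning of the mutations on the genealogy. Inverting the cosine
# transform yields a linear map (kernel) from the observed pmf to the
# rarefied pmf. Rarefied heterozygosity is 1 - p_rarefied(0).
#
# The map only removes information, so it is restricted to r <= 1:
# extrapolating to a higher mutation rate is numerically unstable and
# refused.

#' Pairwise repeat-difference distribution
#'
#' @param pmf numeric vector of probabilities for Delta = 0, 1, ...,
#'   `length(pmf) - 1`; must be non-negative and sum to one.
#' @param n_pairs number of allele pairs that contributed (NA for
#'   theoretical distributions).
#' @return An object of class `pdiff`.
#' @export
pdiff <- function(pmf, n_pairs = NA_real_) {
  pmf <- as.numeric(pmf)
  if (any(pmf < 0)) stop("pmf entries must be non-negative")
  if (abs(sum(pmf) - 1) > 1e-12) stop("pmf must sum to 1 (within 1e-12)")
  structure(pmf, n_pairs = n_pairs, class = "pdiff")
}

#' @export
print.pdiff <- function(x, ...) {
  cat(sprintf("pdiff: support 0..%d, H = 1 - p(0) = %.6f, variance = %.4f\n",
              length(x) - 1L, 1 - x[1], pdiff_variance(x)))
  invisible(x)
}

#' @export
plot.pdiff <- function(x, ..., xlab = expression(Delta), ylab = "probability") {
  graphics::plot(seq_along(unclass(x)) - 1L, unclass(x), type = "h",
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Heterozygosity and variance of a repeat-difference distribution
#'
#' Heterozygosity is the probability that two sampled alleles differ,
#' `1 - p(0)`. The variance is the second moment `sum(Delta^2 p(Delta))`
#' of the (symmetric, mean-zero) signed repeat difference — the quantity
#' used in classical variance-based mutation-rate calibration.
#'
#' @param p a [pdiff()].
#' @return a single number.
#' @export
pdiff_heterozygosity <- function(p) 1 - unclass(p)[1]

#' @rdname pdiff_heterozygosity
#' @export
pdiff_variance <- function(p) {
  d <- seq_along(unclass(p)) - 1
  sum(d^2 * unclass(p))
}

#' Empirical pairwise difference distribution of a locus
#'
#' Within-population mode (`group_b = NULL`): uniform over all unordered
#' pairs of distinct allele copies in `group_a` — this makes
#' `1 - p(0)` the unbiased (sample-size-corrected) expected
#' heterozygosity. Between-population mode: uniform over all cross-group
#' allele pairs, so `1 - p(0)` is the plug-in between-population
#' heterozygosity.
#'
#' @param cleaned a [clean_dataset()] result.
#' @param locus retained locus id.
#' @param group_a,group_b population labels; `group_b = NULL` selects
#'   within-population mode.
#' @param max_delta truncation bound for the pmf support; default: largest
#'   observed difference.
#' @return a [pdiff()].
#' @export
pairwise_diff_distribution <- function(cleaned, locus, group_a,
                                       group_b = NULL, max_delta = NULL) {
  stopifnot(inherits(cleaned, "cleaned_dataset"))
  if (is.null(cleaned$populations))
    stop("dataset has no population assignments")
  if (!locus %in% dimnames(cleaned$repeats)[[2]])
    stop("locus not retained in cleaned dataset: ", locus)
  ind_a <- names(cleaned$populations)[cleaned$populations == group_a]
  a <- .locus_alleles(cleaned$repeats, locus, ind_a)
  if (is.null(group_b)) {
    if (length(a) < 2L)
      stop(sprintf("need >= 2 typed alleles in population '%s' at locus '%s'",
                   group_a, locus))
    .pdiff_within(a, max_delta)
  } else {
    ind_b <- names(cleaned$populations)[cleaned$populations == group_b]
    b <- .locus_alleles(cleaned$repeats, locus, ind_b)
    if (length(a) < 1L || length(b) < 1L)
      stop(sprintf(
        "need >= 1 typed allele in each of '%s' and '%s' at locus '%s'",
        group_a, group_b, locus))
    .pdiff_between(a, b, max_delta)
  }
}

.pdiff_tab <- function(deltas, max_delta) {
  if (is.null(max_delta)) max_delta <- max(deltas)
  counts <- tabulate(deltas + 1L, nbins = max_delta + 1L)
  pdiff(counts / length(deltas), n_pairs = length(deltas))
}

.pdiff_within <- function(a, max_delta = NULL) {
  d <- abs(outer(a, a, "-"))
  .pdiff_tab(d[upper.tri(d)], max_delta)
}

.pdiff_between <- function(a, b, max_delta = NULL) {
  .pdiff_tab(as.vector(abs(outer(a, b, "-"))), max_delta)
}

#' Characteristic function of a repeat-difference distribution
#'
#' `p-hat(w) = sum_Delta p(Delta) cos(Delta * w)`. Because the pmf is the
#' folded magnitude of a symmetric signed difference, the cosine series is
#' the full (real) characteristic function.
#'
#' @param p a [pdiff()].
#' @param omegas numeric vector of angular frequencies in `[0, pi]`.
#' @return numeric vector of the same length as `omegas`.
#' @export
characteristic_function <- function(p, omegas) {
  d <- seq_along(unclass(p)) - 1
  as.vector(cos(outer(omegas, d)) %*% unclass(p))
}

# Trapezoid nodes/weights on [0, pi]; the integrands are smooth with even
# periodic extensions, so the trapezoid rule converges spectrally here.
.trapezoid_grid <- function(nodes) {
  w <- seq(0, pi, length.out = nodes)
  wt <- rep(pi / (nodes - 1), nodes)
  wt[c(1, nodes)] <- wt[c(1, nodes)] / 2
  list(omega = w, weight = wt)
}

# Inverse cosine transform of a characteristic function sampled on the
# grid: p(Delta) = (c_Delta/pi) * int_0^pi cos(Delta w) phat(w) dw with
# c_0 = 1 and c_Delta = 2 for Delta > 0 (folding the symmetric signed
# distribution onto Delta >= 0).
.inverse_cosine <- function(phat, grid, max_delta) {
  d <- 0:max_delta
  cfac <- c(1, rep(2, max_delta)) / pi
  as.vector((cos(outer(d, grid$omega)) %*% (phat * grid$weight)) * cfac)
}

#' Build a rarefaction kernel
#'
#' The linear map taking an observed pmf of repeat differences to the pmf
#' rarefied by the mutation-rate ratio `r = mu'/mu`:
#' \deqn{K[\Delta,\Delta'] = \frac{c_\Delta}{\pi}\int_0^\pi
#'   \cos(\Delta\omega)\,
#'   \cos\!\big(\Delta' \arccos[1 - r(1-\cos\omega)]\big)\, d\omega}
#' with `c_0 = 1`, `c_Delta = 2` otherwise. At `r = 1` the kernel is the
#' identity; for `r < 1` its columns still sum to one (total probability is
#' conserved), up to quadrature error.
#'
#' @param ratio mutation-rate ratio `r` in `(0, 1]`.
#' @param max_delta support bound; the kernel is
#'   `(max_delta+1) x (max_delta+1)`.
#' @param nodes number of trapezoid quadrature nodes on `[0, pi]`.
#' @return matrix of class `rarefaction_kernel` with attributes `ratio`,
#'   `nodes` and `colsum_error` (max deviation of column sums from one).
#' @export
build_kernel <- function(ratio, max_delta, nodes = 4096) {
  if (!is.numeric(ratio) || length(ratio) != 1L || is.na(ratio) || ratio <= 0)
    stop("rarefaction ratio must be a single number in (0, 1]")
  if (ratio > 1)
    stop("rarefaction ratio > 1: rarefaction only runs from larger to ",
         "smaller mutation rates; extrapolating upward is unstable and refused")
  grid <- .trapezoid_grid(nodes)
  theta <- acos(pmin(1, pmax(-1, 1 - ratio * (1 - cos(grid$omega)))))
  d <- 0:max_delta
  cfac <- c(1, rep(2, max_delta)) / pi
  A <- cos(outer(d, grid$omega)) * rep(grid$weight, each = max_delta + 1L)
  B <- cos(outer(theta, d))
  K <- (A %*% B) * cfac
  err <- max(abs(colSums(K) - 1))
  structure(K, ratio = ratio, nodes = nodes, colsum_error = err,
            class = c("rarefaction_kernel", "matrix", "array"))
}

#' Rarefy a repeat-difference distribution
#'
#' Applies the rarefaction kernel for mutation-rate ratio `ratio` to the
#' pmf. Tiny negative entries arising from truncation/quadrature are
#' clipped to zero and the pmf renormalised; the clipped mass and the
#' pre-normalisation deviation from unit mass are recorded as attributes
#' (`clipped`, `mass_error`) and a warning is raised if the clipped mass
#' exceeds `1e-6`.
#'
#' @param p a [pdiff()].
#' @param ratio mutation-rate ratio in `(0, 1]`.
#' @param nodes quadrature nodes (see [build_kernel()]).
#' @param kernel optional precomputed [build_kernel()] of matching
#'   dimension and ratio (used to avoid rebuilding in optimisation loops).
#' @return a [pdiff()] on the same support.
#' @export
rarefy_distribution <- function(p, ratio, nodes = 4096, kernel = NULL) {
  stopifnot(inherits(p, "pdiff"))
  if (identical(as.numeric(ratio), 1)) {
    out <- pdiff(unclass(p), n_pairs = attr(p, "n_pairs"))
    attr(out, "clipped") <- 0; attr(out, "mass_error") <- 0
    return(out)
  }
  max_delta <- length(p) - 1L
  if (is.null(kernel)) kernel <- build_kernel(ratio, max_delta, nodes)
  stopifnot(nrow(kernel) == max_delta + 1L)
  q <- as.vector(kernel %*% unclass(p))
  clipped <- -sum(q[q < 0])
  if (clipped > 1e-6)
    warning(sprintf("rarefaction clipped %.3g of negative mass; increase max_delta or quadrature nodes", clipped))
  q[q < 0] <- 0
  mass_error <- abs(sum(q) - 1)
  out <- pdiff(q / sum(q), n_pairs = attr(p, "n_pairs"))
  attr(out, "clipped") <- clipped
  attr(out, "mass_error") <- mass_error
  out
}

#' Rarefied heterozygosity
#'
#' `H_rarefied = 1 - p_rarefied(0)`: the heterozygosity the locus would
#' show at mutation rate `ratio` times its actual rate.
#'
#' @inheritParams rarefy_distribution
#' @return number in `[0, 1]`.
#' @export
rarefied_heterozygosity <- function(p, ratio, nodes = 4096, kernel = NULL) {
  pdiff_heterozygosity(rarefy_distribution(p, ratio, nodes, kernel))
}

#' Closed-form difference distribution at fixed TMRCA
#'
#' For a pair of alleles whose lineages coalesced exactly `t` generations
#' ago, the signed repeat difference is a sum of `2t` i.i.d. steps that are
#' -1, 0, +1 with probabilities `mu/2`, `1 - mu`, `mu/2`, so its
#' characteristic function is `(1 - mu + mu*cos(w))^(2t)`. The pmf is
#' recovered by the inverse cosine transform. This is the analytic oracle
#' for the rarefaction identity: rarefying `p(t, mu)` by `r` must equal
#' `p(t, r*mu)`.
#'
#' @param t TMRCA in generations (non-negative).
#' @param mu per-generation mutation rate in `(0, 1)`.
#' @param max_delta support bound; default covers the mean number of
#'   mutations `2*t*mu` plus ten standard deviations (at least 20).
#' @param nodes quadrature nodes.
#' @return a [pdiff()].
#' @export
fixed_tmrca_distribution <- function(t, mu, max_delta = NULL, nodes = 4096) {
  stopifnot(t >= 0, mu > 0, mu < 1)
  if (is.null(max_delta)) {
    m <- 2 * t * mu
    max_delta <- max(20L, ceiling(m + 10 * sqrt(m)))
  }
  grid <- .trapezoid_grid(nodes)
  phat <- (1 - mu + mu * cos(grid$omega))^(2 * t)
  q <- .inverse_cosine(phat, grid, max_delta)
  q[q < 0] <- 0
  pdiff(q / sum(q))
}

#' Check the variance-scaling identity
#'
#' Classical SMM calibration scales the variance of repeat counts between
#' markers: rarefaction must reproduce `V_rarefied = r * V` (it does,
#' by a Taylor expansion of the characteristic function around
#' `omega = 0`). This helper computes both sides numerically.
#'
#' @inheritParams rarefy_distribution
#' @return list with `v_rarefied`, `v_scaled` (`ratio` times the input
#'   variance) and `relative_difference`. A warning is raised when the
#'   input pmf carries mass above `max_delta / 2` (truncation too tight
#'   for a reliable variance).
#' @export
check_variance_scaling <- function(p, ratio, nodes = 4096) {
  stopifnot(inherits(p, "pdiff"))
  max_delta <- length(p) - 1L
  tail_mass <- sum(unclass(p)[seq_len(max_delta + 1L) - 1L > max_delta / 2])
  if (tail_mass > 1e-10)
    warning(sprintf("pmf carries %.3g mass beyond max_delta/2; variance check unreliable under this truncation", tail_mass))
  v0 <- pdiff_variance(p)
  vr <- pdiff_variance(rarefy_distribution(p, ratio, nodes))
  vs <- ratio * v0
  rel <- if (vs == 0) abs(vr - vs) else abs(vr - vs) / vs
  list(v_rarefied = vr, v_scaled = vs, relative_difference = rel)
}
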