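# Relative mutation-rate estimation between marker classes: find the
# rarefaction factor k = mu_target / mu_source that best matches the
# source class's diversity structure to a reference class. Three fitting
# schemes: the full pairwise-difference distributions, the heterozygosity
# matrix only, or the classical variance-scaling closed form.

#' Per-class diversity summary
#'
#' Aggregates a set of loci (typically one motif class) into the objects
#' the rate fit and the rarefied statistics consume: per population pair,
#' the pairwise repeat-difference pmf averaged over loci with equal locus
#' weight; the within/between heterozygosity matrix implied by those pmfs;
#' and the mean across loci of the pooled allele repeat-count variance.
#'
#' @param cleaned a [clean_dataset()] result with population assignments.
#' @param loci character vector of retained locus ids (e.g. from
#'   [loci_by_motif()]); default all retained loci.
#' @param label class label carried through to results.
#' @param max_delta common truncation bound; default is the largest
#'   observed per-locus repeat-count range plus 20.
#' @return object of class `class_diversity`: list with `label`,
#'   `populations`, `pmfs` ((max_delta+1) x n_pairs matrix), `pair_i`,
#'   `pair_j` (population indices per column), `n_loci_per_pair`, `H`
#'   (population x population heterozygosity matrix), `mean_variance`
#'   and `n_loci`.
#' @export
class_diversity <- function(cleaned, loci = NULL, label = NULL,
                            max_delta = NULL) {
  stopifnot(inherits(cleaned, "cleaned_dataset"))
  if (is.null(cleaned$populations))
    stop("dataset has no population assignments")
  if (is.null(loci)) loci <- loci_by_motif(cleaned)
  stopifnot(all(loci %in% dimnames(cleaned$repeats)[[2]]))
  pops <- sort(unique(cleaned$populations))
  P <- length(pops)
  ind_by_pop <- lapply(pops, function(p)
    names(cleaned$populations)[cleaned$populations == p])
  alleles <- lapply(loci, function(l)
    lapply(ind_by_pop, function(ids) .locus_alleles(cleaned$repeats, l, ids)))
  if (is.null(max_delta)) {
    rng <- vapply(alleles, function(al) {
      v <- unlist(al)
      if (length(v)) diff(range(v)) else 0L
    }, numeric(1))
    max_delta <- max(rng) + 20L
  }
  pair_i <- pair_j <- integer(0)
  for (a in seq_len(P)) for (b in a:P) {
    pair_i <- c(pair_i, a); pair_j <- c(pair_j, b)
  }
  n_pairs <- length(pair_i)
  acc <- matrix(0, max_delta + 1L, n_pairs)
  n_contrib <- integer(n_pairs)
  variances <- numeric(length(loci))
  for (li in seq_along(loci)) {
    al <- alleles[[li]]
    pooled <- unlist(al)
    variances[li] <- if (length(pooled) >= 2) stats::var(pooled) else NA_real_
    for (k in seq_len(n_pairs)) {
      a <- al[[pair_i[k]]]; b <- al[[pair_j[k]]]
      p <- if (pair_i[k] == pair_j[k]) {
        if (length(a) < 2L) next
        .pdiff_within(a, max_delta)
      } else {
        if (length(a) < 1L || length(b) < 1L) next
        .pdiff_between(a, b, max_delta)
      }
      acc[, k] <- acc[, k] + unclass(p)
      n_contrib[k] <- n_contrib[k] + 1L
    }
  }
  if (any(n_contrib == 0L))
    stop("population pair(s) with no informative locus: ",
         paste(sprintf("%s-%s", pops[pair_i[n_contrib == 0]],
                       pops[pair_j[n_contrib == 0]]), collapse = ", "))
  pmfs <- sweep(acc, 2, n_contrib, "/")
  H <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  for (k in seq_len(n_pairs)) {
    H[pair_i[k], pair_j[k]] <- 1 - pmfs[1, k]
    H[pair_j[k], pair_i[k]] <- 1 - pmfs[1, k]
  }
  structure(list(label = label, populations = pops, pmfs = pmfs,
                 pair_i = pair_i, pair_j = pair_j,
                 n_loci_per_pair = n_contrib, H = H,
                 mean_variance = mean(variances, na.rm = TRUE),
                 n_loci = length(loci), max_delta = max_delta),
            class = "class_diversity")
}

#' @export
print.class_diversity <- function(x, ...) {
  cat(sprintf("class_diversity '%s': %d loci, %d populations, mean H(within) = %.4f, mean variance = %.3f\n",
              if (is.null(x$label)) "?" else x$label, x$n_loci,
              length(x$populations), mean(diag(x$H)), x$mean_variance))
  invisible(x)
}

# Pad two pmf matrices to a common support.
.common_support <- function(src, ref) {
  md <- max(nrow(src), nrow(ref))
  pad <- function(m) rbind(m, matrix(0, md - nrow(m), ncol(m)))
  list(src = pad(src), ref = pad(ref), max_delta = md - 1L)
}

#' Fit the rarefaction factor between two marker classes
#'
#' Finds the mutation-rate ratio `k = mu_reference / mu_source` in
#' `(0, 1]` that brings the source class's diversity closest to the
#' reference class's. Methods: `"full_distribution"` minimises the mean
#' squared difference between the rarefied source pmfs and the reference
#' pmfs over all population pairs and all differences; `"heterozygosity"`
#' minimises the mean squared difference of the within/between
#' heterozygosity matrices; `"variance"` is the classical closed form
#' `k = mean reference variance / mean source variance` (no optimisation).
#'
#' Rarefaction can only run from a faster to a slower marker class. When
#' the reference is the more diverse class no `k <= 1` exists; the fit is
#' then reported as infeasible (`feasible = FALSE`, `k = NA`) — the
#' analogue of a dash in a rate table.
#'
#' @param source,reference [class_diversity()] objects over the same
#'   populations; `source` is rarefied towards `reference`.
#' @param method fitting scheme (see above).
#' @param anchor optional known absolute mutation rate of the source
#'   class; when given, the reference-class rate `mu = k * anchor` is
#'   reported.
#' @param lower lower search bound for `k`.
#' @param tol optimiser tolerance on `k`.
#' @param nodes quadrature nodes for the rarefaction kernels.
#' @return object of class `rarefit`: list with `k`, `method`,
#'   `objective_value`, `mu`, `anchor`, `feasible`, labels and the data
#'   needed by `predict`/`plot` methods.
#' @export
fit_rarefaction_factor <- function(source, reference,
                                   method = c("full_distribution",
                                              "heterozygosity", "variance"),
                                   anchor = NULL, lower = 1e-3, tol = 1e-5,
                                   nodes = 2048) {
  method <- match.arg(method)
  stopifnot(inherits(source, "class_diversity"),
            inherits(reference, "class_diversity"))
  if (!identical(source$populations, reference$populations))
    stop("source and reference must cover the same populations")
  out <- list(method = method, anchor = anchor,
              source_label = source$label, reference_label = reference$label,
              populations = source$populations,
              source = source, reference = reference,
              k = NA_real_, objective_value = NA_real_, mu = NA_real_,
              feasible = TRUE, tol = tol, nodes = nodes)
  class(out) <- "rarefit"
  if (method == "variance") {
    k <- reference$mean_variance / source$mean_variance
    if (k > 1) {
      out$feasible <- FALSE
      out$reason <- "reference markers more diverse than source (variance ratio > 1)"
      return(out)
    }
    out$k <- k
  } else {
    cs <- .common_support(source$pmfs, reference$pmfs)
    objective <- .rarefit_objective(cs, method, nodes)
    opt <- stats::optimize(objective, interval = c(lower, 1), tol = tol)
    # boundary diagnosis: with a more diverse reference the optimum pushes
    # against k = 1 while the reference stays more heterozygous
    at_boundary <- opt$minimum > 1 - 10 * tol
    ref_more_diverse <- mean(reference$H) > mean(source$H)
    if (at_boundary && ref_more_diverse) {
      out$feasible <- FALSE
      out$reason <- "reference markers more diverse than source (optimum at k = 1)"
      return(out)
    }
    out$k <- opt$minimum
    out$objective_value <- opt$objective
  }
  if (!is.null(anchor)) out$mu <- out$k * anchor
  out
}

.rarefit_objective <- function(cs, method, nodes) {
  md <- cs$max_delta
  function(k) {
    K <- build_kernel(k, md, nodes)
    q <- K %*% cs$src
    q[q < 0] <- 0
    q <- sweep(q, 2, colSums(q), "/")
    if (method == "full_distribution") {
      mean((q - cs$ref)^2)
    } else {
      mean((q[1, ] - cs$ref[1, ])^2)
    }
  }
}

#' @export
print.rarefit <- function(x, ...) {
  cat(sprintf("rarefit (%s): %s -> %s\n", x$method,
              if (is.null(x$source_label)) "source" else x$source_label,
              if (is.null(x$reference_label)) "reference" else x$reference_label))
  if (!x$feasible) {
    cat("  infeasible:", x$reason, "\n")
  } else {
    cat(sprintf("  k = %.5f%s\n", x$k,
                if (!is.na(x$mu)) sprintf(", mu = %.4g (anchor %.4g)",
                                          x$mu, x$anchor) else ""))
    if (!is.na(x$objective_value))
      cat(sprintf("  objective = %.3g\n", x$objective_value))
  }
  invisible(x)
}

#' @export
summary.rarefit <- function(object, ...) {
  print(object)
  if (object$feasible) {
    Hs <- object$source$H; Hr <- object$reference$H
    Hp <- stats::predict(object)
    cat(sprintf("  mean within-H: source %.4f, rarefied source %.4f, reference %.4f\n",
                mean(diag(Hs)), mean(diag(Hp)), mean(diag(Hr))))
  }
  invisible(object)
}

#' @export
coef.rarefit <- function(object, ...) c(k = object$k, mu = object$mu)

#' Rarefied heterozygosity matrix at the fitted factor
#'
#' @param object a [fit_rarefaction_factor()] result.
#' @param k override the rarefaction factor (default: the fitted one).
#' @param ... unused.
#' @return population x population heterozygosity matrix of the source
#'   class rarefied by `k`.
#' @export
predict.rarefit <- function(object, k = object$k, ...) {
  if (is.na(k)) stop("no feasible k to predict from")
  src <- object$source
  K <- build_kernel(k, nrow(src$pmfs) - 1L, object$nodes)
  q <- K %*% src$pmfs
  q[q < 0] <- 0
  q <- sweep(q, 2, colSums(q), "/")
  P <- length(src$populations)
  H <- matrix(NA_real_, P, P, dimnames = list(src$populations, src$populations))
  for (idx in seq_along(src$pair_i)) {
    H[src$pair_i[idx], src$pair_j[idx]] <- 1 - q[1, idx]
    H[src$pair_j[idx], src$pair_i[idx]] <- 1 - q[1, idx]
  }
  H
}

#' @export
plot.rarefit <- function(x, k_grid = seq(max(0.02, x$k / 3), 1, length.out = 40),
                         ...) {
  if (x$method == "variance")
    stop("the variance method has no objective curve to plot")
  cs <- .common_support(x$source$pmfs, x$reference$pmfs)
  objective <- .rarefit_objective(cs, x$method, x$nodes)
  obj <- vapply(k_grid, objective, numeric(1))
  graphics::plot(k_grid, obj, type = "l", xlab = "rarefaction factor k",
                 ylab = "objective", ...)
  if (x$feasible) graphics::abline(v = x$k, lty = 2)
  invisible(data.frame(k = k_grid, objective = obj))
}

#' Composite rate estimate through a common reference
#'
#' When classes B and C have both been rarefied to a common reference R,
#' the rate of B follows from the anchor rate of A as
#' `mu_B = anchor * k_AR / k_BR`: both factors share the unknown reference
#' rate, which cancels.
#'
#' @param k_anchor_ref rarefaction factor anchor class -> reference.
#' @param k_target_ref rarefaction factor target class -> reference.
#' @param anchor absolute mutation rate of the anchor class.
#' @return absolute rate of the target class.
#' @export
composite_rate <- function(k_anchor_ref, k_target_ref, anchor) {
  stopifnot(k_anchor_ref > 0, k_anchor_ref <= 1,
            k_target_ref <= 1)
  if (k_target_ref <= 0) stop("k_target_ref must be positive")
  anchor * k_anchor_ref / k_target_ref
}

#' Mutation-rate table across marker classes
#'
#' For every reference class, rarefies every class down to it and converts
#' the fitted factors to absolute rates through the anchor class (whose
#' rate is known, e.g. from pedigree data). Cells where the reference is
#' more diverse than the class being scaled are infeasible and reported as
#' `NA` (a dash). The `"variance"` method is reference-free and produces a
#' single row.
#'
#' @param divs named list of [class_diversity()] objects.
#' @param anchor_class name (in `divs`) of the class with a known rate.
#' @param anchor_rate its absolute per-generation mutation rate.
#' @param methods subset of the three fitting schemes.
#' @param ... passed to [fit_rarefaction_factor()].
#' @return data frame with columns `method`, `reference`, then one rate
#'   column per class.
#' @export
rate_table <- function(divs, anchor_class, anchor_rate,
                       methods = c("full_distribution", "heterozygosity",
                                   "variance"), ...) {
  stopifnot(is.list(divs), length(divs) >= 2, anchor_class %in% names(divs))
  cls <- names(divs)
  rows <- list()
  for (m in methods) {
    refs <- if (m == "variance") cls[1] else cls
    for (r in refs) {
      if (m == "variance") {
        # reference-free: mu_c / mu_anchor = mean variance ratio
        rates <- anchor_rate * divs_var_ratio(divs, anchor_class)
      } else {
        # k_CR = mu_R / mu_C from rarefying class C down to reference R,
        # so mu_C = anchor * k_AR / k_CR (the unknown mu_R cancels)
        ks <- vapply(cls, function(cc) {
          if (cc == r) return(1)
          fit <- fit_rarefaction_factor(divs[[cc]], divs[[r]], method = m, ...)
          if (fit$feasible) fit$k else NA_real_
        }, numeric(1))
        k_ar <- ks[anchor_class]
        rates <- if (is.na(k_ar)) rep(NA_real_, length(cls))
                 else anchor_rate * k_ar / ks
      }
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, reference = if (m == "variance") "(none)" else r,
        t(stats::setNames(rates, cls)), check.names = FALSE)
    }
  }
  do.call(rbind, rows)
}

# variance-scaling rates relative to the anchor class: mu_c/mu_anchor =
# var_c / var_anchor (mean per-locus pooled allele variance).
divs_var_ratio <- function(divs, anchor_class) {
  v <- vapply(divs, function(d) d$mean_variance, numeric(1))
  v / v[[anchor_class]]
}
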