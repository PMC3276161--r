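# Coalescent-backed stepwise-mutation simulator: multi-population diploid
# microsatellite panels with known genealogies, mutation rates, motif
# lengths and offsets — the ground-truthed test bed for cleaning,
# rarefaction, rate fitting and the population statistics.

#' Simulation configuration
#'
#' @param n_populations number of demes.
#' @param samples_per_population diploid individuals sampled per deme.
#' @param demography `"island"` (constant-size demes, symmetric
#'   migration), `"founder"` (serial-founder chain: deme `i` is founded
#'   from deme `i-1`, passing through a bottleneck) or `"star"`
#'   (instantaneous expansion: every pair of lineages coalesces exactly
#'   `expansion_time` generations ago, giving a star genealogy with fixed
#'   TMRCA — the controlled design used for estimator-recovery
#'   experiments, where genealogical variance would otherwise drown the
#'   mutation-rate signal).
#' @param deme_size diploid effective size N of each deme.
#' @param migration_rate per-lineage per-generation migration probability
#'   (island model).
#' @param founding_interval generations between successive founder events
#'   (founder chain).
#' @param bottleneck_size diploid size during the post-founding bottleneck.
#' @param bottleneck_duration bottleneck length in generations.
#' @param expansion_time TMRCA, in generations, of every lineage pair
#'   under the `"star"` demography.
#' @param marker_classes data frame with columns `label`, `motif_length`
#'   (bp), `n_loci`, `mu` (per-locus per-generation mutation rate).
#' @param gamma per-locus offset policy: `"random"` draws an offset
#'   uniformly in `0..motif_length-1` per locus, or a single fixed integer.
#' @param contamination_rate fraction of allele copies per locus given an
#'   off-ladder shift (genotyping contamination).
#' @param root_repeat ancestral repeat count (kept comfortably above zero
#'   so repeat counts stay positive under drift).
#' @param mutation_model `"poisson"` (continuous-time, default) or
#'   `"discrete"` (per-generation Bernoulli steps, exactly matching the
#'   `(1 - mu + mu*cos w)^(2t)` characteristic function).
#' @param share_genealogies if TRUE, all marker classes reuse the same
#'   per-locus genealogies (a matched-loci design that isolates the
#'   mutation-rate contrast between classes); requires equal `n_loci`
#'   across classes.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 4,
                       samples_per_population = 20,
                       demography = c("island", "founder", "star"),
                       deme_size = 1000,
                       migration_rate = 1e-3,
                       founding_interval = 300,
                       bottleneck_size = 50,
                       bottleneck_duration = 30,
                       expansion_time = 2000,
                       marker_classes = data.frame(
                         label = c("di", "tri"),
                         motif_length = c(2L, 3L),
                         n_loci = c(60L, 60L),
                         mu = c(1.5e-3, 0.75e-3)),
                       gamma = "random",
                       contamination_rate = 0,
                       root_repeat = 20,
                       mutation_model = c("poisson", "discrete"),
                       share_genealogies = FALSE) {
  demography <- match.arg(demography)
  mutation_model <- match.arg(mutation_model)
  stopifnot(all(marker_classes$mu > 0), all(marker_classes$mu < 1),
            contamination_rate >= 0, contamination_rate < 1,
            n_populations >= 1, samples_per_population >= 1)
  if (share_genealogies && length(unique(marker_classes$n_loci)) != 1L)
    stop("share_genealogies requires equal n_loci across classes")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate one gene genealogy
#'
#' Structured coalescent for `2 * samples_per_population` allele lineages
#' per deme, run backwards in time until the grand MRCA. Island model:
#' within-deme pairwise coalescence at rate `1/(2N)` per generation,
#' per-lineage migration at `migration_rate`. Founder chain: deme `i`
#' (of `P`) was founded `(P - i + 1) * founding_interval` generations ago
#' from deme `i-1`, preceded (forward in time) by a bottleneck of size
#' `bottleneck_size` lasting `bottleneck_duration` generations; backwards,
#' lineages coalesce faster inside the bottleneck and then merge into the
#' source deme.
#'
#' @param config a [sim_config()].
#' @return list with `n_tips`, `tip_deme`, `parent`, `node_time` (time ago
#'   in generations; tips at 0) and `tmrca` (tips x tips symmetric matrix
#'   of pairwise TMRCAs).
#' @export
simulate_genealogy <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  P <- config$n_populations
  n_tips <- 2L * config$samples_per_population * P
  tip_deme <- rep(seq_len(P), each = 2L * config$samples_per_population)
  if (config$demography == "star") {
    root <- n_tips + 1L
    tm <- matrix(config$expansion_time, n_tips, n_tips)
    diag(tm) <- 0
    return(list(n_tips = n_tips, tip_deme = tip_deme,
                parent = c(rep(root, n_tips), 0L),
                node_time = c(rep(0, n_tips), config$expansion_time),
                tmrca = tm))
  }
  parent <- integer(2L * n_tips - 1L)
  node_time <- numeric(2L * n_tips - 1L)
  # active lineages: node index, deme, and member tip sets for TMRCA record
  act_node <- seq_len(n_tips)
  act_deme <- tip_deme
  members <- lapply(seq_len(n_tips), identity)
  tmrca <- matrix(0, n_tips, n_tips)
  next_node <- n_tips + 1L
  t_now <- 0
  founder <- config$demography == "founder"
  f_time <- if (founder && P > 1)
    stats::setNames((P - 2:P + 1) * config$founding_interval, 2:P)
  else numeric(0)
  deme_size_at <- function(d, t) {
    if (!founder || d == 1L) return(config$deme_size)
    f <- f_time[as.character(d)]
    if (t >= f - config$bottleneck_duration && t < f)
      config$bottleneck_size else config$deme_size
  }
  while (length(act_node) > 1L) {
    k_by_deme <- tabulate(act_deme, nbins = P)
    sizes <- vapply(seq_len(P), function(d) deme_size_at(d, t_now), numeric(1))
    coal_rate <- k_by_deme * (k_by_deme - 1) / 2 / (2 * sizes)
    mig_rate <- if (founder || P == 1L) rep(0, P) else
      k_by_deme * config$migration_rate
    total <- sum(coal_rate) + sum(mig_rate)
    # next deterministic epoch boundary (bottleneck start or deme merge)
    boundary <- Inf
    if (founder && P > 1) {
      cand <- c(f_time - config$bottleneck_duration, f_time)
      cand <- cand[cand > t_now + 1e-12]
      if (length(cand)) boundary <- min(cand)
    }
    dt <- if (total > 0) stats::rexp(1, total) else Inf
    if (t_now + dt >= boundary) {
      t_now <- boundary
      merge_d <- which(abs(f_time - boundary) < 1e-9)
      if (length(merge_d)) {             # founder event: deme joins source
        d <- as.integer(names(f_time)[merge_d[1]])
        act_deme[act_deme == d] <- d - 1L
      }
      next
    }
    if (!is.finite(dt)) stop("structured coalescent stalled (zero total rate)")
    t_now <- t_now + dt
    u <- stats::runif(1, 0, total)
    if (u < sum(coal_rate)) {
      d <- which(cumsum(coal_rate) >= u)[1]
      in_d <- which(act_deme == d)
      pair <- sample(in_d, 2L)
      i <- pair[1]; j <- pair[2]
      node_time[next_node] <- t_now
      parent[act_node[i]] <- next_node
      parent[act_node[j]] <- next_node
      mi <- members[[i]]; mj <- members[[j]]
      tmrca[mi, mj] <- t_now
      tmrca[mj, mi] <- t_now
      act_node[i] <- next_node
      members[[i]] <- c(mi, mj)
      act_node <- act_node[-j]; act_deme <- act_deme[-j]
      members[[j]] <- NULL
      next_node <- next_node + 1L
    } else {
      u <- u - sum(coal_rate)
      d <- which(cumsum(mig_rate) >= u)[1]
      i <- sample(which(act_deme == d), 1L)
      act_deme[i] <- sample(setdiff(seq_len(P), d), 1L)
    }
  }
  n_nodes <- next_node - 1L
  list(n_tips = n_tips, tip_deme = tip_deme,
       parent = parent[seq_len(n_nodes)],
       node_time = node_time[seq_len(n_nodes)],
       tmrca = tmrca)
}

#' Drop stepwise mutations on a genealogy
#'
#' Places mutations on every branch and propagates net repeat-count
#' changes from the root to the tips; each mutation adds or removes one
#' repeat unit with equal probability. `"poisson"` draws mutation counts
#' as Poisson(mu * branch length); `"discrete"` draws one Bernoulli(mu)
#' trial per generation, matching the discrete-generation SMM exactly.
#' Loci whose tips would reach repeat counts below one are redrawn
#' (bounded retries, count recorded).
#'
#' @param tree a [simulate_genealogy()] result.
#' @param mu per-generation mutation rate.
#' @param model `"poisson"` or `"discrete"`.
#' @param root_repeat ancestral repeat count.
#' @param max_retries redraw budget for loci hitting the positivity bound.
#' @return integer vector of tip repeat counts, with attribute `retries`.
#' @export
drop_mutations_smm <- function(tree, mu, model = c("poisson", "discrete"),
                               root_repeat = 20, max_retries = 50) {
  model <- match.arg(model)
  stopifnot(mu >= 0, mu < 1)
  n_nodes <- length(tree$parent)
  root <- which(tree$parent == 0L)
  ord <- order(tree$node_time, decreasing = TRUE)   # root first
  for (retry in 0:max_retries) {
    value <- numeric(n_nodes)
    value[root] <- root_repeat
    for (v in ord) {
      if (v == root) next
      len <- tree$node_time[tree$parent[v]] - tree$node_time[v]
      n_mut <- if (model == "poisson") stats::rpois(1, mu * len)
               else stats::rbinom(1, round(len), mu)
      net <- if (n_mut > 0) 2L * stats::rbinom(1, n_mut, 0.5) - n_mut else 0L
      value[v] <- value[tree$parent[v]] + net
    }
    tips <- value[seq_len(tree$n_tips)]
    if (all(tips >= 1)) {
      return(structure(as.integer(tips), retries = retry))
    }
  }
  stop("repeat counts repeatedly fell below 1; raise root_repeat")
}

#' Encode repeat counts as raw fragment lengths
#'
#' The inverse of cleaning: `L = motif_length * n + gamma`. A random
#' fraction `contamination_rate` of allele copies is shifted by a uniform
#' non-multiple of the motif length (1 .. motif_length - 1), emulating
#' off-ladder genotyping artefacts; the affected positions are returned as
#' ground truth.
#'
#' @param repeats individuals x 2 integer matrix of repeat counts for one
#'   locus.
#' @param motif_length repeat-unit length in bp.
#' @param gamma offset in `0 .. motif_length - 1`.
#' @param contamination_rate fraction of allele copies contaminated.
#' @return list with `lengths` (same shape as `repeats`) and
#'   `contaminated` (logical matrix marking shifted allele copies).
#' @export
encode_fragment_lengths <- function(repeats, motif_length, gamma,
                                    contamination_rate = 0) {
  stopifnot(gamma >= 0, gamma < motif_length)
  L <- motif_length * repeats + gamma
  contam <- array(FALSE, dim = dim(L))
  if (contamination_rate > 0) {
    idx <- which(!is.na(L))
    hit <- idx[stats::runif(length(idx)) < contamination_rate]
    if (length(hit)) {
      shift <- sample(seq_len(motif_length - 1L), length(hit), replace = TRUE)
      L[hit] <- L[hit] + shift
      contam[hit] <- TRUE
    }
  }
  list(lengths = L, contaminated = contam)
}

#' Simulate a complete microsatellite panel
#'
#' Composes [simulate_genealogy()], [drop_mutations_smm()] and
#' [encode_fragment_lengths()] for every locus of every marker class,
#' producing raw fragment lengths plus full ground truth.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; fully determines the panel.
#' @return list of class `sim_panel` with elements
#'   `table` (an [allele_table()] with population assignments),
#'   `truth` (data frame per locus: `locus`, `class`, `motif_length`,
#'   `gamma`, `mu`, `n_contaminated`),
#'   `repeats` (true repeat counts, individuals x loci x 2),
#'   `contaminated` (same shape, logical), `tmrca` (list of per-locus tip
#'   TMRCA matrices) and `config`.
#' @export
simulate_panel <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  P <- config$n_populations
  n_ind <- P * config$samples_per_population
  ind_ids <- sprintf("ind%04d", seq_len(n_ind))
  pops <- stats::setNames(rep(sprintf("pop%02d", seq_len(P)),
                              each = config$samples_per_population), ind_ids)
  mc <- config$marker_classes
  n_loci_tot <- sum(mc$n_loci)
  locus_ids <- character(n_loci_tot)
  truth <- vector("list", n_loci_tot)
  lengths <- array(NA_integer_, c(n_ind, n_loci_tot, 2L))
  repeats <- array(NA_integer_, c(n_ind, n_loci_tot, 2L))
  contam <- array(FALSE, c(n_ind, n_loci_tot, 2L))
  tmrca <- vector("list", n_loci_tot)
  shared_trees <- NULL
  if (config$share_genealogies)
    shared_trees <- lapply(seq_len(mc$n_loci[1]),
                           function(i) simulate_genealogy(config))
  col <- 0L
  for (ci in seq_len(nrow(mc))) {
    Lm <- mc$motif_length[ci]
    for (li in seq_len(mc$n_loci[ci])) {
      col <- col + 1L
      locus_ids[col] <- sprintf("%s_L%03d", mc$label[ci], li)
      tree <- if (config$share_genealogies) shared_trees[[li]]
              else simulate_genealogy(config)
      tips <- drop_mutations_smm(tree, mc$mu[ci],
                                 model = config$mutation_model,
                                 root_repeat = config$root_repeat)
      # tips 2i-1, 2i are the two alleles of individual i
      rc <- cbind(tips[seq(1L, tree$n_tips, 2L)],
                  tips[seq(2L, tree$n_tips, 2L)])
      g <- if (identical(config$gamma, "random"))
        sample(0:(Lm - 1L), 1L) else as.integer(config$gamma) %% Lm
      enc <- encode_fragment_lengths(rc, Lm, g, config$contamination_rate)
      lengths[, col, ] <- enc$lengths
      repeats[, col, ] <- rc
      contam[, col, ] <- enc$contaminated
      truth[[col]] <- data.frame(locus = locus_ids[col], class = mc$label[ci],
                                 motif_length = Lm, gamma = g, mu = mc$mu[ci],
                                 n_contaminated = sum(enc$contaminated))
      tmrca[[col]] <- tree$tmrca
    }
  }
  dimnames(lengths) <- list(ind_ids, locus_ids, NULL)
  dimnames(repeats) <- list(ind_ids, locus_ids, NULL)
  dimnames(contam) <- list(ind_ids, locus_ids, NULL)
  names(tmrca) <- locus_ids
  structure(
    list(table = allele_table(lengths, populations = pops),
         truth = do.call(rbind, truth), repeats = repeats,
         contaminated = contam, tmrca = tmrca, config = config),
    class = "sim_panel")
}

#' Ground-truth repeat counts as a cleaned dataset
#'
#' Wraps a simulated panel's true repeat counts in the container the
#' downstream statistics consume, bypassing fragment-length cleaning.
#' Useful for separating estimator behaviour from cleaning behaviour in
#' recovery experiments.
#'
#' @param panel a [simulate_panel()] result.
#' @return a `cleaned_dataset` whose repeat counts are the simulation
#'   truth (all loci `"clean"`).
#' @export
truth_dataset <- function(panel) {
  stopifnot(inherits(panel, "sim_panel"))
  qc <- data.frame(locus = panel$truth$locus,
                   motif_length = panel$truth$motif_length,
                   offset = panel$truth$gamma,
                   offset_mode_fraction = 1, status = "clean",
                   n_recoded = 0L, reason = NA_character_,
                   motif_tie = FALSE, offset_tie = FALSE)
  by_motif <- table(qc$motif_length)
  structure(
    list(repeats = panel$repeats, qc = qc,
         populations = panel$table$populations,
         summary = list(n_input = nrow(qc), n_retained = nrow(qc),
                        n_rejected = 0L,
                        retained_by_motif = stats::setNames(
                          as.integer(by_motif), names(by_motif)))),
    class = "cleaned_dataset")
}

#' @export
print.sim_panel <- function(x, ...) {
  cat(sprintf("sim_panel: %d individuals, %d populations, %d loci (%s demography)\n",
              length(x$table$individuals), x$config$n_populations,
              length(x$table$loci), x$config$demography))
  cat("  classes:", paste(sprintf("%s (Lm=%d, mu=%g, n=%d)",
                                  x$config$marker_classes$label,
                                  x$config$marker_classes$motif_length,
                                  x$config$marker_classes$mu,
                                  x$config$marker_classes$n_loci),
                          collapse = "; "), "\n")
  invisible(x)
}
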