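# In-code fixture builders shared across test files.

# Allele table from a list of per-locus individual x 2 length matrices.
make_table <- function(locus_lengths, populations = NULL) {
  n_ind <- nrow(locus_lengths[[1]])
  ids <- sprintf("i%02d", seq_len(n_ind))
  arr <- array(NA_integer_, c(n_ind, length(locus_lengths), 2L),
               dimnames = list(ids, names(locus_lengths), NULL))
  for (j in seq_along(locus_lengths)) arr[, j, ] <- locus_lengths[[j]]
  if (!is.null(populations)) names(populations) <- ids
  allele_table(arr, populations = populations)
}

# Minimal cleaned_dataset straight from a repeats array (for popgen /
# rarefaction tests that do not exercise cleaning).
make_cleaned <- function(repeats, populations) {
  stopifnot(length(dim(repeats)) == 3L)
  ids <- dimnames(repeats)[[1]]
  loci <- dimnames(repeats)[[2]]
  names(populations) <- ids
  qc <- data.frame(locus = loci, motif_length = 2L, offset = 0L,
                   offset_mode_fraction = 1, status = "clean",
                   n_recoded = 0L, reason = NA_character_,
                   motif_tie = FALSE, offset_tie = FALSE)
  structure(list(repeats = repeats, qc = qc, populations = populations,
                 summary = list(n_input = length(loci),
                                n_retained = length(loci), n_rejected = 0L,
                                retained_by_motif = c("2" = length(loci)))),
            class = "cleaned_dataset")
}

# One-locus repeats array from a vector of per-individual allele pairs.
repeats_one_locus <- function(genotypes, populations) {
  n <- length(genotypes)
  arr <- array(NA_integer_, c(n, 1L, 2L),
               dimnames = list(sprintf("i%02d", seq_len(n)), "L1", NULL))
  for (i in seq_len(n)) arr[i, 1L, ] <- genotypes[[i]]
  make_cleaned(arr, populations)
}

# Exact pmf of |sum of 2t iid steps (-1,0,+1 w.p. mu/2, 1-mu, mu/2)|:
# the number of mutations is Binomial(2t, mu) and, given m mutations, the
# signed sum is 2*Binomial(m, 1/2) - m. Independent closed-form oracle for
# fixed_tmrca_distribution.
exact_fixed_tmrca_pmf <- function(t, mu, max_delta) {
  m <- 0:(2 * t)
  pm <- stats::dbinom(m, 2 * t, mu)
  vapply(0:max_delta, function(d) {
    ok <- m >= d & (m + d) %% 2 == 0
    s <- sum(pm[ok] * stats::dbinom((m[ok] + d) / 2, m[ok], 0.5))
    if (d > 0) 2 * s else s
  }, numeric(1))
}
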