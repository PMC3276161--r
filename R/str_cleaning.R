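# Fragment-length quality control: infer each locus's repeat-unit length
# and offset from its allele-length spectrum, filter inconsistent loci, and
# convert fragment lengths (bp) to repeat counts.
#
# Every fragment length decomposes as L = Lm * n + gamma, where Lm is the
# repeat-unit (motif) length, n the repeat count (plus an unknown constant
# from the flanking sequence) and gamma the remainder of L modulo Lm.

#' Allele-length spectrum of one locus
#'
#' @param lengths integer vector of fragment lengths (bp), one entry per
#'   observed allele copy (missing already removed).
#' @return A `locus_spectrum`: data frame with columns `length` and `freq`
#'   (relative frequencies summing to one).
#' @export
locus_spectrum <- function(lengths) {
  lengths <- lengths[!is.na(lengths)]
  if (!length(lengths)) stop("empty allele set: no typed alleles")
  if (any(lengths <= 0)) stop("fragment lengths must be positive")
  tab <- table(lengths)
  out <- data.frame(length = as.integer(names(tab)),
                    freq = as.numeric(tab) / sum(tab))
  class(out) <- c("locus_spectrum", "data.frame")
  out
}

#' Infer the repeat-unit length of a locus
#'
#' Scores each candidate motif length `Lm` by the relative overlap of the
#' allele-length spectrum with itself shifted by `Lm` base pairs,
#' `sum(f_i * f_{i+Lm}) / sum(f_i^2)`, and returns the candidate with the
#' maximal score. A ladder of alleles spaced by the true motif length
#' overlaps itself strongly under that shift and not under others.
#'
#' @param spectrum a [locus_spectrum()].
#' @param candidates integer candidate motif lengths (default 2:5).
#' @return list with `motif_length`, named numeric `scores`, and `tie`
#'   (TRUE when the maximum was shared and the smallest candidate chosen).
#' @export
infer_motif_length <- function(spectrum, candidates = 2:5) {
  stopifnot(inherits(spectrum, "locus_spectrum"), length(candidates) >= 1)
  f <- stats::setNames(spectrum$freq, spectrum$length)
  lens <- spectrum$length
  denom <- sum(f^2)
  scores <- vapply(candidates, function(Lm) {
    partner <- match(lens + Lm, lens)
    ok <- !is.na(partner)
    sum(f[ok] * f[partner[ok]]) / denom
  }, numeric(1))
  names(scores) <- candidates
  if (all(scores == 0))
    stop("degenerate spectrum: no shift produces overlap; motif length undecidable")
  best <- which(scores == max(scores))
  list(motif_length = as.integer(candidates[best[1]]), scores = scores,
       tie = length(best) > 1L)
}

#' Tabulate fragment-length offsets modulo the motif length
#'
#' @param lengths integer vector of fragment lengths (one per allele copy).
#' @param motif_length repeat-unit length in bp (>= 2).
#' @return list with `counts` (named vector, offset -> allele count),
#'   `modal_offset`, `fraction` (modal count / total) and `tie`.
#'   Ties in the modal offset are broken towards the smallest offset.
#' @export
infer_offsets <- function(lengths, motif_length) {
  lengths <- lengths[!is.na(lengths)]
  if (!length(lengths)) stop("empty allele set: cannot tabulate offsets")
  stopifnot(motif_length >= 2)
  off <- lengths %% motif_length
  counts <- table(factor(off, levels = sort(unique(off))))
  counts <- stats::setNames(as.integer(counts), names(counts))
  best <- which(counts == max(counts))
  list(counts = counts,
       modal_offset = as.integer(names(counts)[best[1]]),
       fraction = max(counts) / sum(counts),
       tie = length(best) > 1L)
}

#' Clean a single locus
#'
#' Infers the motif length and modal offset from the pooled allele-length
#' spectrum, then applies the consistency filter: when the modal offset
#' accounts for at least `threshold` of all allele copies, individuals
#' carrying at least one off-offset allele are recoded as missing at this
#' locus and the remaining lengths converted to repeat counts
#' `n = (L - gamma) / Lm`; otherwise the locus deviates too strongly from
#' the model and is rejected outright.
#'
#' @param table an [allele_table()].
#' @param locus locus id.
#' @param threshold minimal modal-offset fraction for retention
#'   (default 0.95; the comparison is `>=`).
#' @param candidates candidate motif lengths passed to
#'   [infer_motif_length()].
#' @return A `cleaned_locus`: list with `locus`, `motif_length`, `offset`,
#'   `offset_mode_fraction`, `status` (one of `"clean"`,
#'   `"cleaned_with_recoding"`, `"rejected"`), `reason` (for rejections),
#'   `repeat_counts` (individuals x 2 integer matrix, NA = missing),
#'   `n_recoded`, `scores`, and tie flags.
#' @export
clean_locus <- function(table, locus, threshold = 0.95, candidates = 2:5) {
  stopifnot(inherits(table, "allele_table"), locus %in% table$loci)
  geno <- table$lengths[, locus, , drop = TRUE]
  if (length(table$individuals) == 1L)
    geno <- matrix(geno, 1, 2, dimnames = list(table$individuals, NULL))
  alleles <- as.vector(geno); alleles <- alleles[!is.na(alleles)]
  base <- list(locus = locus, motif_length = NA_integer_,
               offset = NA_integer_, offset_mode_fraction = NA_real_,
               status = "rejected", reason = NA_character_,
               repeat_counts = NULL, n_recoded = 0L,
               scores = NULL, motif_tie = FALSE, offset_tie = FALSE)
  class(base) <- "cleaned_locus"
  if (length(unique(alleles)) < 2L) {
    base$reason <- "degenerate spectrum (<2 distinct allele lengths)"
    return(base)
  }
  spec <- locus_spectrum(alleles)
  ml <- tryCatch(infer_motif_length(spec, candidates), error = function(e) e)
  if (inherits(ml, "error")) {
    base$reason <- conditionMessage(ml)
    return(base)
  }
  off <- infer_offsets(alleles, ml$motif_length)
  base$motif_length <- ml$motif_length
  base$offset <- off$modal_offset
  base$offset_mode_fraction <- off$fraction
  base$scores <- ml$scores
  base$motif_tie <- ml$tie
  base$offset_tie <- off$tie
  if (off$fraction < threshold) {
    base$reason <- sprintf("modal offset fraction %.4f below threshold %.2f",
                           off$fraction, threshold)
    return(base)
  }
  # recode individuals carrying any off-offset allele; convert the rest
  off_ok <- geno %% ml$motif_length == off$modal_offset
  bad_ind <- which(apply(!off_ok & !is.na(geno), 1, any))
  rc <- (geno - off$modal_offset) %/% ml$motif_length
  if (length(bad_ind)) rc[bad_ind, ] <- NA_integer_
  storage.mode(rc) <- "integer"
  base$repeat_counts <- rc
  base$n_recoded <- length(bad_ind)
  base$status <- if (length(bad_ind)) "cleaned_with_recoding" else "clean"
  base
}

#' Clean a whole dataset
#'
#' Applies [clean_locus()] to every locus (per-locus failures are recorded
#' in the QC table, never raised) and assembles the retained repeat-count
#' genotypes. Penta-nucleotide loci are retained but flagged so callers can
#' drop them when a class has too few markers to analyse.
#'
#' @inheritParams clean_locus
#' @return A `cleaned_dataset`: list with
#'   \describe{
#'     \item{repeats}{integer array individuals x loci x 2 of repeat
#'       counts (only retained loci; NA = missing or recoded).}
#'     \item{qc}{data frame, one row per input locus: `locus`,
#'       `motif_length`, `offset`, `offset_mode_fraction`, `status`,
#'       `n_recoded`, `reason`, `motif_tie`, `offset_tie`.}
#'     \item{populations}{carried over from the input table.}
#'     \item{summary}{retained-locus counts by motif length and rejection
#'       count.}
#'   }
#' @export
clean_dataset <- function(table, threshold = 0.95, candidates = 2:5) {
  stopifnot(inherits(table, "allele_table"))
  cleaned <- lapply(table$loci, function(l)
    clean_locus(table, l, threshold = threshold, candidates = candidates))
  qc <- do.call(rbind, lapply(cleaned, function(cl)
    data.frame(locus = cl$locus, motif_length = cl$motif_length,
               offset = cl$offset,
               offset_mode_fraction = cl$offset_mode_fraction,
               status = cl$status, n_recoded = cl$n_recoded,
               reason = cl$reason, motif_tie = cl$motif_tie,
               offset_tie = cl$offset_tie)))
  keep <- qc$status != "rejected"
  repeats <- array(NA_integer_,
                   c(length(table$individuals), sum(keep), 2L),
                   dimnames = list(table$individuals, qc$locus[keep], NULL))
  for (l in which(keep)) repeats[, qc$locus[l], ] <- cleaned[[l]]$repeat_counts
  by_motif <- table(qc$motif_length[keep])
  out <- structure(
    list(repeats = repeats, qc = qc, populations = table$populations,
         summary = list(n_input = nrow(qc), n_retained = sum(keep),
                        n_rejected = sum(!keep),
                        retained_by_motif = stats::setNames(
                          as.integer(by_motif), names(by_motif)))),
    class = "cleaned_dataset")
  out
}

#' @export
print.cleaned_dataset <- function(x, ...) {
  s <- x$summary
  cat(sprintf("cleaned_dataset: %d/%d loci retained (%d rejected)\n",
              s$n_retained, s$n_input, s$n_rejected))
  if (length(s$retained_by_motif)) {
    cat("  retained by motif length (bp):",
        paste(sprintf("%s: %d", names(s$retained_by_motif),
                      s$retained_by_motif), collapse = ", "), "\n")
  }
  n_rec <- sum(x$qc$n_recoded)
  if (n_rec) cat(sprintf("  %d individual-locus genotype(s) recoded missing\n", n_rec))
  invisible(x)
}

#' @export
summary.cleaned_dataset <- function(object, ...) {
  print(object)
  cat("\nPer-status locus counts:\n")
  print(table(object$qc$status))
  invisible(object$qc)
}

#' Select retained loci of given motif length(s)
#'
#' @param cleaned a [clean_dataset()] result.
#' @param motif_length integer vector of motif lengths (bp), e.g. `2` for
#'   di-nucleotides; `NULL` selects all retained loci.
#' @return character vector of locus ids.
#' @export
loci_by_motif <- function(cleaned, motif_length = NULL) {
  stopifnot(inherits(cleaned, "cleaned_dataset"))
  qc <- cleaned$qc[cleaned$qc$status != "rejected", ]
  if (is.null(motif_length)) return(qc$locus)
  qc$locus[qc$motif_length %in% motif_length]
}

#' QC report as a plain list (for JSON export)
#'
#' @param cleaned a [clean_dataset()] result.
#' @return nested list mirroring the QC table, suitable for
#'   [write_report()].
#' @export
qc_report <- function(cleaned) {
  stopifnot(inherits(cleaned, "cleaned_dataset"))
  list(summary = cleaned$summary,
       loci = lapply(seq_len(nrow(cleaned$qc)), function(i)
         as.list(cleaned$qc[i, , drop = FALSE])))
}
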