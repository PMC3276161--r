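# Brute-force overlap oracle: shift score computed straight from the
# definition on a named frequency vector.
overlap_score <- function(freq, shift) {
  lens <- as.integer(names(freq))
  s <- 0
  for (i in seq_along(lens)) {
    j <- match(lens[i] + shift, lens)
    if (!is.na(j)) s <- s + freq[i] * freq[j]
  }
  unname(s / sum(freq^2))
}

test_that("motif length is the shift maximising spectrum self-overlap", {
  sp <- locus_spectrum(c(100L, 102L, 104L, 106L))
  res <- infer_motif_length(sp)
  expect_identical(res$motif_length, 2L)
  f <- setNames(sp$freq, sp$length)
  expect_equal(unname(res$scores["2"]), overlap_score(f, 2))
  expect_equal(unname(res$scores["2"]), 0.75)
  expect_equal(unname(res$scores["4"]), 0.5)

  sp4 <- locus_spectrum(c(200L, 204L, 208L))
  res4 <- infer_motif_length(sp4)
  expect_identical(res4$motif_length, 4L)
  expect_equal(unname(res4$scores["2"]), 0)
  f4 <- setNames(sp4$freq, sp4$length)
  for (s in 2:5)
    expect_equal(unname(res4$scores[as.character(s)]), overlap_score(f4, s))
})

test_that("a spectrum without informative shifts is degenerate", {
  expect_error(infer_motif_length(locus_spectrum(150L)), "degenerate")
  # two alleles one unit apart under no candidate shift
  expect_error(infer_motif_length(locus_spectrum(c(150L, 151L))), "degenerate")
})

test_that("offset tabulation counts alleles and breaks ties toward small gamma", {
  o <- infer_offsets(c(101L, 103L, 105L), 2L)
  expect_identical(o$counts, c("1" = 3L))
  expect_identical(o$modal_offset, 1L)
  expect_equal(o$fraction, 1.0)

  lens <- c(rep(101L, 97), rep(100L, 3))
  o2 <- infer_offsets(lens, 2L)
  expect_identical(o2$modal_offset, 1L)
  expect_equal(o2$fraction, 0.97)

  o3 <- infer_offsets(c(100L, 101L), 2L)
  expect_identical(o3$modal_offset, 0L)
  expect_equal(o3$fraction, 0.5)
  expect_true(o3$tie)
  expect_error(infer_offsets(integer(0), 2L), "empty")
})

# 100-individual single-locus table on a clean di ladder (gamma = 1),
# with n_bad individuals carrying one off-offset allele.
ladder_table <- function(n_bad = 0L) {
  set.seed(99)
  lens <- matrix(sample(c(101L, 103L, 105L, 107L), 200, replace = TRUE),
                 100, 2)
  if (n_bad > 0) lens[seq_len(n_bad), 1] <- lens[seq_len(n_bad), 1] + 1L
  make_table(list(L1 = lens))
}

test_that("clean loci convert lengths to repeat counts exactly", {
  tab <- ladder_table(0L)
  cl <- clean_locus(tab, "L1")
  expect_identical(cl$status, "clean")
  expect_identical(cl$motif_length, 2L)
  expect_identical(cl$offset, 1L)
  expect_identical(cl$repeat_counts, (tab$lengths[, "L1", ] - 1L) %/% 2L)
  expect_identical(unname(cl$repeat_counts[tab$lengths[, "L1", 1] == 105L, 1][1]),
                   52L)
})

test_that("the 95% rule recodes mildly contaminated loci and rejects bad ones", {
  # 3 of 200 alleles off-offset: fraction 0.985 -> recode those individuals
  cl <- clean_locus(ladder_table(3L), "L1")
  expect_identical(cl$status, "cleaned_with_recoding")
  expect_identical(cl$n_recoded, 3L)
  expect_true(all(is.na(cl$repeat_counts[1:3, ])))
  expect_true(all(!is.na(cl$repeat_counts[4:100, ])))
  # 20 of 200 alleles off-offset: fraction 0.90 -> rejected
  cl2 <- clean_locus(ladder_table(20L), "L1")
  expect_identical(cl2$status, "rejected")
  expect_null(cl2$repeat_counts)
})

test_that("retention switches exactly at the threshold (>= comparison)", {
  # 10/200 off -> modal fraction exactly 0.95 -> retained
  expect_identical(clean_locus(ladder_table(10L), "L1")$status,
                   "cleaned_with_recoding")
  # 11/200 off -> 0.945 -> rejected
  expect_identical(clean_locus(ladder_table(11L), "L1")$status, "rejected")
})

test_that("cleaning a clean simulated panel retains everything and recovers truth", {
  # dense spectra (100 allele copies per locus) keep the overlap statistic
  # well away from its sparse-data failure mode
  cfg <- sim_config(n_populations = 2, samples_per_population = 25,
                    demography = "star",
                    marker_classes = data.frame(
                      label = c("di", "tri", "tetra"),
                      motif_length = c(2L, 3L, 4L),
                      n_loci = c(7L, 7L, 6L),
                      mu = c(1.5e-3, 1e-3, 8e-4)))
  panel <- simulate_panel(cfg, seed = 5)
  cleaned <- clean_dataset(panel$table)
  expect_identical(cleaned$summary$n_retained, 20L)
  expect_identical(sum(cleaned$qc$n_recoded), 0L)
  expect_identical(cleaned$qc$motif_length, panel$truth$motif_length)
  expect_identical(cleaned$qc$offset, panel$truth$gamma)
  expect_identical(cleaned$repeats, panel$repeats)
})

test_that("on sparse coalescent panels every locus is recovered exactly or rejected", {
  cfg <- sim_config(n_populations = 3, samples_per_population = 8,
                    marker_classes = data.frame(
                      label = c("di", "tri"), motif_length = c(2L, 3L),
                      n_loci = c(15L, 15L), mu = c(1.5e-3, 0.75e-3)))
  for (s in 1:3) {
    panel <- simulate_panel(cfg, seed = 40 + s)
    qc <- clean_dataset(panel$table)$qc
    kept <- qc$status != "rejected"
    expect_identical(qc$motif_length[kept], panel$truth$motif_length[kept])
    expect_identical(qc$offset[kept], panel$truth$gamma[kept])
  }
})

test_that("raising the threshold never increases retained genotypes", {
  cfg <- sim_config(n_populations = 2, samples_per_population = 15,
                    demography = "star", contamination_rate = 0.04,
                    marker_classes = data.frame(label = "di",
                                                motif_length = 2L,
                                                n_loci = 15L, mu = 1.5e-3))
  panel <- simulate_panel(cfg, seed = 8)
  n_geno <- vapply(c(0.90, 0.95, 0.99), function(th)
    sum(!is.na(clean_dataset(panel$table, threshold = th)$repeats)),
    numeric(1))
  expect_true(all(diff(n_geno) <= 0))
})

test_that("per-locus failures are recorded in the QC table, not raised", {
  tab <- make_table(list(
    good = rbind(c(101L, 103L), c(103L, 105L), c(105L, 105L)),
    mono = rbind(c(150L, 150L), c(150L, 150L), c(150L, 150L))))
  cleaned <- clean_dataset(tab)
  expect_identical(cleaned$summary$n_retained, 1L)
  expect_identical(cleaned$qc$status[cleaned$qc$locus == "mono"], "rejected")
  expect_match(cleaned$qc$reason[cleaned$qc$locus == "mono"], "degenerate")
})
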