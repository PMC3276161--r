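# Readers and writers for the plain-text table dialects used throughout the
# package, plus the core in-memory genotype container.

#' Diploid fragment-length table
#'
#' The core raw-data container: per-individual, per-locus microsatellite
#' allele fragment lengths in base pairs. Genotypes are unordered allele
#' pairs; a half-missing genotype is normalised to fully missing so that
#' both alleles are always jointly present or jointly absent.
#'
#' @param lengths integer array of dimension `c(n_individuals, n_loci, 2)`
#'   with dimnames giving individual and locus identifiers; `NA` marks
#'   missing alleles.
#' @param populations named character vector mapping every individual to a
#'   population label, or `NULL` if assignments are supplied later via
#'   [assign_populations()].
#' @param log character vector of validation messages accumulated while
#'   building the table (never silently dropped).
#'
#' @return An object of class `allele_table` with elements `lengths`,
#'   `individuals`, `loci`, `populations` and `log`.
#' @seealso [read_genotypes()], [clean_dataset()]
#' @export
allele_table <- function(lengths, populations = NULL, log = character()) {
  stopifnot(is.array(lengths), length(dim(lengths)) == 3L, dim(lengths)[3] == 2L)
  if (is.null(dimnames(lengths)[[1]]) || is.null(dimnames(lengths)[[2]]))
    stop("'lengths' must carry individual and locus dimnames")
  storage.mode(lengths) <- "integer"
  bad <- which(!is.na(lengths) & lengths <= 0L)
  if (length(bad))
    stop("fragment lengths must be positive integers; found non-positive values")
  individuals <- dimnames(lengths)[[1]]
  loci <- dimnames(lengths)[[2]]
  if (anyDuplicated(individuals))
    stop("duplicate individual id: ",
         paste(unique(individuals[duplicated(individuals)]), collapse = ", "))
  if (anyDuplicated(loci))
    stop("duplicate locus id: ",
         paste(unique(loci[duplicated(loci)]), collapse = ", "))
  # normalise half-missing genotypes to fully missing
  half <- is.na(lengths[, , 1, drop = FALSE]) != is.na(lengths[, , 2, drop = FALSE])
  if (any(half)) {
    idx <- which(half, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      lengths[idx[r, 1], idx[r, 2], ] <- NA_integer_
    }
    log <- c(log, sprintf("%d half-missing genotype(s) normalised to missing",
                          nrow(idx)))
  }
  obj <- structure(
    list(lengths = lengths, individuals = individuals, loci = loci,
         populations = NULL, log = log),
    class = "allele_table")
  if (!is.null(populations)) obj <- assign_populations(obj, populations)
  obj
}

#' @export
print.allele_table <- function(x, ...) {
  n_geno <- sum(!is.na(x$lengths[, , 1]))
  cat(sprintf("allele_table: %d individuals x %d loci (%d typed genotypes)\n",
              length(x$individuals), length(x$loci), n_geno))
  if (!is.null(x$populations))
    cat(sprintf("  populations: %d (%s%s)\n",
                length(unique(x$populations)),
                paste(utils::head(unique(x$populations), 5), collapse = ", "),
                if (length(unique(x$populations)) > 5) ", ..." else ""))
  if (length(x$log)) cat("  log:", length(x$log), "message(s)\n")
  invisible(x)
}

#' Attach population assignments to an allele table
#'
#' @param table an [allele_table()].
#' @param populations named character vector, individual id -> population
#'   label. Every individual in the table must be covered.
#' @return The table with `populations` set (in table individual order).
#' @export
assign_populations <- function(table, populations) {
  stopifnot(inherits(table, "allele_table"))
  missing_ids <- setdiff(table$individuals, names(populations))
  if (length(missing_ids))
    stop("individuals absent from population map: ",
         paste(missing_ids, collapse = ", "))
  table$populations <- populations[table$individuals]
  table
}

.split_fields <- function(lines, sep = "\t") strsplit(lines, sep, fixed = TRUE)

.parse_length <- function(x, missing_codes) {
  out <- suppressWarnings(as.integer(x))
  out[x %in% missing_codes | x == "" | is.na(out) | out <= 0L] <- NA_integer_
  out
}

#' Read a genotype table
#'
#' Two tab-separated dialects are supported. `"wide"` has one row per
#' individual: an `id` column followed by two columns per locus named
#' `<locus>_1` and `<locus>_2`. `"long"` has columns
#' `individual`, `locus`, `allele1`, `allele2`, one row per genotype.
#' Unknown or non-positive length codes (default sentinel `"-9"`, and the
#' empty field) are mapped to missing.
#'
#' @param path file path.
#' @param dialect `"wide"` or `"long"`.
#' @param missing_codes character vector of sentinel codes treated as
#'   missing data.
#' @return An [allele_table()] (without population assignments).
#' @export
read_genotypes <- function(path, dialect = c("wide", "long"),
                           missing_codes = "-9") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("genotype file has no data rows: ", path)
  fields <- .split_fields(lines)
  header <- fields[[1]]
  if (dialect == "wide") {
    if (header[1] != "id" || length(header) < 3L || (length(header) - 1L) %% 2L)
      stop("malformed wide header: expected 'id' plus two columns per locus")
    loci <- unique(sub("_[12]$", "", header[-1]))
    if (length(loci) * 2L != length(header) - 1L)
      stop("malformed wide header: locus columns must come in _1/_2 pairs")
    n_fields <- length(header)
    ids <- character(length(fields) - 1L)
    mat <- matrix(NA_integer_, length(fields) - 1L, n_fields - 1L)
    for (i in seq_along(fields)[-1]) {
      f <- fields[[i]]
      if (length(f) != n_fields)
        stop(sprintf("parse error at line %d: expected %d fields, found %d",
                     i, n_fields, length(f)))
      ids[i - 1L] <- f[1]
      mat[i - 1L, ] <- .parse_length(f[-1], missing_codes)
    }
    lengths <- array(NA_integer_, c(length(ids), length(loci), 2L),
                     dimnames = list(ids, loci, NULL))
    lengths[, , 1] <- mat[, seq(1L, ncol(mat), by = 2L), drop = FALSE]
    lengths[, , 2] <- mat[, seq(2L, ncol(mat), by = 2L), drop = FALSE]
  } else {
    if (length(header) != 4L)
      stop("malformed long header: expected individual, locus, allele1, allele2")
    n <- length(fields) - 1L
    ind <- loc <- character(n)
    a1 <- a2 <- integer(n)
    for (i in seq_along(fields)[-1]) {
      f <- fields[[i]]
      if (length(f) != 4L)
        stop(sprintf("parse error at line %d: expected 4 fields, found %d",
                     i, length(f)))
      ind[i - 1L] <- f[1]; loc[i - 1L] <- f[2]
      a1[i - 1L] <- .parse_length(f[3], missing_codes)
      a2[i - 1L] <- .parse_length(f[4], missing_codes)
    }
    ids <- unique(ind); loci <- unique(loc)
    lengths <- array(NA_integer_, c(length(ids), length(loci), 2L),
                     dimnames = list(ids, loci, NULL))
    lengths[cbind(match(ind, ids), match(loc, loci), 1L)] <- a1
    lengths[cbind(match(ind, ids), match(loc, loci), 2L)] <- a2
  }
  allele_table(lengths)
}

#' Write a genotype table
#'
#' Inverse of [read_genotypes()]. Within each genotype alleles are emitted
#' in `min,max` order (allele order carries no meaning), and missing
#' genotypes as the sentinel, so canonical files round-trip byte-identically.
#'
#' @param table an [allele_table()].
#' @inheritParams read_genotypes
#' @param missing_code sentinel written for missing alleles.
#' @export
write_genotypes <- function(table, path, dialect = c("wide", "long"),
                            missing_code = "-9") {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "allele_table"))
  a1 <- pmin(table$lengths[, , 1, drop = FALSE], table$lengths[, , 2, drop = FALSE])
  a2 <- pmax(table$lengths[, , 1, drop = FALSE], table$lengths[, , 2, drop = FALSE])
  fmt <- function(x) ifelse(is.na(x), missing_code, as.character(x))
  if (dialect == "wide") {
    header <- c("id", as.vector(rbind(paste0(table$loci, "_1"),
                                      paste0(table$loci, "_2"))))
    rows <- vapply(seq_along(table$individuals), function(i) {
      paste(c(table$individuals[i],
              fmt(as.vector(rbind(a1[i, , 1], a2[i, , 1])))), collapse = "\t")
    }, character(1))
    writeLines(c(paste(header, collapse = "\t"), rows), path)
  } else {
    header <- "individual\tlocus\tallele1\tallele2"
    grid <- expand.grid(i = seq_along(table$individuals),
                        j = seq_along(table$loci))
    grid <- grid[order(grid$i, grid$j), ]
    rows <- paste(table$individuals[grid$i], table$loci[grid$j],
                  fmt(a1[cbind(grid$i, grid$j, 1L)]),
                  fmt(a2[cbind(grid$i, grid$j, 1L)]), sep = "\t")
    writeLines(c(header, rows), path)
  }
  invisible(path)
}

#' Read a population map (individual TAB population)
#'
#' @param path file path to a two-column TSV with header.
#' @return named character vector, individual -> population.
#' @export
read_populations <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (ncol(df) != 2L) stop("population map must have exactly two columns")
  if (anyDuplicated(df[[1]]))
    stop("duplicate individual in population map: ",
         paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "))
  stats::setNames(df[[2]], df[[1]])
}

#' Write a population map
#' @param populations named character vector, individual -> population.
#' @param path output path.
#' @export
write_populations <- function(populations, path) {
  writeLines(c("individual\tpopulation",
               paste(names(populations), populations, sep = "\t")), path)
  invisible(path)
}

#' Read a per-population covariate table (population TAB value)
#'
#' Typical use: geographic distance of each sampled population from
#' sub-Saharan Africa, in km, as the predictor for diversity clines.
#'
#' @param path file path to a two-column TSV with header.
#' @param populations optional character vector; if given, the covariate's
#'   populations must be a subset of it.
#' @return named numeric vector, population -> covariate value.
#' @export
read_covariate <- function(path, populations = NULL) {
  df <- utils::read.delim(path, header = TRUE,
                          colClasses = c("character", "numeric"))
  if (ncol(df) != 2L) stop("covariate table must have exactly two columns")
  if (anyDuplicated(df[[1]]))
    stop("duplicate population in covariate table: ",
         paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "))
  if (!is.null(populations)) {
    extra <- setdiff(df[[1]], populations)
    if (length(extra))
      stop("covariate populations not present in genotype data: ",
           paste(extra, collapse = ", "))
  }
  stats::setNames(df[[2]], df[[1]])
}

#' Write / read a labelled square matrix as CSV
#'
#' Used for heterozygosity and F\[ST\] matrices. The first column holds row
#' labels; values are written with full double precision so a written
#' matrix re-reads exactly.
#'
#' @param m square numeric matrix with identical row and column names.
#' @param path file path.
#' @export
write_matrix <- function(m, path) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m),
            identical(rownames(m), colnames(m)))
  header <- paste(c("", colnames(m)), collapse = ",")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], formatC(m[i, ], format = "g", digits = 17)),
          collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.csv(path, header = TRUE, row.names = 1,
                        check.names = FALSE)
  as.matrix(df)
}

#' Write a structured JSON report
#'
#' @param x a list (typically a QC or fitting report).
#' @param path output path.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

# Alleles of one locus as a vector (2 per individual), restricted to a set
# of individuals; NAs dropped.
.locus_alleles <- function(lengths3, locus, individuals = NULL) {
  m <- lengths3[, locus, , drop = FALSE]
  if (!is.null(individuals)) m <- m[individuals, , , drop = FALSE]
  v <- as.vector(m)
  v[!is.na(v)]
}
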