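#' SNP genotype container
#'
#' Holds an individuals x loci matrix of alternate-allele dosages (0, 1, 2 or
#' `NA` for missing), with optional per-genotype allele read depths and an
#' optional tri-allelic annotation channel (reads supporting a third allele,
#' used by the filtering rules).
#'
#' Dosage counts copies of the alternate allele; `NA` is the only missing
#' sentinel (a dosage of 0 is a valid homozygote). All estimators downstream
#' are invariant to flipping ref/alt orientation at any locus.
#'
#' @param dosage integer matrix (individuals x loci), entries in {0,1,2,NA}.
#'   Row names are individual IDs, column names locus IDs; both required and
#'   unique.
#' @param depths optional list with matrices `ref` and `alt` of non-negative
#'   read counts, same dimensions as `dosage`.
#' @param tri_allelic optional logical matrix flagging genotypes whose reads
#'   support a third allele.
#' @return an object of class `snp_genotypes`.
#' @export
snp_genotypes <- function(dosage, depths = NULL, tri_allelic = NULL) {
  assert_that(is.matrix(dosage), "dosage must be a matrix")
  assert_that(nrow(dosage) == 0 || !is.null(rownames(dosage)),
              "dosage needs individual row names")
  assert_that(ncol(dosage) == 0 || !is.null(colnames(dosage)),
              "dosage needs locus column names")
  assert_that(!anyDuplicated(rownames(dosage)), "duplicate individual IDs")
  dup <- colnames(dosage)[duplicated(colnames(dosage))]
  assert_that(length(dup) == 0, "duplicate locus ID(s): %s",
              paste(unique(dup), collapse = ", "))
  vals <- dosage[!is.na(dosage)]
  assert_that(all(vals %in% c(0, 1, 2)),
              "non-missing dosages must be 0, 1 or 2")
  storage.mode(dosage) <- "integer"
  if (!is.null(depths)) {
    assert_that(is.list(depths) && all(c("ref", "alt") %in% names(depths)),
                "depths must be a list with 'ref' and 'alt' matrices")
    for (m in c("ref", "alt")) {
      assert_that(all(dim(depths[[m]]) == dim(dosage)),
                  "depth matrix '%s' dimensions must match dosage", m)
      assert_that(all(depths[[m]] >= 0, na.rm = TRUE),
                  "negative read depth in '%s'", m)
      dimnames(depths[[m]]) <- dimnames(dosage)
      storage.mode(depths[[m]]) <- "integer"
    }
  }
  if (!is.null(tri_allelic)) {
    assert_that(all(dim(tri_allelic) == dim(dosage)),
                "tri_allelic dimensions must match dosage")
    dimnames(tri_allelic) <- dimnames(dosage)
    storage.mode(tri_allelic) <- "logical"
  }
  structure(list(dosage = dosage, depths = depths, tri_allelic = tri_allelic),
            class = "snp_genotypes")
}

#' @export
print.snp_genotypes <- function(x, ...) {
  cat(sprintf("snp_genotypes: %d individuals x %d loci, %.1f%% missing%s\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage)),
              if (is.null(x$depths)) "" else ", with read depths"))
  invisible(x)
}

#' @export
dim.snp_genotypes <- function(x) dim(x$dosage)

individual_ids <- function(g) rownames(g$dosage %||% g$a1)
locus_ids <- function(g) colnames(g$dosage %||% g$a1)

#' Subset a SNP genotype object
#'
#' @param g `snp_genotypes`
#' @param individuals,loci index vectors (logical, integer or names)
#' @return `snp_genotypes`
#' @export
subset_snps <- function(g, individuals = NULL, loci = NULL) {
  i <- individuals %||% seq_len(nrow(g$dosage))
  j <- loci %||% seq_len(ncol(g$dosage))
  pick <- function(m) if (is.null(m)) NULL else m[i, j, drop = FALSE]
  snp_genotypes(pick(g$dosage),
                depths = if (is.null(g$depths)) NULL else
                  list(ref = pick(g$depths$ref), alt = pick(g$depths$alt)),
                tri_allelic = pick(g$tri_allelic))
}

#' Microsatellite genotype container
#'
#' Unordered pairs of integer allele labels (allele sizes) per individual and
#' locus; storage is canonicalized so that `a1 <= a2`. A missing genotype is
#' `NA` in both allele matrices.
#'
#' @param a1,a2 integer matrices (individuals x loci) of allele labels
#'   (positive integers), `NA` for missing. Dimnames as in [snp_genotypes()].
#' @return an object of class `microsat_genotypes`.
#' @export
microsat_genotypes <- function(a1, a2) {
  assert_that(is.matrix(a1) && is.matrix(a2) && all(dim(a1) == dim(a2)),
              "a1 and a2 must be matrices of identical dimensions")
  assert_that(!is.null(rownames(a1)) && !is.null(colnames(a1)),
              "allele matrices need individual row names and locus column names")
  assert_that(!anyDuplicated(rownames(a1)), "duplicate individual IDs")
  assert_that(!anyDuplicated(colnames(a1)), "duplicate locus IDs")
  assert_that(all(xor(is.na(a1), is.na(a2)) == FALSE),
              "half-missing genotype: one allele NA, the other not")
  assert_that(all(a1 > 0, na.rm = TRUE) && all(a2 > 0, na.rm = TRUE),
              "allele labels must be positive integers")
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  dimnames(lo) <- dimnames(hi) <- dimnames(a1)
  storage.mode(lo) <- storage.mode(hi) <- "integer"
  structure(list(a1 = lo, a2 = hi), class = "microsat_genotypes")
}

#' @export
print.microsat_genotypes <- function(x, ...) {
  nall <- vapply(seq_len(ncol(x$a1)), function(j) {
    length(unique(stats::na.omit(c(x$a1[, j], x$a2[, j]))))
  }, integer(1))
  cat(sprintf(
    "microsat_genotypes: %d individuals x %d loci, %d-%d alleles/locus, %.1f%% missing\n",
    nrow(x$a1), ncol(x$a1), min(nall), max(nall), 100 * mean(is.na(x$a1))))
  invisible(x)
}

#' @export
dim.microsat_genotypes <- function(x) dim(x$a1)

is_snp <- function(g) inherits(g, "snp_genotypes")

#' Sample metadata table
#'
#' One row per individual: population, country, sex, and the population's
#' longitude/latitude in decimal degrees (coordinates are sampled per
#' population and broadcast to its individuals).
#'
#' @param df data frame with columns `individual`, `population`, `country`,
#'   and `X` (longitude), `Y` (latitude); optional `sex` in {"M","F",
#'   "unknown"} (absent column means all unknown).
#' @return a validated `sample_metadata` data frame.
#' @export
sample_metadata <- function(df) {
  need <- c("individual", "population", "country", "X", "Y")
  miss <- setdiff(need, names(df))
  assert_that(length(miss) == 0, "metadata missing column(s): %s",
              paste(miss, collapse = ", "))
  if (!"sex" %in% names(df)) df$sex <- "unknown"
  df$sex[is.na(df$sex) | !(df$sex %in% c("M", "F"))] <- "unknown"
  df$individual <- as.character(df$individual)
  df$population <- as.character(df$population)
  df$country <- as.character(df$country)
  assert_that(!anyDuplicated(df$individual), "duplicate individuals in metadata")
  assert_that(all(abs(df$Y) <= 90), "latitude outside [-90, 90]")
  # each population maps to exactly one country and one coordinate pair
  per_pop <- unique(df[, c("population", "country", "X", "Y")])
  dup <- per_pop$population[duplicated(per_pop$population)]
  assert_that(length(dup) == 0,
              "population(s) with conflicting country/coordinates: %s",
              paste(unique(dup), collapse = ", "))
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Check that every genotyped individual has metadata
#'
#' @param g genotype object
#' @param meta `sample_metadata`
#' @return `meta` reordered to the genotype individuals, invisibly usable
#'   downstream.
#' @export
align_metadata <- function(g, meta) {
  ids <- individual_ids(g)
  missing_ids <- setdiff(ids, meta$individual)
  assert_that(length(missing_ids) == 0,
              "individual(s) without metadata: %s",
              paste(missing_ids, collapse = ", "))
  out <- meta[match(ids, meta$individual), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consistency check between dosages and read depths
#'
#' A non-missing heterozygote backed by depths must have reads for both
#' alleles.
#'
#' @param g `snp_genotypes` with depths
#' @return data frame of offending (individual, locus) cells (0 rows if clean)
#' @export
check_dosage_depth_consistency <- function(g) {
  assert_that(is_snp(g) && !is.null(g$depths), "needs snp_genotypes with depths")
  bad <- which(!is.na(g$dosage) & g$dosage == 1L &
                 (g$depths$ref == 0L | g$depths$alt == 0L), arr.ind = TRUE)
  data.frame(individual = rownames(g$dosage)[bad[, 1]],
             locus = colnames(g$dosage)[bad[, 2]])
}
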