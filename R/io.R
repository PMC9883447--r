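# Readers and writers for the dialects the workflow touches: tab-delimited
# dosage matrices, minimal VCF (GT + AD), microsatellite "a/b" tables and CSV
# metadata. One reserved missing sentinel per format: "NA" in TSV, "./." in
# VCF GT, 0 or blank in microsatellite cells.

#' Read a SNP genotype matrix
#'
#' @param path file path.
#' @param format `"tsv"` (individuals x loci dosage matrix, first column
#'   individual IDs, header of locus IDs, `NA` = missing) or `"vcf"`
#'   (biallelic records; GT consumed, AD consumed when present; phased
#'   separators treated as unphased).
#' @return [snp_genotypes()]
#' @export
read_snp_table <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  assert_that(file.exists(path), "file not found: %s", path)
  if (format == "tsv") read_snp_tsv(path) else read_snp_vcf(path)
}

read_snp_tsv <- function(path) {
  lines <- readLines(path)
  assert_that(length(lines) >= 2, "SNP table %s has no data rows", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  loci <- header[-1]
  dup <- unique(loci[duplicated(loci)])
  assert_that(length(dup) == 0, "duplicate locus ID: %s",
              paste(dup, collapse = ", "))
  n_loci <- length(loci)
  rows <- lapply(seq_along(lines)[-1], function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != n_loci + 1) {
      stopf("malformed row at line %d of %s: %d fields, expected %d",
            i, path, length(f), n_loci + 1)
    }
    v <- suppressWarnings(as.integer(f[-1]))
    bad <- which(!(f[-1] %in% c("NA", "")) & is.na(v))
    if (length(bad)) {
      stopf("malformed row at line %d of %s: non-integer dosage '%s'",
            i, path, f[-1][bad[1]])
    }
    list(id = f[1], v = v)
  })
  dosage <- do.call(rbind, lapply(rows, `[[`, "v"))
  rownames(dosage) <- vapply(rows, `[[`, "", "id")
  colnames(dosage) <- loci
  depths <- NULL
  sidecar <- paste0(path, ".depths")
  if (file.exists(sidecar)) {
    dd <- utils::read.table(sidecar, sep = "\t", header = TRUE,
                            check.names = FALSE, colClasses = "character")
    cells <- as.matrix(dd[, -1])
    rownames(cells) <- dd[[1]]
    cells <- cells[rownames(dosage), colnames(dosage), drop = FALSE]
    ref <- matrix(as.integer(sub(",.*", "", cells)), nrow(dosage),
                  dimnames = dimnames(dosage))
    alt <- matrix(as.integer(sub(".*,", "", cells)), nrow(dosage),
                  dimnames = dimnames(dosage))
    depths <- list(ref = ref, alt = alt)
  }
  snp_genotypes(dosage, depths = depths)
}

read_snp_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  assert_that(!any(multi), "multiallelic VCF record(s): %s",
              paste(ids[multi], collapse = ", "))
  dup <- unique(ids[duplicated(ids)])
  assert_that(length(dup) == 0, "duplicate locus ID: %s",
              paste(dup, collapse = ", "))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  dosage <- matrix(NA_integer_, nrow = ncol(gt_clean), ncol = nrow(gt_clean),
                   dimnames = list(colnames(gt_clean), ids))
  lookup <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  known <- gt_clean %in% c(names(lookup), "./.", ".", NA)
  if (!all(known, na.rm = TRUE)) {
    bad <- gt_clean[!known][1]
    stopf("unsupported genotype '%s' in %s (biallelic GT expected)", bad, path)
  }
  dosage[] <- t(matrix(lookup[gt_clean], nrow = nrow(gt_clean)))
  depths <- NULL
  if ("AD" %in% vcfR::vcf_field_names(vcf, tag = "FORMAT")$ID) {
    ad <- vcfR::extract.gt(vcf, element = "AD")
    ref <- t(matrix(suppressWarnings(as.integer(sub(",.*", "", ad))),
                    nrow = nrow(ad)))
    alt <- t(matrix(suppressWarnings(as.integer(sub(".*,", "", ad))),
                    nrow = nrow(ad)))
    ref[is.na(ref)] <- 0L
    alt[is.na(alt)] <- 0L
    dimnames(ref) <- dimnames(alt) <- dimnames(dosage)
    depths <- list(ref = ref, alt = alt)
  }
  snp_genotypes(dosage, depths = depths)
}

#' Write a SNP dosage matrix as TSV
#'
#' @param g [snp_genotypes()]
#' @param path output path; depths, when present, go to `paste0(path,
#'   ".depths")` as `ref,alt` cells.
#' @export
write_snp_table <- function(g, path) {
  df <- data.frame(individual = rownames(g$dosage), g$dosage,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(g$depths)) {
    cells <- matrix(paste0(g$depths$ref, ",", g$depths$alt),
                    nrow = nrow(g$dosage), dimnames = dimnames(g$dosage))
    dd <- data.frame(individual = rownames(g$dosage), cells,
                     check.names = FALSE)
    utils::write.table(dd, paste0(path, ".depths"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write SNP genotypes as a minimal VCF (GT, and AD when depths present)
#'
#' @param g [snp_genotypes()]
#' @param path output path
#' @export
write_snp_vcf <- function(g, path) {
  n_loci <- ncol(g$dosage)
  has_ad <- !is.null(g$depths)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_ad)
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(g$dosage)), collapse = "\t"))
  gt_map <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(n_loci), function(j) {
    d <- g$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_map[d + 1L])
    cells <- if (has_ad) {
      paste0(gt, ":", g$depths$ref[, j], ",", g$depths$alt[, j])
    } else gt
    paste(c("1", j, colnames(g$dosage)[j], "A", "G", ".", ".", ".",
            if (has_ad) "GT:AD" else "GT", cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a microsatellite genotype table
#'
#' One row per individual. Either one column per locus with `"a/b"` cells, or
#' two integer columns per locus (`locus.1`, `locus.2`). `0`, `"0/0"` or blank
#' mean missing.
#'
#' @param path file path (tab-delimited, header, first column individual IDs)
#' @return [microsat_genotypes()]
#' @export
read_microsat_table <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  raw <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           colClasses = "character")
  ids <- raw[[1]]
  body <- raw[, -1, drop = FALSE]
  slash <- any(grepl("/", unlist(body[1, ]), fixed = TRUE))
  if (slash) {
    loci <- colnames(body)
    parse_cell <- function(x) {
      x[x == "" | is.na(x)] <- "0/0"
      parts <- strsplit(x, "/", fixed = TRUE)
      bad <- which(lengths(parts) != 2)
      if (length(bad)) stopf("malformed microsat cell '%s'", x[bad[1]])
      m <- matrix(suppressWarnings(as.integer(unlist(parts))), ncol = 2,
                  byrow = TRUE)
      if (anyNA(m)) {
        stopf("non-integer allele label '%s'",
              x[which(is.na(m[, 1]) | is.na(m[, 2]))[1]])
      }
      m
    }
    a1 <- a2 <- matrix(NA_integer_, nrow(body), length(loci),
                       dimnames = list(ids, loci))
    for (j in seq_along(loci)) {
      m <- parse_cell(body[[j]])
      a1[, j] <- m[, 1]
      a2[, j] <- m[, 2]
    }
  } else {
    assert_that(ncol(body) %% 2 == 0,
                "odd number of allele columns (%d); expected two per locus",
                ncol(body))
    loci <- unique(sub("\\.[12]$", "", colnames(body)))
    assert_that(length(loci) == ncol(body) / 2,
                "allele columns do not pair up into loci")
    to_int <- function(v) {
      out <- suppressWarnings(as.integer(v))
      bad <- which(!(v %in% c("", "0", "NA")) & is.na(out))
      if (length(bad)) stopf("non-integer allele label '%s'", v[bad[1]])
      out[is.na(out)] <- 0L
      out
    }
    a1 <- matrix(0L, nrow(body), length(loci), dimnames = list(ids, loci))
    a2 <- a1
    for (j in seq_along(loci)) {
      a1[, j] <- to_int(body[[2 * j - 1]])
      a2[, j] <- to_int(body[[2 * j]])
    }
  }
  # 0 on either side = missing genotype
  miss <- (a1 == 0L) | (a2 == 0L) | is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_
  a2[miss] <- NA_integer_
  microsat_genotypes(a1, a2)
}

#' Write a microsatellite table ("a/b" cells, 0/0 = missing)
#'
#' @param g [microsat_genotypes()]
#' @param path output path
#' @export
write_microsat_table <- function(g, path) {
  cells <- matrix(paste0(ifelse(is.na(g$a1), 0L, g$a1), "/",
                         ifelse(is.na(g$a2), 0L, g$a2)),
                  nrow = nrow(g$a1), dimnames = dimnames(g$a1))
  df <- data.frame(individual = rownames(g$a1), cells, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' CSV with columns `individual`, `population`, `country`, `X`, `Y` and
#' optional `sex`. The packaged fixture
#' `system.file("extdata", "population_design.csv", package = "popresolve")`
#' carries the study design used throughout: 19 populations in 7 countries
#' with their sampling coordinates and sizes (see [population_design()]).
#'
#' @param path CSV path
#' @return [sample_metadata()]
#' @export
read_metadata <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  sample_metadata(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write sample metadata as CSV
#' @param meta `sample_metadata`
#' @param path output path
#' @export
write_metadata <- function(meta, path) {
  utils::write.csv(as.data.frame(meta), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The study's population design (19 populations, 7 countries)
#'
#' Longitude/latitude, sample size and country for each of the 19 sampled
#' colonies; used as the default template of the synthetic generator.
#'
#' @return data frame with columns `population`, `country`, `X`, `Y`, `n`
#' @export
population_design <- function() {
  path <- system.file("extdata", "population_design.csv",
                      package = "popresolve", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(population = "character"))
}
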