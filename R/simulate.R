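# Hierarchical Balding-Nichols generator. Allele frequencies drift from an
# ancestral value first into countries (parameter F_CT) and then into
# populations within countries (F_SC): for a biallelic locus with ancestral
# frequency p and differentiation F, the daughter frequency is
# Beta(p(1-F)/F, (1-p)(1-F)/F); multiallelic loci use the Dirichlet analogue
# with concentration (1-F)/F. Genotypes are binomial(2, p_pop). No explicit
# coalescent is simulated: the downstream analyses consume frequencies, not
# genealogies, and the Beta construction hits the target F values exactly in
# expectation. A one-dimensional stepping-stone variant exists solely to
# exercise the isolation-by-distance test.

#' Simulation configuration
#'
#' @param design data frame with columns `population`, `country`, `n`
#'   (individuals per population) and optionally `X`, `Y` coordinates; the
#'   packaged [population_design()] (19 populations in 7 countries, sizes
#'   5-15) is the `paper_like` default
#' @param n_snps number of biallelic loci (default 4994)
#' @param n_microsats number of multiallelic loci (default 11)
#' @param msat_allele_range allele count range per microsatellite locus
#'   (default 3-18)
#' @param f_ct between-country differentiation (default 0.058)
#' @param f_sc between-population-within-country differentiation (default
#'   0.019)
#' @param ancestral_freq_range SNP ancestral frequencies drawn uniformly
#'   from this interval (default c(0.05, 0.95))
#' @param missing_rate per-population probability that a SNP genotype is
#'   missing; scalar or named vector by population (default 0)
#' @param depth_mean,depth_dispersion negative-binomial read-depth model;
#'   `depth_mean` scalar or named per-population vector (defaults 25 and 4)
#' @param error_rate per-read sequencing error rate (default 0.005)
#' @param triallelic_rate fraction of genotypes flagged as carrying reads
#'   from a third allele (default 0)
#' @param sex_ratio probability an individual is male (default 0.5)
#' @return `sim_config` list
#' @export
sim_config <- function(design = NULL, n_snps = 4994, n_microsats = 11,
                       msat_allele_range = c(3, 18), f_ct = 0.058,
                       f_sc = 0.019, ancestral_freq_range = c(0.05, 0.95),
                       missing_rate = 0, depth_mean = 25,
                       depth_dispersion = 4, error_rate = 0.005,
                       triallelic_rate = 0, sex_ratio = 0.5) {
  if (is.null(design)) design <- population_design()
  assert_that(all(c("population", "country", "n") %in% names(design)),
              "design needs population, country, n columns")
  assert_that(all(design$n >= 1), "population sizes must be >= 1")
  assert_that(f_ct >= 0 && f_ct < 1 && f_sc >= 0 && f_sc < 1,
              "F values must be in [0, 1)")
  assert_that(all(missing_rate >= 0 & missing_rate <= 1),
              "missing_rate must be in [0, 1]")
  structure(list(design = design, n_snps = n_snps, n_microsats = n_microsats,
                 msat_allele_range = msat_allele_range, f_ct = f_ct,
                 f_sc = f_sc, ancestral_freq_range = ancestral_freq_range,
                 missing_rate = missing_rate, depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion, error_rate = error_rate,
                 triallelic_rate = triallelic_rate, sex_ratio = sex_ratio),
            class = "sim_config")
}

#' The `paper_like` preset
#'
#' 19 populations nested in 7 countries with the study's sample sizes and
#' coordinates, 4994 SNPs, 11 microsatellites with 3-18 alleles,
#' F_CT = 0.058 and F_SC = 0.019, and missingness/read-depth concentrated in
#' the small high-missingness population ("9"): genotype dropout ~0.45 there
#' against 0.04 elsewhere, with a correspondingly low read-depth mean so the
#' depth-driven filtering rules reproduce the heterozygote-depletion
#' mechanism.
#'
#' @param with_missingness apply the concentrated missingness/depth pattern
#'   (default TRUE); FALSE gives complete matrices for parameter-recovery
#'   work
#' @return `sim_config`
#' @export
paper_like_config <- function(with_missingness = TRUE) {
  design <- population_design()
  if (with_missingness) {
    miss <- stats::setNames(rep(0.04, nrow(design)), design$population)
    miss["9"] <- 0.45
    dm <- stats::setNames(rep(25, nrow(design)), design$population)
    dm["9"] <- 10
  } else {
    miss <- 0
    dm <- 25
  }
  sim_config(design = design, missing_rate = miss, depth_mean = dm)
}

bn_freq <- function(p, f) {
  if (f <= 0) return(p)
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

dirichlet_around <- function(p, f) {
  if (f <= 0) return(p)
  g <- stats::rgamma(length(p), shape = p * (1 - f) / f, rate = 1)
  if (sum(g) <= 0) g <- rep(1, length(p))
  g / sum(g)
}

#' Simulate a matched SNP + microsatellite dataset
#'
#' @param config [sim_config()]
#' @param seed RNG seed (same seed, same dataset bit-for-bit)
#' @return list of class `sim_dataset`: `snp` ([snp_genotypes()]),
#'   `microsat` ([microsat_genotypes()]), `meta` ([sample_metadata()]),
#'   `truth` (latent country/population frequencies, config, seed, migrant
#'   record)
#' @export
simulate_dataset <- function(config = sim_config(), seed = NULL) {
  with_seed(seed, {
    des <- config$design
    pops <- as.character(des$population)
    n_pop <- nrow(des)
    countries <- unique(des$country)
    n_ind <- sum(des$n)
    pop_of_ind <- rep(pops, des$n)
    ids <- sprintf("ind%03d", seq_len(n_ind))

    # SNP latent frequencies
    p_anc <- stats::runif(config$n_snps, config$ancestral_freq_range[1],
                          config$ancestral_freq_range[2])
    p_cty <- vapply(countries, function(ct) bn_freq(p_anc, config$f_ct),
                    numeric(config$n_snps))
    p_pop <- vapply(seq_len(n_pop), function(ip) {
      bn_freq(p_cty[, des$country[ip]], config$f_sc)
    }, numeric(config$n_snps))
    colnames(p_pop) <- pops

    dosage <- matrix(NA_integer_, n_ind, config$n_snps,
                     dimnames = list(ids, sprintf("snp%05d",
                                                  seq_len(config$n_snps))))
    for (ip in seq_len(n_pop)) {
      rows <- which(pop_of_ind == pops[ip])
      dosage[rows, ] <- matrix(
        stats::rbinom(length(rows) * config$n_snps, 2L,
                      rep(p_pop[, ip], each = length(rows))),
        length(rows), config$n_snps)
    }

    # per-population missingness
    mr <- config$missing_rate
    if (length(mr) == 1) mr <- stats::setNames(rep(mr, n_pop), pops)
    for (ip in seq_len(n_pop)) {
      r <- mr[pops[ip]]
      if (is.na(r) || r <= 0) next
      rows <- which(pop_of_ind == pops[ip])
      drop <- matrix(stats::runif(length(rows) * config$n_snps) < r,
                     length(rows), config$n_snps)
      dosage[rows, ][drop] <- NA_integer_
    }

    # microsatellites: hierarchical Dirichlet
    msat_truth <- vector("list", config$n_microsats)
    a1 <- a2 <- matrix(NA_integer_, n_ind, config$n_microsats,
                       dimnames = list(ids, sprintf("msat%02d",
                                                    seq_len(config$n_microsats))))
    for (j in seq_len(config$n_microsats)) {
      k <- sample(seq(config$msat_allele_range[1],
                      config$msat_allele_range[2]), 1)
      labels <- 100L + 2L * seq_len(k)
      f_anc <- dirichlet_around(rep(1 / k, k), 1 / (1 + k))  # broad ancestral
      f_cty <- lapply(countries, function(ct)
        dirichlet_around(f_anc, config$f_ct))
      names(f_cty) <- countries
      f_pop <- lapply(seq_len(n_pop), function(ip)
        dirichlet_around(f_cty[[des$country[ip]]], config$f_sc))
      for (ip in seq_len(n_pop)) {
        rows <- which(pop_of_ind == pops[ip])
        draws <- matrix(sample(labels, 2 * length(rows), replace = TRUE,
                               prob = f_pop[[ip]]), ncol = 2)
        a1[rows, j] <- pmin(draws[, 1], draws[, 2])
        a2[rows, j] <- pmax(draws[, 1], draws[, 2])
      }
      msat_truth[[j]] <- list(labels = labels, f_anc = f_anc, f_cty = f_cty,
                              f_pop = f_pop)
    }

    meta <- sample_metadata(data.frame(
      individual = ids,
      population = pop_of_ind,
      country = des$country[match(pop_of_ind, pops)],
      sex = ifelse(stats::runif(n_ind) < config$sex_ratio, "M", "F"),
      X = (des$X %||% seq_len(n_pop))[match(pop_of_ind, pops)],
      Y = (des$Y %||% rep(0, n_pop))[match(pop_of_ind, pops)]))

    structure(list(
      snp = snp_genotypes(dosage),
      microsat = microsat_genotypes(a1, a2),
      meta = meta,
      truth = list(config = config, seed = seed, p_anc = p_anc,
                   p_cty = p_cty, p_pop = p_pop, msat = msat_truth,
                   migrants = character(0))),
      class = "sim_dataset")
  })
}

#' Attach simulated read depths to SNP genotypes
#'
#' Total depth per genotype is negative-binomial; heterozygotes split reads
#' binomially at 1/2; homozygotes receive wrong-allele reads at the
#' sequencing error rate; a configurable fraction of genotypes is flagged
#' tri-allelic.
#'
#' @param g [snp_genotypes()]
#' @param config [sim_config()] (uses `depth_mean`, `depth_dispersion`,
#'   `error_rate`, `triallelic_rate`)
#' @param meta optional [sample_metadata()]; required when `depth_mean` is
#'   per-population
#' @param seed RNG seed
#' @return [snp_genotypes()] with `depths` (and `tri_allelic` if requested)
#' @export
simulate_read_depths <- function(g, config, meta = NULL, seed = NULL) {
  with_seed(seed, {
    n <- nrow(g$dosage); L <- ncol(g$dosage)
    dm <- config$depth_mean
    if (length(dm) > 1) {
      assert_that(!is.null(meta), "per-population depth_mean needs meta")
      meta <- align_metadata(g, meta)
      mu_ind <- unname(dm[meta$population])
    } else {
      mu_ind <- rep(dm, n)
    }
    tot <- matrix(stats::rnbinom(n * L, mu = rep(mu_ind, L),
                                 size = config$depth_dispersion), n, L)
    alt <- matrix(0L, n, L)
    d <- g$dosage
    hom_ref <- !is.na(d) & d == 0L
    het <- !is.na(d) & d == 1L
    hom_alt <- !is.na(d) & d == 2L
    alt[hom_ref] <- stats::rbinom(sum(hom_ref), tot[hom_ref],
                                  config$error_rate)
    alt[het] <- stats::rbinom(sum(het), tot[het], 0.5)
    alt[hom_alt] <- tot[hom_alt] -
      stats::rbinom(sum(hom_alt), tot[hom_alt], config$error_rate)
    ref <- tot - alt
    tri <- NULL
    if (config$triallelic_rate > 0) {
      tri <- matrix(stats::runif(n * L) < config$triallelic_rate, n, L)
    }
    snp_genotypes(g$dosage, depths = list(ref = ref, alt = alt),
                  tri_allelic = tri)
  })
}

#' Replace a fraction of a hub population by unadmixed migrants
#'
#' Redraws the genotypes of the chosen hub individuals from the source
#' population's latent frequencies — pure source ancestry, no admixture —
#' emulating colonies where seasonal migrators of distinct origin sit side
#' by side. Optionally skews the migrants' sex to implement sex-biased
#' dispersal.
#'
#' @param dataset `sim_dataset` from [simulate_dataset()]
#' @param hub_population,source_population population IDs (must differ)
#' @param fraction fraction of hub individuals replaced
#' @param sex_ratio probability a migrant is male (NA = leave sexes as
#'   drawn)
#' @param seed RNG seed
#' @return modified `sim_dataset`; migrant IDs recorded in
#'   `truth$migrants`
#' @export
inject_migrants <- function(dataset, hub_population, source_population,
                            fraction, sex_ratio = NA, seed = NULL) {
  assert_that(hub_population != source_population,
              "hub and source populations must differ")
  assert_that(fraction >= 0 && fraction <= 1, "fraction must be in [0, 1]")
  if (fraction == 0) return(dataset)
  with_seed(seed, {
    meta <- dataset$meta
    hub_ids <- meta$individual[meta$population == hub_population]
    assert_that(length(hub_ids) > 0, "hub population not found or empty")
    assert_that(source_population %in% colnames(dataset$truth$p_pop),
                "source population not in truth record")
    n_mig <- max(1L, round(fraction * length(hub_ids)))
    mig <- sample(hub_ids, n_mig)
    rows <- match(mig, rownames(dataset$snp$dosage))
    p_src <- dataset$truth$p_pop[, source_population]
    L <- length(p_src)
    new_dos <- matrix(stats::rbinom(n_mig * L, 2L, rep(p_src, each = n_mig)),
                      n_mig, L)
    keep_na <- is.na(dataset$snp$dosage[rows, , drop = FALSE])
    new_dos[keep_na] <- NA_integer_
    dataset$snp$dosage[rows, ] <- new_dos
    # microsatellites follow the same ancestry switch
    ip_src <- which(colnames(dataset$truth$p_pop) == source_population)
    for (j in seq_along(dataset$truth$msat)) {
      tr <- dataset$truth$msat[[j]]
      draws <- matrix(sample(tr$labels, 2 * n_mig, replace = TRUE,
                             prob = tr$f_pop[[ip_src]]), ncol = 2)
      dataset$microsat$a1[rows, j] <- pmin(draws[, 1], draws[, 2])
      dataset$microsat$a2[rows, j] <- pmax(draws[, 1], draws[, 2])
    }
    if (!is.na(sex_ratio)) {
      idx <- match(mig, dataset$meta$individual)
      dataset$meta$sex[idx] <- ifelse(stats::runif(n_mig) < sex_ratio,
                                      "M", "F")
    }
    dataset$truth$migrants <- union(dataset$truth$migrants, mig)
    dataset$truth$migrant_source <- source_population
    dataset
  })
}

#' One-dimensional stepping-stone dataset (isolation-by-distance testbed)
#'
#' Demes sit on a line; allele frequencies perform a Balding-Nichols drift
#' chain along it (`f_step` per step), so differentiation accumulates with
#' distance. `f_step = 0` collapses to an island model with no geographic
#' signal. Deme coordinates are spaced `spacing_km` apart along a parallel.
#'
#' @param n_demes number of demes (default 8)
#' @param n_per_deme individuals per deme (default 10)
#' @param n_loci SNP count (default 500)
#' @param f_step differentiation accumulated between neighbours (default
#'   0.02)
#' @param spacing_km distance between neighbouring demes (default 100)
#' @param seed RNG seed
#' @return `sim_dataset` (SNPs only; `microsat` = NULL)
#' @export
simulate_stepping_stone <- function(n_demes = 8, n_per_deme = 10,
                                    n_loci = 500, f_step = 0.02,
                                    spacing_km = 100, seed = NULL) {
  with_seed(seed, {
    p <- matrix(0, n_loci, n_demes)
    p[, 1] <- stats::runif(n_loci, 0.1, 0.9)
    for (d in seq_len(n_demes - 1)) {
      p[, d + 1] <- bn_freq(p[, d], f_step)
    }
    pops <- sprintf("deme%02d", seq_len(n_demes))
    ids <- sprintf("ind%03d", seq_len(n_demes * n_per_deme))
    pop_of_ind <- rep(pops, each = n_per_deme)
    dosage <- matrix(NA_integer_, length(ids), n_loci,
                     dimnames = list(ids, sprintf("snp%04d", seq_len(n_loci))))
    for (d in seq_len(n_demes)) {
      rows <- which(pop_of_ind == pops[d])
      dosage[rows, ] <- matrix(
        stats::rbinom(length(rows) * n_loci, 2L,
                      rep(p[, d], each = length(rows))),
        length(rows), n_loci)
    }
    # ~111 km per degree of longitude at the equator
    lon <- (seq_len(n_demes) - 1) * spacing_km / 111.195
    meta <- sample_metadata(data.frame(
      individual = ids, population = pop_of_ind, country = pop_of_ind,
      sex = "unknown", X = lon[match(pop_of_ind, pops)], Y = 0))
    structure(list(snp = snp_genotypes(dosage), microsat = NULL, meta = meta,
                   truth = list(p_deme = p, f_step = f_step,
                                migrants = character(0))),
              class = "sim_dataset")
  })
}

#' Simulate sex-biased dispersal
#'
#' Each individual of the dispersing sex is, with the stated probability, an
#' unadmixed immigrant from a uniformly chosen other population.
#'
#' @param dataset `sim_dataset`
#' @param male_rate,female_rate per-sex migration probabilities
#' @param seed RNG seed
#' @return modified `sim_dataset` with `truth$migrants` updated
#' @export
apply_sex_biased_dispersal <- function(dataset, male_rate = 0.3,
                                       female_rate = 0, seed = NULL) {
  with_seed(seed, {
    meta <- dataset$meta
    pops <- colnames(dataset$truth$p_pop)
    rate <- ifelse(meta$sex == "M", male_rate,
                   ifelse(meta$sex == "F", female_rate, 0))
    mig <- which(stats::runif(nrow(meta)) < rate)
    for (i in mig) {
      src <- sample(setdiff(pops, meta$population[i]), 1)
      p_src <- dataset$truth$p_pop[, src]
      row <- match(meta$individual[i], rownames(dataset$snp$dosage))
      keep_na <- is.na(dataset$snp$dosage[row, ])
      new_dos <- stats::rbinom(length(p_src), 2L, p_src)
      new_dos[keep_na] <- NA_integer_
      dataset$snp$dosage[row, ] <- new_dos
    }
    dataset$truth$migrants <- union(dataset$truth$migrants,
                                    meta$individual[mig])
    dataset
  })
}
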