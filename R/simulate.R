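#' SNP-chip-like genome skeleton for simulation
#'
#' Evenly spaced SNPs (optional positional jitter) on equally sized
#' chromosomes, emulating a medium-density genotyping array. Defaults mirror
#' a porcine 50K-class chip: 18 autosomes, ~66 kb mean spacing.
#'
#' @param n_chromosomes number of autosomes.
#' @param chrom_length_mb chromosome length in Mb.
#' @param n_snps_per_chrom SNPs per chromosome.
#' @param cm_per_mb uniform recombination rate, cM/Mb.
#' @param jitter_frac uniform positional jitter as a fraction of the spacing.
#' @return a \code{sim_genome} list: map skeleton plus per-SNP positions in
#'   Morgans and chromosome index.
#' @export
sim_genome <- function(n_chromosomes = 18L, chrom_length_mb = 146,
                       n_snps_per_chrom = 2222L, cm_per_mb = 1,
                       jitter_frac = 0) {
  spacing <- chrom_length_mb * 1e6 / n_snps_per_chrom
  maps <- lapply(seq_len(n_chromosomes), function(ch) {
    pos <- spacing * (seq_len(n_snps_per_chrom) - 0.5)
    if (jitter_frac > 0)
      pos <- pos + stats::runif(n_snps_per_chrom, -jitter_frac, jitter_frac) *
        spacing
    pos <- as.integer(round(sort(pos)))
    pos <- pos + cumsum(c(0L, diff(pos) == 0L))      # enforce strict increase
    data.frame(chrom = as.character(ch),
               snp_id = sprintf("snp%d_%d", ch, seq_len(n_snps_per_chrom)),
               cm = pos / 1e6 * cm_per_mb, pos = pos,
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  structure(list(map = map,
                 morgans = map$cm / 100,
                 chrom_index = split(seq_len(nrow(map)), map$chrom),
                 chrom_length_morgans = chrom_length_mb * cm_per_mb / 100,
                 cm_per_mb = cm_per_mb),
            class = "sim_genome")
}

# one gamete per row of `parents`: recombine the two haplotypes of each
# parent with Poisson crossovers along each chromosome
make_gametes <- function(haps, parents, genome) {
  n_g <- length(parents)
  m <- ncol(haps)
  out <- matrix(0L, n_g, m)
  lm <- genome$chrom_length_morgans
  for (ci in genome$chrom_index) {
    gpos <- genome$map$cm[ci] / 100    # within-chromosome position, Morgans
    k <- stats::rpois(n_g, lm)
    start <- sample.int(2L, n_g, replace = TRUE) - 1L
    for (g in seq_len(n_g)) {
      h1 <- 2L * parents[g] - 1L
      if (k[g] == 0L) {
        out[g, ci] <- haps[h1 + start[g], ci]
      } else {
        xo <- sort(stats::runif(k[g], 0, lm))
        pat <- (start[g] + findInterval(gpos, xo)) %% 2L
        row1 <- haps[h1, ci]; row2 <- haps[h1 + 1L, ci]
        out[g, ci] <- ifelse(pat == 0L, row1, row2)
      }
    }
  }
  out
}

# one Wright-Fisher generation: N offspring, two parents each drawn uniformly
# with replacement (monoecious random mating); returns the 2N x m haplotype
# matrix of the offspring and the parent pairs used
wf_generation <- function(haps, n_offspring, genome, parent_pool_n = NULL) {
  np <- if (is.null(parent_pool_n)) nrow(haps) %/% 2L else parent_pool_n
  mothers <- sample.int(np, n_offspring, replace = TRUE)
  fathers <- sample.int(np, n_offspring, replace = TRUE)
  g1 <- make_gametes(haps, mothers, genome)
  g2 <- make_gametes(haps, fathers, genome)
  h <- matrix(0L, 2L * n_offspring, ncol(haps))
  h[seq(1L, 2L * n_offspring, 2L), ] <- g1
  h[seq(2L, 2L * n_offspring, 2L), ] <- g2
  list(haps = h, parents = cbind(mothers, fathers))
}

#' Multi-breed simulation configuration
#'
#' The stated world the simulator emulates by default: 12 labelled breeds of
#' effective size 100 diverging independently for 50 generations from one
#' ancestral gene pool, ~30 genotyped individuals each, a 40k-SNP chip on 18
#' autosomes with ~66 kb spacing, founder MAF uniform on [0.05, 0.5],
#' uniform 1 cM/Mb recombination, and 1\% randomly missing calls.
#'
#' @param genome a \code{\link{sim_genome}}.
#' @param breeds data.frame with columns \code{breed}, \code{N} (diploid
#'   size) and \code{generations} since the split.
#' @param founder_maf_range range of the founder minor-allele frequency
#'   (uniform law).
#' @param ancestral_n,ancestral_generations size and duration of an optional
#'   ancestral burn-in before the splits (0 = founders in linkage
#'   equilibrium at the split, drift-only LD accumulates within breeds).
#' @param samples_per_breed genotyped individuals per breed (must not exceed
#'   any breed's N).
#' @param admixture optional data.frame (source, target, proportion,
#'   generation): at that generation the target breed draws each parent from
#'   the source breed with the given probability.
#' @param missing_rate post-hoc missing-call rate.
#' @param seed RNG seed (reproducible runs).
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(genome = sim_genome(),
                       breeds = data.frame(
                         breed = sprintf("Breed%02d", 1:12),
                         N = 100L, generations = 50L),
                       founder_maf_range = c(0.05, 0.5),
                       ancestral_n = 500L, ancestral_generations = 0L,
                       samples_per_breed = 30L,
                       admixture = NULL, missing_rate = 0.01, seed = NULL) {
  stopifnot(all(breeds$N > 0), all(breeds$generations >= 0),
            samples_per_breed > 0, missing_rate >= 0, missing_rate < 1)
  if (any(samples_per_breed > 2L * breeds$N))
    stop("samples_per_breed exceeds 2N for some breed")
  if (any(samples_per_breed > breeds$N))
    stop("samples_per_breed exceeds breed size N; cannot sample that many individuals")
  if (!is.null(admixture))
    stopifnot(all(admixture$proportion > 0), all(admixture$proportion < 1),
              all(admixture$source %in% breeds$breed),
              all(admixture$target %in% breeds$breed))
  structure(list(genome = genome, breeds = breeds,
                 founder_maf_range = founder_maf_range,
                 ancestral_n = as.integer(ancestral_n),
                 ancestral_generations = as.integer(ancestral_generations),
                 samples_per_breed = as.integer(samples_per_breed),
                 admixture = admixture, missing_rate = missing_rate,
                 seed = seed),
            class = "sim_config")
}

#' Forward-time Wright-Fisher simulation of diverging breeds
#'
#' Founder haplotypes are drawn in linkage equilibrium from the founder MAF
#' law; an optional ancestral burn-in accumulates background LD; each breed
#' then evolves independently by diploid WF random mating with Poisson
#' recombination, optionally receiving admixture pulses. The final
#' generation is genotyped to a \code{genotype_dataset} (dosage oriented to
#' the realized minor allele, as \code{read_plink} would) together with the
#' simulation truth.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list: \code{dataset} (a \code{genotype_dataset}) and \code{truth}
#'   (founder allele_b frequencies in the dataset's orientation, each
#'   breed's expected F_ST to the ancestor \code{1 - (1 - 1/(2N))^t}, true
#'   Ne per breed, per-breed parent pedigrees, the config).
#' @export
simulate_breeds <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  genome <- config$genome
  m <- nrow(genome$map)
  f0 <- stats::runif(m, config$founder_maf_range[1], config$founder_maf_range[2])
  flip0 <- stats::runif(m) < 0.5        # which side of 0.5 the '1' allele is
  f0 <- ifelse(flip0, 1 - f0, f0)
  anc <- matrix(stats::rbinom(2L * config$ancestral_n * m, 1L,
                              rep(f0, each = 2L * config$ancestral_n)),
                2L * config$ancestral_n, m)
  if (config$ancestral_generations > 0L)
    for (g in seq_len(config$ancestral_generations))
      anc <- wf_generation(anc, config$ancestral_n, genome)$haps

  nb <- nrow(config$breeds)
  pools <- vector("list", nb)
  pedigrees <- vector("list", nb)
  names(pools) <- names(pedigrees) <- config$breeds$breed
  # split: each breed's founding generation is a WF draw from the ancestor
  for (b in seq_len(nb))
    pools[[b]] <- wf_generation(anc, config$breeds$N[b], genome)$haps
  max_t <- max(config$breeds$generations)
  for (g in seq_len(max_t)) {
    prev <- pools                        # previous-generation pools
    for (b in seq_len(nb)) {
      if (g > config$breeds$generations[b]) next
      N <- config$breeds$N[b]
      adm <- NULL
      if (!is.null(config$admixture)) {
        adm <- config$admixture[config$admixture$target ==
                                  config$breeds$breed[b] &
                                config$admixture$generation == g, ]
        if (nrow(adm) == 0L) adm <- NULL
      }
      if (is.null(adm)) {
        step <- wf_generation(prev[[b]], N, genome)
        pools[[b]] <- step$haps
        pedigrees[[b]][[g]] <- step$parents
      } else {
        # each parent slot comes from the source pool with prob alpha
        src <- prev[[adm$source[1]]]
        alpha <- adm$proportion[1]
        pick <- function() {
          from_src <- stats::runif(N) < alpha
          idx <- ifelse(from_src, sample.int(nrow(src) %/% 2L, N, TRUE),
                        sample.int(N, N, TRUE))
          list(from_src = from_src, idx = idx)
        }
        mo <- pick(); fa <- pick()
        gam <- function(p) {
          g1 <- matrix(0L, N, m)
          if (any(p$from_src))
            g1[p$from_src, ] <- make_gametes(src, p$idx[p$from_src], genome)
          if (any(!p$from_src))
            g1[!p$from_src, ] <- make_gametes(prev[[b]], p$idx[!p$from_src],
                                              genome)
          g1
        }
        h <- matrix(0L, 2L * N, m)
        h[seq(1L, 2L * N, 2L), ] <- gam(mo)
        h[seq(2L, 2L * N, 2L), ] <- gam(fa)
        pools[[b]] <- h
        pedigrees[[b]][[g]] <- cbind(ifelse(mo$from_src, -mo$idx, mo$idx),
                                     ifelse(fa$from_src, -fa$idx, fa$idx))
      }
    }
  }

  # genotype the final generations
  calls <- list(); labels <- character(0)
  for (b in seq_len(nb)) {
    take <- sample.int(config$breeds$N[b], config$samples_per_breed)
    h <- pools[[b]]
    calls[[b]] <- h[2L * take - 1L, , drop = FALSE] +
      h[2L * take, , drop = FALSE]
    labels <- c(labels, rep(config$breeds$breed[b], config$samples_per_breed))
  }
  calls <- do.call(rbind, calls)
  if (config$missing_rate > 0) {
    drop <- stats::runif(length(calls)) < config$missing_rate
    calls[drop] <- NA_integer_
  }
  map <- genome$map
  pair <- t(replicate(m, sample(c("A", "C", "G", "T"), 2L)))
  map$allele_a <- pair[, 1]; map$allele_b <- pair[, 2]
  samples <- data.frame(
    sample_id = sprintf("%s_i%02d", labels,
                        stats::ave(seq_along(labels), labels, FUN = seq_along)),
    breed = labels, sex = NA_integer_, stringsAsFactors = FALSE)
  ds <- genotype_dataset(calls, samples, map, sort = TRUE)
  ds <- normalize_alleles(ds)
  flip <- attr(ds, "flipped")
  truth <- list(
    founder_freq_b = ifelse(flip, 1 - f0, f0),
    founder_freq_sim = f0,      # original '1'-allele orientation
    flipped = flip,             # TRUE where allele_b is the other side
    expected_fst = stats::setNames(
      1 - (1 - 1 / (2 * config$breeds$N))^config$breeds$generations,
      config$breeds$breed),
    true_ne = stats::setNames(config$breeds$N, config$breeds$breed),
    pedigrees = pedigrees,
    config = config)
  list(dataset = ds, truth = truth)
}

#' Pedigree inbreeding coefficient under repeated full-sib mating
#'
#' Recursion \code{F_t = 0.25 (1 + 2 F_(t-1) + F_(t-2))} with unrelated,
#' non-inbred founders; \code{t = 1} (offspring of one full-sib pair) gives
#' 0.25.
#'
#' @param t number of sib-mating generations (vectorized).
#' @return pedigree F for individuals born at generation t.
#' @export
sib_mating_f <- function(t) {
  tmax <- max(t)
  f <- numeric(tmax + 2L)                # f[1] = F_{-1}, f[2] = F_0
  for (k in seq_len(tmax)) f[k + 2L] <- 0.25 * (1 + 2 * f[k + 1L] + f[k])
  f[t + 2L]
}

#' Simulate a full-sib mating line
#'
#' An outbred founder pool provides one unrelated couple; their two children
#' start a closed full-sib line continued for \code{t_generations}. The
#' returned dataset holds \code{n_offspring} genotyped individuals from the
#' final generation, whose pedigree inbreeding is \code{sib_mating_f(t)}.
#' Long autozygous tracts in these genomes are the ground truth for ROH
#' detection.
#'
#' @param t_generations sib-mating generations (>= 1).
#' @param genome a \code{\link{sim_genome}}.
#' @param founder_maf_range uniform founder MAF law.
#' @param n_offspring genotyped individuals from the final generation.
#' @param line_label breed label for the output dataset.
#' @param seed RNG seed.
#' @return list: \code{dataset}, \code{truth} (pedigree_f, f_by_generation).
#' @export
simulate_inbred_line <- function(t_generations, genome = sim_genome(),
                                 founder_maf_range = c(0.05, 0.5),
                                 n_offspring = 2L, line_label = "line",
                                 seed = NULL) {
  stopifnot(t_generations >= 1L)
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(genome$map)
  f0 <- stats::runif(m, founder_maf_range[1], founder_maf_range[2])
  founders <- matrix(stats::rbinom(4L * m, 1L, rep(f0, each = 4L)), 4L, m)
  # generation 0: two full sibs (children of the founder couple)
  pair <- wf_pair_offspring(founders, 2L, genome)
  for (g in seq_len(t_generations - 1L))
    pair <- wf_pair_offspring(pair, 2L, genome)
  off <- wf_pair_offspring(pair, n_offspring, genome)
  calls <- off[seq(1L, nrow(off), 2L), , drop = FALSE] +
    off[seq(2L, nrow(off), 2L), , drop = FALSE]
  map <- genome$map
  pr <- t(replicate(m, sample(c("A", "C", "G", "T"), 2L)))
  map$allele_a <- pr[, 1]; map$allele_b <- pr[, 2]
  samples <- data.frame(
    sample_id = sprintf("%s_o%d", line_label, seq_len(nrow(calls))),
    breed = line_label, sex = NA_integer_, stringsAsFactors = FALSE)
  ds <- normalize_alleles(genotype_dataset(calls, samples, map, sort = TRUE))
  list(dataset = ds,
       truth = list(pedigree_f = sib_mating_f(t_generations),
                    f_by_generation = sib_mating_f(seq_len(t_generations))))
}

# offspring of the couple formed by the first two individuals of `haps`
wf_pair_offspring <- function(haps, n_offspring, genome) {
  g1 <- make_gametes(haps, rep(1L, n_offspring), genome)
  g2 <- make_gametes(haps, rep(2L, n_offspring), genome)
  h <- matrix(0L, 2L * n_offspring, ncol(haps))
  h[seq(1L, 2L * n_offspring, 2L), ] <- g1
  h[seq(2L, 2L * n_offspring, 2L), ] <- g2
  h
}
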