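#' Pairwise genotypic r2 within a breed
#'
#' Squared Pearson correlation between 0/1/2 dosage vectors (composite,
#' i.e. genotypic LD -- no phasing), for all within-chromosome SNP pairs
#' separated by at most \code{max_dist_mb}. SNPs with fewer than 2 non-missing
#' calls or zero variance in the breed are excluded; pairs whose jointly
#' non-missing calls have zero variance are skipped. Both counts are logged
#' in attributes \code{"n_snps_skipped"} and \code{"n_pairs_skipped"}.
#' Physically adjacent pairs (consecutive usable SNPs on a chromosome) are
#' flagged in column \code{adjacent} regardless of distance.
#'
#' @param ds a \code{genotype_dataset}.
#' @param breed_label one of \code{breeds(ds)}.
#' @param max_dist_mb maximum pair separation in Mb.
#' @param chroms chromosomes used (default: the 18 autosomes).
#' @return data.frame: chrom, snp_i, snp_j, dist_bp, r2, adjacent.
#' @export
pairwise_r2 <- function(ds, breed_label, max_dist_mb = 5,
                        chroms = AUTOSOMES) {
  rows <- breed_rows(ds, breed_label)
  g <- ds$calls[rows, , drop = FALSE]
  n_called <- colSums(!is.na(g))
  v <- apply(g, 2L, stats::var, na.rm = TRUE)
  usable <- n_called >= 2L & !is.na(v) & v > 0
  n_snps_skipped <- sum(!usable & ds$map$chrom %in% chroms)
  out <- list()
  n_pairs_skipped <- 0L
  for (ch in intersect(unique(ds$map$chrom), chroms)) {
    idx <- which(ds$map$chrom == ch & usable)
    if (length(idx) < 2L) next
    pos <- ds$map$pos[idx]
    x <- g[, idx, drop = FALSE]
    # zero-sd warnings arise when a pair's complete cases are monomorphic;
    # those pairs come back NA and are counted in n_pairs_skipped
    cm <- if (anyNA(x))
      suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
    else stats::cor(x)
    m <- length(idx)
    ii <- rep(seq_len(m - 1L), times = (m - 1L):1L)
    jj <- sequence((m - 1L):1L) + ii
    d <- pos[jj] - pos[ii]
    keep <- d <= max_dist_mb * 1e6
    ii <- ii[keep]; jj <- jj[keep]; d <- d[keep]
    r <- cm[cbind(ii, jj)]
    bad <- is.na(r)
    n_pairs_skipped <- n_pairs_skipped + sum(bad)
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, snp_i = ds$map$snp_id[idx][ii][!bad],
      snp_j = ds$map$snp_id[idx][jj][!bad],
      dist_bp = d[!bad], r2 = r[!bad]^2,
      adjacent = (jj - ii == 1L)[!bad],
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), snp_i = character(), snp_j = character(),
               dist_bp = numeric(), r2 = numeric(), adjacent = logical())
  attr(res, "n_snps_skipped") <- n_snps_skipped
  attr(res, "n_pairs_skipped") <- n_pairs_skipped
  attr(res, "n_samples") <- length(rows)
  res
}

#' Distance-bin edges for LD profiles
#'
#' The default scheme: 0.01 Mb steps up to 0.05 Mb, 0.05 Mb steps up to 1 Mb,
#' then whole-Mb bins up to \code{max_mb}. A pair at distance d falls in the
#' bin with lower < d <= upper.
#'
#' @param max_mb upper end of the profile.
#' @return numeric vector of bin edges in Mb, starting at 0.
#' @export
ld_bin_edges <- function(max_mb = 5) {
  edges <- c(seq(0, 0.05, by = 0.01), seq(0.10, 1, by = 0.05))
  if (max_mb > 1) edges <- c(edges, seq(2, max_mb, by = 1))
  edges
}

#' Bin pairwise r2 into an LD-decay profile
#'
#' Assigns each pair to a distance bin (lower-exclusive, upper-inclusive)
#' and records the mean r2 and pair count per bin. The "adjacent" summary is
#' the mean r2 over physically adjacent SNP pairs regardless of their
#' distance. Empty bins keep mean \code{NA} and \code{n_pairs = 0}.
#'
#' @param pairs output of \code{\link{pairwise_r2}} for one breed.
#' @param breed_label label stored in the profile.
#' @param edges bin edges in Mb (see \code{\link{ld_bin_edges}}).
#' @return an \code{ld_profile}: list with \code{breed}, \code{bins}
#'   (lower_mb, upper_mb, mid_mb, n_pairs, mean_r2), \code{adjacent_mean_r2},
#'   \code{adjacent_n}, \code{r2_at_1mb}, \code{r2_at_5mb},
#'   \code{n_samples}.
#' @export
bin_ld <- function(pairs, breed_label = "", edges = ld_bin_edges()) {
  lower <- edges[-length(edges)]; upper <- edges[-1]
  # bin in integer bp so edge cases like exactly 0.05 Mb land upper-inclusive
  edges_bp <- round(edges * 1e6)
  bin <- findInterval(pairs$dist_bp, edges_bp, left.open = TRUE,
                      rightmost.closed = FALSE)
  bin[bin < 1L | bin > length(lower)] <- NA_integer_
  n_pairs <- tabulate(bin, nbins = length(lower))
  sums <- vapply(seq_along(lower), function(b)
    sum(pairs$r2[!is.na(bin) & bin == b]), 0)
  mean_r2 <- ifelse(n_pairs > 0L, sums / n_pairs, NA_real_)
  bins <- data.frame(lower_mb = lower, upper_mb = upper,
                     mid_mb = (lower + upper) / 2,
                     n_pairs = n_pairs, mean_r2 = mean_r2)
  adj <- pairs$r2[pairs$adjacent]
  at <- function(lo, hi) {
    i <- which(abs(lower - lo) < 1e-9 & abs(upper - hi) < 1e-9)
    if (length(i) && n_pairs[i] > 0L) mean_r2[i] else NA_real_
  }
  structure(list(breed = breed_label, bins = bins,
                 adjacent_mean_r2 = if (length(adj)) mean(adj) else NA_real_,
                 adjacent_n = length(adj),
                 r2_at_1mb = at(0.95, 1), r2_at_5mb = at(4, 5),
                 n_samples = attr(pairs, "n_samples")),
            class = "ld_profile")
}

#' Half-decay distance of an LD profile
#'
#' Smallest distance at which the piecewise-linear interpolation of the
#' profile (anchored at distance 0 with the adjacent-pair mean, then through
#' the bin midpoints) drops to half the adjacent-pair mean; \code{NA} when
#' never reached within the profile.
#'
#' @param profile an \code{ld_profile}.
#' @return distance in Mb, or \code{NA}.
#' @export
half_decay_distance <- function(profile) {
  if (is.na(profile$adjacent_mean_r2)) stop("profile has no adjacent-pair mean")
  target <- profile$adjacent_mean_r2 / 2
  ok <- !is.na(profile$bins$mean_r2)
  x <- c(0, profile$bins$mid_mb[ok])
  y <- c(profile$adjacent_mean_r2, profile$bins$mean_r2[ok])
  for (i in seq_along(x)) {
    if (y[i] <= target) {
      if (i == 1L) return(x[1])
      # linear crossing between i-1 and i
      return(x[i - 1] + (x[i] - x[i - 1]) * (y[i - 1] - target) /
               (y[i - 1] - y[i]))
    }
  }
  NA_real_
}

#' LD-based effective population size
#'
#' Sved's relation between equilibrium LD and population size:
#' \code{Ne = (1 / (4c)) * (1 / r2 - 1)} with \code{c} the genetic distance
#' in Morgans. LD at genetic distance c reflects the effective size about
#' \code{T = 1 / (2c)} generations ago.
#'
#' @param r2 mean squared correlation, in (0, 1].
#' @param c genetic distance in Morgans, > 0.
#' @return effective population size.
#' @export
ne_from_r2 <- function(r2, c) {
  if (any(c <= 0)) stop("genetic distance c must be positive")
  if (any(r2 <= 0)) stop("r2 must be positive (r2 = 0 implies infinite Ne)")
  if (any(r2 > 1)) stop("r2 cannot exceed 1")
  (1 / (4 * c)) * (1 / r2 - 1)
}

#' Current effective population size from an LD profile
#'
#' Uses the mean r2 of pairs about 1 Mb apart -- by default the (0.95, 1] Mb
#' bin; with \code{all_pairs_below_1mb = TRUE} the pair-count-weighted mean
#' over every bin up to 1 Mb -- converted to Morgans with the genome-average
#' recombination rate and fed to \code{\link{ne_from_r2}}. The optional
#' finite-sample correction subtracts \code{1/n} (n = sample size) from the
#' mean r2 before inversion.
#'
#' @param profile an \code{ld_profile}.
#' @param cm_per_mb genome-average recombination rate in cM/Mb.
#' @param sample_correction subtract 1/n from the mean r2.
#' @param all_pairs_below_1mb alternative reading of "all 1 Mb bins".
#' @return effective population size.
#' @export
current_ne <- function(profile, cm_per_mb = 1, sample_correction = FALSE,
                       all_pairs_below_1mb = FALSE) {
  if (all_pairs_below_1mb) {
    b <- profile$bins
    sel <- b$upper_mb <= 1 & b$n_pairs > 0
    if (!any(sel)) stop("no populated bin at or below 1 Mb")
    r2 <- sum(b$mean_r2[sel] * b$n_pairs[sel]) / sum(b$n_pairs[sel])
  } else {
    r2 <- profile$r2_at_1mb
    if (is.na(r2)) stop("empty (0.95, 1] Mb bin; cannot estimate current Ne")
  }
  if (sample_correction) {
    if (is.null(profile$n_samples)) stop("profile lacks a sample size")
    r2 <- r2 - 1 / profile$n_samples
  }
  ne_from_r2(r2, 1 * cm_per_mb / 100)
}

#' Historical Ne trajectory from an LD profile
#'
#' Each populated bin at midpoint distance d Mb maps to genetic distance
#' \code{c = d * cm_per_mb / 100} Morgans, time \code{T = 1/(2c)} generations
#' ago, and \code{Ne(T) = ne_from_r2(mean_r2, c)}; the trajectory is sorted
#' by T ascending.
#'
#' @param profile an \code{ld_profile}.
#' @param cm_per_mb genome-average recombination rate in cM/Mb.
#' @param sample_correction subtract 1/n from each bin mean.
#' @return data.frame: t_generations, c_morgans, mid_mb, ne.
#' @export
past_ne_trajectory <- function(profile, cm_per_mb = 1,
                               sample_correction = FALSE) {
  b <- profile$bins
  sel <- b$n_pairs > 0 & !is.na(b$mean_r2)
  r2 <- b$mean_r2[sel]
  if (sample_correction) r2 <- r2 - 1 / profile$n_samples
  keep <- r2 > 0 & r2 <= 1
  cc <- b$mid_mb[sel][keep] * cm_per_mb / 100
  out <- data.frame(t_generations = 1 / (2 * cc), c_morgans = cc,
                    mid_mb = b$mid_mb[sel][keep],
                    ne = ne_from_r2(r2[keep], cc))
  out[order(out$t_generations), , drop = FALSE]
}

#' LD profiles for every breed
#'
#' Convenience wrapper running \code{\link{pairwise_r2}} and
#' \code{\link{bin_ld}} per breed.
#'
#' @param ds a \code{genotype_dataset}.
#' @param max_dist_mb maximum pair separation in Mb.
#' @param chroms chromosomes used.
#' @return named list of \code{ld_profile} objects.
#' @export
ld_profiles <- function(ds, max_dist_mb = 5, chroms = AUTOSOMES) {
  out <- lapply(breeds(ds), function(b)
    bin_ld(pairwise_r2(ds, b, max_dist_mb, chroms), breed_label = b,
           edges = ld_bin_edges(max_dist_mb)))
  names(out) <- breeds(ds)
  out
}
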