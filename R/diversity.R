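#' Per-SNP allele frequencies within a breed
#'
#' Frequency of \code{allele_b} computed over the breed's non-missing calls;
#' MAF is \code{min(f, 1 - f)}. SNPs with no call in the breed get \code{NA}
#' frequency and are skipped by downstream means (with a logged count).
#'
#' @param ds a \code{genotype_dataset}.
#' @param breed_label one of \code{breeds(ds)}.
#' @return data.frame: snp_id, n_called, freq_b, maf.
#' @export
breed_allele_freqs <- function(ds, breed_label) {
  rows <- breed_rows(ds, breed_label)
  g <- ds$calls[rows, , drop = FALSE]
  n_called <- colSums(!is.na(g))
  f <- colSums(g, na.rm = TRUE) / (2 * n_called)
  f[n_called == 0L] <- NA_real_
  data.frame(snp_id = ds$map$snp_id, n_called = n_called,
             freq_b = f, maf = pmin(f, 1 - f), stringsAsFactors = FALSE)
}

#' Per-SNP observed and expected heterozygosity within a breed
#'
#' \code{Ho} = heterozygote fraction among non-missing calls; \code{He} =
#' \code{2 f (1-f)} with \code{f} the breed allele frequency. No small-sample
#' correction by default; \code{unbiased = TRUE} multiplies He by
#' \code{2n/(2n-1)} (Nei's correction, n = called diploids).
#'
#' @param ds a \code{genotype_dataset}.
#' @param breed_label one of \code{breeds(ds)}.
#' @param unbiased apply the small-sample correction to He.
#' @return data.frame: snp_id, n_called, ho, he.
#' @export
heterozygosities <- function(ds, breed_label, unbiased = FALSE) {
  rows <- breed_rows(ds, breed_label)
  g <- ds$calls[rows, , drop = FALSE]
  n_called <- colSums(!is.na(g))
  ho <- colSums(g == 1L, na.rm = TRUE) / n_called
  ho[n_called == 0L] <- NA_real_
  f <- colSums(g, na.rm = TRUE) / (2 * n_called)
  he <- 2 * f * (1 - f)
  if (unbiased) he <- he * (2 * n_called) / pmax(2 * n_called - 1, 1)
  he[n_called == 0L] <- NA_real_
  data.frame(snp_id = ds$map$snp_id, n_called = n_called, ho = ho, he = he,
             stringsAsFactors = FALSE)
}

#' Count informative SNPs in a breed
#'
#' SNPs whose within-breed MAF is strictly greater than \code{threshold}.
#'
#' @param ds a \code{genotype_dataset}.
#' @param breed_label one of \code{breeds(ds)}.
#' @param threshold MAF cut-off (strict inequality).
#' @return integer count.
#' @export
informative_snp_count <- function(ds, breed_label, threshold = 0.05) {
  maf <- breed_allele_freqs(ds, breed_label)$maf
  sum(maf > threshold, na.rm = TRUE)
}

#' Identity-by-state genetic distance between two samples
#'
#' Over SNPs called in both samples, per-SNP allele-sharing similarity is 1
#' for identical genotypes, 0.5 when they share one allele, 0 for opposite
#' homozygotes (equivalently \code{1 - |g_i - g_j| / 2} on dosages). The IBS
#' similarity \code{D_ST} is the mean; the distance returned is
#' \code{D = 1 - D_ST}.
#'
#' @param ds a \code{genotype_dataset}.
#' @param sample_i,sample_j sample identifiers.
#' @return distance in [0, 1].
#' @export
ibs_distance <- function(ds, sample_i, sample_j) {
  gi <- ds$calls[match_sample(ds, sample_i), ]
  gj <- ds$calls[match_sample(ds, sample_j), ]
  ok <- !is.na(gi) & !is.na(gj)
  if (!any(ok))
    stop(sprintf("no jointly called SNP between %s and %s; distance undefined",
                 sample_i, sample_j))
  1 - mean(1 - abs(gi[ok] - gj[ok]) / 2)
}

match_sample <- function(ds, sample_id) {
  i <- match(sample_id, ds$samples$sample_id)
  if (is.na(i)) stop(sprintf("unknown sample_id: '%s'", sample_id))
  i
}

#' Mean within-breed IBS distance
#'
#' Unweighted mean of \code{\link{ibs_distance}} over all C(n,2) sample pairs
#' of the breed.
#'
#' @param ds a \code{genotype_dataset}.
#' @param breed_label one of \code{breeds(ds)}.
#' @return mean pairwise D.
#' @export
breed_mean_distance <- function(ds, breed_label) {
  rows <- breed_rows(ds, breed_label)
  if (length(rows) < 2L)
    stop(sprintf("breed '%s' has fewer than 2 samples", breed_label))
  g <- ds$calls[rows, , drop = FALSE]
  pairs <- utils::combn(length(rows), 2L)
  d <- apply(pairs, 2L, function(p) {
    gi <- g[p[1], ]; gj <- g[p[2], ]
    ok <- !is.na(gi) & !is.na(gj)
    if (!any(ok)) stop("no jointly called SNP in a within-breed pair")
    1 - mean(1 - abs(gi[ok] - gj[ok]) / 2)
  })
  mean(d)
}

#' Per-breed diversity summary table
#'
#' One row per breed: sample size, mean MAF, informative-SNP count (within-
#' breed MAF > 0.05), mean observed and expected heterozygosity, and mean
#' within-breed IBS distance D. Means are over the common SNP panel: SNPs
#' monomorphic within a breed contribute MAF 0 / Ho 0 / He 0; SNPs with no
#' call in the breed are dropped from that breed's means (count in column
#' \code{n_uncalled}). With \code{drop_monomorphic = TRUE}, within-breed
#' monomorphic SNPs are excluded from the means instead (the alternative
#' reporting convention).
#'
#' @param ds a \code{genotype_dataset}.
#' @param informative_threshold MAF cut-off for the informative-SNP count.
#' @param drop_monomorphic exclude breed-monomorphic SNPs from the means.
#' @param unbiased small-sample correction for He (see
#'   \code{\link{heterozygosities}}).
#' @return data.frame, one row per breed.
#' @export
diversity_table <- function(ds, informative_threshold = 0.05,
                            drop_monomorphic = FALSE, unbiased = FALSE) {
  rows <- lapply(breeds(ds), function(b) {
    af <- breed_allele_freqs(ds, b)
    het <- heterozygosities(ds, b, unbiased = unbiased)
    use <- !is.na(af$maf)
    if (drop_monomorphic) use <- use & af$maf > 0
    n_b <- length(breed_rows(ds, b))
    data.frame(
      breed = b, n = n_b,
      mean_maf = mean(af$maf[use]),
      informative_snps = sum(af$maf > informative_threshold, na.rm = TRUE),
      mean_ho = mean(het$ho[use]),
      mean_he = mean(het$he[use]),
      mean_d = if (n_b >= 2L) breed_mean_distance(ds, b) else NA_real_,
      n_uncalled = sum(is.na(af$maf)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
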