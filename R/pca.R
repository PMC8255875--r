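#' Principal component analysis of the genotype matrix
#'
#' Standard genotype PCA on the genomic relationship matrix: per SNP the
#' dosage column is mean-imputed, centered by \code{2f} and scaled by
#' \code{sqrt(2f(1-f))} (f = pooled allele frequency; SNPs with f of 0 or 1,
#' or no calls, are dropped); the sample covariance \code{Z Z' / m} is
#' eigendecomposed. Scores are eigenvectors scaled by the square root of
#' their eigenvalue; variance fractions are each positive eigenvalue over
#' the sum of all positive eigenvalues (fractions over the top-K sum are
#' also returned, since published percentages often use that denominator).
#' Sign convention: the largest-magnitude entry of each eigenvector is made
#' positive.
#'
#' @param ds a \code{genotype_dataset}.
#' @param K number of components to return.
#' @return a \code{pca_result}: list with \code{scores} (samples x K),
#'   \code{variance_fractions}, \code{variance_fractions_topk},
#'   \code{eigenvalues}, \code{n_snps_used}, and the sample table.
#' @export
genotype_pca <- function(ds, K = 10L) {
  if (n_samples(ds) < 2L) stop("PCA needs at least 2 samples")
  g <- ds$calls
  called <- colSums(!is.na(g))
  f <- colSums(g, na.rm = TRUE) / (2 * pmax(called, 1L))
  keep <- called > 0L & f > 0 & f < 1
  if (!any(keep)) stop("no polymorphic SNP: PCA undefined")
  g <- g[, keep, drop = FALSE]; f <- f[keep]
  z <- sweep(g, 2L, 2 * f, `-`)
  z[is.na(z)] <- 0                       # mean imputation after centering
  z <- sweep(z, 2L, sqrt(2 * f * (1 - f)), `/`)
  grm <- tcrossprod(z) / ncol(z)
  e <- eigen(grm, symmetric = TRUE)
  tol <- max(e$values) * 1e-10
  if (max(e$values) <= 0) stop("zero total variance: all samples identical")
  pos <- e$values > tol
  K <- min(K, sum(pos))
  vals <- e$values[seq_len(K)]
  vecs <- e$vectors[, seq_len(K), drop = FALSE]
  for (k in seq_len(K)) {                # deterministic sign
    i <- which.max(abs(vecs[, k]))
    if (vecs[i, k] < 0) vecs[, k] <- -vecs[, k]
  }
  scores <- sweep(vecs, 2L, sqrt(vals), `*`)
  dimnames(scores) <- list(ds$samples$sample_id, paste0("PC", seq_len(K)))
  structure(list(scores = scores,
                 eigenvalues = e$values,
                 variance_fractions = vals / sum(e$values[pos]),
                 variance_fractions_topk = vals / sum(vals),
                 n_snps_used = sum(keep),
                 samples = ds$samples),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("genotype PCA: %d samples, %d SNPs, %d PCs\n",
              nrow(x$scores), x$n_snps_used, ncol(x$scores)))
  vf <- round(100 * x$variance_fractions, 2)
  cat("  variance explained (%):", paste(vf, collapse = " "), "\n")
  invisible(x)
}
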