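# fixture builders and independent oracles shared across test files

# dataset from a dosage matrix (samples x SNPs); one chromosome by default
toy_dataset <- function(calls, breeds = rep("B1", nrow(calls)),
                        chrom = rep("1", ncol(calls)),
                        pos = seq_len(ncol(calls)) * 10000L,
                        allele_a = rep("A", ncol(calls)),
                        allele_b = rep("G", ncol(calls))) {
  n <- nrow(calls)
  genotype_dataset(
    calls,
    samples = data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                         breed = breeds, stringsAsFactors = FALSE),
    map = data.frame(chrom = chrom, snp_id = sprintf("m%04d", seq_len(ncol(calls))),
                     cm = 0, pos = pos, allele_a = allele_a,
                     allele_b = allele_b, stringsAsFactors = FALSE))
}

# write a PED/MAP pair from raw character fields (for parser edge cases)
write_ped_map <- function(ped_rows, map_rows, dir = tempfile()) {
  dir.create(dir)
  ped <- file.path(dir, "t.ped"); map <- file.path(dir, "t.map")
  writeLines(ped_rows, ped); writeLines(map_rows, map)
  list(ped = ped, map = map)
}

# ---- ROH brute-force oracle -------------------------------------------------
# enumerate every interval bounded by homozygous SNPs, keep those passing all
# segment invariants, then select greedily left to right (smallest start;
# ties -> longest). Independent of the scanning code in R/roh.R.
roh_oracle <- function(pos, geno, params) {
  m <- length(pos)
  hom <- !is.na(geno) & geno != 1L
  het <- !is.na(geno) & geno == 1L
  mis <- is.na(geno)
  d <- diff(pos)
  hidx <- which(hom)
  pass <- list()
  for (s in hidx) {
    ends <- hidx[hidx >= s]
    if (!length(ends)) next
    nhet <- cumsum(het[s:m])[ends - s + 1L]
    nmis <- cumsum(mis[s:m])[ends - s + 1L]
    nhom <- cumsum(hom[s:m])[ends - s + 1L]
    maxgap <- c(0, cummax(d[s:(m - 1)]))[ends - s + 1L]
    maxgap[ends == s] <- 0
    span <- pos[ends] - pos[s]
    ok <- nhet <= params$max_het & nmis <= params$max_missing &
      maxgap <= params$max_gap_kb * 1000 &
      nhom >= params$min_snps &
      span >= params$min_length_kb * 1000 &
      span / nhom <= params$min_density_kb_per_snp * 1000
    if (any(ok))
      pass[[length(pass) + 1L]] <- data.frame(s = s, e = ends[ok])
  }
  if (!length(pass)) return(data.frame(start_bp = integer(), end_bp = integer()))
  pass <- do.call(rbind, pass)
  sel <- list(); last_e <- 0L
  repeat {
    cand <- pass[pass$s > last_e, , drop = FALSE]
    if (!nrow(cand)) break
    cand <- cand[cand$s == min(cand$s), , drop = FALSE]
    pick <- cand[which.max(cand$e), ]
    sel[[length(sel) + 1L]] <- pick
    last_e <- pick$e
  }
  sel <- do.call(rbind, sel)
  data.frame(start_bp = pos[sel$s], end_bp = pos[sel$e])
}

# random single-chromosome ROH scenario (positions + genotypes + params)
random_roh_case <- function() {
  m <- sample(30:200, 1)
  spacing <- stats::rexp(m - 1, 1 / 40000)
  if (stats::runif(1) < 0.3)   # sprinkle oversized gaps
    spacing[sample(m - 1, max(1, m %/% 40))] <- stats::runif(1, 1.2e6, 3e6)
  pos <- as.integer(round(cumsum(c(1e4, spacing))))
  pos <- pos + seq_len(m)                       # strictly increasing
  inbred <- stats::runif(1) < 0.6
  p_het <- if (inbred) 0.03 else 0.25
  p_mis <- stats::runif(1, 0, 0.06)
  u <- stats::runif(m)
  geno <- ifelse(u < p_mis, NA_integer_,
                 ifelse(u < p_mis + p_het, 1L,
                        sample(c(0L, 2L), m, replace = TRUE)))
  params <- roh_params(
    min_snps = sample(c(10L, 20L, 40L), 1),
    min_length_kb = sample(c(250, 500, 1000), 1),
    min_density_kb_per_snp = sample(c(100, 1000), 1),
    max_gap_kb = 1000,
    max_het = sample(0:2, 1), max_missing = sample(c(0L, 2L, 5L), 1))
  list(pos = pos, geno = geno, params = params)
}

# ---- Weir & Cockerham (1984) textbook oracle --------------------------------
# literal scalar transcription of the two-population variance components,
# looping over SNPs; intentionally unvectorized and separate from R/.
wc_oracle <- function(g1, g2) {
  stopifnot(ncol(g1) == ncol(g2))
  A <- B <- C <- numeric(0)
  for (j in seq_len(ncol(g1))) {
    x1 <- g1[, j][!is.na(g1[, j])]; x2 <- g2[, j][!is.na(g2[, j])]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 < 1 || n2 < 1 || n1 + n2 <= 2) next
    p1 <- sum(x1) / (2 * n1); p2 <- sum(x2) / (2 * n2)
    h1 <- mean(x1 == 1); h2 <- mean(x2 == 1)
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
        ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    A <- c(A, a); B <- c(B, b); C <- c(C, cc)
  }
  den <- A + B + C
  use <- den > 0
  list(a = A, b = B, c = C, weighted = sum(A[use]) / sum(den[use]))
}

# random two-population toy for the F_ST equivalence check
random_fst_toy <- function() {
  m <- sample(1:5, 1)
  n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
  g1 <- matrix(sample(0:2, n1 * m, replace = TRUE), n1, m)
  g2 <- matrix(sample(0:2, n2 * m, replace = TRUE), n2, m)
  if (stats::runif(1) < 0.3) g1[sample(length(g1), 1)] <- NA
  list(g1 = g1, g2 = g2)
}

fst_toy_dataset <- function(g1, g2) {
  toy_dataset(rbind(g1, g2),
              breeds = c(rep("P1", nrow(g1)), rep("P2", nrow(g2))))
}

# small genome used by simulation-driven tests (kept small for runtime)
test_genome <- function(n_chrom = 2L, mb = 50, m = 250L, cm_per_mb = 1)
  sim_genome(n_chrom, mb, m, cm_per_mb)

# mean silhouette on the first two PCs, euclidean, no dependencies
silhouette_pc12 <- function(scores, labels) {
  x <- scores[, 1:2, drop = FALSE]
  d <- as.matrix(dist(x))
  sil <- vapply(seq_len(nrow(x)), function(i) {
    own <- labels == labels[i]; own[i] <- FALSE
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(sil)
}
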