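AUTOSOMES <- as.character(1:18)
MISSING_ALLELE <- "0"

chrom_rank <- function(chrom) {
  # autosomes in numeric order, then X, then anything else alphabetically
  suppressWarnings(num <- as.numeric(chrom))
  rank <- ifelse(!is.na(num), num,
                 ifelse(chrom == "X", 1e6, 1e6 + as.numeric(factor(chrom))))
  rank
}

#' Construct a genotype dataset
#'
#' Container for diploid biallelic SNP-array genotypes: a samples x SNPs dosage
#' matrix (counts of \code{allele_b}, \code{NA} = missing call), a sample table
#' carrying breed labels, and a SNP map with chromosome, base-pair position and
#' the two alleles. This is the object all analysis functions operate on.
#'
#' @param calls integer matrix, samples x SNPs, values 0/1/2 or NA.
#' @param samples data.frame with columns \code{sample_id}, \code{breed} and
#'   optionally \code{sex}.
#' @param map data.frame with columns \code{chrom}, \code{snp_id}, \code{cm},
#'   \code{pos}, \code{allele_a}, \code{allele_b}. Positions are 1-based bp.
#' @param sort if TRUE (default) SNPs are sorted by (chromosome, position).
#' @return an object of class \code{genotype_dataset}.
#' @export
genotype_dataset <- function(calls, samples, map, sort = TRUE) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(nrow(calls) == nrow(samples), ncol(calls) == nrow(map))
  if (any(!is.na(calls) & (calls < 0L | calls > 2L)))
    stop("genotype calls must be 0, 1, 2 or NA")
  if (any(is.na(samples$breed)) || any(!nzchar(samples$breed)))
    stop("breed labels must be non-empty")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id")
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  if (any(map$pos < 0L)) stop("negative bp position in map")
  if (sort) {
    o <- order(chrom_rank(map$chrom), map$pos)
    map <- map[o, , drop = FALSE]
    calls <- calls[, o, drop = FALSE]
  }
  rownames(map) <- NULL
  rownames(samples) <- NULL
  dimnames(calls) <- list(samples$sample_id, map$snp_id)
  structure(list(calls = calls, samples = samples, map = map),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples x %d SNPs, %d breeds, %d chromosomes\n",
              nrow(x$calls), ncol(x$calls),
              length(unique(x$samples$breed)), length(unique(x$map$chrom))))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of samples / SNPs in a dataset
#' @param ds a \code{genotype_dataset}.
#' @return integer count.
#' @export
n_samples <- function(ds) nrow(ds$calls)

#' @rdname n_samples
#' @export
n_snps <- function(ds) ncol(ds$calls)

#' Breed labels present in a dataset
#' @param ds a \code{genotype_dataset}.
#' @return character vector of unique breed labels, in order of appearance.
#' @export
breeds <- function(ds) unique(ds$samples$breed)

breed_rows <- function(ds, breed_label) {
  idx <- which(ds$samples$breed == breed_label)
  if (length(idx) == 0L)
    stop(sprintf("unknown breed label: '%s'", breed_label))
  idx
}

#' Subset a dataset by SNP or sample index
#' @param ds a \code{genotype_dataset}.
#' @param snps integer or logical index into the SNP panel.
#' @param samples integer or logical index into the samples.
#' @return a new \code{genotype_dataset}.
#' @export
subset_dataset <- function(ds, snps = NULL, samples = NULL) {
  calls <- ds$calls; map <- ds$map; smp <- ds$samples
  if (!is.null(snps)) {
    calls <- calls[, snps, drop = FALSE]
    map <- map[snps, , drop = FALSE]
  }
  if (!is.null(samples)) {
    calls <- calls[samples, , drop = FALSE]
    smp <- smp[samples, , drop = FALSE]
  }
  genotype_dataset(calls, smp, map, sort = FALSE)
}

split_fields <- function(lines) strsplit(trimws(lines), "[ \t]+")

#' Read PLINK text-format genotypes (PED + MAP)
#'
#' Parses a whitespace-delimited PED/MAP pair into a \code{genotype_dataset}.
#' The PED family-ID column is stored as the breed label. Genotypes are recoded
#' to counts of \code{allele_b}, where \code{allele_b} is the minor allele over
#' the whole file (ties broken by taking the lexicographically smaller allele
#' as \code{allele_b}); "0 0" becomes a missing call. SNPs are sorted by
#' (chromosome, position) after loading.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @return a \code{genotype_dataset}.
#' @export
read_plink <- function(ped_path, map_path) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  mf <- split_fields(map_lines)
  ncol_map <- lengths(mf)
  if (any(ncol_map < 3L | ncol_map > 4L))
    stop(sprintf("MAP parse error at line %d: expected 3 or 4 columns, got %d",
                 which(ncol_map < 3L | ncol_map > 4L)[1],
                 ncol_map[which(ncol_map < 3L | ncol_map > 4L)[1]]))
  has_cm <- ncol_map == 4L
  map <- data.frame(
    chrom = vapply(mf, `[`, "", 1L),
    snp_id = vapply(mf, `[`, "", 2L),
    cm = ifelse(has_cm, as.numeric(vapply(mf, `[`, "", 3L)), 0),
    pos = as.integer(vapply(seq_along(mf), function(i)
      mf[[i]][if (has_cm[i]) 4L else 3L], "")),
    stringsAsFactors = FALSE)
  m <- nrow(map)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  pf <- split_fields(ped_lines)
  want <- 6L + 2L * m
  bad <- which(lengths(pf) != want)
  if (length(bad))
    stop(sprintf("PED parse error at line %d: expected %d fields for %d SNPs, got %d",
                 bad[1], want, m, lengths(pf)[bad[1]]))
  n <- length(pf)
  samples <- data.frame(
    sample_id = vapply(pf, `[`, "", 2L),
    breed = vapply(pf, `[`, "", 1L),
    sex = suppressWarnings(as.integer(vapply(pf, `[`, "", 5L))),
    stringsAsFactors = FALSE)

  # allele matrix: n x 2m characters
  al <- matrix(unlist(lapply(pf, `[`, -(1:6))), nrow = n, byrow = TRUE)
  a1 <- al[, seq(1L, 2L * m, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * m, by = 2L), drop = FALSE]
  half_missing <- xor(a1 == MISSING_ALLELE, a2 == MISSING_ALLELE)
  if (any(half_missing))
    stop(sprintf("half-missing genotype ('%s %s') at SNP %s",
                 a1[half_missing][1], a2[half_missing][1],
                 map$snp_id[ceiling(which(half_missing)[1] / n)]))

  calls <- matrix(NA_integer_, n, m)
  allele_a <- allele_b <- character(m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    obs <- obs[obs != MISSING_ALLELE]
    tab <- sort(table(obs), decreasing = TRUE)
    alleles <- names(tab)
    if (length(alleles) > 2L)
      stop(sprintf("format error at SNP %s: %d distinct alleles (%s)",
                   map$snp_id[j], length(alleles),
                   paste(alleles, collapse = ",")))
    if (length(alleles) == 0L) {           # fully missing column
      allele_a[j] <- MISSING_ALLELE; allele_b[j] <- MISSING_ALLELE
      next
    }
    if (length(alleles) == 1L) {
      allele_a[j] <- alleles[1]; allele_b[j] <- MISSING_ALLELE
      calls[, j] <- ifelse(a1[, j] == MISSING_ALLELE, NA_integer_, 0L)
      next
    }
    if (tab[1] == tab[2]) alleles <- sort(alleles)  # tie: smaller is allele_b
    allele_a[j] <- alleles[if (tab[1] == tab[2]) 2L else 1L]
    allele_b[j] <- alleles[if (tab[1] == tab[2]) 1L else 2L]
    dos <- (a1[, j] == allele_b[j]) + (a2[, j] == allele_b[j])
    dos[a1[, j] == MISSING_ALLELE] <- NA_integer_
    calls[, j] <- dos
  }
  map$allele_a <- allele_a
  map$allele_b <- allele_b
  genotype_dataset(calls, samples, map, sort = TRUE)
}

#' Write a dataset back to PLINK PED/MAP text files
#'
#' Inverse of \code{\link{read_plink}}: re-reading the written pair reproduces
#' calls, breed labels and map exactly for any dataset whose \code{allele_b} is
#' the minor allele (the orientation \code{read_plink} and the simulator
#' guarantee). Missing calls are written as "0 0".
#'
#' @param ds a \code{genotype_dataset}.
#' @param ped_path,map_path output paths.
#' @return invisibly, the two paths.
#' @export
write_plink <- function(ds, ped_path, map_path) {
  if (n_samples(ds) == 0L) stop("cannot write a dataset with no samples")
  map <- ds$map
  writeLines(sprintf("%s\t%s\t%g\t%d", map$chrom, map$snp_id,
                     if (!is.null(map$cm)) map$cm else 0, map$pos),
             map_path)
  n <- n_samples(ds); m <- n_snps(ds)
  a_rep <- matrix(rep(map$allele_a, each = n), n, m)
  b_rep <- matrix(rep(ifelse(map$allele_b == MISSING_ALLELE, map$allele_a,
                             map$allele_b), each = n), n, m)
  g <- ds$calls
  first <- ifelse(is.na(g), MISSING_ALLELE, ifelse(g == 2L, b_rep, a_rep))
  second <- ifelse(is.na(g), MISSING_ALLELE, ifelse(g == 0L, a_rep, b_rep))
  geno <- matrix(paste(first, second, sep = "\t"), n, m)
  sex <- if (!is.null(ds$samples$sex)) ifelse(is.na(ds$samples$sex), 0L,
                                              ds$samples$sex) else rep(0L, n)
  lead <- sprintf("%s\t%s\t0\t0\t%d\t-9", ds$samples$breed,
                  ds$samples$sample_id, sex)
  writeLines(paste(lead, apply(geno, 1L, paste, collapse = "\t"), sep = "\t"),
             ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Quality-control parameters
#'
#' Defaults are the standard SNP-chip thresholds used throughout the package:
#' per-SNP call rate at least 0.95 and pooled minor allele frequency at least
#' 0.05 (both inclusive).
#'
#' @param call_rate_min minimum fraction of non-missing calls per SNP.
#' @param maf_min minimum whole-dataset MAF.
#' @return a \code{qc_params} list.
#' @export
qc_params <- function(call_rate_min = 0.95, maf_min = 0.05) {
  stopifnot(call_rate_min >= 0, call_rate_min <= 1,
            maf_min >= 0, maf_min <= 0.5)
  structure(list(call_rate_min = call_rate_min, maf_min = maf_min),
            class = "qc_params")
}

#' Apply SNP quality control
#'
#' Retains SNPs whose call rate (over all samples) and whole-dataset MAF (all
#' breeds pooled) meet the thresholds; both comparisons are inclusive. The
#' sample set is unchanged. The removal log (one row per dropped SNP with the
#' first failing reason, "call_rate" or "maf") is attached as attribute
#' \code{"qc_log"} and retrievable with \code{\link{qc_removals}}.
#'
#' @param ds a \code{genotype_dataset}.
#' @param qc a \code{\link{qc_params}} object.
#' @return the filtered \code{genotype_dataset}.
#' @export
apply_qc <- function(ds, qc = qc_params()) {
  if (n_snps(ds) == 0L || n_samples(ds) == 0L) stop("empty dataset")
  called <- colSums(!is.na(ds$calls))
  call_rate <- called / n_samples(ds)
  f <- colSums(ds$calls, na.rm = TRUE) / (2 * pmax(called, 1L))
  maf <- pmin(f, 1 - f)
  maf[called == 0L] <- 0
  fail_cr <- call_rate < qc$call_rate_min
  fail_maf <- maf < qc$maf_min
  keep <- !(fail_cr | fail_maf)
  if (!any(keep)) stop("empty after QC: no SNP passed the filters")
  log <- data.frame(
    snp_id = ds$map$snp_id[!keep],
    reason = ifelse(fail_cr[!keep], "call_rate", "maf"),
    stringsAsFactors = FALSE)
  out <- subset_dataset(ds, snps = which(keep))
  attr(out, "qc_log") <- log
  out
}

#' @rdname apply_qc
#' @export
qc_removals <- function(ds) {
  log <- attr(ds, "qc_log")
  if (is.null(log)) data.frame(snp_id = character(), reason = character()) else log
}

#' Per-chromosome map summary
#'
#' For each chromosome: SNP count, mean adjacent spacing (mean of successive
#' position differences; \code{NA} where fewer than 2 SNPs), and the min/max
#' position. The grand mean spacing is the unweighted mean of the defined
#' per-chromosome means.
#'
#' @param ds a \code{genotype_dataset}.
#' @return a data.frame with one row per chromosome, plus attribute
#'   \code{"grand_mean_spacing_bp"}.
#' @export
summarize_map <- function(ds) {
  sp <- split(ds$map$pos, ds$map$chrom)
  chroms <- names(sp)[order(chrom_rank(names(sp)))]
  rows <- lapply(chroms, function(ch) {
    pos <- sort(sp[[ch]])
    data.frame(chrom = ch, n_snps = length(pos),
               mean_spacing_bp = if (length(pos) >= 2L) mean(diff(pos)) else NA_real_,
               min_pos = min(pos), max_pos = max(pos),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "grand_mean_spacing_bp") <- mean(out$mean_spacing_bp, na.rm = TRUE)
  out
}

# Orient every SNP so allele_b is the minor allele over the whole dataset
# (tie -> lexicographically smaller allele), matching read_plink's convention.
normalize_alleles <- function(ds) {
  called <- colSums(!is.na(ds$calls))
  cnt_b <- colSums(ds$calls, na.rm = TRUE)
  cnt_a <- 2L * called - cnt_b
  flip <- cnt_b > cnt_a |
    (cnt_b == cnt_a & ds$map$allele_b > ds$map$allele_a)
  flip[ds$map$allele_b == MISSING_ALLELE] <- FALSE
  if (any(flip)) {
    ds$calls[, flip] <- 2L - ds$calls[, flip, drop = FALSE]
    tmp <- ds$map$allele_a[flip]
    ds$map$allele_a[flip] <- ds$map$allele_b[flip]
    ds$map$allele_b[flip] <- tmp
  }
  attr(ds, "flipped") <- flip
  ds
}
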