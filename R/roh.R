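#' Runs-of-homozygosity detection parameters
#'
#' Defaults are the standard SNP-chip ROH criteria used throughout the
#' package: a run must contain at least 40 homozygous SNPs, span at least
#' 1,000 kb, have a density of at least one SNP per 1,000 kb, contain no
#' adjacent-SNP gap larger than 1 Mb, and may include at most one
#' heterozygous and five missing calls.
#'
#' @param min_snps minimum number of homozygous SNPs in a run.
#' @param min_length_kb minimum run span (end - start) in kb.
#' @param min_density_kb_per_snp maximum kb of span per homozygous SNP.
#' @param max_gap_kb maximum gap between consecutive map SNPs inside a run.
#' @param max_het maximum heterozygous calls tolerated inside a run.
#' @param max_missing maximum missing calls tolerated inside a run.
#' @return a \code{roh_params} list.
#' @export
roh_params <- function(min_snps = 40L, min_length_kb = 1000,
                       min_density_kb_per_snp = 1000, max_gap_kb = 1000,
                       max_het = 1L, max_missing = 5L) {
  stopifnot(min_snps >= 1, min_length_kb >= 0, min_density_kb_per_snp > 0,
            max_gap_kb > 0, max_het >= 0, max_missing >= 0)
  structure(list(min_snps = as.integer(min_snps),
                 min_length_kb = min_length_kb,
                 min_density_kb_per_snp = min_density_kb_per_snp,
                 max_gap_kb = max_gap_kb,
                 max_het = as.integer(max_het),
                 max_missing = as.integer(max_missing)),
            class = "roh_params")
}

#' Length of the autosomal genome covered by SNPs
#'
#' Sum over autosomes (chromosomes "1".."18") of (max position - min
#' position). This is the denominator L_AUTO of the genomic inbreeding
#' coefficient F_ROH.
#'
#' @param ds a \code{genotype_dataset}.
#' @param autosomes chromosome labels counted as autosomal.
#' @return total covered length in bp.
#' @export
autosome_length <- function(ds, autosomes = AUTOSOMES) {
  keep <- ds$map$chrom %in% autosomes
  if (!any(keep)) stop("no autosomal SNPs in dataset")
  pos <- split(ds$map$pos[keep], ds$map$chrom[keep])
  sum(vapply(pos, function(p) as.numeric(max(p) - min(p)), 0))
}

# scan one chromosome of one individual; geno 0/1/2/NA sorted by pos
scan_chrom_roh <- function(pos, geno, params) {
  m <- length(pos)
  if (m < 2L) return(NULL)
  max_gap_bp <- params$max_gap_kb * 1000
  min_len_bp <- params$min_length_kb * 1000
  dens_bp <- params$min_density_kb_per_snp * 1000
  hom <- !is.na(geno) & geno != 1L
  het <- !is.na(geno) & geno == 1L
  mis <- is.na(geno)
  # blocks: a gap > max_gap can never be inside a run
  gaps <- diff(pos)
  block_id <- cumsum(c(0L, gaps > max_gap_bp))
  out <- list()
  for (blk in split(seq_len(m), block_id)) {
    if (length(blk) < params$min_snps) next
    res <- scan_block_roh(pos[blk], hom[blk], het[blk], mis[blk],
                          params, min_len_bp, dens_bp)
    if (!is.null(res)) out[[length(out) + 1L]] <- res
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# greedy left-to-right selection: at each admissible start (a homozygous SNP
# after the previous emitted segment), take the longest passing run; emit it,
# or advance one homozygous SNP if none passes.
scan_block_roh <- function(pos, hom, het, mis, params, min_len_bp, dens_bp) {
  k <- length(pos)
  chet <- cumsum(het); cmis <- cumsum(mis); chom <- cumsum(hom)
  hom_idx <- which(hom)
  if (!length(hom_idx)) return(NULL)
  segs <- list()
  si <- 1L                                   # index into hom_idx
  while (si <= length(hom_idx)) {
    s <- hom_idx[si]
    het0 <- chet[s] - het[s]; mis0 <- cmis[s] - mis[s]
    # furthest extension keeping het/missing within budget
    jmax <- max(which(chet - het0 <= params$max_het &
                      cmis - mis0 <= params$max_missing &
                      seq_len(k) >= s))
    ends <- hom_idx[hom_idx >= s & hom_idx <= jmax]
    span <- pos[ends] - pos[s]
    nhom <- chom[ends] - chom[s] + 1L
    pass <- nhom >= params$min_snps & span >= min_len_bp &
      span / nhom <= dens_bp
    if (any(pass)) {
      e <- ends[max(which(pass))]
      segs[[length(segs) + 1L]] <- data.frame(
        start_idx = s, end_idx = e, start_bp = pos[s], end_bp = pos[e],
        n_snps = chom[e] - chom[s] + 1L,
        n_het = chet[e] - het0, n_missing = cmis[e] - mis0)
      si <- which(hom_idx > e)[1]
      if (is.na(si)) break
    } else {
      si <- si + 1L
    }
  }
  if (!length(segs)) return(NULL)
  do.call(rbind, segs)
}

#' Detect runs of homozygosity for one individual
#'
#' Scans each autosome of the given sample for maximal runs satisfying all
#' criteria in \code{params}; runs start and end on homozygous SNPs
#' (heterozygous/missing edges are trimmed), are non-overlapping within a
#' chromosome, and are selected greedily left to right (longest passing run
#' at the leftmost admissible start).
#'
#' @param ds a \code{genotype_dataset}.
#' @param sample_id sample identifier.
#' @param params a \code{\link{roh_params}} object.
#' @param autosomes chromosome labels scanned.
#' @return data.frame of segments: sample_id, chrom, start_bp, end_bp,
#'   n_snps (homozygous SNPs), n_het, n_missing, length_bp; zero rows when no
#'   run qualifies.
#' @export
detect_roh <- function(ds, sample_id, params = roh_params(),
                       autosomes = AUTOSOMES) {
  i <- match_sample(ds, sample_id)
  out <- list()
  for (ch in intersect(unique(ds$map$chrom), autosomes)) {
    idx <- which(ds$map$chrom == ch)
    res <- scan_chrom_roh(ds$map$pos[idx], ds$calls[i, idx], params)
    if (!is.null(res)) {
      res$chrom <- ch
      out[[length(out) + 1L]] <- res
    }
  }
  empty <- data.frame(sample_id = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), n_het = integer(),
                      n_missing = integer(), length_bp = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  data.frame(sample_id = sample_id, chrom = res$chrom,
             start_bp = res$start_bp, end_bp = res$end_bp,
             n_snps = res$n_snps, n_het = res$n_het,
             n_missing = res$n_missing,
             length_bp = as.numeric(res$end_bp - res$start_bp),
             stringsAsFactors = FALSE)
}

#' Genomic inbreeding coefficient from ROH
#'
#' \code{F_ROH = sum(L_ROH) / L_AUTO}, with segment length \code{end_bp -
#' start_bp} and \code{L_AUTO} from \code{\link{autosome_length}}.
#'
#' @param ds a \code{genotype_dataset}.
#' @param sample_id sample identifier.
#' @param segments segment table from \code{\link{detect_roh}} (computed if
#'   missing).
#' @param params a \code{\link{roh_params}} object, used when segments are
#'   computed here.
#' @return list: sample_id, n_segments, total_length_bp, f_roh.
#' @export
froh <- function(ds, sample_id, segments = NULL, params = roh_params()) {
  if (is.null(segments)) segments <- detect_roh(ds, sample_id, params)
  if (nrow(segments)) {
    for (ch in unique(segments$chrom)) {
      s <- segments[segments$chrom == ch, ]
      s <- s[order(s$start_bp), ]
      if (nrow(s) > 1L && any(s$start_bp[-1] <= s$end_bp[-nrow(s)]))
        stop("overlapping ROH segments on chromosome ", ch,
             ": detector bug or foreign input")
    }
  }
  l_auto <- autosome_length(ds)
  total <- sum(as.numeric(segments$end_bp - segments$start_bp))
  list(sample_id = sample_id, n_segments = nrow(segments),
       total_length_bp = total, f_roh = total / l_auto)
}

#' Per-breed ROH summary table
#'
#' For every breed: mean, sample SD (n-1 denominator), min and max of the
#' per-individual segment count, total ROH length (kb) and F_ROH. For
#' single-sample breeds the SD is reported as 0 with \code{sd_defined =
#' FALSE}.
#'
#' @param ds a \code{genotype_dataset}.
#' @param params a \code{\link{roh_params}} object.
#' @return data.frame, one row per breed.
#' @export
breed_roh_table <- function(ds, params = roh_params()) {
  per_ind <- lapply(ds$samples$sample_id, function(sid)
    froh(ds, sid, params = params))
  nseg <- vapply(per_ind, `[[`, 0, "n_segments")
  tot_kb <- vapply(per_ind, `[[`, 0, "total_length_bp") / 1000
  fr <- vapply(per_ind, `[[`, 0, "f_roh")
  breed <- ds$samples$breed
  stat <- function(x) {
    n <- length(x)
    c(mean = mean(x), sd = if (n > 1L) stats::sd(x) else 0,
      min = min(x), max = max(x))
  }
  rows <- lapply(breeds(ds), function(b) {
    sel <- breed == b
    s1 <- stat(nseg[sel]); s2 <- stat(tot_kb[sel]); s3 <- stat(fr[sel])
    data.frame(breed = b, n = sum(sel),
               nseg_mean = s1["mean"], nseg_sd = s1["sd"],
               nseg_min = s1["min"], nseg_max = s1["max"],
               length_kb_mean = s2["mean"], length_kb_sd = s2["sd"],
               length_kb_min = s2["min"], length_kb_max = s2["max"],
               froh_mean = s3["mean"], froh_sd = s3["sd"],
               froh_min = s3["min"], froh_max = s3["max"],
               sd_defined = sum(sel) > 1L,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
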