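#' Weir-Cockerham F_ST between two breeds
#'
#' Per-SNP variance components of the Weir & Cockerham (1984) two-level
#' estimator for diploid data: \code{a} (among populations), \code{b} (among
#' individuals within populations) and \code{c} (within individuals), from
#' sample sizes, allele frequencies and observed heterozygote frequencies.
#' The headline genome-wide value is the weighted (ratio-of-sums) estimate
#' \code{sum(a) / sum(a + b + c)}; the unweighted mean of per-SNP ratios is
#' also returned. Negative component sums are kept in the sums; only the
#' reported weighted estimate is clamped at 0 (\code{weighted_clamped}).
#'
#' @param ds a \code{genotype_dataset}.
#' @param breed_a,breed_b breed labels; both need at least 2 samples.
#' @return an \code{fst_result}: list with \code{breed_pair}, \code{per_snp}
#'   (data.frame snp_id, a, b, c, ratio), \code{weighted},
#'   \code{weighted_clamped}, \code{mean_ratio}, \code{n_snps_used}.
#' @export
wc_fst <- function(ds, breed_a, breed_b) {
  ra <- breed_rows(ds, breed_a); rb <- breed_rows(ds, breed_b)
  if (length(ra) < 2L || length(rb) < 2L)
    stop("both breeds need at least 2 samples for the W&C estimator")
  ga <- ds$calls[ra, , drop = FALSE]; gb <- ds$calls[rb, , drop = FALSE]
  comp <- wc_components(
    n1 = colSums(!is.na(ga)), n2 = colSums(!is.na(gb)),
    p1 = colSums(ga, na.rm = TRUE) / (2 * pmax(colSums(!is.na(ga)), 1L)),
    p2 = colSums(gb, na.rm = TRUE) / (2 * pmax(colSums(!is.na(gb)), 1L)),
    h1 = colSums(ga == 1L, na.rm = TRUE) / pmax(colSums(!is.na(ga)), 1L),
    h2 = colSums(gb == 1L, na.rm = TRUE) / pmax(colSums(!is.na(gb)), 1L))
  # W&C components need nbar > 1; require both breeds called and >2 genomes
  ok <- colSums(!is.na(ga)) >= 1L & colSums(!is.na(gb)) >= 1L &
    (colSums(!is.na(ga)) + colSums(!is.na(gb))) > 2L
  a <- comp$a[ok]; b <- comp$b[ok]; cc <- comp$c[ok]
  denom <- a + b + cc
  use <- denom > 0
  if (!any(use))
    stop(sprintf("F_ST undefined for (%s, %s): no SNP with positive denominator",
                 breed_a, breed_b))
  weighted <- sum(a[use]) / sum(denom[use])
  ratio <- rep(NA_real_, length(a)); ratio[use] <- a[use] / denom[use]
  structure(list(
    breed_pair = c(breed_a, breed_b),
    per_snp = data.frame(snp_id = ds$map$snp_id[ok], a = a, b = b, c = cc,
                         ratio = ratio, stringsAsFactors = FALSE),
    weighted = weighted, weighted_clamped = max(0, weighted),
    mean_ratio = mean(ratio, na.rm = TRUE), n_snps_used = sum(use)),
    class = "fst_result")
}

# Weir & Cockerham (1984) variance components, r = 2 populations, vectorized
# over SNPs. n = called diploids, p = allele frequency, h = observed
# heterozygote frequency.
wc_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  c <- hbar / 2
  list(a = a, b = b, c = c)
}

IUPAC2 <- c("AC" = "M", "AG" = "R", "AT" = "W",
            "CG" = "S", "CT" = "Y", "GT" = "K")

#' Breed consensus sequence
#'
#' One symbol per SNP: the breed's majority allele; the IUPAC two-base
#' ambiguity code on an exact 50/50 tie; \code{"-"} when the breed has no
#' call at the SNP (or the SNP is monomorphic for an unknown second allele
#' and uncalled).
#'
#' @param ds a \code{genotype_dataset}.
#' @param breed_label one of \code{breeds(ds)}.
#' @return character vector of length \code{n_snps(ds)}.
#' @export
consensus_sequence <- function(ds, breed_label) {
  af <- breed_allele_freqs(ds, breed_label)
  a <- ds$map$allele_a; b <- ds$map$allele_b
  out <- character(n_snps(ds))
  for (j in seq_along(out)) {
    f <- af$freq_b[j]
    if (is.na(f)) { out[j] <- "-"; next }
    if (b[j] == MISSING_ALLELE) { out[j] <- a[j]; next }  # monomorphic column
    if (f > 0.5) out[j] <- b[j]
    else if (f < 0.5) out[j] <- a[j]
    else {
      key <- paste(sort(c(a[j], b[j])), collapse = "")
      out[j] <- if (key %in% names(IUPAC2)) IUPAC2[[key]] else "N"
    }
  }
  out
}

#' Tajima-Nei evolutionary distance between two sequences
#'
#' Equal-input substitution distance with uniform rates: after pairwise
#' deletion of sites where either sequence has a gap or an ambiguity (any
#' symbol outside A/C/G/T), with \code{p} the fraction of differing retained
#' sites, \code{d = -b * log(1 - p/b)} where
#' \code{b = (1 - sum(g_i^2) + p^2/h) / 2}, \code{g_i} the base frequencies
#' pooled over both sequences, and \code{h = sum_{i<j} x_ij^2 / (2 g_i g_j)}
#' over the unordered site-pattern frequencies \code{x_ij} of the differing
#' sites. With equal base frequencies this reduces to the Jukes-Cantor
#' formula (b = 3/4).
#'
#' @param seq_x,seq_y character vectors (one symbol per site) or single
#'   strings of equal length.
#' @return distance >= 0.
#' @export
tajima_nei_distance <- function(seq_x, seq_y) {
  x <- toupper(as_sites(seq_x)); y <- toupper(as_sites(seq_y))
  if (length(x) != length(y)) stop("sequences differ in length")
  bases <- c("A", "C", "G", "T")
  ok <- x %in% bases & y %in% bases
  if (!any(ok)) stop("no jointly unambiguous site after pairwise deletion")
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  diff <- x != y
  p <- mean(diff)
  if (p == 0) return(0)
  g <- (table(factor(x, bases)) + table(factor(y, bases))) / (2 * n)
  h <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    xij <- sum((x == bases[i] & y == bases[j]) |
               (x == bases[j] & y == bases[i])) / n
    if (xij > 0) h <- h + xij^2 / (2 * g[i] * g[j])
  }
  b <- (1 - sum(g^2) + p^2 / h) / 2
  if (p >= b)
    stop(sprintf("saturation: p = %.4f >= b = %.4f, distance undefined", p, b))
  as.numeric(-b * log(1 - p / b))
}

as_sites <- function(s) {
  if (length(s) == 1L && nchar(s) > 1L) strsplit(s, "")[[1]] else as.character(s)
}

#' Breed-level distance matrices
#'
#' Computes, for every breed pair, the Tajima-Nei distance between breed
#' consensus sequences and the Weir-Cockerham weighted F_ST. Both matrices
#' are symmetric with a zero diagonal.
#'
#' @param ds a \code{genotype_dataset}.
#' @param clamp_fst report the at-0 clamped weighted F_ST.
#' @return list with matrices \code{tajima_nei} and \code{fst}, dimnames =
#'   breed labels.
#' @export
distance_matrix <- function(ds, clamp_fst = TRUE) {
  br <- breeds(ds)
  if (length(br) < 2L) stop("need at least 2 breeds")
  k <- length(br)
  tn <- fst <- matrix(0, k, k, dimnames = list(br, br))
  cons <- lapply(br, function(b) consensus_sequence(ds, b))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    tn[i, j] <- tn[j, i] <- tryCatch(
      tajima_nei_distance(cons[[i]], cons[[j]]),
      error = function(e) stop(sprintf("pair (%s, %s): %s", br[i], br[j],
                                       conditionMessage(e))))
    f <- tryCatch(wc_fst(ds, br[i], br[j]),
                  error = function(e) stop(sprintf("pair (%s, %s): %s",
                                                   br[i], br[j],
                                                   conditionMessage(e))))
    fst[i, j] <- fst[j, i] <- if (clamp_fst) f$weighted_clamped else f$weighted
  }
  list(tajima_nei = tn, fst = fst)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: repeatedly join the pair minimizing
#' \code{Q_ij = (r - 2) d_ij - R_i - R_j} (ties broken by lexicographic order
#' of the taxon-pair labels), with the standard branch-length and distance-
#' reduction formulas, finishing with the 3-taxon star resolution. Negative
#' branch lengths are clamped to 0 with the deficit transferred to the sister
#' branch (count in attribute \code{"n_clamped"}). The tree is unrooted
#' (trifurcating at the last join).
#'
#' @param dm symmetric numeric matrix with zero diagonal and taxon labels as
#'   dimnames, at least 3 taxa.
#' @return an \code{nj_tree}: list with \code{newick} (string, branch lengths
#'   included) and \code{labels}.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (is.null(rownames(dm))) stop("distance matrix needs taxon labels")
  if (nrow(dm) < 3L) stop("need at least 3 taxa")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(diag(dm) != 0)) stop("distance matrix diagonal must be zero")
  labels <- rownames(dm)
  nodes <- as.list(labels)          # newick fragment per active node
  key <- labels                     # lexicographic tie-break key per node
  n_clamped <- 0L
  clamp <- function(l1, l2) {
    # keep l1 + l2, move any deficit onto the sister branch
    if (l1 < 0) { l2 <- l2 + l1; l1 <- 0; n_clamped <<- n_clamped + 1L }
    if (l2 < 0) { l1 <- l1 + l2; l2 <- 0; n_clamped <<- n_clamped + 1L }
    c(max(l1, 0), max(l2, 0))
  }
  while (nrow(dm) > 3L) {
    r <- nrow(dm)
    R <- rowSums(dm)
    q <- (r - 2) * dm - outer(R, R, `+`)
    diag(q) <- Inf
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    if (nrow(best) > 1L) {
      pk <- apply(best, 1L, function(ij)
        paste(sort(c(key[ij[1]], key[ij[2]])), collapse = "\r"))
      best <- best[order(pk)[1], , drop = FALSE]
    }
    f <- best[1, 1]; g <- best[1, 2]
    lf <- dm[f, g] / 2 + (R[f] - R[g]) / (2 * (r - 2))
    lg <- dm[f, g] - lf
    l <- clamp(lf, lg)
    new_frag <- sprintf("(%s:%s,%s:%s)", nodes[[f]], fmt_bl(l[1]),
                        nodes[[g]], fmt_bl(l[2]))
    new_key <- min(key[f], key[g])
    du <- (dm[f, ] + dm[g, ] - dm[f, g]) / 2
    keep <- setdiff(seq_len(r), c(f, g))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    nodes <- c(nodes[keep], new_frag)
    key <- c(key[keep], new_key)
    rownames(dm) <- colnames(dm) <- key
  }
  # terminal 3-taxon star
  l1 <- (dm[1, 2] + dm[1, 3] - dm[2, 3]) / 2
  l2 <- (dm[1, 2] + dm[2, 3] - dm[1, 3]) / 2
  l3 <- (dm[1, 3] + dm[2, 3] - dm[1, 2]) / 2
  ls <- pmax(c(l1, l2, l3), 0)
  n_clamped <- n_clamped + sum(c(l1, l2, l3) < 0)
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    nodes[[1]], fmt_bl(ls[1]), nodes[[2]], fmt_bl(ls[2]),
                    nodes[[3]], fmt_bl(ls[3]))
  structure(list(newick = newick, labels = labels),
            class = "nj_tree", n_clamped = n_clamped)
}

fmt_bl <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)

#' @export
print.nj_tree <- function(x, ...) {
  cat("neighbour-joining tree over", length(x$labels), "taxa\n")
  cat(x$newick, "\n")
  invisible(x)
}

#' Write a tree to a Newick file
#' @param tree an \code{nj_tree}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_newick <- function(tree, path) {
  writeLines(tree$newick, path)
  invisible(path)
}

#' Write a distance matrix in PHYLIP format
#' @param dm labelled symmetric matrix.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_phylip <- function(dm, path) {
  lines <- c(sprintf("%5d", nrow(dm)),
             vapply(seq_len(nrow(dm)), function(i)
               paste0(formatC(rownames(dm)[i], width = -10),
                      paste(sprintf("%.6f", dm[i, ]), collapse = "  ")), ""))
  writeLines(lines, path)
  invisible(path)
}
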