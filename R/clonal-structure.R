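## Clonal population structure: pairwise mismatch distances, the
## clone-defining saddle threshold of the distance histogram, multilocus
## lineage (MLL) assignment and heterozygosity summaries.

#' Pairwise mismatch distance matrix
#'
#' Distance between two samples is the fraction of jointly non-missing
#' sites at which their genotype multisets differ.
#'
#' @param gm a [genotype_matrix()].
#' @param samples sample ids (default: all).
#' @return symmetric matrix of class `dist_matrix`; pairs with no
#'   overlap are `NA` with a warning.
#' @export
pairwise_mismatch <- function(gm, samples = colnames(gm$geno)) {
  stopifnot(length(samples) >= 2)
  g <- gm$geno[, samples, drop = FALSE]
  code <- matrix(match(g, sort(unique(as.vector(g)))), nrow(g))
  k <- length(samples)
  d <- matrix(0, k, k, dimnames = list(samples, samples))
  warned <- FALSE
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    use <- !is.na(code[, i]) & !is.na(code[, j])
    if (!any(use)) {
      d[i, j] <- d[j, i] <- NA_real_
      warned <- TRUE
    } else d[i, j] <- d[j, i] <- mean(code[use, i] != code[use, j])
  }
  if (warned) warning("sample pair(s) with zero site overlap: NA distance")
  class(d) <- c("dist_matrix", class(d))
  d
}

#' Detect the clone-defining saddle of the distance distribution
#'
#' Smooths the off-diagonal pairwise distances by a Gaussian kernel
#' density (Silverman's bandwidth by default) and returns the location
#' of the lowest internal minimum between the two dominant modes. A
#' unimodal distribution is an explicit error unless `fallback` gives a
#' user threshold.
#'
#' @param dist a [pairwise_mismatch()] matrix.
#' @param bandwidth density bandwidth (`"nrd0"` default; numeric ok).
#' @param fallback optional numeric threshold used when no saddle
#'   exists.
#' @return the threshold distance `d*`.
#' @export
find_saddle_threshold <- function(dist, bandwidth = "nrd0",
                                  fallback = NULL) {
  v <- dist[upper.tri(dist)]
  v <- v[!is.na(v)]
  if (length(unique(v)) < 2) {
    if (!is.null(fallback)) return(fallback)
    stop("distance distribution is degenerate (all values equal); ",
         "supply a user threshold")
  }
  den <- density(v, bw = bandwidth)
  y <- den$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                y[2:(n - 1)] >= y[3:n], FALSE)
  is_min <- c(FALSE, y[2:(n - 1)] < y[1:(n - 2)] &
                y[2:(n - 1)] <= y[3:n], FALSE)
  maxima <- which(is_max)
  mins <- which(is_min)
  if (length(maxima) >= 2)
    mins <- mins[mins > min(maxima) & mins < max(maxima)]
  if (length(maxima) < 2 || !length(mins)) {
    if (!is.null(fallback)) return(fallback)
    stop("distance density is unimodal: no saddle point; ",
         "supply a user threshold")
  }
  # the saddle is the deepest internal valley: the minimum whose
  # flanking peaks rise highest above it (robust to ripples on the
  # dominant mode)
  depth <- vapply(mins, function(m) {
    left <- max(y[maxima[maxima < m]])
    right <- max(y[maxima[maxima > m]])
    min(left, right) - y[m]
  }, numeric(1))
  den$x[mins[which.max(depth)]]
}

#' Assign multilocus lineages (MLLs)
#'
#' Single-linkage clustering: connected components of the graph joining
#' samples at distance `< d_star` (complete linkage available as
#' option). Ids are dense from 1, in order of first appearance.
#'
#' @param dist a [pairwise_mismatch()] matrix.
#' @param d_star threshold distance.
#' @param linkage `"single"` (default) or `"complete"`.
#' @return data.frame of class `mll_assignment` (`sample`, `mll`), with
#'   `d_star` attribute.
#' @export
assign_mll <- function(dist, d_star, linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(is.numeric(d_star), length(d_star) == 1)
  ids <- rownames(dist)
  k <- length(ids)
  if (linkage == "single") {
    parent <- seq_len(k)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (!is.na(dist[i, j]) && dist[i, j] < d_star) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
    root <- vapply(seq_len(k), find, integer(1))
  } else {
    hc <- stats::hclust(stats::as.dist(dist), method = "complete")
    root <- stats::cutree(hc, h = d_star)
  }
  mll <- match(root, unique(root))
  out <- data.frame(sample = ids, mll = mll, stringsAsFactors = FALSE)
  attr(out, "d_star") <- d_star
  class(out) <- c("mll_assignment", "data.frame")
  out
}

#' Observed heterozygosity of a sample
#'
#' Proportion of heterozygous calls among the sample's non-missing
#' sites that are variable within the ingroup.
#'
#' @param gm a [genotype_matrix()].
#' @param sample sample id.
#' @param ingroup_samples samples defining within-ingroup variability.
#' @return proportion in `[0, 1]`.
#' @export
heterozygosity <- function(gm, sample, ingroup_samples = colnames(gm$geno)) {
  g_in <- gm$geno[, ingroup_samples, drop = FALSE]
  variable <- vapply(seq_len(nrow(g_in)), function(i)
    length(site_alleles(g_in[i, ])) > 1, logical(1))
  g <- gm$geno[, sample]
  use <- variable & !is.na(g)
  if (!sum(use)) stop("no non-missing ingroup-variable sites for ", sample)
  mean(gt_is_het(g[use]))
}

#' Expected hybrid heterozygosity from parental pseudohaplotypes
#'
#' Splits each parental individual into two pseudohaplotypes without
#' phasing (heterozygous sites contribute their alleles in fixed sorted
#' order) and, for every cross of one side-A with one side-B
#' pseudohaplotype, reports the proportion of sites with differing
#' alleles -- the heterozygosity a fresh F1 hybrid would carry.
#'
#' @param gm a [genotype_matrix()].
#' @param parentsA,parentsB sample ids of the two parental species.
#' @param sites optional site index restriction.
#' @return numeric vector, one value per pseudohaplotype cross.
#' @export
expected_hybrid_heterozygosity <- function(gm, parentsA, parentsB,
                                           sites = seq_len(nrow(gm$geno))) {
  haps <- function(ids) {
    out <- list()
    for (s in ids) {
      g <- gm$geno[sites, s]
      a <- vapply(g, function(x) {
        al <- gt_alleles(x)
        if (!length(al)) NA_character_ else al[1]
      }, "", USE.NAMES = FALSE)
      b <- vapply(g, function(x) {
        al <- gt_alleles(x)
        if (!length(al)) NA_character_ else al[length(al)]
      }, "", USE.NAMES = FALSE)
      out <- c(out, list(a, b))
    }
    out
  }
  ha <- haps(parentsA)
  hb <- haps(parentsB)
  vals <- numeric(0)
  for (x in ha) for (y in hb) {
    use <- !is.na(x) & !is.na(y)
    if (any(use)) vals <- c(vals, mean(x[use] != y[use]))
  }
  vals
}
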