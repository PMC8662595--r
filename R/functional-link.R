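## Functional correlates of LOH: expression level, allele-specific
## expression divergence, dN/dS and gene-set enrichment.

#' TPM normalization
#'
#' `TPM_g = (count_g / length_g) / sum_h(count_h / length_h) * 1e6`.
#'
#' @param counts numeric matrix, genes x samples.
#' @param lengths effective gene lengths (> 0), one per gene.
#' @return TPM matrix; each column sums to 1e6.
#' @export
tpm_normalize <- function(counts, lengths) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths) == nrow(counts), all(lengths > 0))
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) stop("zero library after length scaling in column(s): ",
                          paste(which(tot == 0), collapse = ", "))
  sweep(rate, 2, tot, `/`) * 1e6
}

# Internal WMW wrapper shared by the comparison functions
wmw <- function(x, y, alternative = "two.sided", min_n = 3) {
  if (length(x) < min_n || length(y) < min_n) {
    warning("group below minimum size; test skipped")
    return(list(p = NA_real_, W = NA_real_, skipped = TRUE,
                mean_x = mean(x), mean_y = mean(y),
                n_x = length(x), n_y = length(y)))
  }
  wt <- suppressWarnings(wilcox.test(x, y, alternative = alternative))
  list(p = wt$p.value, W = unname(wt$statistic), skipped = FALSE,
       mean_x = mean(x), mean_y = mean(y),
       n_x = length(x), n_y = length(y))
}

#' Compare expression of LOH-positive vs LOH-negative genes
#'
#' Two-sided Wilcoxon-Mann-Whitney on TPM values per biotype/tissue
#' stratum, BH-corrected across strata. Only genes with a diagnostic
#' site (i.e. genes where LOH was detectable) should be supplied.
#'
#' @param tpm named numeric vector of gene TPM values for one stratum,
#'   or a list of such vectors (one per stratum).
#' @param loh_genes character vector of LOH-positive gene ids.
#' @return data.frame: stratum, group means, W, raw and adjusted p.
#' @export
compare_expression_by_loh <- function(tpm, loh_genes) {
  if (!is.list(tpm)) tpm <- list(all = tpm)
  rows <- lapply(names(tpm), function(st) {
    v <- tpm[[st]]
    pos <- v[names(v) %in% loh_genes]
    neg <- v[!names(v) %in% loh_genes]
    t <- wmw(pos, neg)
    data.frame(stratum = st, mean_loh = t$mean_x, mean_noloh = t$mean_y,
               n_loh = t$n_x, n_noloh = t$n_y, W = t$W, p = t$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}

#' Compare allelic log2 fold change by LOH direction
#'
#' WMW of side1/side2 allele-specific log2 fold change between genes
#' with a direction-specific LOH event and LOH-negative genes.
#'
#' @param log2fc named numeric vector (or list per stratum) of per-gene
#'   allelic log2 fold changes.
#' @param loh_genes genes with LOH of the direction under test.
#' @param background_genes LOH-negative genes (comparison group).
#' @return data.frame as in [compare_expression_by_loh()].
#' @export
compare_log2fc_by_loh <- function(log2fc, loh_genes, background_genes) {
  if (!is.list(log2fc)) log2fc <- list(all = log2fc)
  rows <- lapply(names(log2fc), function(st) {
    v <- log2fc[[st]]
    pos <- v[names(v) %in% loh_genes]
    neg <- v[names(v) %in% background_genes]
    t <- wmw(pos, neg)
    data.frame(stratum = st, mean_loh = t$mean_x, mean_noloh = t$mean_y,
               n_loh = t$n_x, n_noloh = t$n_y, W = t$W, p = t$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}

#' Compare dN/dS of LOH-positive vs LOH-negative genes
#'
#' One-sided WMW with alternative "LOH-positive genes have lower
#' dN/dS". (A linear mixed model with individual pairs as random factor
#' would be the fuller treatment; the rank test is the deliberate,
#' lighter substitute and is flagged in the result.)
#'
#' @param dnds named numeric vector of per-gene dN/dS values.
#' @param loh_genes LOH-positive gene ids.
#' @return list `p`, `W`, group medians, `n_dropped` (missing values),
#'   `method`.
#' @export
compare_dnds_by_loh <- function(dnds, loh_genes) {
  n_dropped <- sum(is.na(dnds))
  dnds <- dnds[!is.na(dnds)]
  pos <- dnds[names(dnds) %in% loh_genes]
  neg <- dnds[!names(dnds) %in% loh_genes]
  t <- wmw(pos, neg, alternative = "less")
  list(p = t$p, W = t$W, median_loh = median(pos),
       median_noloh = median(neg), n_loh = length(pos),
       n_noloh = length(neg), n_dropped = n_dropped,
       method = "one-sided WMW (rank substitute for mixed model)")
}

#' Hypergeometric gene-set enrichment with permutation correction
#'
#' Per term, the upper-tail hypergeometric probability of observing at
#' least the overlap between the test set and the term, within the
#' background. Family-wise correction is GO-structure-agnostic: the
#' corrected p of a term is the fraction of `n_perm` random test sets
#' (same size, drawn from the background) whose *minimum* per-term p is
#' at or below the term's observed p.
#'
#' @param test_genes LOH-positive gene ids (must be within background).
#' @param background all genes in which LOH was detectable.
#' @param term_map named list: term id -> character vector of genes.
#' @param n_perm permutation count for the corrected p.
#' @param seed integer seed.
#' @return data.frame: term, overlap (`k`), term size in background
#'   (`m`), p, p_corrected, sorted by p.
#' @export
hypergeom_enrichment <- function(test_genes, background, term_map,
                                 n_perm = 1000, seed = 1) {
  test_genes <- unique(test_genes)
  background <- unique(background)
  if (!all(test_genes %in% background))
    stop("test set must be a subset of the background")
  term_bg <- lapply(term_map, intersect, background)
  keep <- lengths(term_bg) > 0
  if (!all(keep))
    message(sum(!keep), " term(s) absent from background skipped")
  term_bg <- term_bg[keep]
  N <- length(background)
  n <- length(test_genes)
  m <- lengths(term_bg)
  k <- vapply(term_bg, function(g) length(intersect(g, test_genes)),
              integer(1))
  p <- phyper(k - 1, m, N - m, n, lower.tail = FALSE)

  memb <- vapply(term_bg, function(g) background %in% g,
                 logical(N))  # N x terms
  min_p <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    draw <- sample.int(N, n)
    kk <- colSums(memb[draw, , drop = FALSE])
    min(phyper(kk - 1, m, N - m, n, lower.tail = FALSE))
  }, numeric(1)))
  p_corr <- vapply(p, function(pp) mean(min_p <= pp), numeric(1))

  out <- data.frame(term = names(term_bg), overlap = k, term_size = m,
                    p = p, p_corrected = p_corr,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p), ]
}
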