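## LOH calling at diagnostic sites and its population patterns:
## sharing within clonal lineages, correlation with the private-SNP age
## proxy, parental retention bias, and the within-gene contiguity
## (clustering) permutation test.

#' Call loss of heterozygosity at diagnostic sites
#'
#' One call per diagnostic site at which the hybrid is homozygous for
#' either parental diagnostic allele. Heterozygous sites yield no call;
#' missing sites are skipped; homozygosity for a third allele (a private
#' mutation on top of the site) is excluded and counted.
#'
#' @param gm a filtered [genotype_matrix()].
#' @param diagset a [find_diagnostic_sites()] result.
#' @param sample hybrid sample id.
#' @return data.frame of class `loh_calls`: `contig`, `pos`, `gene`,
#'   `site`, `retained` (`"side1-like"`/`"side2-like"`),
#'   `retained_allele`, `lost_allele`; attributes `pair`,
#'   `n_excluded` (homozygous non-parental), `n_het`, `n_missing`.
#' @export
call_loh <- function(gm, diagset, sample) {
  g <- gm$geno[diagset$site, sample]
  hom1 <- !is.na(g) & g == diagset$allele1
  hom2 <- !is.na(g) & g == diagset$allele2
  het <- gt_is_het(g)
  hom_other <- !is.na(g) & !het & !hom1 & !hom2
  take <- hom1 | hom2
  out <- data.frame(contig = diagset$contig[take],
                    pos = diagset$pos[take],
                    gene = diagset$gene[take],
                    site = diagset$site[take],
                    retained = ifelse(hom1[take], "side1-like",
                                      "side2-like"),
                    retained_allele = ifelse(hom1[take],
                                             diagset$allele1[take],
                                             diagset$allele2[take]),
                    lost_allele = ifelse(hom1[take],
                                         diagset$allele2[take],
                                         diagset$allele1[take]),
                    stringsAsFactors = FALSE)
  attr(out, "pair") <- attr(diagset, "pair")
  attr(out, "sample") <- sample
  attr(out, "n_excluded") <- sum(hom_other)
  attr(out, "n_het") <- sum(het, na.rm = TRUE)
  attr(out, "n_missing") <- sum(is.na(g))
  class(out) <- c("loh_calls", "data.frame")
  out
}

#' Pairwise sharing of genotypes at LOH positions, by lineage
#'
#' For every pair of hybrids, the proportion of positions -- over the
#' union of the pair's LOH positions on a common diagnostic set -- at
#' which both individuals carry the same genotype. Same-MLL pairs are
#' compared against different-MLL pairs by a two-sided Wilcoxon rank-sum
#' test (exact below 50 observations per group).
#'
#' @param gm a filtered [genotype_matrix()].
#' @param diagset common diagnostic set (use the E-TN set when mixing
#'   hybrid types).
#' @param mll a [assign_mll()] result covering the hybrids.
#' @param hybrids sample ids (default: all samples in `mll`).
#' @return list with `pairs` (per-pair sharing data.frame) and `test`
#'   (`wilcox.test` result, or `NULL` with a warning when one group is
#'   empty).
#' @export
sharing_by_mll <- function(gm, diagset, mll, hybrids = mll$sample) {
  calls <- lapply(hybrids, function(s) call_loh(gm, diagset, s))
  names(calls) <- hybrids
  k <- length(hybrids)
  stopifnot(k >= 2)
  res <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    si <- hybrids[i]; sj <- hybrids[j]
    sites <- union(calls[[si]]$site, calls[[sj]]$site)
    if (!length(sites)) next
    gi <- gm$geno[sites, si]; gj <- gm$geno[sites, sj]
    use <- !is.na(gi) & !is.na(gj)
    if (!any(use)) next
    same_mll <- mll$mll[mll$sample == si] == mll$mll[mll$sample == sj]
    res[[length(res) + 1]] <- data.frame(
      sample1 = si, sample2 = sj,
      sharing = mean(gi[use] == gj[use]),
      n_positions = sum(use), same_mll = same_mll,
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, res)
  test <- NULL
  if (!is.null(pairs) && length(unique(pairs$same_mll)) == 2) {
    x <- pairs$sharing[pairs$same_mll]
    y <- pairs$sharing[!pairs$same_mll]
    exact <- length(x) < 50 && length(y) < 50
    test <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = exact,
                  correct = TRUE))
  } else {
    warning("need both same-MLL and different-MLL pairs for the test")
  }
  list(pairs = pairs, test = test)
}

#' Correlation between LOH proportion and private-SNP proportion
#'
#' Pearson correlation with Fisher-z confidence interval, across
#' individuals, of the per-individual LOH proportion against the
#' private-asexual SNP proportion (clone-age proxy).
#'
#' @param loh_prop,private_prop numeric vectors, one value per hybrid.
#' @param conf_level CI level.
#' @return list `r`, `ci`, `p`, `n`.
#' @export
loh_vs_private_correlation <- function(loh_prop, private_prop,
                                       conf_level = 0.95) {
  stopifnot(length(loh_prop) == length(private_prop))
  use <- complete.cases(loh_prop, private_prop)
  if (sum(use) < 3) stop("need >= 3 complete pairs")
  if (sd(loh_prop[use]) == 0 || sd(private_prop[use]) == 0)
    stop("zero variance in one of the inputs")
  ct <- cor.test(loh_prop[use], private_prop[use], method = "pearson",
                 conf.level = conf_level)
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
       p = ct$p.value, n = sum(use))
}

#' Parental retention bias at LOH sites
#'
#' Fraction of LOH calls retaining the side-1 (e.g. *C. elongatoides*)
#' allele, with a two-sided exact binomial test against 0.5.
#'
#' @param calls a [call_loh()] result.
#' @return list `fraction_side1`, `n`, `p`.
#' @export
retention_bias <- function(calls) {
  n <- nrow(calls)
  if (!n) stop("no LOH calls")
  k <- sum(calls$retained == "side1-like")
  bt <- binom.test(k, n, p = 0.5, alternative = "two.sided")
  list(fraction_side1 = k / n, n = n, p = bt$p.value)
}

# Internal: run-length clustering score from an ordered logical vector
# of LOH states (NA breaks or is dropped according to `missing_breaks`).
score_runs <- function(is_loh, missing_breaks = TRUE) {
  if (!missing_breaks) is_loh <- is_loh[!is.na(is_loh)]
  is_loh[is.na(is_loh)] <- FALSE
  r <- rle(is_loh)
  sum(r$lengths[r$values]^2)
}

#' Within-gene LOH contiguity score
#'
#' For each gene, maximal runs of consecutive diagnostic sites (in
#' gene-internal order) that are all LOH contribute `n_i^2`; the score
#' is the sum over genes and runs. Heterozygous diagnostic sites break
#' runs; missing genotypes break runs too by default (conservative --
#' an unknown state never bridges a gap).
#'
#' @param gm a filtered [genotype_matrix()].
#' @param diagset the sample's pair diagnostic set.
#' @param sample hybrid sample id.
#' @param missing_breaks logical; `FALSE` skips missing sites instead.
#' @return list `S` (observed score), `n_loh`, `states` (per-gene list
#'   of LOH state vectors, reused by the permutation test).
#' @export
clustering_score <- function(gm, diagset, sample, missing_breaks = TRUE) {
  g <- gm$geno[diagset$site, sample]
  is_loh <- ifelse(is.na(g), NA,
                   g == diagset$allele1 | g == diagset$allele2)
  is_loh[!is.na(g) & gt_is_het(g)] <- FALSE
  # homozygous third alleles are not LOH for the pair
  ord <- order(diagset$gene, diagset$pos)
  states <- split(is_loh[ord], diagset$gene[ord])
  S <- sum(vapply(states, score_runs, numeric(1),
                  missing_breaks = missing_breaks))
  list(S = S, n_loh = sum(is_loh, na.rm = TRUE), states = states)
}

#' Permutation test for LOH contiguity
#'
#' Redistributes the observed number of LOH sites uniformly over the
#' sample's non-missing diagnostic sites (across all genes), recomputes
#' the clustering score, and reports the add-one empirical p-value
#' `(1 + #{S_perm >= S_obs}) / (n_perm + 1)`.
#'
#' @inheritParams clustering_score
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return list `S_obs`, `p`, `n_loh`, `S_perm`.
#' @export
clustering_permutation <- function(gm, diagset, sample, n_perm = 999,
                                   seed = 1, missing_breaks = TRUE) {
  stopifnot(n_perm >= 100)
  cs <- clustering_score(gm, diagset, sample, missing_breaks)
  if (cs$n_loh == 0)
    return(list(S_obs = 0, p = 1, n_loh = 0, S_perm = numeric(0)))
  obs <- unlist(cs$states, use.names = FALSE)
  observable <- !is.na(obs)
  gene_of <- rep(names(cs$states), lengths(cs$states))
  n_sites <- sum(observable)
  L <- cs$n_loh
  # missing sites keep their place (as run breakers) but never receive
  # an LOH label; gene block boundaries are fixed across permutations
  blocks <- unname(split(seq_along(obs), gene_of))
  observable_idx <- which(observable)
  S_perm <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    lab <- logical(length(obs))
    lab[observable_idx[sample.int(n_sites, L)]] <- TRUE
    if (missing_breaks) lab[!observable] <- NA
    sum(vapply(blocks, function(ix) score_runs(lab[ix], missing_breaks),
               numeric(1)))
  }, numeric(1)))
  list(S_obs = cs$S, p = (1 + sum(S_perm >= cs$S)) / (n_perm + 1),
       n_loh = L, S_perm = S_perm)
}
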