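# LOH calling, sharing, retention bias, contiguity score & permutation.

test_that("call_loh: minimal semantics", {
  geno <- cbind(hyb = c("A", "A/G", "G", NA, "C"))
  gm <- genotype_matrix(geno, data.frame(contig = "g1", pos = 1:5))
  d <- manual_diagset(rep("A", 5), rep("G", 5))
  calls <- call_loh(gm, d, "hyb")
  expect_identical(calls$pos, c(1L, 3L))
  expect_identical(calls$retained, c("side1-like", "side2-like"))
  expect_identical(calls$lost_allele, c("G", "A"))
  expect_identical(attr(calls, "n_het"), 1L)
  expect_identical(attr(calls, "n_missing"), 1L)
  expect_identical(attr(calls, "n_excluded"), 1L)  # the C homozygote
})

test_that("call_loh agrees exactly with the truth ledger on zero-noise data", {
  w <- shared_world()
  calls <- call_loh(w$gm, w$diag, "hyb1")
  led <- w$clone$ledger
  truth_sites <- which(!is.na(led$retained_ancestry) &
                         led$mechanism != "none")
  # sensitivity and specificity 1 against the ledger
  expect_setequal(calls$site, truth_sites)
  expect_identical(
    calls$retained[order(calls$site)],
    ifelse(led$retained_ancestry[truth_sites] == "E-like",
           "side1-like", "side2-like"))
})

test_that("clustering score: direct application of S = sum n_i^2", {
  gm <- genotype_matrix(
    cbind(h = c("A", "A", "A", "A/G", "A/G",   # gene a: [L,L,L,H,H] -> 9
                "A", "A/G", "A", "A/G", "A")), # gene b: [L,H,L,H,L] -> 3
    data.frame(contig = rep(c("ga", "gb"), each = 5), pos = rep(1:5, 2)))
  d <- manual_diagset(rep("A", 10), rep("G", 10),
                      gene = rep(c("ga", "gb"), each = 5))
  cs <- clustering_score(gm, d, "h")
  expect_identical(cs$S, 12)
  expect_identical(cs$n_loh, 6L)
  # no LOH -> 0
  gm0 <- gm; gm0$geno[, 1] <- "A/G"
  expect_identical(clustering_score(gm0, d, "h")$S, 0)
  # run decomposition partitions the LOH sites: sum n_i = n_loh
  r <- rle(c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE,
             TRUE))
  expect_identical(sum(r$lengths[r$values]), 6L)
})

test_that("missing genotypes break runs by default, bridge when skipped", {
  gm <- genotype_matrix(cbind(h = c("A", NA, "A")),
                        data.frame(contig = "g", pos = 1:3))
  d <- manual_diagset(rep("A", 3), rep("G", 3))
  expect_identical(clustering_score(gm, d, "h")$S, 2)              # 1+1
  expect_identical(clustering_score(gm, d, "h",
                                    missing_breaks = FALSE)$S, 4)  # 2^2
})

test_that("S is invariant to gene order and ancestry relabelling", {
  w <- shared_world()
  S1 <- clustering_score(w$gm, w$diag, "hyb1")$S
  perm <- sample(nrow(w$diag))
  dperm <- w$diag[perm, ]
  attr(dperm, "pair") <- attr(w$diag, "pair")
  class(dperm) <- class(w$diag)
  expect_identical(clustering_score(w$gm, dperm, "hyb1")$S, S1)
  # swapping which side is allele1/allele2 leaves LOH runs unchanged
  dswap <- w$diag
  dswap$allele1 <- w$diag$allele2
  dswap$allele2 <- w$diag$allele1
  expect_identical(clustering_score(w$gm, dswap, "hyb1")$S, S1)
})

test_that("permutation p: trivial conventions and add-one floor", {
  gm <- genotype_matrix(cbind(h = c("A", "A/G", "A/G")),
                        data.frame(contig = "g", pos = 1:3))
  d <- manual_diagset(rep("A", 3), rep("G", 3))
  # single LOH site: every permutation scores 1 -> p = 1
  res <- clustering_permutation(gm, d, "h", n_perm = 199, seed = 1)
  expect_identical(res$p, 1)
  # zero LOH -> p = 1 by convention
  gm0 <- gm; gm0$geno[, 1] <- "A/G"
  expect_identical(clustering_permutation(gm0, d, "h", n_perm = 199,
                                          seed = 1)$p, 1)
  expect_error(clustering_permutation(gm, d, "h", n_perm = 10), "100")
  # p can never be 0
  w <- shared_world()
  r <- clustering_permutation(w$gm, w$diag, "hyb1", n_perm = 199,
                              seed = 2)
  expect_gt(r$p, 0)
})

test_that("retention bias: arithmetic and exact binomial", {
  calls <- data.frame(retained = c(rep("side1-like", 80),
                                   rep("side2-like", 20)))
  rb <- retention_bias(calls)
  expect_equal(rb$fraction_side1, 0.8)
  expect_equal(rb$p, binom.test(80, 100)$p.value)
  expect_equal(retention_bias(
    data.frame(retained = rep(c("side1-like", "side2-like"), 50)))$p, 1)
  expect_error(retention_bias(calls[0, , drop = FALSE]), "no LOH")
})

test_that("template bias 0.87 is recovered through call_loh", {
  lay <- genome_layout(n_genes = 1500, sites_per_gene = 10,
                       fraction_diagnostic = c("E-T" = 1),
                       fraction_shared = 0, fraction_private = 0,
                       jitter_sites = FALSE)
  par <- simulate_parents(lay, c(E = 4, T = 4), seed = 31)
  cl <- simulate_clone(par, clone_spec(c("E", "T"),
                                       conversion_rate = 0.7,
                                       tract_length = 1,
                                       template_bias_E = 0.87,
                                       name = "h"), seed = 32)
  comb <- combine_genotypes(par, list(cl))
  d <- find_diagnostic_sites(comb$gm, comb$meta, "E", "T")
  rb <- retention_bias(call_loh(comb$gm, d, "h"))
  expect_gt(rb$n, 9000)
  expect_lt(abs(rb$fraction_side1 - 0.87), 0.015)
})

test_that("LOH/private correlation: closed form and degeneracies", {
  r <- loh_vs_private_correlation(c(1, 2, 3, 4) / 10,
                                  c(2, 4, 6, 8) / 100)
  expect_equal(r$r, 1)
  # 4-point toy against the closed-form Pearson formula
  x <- c(0.01, 0.04, 0.02, 0.08); y <- c(0.1, 0.5, 0.15, 0.7)
  rr <- loh_vs_private_correlation(x, y)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(rr$r, num / den)
  expect_identical(rr$n, 4L)
  expect_error(loh_vs_private_correlation(c(1, 1, 1), c(1, 2, 3)),
               "zero variance")
  expect_error(loh_vs_private_correlation(1:2 / 10, 1:2 / 10), ">= 3")
})

test_that("sharing is near 1 within a clone family, tested across MLLs", {
  fam <- make_clone_family_gm(n_clones = 3, seed = 23,
                              mates_per_clone = c(3, 3, 2))
  par <- fam$parents
  comb_meta <- sample_meta(samples(fam$gm), "hybrid", "ET", 2)
  pmeta <- par$meta
  gm_all <- genotype_matrix(cbind(par$gm$geno, fam$gm$geno),
                            par$gm$sites)
  meta_all <- sample_meta(c(pmeta$sample, comb_meta$sample),
                          c(pmeta$class, comb_meta$class),
                          c(pmeta$label, comb_meta$label),
                          c(pmeta$ploidy, comb_meta$ploidy))
  diag <- find_diagnostic_sites(gm_all, meta_all, "E", "T")
  mll <- data.frame(sample = samples(fam$gm), mll = fam$truth)
  rep <- sharing_by_mll(gm_all, diag, mll)
  same <- rep$pairs$sharing[rep$pairs$same_mll]
  diff <- rep$pairs$sharing[!rep$pairs$same_mll]
  # clone-mates share all ancestral events; the few individual-private
  # conversions the generator adds keep sharing just below 1
  expect_gt(min(same), 0.8)
  expect_gt(mean(same), 0.85)
  expect_gt(mean(same), mean(diff))
  expect_s3_class(rep$test, "htest")
  # single MLL: no test, warning
  mll1 <- data.frame(sample = samples(fam$gm)[1:3], mll = 1L)
  expect_warning(r1 <- sharing_by_mll(gm_all, diag, mll1,
                                      hybrids = mll1$sample),
                 "same-MLL")
  expect_null(r1$test)
})
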