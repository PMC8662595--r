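# Generator: parental panels, clones with truth ledger, capture depth.

test_that("degenerate layout: all sites diagnostic, parents fully homozygous", {
  lay <- genome_layout(n_genes = 20, sites_per_gene = 5,
                       fraction_diagnostic = c("E-T" = 1),
                       fraction_shared = 0, fraction_private = 0,
                       jitter_sites = FALSE)
  par <- simulate_parents(lay, c(E = 4, T = 4), seed = 1)
  expect_true(all(par$sites$category == "diag:E-T"))
  expect_false(any(gt_is_het(par$gm$geno)))
  expect_true(all(truth_diagnostic(par, "E", "T")))
})

test_that("invalid layout proportions are a configuration error", {
  expect_error(genome_layout(fraction_diagnostic = c("E-T" = 0.8),
                             fraction_shared = 0.3),
               "sum to <= 1")
  expect_error(genome_layout(fraction_diagnostic = c(0.2)), "named")
})

test_that("diagnostic fraction 0.2 over 10,000 sites: independent recount", {
  lay <- genome_layout(n_genes = 1250, sites_per_gene = 8,
                       fraction_diagnostic = c("E-T" = 0.2),
                       fraction_shared = 0, fraction_private = 0,
                       jitter_sites = FALSE)
  par <- simulate_parents(lay, c(E = 10, T = 10), seed = 42)
  g <- par$gm$geno
  eg <- g[, par$meta$sample[par$meta$label == "E"]]
  tg <- g[, par$meta$sample[par$meta$label == "T"]]
  # brute-force recount over the emitted matrix, independent of the
  # generator's flags: one allele state per side, sides differ
  one_state <- function(m) apply(m, 1, function(r)
    length(unique(r[!is.na(r)])) == 1 && !any(gt_is_het(r), na.rm = TRUE))
  recount <- sum(one_state(eg) & one_state(tg) & eg[, 1] != tg[, 1])
  truth_n <- sum(par$sites$category == "diag:E-T")
  expect_identical(recount, truth_n)
  expect_lt(abs(recount - 2000), 4 * sqrt(10000 * 0.2 * 0.8))
})

test_that("no-event clone is heterozygous at every pair-diagnostic site", {
  w <- shared_world()
  cl0 <- simulate_clone(w$parents, clone_spec(c("E", "T"), name = "z"),
                        seed = 5)
  d <- truth_diagnostic(w$parents, "E", "T")
  expect_true(all(gt_is_het(cl0$genotype[d])))
  expect_true(all(cl0$ledger$mechanism == "none"))
  expect_true(all(cl0$copy_number == 2))
})

test_that("double deletion in a diploid is a configuration error", {
  expect_error(clone_spec(c("E", "T"), double_deletion_rate = 0.01),
               "diploid")
})

test_that("ledger copy-number semantics: conversions conserve, deletions subtract", {
  w <- shared_world()
  led <- w$clone$ledger
  expect_true(all(led$copy_number[led$mechanism == "conversion"] == 2))
  expect_true(all(led$copy_number[led$mechanism == "hemi_deletion"] == 1))
  # triploid: double deletions leave exactly one copy
  tri <- simulate_clone(w$parents, clone_spec(
    c("E", "E", "T"), hemi_deletion_rate = 0.01,
    double_deletion_rate = 0.01, name = "tri"), seed = 9)
  led3 <- tri$ledger
  expect_true(all(led3$copy_number[led3$mechanism == "hemi_deletion"] == 2))
  expect_true(all(led3$copy_number[led3$mechanism == "double_deletion"] == 1))
  expect_true(all(led3$copy_number >= 1))
  # per-subgenome bookkeeping adds up
  expect_equal(rowSums(tri$copy_by_sub), tri$copy_number)
})

test_that("ledger and genotypes are mutually consistent at diagnostic sites", {
  w <- shared_world()
  d <- truth_diagnostic(w$parents, "E", "T")
  active <- w$clone$ledger$mechanism != "none" & d
  expect_true(all(!gt_is_het(w$clone$genotype[active])))
  expect_true(all(!is.na(w$clone$ledger$retained_ancestry[active])))
})

test_that("tract process matches an independent Monte-Carlo oracle", {
  # 20-site gene, initiation rate r, geometric tracts of mean 3.
  r <- 0.05; tl <- 3; n_sites <- 20
  oracle_reps <- 1e5
  set.seed(314)
  covered <- replicate(oracle_reps, {
    starts <- which(runif(n_sites) < r)
    if (!length(starts)) return(0)
    len <- 1L + rgeom(length(starts), 1 / tl)
    hit <- logical(n_sites)
    for (i in seq_along(starts))
      hit[starts[i]:min(starts[i] + len[i] - 1L, n_sites)] <- TRUE
    mean(hit)
  })
  lay <- genome_layout(n_genes = 1, sites_per_gene = n_sites,
                       fraction_diagnostic = c("E-T" = 1),
                       fraction_shared = 0, fraction_private = 0,
                       jitter_sites = FALSE)
  par <- simulate_parents(lay, c(E = 2, T = 2), seed = 8)
  sim_reps <- 400
  frac <- vapply(seq_len(sim_reps), function(k) {
    cl <- simulate_clone(par, clone_spec(c("E", "T"),
                                         conversion_rate = r,
                                         tract_length = tl, name = "x"),
                         seed = 9000 + k)
    mean(cl$ledger$mechanism != "none")
  }, numeric(1))
  se <- sqrt(var(covered) / oracle_reps + var(frac) / sim_reps)
  expect_lt(abs(mean(frac) - mean(covered)), 3 * se)
})

test_that("conversion template bias is recovered (binomial CI, n ~ 1e4)", {
  lay <- genome_layout(n_genes = 2000, sites_per_gene = 10,
                       fraction_diagnostic = c("E-T" = 1),
                       fraction_shared = 0, fraction_private = 0,
                       jitter_sites = FALSE)
  par <- simulate_parents(lay, c(E = 3, T = 3), seed = 21)
  b <- 0.87
  cl <- simulate_clone(par, clone_spec(c("E", "T"),
                                       conversion_rate = 0.5,
                                       tract_length = 1,
                                       template_bias_E = b,
                                       name = "x"), seed = 22)
  ra <- cl$ledger$retained_ancestry[cl$ledger$mechanism == "conversion"]
  ra <- ra[!is.na(ra)]
  expect_gt(length(ra), 5000)
  phat <- mean(ra == "E-like")
  ci99 <- qnorm(0.995) * sqrt(b * (1 - b) / length(ra))
  expect_lt(abs(phat - b), ci99 * 1.2)  # small slack over the 99% CI
})

test_that("age-driven private mutations are heterozygous at monomorphic sites", {
  w <- shared_world()
  cl <- simulate_clone(w$parents, clone_spec(c("E", "T"), age = 0.2,
                                             name = "aged"), seed = 33)
  mono <- w$parents$sites$category == "mono"
  changed <- !is.na(cl$genotype) & mono &
    cl$genotype != w$parents$sites$allele1
  expect_gt(sum(changed), 10)
  expect_true(all(gt_is_het(cl$genotype[changed])))
  non_mono_events <- !mono & !is.na(cl$genotype) &
    gt_is_het(cl$genotype) & cl$ledger$mechanism == "none"
  # no private mutation placed outside monomorphic sites
  expect_false(any(grepl("[^ACGT/]", cl$genotype[!mono])))
})

test_that("depth model: Poisson limit gives variance ~ mean", {
  lay <- genome_layout(n_genes = 500, sites_per_gene = 10,
                       fraction_diagnostic = c("E-T" = 1),
                       fraction_shared = 0, fraction_private = 0,
                       jitter_sites = FALSE)
  par <- simulate_parents(lay, c(E = 2, T = 2), seed = 3)
  dep <- simulate_depth(par, list(), coverage_params(
    site_efficiency_sd = 0, dispersion = Inf,
    individual_depth_sd = 0), seed = 4)
  x <- dep$depth[, 1]
  expect_lt(abs(var(x) / mean(x) - 1), 0.15)
  expect_true(all(dep$depth >= 0 & dep$depth == round(dep$depth)))
})

test_that("identical seeds give identical output; different seeds differ", {
  lay <- genome_layout(n_genes = 30, sites_per_gene = 5,
                       fraction_diagnostic = c("E-T" = 0.3))
  p1 <- simulate_parents(lay, c(E = 3, T = 3), seed = 11)
  p2 <- simulate_parents(lay, c(E = 3, T = 3), seed = 11)
  p3 <- simulate_parents(lay, c(E = 3, T = 3), seed = 12)
  expect_identical(p1$gm$geno, p2$gm$geno)
  expect_false(identical(p1$gm$geno, p3$gm$geno))
})

test_that("fixtures round-trip and honour the file contracts", {
  w <- shared_world()
  dep <- simulate_depth(w$parents, list(w$clone), coverage_params(),
                        seed = 55)
  out <- withr::local_tempdir()
  fx <- emit_fixtures(w$parents, list(w$clone), dep, out)
  rt <- read_genotypes(fx$vcf, fx$meta)
  expect_identical(rt$gm$geno, w$gm$geno)
  expect_identical(rt$gm$sites$contig, w$gm$sites$contig)
  expect_identical(rt$gm$sites$pos, w$gm$sites$pos)
  # DP round-trips from the depth table
  expect_equal(unname(rt$gm$dp), unname(dep$depth[, samples(rt$gm)]))
  # truth TSV completeness: one row per clone per site
  truth <- read.delim(fx$truth)
  expect_identical(nrow(truth), nrow(w$parents$sites) * 1L)
  # VCF header declares the layout's gene ids as contigs
  hdr <- grep("^##contig", readLines(fx$vcf), value = TRUE)
  expect_setequal(sub("##contig=<ID=(.*)>", "\\1", hdr),
                  unique(w$parents$sites$gene))
  # depth TSV round-trip
  dt <- read_depth(fx$depth)
  expect_equal(unname(dt$depth), unname(dep$depth))
})

test_that("parental relative coverage against the panel is centred at 1", {
  lay <- genome_layout(n_genes = 250, sites_per_gene = 10,
                       fraction_diagnostic = c("E-T" = 1),
                       fraction_shared = 0, fraction_private = 0,
                       jitter_sites = FALSE)
  par <- simulate_parents(lay, c(E = 10, T = 10), seed = 61)
  dep <- simulate_depth(par, list(), coverage_params(), seed = 62)
  normed <- normalize_depth(dep)
  panel <- samples(par$gm)
  for (s in panel[c(1, 8, 15)]) {
    rc <- relative_coverage(normed, s, setdiff(panel, s),
                            seq_len(2500))
    expect_lt(abs(mean(rc) - 1), 0.02)
  }
})
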