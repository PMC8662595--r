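## End-to-end simulation experiments: convenience wrappers that chain
## the generator and the analysis stages, used by the worked examples
## and the acceptance checks.

#' Combine parental panel and clones into one genotype matrix
#'
#' @param parents a [simulate_parents()] result.
#' @param clones list of [simulate_clone()] results.
#' @param depth optional [depth_table()] supplying per-call DP.
#' @return list `gm`, `meta` covering parents and clones.
#' @export
combine_genotypes <- function(parents, clones = list(), depth = NULL) {
  if (inherits(clones, "clone_sim")) clones <- list(clones)
  geno <- parents$gm$geno
  for (cl in clones) {
    geno <- cbind(geno, cl$genotype)
    colnames(geno)[ncol(geno)] <- cl$name
  }
  dp <- if (!is.null(depth))
    depth$depth[, colnames(geno), drop = FALSE] else NULL
  meta <- rbind(
    data.frame(parents$meta, stringsAsFactors = FALSE),
    do.call(rbind, lapply(clones, function(cl)
      data.frame(sample = cl$name, class = "hybrid",
                 label = paste(cl$composition, collapse = ""),
                 ploidy = length(cl$composition),
                 stringsAsFactors = FALSE))))
  list(gm = genotype_matrix(geno, parents$gm$sites, dp = dp),
       meta = sample_meta(meta$sample, meta$class, meta$label,
                          meta$ploidy))
}

#' Simulated LOH coverage experiment
#'
#' Simulates a parental panel, one clonal hybrid with the given tract
#' event rates, and capture depth; finds diagnostic sites, calls LOH,
#' normalizes depth by total read count, and returns relative coverage
#' at the hybrid's LOH sites labelled by true mechanism. The default
#' genome (190,000 sites) keeps the hybrid's ~2,000 events a small
#' fraction of the exome, as in real capture data, so that total-count
#' normalization is essentially unaffected by the deletions themselves.
#'
#' @param composition subgenome letters, e.g. `c("E","T")`.
#' @param conversion_rate,hemi_deletion_rate,double_deletion_rate tract
#'   initiation rates per site.
#' @param tract_length mean geometric tract length.
#' @param n_genes,sites_per_gene genome size (all sites diagnostic for
#'   the hybrid's pair); the default 190,000 sites matches the scale of
#'   a quality-filtered fish exome SNP set.
#' @param n_per_species parental individuals per species.
#' @param params a [coverage_params()].
#' @param seed integer seed.
#' @return list with `relcov` (relative coverage at usable LOH sites),
#'   `mechanism` (matched truth labels), `calls`, `diag`, `normed`,
#'   `clone`, `parents`, `parental_panel`.
#' @export
simulate_loh_coverage <- function(composition,
                                  conversion_rate = 0,
                                  hemi_deletion_rate = 0,
                                  double_deletion_rate = 0,
                                  tract_length = 1,
                                  n_genes = 9500, sites_per_gene = 20,
                                  n_per_species = 10,
                                  params = coverage_params(),
                                  seed = 1) {
  sides <- unique(composition)
  stopifnot(length(sides) == 2)
  s1 <- if ("E" %in% sides) "E" else sides[1]
  s2 <- setdiff(sides, s1)
  seeds <- derive_seeds(seed, 3)
  layout <- genome_layout(
    n_genes = n_genes, sites_per_gene = sites_per_gene,
    fraction_diagnostic = setNames(1, paste(s1, s2, sep = "-")),
    fraction_shared = 0, fraction_private = 0, jitter_sites = FALSE)
  species <- setNames(rep(n_per_species, 2), c(s1, s2))
  parents <- simulate_parents(layout, species, seed = seeds[1])
  spec <- clone_spec(composition,
                     conversion_rate = conversion_rate,
                     hemi_deletion_rate = hemi_deletion_rate,
                     double_deletion_rate = double_deletion_rate,
                     tract_length = tract_length, name = "hyb1")
  clone <- simulate_clone(parents, spec, seed = seeds[2])
  depth <- simulate_depth(parents, list(clone), params, seed = seeds[3])

  comb <- combine_genotypes(parents, list(clone))
  diag <- find_diagnostic_sites(comb$gm, comb$meta, s1, s2)
  calls <- call_loh(comb$gm, diag, "hyb1")
  normed <- normalize_depth(depth)
  panel <- samples(parents$gm)
  rc <- relative_coverage(normed, "hyb1", panel, calls$site)
  # relative_coverage drops unusable sites in order; recover the map
  ref <- rowMeans(normed$depth[calls$site, panel, drop = FALSE],
                  na.rm = TRUE)
  ok <- !is.na(ref) & ref > 0 & !is.na(normed$depth[calls$site, "hyb1"])
  mech <- clone$ledger$mechanism[calls$site][ok]
  list(relcov = as.numeric(rc), mechanism = mech, calls = calls,
       diag = diag, normed = normed, clone = clone, parents = parents,
       parental_panel = panel)
}
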