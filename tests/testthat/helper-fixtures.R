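# Shared fixtures: built in code, once per test run.

# Hand-built 10-site, 5-sample matrix exercising the filter rules:
# sites 1-7 clean biallelic, site 8-9 triallelic, site 10 all-low-GQ.
tiny_gm <- function() {
  geno <- rbind(
    c("A",   "A",   "A/G", "G",   "A/G"),
    c("C",   "C/T", "C",   "T",   "C"),
    c("G",   "G",   "G",   "G",   "G"),
    c("A/T", "A",   "T",   "A/T", "T"),
    c("C",   "C",   "C/G", "C/G", "G"),
    c("T",   "T",   "T",   "A/T", "A"),
    c("G",   "A/G", "A",   "G",   "A"),
    c("A",   "A/G", "T",   "A",   "A"),   # triallelic {A,G,T}
    c("C",   "C/G", "T",   "C",   "C"),   # triallelic {C,G,T}
    c("A",   "A/G", "G",   "A",   "G"))   # all GQ below threshold
  colnames(geno) <- c("s1", "s2", "s3", "s4", "s5")
  dp <- matrix(30, 10, 5, dimnames = dimnames(geno))
  gq <- matrix(99, 10, 5, dimnames = dimnames(geno))
  gq[10, ] <- 19
  sites <- data.frame(contig = rep(c("gA", "gB"), each = 5),
                      pos = rep(1:5, 2))
  genotype_matrix(geno, sites, dp = dp, gq = gq)
}

# Small simulated world shared across variant-table / LOH tests:
# E-T diagnostic plus private and monomorphic sites, 10 parents per
# species -- large enough that realized diagnostic sites equal truth.
shared_world <- local({
  w <- NULL
  function() {
    if (is.null(w)) {
      lay <- genome_layout(n_genes = 150, sites_per_gene = 6,
                           fraction_diagnostic = c("E-T" = 0.35),
                           fraction_shared = 0.05,
                           fraction_private = 0.10)
      par <- simulate_parents(lay, c(E = 10, T = 10), seed = 101)
      cl <- simulate_clone(par, clone_spec(
        c("E", "T"), conversion_rate = 0.02, hemi_deletion_rate = 0.005,
        tract_length = 3, name = "hyb1"), seed = 102)
      comb <- combine_genotypes(par, list(cl))
      diag <- find_diagnostic_sites(comb$gm, comb$meta, "E", "T")
      w <<- list(parents = par, clone = cl, gm = comb$gm,
                 meta = comb$meta, diag = diag)
    }
    w
  }
})

# Genotype matrix of several simulated clonal families (clone-mates =
# shared ancestral events + individual private mutations).
make_clone_family_gm <- function(n_clones = 11, seed = 7,
                                 mates_per_clone = NULL) {
  lay <- genome_layout(n_genes = 250, sites_per_gene = 6,
                       fraction_diagnostic = c("E-T" = 0.5),
                       fraction_shared = 0, fraction_private = 0)
  par <- simulate_parents(lay, c(E = 4, T = 4), seed = seed)
  n_sites <- nrow(par$sites)
  set.seed(seed + 1)
  if (is.null(mates_per_clone))
    mates_per_clone <- sample(2:4, n_clones, replace = TRUE)
  cols <- list(); labs <- character(0); truth <- integer(0)
  for (k in seq_len(n_clones)) {
    anc <- simulate_clone(par, clone_spec(
      c("E", "T"), conversion_rate = 0.05, tract_length = 3,
      name = sprintf("c%02d", k)), seed = seed + 100 + k)
    for (m in seq_len(mates_per_clone[k])) {
      g <- anc$genotype
      # individual-private events: a few extra conversions
      mut <- sample(n_sites, 8)
      g[mut] <- par$sites$allele1[mut]
      cols[[length(cols) + 1]] <- g
      labs <- c(labs, sprintf("c%02d_m%d", k, m))
      truth <- c(truth, k)
    }
  }
  hyb <- do.call(cbind, cols)
  colnames(hyb) <- labs
  list(gm = genotype_matrix(hyb, par$gm$sites), truth = truth,
       parents = par)
}

# Hand-built diagnostic set (data.frame contract of
# find_diagnostic_sites) for unit tests that need full control.
manual_diagset <- function(allele1, allele2, gene = NULL, pair = "E-T") {
  n <- length(allele1)
  out <- data.frame(contig = gene %||% rep("g1", n),
                    pos = seq_len(n),
                    gene = gene %||% rep("g1", n),
                    allele1 = allele1, allele2 = allele2,
                    site = seq_len(n), stringsAsFactors = FALSE)
  attr(out, "pair") <- pair
  class(out) <- c("diagnostic_set", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
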