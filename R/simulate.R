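## Synthetic hybrid-genome generator.
##
## The generator emulates the statistical world the analysis assumes:
## two or three sexual parental species fixed for different alleles at
## species-diagnostic sites plus shared and private polymorphism; clonal
## diploid/triploid hybrids that start fully heterozygous at the
## diagnostic sites of their parental pair and then accumulate tract
## events (gene conversions, hemizygous deletions, double deletions) and
## age-dependent private mutations; and capture-style sequencing depth
## with a per-site efficiency shared across individuals. Every event is
## recorded in a truth ledger so that recovery can be tested exactly.

#' Genome layout for the simulator
#'
#' Describes the simulated transcriptome: number of genes (= contigs),
#' sites per gene, and the mixture of site categories. Remaining mass
#' (1 - sum of fractions) is monomorphic across all parents; private
#' hybrid mutations are only ever placed there.
#'
#' @param n_genes number of genes/contigs.
#' @param sites_per_gene expected SNP sites per gene; drawn as
#'   `1 + Poisson(sites_per_gene - 1)` unless `jitter_sites = FALSE`.
#' @param fraction_diagnostic named numeric of per-pair diagnostic
#'   proportions; names like `"E-T"`, `"E-N"`, `"E-TN"` (a multi-letter
#'   second side means the listed species are jointly fixed).
#' @param fraction_shared proportion of sites polymorphic in all species.
#' @param fraction_private proportion of sites polymorphic in exactly one
#'   species.
#' @param jitter_sites logical; fixed site count per gene when `FALSE`.
#' @return list of class `genome_layout`.
#' @export
genome_layout <- function(n_genes = 500, sites_per_gene = 8,
                          fraction_diagnostic = c("E-T" = 0.10,
                                                  "E-N" = 0.08,
                                                  "E-TN" = 0.07),
                          fraction_shared = 0.05,
                          fraction_private = 0.10,
                          jitter_sites = TRUE) {
  tot <- sum(fraction_diagnostic) + fraction_shared + fraction_private
  if (any(c(fraction_diagnostic, fraction_shared, fraction_private) < 0) ||
      tot > 1 + 1e-12)
    stop("site-category proportions must be non-negative and sum to <= 1")
  if (is.null(names(fraction_diagnostic)) && length(fraction_diagnostic))
    stop("fraction_diagnostic must be named by species pair, e.g. 'E-T'")
  structure(list(n_genes = n_genes, sites_per_gene = sites_per_gene,
                 fraction_diagnostic = fraction_diagnostic,
                 fraction_shared = fraction_shared,
                 fraction_private = fraction_private,
                 jitter_sites = jitter_sites),
            class = "genome_layout")
}

#' Clone specification
#'
#' @param composition character vector of subgenome letters, one per
#'   haploid genome copy (e.g. `c("E","T")`, `c("E","E","T")`).
#' @param age expected private mutations per monomorphic site (clone-age
#'   proxy).
#' @param conversion_rate,hemi_deletion_rate,double_deletion_rate
#'   expected tract initiations per site.
#' @param tract_length mean tract length (geometric law, in gene-internal
#'   site units; tracts truncate at gene boundaries since the reference
#'   is transcriptome-based and physical distance across genes is
#'   meaningless).
#' @param template_bias_E probability that a conversion uses the `"E"`
#'   subgenome as template (retains the E allele).
#' @param gc_template_bias extra multiplicative weight, per tract site at
#'   which a side carries G or C, in favour of that side as conversion
#'   template. 0 disables GC bias.
#' @param name sample id of the clone.
#' @return list of class `clone_spec`.
#' @export
clone_spec <- function(composition, age = 0,
                       conversion_rate = 0, hemi_deletion_rate = 0,
                       double_deletion_rate = 0, tract_length = 3,
                       template_bias_E = 0.8, gc_template_bias = 0,
                       name = paste(composition, collapse = "")) {
  stopifnot(length(composition) %in% c(2L, 3L),
            age >= 0, conversion_rate >= 0, hemi_deletion_rate >= 0,
            double_deletion_rate >= 0, tract_length >= 1,
            template_bias_E >= 0, template_bias_E <= 1,
            gc_template_bias >= 0)
  if (length(composition) == 2L && double_deletion_rate > 0)
    stop("double deletions are impossible in a diploid clone")
  structure(list(composition = composition, age = age,
                 conversion_rate = conversion_rate,
                 hemi_deletion_rate = hemi_deletion_rate,
                 double_deletion_rate = double_deletion_rate,
                 tract_length = tract_length,
                 template_bias_E = template_bias_E,
                 gc_template_bias = gc_template_bias, name = name),
            class = "clone_spec")
}

#' Capture-depth model parameters
#'
#' Expected depth at a site is
#' `efficiency(site) * library_factor(individual) * depth_per_copy *
#' copy_number`, with lognormal per-site capture efficiency shared across
#' individuals (capture probes behave the same in every library) and
#' negative-binomial counts.
#'
#' @param site_efficiency_sd log-scale SD of per-site capture efficiency.
#' @param individual_depth_mean mean depth per haploid genome copy.
#' @param dispersion negative-binomial size parameter; `Inf` gives the
#'   Poisson limit.
#' @param individual_depth_sd log-scale SD of per-individual library-size
#'   factors (what total-count normalization is meant to cancel).
#' @return list of class `coverage_params`.
#' @export
coverage_params <- function(site_efficiency_sd = 0.7,
                            individual_depth_mean = 50,
                            dispersion = 60,
                            individual_depth_sd = 0.3) {
  stopifnot(site_efficiency_sd >= 0, individual_depth_mean > 0,
            dispersion > 0, individual_depth_sd >= 0)
  structure(list(site_efficiency_sd = site_efficiency_sd,
                 individual_depth_mean = individual_depth_mean,
                 dispersion = dispersion,
                 individual_depth_sd = individual_depth_sd),
            class = "coverage_params")
}

## ---- parents ----

#' Simulate parental species panels
#'
#' @param layout a [genome_layout()].
#' @param species named integer vector: individuals per species; at
#'   least two species, single-letter names (needed for joint-side
#'   pair syntax such as `"E-TN"`).
#' @param seed integer seed.
#' @return list of class `parent_sim` with elements `gm`
#'   (a [genotype_matrix()]), `meta`, `sites` (incl. truth `category`,
#'   `allele1`, `allele2`), and `freq` (per-site per-species frequency of
#'   `allele2`).
#' @export
simulate_parents <- function(layout, species = c(E = 10, T = 10, N = 10),
                             seed = 1) {
  stopifnot(inherits(layout, "genome_layout"), length(species) >= 2,
            !is.null(names(species)), all(nchar(names(species)) == 1))
  for (p in names(layout$fraction_diagnostic)) {
    sides <- strsplit(p, "-", fixed = TRUE)[[1]]
    if (length(sides) != 2 ||
        !all(strsplit(paste(sides, collapse = ""), "")[[1]] %in%
             names(species)))
      stop("diagnostic pair '", p, "' references unknown species")
  }
  with_seed(seed, {
    n_per_gene <- if (layout$jitter_sites)
      1L + rpois(layout$n_genes, max(layout$sites_per_gene - 1, 0))
    else rep(as.integer(layout$sites_per_gene), layout$n_genes)
    gene <- rep(sprintf("g%05d", seq_len(layout$n_genes)), n_per_gene)
    pos <- unlist(lapply(n_per_gene, seq_len), use.names = FALSE)
    n <- length(gene)

    cats <- c(paste0("diag:", names(layout$fraction_diagnostic)),
              "shared", "private", "mono")
    probs <- c(layout$fraction_diagnostic, layout$fraction_shared,
               layout$fraction_private,
               1 - sum(layout$fraction_diagnostic) -
                 layout$fraction_shared - layout$fraction_private)
    category <- sample(cats, n, replace = TRUE, prob = pmax(probs, 0))

    a1 <- sample(.NUC, n, replace = TRUE)
    shift <- sample(1:3, n, replace = TRUE)
    a2 <- .NUC[(match(a1, .NUC) + shift - 1L) %% 4L + 1L]

    sp <- names(species)
    freq <- matrix(0, n, length(sp), dimnames = list(NULL, sp))
    for (cat in unique(category)) {
      idx <- which(category == cat)
      if (startsWith(cat, "diag:")) {
        sides <- strsplit(sub("^diag:", "", cat), "-", fixed = TRUE)[[1]]
        side1 <- strsplit(sides[1], "")[[1]]
        side2 <- strsplit(sides[2], "")[[1]]
        freq[idx, side2] <- 1
        others <- setdiff(sp, c(side1, side2))
        for (s in others)
          freq[idx, s] <- rbinom(length(idx), 1, 0.5)
      } else if (cat == "shared") {
        for (s in sp) freq[idx, s] <- runif(length(idx), 0.2, 0.8)
      } else if (cat == "private") {
        who <- sample(sp, length(idx), replace = TRUE)
        for (s in sp) {
          k <- idx[who == s]
          freq[k, s] <- runif(length(k), 0.2, 0.8)
        }
      } # mono: stays 0
    }

    het <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
    ids <- unlist(lapply(sp, function(s)
      paste0(s, seq_len(species[[s]]))), use.names = FALSE)
    geno <- matrix(NA_character_, n, length(ids),
                   dimnames = list(NULL, ids))
    j <- 0L
    for (s in sp) for (k in seq_len(species[[s]])) {
      j <- j + 1L
      cnt <- rbinom(n, 2L, freq[, s])
      geno[, j] <- ifelse(cnt == 0L, a1, ifelse(cnt == 2L, a2, het))
    }

    sites <- data.frame(contig = gene, pos = pos, gene = gene,
                        category = category, allele1 = a1, allele2 = a2,
                        stringsAsFactors = FALSE)
    gm <- genotype_matrix(geno, sites[c("contig", "pos", "gene")])
    meta <- sample_meta(ids, "parent", rep(sp, species[sp]),
                        rep(2L, length(ids)))
    structure(list(gm = gm, meta = meta, sites = sites, freq = freq,
                   species = species, layout = layout, seed = seed),
              class = "parent_sim")
  })
}

#' @export
print.parent_sim <- function(x, ...) {
  cat(sprintf("<parent_sim> %d sites, species: %s\n", nrow(x$sites),
              paste(sprintf("%s(n=%d)", names(x$species), x$species),
                    collapse = ", ")))
  print(table(x$sites$category))
  invisible(x)
}

#' Truth diagnostic indicator for a species pair
#'
#' Computed from the generator's population allele frequencies: side 1
#' fixed for one allele, every side-2 species jointly fixed for the
#' other. This is the simulator's ground truth against which
#' [find_diagnostic_sites()] can be validated.
#'
#' @param parents a [simulate_parents()] result.
#' @param side1,side2 species name vectors.
#' @return logical vector over sites.
#' @export
truth_diagnostic <- function(parents, side1, side2) {
  f <- parents$freq
  s1 <- rowSums(f[, side1, drop = FALSE] == 0) == length(side1)
  s2 <- rowSums(f[, side2, drop = FALSE] == 1) == length(side2)
  s1r <- rowSums(f[, side1, drop = FALSE] == 1) == length(side1)
  s2r <- rowSums(f[, side2, drop = FALSE] == 0) == length(side2)
  (s1 & s2) | (s1r & s2r)
}

# side1 allele at truth-diagnostic sites (NA elsewhere)
truth_side1_allele <- function(parents, side1, side2) {
  f <- parents$freq
  out <- rep(NA_character_, nrow(f))
  d <- truth_diagnostic(parents, side1, side2)
  s1_ref <- rowSums(f[, side1, drop = FALSE] == 0) == length(side1)
  out[d & s1_ref] <- parents$sites$allele1[d & s1_ref]
  out[d & !s1_ref] <- parents$sites$allele2[d & !s1_ref]
  out
}

## ---- clones ----

# Vectorised unordered-genotype encoding from per-slot alleles/presence
encode_presence <- function(alleles, present) {
  n <- nrow(alleles)
  out <- rep("", n)
  any_present <- rowSums(present) > 0
  for (nuc in .NUC) {
    has <- rowSums((alleles == nuc) & present) > 0
    out <- ifelse(has, ifelse(out == "", nuc, paste(out, nuc, sep = "/")),
                  out)
  }
  out[!any_present] <- NA_character_
  out
}

#' Simulate a clonal hybrid with ground truth
#'
#' The clone inherits one haplotype per subgenome copy from its parental
#' species, then accumulates conversion and deletion tracts and private
#' mutations. Conversions homogenize all surviving copies at a site to
#' the template side's allele (copy number conserved); hemizygous /
#' double deletions remove exactly one / two copies, never the last one.
#'
#' @param parents a [simulate_parents()] result.
#' @param spec a [clone_spec()].
#' @param seed integer seed.
#' @return list of class `clone_sim`: `genotype` (character vector of
#'   unordered calls), `copy_number`, `copy_by_sub`, and `ledger`
#'   (per-site mechanism, retained ancestry, copy number).
#' @export
simulate_clone <- function(parents, spec, seed = 1) {
  stopifnot(inherits(parents, "parent_sim"), inherits(spec, "clone_spec"))
  comp <- spec$composition
  if (!all(comp %in% names(parents$species)))
    stop("composition references species absent from the parental panel: ",
         paste(setdiff(comp, names(parents$species)), collapse = ", "))
  n <- nrow(parents$sites)
  a1 <- parents$sites$allele1
  a2 <- parents$sites$allele2
  gene <- parents$sites$gene
  # index of the last site of each site's gene (tracts truncate there)
  last_of_gene <- ave(seq_len(n), gene, FUN = max)

  with_seed(seed, {
    ploidy <- length(comp)
    alleles <- matrix(NA_character_, n, ploidy)
    for (g in seq_len(ploidy)) {
      take2 <- runif(n) < parents$freq[, comp[g]]
      alleles[, g] <- ifelse(take2, a2, a1)
    }
    present <- matrix(TRUE, n, ploidy)
    converted <- logical(n)

    rates <- c(conversion = spec$conversion_rate,
               hemi_deletion = spec$hemi_deletion_rate,
               double_deletion = spec$double_deletion_rate)
    events <- list()
    for (mech in names(rates)) {
      r <- rates[[mech]]
      if (r <= 0) next
      starts <- which(runif(n) < r)
      if (!length(starts)) next
      len <- 1L + rgeom(length(starts), 1 / spec$tract_length)
      ends <- pmin(starts + len - 1L, last_of_gene[starts])
      events[[mech]] <- data.frame(start = starts, end = ends,
                                   mech = mech)
    }
    ev <- do.call(rbind, events)
    if (!is.null(ev) && nrow(ev)) {
      ev <- ev[sample.int(nrow(ev)), , drop = FALSE]
      sides <- unique(comp)
      slots_of <- lapply(sides, function(s) which(comp == s))
      names(slots_of) <- sides
      for (e in seq_len(nrow(ev))) {
        idx <- ev$start[e]:ev$end[e]
        if (ev$mech[e] == "conversion") {
          # template side: E-bias times GC template preference
          w <- vapply(sides, function(s) {
            base <- if (s == "E") spec$template_bias_E
                    else (1 - spec$template_bias_E) /
                         max(1, length(sides) - ("E" %in% sides))
            if (!("E" %in% sides)) base <- 1 / length(sides)
            if (spec$gc_template_bias > 0) {
              sl <- slots_of[[s]][1]
              al <- alleles[idx, sl]
              ngc <- sum(al %in% c("G", "C"), na.rm = TRUE)
              base * (1 + spec$gc_template_bias)^ngc
            } else base
          }, numeric(1))
          if (all(w <= 0)) w[] <- 1
          tmpl <- sample(sides, 1, prob = w)
          tslots <- slots_of[[tmpl]]
          for (i in idx) {
            live_t <- tslots[present[i, tslots]]
            if (!length(live_t)) next
            tal <- alleles[i, live_t[1]]
            alleles[i, present[i, ]] <- tal
            converted[i] <- TRUE
          }
        } else {
          n_del <- if (ev$mech[e] == "hemi_deletion") 1L else 2L
          pick <- sample.int(ploidy, n_del)
          for (i in idx) {
            live <- which(present[i, ])
            for (p_ in pick) {
              if (length(live) <= 1L) break
              drop_slot <- if (p_ %in% live) p_ else sample(live, 1)
              present[i, drop_slot] <- FALSE
              live <- setdiff(live, drop_slot)
            }
          }
        }
      }
    }

    # clone-age private mutations: only at ancestrally monomorphic sites,
    # heterozygous on a single subgenome copy
    mono <- which(parents$sites$category == "mono")
    if (spec$age > 0 && length(mono)) {
      hit <- mono[runif(length(mono)) < spec$age]
      for (i in hit) {
        live <- which(present[i, ])
        slot <- if (length(live) == 1) live else sample(live, 1)
        cur <- unique(alleles[i, live])
        alleles[i, slot] <- sample(setdiff(.NUC, cur), 1)
      }
    }

    genotype <- encode_presence(alleles, present)
    copy_number <- rowSums(present)
    sides <- unique(comp)
    copy_by_sub <- vapply(sides, function(s)
      rowSums(present[, which(comp == s), drop = FALSE]), numeric(n))
    colnames(copy_by_sub) <- sides

    removed <- ploidy - copy_number
    mechanism <- ifelse(removed >= 2, "double_deletion",
                 ifelse(removed == 1, "hemi_deletion",
                 ifelse(converted, "conversion", "none")))

    # retained ancestry at the clone pair's truth-diagnostic sites
    retained <- rep(NA_character_, n)
    if (length(sides) == 2) {
      sA <- if ("E" %in% sides) "E" else sides[1]
      sB <- setdiff(sides, sA)
      d <- truth_diagnostic(parents, sA, sB)
      alA <- truth_side1_allele(parents, sA, sB)
      hom <- !is.na(genotype) & !gt_is_het(genotype)
      retained[d & hom & genotype == alA] <- paste0(sA, "-like")
      alB <- ifelse(alA == a1, a2, a1)
      retained[d & hom & genotype == alB] <- paste0(sB, "-like")
    }

    ledger <- data.frame(sample = spec$name,
                         contig = parents$sites$contig,
                         pos = parents$sites$pos,
                         mechanism = mechanism,
                         retained_ancestry = retained,
                         copy_number = copy_number,
                         stringsAsFactors = FALSE)
    structure(list(name = spec$name, composition = comp,
                   genotype = genotype, copy_number = copy_number,
                   copy_by_sub = copy_by_sub, ledger = ledger,
                   spec = spec, seed = seed),
              class = "clone_sim")
  })
}

#' @export
print.clone_sim <- function(x, ...) {
  cat(sprintf("<clone_sim> %s (%s): %d sites\n", x$name,
              paste(x$composition, collapse = "+"), length(x$genotype)))
  print(table(x$ledger$mechanism))
  invisible(x)
}

## ---- depth ----

#' Depth table container
#'
#' @param depth numeric matrix, sites x samples, of raw read counts.
#' @param sites data.frame with `contig`, `pos`.
#' @return object of class `depth_table`.
#' @export
depth_table <- function(depth, sites) {
  depth <- as.matrix(depth)
  stopifnot(nrow(depth) == nrow(sites), !is.null(colnames(depth)),
            all(depth >= 0, na.rm = TRUE))
  structure(list(depth = depth,
                 sites = data.frame(contig = as.character(sites$contig),
                                    pos = as.integer(sites$pos),
                                    stringsAsFactors = FALSE)),
            class = "depth_table")
}

#' @export
print.depth_table <- function(x, ...) {
  cat(sprintf("<depth_table> %d sites x %d samples; mean depth %.1f\n",
              nrow(x$depth), ncol(x$depth), mean(x$depth, na.rm = TRUE)))
  invisible(x)
}

#' Simulate capture sequencing depth
#'
#' Expected count is `site_efficiency * library_factor * depth_per_copy *
#' copy_number`; site efficiency is lognormal and identical across
#' individuals, counts are negative binomial (`dispersion = Inf` gives
#' Poisson).
#'
#' @param parents a `parent_sim` (all parents carry 2 copies everywhere).
#' @param clones list of `clone_sim` objects (may be empty).
#' @param params a [coverage_params()].
#' @param seed integer seed.
#' @return a [depth_table()] covering parents and clones.
#' @export
simulate_depth <- function(parents, clones = list(), params = coverage_params(),
                           seed = 1) {
  stopifnot(inherits(parents, "parent_sim"),
            inherits(params, "coverage_params"))
  if (inherits(clones, "clone_sim")) clones <- list(clones)
  n <- nrow(parents$sites)
  ids <- c(samples(parents$gm), vapply(clones, `[[`, "", "name"))
  if (anyDuplicated(ids)) stop("duplicated sample ids across panels")
  copy <- cbind(matrix(2, n, ncol(parents$gm$geno)),
                vapply(clones, `[[`, numeric(n), "copy_number"))
  colnames(copy) <- ids
  with_seed(seed, {
    eff <- rlnorm(n, 0, params$site_efficiency_sd)
    libf <- rlnorm(length(ids), 0, params$individual_depth_sd)
    mu <- (eff * copy) %*% diag(libf, length(ids)) *
      params$individual_depth_mean
    counts <- if (is.infinite(params$dispersion))
      rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = params$dispersion)
    dim(counts) <- dim(mu)
    colnames(counts) <- ids
    depth_table(counts, parents$sites)
  })
}

## ---- fixtures on disk ----

#' Write simulator output as plain-text fixtures
#'
#' Emits a VCF 4.2 (GT/DP/GQ, contigs = gene ids), a long-format depth
#' TSV, a metadata TSV and a truth-ledger TSV that round-trip losslessly
#' through [read_genotypes()] and [read_depth()].
#'
#' @param parents a `parent_sim`.
#' @param clones list of `clone_sim` objects.
#' @param depth optional [depth_table()]; per-call DP defaults to 50
#'   when absent.
#' @param out_dir output directory (created if needed).
#' @param gq constant genotype quality written per call.
#' @return named list of file paths (`vcf`, `depth`, `meta`, `truth`).
#' @export
emit_fixtures <- function(parents, clones = list(), depth = NULL,
                          out_dir, gq = 99L) {
  if (inherits(clones, "clone_sim")) clones <- list(clones)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(parents$sites)
  geno <- parents$gm$geno
  for (cl in clones) {
    geno <- cbind(geno, cl$genotype)
    colnames(geno)[ncol(geno)] <- cl$name
  }
  ids <- colnames(geno)
  dp <- if (!is.null(depth)) {
    stopifnot(identical(depth$sites$contig, parents$sites$contig))
    depth$depth[, ids, drop = FALSE]
  } else matrix(50L, n, length(ids), dimnames = list(NULL, ids))

  ref <- parents$sites$allele1
  alt_list <- vector("list", n)
  gt_codes <- matrix(".", n, length(ids))
  for (i in seq_len(n)) {
    als <- site_alleles(geno[i, ])
    alt <- sort(setdiff(als, ref[i]))
    alt_list[[i]] <- alt
    codes <- setNames(seq_along(c(ref[i], alt)) - 1L, c(ref[i], alt))
    for (j in seq_along(ids)) {
      g <- geno[i, j]
      gt_codes[i, j] <- if (is.na(g)) "./." else {
        a <- gt_alleles(g)
        k <- sort(codes[a])
        if (length(k) == 1) paste(k, k, sep = "/")
        else paste(k, collapse = "/")
      }
    }
  }
  alt_str <- vapply(alt_list, function(a)
    if (length(a)) paste(a, collapse = ",") else ".", "")

  vcf_path <- file.path(out_dir, "sim.vcf")
  con <- file(vcf_path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c("##fileformat=VCFv4.2",
               "##source=clonalLOH_simulator",
               sprintf("##contig=<ID=%s>", unique(parents$sites$contig)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
               '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", ids), collapse = "\t")),
             con)
  body <- matrix("", n, length(ids))
  for (j in seq_along(ids))
    body[, j] <- paste(gt_codes[, j], dp[, j], gq, sep = ":")
  lines <- paste(parents$sites$contig, parents$sites$pos, ".",
                 ref, alt_str, ".", "PASS", ".", "GT:DP:GQ",
                 apply(body, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)

  depth_path <- file.path(out_dir, "depth.tsv")
  long <- data.frame(contig = rep(parents$sites$contig, length(ids)),
                     pos = rep(parents$sites$pos, length(ids)),
                     sample = rep(ids, each = n),
                     depth = as.vector(dp))
  write.table(long, depth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  meta_path <- file.path(out_dir, "meta.tsv")
  meta <- rbind(
    data.frame(sample = parents$meta$sample, class = parents$meta$class,
               label = parents$meta$label, ploidy = parents$meta$ploidy,
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(clones, function(cl)
      data.frame(sample = cl$name, class = "hybrid",
                 label = paste(cl$composition, collapse = ""),
                 ploidy = length(cl$composition),
                 stringsAsFactors = FALSE))))
  write.table(meta, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  truth_path <- file.path(out_dir, "truth.tsv")
  truth <- do.call(rbind, lapply(clones, `[[`, "ledger"))
  if (is.null(truth))
    truth <- data.frame(sample = character(), contig = character(),
                        pos = integer(), mechanism = character(),
                        retained_ancestry = character(),
                        copy_number = integer())
  write.table(truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")

  list(vcf = vcf_path, depth = depth_path, meta = meta_path,
       truth = truth_path)
}

#' Read a long-format depth TSV
#'
#' @param path TSV with columns `contig`, `pos`, `sample`, `depth`.
#' @return a [depth_table()].
#' @export
read_depth <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("contig", "pos", "sample", "depth") %in% names(x)))
  key <- paste(x$contig, x$pos)
  sites_key <- unique(key)
  ids <- unique(x$sample)
  m <- matrix(NA_real_, length(sites_key), length(ids),
              dimnames = list(NULL, ids))
  m[cbind(match(key, sites_key), match(x$sample, ids))] <- x$depth
  first <- !duplicated(key)
  depth_table(m, data.frame(contig = x$contig[first], pos = x$pos[first]))
}
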