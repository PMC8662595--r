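## Genotype I/O, quality filtering, diagnostic-site discovery and the
## ten-category hybrid SNP classification.

#' Read genotypes from a VCF plus sample metadata
#'
#' Reads GT/DP/GQ for all samples (via `VariantAnnotation`) into a
#' [genotype_matrix()]. Genotypes are decoded into unordered allele
#' sets, so diploid-style and triploid presence calls are handled
#' uniformly. Multiallelic records are preserved (they are removed
#' later by [filter_sites()] when `biallelic_only = TRUE`).
#'
#' @param vcf_path path to an (uncompressed or bgzipped) VCF 4.x file.
#' @param meta_path path to a metadata TSV with columns `sample`,
#'   `class`, `label`, `ploidy` (as written by [emit_fixtures()]).
#' @return list with elements `gm` ([genotype_matrix()]) and `meta`
#'   ([sample_meta()]).
#' @export
read_genotypes <- function(vcf_path, meta_path) {
  meta_raw <- read.delim(meta_path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "class", "label", "ploidy") %in%
                  names(meta_raw)))
  meta <- sample_meta(meta_raw$sample, meta_raw$class, meta_raw$label,
                      meta_raw$ploidy)
  vcf <- VariantAnnotation::readVcf(vcf_path)
  ids <- colnames(vcf)
  missing_meta <- setdiff(ids, meta$sample)
  if (length(missing_meta))
    stop("VCF samples absent from metadata: ",
         paste(missing_meta, collapse = ", "))

  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt <- S4Vectors::unstrsplit(
    methods::as(rr$ALT, "CharacterList"), ",")
  gt <- VariantAnnotation::geno(vcf)$GT
  n <- nrow(gt)

  # decode GT index strings against per-site allele lists
  allele_tab <- strsplit(paste(ref, alt, sep = ","), ",", fixed = TRUE)
  allele_tab <- lapply(allele_tab, function(a) a[a != "." & a != ""])
  decode <- function(g, alleles) {
    if (is.na(g) || g %in% c(".", "./.", ".|.", "././.")) return(NA_character_)
    idx <- suppressWarnings(
      as.integer(strsplit(g, "[/|]")[[1]]))
    if (anyNA(idx)) return(NA_character_)
    gt_encode(alleles[idx + 1L])
  }
  geno <- matrix(NA_character_, n, length(ids),
                 dimnames = list(NULL, ids))
  for (j in seq_along(ids))
    geno[, j] <- mapply(decode, gt[, j], allele_tab, USE.NAMES = FALSE)

  grab_num <- function(field) {
    g <- VariantAnnotation::geno(vcf)
    if (!field %in% names(g))
      return(matrix(NA_real_, n, length(ids), dimnames = list(NULL, ids)))
    m <- g[[field]]
    storage.mode(m) <- "double"
    m
  }
  sites <- data.frame(contig = as.character(GenomicRanges::seqnames(rr)),
                      pos = GenomicRanges::start(rr))
  gm <- genotype_matrix(geno, sites, dp = grab_num("DP"),
                        gq = grab_num("GQ"))
  list(gm = gm, meta = meta)
}

#' Quality-filter a genotype matrix
#'
#' Calls below the depth/quality thresholds are set to missing; sites
#' with more than two allele states across the whole data set are
#' dropped when `biallelic_only`; sites left with no call at all are
#' dropped.
#'
#' @param gm a [genotype_matrix()].
#' @param dp_min minimum per-call read depth (default 10).
#' @param gq_min minimum per-call genotype quality (default 20).
#' @param biallelic_only drop sites with >2 alleles data-set-wide.
#' @return the filtered [genotype_matrix()].
#' @export
filter_sites <- function(gm, dp_min = 10, gq_min = 20,
                         biallelic_only = TRUE) {
  geno <- gm$geno
  bad <- (!is.na(gm$dp) & gm$dp < dp_min) |
    (!is.na(gm$gq) & gm$gq < gq_min)
  # calls lacking DP or GQ where thresholds are active are untrusted
  if (dp_min > 0) bad <- bad | is.na(gm$dp)
  if (gq_min > 0) bad <- bad | is.na(gm$gq)
  geno[bad] <- NA_character_
  keep <- rowSums(!is.na(geno)) > 0
  if (biallelic_only) {
    nal <- rowSums(vapply(.NUC, function(nuc)
      rowSums(matrix(grepl(nuc, geno, fixed = TRUE), nrow(geno))) > 0,
      logical(nrow(geno))))
    keep <- keep & nal <= 2L
  }
  genotype_matrix(geno[keep, , drop = FALSE],
                  gm$sites[keep, , drop = FALSE],
                  gm$dp[keep, , drop = FALSE],
                  gm$gq[keep, , drop = FALSE])
}

#' Remove sites at which lab F1 hybrids contradict their parents
#'
#' A site is removed when an F1's genotype cannot be composed of one
#' allele drawn from each parent's genotype (such sites indicate
#' sequencing or demultiplexing artefacts).
#'
#' @param gm a [genotype_matrix()].
#' @param trios list of character vectors `c(mother, father, f1)`.
#' @return list with `gm` (filtered) and `removed` (site data.frame).
#' @export
remove_f1_discordant <- function(gm, trios) {
  if (!length(trios)) return(list(gm = gm, removed = gm$sites[0, ]))
  ids <- samples(gm)
  discordant <- logical(nrow(gm$geno))
  for (trio in trios) {
    if (!all(trio %in% ids))
      stop("trio member(s) missing from genotype matrix: ",
           paste(setdiff(trio, ids), collapse = ", "))
    gm_ <- gm$geno[, trio, drop = FALSE]
    for (i in seq_len(nrow(gm_))) {
      g <- gm_[i, ]
      if (anyNA(g)) next
      am <- gt_alleles(g[1]); af <- gt_alleles(g[2]); f1 <- gt_alleles(g[3])
      # every F1 allele must be available from a parent, and some
      # one-from-each-parent pair must produce exactly the F1 allele set
      ok <- any(vapply(am, function(x) any(vapply(af, function(y)
        setequal(unique(c(x, y)), f1), logical(1))), logical(1)))
      if (!ok) discordant[i] <- TRUE
    }
  }
  list(gm = gm[!discordant, ], removed = gm$sites[discordant, ])
}

#' Find species-diagnostic sites
#'
#' A site is diagnostic for `side1` vs `side2` when every non-missing
#' individual of side 1 is homozygous for one allele, every non-missing
#' individual of side 2 (jointly over its species) is homozygous for a
#' different allele, and both sides have at least `min_individuals`
#' non-missing calls. `max_minor_count` discordant parental calls per
#' side may be tolerated for real-data robustness (default 0: strict).
#'
#' @param gm a [genotype_matrix()].
#' @param meta a [sample_meta()].
#' @param side1,side2 character vectors of species labels (a
#'   multi-species side requires joint monomorphism, e.g.
#'   `side2 = c("T","N")` for E-TN diagnosis).
#' @param min_individuals minimum non-missing individuals per side.
#' @param max_minor_count tolerated discordant calls per side.
#' @return data.frame of class `diagnostic_set` with columns `contig`,
#'   `pos`, `gene`, `allele1`, `allele2`, `site` (row index into `gm`)
#'   and attribute `pair`.
#' @export
find_diagnostic_sites <- function(gm, meta, side1, side2,
                                  min_individuals = 2,
                                  max_minor_count = 0) {
  if (!length(side1) || !length(side2))
    stop("both sides of the diagnostic pair must name >= 1 species")
  pick <- function(side) meta$sample[meta$class %in% c("parent") &
                                       meta$label %in% side]
  s1 <- intersect(pick(side1), samples(gm))
  s2 <- intersect(pick(side2), samples(gm))
  if (!length(s1) || !length(s2))
    stop("no parental individuals found for one of the sides")

  side_state <- function(cols) {
    g <- gm$geno[, cols, drop = FALSE]
    nr <- nrow(g)
    nm <- rowSums(!is.na(g))
    # homozygous calls equal their single-nucleotide allele string, so
    # per-nucleotide homozygote counts are exact-match counts
    cnt <- vapply(.NUC, function(nuc)
      rowSums(matrix(!is.na(g) & g == nuc, nr)), numeric(nr))
    cnt <- matrix(cnt, nr, 4)
    best <- max.col(cnt, ties.method = "first")
    maxc <- cnt[cbind(seq_len(nr), best)]
    allele <- .NUC[best]
    allele[maxc == 0] <- NA_character_
    minor <- nm - maxc  # heterozygous or discordant homozygous calls
    list(n = nm, allele = allele, minor = minor)
  }
  st1 <- side_state(s1)
  st2 <- side_state(s2)
  ok <- st1$n >= min_individuals & st2$n >= min_individuals &
    !is.na(st1$allele) & !is.na(st2$allele) &
    st1$allele != st2$allele &
    !is.na(st1$minor) & st1$minor <= max_minor_count &
    !is.na(st2$minor) & st2$minor <= max_minor_count
  ok[is.na(ok)] <- FALSE
  out <- data.frame(contig = gm$sites$contig[ok], pos = gm$sites$pos[ok],
                    gene = gm$sites$gene[ok],
                    allele1 = st1$allele[ok], allele2 = st2$allele[ok],
                    site = which(ok), stringsAsFactors = FALSE)
  attr(out, "pair") <- paste(paste(side1, collapse = ""),
                             paste(side2, collapse = ""), sep = "-")
  class(out) <- c("diagnostic_set", "data.frame")
  out
}

#' Classify a hybrid's SNPs into the ten standard categories
#'
#' Categories follow the standard hybrid-SNP scheme: `pr1a`/`pr1b`
#' (private-asexual variant in het/hom state), `sh3a` (heterozygous for
#' both parental diagnostic variants), `sh3b11`/`sh3b12` (homozygous for
#' the side-1 / side-2 diagnostic allele, i.e. LOH), `prh2a`/`prh2b`/
#' `prh2b1` (heterozygosity private to one parental species, shared or
#' not with the hybrid; `b` vs `b1` distinguishes which side carries
#' it), `sh4a`/`sh4b` (heterozygosity shared by both parental species,
#' present or absent in the hybrid), and `other`.
#'
#' @param gm a filtered [genotype_matrix()].
#' @param meta a [sample_meta()].
#' @param hybrid sample id of the hybrid to classify.
#' @param side1,side2 parental species sets of the hybrid's pair.
#' @param diagset optional precomputed [find_diagnostic_sites()] result.
#' @return data.frame with `contig`, `pos`, `category`, `site`.
#' @export
classify_snps <- function(gm, meta, hybrid, side1, side2,
                          diagset = NULL) {
  if (!hybrid %in% meta$sample[meta$class %in% c("hybrid", "f1")])
    stop("'", hybrid, "' is not a hybrid sample")
  hg <- gm$geno[, hybrid]
  par_ids <- meta$sample[meta$class == "parent" &
                           meta$label %in% c(side1, side2)]
  par_ids <- intersect(par_ids, samples(gm))
  p1 <- intersect(meta$sample[meta$label %in% side1], par_ids)
  p2 <- intersect(meta$sample[meta$label %in% side2], par_ids)
  if (is.null(diagset))
    diagset <- find_diagnostic_sites(gm, meta, side1, side2)

  n <- nrow(gm$geno)
  cat <- rep("other", n)
  het <- gt_is_het(hg)

  # parental allele pools per site
  pool1 <- lapply(seq_len(n), function(i) site_alleles(gm$geno[i, p1]))
  pool2 <- lapply(seq_len(n), function(i) site_alleles(gm$geno[i, p2]))
  pool <- mapply(function(a, b) unique(c(a, b)), pool1, pool2,
                 SIMPLIFY = FALSE)

  # private-asexual: hybrid carries an allele absent from all parents
  priv <- mapply(function(g, p) {
    if (is.na(g)) FALSE else length(setdiff(gt_alleles(g), p)) > 0
  }, hg, pool)
  cat[priv & het] <- "pr1a"
  cat[priv & !het & !is.na(hg)] <- "pr1b"

  # diagnostic sites: sh3a / sh3b11 / sh3b12
  d <- diagset$site
  both <- paste(pmin(diagset$allele1, diagset$allele2),
                pmax(diagset$allele1, diagset$allele2), sep = "/")
  cat[d][!is.na(hg[d]) & hg[d] == both & !priv[d]] <- "sh3a"
  cat[d][!is.na(hg[d]) & hg[d] == diagset$allele1 & !priv[d]] <- "sh3b11"
  cat[d][!is.na(hg[d]) & hg[d] == diagset$allele2 & !priv[d]] <- "sh3b12"

  # parental heterozygosity classes (non-diagnostic, non-private sites)
  het1 <- vapply(seq_len(n), function(i)
    any(gt_is_het(gm$geno[i, p1])), logical(1))
  het2 <- vapply(seq_len(n), function(i)
    any(gt_is_het(gm$geno[i, p2])), logical(1))
  rest <- !priv & !(seq_len(n) %in% d) & !is.na(hg)
  cat[rest & het1 & het2 & het] <- "sh4a"
  cat[rest & het1 & het2 & !het] <- "sh4b"
  cat[rest & het1 & !het2 & het] <- "prh2a"
  cat[rest & het2 & !het1 & het] <- "prh2a"
  cat[rest & het1 & !het2 & !het] <- "prh2b"
  cat[rest & het2 & !het1 & !het] <- "prh2b1"

  cat[is.na(hg)] <- NA_character_
  data.frame(contig = gm$sites$contig, pos = gm$sites$pos,
             category = cat, site = seq_len(n),
             stringsAsFactors = FALSE)
}

#' Genotype concordance between two matrices
#'
#' @param gmA,gmB two [genotype_matrix()] objects sharing `sample`.
#' @param sample sample id present in both.
#' @param sites optional data.frame (`contig`, `pos`) restricting the
#'   comparison.
#' @return list with `discordance` (proportion differing among jointly
#'   non-missing shared sites) and `n` (shared sites used).
#' @export
genotype_concordance <- function(gmA, gmB, sample, sites = NULL) {
  keyA <- paste(gmA$sites$contig, gmA$sites$pos)
  keyB <- paste(gmB$sites$contig, gmB$sites$pos)
  shared <- intersect(keyA, keyB)
  if (!is.null(sites))
    shared <- intersect(shared, paste(sites$contig, sites$pos))
  a <- gmA$geno[match(shared, keyA), sample]
  b <- gmB$geno[match(shared, keyB), sample]
  use <- !is.na(a) & !is.na(b)
  if (!sum(use)) stop("no jointly non-missing shared sites")
  list(discordance = mean(a[use] != b[use]), n = sum(use))
}
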