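#' Genotype matrix container
#'
#' Sites-by-individuals genotype calls with per-call read depth (DP) and
#' genotype quality (GQ). Genotypes are unordered allele sets encoded as
#' sorted `/`-joined nucleotide strings (`"A"`, `"A/G"`); `NA` marks a
#' missing call. Triploid calls are presence/absence based, mirroring a
#' diploid-style caller: a site is heterozygous when at least two distinct
#' alleles are present, so e.g. an E/E/T individual carrying both alleles
#' is encoded exactly like an E/T diploid.
#'
#' @param geno character matrix (sites x samples) of genotype strings.
#' @param sites data.frame with columns `contig`, `pos` (1-based) and
#'   optionally `gene` (defaults to `contig`: the reference is
#'   transcriptome-based, one contig per gene).
#' @param dp,gq numeric matrices of the same dimension as `geno`, or
#'   `NULL` (treated as unknown).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, sites, dp = NULL, gq = NULL) {
  geno <- as.matrix(geno)
  stopifnot(is.character(geno), nrow(geno) == nrow(sites))
  if (is.null(sites$gene)) sites$gene <- sites$contig
  sites <- data.frame(contig = as.character(sites$contig),
                      pos = as.integer(sites$pos),
                      gene = as.character(sites$gene),
                      stringsAsFactors = FALSE)
  if (is.null(colnames(geno)))
    stop("genotype matrix must have sample names as column names")
  blank <- function(m) {
    if (is.null(m)) m <- matrix(NA_real_, nrow(geno), ncol(geno),
                                dimnames = dimnames(geno))
    storage.mode(m) <- "double"
    stopifnot(all(dim(m) == dim(geno)))
    m
  }
  structure(list(geno = geno, sites = sites, dp = blank(dp), gq = blank(gq)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d sites x %d samples (%d genes)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$sites$gene))))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing calls: %.1f%%; samples: %s%s\n", 100 * miss,
              paste(head(colnames(x$geno), 6), collapse = ", "),
              if (ncol(x$geno) > 6) ", ..." else ""))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by sites and/or samples
#' @param x a `genotype_matrix`.
#' @param i site index (logical or integer).
#' @param j sample index or names.
#' @param ... ignored.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$geno))
  if (missing(j)) j <- seq_len(ncol(x$geno))
  genotype_matrix(x$geno[i, j, drop = FALSE], x$sites[i, , drop = FALSE],
                  x$dp[i, j, drop = FALSE], x$gq[i, j, drop = FALSE])
}

#' @export
samples.genotype_matrix <- function(x) colnames(x$geno)

#' Sample names of a container
#' @param x a container with samples.
#' @export
samples <- function(x) UseMethod("samples")

## ---- genotype string helpers ----

# Canonical unordered encoding: sorted unique alleles joined by "/"
gt_encode <- function(alleles) {
  alleles <- sort(unique(alleles))
  if (length(alleles) == 0) NA_character_ else paste(alleles, collapse = "/")
}

gt_alleles <- function(gt) if (is.na(gt)) character(0) else strsplit(gt, "/", fixed = TRUE)[[1]]

#' Is a genotype call heterozygous?
#'
#' Vectorised test for >= 2 distinct alleles in an unordered genotype
#' string; `NA` calls give `FALSE`.
#' @param gt character vector of genotype strings.
#' @return logical vector.
#' @export
gt_is_het <- function(gt) !is.na(gt) & grepl("/", gt, fixed = TRUE)

# Vectorised: homozygous for exactly `allele`
gt_is_hom <- function(gt, allele) !is.na(gt) & gt == allele

# Alleles present at a site across a set of genotype strings (NA dropped)
site_alleles <- function(gts) {
  gts <- gts[!is.na(gts)]
  unique(unlist(strsplit(gts, "/", fixed = TRUE), use.names = FALSE))
}

#' Sample metadata table
#'
#' @param sample character vector of sample ids.
#' @param class one of `"parent"`, `"hybrid"`, `"outgroup"`, `"f1"` per
#'   sample.
#' @param label species name for parents, genome composition (e.g.
#'   `"ET"`, `"EET"`) for hybrids.
#' @param ploidy integer ploidy per sample.
#' @return data.frame of class `sample_meta`.
#' @export
sample_meta <- function(sample, class, label, ploidy) {
  class <- match.arg(class, c("parent", "hybrid", "outgroup", "f1"),
                     several.ok = TRUE)
  if (length(class) == 1) class <- rep(class, length(sample))
  out <- data.frame(sample = as.character(sample), class = class,
                    label = as.character(label),
                    ploidy = as.integer(ploidy), stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(out$sample))
  structure(out, class = c("sample_meta", "data.frame"))
}

# Split a hybrid composition label ("EET") into subgenome letters
composition_letters <- function(label) strsplit(label, "")[[1]]
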