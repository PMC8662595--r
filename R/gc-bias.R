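## GC bias of allele retention at LOH sites: classify each event as a
## weak-to-strong (A/T -> G/C), strong-to-weak (G/C -> A/T) or
## GC-neutral (A <-> T, G <-> C) substitution, and compare the class
## counts per retained-ancestry group against the interparental
## divergence baseline over all diagnostic sites.

.WEAK <- c("A", "T")
.STRONG <- c("G", "C")

#' Classify the substitution direction of an LOH event
#'
#' @param lost_allele,retained_allele nucleotide(s); vectorised.
#' @return character vector in `{"WS", "SW", "neutral"}`.
#' @export
classify_substitution <- function(lost_allele, retained_allele) {
  if (any(lost_allele == retained_allele))
    stop("lost and retained alleles must differ")
  lw <- lost_allele %in% .WEAK
  rw <- retained_allele %in% .WEAK
  ifelse(lw & !rw, "WS", ifelse(!lw & rw, "SW", "neutral"))
}

#' Interparental divergence baseline over diagnostic sites
#'
#' For each diagnostic site, the substitution class implied by
#' replacing the side-2 allele with the side-1 allele (side-1-like
#' polarity: what an LOH retaining side 1 would do) and vice versa.
#'
#' @param diagset a [find_diagnostic_sites()] result.
#' @return list with two 3-way count tables, `side1_like` and
#'   `side2_like` (each named `WS`, `SW`, `neutral`).
#' @export
baseline_divergence <- function(diagset) {
  stopifnot(nrow(diagset) > 0)
  tab <- function(cls) {
    out <- c(WS = 0, SW = 0, neutral = 0)
    t0 <- table(cls)
    out[names(t0)] <- t0
    out
  }
  list(side1_like = tab(classify_substitution(diagset$allele2,
                                              diagset$allele1)),
       side2_like = tab(classify_substitution(diagset$allele1,
                                              diagset$allele2)))
}

#' GC-bias contingency test for one sample and ancestry class
#'
#' Compares the WS/SW/neutral counts of the sample's LOH events of one
#' retained-ancestry class against the baseline counts of the matching
#' polarity in a 2x3 contingency table (2x2 with the neutral class
#' collapsed when `collapse_neutral`). Chi-square test; Monte-Carlo p
#' (seeded) when any expected cell is below 5.
#'
#' @param calls a [call_loh()] result.
#' @param diagset the diagnostic set the calls came from.
#' @param ancestry `"side1-like"` or `"side2-like"`.
#' @param collapse_neutral use a 2x2 table (WS vs rest).
#' @param seed seed for the Monte-Carlo p-value.
#' @return list of class `gc_bias_test`: `counts`, `baseline`, `p`,
#'   `statistic`, `method`, `ws_excess` (relative excess of the WS
#'   proportion over baseline), `skipped` (logical, with `reason`).
#' @export
gc_bias_test <- function(calls, diagset, ancestry = "side1-like",
                         collapse_neutral = FALSE, seed = 1) {
  cc <- calls[calls$retained == ancestry, ]
  base <- baseline_divergence(diagset)[[
    if (ancestry == "side1-like") "side1_like" else "side2_like"]]
  empty <- list(counts = c(WS = 0, SW = 0, neutral = 0), baseline = base,
                p = NA_real_, statistic = NA_real_, method = "skipped",
                ws_excess = NA_real_, skipped = TRUE)
  if (nrow(cc) < 2) {
    empty$reason <- "fewer than 2 LOH events in ancestry class"
    if (nrow(cc) == 1) {
      cls <- classify_substitution(cc$lost_allele, cc$retained_allele)
      empty$counts[cls] <- 1
    }
    return(structure(empty, class = "gc_bias_test"))
  }
  cls <- classify_substitution(cc$lost_allele, cc$retained_allele)
  cnt <- c(WS = sum(cls == "WS"), SW = sum(cls == "SW"),
           neutral = sum(cls == "neutral"))
  obs <- cnt; bas <- base
  if (collapse_neutral) {
    obs <- c(WS = unname(obs["WS"]), other = sum(obs[c("SW", "neutral")]))
    bas <- c(WS = unname(bas["WS"]), other = sum(bas[c("SW", "neutral")]))
  }
  tab <- rbind(loh = obs, baseline = bas)
  nonzero <- colSums(tab) > 0
  tab <- tab[, nonzero, drop = FALSE]
  if (ncol(tab) < 2 || any(rowSums(tab) == 0)) {
    empty$counts <- cnt
    empty$reason <- "degenerate margins"
    return(structure(empty, class = "gc_bias_test"))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  test <- if (any(expected < 5)) {
    with_seed(seed, suppressWarnings(
      chisq.test(tab, simulate.p.value = TRUE, B = 2000)))
  } else suppressWarnings(chisq.test(tab, correct = FALSE))
  ws_prop_loh <- cnt[["WS"]] / sum(cnt)
  ws_prop_base <- base[["WS"]] / sum(base)
  structure(list(counts = cnt, baseline = base, p = test$p.value,
                 statistic = unname(test$statistic),
                 method = test$method,
                 ws_excess = ws_prop_loh / ws_prop_base - 1,
                 skipped = FALSE),
            class = "gc_bias_test")
}

#' GC-bias report across samples with FDR correction
#'
#' Runs [gc_bias_test()] per hybrid and ancestry class and applies
#' Benjamini-Hochberg within each ancestry class across samples.
#'
#' @param call_list named list of [call_loh()] results (one per hybrid).
#' @param diagset shared diagnostic set.
#' @param fdr_alpha significance level on adjusted p.
#' @param collapse_neutral passed through.
#' @param seed passed through.
#' @return data.frame: sample, ancestry, WS/SW/neutral counts, raw and
#'   BH-adjusted p, ws_excess, significant.
#' @export
gc_bias_report <- function(call_list, diagset, fdr_alpha = 0.05,
                           collapse_neutral = FALSE, seed = 1) {
  rows <- list()
  for (anc in c("side1-like", "side2-like")) {
    for (s in names(call_list)) {
      t <- gc_bias_test(call_list[[s]], diagset, anc,
                        collapse_neutral, seed)
      rows[[length(rows) + 1]] <- data.frame(
        sample = s, ancestry = anc,
        WS = t$counts[["WS"]], SW = t$counts[["SW"]],
        neutral = t$counts[["neutral"]],
        p = t$p, ws_excess = t$ws_excess,
        skipped = t$skipped, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  for (anc in unique(out$ancestry)) {
    k <- out$ancestry == anc & !is.na(out$p)
    out$p_adj[k] <- p.adjust(out$p[k], method = "BH")
  }
  out$significant <- !is.na(out$p_adj) & out$p_adj < fdr_alpha
  out
}

#' GC content of consensus sequences
#'
#' @param seqs named character vector of sequences (one per sample).
#' @param third_codon_only count only third codon positions.
#' @param frames named integer vector of reading-frame offsets (0-2),
#'   required when `third_codon_only`.
#' @return named numeric vector of GC proportions.
#' @export
sequence_gc_content <- function(seqs, third_codon_only = FALSE,
                                frames = NULL) {
  if (third_codon_only && is.null(frames))
    stop("third_codon_only requires reading-frame offsets")
  vapply(seq_along(seqs), function(i) {
    chars <- strsplit(toupper(seqs[[i]]), "")[[1]]
    if (third_codon_only) {
      off <- frames[[names(seqs)[i] %||% i]]
      idx <- seq(from = off + 3, to = length(chars), by = 3)
      chars <- chars[idx]
    }
    chars <- chars[chars %in% .NUC]
    if (!length(chars)) return(NA_real_)
    mean(chars %in% .STRONG)
  }, numeric(1), USE.NAMES = FALSE) -> out
  names(out) <- names(seqs)
  out
}
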