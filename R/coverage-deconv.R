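## Read-depth deconvolution of LOH mechanisms.
##
## Conversions conserve allelic copy number (relative coverage ~ 1);
## hemizygous deletions drop it to 1/2 (diploid) or 2/3 (triploid), and
## double deletions in triploids to 1/3. After total-count
## normalization, the histogram of hybrid-vs-parental relative
## coverages at LOH sites is fitted by mixtures of Gamma densities with
## free shape k and mean fixed at those biologically meaningful values;
## the amplitude ratio B/(A+B) estimates the deletion fraction.

#' Total-read-count depth normalization
#'
#' Per-sample totals are computed over `site_set`; normalized depth is
#' `raw * mean(totals) / sample_total`, so samples become comparable
#' regardless of library size.
#'
#' @param depth a [depth_table()].
#' @param samples samples to normalize (default all).
#' @param site_set integer site indices used for the totals (default
#'   all sites).
#' @return a [depth_table()] whose `depth` holds normalized values (the
#'   raw matrix is kept as `raw`).
#' @export
normalize_depth <- function(depth, samples = colnames(depth$depth),
                            site_set = seq_len(nrow(depth$depth))) {
  stopifnot(length(site_set) > 0)
  m <- depth$depth[, samples, drop = FALSE]
  totals <- colSums(m[site_set, , drop = FALSE], na.rm = TRUE)
  if (any(totals == 0)) stop("zero total depth for sample(s): ",
                             paste(samples[totals == 0], collapse = ", "))
  normed <- sweep(m, 2, mean(totals) / totals, `*`)
  out <- depth_table(normed, depth$sites)
  out$raw <- m
  out$totals <- totals
  out
}

#' Relative coverage of a hybrid against a parental panel
#'
#' For each LOH site, the hybrid's normalized depth divided by the mean
#' normalized depth of the parental panel at the same site. Sites with
#' no usable parental reference are dropped (count reported).
#'
#' @param normed a [normalize_depth()] result.
#' @param hybrid hybrid sample id.
#' @param parental_panel parental sample ids.
#' @param loh_sites integer site indices (rows of the depth table), as
#'   in `loh_calls$site` when genotypes and depth share site order, or
#'   from [match_depth_sites()].
#' @return numeric vector of relative coverages with attribute
#'   `n_dropped`.
#' @export
relative_coverage <- function(normed, hybrid, parental_panel, loh_sites) {
  ref <- rowMeans(normed$depth[loh_sites, parental_panel, drop = FALSE],
                  na.rm = TRUE)
  hyb <- normed$depth[loh_sites, hybrid]
  ok <- !is.na(ref) & ref > 0 & !is.na(hyb)
  if (!any(ok)) stop("no LOH site has a usable parental reference")
  out <- hyb[ok] / ref[ok]
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Match genotype-site coordinates to depth-table rows
#'
#' @param depth a [depth_table()].
#' @param sites data.frame with `contig`, `pos`.
#' @return integer row indices into the depth table (NA if absent).
#' @export
match_depth_sites <- function(depth, sites) {
  match(paste(sites$contig, sites$pos),
        paste(depth$sites$contig, depth$sites$pos))
}

#' Freedman-Diaconis histogram
#'
#' Bin width `h = 2 * IQR * n^(-1/3)`; values are clipped to
#' `[0, clip_max]` before binning (clipped count logged as attribute).
#' A zero IQR falls back to a fixed number of bins with a warning.
#'
#' @param values numeric vector (n >= 4).
#' @param clip_max upper clip (default 2).
#' @param fallback_bins bin count used when IQR is zero.
#' @return list of class `binned_histogram`: `mids`, `density`,
#'   `breaks`, `n`, `n_clipped`.
#' @export
fd_histogram <- function(values, clip_max = 2, fallback_bins = 30) {
  stopifnot(length(values) >= 4)
  n_clipped <- sum(values > clip_max | values < 0)
  v <- pmin(pmax(values, 0), clip_max)
  iqr <- IQR(v)
  if (iqr <= 0) {
    warning("zero IQR; falling back to ", fallback_bins, " fixed bins")
    breaks <- seq(min(v), max(v) + 1e-9, length.out = fallback_bins + 1)
  } else {
    h <- 2 * iqr * length(v)^(-1 / 3)
    breaks <- seq(floor(min(v) / h) * h, max(v) + h, by = h)
  }
  hh <- graphics::hist(v, breaks = breaks, plot = FALSE)
  structure(list(mids = hh$mids, density = hh$density,
                 breaks = hh$breaks, n = length(v),
                 n_clipped = n_clipped),
            class = "binned_histogram")
}

# Mixture density at x for fixed means mu and parameters (k_j, A_j)
mixture_density <- function(x, mu, k, A) {
  y <- 0
  for (j in seq_along(mu))
    y <- y + A[j] * dgamma(x, shape = k[j], rate = k[j] / mu[j])
  y
}

# Free-parameter count used in residual-df bookkeeping: each component
# contributes (amplitude, shape); a free mean adds one more.
n_free_params <- function(n_comp, free_mean) 2L * n_comp + free_mean

#' Fit a fixed-mean Gamma mixture to a relative-coverage histogram
#'
#' Minimizes, by nonlinear least squares at the bin midpoints
#' (unweighted, matching Gnuplot's default), the squared difference
#' between the binned density and
#' `sum_j A_j * dgamma(x; k_j, rate = k_j / mu_j)` with the means
#' `mu_j` fixed (1 and 0.5 for diploids; 1, 2/3, 1/3 for triploids).
#' Shapes `k_j` and amplitudes `A_j >= 0` are free. With
#' `free_mean = TRUE` a single component is fitted with its mean free
#' as well (the non-nested alternative model). Multi-start over
#' `k in {5, 20, 80}`; amplitudes are initialized from the histogram
#' mass on either side of the midpoint between adjacent means.
#'
#' @param hist a [fd_histogram()].
#' @param means numeric vector of 1-3 fixed component means.
#' @param free_mean fit a single free-mean Gamma instead.
#' @param weights optional per-bin weights for weighted least squares.
#' @return list of class `mixture_fit`: `means`, `shape`, `amplitude`,
#'   `rss`, `df` (= n_bins - free parameters), `n_bins`, `n_params`,
#'   `free_mean`, `cov` (approximate parameter covariance),
#'   `deletion_fraction` (`B/(A+B)` resp. `(B+C)/(A+B+C)`),
#'   `ratio_AB`, `ratio_AB_ci`.
#' @export
fit_fixed_mean_mixture <- function(hist, means = c(1, 0.5),
                                   free_mean = FALSE, weights = NULL) {
  stopifnot(inherits(hist, "binned_histogram"),
            length(means) %in% 1:3)
  if (free_mean && length(means) != 1)
    stop("free_mean fits are single-component")
  x <- hist$mids
  y <- hist$density
  w <- weights %||% rep(1, length(x))
  nb <- length(x)
  np <- n_free_params(length(means), free_mean)
  if (nb <= np) stop("fewer bins than free parameters")

  # amplitude starts: histogram mass split at midpoints between means
  cuts <- if (length(means) > 1)
    (means[-1] + means[-length(means)]) / 2 else numeric(0)
  edges <- c(Inf, cuts, -Inf)
  binw <- diff(hist$breaks)[1]
  A0 <- vapply(seq_along(means), function(j)
    max(sum(y[x <= edges[j] & x > edges[j + 1]] * binw), 0.05),
    numeric(1))

  # parameter vector: (k_1..k_J, A_1..A_J[, m]); bounded least squares
  J <- length(means)
  model_at <- function(par) {
    k <- par[seq_len(J)]
    A <- par[J + seq_len(J)]
    mu <- if (free_mean) par[2 * J + 1] else means
    mixture_density(x, mu, k, A)
  }
  obj <- function(par) sum(w * (y - model_at(par))^2)
  lower <- c(rep(0.5, J), rep(0, J), if (free_mean) 0.05)
  upper <- c(rep(500, J), rep(10, J), if (free_mean) 3)
  m0 <- sum(x * y * binw)  # free-mean start: histogram mean
  starts <- lapply(c(5, 20, 80), function(k0)
    c(rep(k0, J), pmax(A0, 0.02), if (free_mean) max(m0, 0.1)))
  if (J > 1)  # degenerate start: all mass on the first component, so a
    starts <- c(starts, list(c(rep(20, J),                # single-gamma
                               c(sum(A0), rep(1e-3, J - 1)),  # solution
                               if (free_mean) max(m0, 0.1)))) # is nested
  best <- NULL
  for (par0 in starts) {
    opt <- tryCatch(
      optim(par0, obj, method = "L-BFGS-B", lower = lower,
            upper = upper, control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value) &&
        (is.null(best) || opt$value < best$value - 1e-14))
      best <- opt
  }
  if (is.null(best))
    stop("gamma-mixture fit failed to converge from all starts ",
         "(n_bins = ", nb, ", means = ", paste(means, collapse = ","), ")")

  cf <- best$par
  names(cf) <- c(paste0("k", seq_len(J)),
                 c("A", "B", "C")[seq_len(J)], if (free_mean) "m")
  rss <- best$value
  # Gauss-Newton covariance: sigma^2 (J'J)^{-1}, numerical jacobian
  vc <- tryCatch({
    eps <- pmax(abs(cf) * 1e-5, 1e-7)
    Jac <- vapply(seq_along(cf), function(i) {
      up <- cf; up[i] <- up[i] + eps[i]
      dn <- cf; dn[i] <- dn[i] - eps[i]
      (model_at(up) - model_at(dn)) / (2 * eps[i])
    }, numeric(nb))
    sig2 <- rss / max(nb - np, 1)
    v <- sig2 * solve(crossprod(Jac * sqrt(w)))
    dimnames(v) <- list(names(cf), names(cf))
    v
  }, error = function(e)
    matrix(NA_real_, length(cf), length(cf),
           dimnames = list(names(cf), names(cf))))
  shape <- cf[seq_len(J)]
  amp <- cf[J + seq_len(J)]
  mu <- if (free_mean) cf[["m"]] else means
  del_frac <- if (!free_mean && length(means) > 1)
    sum(amp[-1]) / sum(amp) else NA_real_

  # A/B ratio and delta-method 95% CI (two-component fits)
  ratio <- ratio_ci <- NULL
  if (!free_mean && length(means) == 2 &&
      all(c("A", "B") %in% names(cf)) && cf[["B"]] > 0 &&
      !anyNA(vc[c("A", "B"), c("A", "B")])) {
    A <- cf[["A"]]; B <- cf[["B"]]
    ratio <- A / B
    g <- c(1 / B, -A / B^2)
    se <- sqrt(drop(t(g) %*% vc[c("A", "B"), c("A", "B")] %*% g))
    ratio_ci <- ratio + c(-1, 1) * stats::qnorm(0.975) * se
  }

  structure(list(means = mu, shape = unname(shape),
                 amplitude = unname(amp), rss = rss,
                 df = nb - np, n_bins = nb, n_params = np,
                 free_mean = free_mean, cov = vc,
                 deletion_fraction = del_frac,
                 ratio_AB = ratio, ratio_AB_ci = ratio_ci,
                 hist = hist),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> %d component(s)%s, %d bins, RSS %.4g, df %d\n",
              length(x$means), if (x$free_mean) " (free mean)" else "",
              x$n_bins, x$rss, x$df))
  comp <- data.frame(mean = round(x$means, 3), shape = round(x$shape, 2),
                     amplitude = round(x$amplitude, 3))
  print(comp, row.names = FALSE)
  if (!is.na(x$deletion_fraction %||% NA))
    cat(sprintf("  deletion fraction B/(A+B): %.3f\n",
                x$deletion_fraction))
  invisible(x)
}

#' Upper critical value of the F distribution
#'
#' @param df1,df2 degrees of freedom (simple model first).
#' @param alpha upper-tail level (default 0.05).
#' @return the critical value `qf(1 - alpha, df1, df2)`.
#' @export
f_critical <- function(df1, df2, alpha = 0.05) {
  stopifnot(df1 >= 1, df2 >= 1)
  qf(1 - alpha, df1, df2)
}

#' Variance-ratio F comparison of two mixture fits
#'
#' `F = (RSS_simple / df_simple) / (RSS_complex / df_complex)`, compared
#' against `f_critical(df_simple, df_complex, alpha)`. This is the
#' residual-variance-ratio form (not the incremental-SS form): the
#' critical values it produces at the paired residual dfs are the ones
#' printed alongside published fits of this kind.
#'
#' @param fit_simple,fit_complex [fit_fixed_mean_mixture()] results on
#'   the same histogram; the simple fit must have fewer free parameters.
#' @param alpha test level.
#' @return list `F`, `df` (pair), `critical`, `reject`.
#' @export
compare_variance_ratio <- function(fit_simple, fit_complex,
                                   alpha = 0.05) {
  stopifnot(fit_simple$n_bins == fit_complex$n_bins,
            fit_simple$n_params < fit_complex$n_params)
  if (fit_simple$df <= 0 || fit_complex$df <= 0)
    stop("non-positive residual degrees of freedom")
  Fstat <- (fit_simple$rss / fit_simple$df) /
    (fit_complex$rss / fit_complex$df)
  crit <- f_critical(fit_simple$df, fit_complex$df, alpha)
  list(F = Fstat, df = c(fit_simple$df, fit_complex$df),
       critical = crit, reject = Fstat > crit)
}

#' AICc comparison of two (possibly non-nested) fits
#'
#' `AICc = n ln(RSS/n) + 2K + 2K(K+1)/(n-K-1)` with `n` the number of
#' bins and `K` the free-parameter count plus one (for the error
#' variance).
#'
#' @param fitA,fitB fits on the same histogram.
#' @return list `aicc` (named pair), `delta` (loser minus winner),
#'   `preferred` (`"A"` or `"B"`).
#' @export
compare_aicc <- function(fitA, fitB) {
  stopifnot(fitA$n_bins == fitB$n_bins)
  aicc1 <- function(f) {
    n <- f$n_bins
    K <- f$n_params + 1L
    if (n - K - 1 <= 0) stop("AICc undefined: n - K - 1 <= 0")
    n * log(f$rss / n) + 2 * K + 2 * K * (K + 1) / (n - K - 1)
  }
  a <- aicc1(fitA); b <- aicc1(fitB)
  list(aicc = c(A = a, B = b), delta = abs(a - b),
       preferred = if (a <= b) "A" else "B")
}

#' Forced-amplitude-ratio test
#'
#' Refits the two-component mixture with the A/B amplitude ratio
#' constrained to the donor fit's 95% CI bound nearest the free
#' estimate, then compares forced vs free fits by
#' [compare_variance_ratio()] (forced model has one fewer free
#' parameter). Used to ask whether e.g. a diploid data set is
#' compatible with the deletion/conversion balance estimated in the
#' corresponding triploid.
#'
#' @param hist the acceptor histogram.
#' @param free_fit the free two-component fit on `hist`.
#' @param donor_fit two-component fit providing `ratio_AB_ci`.
#' @param alpha test level.
#' @return list `forced_fit`, `ratio_forced`, `F`, `df`, `critical`,
#'   `reject`.
#' @export
forced_ratio_test <- function(hist, free_fit, donor_fit, alpha = 0.05) {
  if (is.null(donor_fit$ratio_AB_ci))
    stop("donor fit carries no A/B ratio CI")
  ci <- pmax(donor_fit$ratio_AB_ci, 0)
  free_ratio <- free_fit$ratio_AB %||%
    (free_fit$amplitude[1] / free_fit$amplitude[2])
  r0 <- ci[which.min(abs(ci - free_ratio))]
  x <- hist$mids; y <- hist$density
  m1 <- free_fit$means[1]; m2 <- free_fit$means[2]
  # constrained fit: A = r0 * B, free (k1, k2, B)
  obj <- function(par) {
    yy <- par[3] * (r0 * dgamma(x, shape = par[1], rate = par[1] / m1) +
                      dgamma(x, shape = par[2], rate = par[2] / m2))
    sum((y - yy)^2)
  }
  starts <- c(lapply(c(5, 20, 80), function(k0)
    c(k0, k0, max(free_fit$amplitude[2], 0.02))),
    list(c(pmax(pmin(free_fit$shape, 500), 0.5),   # free solution as a
           max(free_fit$amplitude[2], 1e-3))))     # warm start
  best <- NULL
  for (par0 in starts) {
    opt <- tryCatch(
      optim(par0, obj, method = "L-BFGS-B", lower = c(0.5, 0.5, 0),
            upper = c(500, 500, 10), control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value) &&
        (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("forced-ratio refit failed to converge")
  cf <- best$par
  forced <- structure(list(means = free_fit$means,
                           shape = unname(cf[1:2]),
                           amplitude = unname(c(r0 * cf[3], cf[3])),
                           rss = best$value,
                           df = free_fit$n_bins - 3L,
                           n_bins = free_fit$n_bins, n_params = 3L,
                           free_mean = FALSE, cov = NULL,
                           deletion_fraction = 1 / (1 + r0),
                           ratio_AB = r0, ratio_AB_ci = NULL,
                           hist = hist),
                      class = "mixture_fit")
  cmp <- compare_variance_ratio(forced, free_fit, alpha)
  c(list(forced_fit = forced, ratio_forced = r0), cmp)
}

#' Site-matched Kolmogorov-Smirnov deletion test
#'
#' Builds the conversion-only null from the parental panel itself:
#' relative coverages at exactly the hybrid's LOH sites, computed for
#' each parental individual against the mean of the remaining panel
#' (leave-one-out), pooled; then a two-sample KS test of the hybrid's
#' relative coverages against that null. An excess of low-coverage LOH
#' sites in the hybrid indicates deletions.
#'
#' @param normed a [normalize_depth()] result.
#' @param hybrid hybrid sample id.
#' @param parental_panel >= 2 parental sample ids.
#' @param loh_sites depth-table row indices of the hybrid's LOH sites.
#' @return list `D`, `p`, `n_hybrid`, `n_null`.
#' @export
ks_site_matched <- function(normed, hybrid, parental_panel, loh_sites) {
  if (length(parental_panel) < 2)
    stop("leave-one-out null needs >= 2 parental individuals")
  if (!length(loh_sites)) stop("no LOH sites supplied")
  hyb <- relative_coverage(normed, hybrid, parental_panel, loh_sites)
  nulls <- unlist(lapply(parental_panel, function(p)
    relative_coverage(normed, p, setdiff(parental_panel, p), loh_sites)),
    use.names = FALSE)
  kt <- suppressWarnings(ks.test(hyb, nulls))
  list(D = unname(kt$statistic), p = kt$p.value,
       n_hybrid = length(hyb), n_null = length(nulls))
}
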