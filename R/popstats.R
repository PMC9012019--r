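#' Windowed nucleotide diversity
#'
#' Per-site diversity is the unbiased heterozygosity
#' `pi = 2 j (n - j) / (n (n - 1))` with `j` the alternate-allele count and
#' `n` the number of called alleles in the population at that site; the window
#' value is the sum of site diversities divided by the window length in bp
#' (per-bp diversity, the usual windowed-pi convention).  Sites with fewer
#' than two called alleles are unusable; a window with zero usable sites
#' carries `NA`, never 0.
#'
#' @param gm a [genotype_matrix()].
#' @param population one or more population labels (pooled).
#' @param window_bp window size in bp (default 100 kb).
#' @param step_bp step in bp; default equal to `window_bp` (non-overlapping).
#' @param anchor `"origin"` (windows tiled from position 1, the VCFtools
#'   convention, default) or `"first_variant"` (per-chromosome anchoring at
#'   the first variant).
#' @return data.frame of class `window_stat`: chrom, start, end (1-based
#'   inclusive), n_sites, value; attribute `statistic = "pi"`.
#' @export
window_pi <- function(gm, population, window_bp = 1e5, step_bp = window_bp,
                      anchor = c("origin", "first_variant")) {
  anchor <- match.arg(anchor)
  if (window_bp <= 0) stop("window_bp must be positive")
  ac <- allele_counts(gm, population)
  if (!any(ac$n >= 2 & ac$j > 0 & ac$j < ac$n)) {
    stop("population has no segregating site with >= 2 called alleles")
  }
  usable <- ac$n >= 2
  pi_site <- rep(0, nrow(ac))
  pi_site[usable] <- 2 * ac$j[usable] * (ac$n[usable] - ac$j[usable]) /
    (ac$n[usable] * (ac$n[usable] - 1))
  out <- lapply(unique(gm$sites$chrom), function(ch) {
    i <- gm$sites$chrom == ch
    pos <- gm$sites$pos[i]
    a0 <- if (anchor == "origin") 1L else min(pos)
    starts <- window_starts(a0, max(pos), window_bp, step_bp)
    agg <- window_aggregate(pos, pi_site[i], usable[i], starts, window_bp)
    data.frame(chrom = ch, start = starts, end = starts + window_bp - 1,
               n_sites = agg$n,
               value = ifelse(agg$n > 0, agg$sum / window_bp, NA_real_))
  })
  res <- do.call(rbind, out)
  attr(res, "statistic") <- "pi"
  class(res) <- c("window_stat", "data.frame")
  res
}

#' Per-site two-population F_ST components
#'
#' Weir & Cockerham's (1984) per-site variance components for two populations
#' (default), or Hudson's estimator (Bhatia et al. 2013 form).  Both are
#' returned as a numerator and denominator so windows can be formed as a
#' ratio of sums (ratio-of-averages), never as an average of ratios.  A site
#' needs at least two called alleles in each population to be usable.
#'
#' @param gm a [genotype_matrix()].
#' @param pop1,pop2 population labels (each may pool several labels).
#' @param method `"wc"` (Weir-Cockerham, default) or `"hudson"`.
#' @return data.frame: chrom, pos, num, den, fst (num/den, `NA` where den is
#'   0 or the site is unusable), usable.
#' @export
site_fst <- function(gm, pop1, pop2, method = c("wc", "hudson")) {
  method <- match.arg(method)
  s1 <- pop_samples(gm, pop1)
  s2 <- pop_samples(gm, pop2)
  if (length(intersect(s1, s2))) stop("pop1 and pop2 overlap")
  g1 <- gm$geno[, s1, drop = FALSE]
  g2 <- gm$geno[, s2, drop = FALSE]
  n1 <- rowSums(!is.na(g1))  # called diploids
  n2 <- rowSums(!is.na(g2))
  usable <- n1 >= 1 & n2 >= 1 & (2 * n1) >= 2 & (2 * n2) >= 2
  p1 <- rowSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(g2, na.rm = TRUE) / (2 * n2)
  if (method == "wc") {
    h1 <- rowSums(g1 == 1L, na.rm = TRUE) / n1
    h2 <- rowSums(g2 == 1L, na.rm = TRUE) / n2
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2v <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
      (s2v - (pbar * (1 - pbar) - (r - 1) / r * s2v - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2v - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- a
    den <- a + b + cc
    # nbar == 1 (one diploid per pop) leaves a/b undefined; flag unusable
    usable <- usable & nbar > 1
  } else {
    m1 <- 2 * n1  # haploid sample sizes
    m2 <- 2 * n2
    num <- (p1 - p2)^2 -
      p1 * (1 - p1) / pmax(m1 - 1, 1) - p2 * (1 - p2) / pmax(m2 - 1, 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
  }
  num[!usable] <- NA_real_
  den[!usable] <- NA_real_
  data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos,
             num = num, den = den,
             fst = ifelse(usable & den != 0, num / den, NA_real_),
             usable = usable & !is.na(den) & den != 0)
}

#' Windowed F_ST as a ratio of summed components
#'
#' Sums the per-site numerator and denominator components inside each window
#' and reports their ratio.  Windows default to the 50 kb / 2 kb sliding
#' configuration anchored at the first variant of each chromosome; setting
#' `step_bp = window_bp` gives non-overlapping windows.
#'
#' @param fst data.frame from [site_fst()].
#' @param window_bp window size in bp (default 50 kb).
#' @param step_bp step in bp (default 2 kb).
#' @param anchor `"first_variant"` (default) or `"origin"`.
#' @return data.frame of class `window_stat`: chrom, start, end, n_sites,
#'   value.
#' @export
window_fst <- function(fst, window_bp = 5e4, step_bp = 2e3,
                       anchor = c("first_variant", "origin")) {
  anchor <- match.arg(anchor)
  if (window_bp <= 0 || step_bp <= 0) stop("window_bp and step_bp must be positive")
  out <- lapply(unique(fst$chrom), function(ch) {
    i <- fst$chrom == ch
    pos <- fst$pos[i]
    a0 <- if (anchor == "origin") 1L else min(pos)
    starts <- window_starts(a0, max(pos), window_bp, step_bp)
    u <- fst$usable[i]
    sn <- window_aggregate(pos, ifelse(u, fst$num[i], 0), u, starts, window_bp)
    sd_ <- window_aggregate(pos, ifelse(u, fst$den[i], 0), u, starts, window_bp)
    val <- ifelse(sn$n > 0 & sd_$sum != 0, sn$sum / sd_$sum, NA_real_)
    data.frame(chrom = ch, start = starts, end = starts + window_bp - 1,
               n_sites = sn$n, value = val)
  })
  res <- do.call(rbind, out)
  attr(res, "statistic") <- "fst"
  class(res) <- c("window_stat", "data.frame")
  res
}

#' PBS from three pairwise F_ST values
#'
#' Branch lengths are `t = -ln(1 - F_ST)` with F_ST clamped into
#' `[0, 1 - 1e-9]`; the population branch statistic of the target `N` against
#' control `OT` and distant group `D` is
#' `PBS = (t_{N,OT} + t_{N,D} - t_{OT,D}) / 2`.
#'
#' @param fst_n_ot,fst_n_d,fst_ot_d pairwise F_ST values (vectors).
#' @return data.frame with the clamped branch lengths `t_n_ot`, `t_n_d`,
#'   `t_ot_d` and `pbs`.
#' @export
pbs_from_fst <- function(fst_n_ot, fst_n_d, fst_ot_d) {
  tr <- function(f) -log(1 - pmin(pmax(f, 0), 1 - 1e-9))
  t1 <- tr(fst_n_ot); t2 <- tr(fst_n_d); t3 <- tr(fst_ot_d)
  data.frame(t_n_ot = t1, t_n_d = t2, t_ot_d = t3,
             pbs = (t1 + t2 - t3) / 2)
}

#' Windowed population-branch-statistic scan
#'
#' Computes windowed F_ST for the three pairs (target vs control, target vs
#' distant, control vs distant) over a common set of windows, transforms each
#' to a branch length and combines them into PBS.  `control` and `distant`
#' may pool several population labels, which covers the usual scenario
#' presets (European control; Asian control; Euro-Asian pooled; other zebu
#' pooled) with the outgroup species as the distant group.
#'
#' @param gm a [genotype_matrix()].
#' @param target,control,distant disjoint population label groups.
#' @param window_bp,step_bp window size and step in bp (default 50 kb / 2 kb
#'   sliding; set `step_bp = window_bp` for non-overlapping windows).
#' @param method F_ST estimator passed to [site_fst()].
#' @param anchor window anchoring, see [window_fst()].
#' @return data.frame of class `window_stat`: chrom, start, end, n_sites,
#'   fst_n_ot, fst_n_d, fst_ot_d, t_n_ot, t_n_d, t_ot_d, value (= PBS).
#' @export
pbs_scan <- function(gm, target, control, distant,
                     window_bp = 5e4, step_bp = 2e3, method = "wc",
                     anchor = "first_variant") {
  groups <- list(target, control, distant)
  smp <- lapply(groups, function(g) pop_samples(gm, g))
  for (i in 1:2) for (j in (i + 1):3) {
    if (length(intersect(smp[[i]], smp[[j]]))) {
      stop("target/control/distant groups must be disjoint")
    }
  }
  f_no <- window_fst(site_fst(gm, target, control, method), window_bp, step_bp, anchor)
  f_nd <- window_fst(site_fst(gm, target, distant, method), window_bp, step_bp, anchor)
  f_od <- window_fst(site_fst(gm, control, distant, method), window_bp, step_bp, anchor)
  stopifnot(nrow(f_no) == nrow(f_nd), nrow(f_no) == nrow(f_od))
  pb <- pbs_from_fst(f_no$value, f_nd$value, f_od$value)
  res <- data.frame(chrom = f_no$chrom, start = f_no$start, end = f_no$end,
                    n_sites = pmin(f_no$n_sites, f_nd$n_sites, f_od$n_sites),
                    fst_n_ot = f_no$value, fst_n_d = f_nd$value,
                    fst_ot_d = f_od$value,
                    t_n_ot = pb$t_n_ot, t_n_d = pb$t_n_d, t_ot_d = pb$t_ot_d,
                    value = pb$pbs)
  attr(res, "statistic") <- "pbs"
  class(res) <- c("window_stat", "data.frame")
  res
}

#' Empirical top-quantile outlier windows
#'
#' Returns the windows whose statistic reaches the empirical top `quantile`
#' (default top 1%): the `ceiling(quantile * n)`-th largest non-missing value
#' defines the threshold and ties at the threshold are included.  Windows
#' with a missing value are excluded from the ranking.
#'
#' @param stats a `window_stat` data.frame (or any data.frame with a `value`
#'   column).
#' @param quantile upper tail mass, e.g. `0.01`.
#' @return the outlier subset of `stats`, ordered by decreasing value.
#' @export
empirical_outliers <- function(stats, quantile = 0.01) {
  v <- stats$value
  ok <- !is.na(v)
  if (!any(ok)) stop("no non-missing window values")
  vv <- v[ok]
  k <- max(1L, ceiling(quantile * length(vv)))
  thr <- sort(vv, decreasing = TRUE)[k]
  out <- stats[ok & v >= thr, , drop = FALSE]
  out[order(out$value, decreasing = TRUE), , drop = FALSE]
}

#' Write window statistics as tab-separated text
#'
#' @param stats a `window_stat` data.frame.
#' @param path output path.
#' @param bed write 0-based half-open coordinates (BED-compatible) instead of
#'   the 1-based inclusive default.
#' @return invisibly, `path`.
#' @export
write_window_stats <- function(stats, path, bed = FALSE) {
  df <- as.data.frame(stats)
  if (bed) {
    bc <- to_bed_coords(df$start, df$end)
    df$start <- bc$start
    df$end <- bc$end
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
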