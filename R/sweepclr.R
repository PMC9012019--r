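# Per-site spectrum classes for a population: sites with a complete set of
# calls in the population and a segregating allele.  Folded classes are minor
# allele counts 1..floor(n/2); unfolded classes are derived counts 1..n-1,
# polarized by requiring every outgroup group to be fixed for the same allele
# (sites with polymorphic, disagreeing or uncalled outgroups are dropped).
.sfs_site_classes <- function(gm, population, folded = TRUE, outgroups = NULL) {
  smp <- pop_samples(gm, population)
  g <- gm$geno[, smp, drop = FALSE]
  n <- 2L * length(smp)
  complete <- rowSums(is.na(g)) == 0
  j <- rowSums(g)  # NA where incomplete
  seg <- complete & !is.na(j) & j > 0 & j < n
  if (folded) {
    keep <- seg
    cls <- pmin(j, n - j)
  } else {
    if (is.null(outgroups)) stop("unfolded spectrum requires outgroups")
    anc <- rep(NA_integer_, nrow(g))  # 0 = ref ancestral, 1 = alt ancestral
    ok <- rep(TRUE, nrow(g))
    for (og in outgroups) {
      go <- gm$geno[, pop_samples(gm, og), drop = FALSE]
      no <- rowSums(!is.na(go))
      jo <- rowSums(go, na.rm = TRUE)
      fixed_ref <- no >= 1 & jo == 0
      fixed_alt <- no >= 1 & jo == 2 * no
      this <- ifelse(fixed_ref, 0L, ifelse(fixed_alt, 1L, NA_integer_))
      ok <- ok & !is.na(this) & (is.na(anc) | anc == this)
      anc <- ifelse(is.na(anc), this, anc)
    }
    keep <- seg & ok
    cls <- ifelse(anc == 0L, j, n - j)
  }
  list(n = n,
       n_classes = if (folded) n %/% 2L else n - 1L,
       sites = data.frame(chrom = gm$sites$chrom[keep],
                          pos = gm$sites$pos[keep],
                          class = cls[keep]))
}

#' Background site-frequency spectrum of a population
#'
#' Empirical spectrum over segregating sites with complete calls in the
#' population.  The folded spectrum (default) is over minor-allele counts
#' `1..floor(n/2)` and needs no outgroup; the unfolded spectrum is over
#' derived-allele counts `1..n-1` and requires outgroup polarization.
#'
#' @param gm a [genotype_matrix()].
#' @param population population label(s), pooled.
#' @param folded logical.
#' @param outgroups character vector of outgroup population labels (unfolded
#'   mode only); sites where any outgroup is polymorphic, uncalled, or where
#'   outgroups disagree are dropped.
#' @return an object of class `sfs_model`: list with `n` (haploid sample
#'   size), `probs` (spectrum over classes, sums to 1), `folded`, `n_sites`.
#' @export
background_sfs <- function(gm, population, folded = TRUE, outgroups = NULL) {
  sc <- .sfs_site_classes(gm, population, folded, outgroups)
  if (nrow(sc$sites) == 0) stop("no usable segregating sites")
  tab <- tabulate(sc$sites$class, nbins = sc$n_classes)
  structure(list(n = sc$n, probs = tab / sum(tab), folded = folded,
                 n_sites = nrow(sc$sites)),
            class = "sfs_model")
}

#' @export
print.sfs_model <- function(x, ...) {
  cat(sprintf("sfs_model: n = %d haploid, %s, %d sites\n",
              x$n, if (x$folded) "folded" else "unfolded", x$n_sites))
  invisible(x)
}

# Unfolded spectrum over 1..n-1 from an sfs_model; folded spectra are
# symmetrized (each folded class split equally between k and n-k).
.unfold_probs <- function(model) {
  n <- model$n
  if (!model$folded) return(model$probs)
  p <- numeric(n - 1)
  for (k in seq_len(n %/% 2L)) {
    if (k == n - k) p[k] <- model$probs[k]
    else {
      p[k] <- p[k] + model$probs[k] / 2
      p[n - k] <- p[n - k] + model$probs[k] / 2
    }
  }
  p
}

# Sweep transition matrix M[(b+1), (k+1)], b = 0..n escaped lineages,
# k = 0..n derived copies after the sweep.  Given b < n escapees, the
# post-sweep sample is b escaped lineages plus the single ancestral lineage
# all non-escapees coalesce into: b + 1 lineages drawn (hypergeometrically)
# from a background sample of n, then the ancestral lineage's allele is
# copied onto the n - b non-escapees.  b = n leaves no coalesced lineage and
# reduces to the background sample itself.
.sweep_transition <- function(punf, n) {
  M <- matrix(0, nrow = n + 1, ncol = n + 1)
  for (b in 0:(n - 1)) {
    m <- b + 1
    for (j in 0:m) {
      q <- sum(punf * stats::dhyper(j, 1:(n - 1), n - 1:(n - 1), m))
      if (q == 0) next
      w_anc_derived <- j / m
      if (j >= 1) {
        k1 <- (j - 1) + (n - b)
        M[b + 1, k1 + 1] <- M[b + 1, k1 + 1] + q * w_anc_derived
      }
      M[b + 1, j + 1] <- M[b + 1, j + 1] + q * (1 - w_anc_derived)
    }
  }
  M[n + 1, 2:n] <- punf
  M
}

#' Site probability under the sweep-distorted spectrum
#'
#' The composite-likelihood sweep model: a lineage at distance `d` bp from
#' the sweep escapes with probability `p_e = 1 - exp(-alpha d)`; escapes are
#' independent across the `n` sampled lineages, non-escapees coalesce into
#' one ancestral lineage at the sweep, and the resulting `B + 1` lineages are
#' a hypergeometric draw from the background spectrum, expanded back to `n`
#' by copying the ancestral lineage.  The returned mass is unconditional
#' (monomorphic classes `k = 0` and `k = n` included), so it sums to 1 over
#' `k = 0..n`; the scan conditions on segregation.
#'
#' @param background an [background_sfs()] model.
#' @param k allele-count class (vector allowed): derived count `0..n` for an
#'   unfolded model, minor count `0..floor(n/2)` for a folded model (class 0
#'   collects both monomorphic states).
#' @param d distance from the sweep in bp (scalar, >= 0).
#' @param alpha sweep strength per bp (scalar, > 0; `Inf` = background).
#' @return numeric vector of probabilities, one per element of `k`.
#' @export
sweep_site_probability <- function(background, k, d, alpha) {
  stopifnot(inherits(background, "sfs_model"), d >= 0, alpha > 0)
  n <- background$n
  kmax <- if (background$folded) n %/% 2L else n
  if (any(k < 0 | k > kmax)) stop("invalid allele-count class")
  pe <- if (is.infinite(alpha) || is.infinite(alpha * d)) 1 else 1 - exp(-alpha * d)
  M <- .sweep_transition(.unfold_probs(background), n)
  w <- stats::dbinom(0:n, n, pe)
  punc <- as.vector(w %*% M)  # over k = 0..n
  if (background$folded) {
    fold <- numeric(kmax + 1)
    fold[1] <- punc[1] + punc[n + 1]
    for (kk in seq_len(kmax)) {
      fold[kk + 1] <- if (kk == n - kk) punc[kk + 1] else punc[kk + 1] + punc[n - kk + 1]
    }
    fold[k + 1]
  } else {
    punc[k + 1]
  }
}

#' Composite likelihood ratio sweep scan
#'
#' For each of `grid` evenly spaced positions per chromosome, maximizes the
#' composite likelihood of the sweep-distorted spectrum over a log-spaced
#' grid of sweep strengths `alpha` and reports
#' `CLR = 2 (ln CL_sweep(alpha_hat) - ln CL_background)`.  Site probabilities
#' are conditioned on segregation; the alpha grid includes an `Inf` sentinel
#' equal to the background model, so CLR is never negative.  Ties in the
#' alpha maximization go to the smallest alpha; `alpha_hat = Inf` means the
#' background model was never beaten (no sweep signal).
#'
#' @param gm a [genotype_matrix()].
#' @param population target population label(s).
#' @param grid number of evenly spaced test positions per chromosome.
#' @param n_alpha number of finite alpha grid values (log-spaced between
#'   `1e1 / L` and `1e6 / L` for chromosome span `L`).
#' @param folded,outgroups spectrum mode, see [background_sfs()].
#' @param background optional precomputed [background_sfs()] model.
#' @return data.frame of class `sweep_scan`: chrom, pos, alpha, clr.
#' @export
clr_scan <- function(gm, population, grid = 200, n_alpha = 12,
                     folded = TRUE, outgroups = NULL, background = NULL) {
  if (grid < 1) stop("grid must be >= 1")
  if (is.null(background)) {
    background <- background_sfs(gm, population, folded, outgroups)
  }
  n <- background$n
  sc <- .sfs_site_classes(gm, population, folded, outgroups)
  if (sc$n != n) stop("background sample size does not match the data")
  M <- .sweep_transition(.unfold_probs(background), n)
  seg_mass <- rowSums(M[, 2:n, drop = FALSE])
  if (background$folded) {
    K <- n %/% 2L
    Mc <- matrix(0, nrow = n + 1, ncol = K)
    for (kk in seq_len(K)) {
      Mc[, kk] <- if (kk == n - kk) M[, kk + 1] else M[, kk + 1] + M[, n - kk + 1]
    }
  } else {
    Mc <- M[, 2:n, drop = FALSE]
  }
  bgp <- background$probs

  out <- lapply(unique(sc$sites$chrom), function(ch) {
    i <- sc$sites$chrom == ch
    pos <- sc$sites$pos[i]
    cls <- sc$sites$class[i]
    if (length(pos) == 0) return(NULL)
    L <- max(pos) - min(pos) + 1
    alphas <- c(exp(seq(log(1e1 / L), log(1e6 / L), length.out = n_alpha)), Inf)
    gridpos <- if (grid == 1) (min(pos) + max(pos)) / 2 else
      seq(min(pos), max(pos), length.out = grid)
    ll_bg <- sum(log(pmax(bgp[cls], 1e-300)))
    Mobs <- t(Mc)[cls, , drop = FALSE]  # sites x (n+1)
    res <- vapply(gridpos, function(gp) {
      dist <- abs(pos - gp)
      ll <- vapply(alphas, function(a) {
        pe <- if (is.infinite(a)) rep(1, length(dist)) else 1 - exp(-a * dist)
        pe[is.nan(pe)] <- 1
        D <- vapply(0:n, function(b) stats::dbinom(b, n, pe),
                    numeric(length(pe)))
        if (is.null(dim(D))) D <- matrix(D, nrow = 1)
        numer <- rowSums(D * Mobs)
        denom <- as.vector(D %*% seg_mass)
        sum(log(pmax(numer, 1e-300)) - log(pmax(denom, 1e-300)))
      }, numeric(1))
      best <- which.max(ll)  # first max = smallest alpha on ties
      c(alphas[best], 2 * (ll[best] - ll_bg))
    }, numeric(2))
    data.frame(chrom = ch, pos = gridpos, alpha = res[1, ], clr = res[2, ])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("sweep_scan", "data.frame")
  res
}

#' Write a sweep scan as tab-separated text
#'
#' Columns mirror a grid-scan report: chrom, position, alpha_hat, CLR.
#'
#' @param scan a `sweep_scan` data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_scan <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
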