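# Independent oracle implementations used to cross-check the package.  These
# deliberately take the slow, literal route (explicit loops, enumeration)
# and never call the functions they verify.

# Quick genotype_matrix from a plain matrix (sites x samples).
make_gm <- function(g, pops = "unassigned", chrom = "chr1",
                    pos = seq_len(nrow(as.matrix(g)))) {
  g <- as.matrix(g)
  genotype_matrix(
    g,
    data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
               stringsAsFactors = FALSE),
    pops
  )
}

# Weir & Cockerham (1984) two-population per-site estimator, transcribed
# formula by formula for a single site.  Returns c(a, a+b+c).
oracle_wc_site <- function(geno1, geno2) {
  geno1 <- geno1[!is.na(geno1)]
  geno2 <- geno2[!is.na(geno2)]
  n1 <- length(geno1); n2 <- length(geno2)
  if (n1 < 1 || n2 < 1) return(c(NA, NA))
  r <- 2
  p1 <- sum(geno1) / (2 * n1)
  p2 <- sum(geno2) / (2 * n2)
  h1 <- mean(geno1 == 1)
  h2 <- mean(geno2 == 1)
  n_bar <- (n1 + n2) / r
  if (n_bar <= 1) return(c(NA, NA))
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (1 / (n_bar - 1)) *
       (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  c(a, a + b + cc)
}

# Nucleotide diversity at one site by explicitly averaging differences over
# all unordered pairs of called alleles.
oracle_pi_site <- function(geno) {
  geno <- geno[!is.na(geno)]
  alleles <- unlist(lapply(geno, function(g) c(rep(1, g), rep(0, 2 - g))))
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  diffs <- 0; pairs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    diffs <- diffs + (alleles[i] != alleles[j])
    pairs <- pairs + 1
  }
  diffs / pairs
}

# Allele-sharing distance by a direct per-pair loop.
oracle_asd <- function(g) {
  ns <- ncol(g)
  D <- matrix(0, ns, ns)
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    if (i == j) next
    ok <- !is.na(g[, i]) & !is.na(g[, j])
    D[i, j] <- mean(abs(g[ok, i] - g[ok, j]) / 2)
  }
  D
}

# Sweep-distorted site probabilities by brute-force enumeration: every escape
# subset of the n lineages, every choice of which background lineages are
# sampled, every choice of the ancestral lineage.  punf is the unfolded
# background over derived counts 1..n-1.  Returns the vector over k = 0..n.
oracle_sweep_probs <- function(punf, n, pe) {
  out <- numeric(n + 1)
  for (esc_bits in 0:(2^n - 1)) {
    esc <- as.integer(intToBits(esc_bits))[1:n] == 1
    b <- sum(esc)
    p_esc <- pe^b * (1 - pe)^(n - b)
    if (p_esc == 0) next
    if (b == n) {
      # nothing coalesces: the sample is the plain background sample
      for (K in 1:(n - 1)) out[K + 1] <- out[K + 1] + p_esc * punf[K]
      next
    }
    m <- b + 1
    for (K in 1:(n - 1)) {
      pK <- punf[K]
      if (pK == 0) next
      bg <- c(rep(1, K), rep(0, n - K))  # background sample of n lineages
      subsets <- utils::combn(n, m, simplify = FALSE)
      for (S in subsets) {
        drawn <- bg[S]
        for (anc_idx in seq_len(m)) {  # which drawn lineage is ancestral
          anc <- drawn[anc_idx]
          escaped <- drawn[-anc_idx]
          k <- sum(escaped) + anc * (n - b)
          out[k + 1] <- out[k + 1] +
            p_esc * pK * (1 / length(subsets)) * (1 / m)
        }
      }
    }
  }
  out
}

# Heterozygote miscall probability under the platform caller: true genotype
# RA, depth ~ Poisson(lambda) truncated at maxd, ML call over {RR, RA, AA}
# with ties to RR.  Conditioned on depth >= 1.
oracle_het_miscall <- function(lambda, error_rate, maxd = 30) {
  p_hom <- 0; p_any <- 0
  for (d in 1:maxd) {
    pd <- stats::dpois(d, lambda)
    for (k in 0:d) {
      pk <- stats::dbinom(k, d, 0.5)
      liks <- c(stats::dbinom(k, d, error_rate),
                stats::dbinom(k, d, 0.5),
                stats::dbinom(k, d, 1 - error_rate))
      call <- which(liks == max(liks))[1]  # tie -> RR
      if (call != 2) p_hom <- p_hom + pd * pk
    }
    p_any <- p_any + pd
  }
  p_hom / p_any
}

# Probability the platform caller returns the true genotype, conditional on
# depth >= 1, by exact enumeration over depths and read draws.
oracle_match_rate <- function(true_g, lambda, error_rate, maxd = 40) {
  q <- c(error_rate, 0.5, 1 - error_rate)[true_g + 1]
  p_match <- 0; p_any <- 0
  for (d in 1:maxd) {
    pd <- stats::dpois(d, lambda)
    for (k in 0:d) {
      pk <- stats::dbinom(k, d, q)
      liks <- c(stats::dbinom(k, d, error_rate),
                stats::dbinom(k, d, 0.5),
                stats::dbinom(k, d, 1 - error_rate))
      call <- which(liks == max(liks))[1] - 1L  # tie -> RR
      if (call == true_g) p_match <- p_match + pd * pk
    }
    p_any <- p_any + pd
  }
  p_match / p_any
}

# Quadratic all-pairs window/gene overlap.
oracle_overlap <- function(windows, genes) {
  hits <- character(0)
  for (i in seq_len(nrow(windows))) for (j in seq_len(nrow(genes))) {
    if (windows$chrom[i] == genes$chrom[j] &&
        windows$start[i] <= genes$end[j] &&
        windows$end[i] >= genes$start[j]) {
      hits <- c(hits, genes$gene[j])
    }
  }
  sort(unique(hits))
}

# Exhaustive membership-vector tally of Venn regions.
oracle_regions <- function(sets) {
  sets <- lapply(sets, tolower)
  univ <- unique(unlist(sets))
  tally <- list()
  for (g in univ) {
    key <- paste(names(sets)[vapply(sets, function(s) g %in% s, TRUE)],
                 collapse = "&")
    tally[[key]] <- (tally[[key]] %||% 0L) + 1L
  }
  tally
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small two-population drift scenario shared by several tests.
two_pop_config <- function(seed, n_dip = 15, t = 100, ne = 1000,
                           len = 2e6, mu = 5e-3) {
  demography_config(
    data.frame(label = c("a", "b"), n_dip = n_dip, ne = ne,
               split_gen = c(t, t)),
    c(chr1 = len), mu, seed = seed
  )
}
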