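#' Demography configuration for the drift simulator
#'
#' Describes a fixed caterpillar population tree: population 1 is the target
#' and every later population joins the backbone at its `split_gen` (so splits
#' must be non-decreasing down the list).  Allele frequencies diverge by
#' Balding-Nichols beta drift: a branch of length `t` generations through
#' effective size `Ne` perturbs a frequency `p` to a Beta draw with mean `p`
#' and variance `p(1-p) F` where `F = 1 - exp(-t / (2 Ne))`.  Two sister
#' populations split `t` generations ago therefore have expected per-site
#' F_ST of `1 - exp(-t / (2 Ne))`.
#'
#' @param populations data.frame with columns `label`, `n_dip` (diploid sample
#'   size), `ne` (effective size, individuals), `split_gen` (generations since
#'   the lineage left the backbone leading to the target; the first row is the
#'   target and its `split_gen` must equal that of the second row).
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @param mu_density expected segregating sites per bp.
#' @param ne_ancestral effective size on internal (backbone) branches; default
#'   is the mean of the population `ne` values.
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return an object of class `demography_config`.
#' @export
demography_config <- function(populations, chrom_lengths, mu_density,
                              ne_ancestral = NULL, seed = 1L) {
  populations <- as.data.frame(populations, stringsAsFactors = FALSE)
  req <- c("label", "n_dip", "ne", "split_gen")
  if (!all(req %in% names(populations))) {
    stop("populations needs columns label, n_dip, ne, split_gen")
  }
  if (anyDuplicated(populations$label)) stop("population labels must be unique")
  if (nrow(populations) < 2) stop("at least two populations required")
  if (any(populations$n_dip <= 0) || any(populations$ne <= 0)) {
    stop("sample sizes and effective sizes must be strictly positive")
  }
  if (any(populations$split_gen[-1] <= 0)) stop("split times must be strictly positive")
  if (is.unsorted(populations$split_gen[-1])) {
    stop("populations must be ordered by non-decreasing split_gen")
  }
  if (is.null(names(chrom_lengths)) || any(chrom_lengths <= 0)) {
    stop("chrom_lengths must be a named vector of positive lengths")
  }
  if (mu_density <= 0) stop("mu_density must be positive")
  populations$split_gen[1] <- populations$split_gen[2]
  if (is.null(ne_ancestral)) ne_ancestral <- mean(populations$ne)
  structure(
    list(populations = populations,
         chrom_lengths = chrom_lengths,
         mu_density = mu_density,
         ne_ancestral = ne_ancestral,
         seed = as.integer(seed)),
    class = "demography_config"
  )
}

#' Default study-scale demography
#'
#' A desk-scale rendering of an admixed West-African zebu panel against its
#' usual comparison groups: the target zebu population, a sister group of
#' other African zebu, Asian zebu, European taurine, and two outgroup species
#' (banteng-like and water-buffalo-like).  Split times and effective sizes are
#' chosen so pairwise differentiation falls where cattle panels put it
#' (F_ST ~ 0.05 within African zebu, ~ 0.2-0.3 zebu vs taurine, > 0.7 against
#' the outgroup species); SNP density matches a filtered joint panel
#' (~2.6e-4 segregating sites per bp).
#'
#' @param seed integer seed.
#' @param chrom_lengths named chromosome lengths in bp.
#' @return a [demography_config()].
#' @export
default_demography <- function(seed = 1L,
                               chrom_lengths = c(chr1 = 10e6, chr2 = 10e6)) {
  demography_config(
    populations = data.frame(
      label = c("target_zebu", "african_zebu", "asian_zebu",
                "european_taurine", "banteng", "water_buffalo"),
      n_dip = c(20L, 12L, 8L, 7L, 5L, 4L),
      ne = c(1000, 1000, 1000, 600, 1000, 1000),
      split_gen = c(100, 100, 250, 600, 2500, 5000)
    ),
    chrom_lengths = chrom_lengths,
    mu_density = 2.6e-4,
    seed = seed
  )
}

#' Localized selective sweep specification
#'
#' Ground-truth sweep injected into the target population: within `radius` bp
#' of `center_bp` the derived (alternate) allele frequency is pushed toward
#' fixation, `p' = p + intensity * w * (1 - p)`, with a linear taper
#' `w = 1 - d/radius` so the distortion is strongest at the center.
#'
#' @param chrom chromosome name.
#' @param center_bp sweep center (bp).
#' @param radius_bp affected radius (bp), > 0.
#' @param intensity in `[0, 1]`.
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(chrom, center_bp, radius_bp, intensity) {
  if (radius_bp <= 0) stop("radius_bp must be positive")
  if (intensity < 0 || intensity > 1) stop("intensity must be in [0, 1]")
  structure(list(chrom = chrom, center_bp = center_bp,
                 radius_bp = radius_bp, intensity = intensity),
            class = "sweep_spec")
}

#' Sequencing-platform emulation parameters
#'
#' Models a reduced-representation, low-coverage re-call of a sample subset:
#' restriction-site subsetting as independent site retention, per-genotype
#' read depth as Poisson(`lambda`), reads drawn binomially from the true two
#' alleles with a per-read base-error rate, and maximum-likelihood genotype
#' re-calling over RR/RA/AA with a flat prior (ties broken toward RR).
#'
#' @param retention site retention probability in `(0, 1]`.
#' @param lambda mean sequencing depth (reads per site).
#' @param error_rate per-read base-error rate in `[0, 0.5)`.
#' @param gq_floor minimum phred-scaled genotype quality; re-called genotypes
#'   below the floor are set missing.  Default 0 (no floor).
#' @param seed integer seed.
#' @return an object of class `platform_config`.
#' @export
platform_config <- function(retention = 0.5, lambda = 5, error_rate = 0.001,
                            gq_floor = 0, seed = 1L) {
  if (retention <= 0 || retention > 1) stop("retention must be in (0, 1]")
  if (lambda <= 0) stop("lambda must be positive")
  if (error_rate < 0 || error_rate >= 0.5) stop("error_rate must be in [0, 0.5)")
  structure(list(retention = retention, lambda = lambda,
                 error_rate = error_rate, gq_floor = gq_floor,
                 seed = as.integer(seed)),
            class = "platform_config")
}

# Balding-Nichols drift: Beta perturbation with mean p and variance p(1-p)F,
# F = 1 - exp(-t/(2 Ne)).  F = 0 returns p unchanged; frequencies at 0/1 are
# absorbing.
drift_freq <- function(p, t_gen, ne) {
  f <- 1 - exp(-t_gen / (2 * ne))
  if (f <= 0) return(p)
  k <- 1 / f - 1
  out <- p
  seg <- p > 0 & p < 1
  out[seg] <- stats::rbeta(sum(seg), p[seg] * k, (1 - p[seg]) * k)
  out
}

#' Simulate multi-population genotype truth with known sweeps
#'
#' Draws ancestral allele frequencies from a neutral-like spectrum
#' (density proportional to 1/p), applies Balding-Nichols drift along the
#' caterpillar tree of the configuration, injects the requested sweeps into
#' the target population, and samples diploid genotypes binomially.  Sites
#' monomorphic across all samples are dropped (they are not SNPs).
#'
#' @param config a [demography_config()].
#' @param sweeps list of [sweep_spec()] objects; sweeps on one chromosome must
#'   not overlap.
#' @param admixture optional `list(from =, to =, weight =)` mixing tip
#'   frequencies `p_to <- (1-w) p_to + w p_from` before genotypes are drawn
#'   (used to create ground-truth gene flow for D-statistic testing).
#' @return list with elements `gm` (a [genotype_matrix()]) and `sweeps`
#'   (the truth record: data.frame chrom/center_bp/radius_bp/intensity).
#' @export
simulate_truth <- function(config, sweeps = list(), admixture = NULL) {
  stopifnot(inherits(config, "demography_config"))
  if (inherits(sweeps, "sweep_spec")) sweeps <- list(sweeps)
  for (sw in sweeps) {
    stopifnot(inherits(sw, "sweep_spec"))
    if (!sw$chrom %in% names(config$chrom_lengths)) {
      stop("sweep chromosome not in config: ", sw$chrom)
    }
    L <- config$chrom_lengths[[sw$chrom]]
    if (sw$center_bp < 1 || sw$center_bp > L) stop("sweep center outside chromosome")
  }
  truth <- if (length(sweeps)) {
    data.frame(chrom = vapply(sweeps, `[[`, "", "chrom"),
               center_bp = vapply(sweeps, `[[`, 0, "center_bp"),
               radius_bp = vapply(sweeps, `[[`, 0, "radius_bp"),
               intensity = vapply(sweeps, `[[`, 0, "intensity"))
  } else {
    data.frame(chrom = character(0), center_bp = numeric(0),
               radius_bp = numeric(0), intensity = numeric(0))
  }
  # overlapping sweeps on one chromosome are ill-defined ground truth
  if (nrow(truth) > 1) {
    for (ch in unique(truth$chrom)) {
      tw <- truth[truth$chrom == ch, , drop = FALSE]
      tw <- tw[order(tw$center_bp), , drop = FALSE]
      if (nrow(tw) > 1) {
        lo <- tw$center_bp - tw$radius_bp
        hi <- tw$center_bp + tw$radius_bp
        if (any(lo[-1] <= hi[-nrow(tw)])) stop("overlapping sweeps on chromosome ", ch)
      }
    }
  }

  pops <- config$populations
  npop <- nrow(pops)
  with_seed(config$seed, {
    per_chrom <- lapply(names(config$chrom_lengths), function(ch) {
      L <- config$chrom_lengths[[ch]]
      ns <- round(config$mu_density * L)
      if (ns < 1) stop("zero sites requested on chromosome ", ch)
      pos <- sort(sample.int(L, ns))
      # ancestral spectrum ~ 1/p on [0.02, 0.98]
      a <- 0.02; b <- 0.98
      p0 <- a * (b / a)^stats::runif(ns)

      # frequencies at backbone nodes, most ancient first
      split <- pops$split_gen
      tipf <- matrix(NA_real_, nrow = ns, ncol = npop)
      node_p <- p0
      node_t <- if (npop > 2) rev(split[-1]) else split[2]
      # walk from root (oldest split) toward the target: node i sits at time
      # node_t[i]; drift along backbone between consecutive nodes.
      for (i in seq_along(node_t)) {
        if (i > 1) node_p <- drift_freq(node_p, node_t[i - 1] - node_t[i], config$ne_ancestral)
        popi <- npop - i + 1  # population leaving the backbone at this node
        tipf[, popi] <- drift_freq(node_p, node_t[i], pops$ne[popi])
      }
      # target tip descends from the most recent node
      tipf[, 1] <- drift_freq(node_p, split[2], pops$ne[1])

      # sweep distortion in the target population only: a site within the
      # radius is hitch-hiked with probability `intensity`; at a hitch-hiked
      # site each sampled lineage escapes the sweep with probability d/radius
      # (0 at the center) and non-escapees carry the derived allele.  The
      # expected derived frequency is therefore pushed toward 1 as
      # p + intensity * (1 - d/radius) * (1 - p), while the sampled spectrum
      # shows the rare/high-derived excess of a real sweep rather than a
      # deterministic band of intermediate frequencies.
      s_sweep <- numeric(ns)  # per-site probability a lineage is swept
      for (k in seq_len(nrow(truth))) {
        if (truth$chrom[k] != ch) next
        d <- abs(pos - truth$center_bp[k])
        hit <- d <= truth$radius_bp[k]
        hh <- hit & stats::runif(ns) < truth$intensity[k]
        s_sweep[hh] <- pmax(0, 1 - d[hh] / truth$radius_bp[k])
      }
      if (!is.null(admixture)) {
        i_from <- match(admixture$from, pops$label)
        i_to <- match(admixture$to, pops$label)
        if (is.na(i_from) || is.na(i_to)) stop("admixture populations not in config")
        w <- admixture$weight
        tipf[, i_to] <- (1 - w) * tipf[, i_to] + w * tipf[, i_from]
      }

      geno <- matrix(NA_integer_, nrow = ns, ncol = sum(pops$n_dip))
      off <- 0L
      for (i in seq_len(npop)) {
        n <- pops$n_dip[i]
        if (i == 1 && any(s_sweep > 0)) {
          m <- stats::rbinom(ns * n, 2L, rep(s_sweep, n))  # swept copies
          geno[, off + seq_len(n)] <-
            m + stats::rbinom(ns * n, 2L - m, rep(tipf[, i], n))
        } else {
          geno[, off + seq_len(n)] <-
            stats::rbinom(ns * n, 2L, rep(tipf[, i], n))
        }
        off <- off + n
      }
      list(pos = pos, geno = geno)
    })
    names(per_chrom) <- names(config$chrom_lengths)

    geno <- do.call(rbind, lapply(per_chrom, `[[`, "geno"))
    sites <- do.call(rbind, lapply(names(per_chrom), function(ch) {
      data.frame(chrom = ch, pos = per_chrom[[ch]]$pos,
                 ref = "A", alt = "G", stringsAsFactors = FALSE)
    }))
    colnames(geno) <- unlist(lapply(seq_len(npop), function(i) {
      sprintf("%s_%02d", pops$label[i], seq_len(pops$n_dip[i]))
    }))
    poplab <- rep(pops$label, pops$n_dip)

    ac <- rowSums(geno)
    seg <- ac > 0 & ac < 2 * ncol(geno)
    gm <- genotype_matrix(geno[seg, , drop = FALSE],
                          sites[seg, , drop = FALSE], poplab)
    list(gm = gm, sweeps = truth)
  })
}

# Genotype log-likelihoods for k alt reads out of d given per-read alt
# probabilities (e, 1/2, 1-e) for RR/RA/AA.
.call_ml <- function(k, d, e) {
  l_rr <- stats::dbinom(k, d, e)
  l_ra <- stats::dbinom(k, d, 0.5)
  l_aa <- stats::dbinom(k, d, 1 - e)
  lik <- cbind(l_rr, l_ra, l_aa)
  call <- max.col(lik, ties.method = "first") - 1L  # tie -> RR first
  best <- lik[cbind(seq_len(nrow(lik)), call + 1L)]
  second <- apply(lik, 1, function(z) sort(z, decreasing = TRUE)[2])
  gq <- 10 * (log10(pmax(best, 1e-300)) - log10(pmax(second, 1e-300)))
  list(call = call, gq = gq)
}

#' Emulate a low-coverage platform re-call of a sample subset
#'
#' Retains each site independently with the retention probability; for
#' retained sites draws per-genotype depth from Poisson(lambda), samples reads
#' binomially from the true alleles with the base-error rate, and re-calls the
#' genotype by flat-prior maximum likelihood over RR/RA/AA.  Depth 0 gives a
#' missing call; heterozygote under-calling emerges mechanically at low depth
#' (all reads from one chromosome).  Positions, ref/alt labels and sample
#' order are never changed.
#'
#' @param truth a [genotype_matrix()] of true genotypes.
#' @param platform a [platform_config()].
#' @param samples character vector of sample identifiers to re-call.
#' @return a [genotype_matrix()] restricted to retained sites and `samples`.
#' @export
emulate_platform <- function(truth, platform, samples = truth$samples) {
  stopifnot(inherits(truth, "genotype_matrix"), inherits(platform, "platform_config"))
  if (length(samples) == 0) stop("sample subset must be non-empty")
  miss <- setdiff(samples, truth$samples)
  if (length(miss)) stop("samples not in truth: ", paste(miss, collapse = ", "))
  with_seed(platform$seed, {
    ns <- nrow(truth$geno)
    keep <- stats::runif(ns) < platform$retention
    sub <- subset_gm(truth, sites = keep, samples = samples)
    g <- sub$geno
    e <- platform$error_rate
    d <- stats::rpois(length(g), platform$lambda)
    q <- c(e, 0.5, 1 - e)[g + 1L]              # per-read alt probability
    k <- stats::rbinom(length(g), d, ifelse(is.na(q), 0, q))
    ml <- .call_ml(k, d, e)
    new_g <- ml$call
    new_g[d == 0L | is.na(g)] <- NA_integer_
    new_g[!is.na(new_g) & ml$gq < platform$gq_floor] <- NA_integer_
    gg <- matrix(new_g, nrow = nrow(g), ncol = ncol(g), dimnames = dimnames(g))
    structure(list(geno = gg, sites = sub$sites, samples = sub$samples,
                   pops = sub$pops),
              class = "genotype_matrix")
  })
}

#' Read simulator configuration from a YAML file
#'
#' Expects top-level keys `populations` (list of label/n_dip/ne/split_gen
#' records), `chrom_lengths` (named map), `mu_density`, optional
#' `ne_ancestral`, `seed`, and optional `platform`
#' (retention/lambda/error_rate/gq_floor/seed).
#'
#' @param path path to a YAML config file.
#' @return list with elements `demography` and (if present) `platform`.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pops <- do.call(rbind, lapply(cfg$populations, as.data.frame))
  dem <- demography_config(
    populations = pops,
    chrom_lengths = unlist(cfg$chrom_lengths),
    mu_density = cfg$mu_density,
    ne_ancestral = cfg$ne_ancestral,
    seed = if (is.null(cfg$seed)) 1L else cfg$seed
  )
  out <- list(demography = dem)
  if (!is.null(cfg$platform)) {
    out$platform <- do.call(platform_config, cfg$platform)
  }
  out
}

#' Write a sweep truth record as tab-separated text
#'
#' @param truth data.frame as returned in `simulate_truth()$sweeps`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_truth_record <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
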