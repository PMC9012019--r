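#' Patterson's D ("ABBA-BABA") on population allele frequencies
#'
#' Per usable site, with derived frequencies `p_i` polarized so the outgroup
#' carries the ancestral (major) allele, the discordant site-pattern weights
#' are `ABBA = (1 - p1) p2 p3 (1 - p4)` and `BABA = p1 (1 - p2) p3 (1 - p4)`;
#' `D = sum(ABBA - BABA) / sum(ABBA + BABA)`.  The standard error comes from
#' a delete-one block jackknife over contiguous genomic blocks and
#' `Z = D / SE`.  Sites where the outgroup derived frequency exceeds
#' `polar_max` after polarization are dropped as unpolarizable; each
#' population needs at least two called alleles at a site.
#'
#' The usual significance convention is `|Z| >= 3`; no multiple-testing
#' correction is applied.
#'
#' @param gm a [genotype_matrix()].
#' @param p1,p2,p3,p4 disjoint population label groups; `p4` is the outgroup.
#'   Under the tree `(((P1, P2), P3), P4)`, an excess of ABBA over BABA
#'   indicates gene flow between P3 and P2 (D > 0) or P3 and P1 (D < 0).
#' @param block_bp jackknife block size in bp; default spans each chromosome
#'   with 20 blocks (block count takes precedence over a fixed size at
#'   desk-scale chromosome lengths).
#' @param polar_max maximum outgroup derived-allele frequency for a site to
#'   count as polarizable (default 0.1).
#' @return an object of class `dstat_result`: one-row data.frame with P1..P4,
#'   abba, baba, D, SE, Z, n_blocks, n_sites.
#' @export
d_statistic <- function(gm, p1, p2, p3, p4, block_bp = NULL, polar_max = 0.1) {
  groups <- list(p1, p2, p3, p4)
  smp <- lapply(groups, function(g) pop_samples(gm, g))
  for (i in 1:3) for (j in (i + 1):4) {
    if (length(intersect(smp[[i]], smp[[j]]))) stop("population groups must be disjoint")
  }
  fr <- lapply(groups, function(g) {
    ac <- allele_counts(gm, g)
    ifelse(ac$n >= 2, ac$j / ac$n, NA_real_)
  })
  f1 <- fr[[1]]; f2 <- fr[[2]]; f3 <- fr[[3]]; f4 <- fr[[4]]
  usable <- !is.na(f1) & !is.na(f2) & !is.na(f3) & !is.na(f4)
  flip <- usable & f4 > 0.5
  for (v in c("f1", "f2", "f3", "f4")) {
    assign(v, ifelse(flip, 1 - get(v), get(v)))
  }
  usable <- usable & f4 <= polar_max
  abba <- (1 - f1) * f2 * f3 * (1 - f4)
  baba <- f1 * (1 - f2) * f3 * (1 - f4)
  abba[!usable] <- 0
  baba[!usable] <- 0
  tot <- sum(abba) + sum(baba)
  if (tot == 0) stop("D undefined: no ABBA/BABA signal at usable sites")

  # contiguous genomic blocks, per chromosome
  blk <- integer(length(abba))
  off <- 0L
  for (ch in unique(gm$sites$chrom)) {
    i <- gm$sites$chrom == ch
    pos <- gm$sites$pos[i]
    bb <- if (is.null(block_bp)) ceiling((max(pos) - min(pos) + 1) / 20) else block_bp
    blk[i] <- off + 1L + (pos - min(pos)) %/% bb
    off <- max(blk[i])
  }
  ab <- tapply(abba, blk, sum)
  bb_ <- tapply(baba, blk, sum)
  nonempty <- (ab + bb_) > 0
  ab <- ab[nonempty]; bb_ <- bb_[nonempty]
  g <- length(ab)
  if (g < 2) stop("need at least two non-empty jackknife blocks")
  D <- (sum(ab) - sum(bb_)) / (sum(ab) + sum(bb_))
  d_jack <- vapply(seq_len(g), function(i) {
    (sum(ab[-i]) - sum(bb_[-i])) / (sum(ab[-i]) + sum(bb_[-i]))
  }, numeric(1))
  se <- sqrt((g - 1) / g * sum((d_jack - mean(d_jack))^2))
  res <- data.frame(
    P1 = paste(p1, collapse = "+"), P2 = paste(p2, collapse = "+"),
    P3 = paste(p3, collapse = "+"), P4 = paste(p4, collapse = "+"),
    abba = sum(abba), baba = sum(baba),
    D = D, SE = se, Z = if (se > 0) D / se else NA_real_,
    n_blocks = g, n_sites = sum(usable),
    stringsAsFactors = FALSE
  )
  class(res) <- c("dstat_result", "data.frame")
  res
}

#' All D-statistic quadruples for a fixed outgroup
#'
#' Runs [d_statistic()] for every unordered pair `{P1, P2}` with every third
#' population `P3`, against the fixed outgroup: `choose(m, 2) * (m - 2)`
#' tests for `m` candidate populations (the `P1 <-> P2` swap only flips the
#' sign of D and is de-duplicated by keeping `P1 < P2` lexicographically).
#'
#' @param gm a [genotype_matrix()].
#' @param outgroup outgroup population label(s).
#' @param populations candidate populations; default all non-outgroup labels.
#' @param ... passed to [d_statistic()].
#' @return data.frame of `dstat_result` rows.
#' @export
all_quadruples <- function(gm, outgroup, populations = NULL, ...) {
  if (is.null(populations)) {
    populations <- setdiff(unique(gm$pops), outgroup)
  }
  populations <- sort(populations)
  if (length(populations) < 3) stop("need at least three non-outgroup populations")
  rows <- list()
  for (pair in utils::combn(populations, 2, simplify = FALSE)) {
    for (p3 in setdiff(populations, pair)) {
      rows[[length(rows) + 1]] <- d_statistic(gm, pair[1], pair[2], p3, outgroup, ...)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Write a D-statistic table as tab-separated text
#'
#' @param d a data.frame of `dstat_result` rows.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_dstat <- function(d, path) {
  utils::write.table(as.data.frame(d), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
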