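#' Partition a query call set against a reference call set
#'
#' Every site of the query call set is assigned to exactly one of three
#' classes: *concordant-shared* (position present in the reference with the
#' same REF/ALT alleles), *discordant-shared* (position present, alleles
#' disagree) or *novel* (position absent from the reference).  Percentages are
#' reported at two decimals with round-half-up, so printed concordance figures
#' are exactly reproducible from the counts.
#'
#' The two call sets must share at least one sample identifier (the framing is
#' a re-call of the same individuals on a second platform).
#'
#' @param query a [genotype_matrix()] (e.g. the GBS-like call set).
#' @param reference a [genotype_matrix()] used as the benchmark (e.g. WGS).
#' @return an object of class `concordance_report`: a list with `counts`
#'   (query_loci, shared, concordant, discordant, novel), `pct`
#'   (shared, concordant_of_shared, discordant_of_shared, novel) and
#'   `class_rates` (filled by [genotype_match_rates()], `NULL` here).
#' @export
classify_sites <- function(query, reference) {
  shared_samples <- intersect(query$samples, reference$samples)
  if (length(shared_samples) == 0) stop("query and reference share no samples")
  kq <- site_key(query$sites)
  kr <- site_key(reference$sites)
  idx <- match(kq, kr)
  shared <- !is.na(idx)
  same_alleles <- shared
  same_alleles[shared] <-
    query$sites$ref[shared] == reference$sites$ref[idx[shared]] &
    query$sites$alt[shared] == reference$sites$alt[idx[shared]]
  counts <- c(
    query_loci = length(kq),
    shared = sum(shared),
    concordant = sum(same_alleles),
    discordant = sum(shared & !same_alleles),
    novel = sum(!shared)
  )
  report <- structure(
    list(counts = counts,
         pct = concordance_percentages(counts),
         class_rates = NULL,
         shared_samples = shared_samples),
    class = "concordance_report"
  )
  stopifnot(counts["shared"] + counts["novel"] == counts["query_loci"],
            counts["concordant"] + counts["discordant"] == counts["shared"])
  report
}

#' Percentages of a site-partition count vector
#'
#' @param counts named vector with `query_loci`, `shared`, `concordant`,
#'   `discordant`, `novel`.
#' @return named vector of two-decimal round-half-up percentages.
#' @export
concordance_percentages <- function(counts) {
  q <- counts[["query_loci"]]
  s <- counts[["shared"]]
  c(
    shared = round_half_up(100 * s / q),
    concordant_of_shared = if (s > 0) round_half_up(100 * counts[["concordant"]] / s) else NA_real_,
    discordant_of_shared = if (s > 0) round_half_up(100 * counts[["discordant"]] / s) else NA_real_,
    novel = round_half_up(100 * counts[["novel"]] / q)
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Call-set concordance report\n")
  cat(sprintf("  query loci        %10d\n", x$counts[["query_loci"]]))
  cat(sprintf("  shared positions  %10d  (%.2f%%)\n",
              x$counts[["shared"]], x$pct[["shared"]]))
  cat(sprintf("  allele-concordant %10d  (%.2f%% of shared)\n",
              x$counts[["concordant"]], x$pct[["concordant_of_shared"]]))
  cat(sprintf("  alt-discordant    %10d  (%.2f%% of shared)\n",
              x$counts[["discordant"]], x$pct[["discordant_of_shared"]]))
  cat(sprintf("  novel positions   %10d  (%.2f%%)\n",
              x$counts[["novel"]], x$pct[["novel"]]))
  if (!is.null(x$class_rates)) {
    cat("  genotype match rates (by reference class):\n")
    for (cl in names(x$class_rates)) {
      cat(sprintf("    %s  %.4f\n", cl, x$class_rates[[cl]]))
    }
  }
  invisible(x)
}

#' Per-genotype-class match rates between two call sets
#'
#' On the shared, allele-concordant sites and shared samples, computes the
#' fraction of genotype calls agreeing with the reference, separately for the
#' reference genotype classes RR, RA and AA.  Pairs with a missing call in
#' either set are excluded from the denominator; a class with no comparable
#' genotype is reported `NA`.
#'
#' @param query,reference [genotype_matrix()] objects sharing samples.
#' @return named numeric vector `c(RR=, RA=, AA=)` with attribute `n`
#'   (comparable genotypes per class).
#' @export
genotype_match_rates <- function(query, reference) {
  shared_samples <- intersect(query$samples, reference$samples)
  if (length(shared_samples) == 0) stop("query and reference share no samples")
  kq <- site_key(query$sites)
  kr <- site_key(reference$sites)
  idx <- match(kq, kr)
  ok <- !is.na(idx)
  ok[ok] <- query$sites$ref[ok] == reference$sites$ref[idx[ok]] &
    query$sites$alt[ok] == reference$sites$alt[idx[ok]]
  gq <- query$geno[ok, shared_samples, drop = FALSE]
  gr <- reference$geno[idx[ok], shared_samples, drop = FALSE]
  both <- !is.na(gq) & !is.na(gr)
  rates <- numeric(3)
  ns <- integer(3)
  for (cl in 0:2) {
    comp <- both & gr == cl
    ns[cl + 1] <- sum(comp)
    rates[cl + 1] <- if (ns[cl + 1] > 0) sum(gq[comp] == cl) / ns[cl + 1] else NA_real_
  }
  structure(stats::setNames(rates, c("RR", "RA", "AA")),
            n = stats::setNames(ns, c("RR", "RA", "AA")))
}

#' Allele-sharing distance matrix
#'
#' `D(i, j)` is the mean over sites called in both samples of
#' `|g_i - g_j| / 2`; 0 for identical samples, 1 for samples homozygous for
#' opposite alleles everywhere.  Missing genotypes are handled
#' pairwise-complete; a pair with no co-called site is an error.
#'
#' @param gm a [genotype_matrix()] with at least two samples.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
allele_sharing_distance <- function(gm) {
  if (ncol(gm$geno) < 2) stop("need at least two samples")
  G <- gm$geno
  M <- !is.na(G)
  # |a-b| over {0,1,2} decomposes into two binary |x-y| terms via the
  # cumulative indicators x1 = (g >= 1), x2 = (g == 2)
  X1 <- (G >= 1L); X1[!M] <- FALSE
  X2 <- (G == 2L); X2[!M] <- FALSE
  Mn <- matrix(as.numeric(M), nrow(M))
  X1 <- matrix(as.numeric(X1), nrow(M))
  X2 <- matrix(as.numeric(X2), nrow(M))
  cnt <- crossprod(Mn)
  if (any(cnt[upper.tri(cnt)] == 0)) {
    bad <- which(cnt == 0 & upper.tri(cnt), arr.ind = TRUE)[1, ]
    stop("no co-called sites for pair ", gm$samples[bad[1]], " / ",
         gm$samples[bad[2]])
  }
  s1 <- crossprod(X1, Mn); a1 <- s1 + t(s1) - 2 * crossprod(X1)
  s2 <- crossprod(X2, Mn); a2 <- s2 + t(s2) - 2 * crossprod(X2)
  D <- (a1 + a2) / (2 * cnt)
  diag(D) <- 0
  dimnames(D) <- list(gm$samples, gm$samples)
  (D + t(D)) / 2
}

#' Pearson correlation between two distance matrices
#'
#' Correlates the strictly-lower-triangle entries of two same-shaped distance
#' matrices with the standard t-distributed p-value (the usual check that two
#' genotyping platforms recover the same genetic distances).
#'
#' @param d1,d2 symmetric matrices of identical dimension with at least three
#'   off-diagonal pairs.
#' @return list with elements `r` and `p`.
#' @export
matrix_correlation <- function(d1, d2) {
  if (!all(dim(d1) == dim(d2))) stop("distance matrices differ in shape")
  v1 <- d1[lower.tri(d1)]
  v2 <- d2[lower.tri(d2)]
  if (length(v1) < 3) stop("need at least three off-diagonal pairs")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("zero variance in a distance vector")
  }
  ct <- stats::cor.test(v1, v2, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Write a concordance report
#'
#' @param report a `concordance_report`.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return invisibly, `path`.
#' @export
write_concordance <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(counts = as.list(report$counts), pct = as.list(report$pct),
           class_rates = as.list(report$class_rates)),
      path, auto_unbox = TRUE, digits = NA, null = "null"
    )
  } else {
    df <- data.frame(metric = c(names(report$counts), names(report$pct)),
                     value = c(unname(report$counts), unname(report$pct)))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a distance matrix as square tab-separated text
#'
#' @param d symmetric matrix with dimnames.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_distance_matrix <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
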