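#' Genotype matrix container
#'
#' The universal carrier between pipeline stages: diploid genotype codes for a
#' set of samples at a set of biallelic SNP sites.  Codes are counts of the
#' alternate allele: `0` = homozygous reference (RR), `1` = heterozygous (RA),
#' `2` = homozygous alternate (AA), `NA` = missing call.
#'
#' @param geno integer matrix, sites in rows, samples in columns; entries in
#'   `{0, 1, 2, NA}`.
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`
#'   (one alternate allele per site).  Positions must be strictly increasing
#'   within each chromosome.
#' @param populations character vector of population labels, one per sample;
#'   recycled if length 1.  Sample identifiers are taken from
#'   `colnames(geno)`.
#' @return an object of class `genotype_matrix` with elements `geno`, `sites`,
#'   `samples`, `pops`.
#' @export
genotype_matrix <- function(geno, sites, populations = "unassigned") {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  rownames(geno) <- NULL
  if (is.null(colnames(geno))) {
    colnames(geno) <- paste0("S", seq_len(ncol(geno)))
  }
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(sites))) {
    stop("sites must have columns chrom, pos, ref, alt")
  }
  if (nrow(sites) != nrow(geno)) stop("sites and geno row counts differ")
  bad <- !(geno %in% c(0L, 1L, 2L, NA))
  if (any(bad, na.rm = TRUE)) stop("genotype codes must be 0, 1, 2 or NA")
  if (grepl(",", paste(sites$alt, collapse = ""))) {
    stop("one alternate allele per site required")
  }
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  dup <- ave(sites$pos, sites$chrom, FUN = function(p) c(0, diff(p)) <= 0 & seq_along(p) > 1)
  if (any(dup > 0)) stop("positions must be strictly increasing within chromosome")
  pops <- rep_len(as.character(populations), ncol(geno))
  names(pops) <- colnames(geno)
  rownames(sites) <- NULL
  structure(
    list(geno = geno, sites = sites, samples = colnames(geno), pops = pops),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d sites x %d samples, %d population(s) [%s]\n",
    nrow(x$geno), ncol(x$geno), length(unique(x$pops)),
    paste(utils::head(unique(x$pops), 6), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param sites logical or integer index over sites (rows).
#' @param samples character sample names or index over samples.
#' @return a `genotype_matrix`.
#' @export
subset_gm <- function(gm, sites = NULL, samples = NULL) {
  g <- gm$geno
  s <- gm$sites
  p <- gm$pops
  if (!is.null(sites)) {
    g <- g[sites, , drop = FALSE]
    s <- s[sites, , drop = FALSE]
  }
  if (!is.null(samples)) {
    if (is.character(samples)) {
      miss <- setdiff(samples, colnames(g))
      if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))
    }
    g <- g[, samples, drop = FALSE]
    p <- p[colnames(g)]
  }
  rownames(s) <- NULL
  structure(list(geno = g, sites = s, samples = colnames(g), pops = p),
            class = "genotype_matrix")
}

# Samples belonging to one or more population labels (pooling = one group).
pop_samples <- function(gm, populations) {
  miss <- setdiff(populations, unique(gm$pops))
  if (length(miss)) stop("unknown population(s): ", paste(miss, collapse = ", "))
  names(gm$pops)[gm$pops %in% populations]
}

#' Per-site allele counts for a population group
#'
#' Missing genotypes are dropped per site; `n` is the number of called alleles
#' (twice the called diploids) and `j` the alternate-allele count among them.
#'
#' @param gm a [genotype_matrix()].
#' @param populations one or more population labels, pooled into a single
#'   group.
#' @return data.frame with columns `n` and `j`, one row per site.
#' @export
allele_counts <- function(gm, populations) {
  sub <- gm$geno[, pop_samples(gm, populations), drop = FALSE]
  called <- !is.na(sub)
  data.frame(
    n = 2L * rowSums(called),
    j = rowSums(sub, na.rm = TRUE)
  )
}

# Key string used wherever sites are matched across call sets.
site_key <- function(sites) paste(sites$chrom, sites$pos, sep = ":")
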