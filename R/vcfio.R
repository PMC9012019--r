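#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF 4.x file (plain or gzip-compressed) with the GT FORMAT field
#' into a [genotype_matrix()].  Phased separators are accepted and unphased
#' internally.  Multiallelic records (comma in ALT) are skipped when
#' `biallelic_only = TRUE` (the default) and rejected with an error otherwise.
#'
#' @param path path to a `.vcf` or `.vcf.gz` file.
#' @param popmap optional path to a two-column tab-separated file mapping
#'   sample identifier to population label, or a named character vector.
#' @param biallelic_only skip multiallelic records instead of erroring.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, popmap = NULL, biallelic_only = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no records: ", path)
  if (ncol(v@gt) < 2 || !any(grepl("GT", v@gt[, 1]))) {
    stop("VCF has no GT field: ", path)
  }
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    if (!biallelic_only) stop(sum(multi), " multiallelic record(s) present")
    keep <- !multi
  } else {
    keep <- rep(TRUE, nrow(fix))
  }
  gt <- tryCatch(vcfR::extract.gt(v, element = "GT"),
                 error = function(e) stop("VCF has no GT field: ", path))
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  s <- gsub("\\|", "/", gt)
  code <- matrix(NA_integer_, nrow = nrow(s), ncol = ncol(s),
                 dimnames = dimnames(s))
  code[s == "0/0"] <- 0L
  code[s == "0/1" | s == "1/0"] <- 1L
  code[s == "1/1"] <- 2L
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  pops <- "unassigned"
  if (!is.null(popmap)) {
    if (is.character(popmap) && length(popmap) == 1 && file.exists(popmap)) {
      popmap <- read_population_map(popmap)
    }
    pops <- unname(popmap[colnames(code)])
    if (anyNA(pops)) {
      stop("samples missing from population map: ",
           paste(colnames(code)[is.na(pops)], collapse = ", "))
    }
  }
  genotype_matrix(code, sites, pops)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a sample-to-population mapping
#'
#' @param path two-column tab-separated text: sample identifier, population
#'   label.  No header.
#' @return named character vector (names = samples).
#' @export
read_population_map <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("sample", "population"))
  stats::setNames(m$population, m$sample)
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits one biallelic record per site with a diploid GT field; missing calls
#' become `./.`.  A `.gz` suffix triggers gzip compression.  Round trips with
#' [read_vcf()]: sites, samples and genotypes are preserved.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path (`.vcf` or `.vcf.gz`).
#' @return invisibly, `path`.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$geno + 1L], nrow = nrow(gm$geno))
  gt_str[is.na(gm$geno)] <- "./."
  body <- paste(
    gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref, gm$sites$alt,
    ".", "PASS", ".", "GT",
    apply(gt_str, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=herdscan_%s", as.character(utils::packageVersion("herdscan"))),
    sprintf("##contig=<ID=%s>", unique(gm$sites$chrom)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Site filter specification
#'
#' @param min_call_rate minimum genotype call rate per site, in `[0, 1]`.
#' @param biallelic require a segregating minor allele (sites monomorphic
#'   among called genotypes are dropped).
#' @param min_mac optional minimum minor-allele count.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(min_call_rate = 0.9, biallelic = TRUE, min_mac = NULL) {
  if (min_call_rate < 0 || min_call_rate > 1) stop("min_call_rate must be in [0, 1]")
  structure(list(min_call_rate = min_call_rate, biallelic = biallelic,
                 min_mac = min_mac),
            class = "filter_spec")
}

#' Apply site filters
#'
#' Retains sites whose genotype call rate is at least the threshold and, if
#' requested, that carry a segregating minor allele (with at least `min_mac`
#' copies).  Site order is preserved; the operation is idempotent.
#'
#' @param gm a [genotype_matrix()].
#' @param spec a [filter_spec()].
#' @return a filtered [genotype_matrix()] (possibly empty).
#' @export
filter_sites <- function(gm, spec = filter_spec()) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(spec, "filter_spec"))
  called <- !is.na(gm$geno)
  rate <- rowMeans(called)
  keep <- rate >= spec$min_call_rate
  if (isTRUE(spec$biallelic) || !is.null(spec$min_mac)) {
    j <- rowSums(gm$geno, na.rm = TRUE)
    n <- 2L * rowSums(called)
    mac <- pmin(j, n - j)
    floor_mac <- max(if (isTRUE(spec$biallelic)) 1L else 0L,
                     spec$min_mac %||% 0L)
    keep <- keep & mac >= floor_mac
  }
  subset_gm(gm, sites = keep)
}

#' Restrict two call sets to their shared positions
#'
#' Both outputs contain exactly the (chromosome, position) pairs present in
#' both inputs, in the same order.  Sites whose REF/ALT labels disagree are
#' kept (and later separated by the concordance report).
#'
#' @param a,b [genotype_matrix()] objects.
#' @return list with elements `a` and `b`.
#' @export
intersect_sites <- function(a, b) {
  ka <- site_key(a$sites)
  kb <- site_key(b$sites)
  common <- intersect(ka, kb)
  list(a = subset_gm(a, sites = ka %in% common),
       b = subset_gm(b, sites = kb %in% common))
}

#' Merge the samples of two call sets over their shared sites
#'
#' The joint-panel construction: restrict both call sets to shared positions,
#' drop sites whose REF/ALT labels disagree, and bind the sample columns.
#' Sample identifiers must be disjoint.
#'
#' @param a,b [genotype_matrix()] objects with disjoint samples.
#' @return a [genotype_matrix()] with `ncol(a) + ncol(b)` samples.
#' @export
merge_samples <- function(a, b) {
  if (length(intersect(a$samples, b$samples))) {
    stop("sample identifiers must be disjoint; use intersect_sites() + ",
         "classify_sites() for shared-sample comparison")
  }
  xs <- intersect_sites(a, b)
  same <- xs$a$sites$ref == xs$b$sites$ref & xs$a$sites$alt == xs$b$sites$alt
  ga <- subset_gm(xs$a, sites = same)
  gb <- subset_gm(xs$b, sites = same)
  genotype_matrix(cbind(ga$geno, gb$geno), ga$sites,
                  c(unname(ga$pops), unname(gb$pops)))
}
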