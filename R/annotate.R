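#' Read gene intervals from GTF/GFF3 or BED
#'
#' GTF/GFF3 files are parsed with rtracklayer; `gene`-typed features are
#' preferred and, when absent, the per-`gene_id` envelope of the remaining
#' features is used.  BED input is treated as 0-based half-open per the
#' standard (rtracklayer converts to 1-based inclusive on import), with the
#' `name` column as the gene identifier.
#'
#' @param path path to a `.gtf`, `.gff`/`.gff3` or `.bed` file.
#' @param format override the extension-based format guess
#'   (`"gtf"`, `"gff3"`, `"bed"`).
#' @return data.frame of gene intervals: gene, chrom, start, end (1-based
#'   inclusive), strand.
#' @export
read_gene_intervals <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     gtf = "gtf", gff = "gff3", gff3 = "gff3", bed = "bed",
                     stop("cannot guess annotation format for ", path))
  }
  gr <- rtracklayer::import(path, format = format)
  if (format == "bed") {
    gene <- if (!is.null(gr$name)) gr$name else paste0("feature", seq_along(gr))
    df <- data.frame(gene = gene,
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     stringsAsFactors = FALSE)
  } else {
    md <- as.data.frame(gr)
    id_col <- intersect(c("gene_id", "ID", "Name"), names(md))[1]
    if (is.na(id_col)) stop("no gene_id/ID/Name attribute in ", path)
    if ("type" %in% names(md) && any(md$type == "gene")) {
      md <- md[md$type == "gene", , drop = FALSE]
      df <- data.frame(gene = md[[id_col]], chrom = as.character(md$seqnames),
                       start = md$start, end = md$end,
                       strand = as.character(md$strand),
                       stringsAsFactors = FALSE)
    } else {
      # envelope per gene id over transcript/exon features
      sp <- split(md, md[[id_col]])
      df <- do.call(rbind, lapply(names(sp), function(g) {
        x <- sp[[g]]
        data.frame(gene = g, chrom = as.character(x$seqnames[1]),
                   start = min(x$start), end = max(x$end),
                   strand = as.character(x$strand[1]),
                   stringsAsFactors = FALSE)
      }))
    }
  }
  if (any(df$end < df$start)) stop("malformed interval (end < start)")
  if (any(!nzchar(df$gene))) stop("empty gene identifier")
  rownames(df) <- NULL
  df
}

#' Named gene set
#'
#' @param name set name.
#' @param genes character vector of gene identifiers; duplicates are removed
#'   and matching downstream is case-insensitive.
#' @return an object of class `gene_set` (character vector with a `name`
#'   attribute).
#' @export
gene_set <- function(name, genes) {
  if (!nzchar(name)) stop("set name must be non-empty")
  structure(sort(unique(as.character(genes))), name = name, class = "gene_set")
}

#' Map outlier windows to overlapping genes
#'
#' A gene is included iff its interval overlaps any outlier window by at
#' least `1 + 2*flank_bp` ... precisely: windows are extended by `flank_bp`
#' on both sides and a >= 1 bp interval overlap is required.  If the window
#' and annotation chromosome names are completely disjoint a warning with
#' both name sets' counts is raised (not an error).
#'
#' @param windows data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive), e.g. from [empirical_outliers()].
#' @param annotation gene-interval data.frame from [read_gene_intervals()].
#' @param flank_bp extra flank added to each window side (default 0).
#' @param name name for the resulting [gene_set()].
#' @return a [gene_set()] of the overlapped genes, deduplicated and sorted.
#' @export
map_windows_to_genes <- function(windows, annotation, flank_bp = 0,
                                 name = "outlier_genes") {
  if (nrow(annotation) == 0) stop("annotation is empty")
  if (nrow(windows) == 0) return(gene_set(name, character(0)))
  shared <- intersect(unique(windows$chrom), unique(annotation$chrom))
  if (length(shared) == 0) {
    warning(sprintf(
      "no shared chromosome names: %d window chrom(s) vs %d annotation chrom(s)",
      length(unique(windows$chrom)), length(unique(annotation$chrom))
    ))
    return(gene_set(name, character(0)))
  }
  w <- GenomicRanges::GRanges(
    windows$chrom,
    IRanges::IRanges(pmax(1, windows$start - flank_bp), windows$end + flank_bp)
  )
  g <- GenomicRanges::GRanges(
    annotation$chrom, IRanges::IRanges(annotation$start, annotation$end)
  )
  hits <- GenomicRanges::findOverlaps(g, w, minoverlap = 1L)
  gene_set(name, annotation$gene[unique(S4Vectors::queryHits(hits))])
}

#' Venn-style overlap accounting over gene sets
#'
#' For every non-empty subset of set names, counts the genes belonging to
#' exactly that subset (the Venn regions), plus per-set totals, pairwise
#' intersection sizes, and "shared by at least k sets" counts.  Gene symbol
#' matching is case-insensitive exact match.
#'
#' @param sets a named list of [gene_set()]s or plain character vectors
#'   (names taken from the list, falling back to the `gene_set` names).
#' @return list of class `overlap_counts` with `regions` (data.frame:
#'   membership pattern, count), `totals`, `pairwise`, `shared_by_k`,
#'   `union_size`.
#' @export
overlap_counts <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- vapply(sets, function(s) attr(s, "name") %||% "", "")
  }
  if (length(sets) < 2) stop("need at least two sets")
  if (anyDuplicated(names(sets))) stop("set names must be unique")
  sets <- lapply(sets, function(s) unique(tolower(as.character(s))))
  univ <- unique(unlist(sets))
  member <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (is.null(dim(member))) member <- matrix(member, nrow = length(univ))
  pattern <- apply(member, 1, function(r) paste(names(sets)[r], collapse = "&"))
  regions <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(regions) <- c("sets", "count")
  totals <- vapply(sets, length, 0L)
  pairs <- utils::combn(names(sets), 2, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(set1 = p[1], set2 = p[2],
               intersection = length(intersect(sets[[p[1]]], sets[[p[2]]])),
               stringsAsFactors = FALSE)
  }))
  k_counts <- rowSums(member)
  shared_by_k <- vapply(seq_along(sets), function(k) sum(k_counts >= k), 0L)
  names(shared_by_k) <- paste0(">=", seq_along(sets))
  structure(
    list(regions = regions, totals = totals, pairwise = pairwise,
         shared_by_k = shared_by_k, union_size = length(univ)),
    class = "overlap_counts"
  )
}

#' Count of genes belonging to exactly one given region pattern
#'
#' Convenience accessor: `region_count(oc, c("PBS"))` is the number of genes
#' unique to PBS, `region_count(oc, c("PBS", "CLR"))` the number in exactly
#' the PBS-and-CLR region.
#'
#' @param oc an [overlap_counts()] result.
#' @param which_sets character vector of set names defining the region.
#' @return integer count (0 when the region is empty).
#' @export
region_count <- function(oc, which_sets) {
  key <- paste(sort(which_sets), collapse = "&")
  pat <- vapply(strsplit(oc$regions$sets, "&", fixed = TRUE),
                function(s) paste(sort(s), collapse = "&"), "")
  i <- match(key, pat)
  if (is.na(i)) 0L else oc$regions$count[i]
}

#' @export
print.overlap_counts <- function(x, ...) {
  cat("Gene-set overlap accounting\n")
  cat("  totals: ", paste(sprintf("%s=%d", names(x$totals), x$totals),
                          collapse = ", "), "\n")
  cat("  union:  ", x$union_size, "\n")
  for (i in seq_len(nrow(x$regions))) {
    cat(sprintf("  [%s] %d\n", x$regions$sets[i], x$regions$count[i]))
  }
  invisible(x)
}
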