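#' PCA of a genotype matrix with Patterson normalization
#'
#' Each site is centered by twice its mean allele frequency `2 p_hat` and
#' scaled by `sqrt(2 p_hat (1 - p_hat))`; missing genotypes are mean-imputed
#' per site before normalization (distances, by contrast, are always
#' pairwise-complete — imputation is confined to PCA).  The sample covariance
#' of the normalized matrix is eigendecomposed; variance explained is each
#' eigenvalue over the trace.
#'
#' @param gm a [genotype_matrix()] with at least two samples and two
#'   polymorphic sites.
#' @param n_comp number of leading components to return.
#' @return an object of class `pca_result`: list with `coords` (samples x
#'   components, unit-norm eigenvectors), `varexp` (percent variance
#'   explained per component, non-increasing), `n_sites`.
#' @export
pca_genotypes <- function(gm, n_comp = 10) {
  G <- gm$geno
  if (ncol(G) < 2) stop("need at least two samples")
  p <- rowMeans(G, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (sum(poly) < 2) stop("need at least two polymorphic sites")
  G <- G[poly, , drop = FALSE]
  p <- p[poly]
  X <- G
  imp <- is.na(X)
  if (any(imp)) X[imp] <- (2 * p)[row(X)[imp]]
  X <- (X - 2 * p) / sqrt(2 * p * (1 - p))
  C <- crossprod(X) / nrow(X)  # samples x samples
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  n_comp <- min(n_comp, ncol(C) - 1)
  coords <- eg$vectors[, seq_len(n_comp), drop = FALSE]
  rownames(coords) <- gm$samples
  colnames(coords) <- paste0("PC", seq_len(n_comp))
  structure(
    list(coords = coords,
         varexp = 100 * ev[seq_len(n_comp)] / sum(diag(C)),
         eigenvalues = eg$values[seq_len(n_comp)],
         n_sites = nrow(X)),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, %d sites\n", nrow(x$coords), x$n_sites))
  for (i in seq_along(x$varexp)) {
    cat(sprintf("  PC%d  %.3f%% of total variation\n", i, x$varexp[i]))
  }
  invisible(x)
}

#' Collapse a sample distance matrix to population level
#'
#' Averages the pairwise sample distances within each population pair (the
#' between-population block mean; within-population diagonal is 0).
#'
#' @param d symmetric sample distance matrix with sample dimnames.
#' @param pops named character vector mapping sample to population (e.g.
#'   `gm$pops`).
#' @return symmetric population-level distance matrix.
#' @export
population_distance <- function(d, pops) {
  labels <- unique(unname(pops[rownames(d)]))
  m <- matrix(0, length(labels), length(labels), dimnames = list(labels, labels))
  for (i in seq_along(labels)) for (j in seq_along(labels)) {
    if (i == j) next
    m[i, j] <- mean(d[pops[rownames(d)] == labels[i],
                      pops[colnames(d)] == labels[j]])
  }
  m
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (via [ape::nj()]) with non-negative branch
#' lengths: a negative estimated branch is clamped to zero and its (negative)
#' excess moved onto the branches adjacent below it, preserving path lengths
#' through the affected node where possible.  On an additive distance matrix
#' the tree's path distances reproduce the input exactly.
#'
#' @param d symmetric numeric matrix with zero diagonal, non-negative
#'   entries, and at least three labelled rows.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need at least three labels")
  if (is.null(rownames(d))) stop("distance matrix must be labelled")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distance matrix must be non-negative")
  if (any(diag(d) != 0)) stop("distance matrix must have zero diagonal")
  tr <- ape::nj(d)
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    excess <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    child <- tr$edge[e, 2]
    below <- which(tr$edge[, 1] == child)
    if (length(below)) tr$edge.length[below] <- tr$edge.length[below] + excess
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Write a tree in Newick format
#'
#' Branch lengths are written with six significant digits.  Optional
#' outgroup rooting inserts the root at the midpoint of the branch leading
#' to the requested label.
#'
#' @param tree a `phylo` object.
#' @param path output path.
#' @param root_at optional leaf label to root at (mid-branch insertion).
#' @return invisibly, `path`.
#' @export
write_newick <- function(tree, path, root_at = NULL) {
  if (!is.null(root_at)) {
    if (!root_at %in% tree$tip.label) stop("unknown root label: ", root_at)
    tree <- ape::root(tree, outgroup = root_at, resolve.root = TRUE)
    # resolve.root leaves the full outgroup branch on one side of the new
    # root; split it evenly (mid-branch insertion)
    root_node <- ape::Ntip(tree) + 1L
    kids <- which(tree$edge[, 1] == root_node)
    if (length(kids) == 2) {
      tot <- sum(tree$edge.length[kids])
      tree$edge.length[kids] <- tot / 2
    }
  }
  tree$edge.length <- signif(tree$edge.length, 6)
  ape::write.tree(tree, file = path)
  invisible(path)
}
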