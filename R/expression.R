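## Expression comparison of culture models vs xenografts on
## already-normalized log2 matrices: fold-change counting, Venn
## partitioning, correlation clustering with ordinary bootstrap support,
## and the xenograft size formula.

#' Read a gene x sample expression matrix
#'
#' Tab-delimited, first column gene/probe identifiers, remaining columns
#' log2 expression per sample.  Replicate columns sharing a sample label
#' (`label`, `label_1`, `label.2`, ...) are averaged on load.  Identifiers
#' must be unique and values complete; sample labels are checked against
#' `samples`.
#'
#' @param path Path to the TSV file.
#' @param samples Admissible sample labels (default [expressionSamples()];
#'   `NULL` skips the check).
#' @return Numeric matrix, genes x samples, log2 scale.
#' @export
readExpressionMatrix <- function(path, samples = expressionSamples()) {
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  ids <- d[[1]]
  if (anyDuplicated(ids))
    stop("duplicated identifiers: ",
         paste(unique(ids[duplicated(ids)])[1:3], collapse = ", "))
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("missing values in expression matrix")
  rownames(m) <- ids
  labels <- sub("[._][0-9]+$", "", colnames(m))
  if (!is.null(samples)) {
    bad <- setdiff(unique(labels), samples)
    if (length(bad))
      stop("unknown sample label(s): ", paste(bad, collapse = ", "))
  }
  ## replicate averaging
  out <- vapply(unique(labels), function(l)
    rowMeans(m[, labels == l, drop = FALSE]), numeric(nrow(m)))
  out
}

#' Count >= fold-change up/down genes between two samples
#'
#' On log2 values, a gene is upregulated in `sampleA` versus `sampleB`
#' when `a - b >= log2(fold)` and downregulated when `a - b <=
#' -log2(fold)`.  Gene lists are sorted by decreasing absolute fold
#' change.  Antisymmetric: `up(a, b)` equals `down(b, a)`.
#'
#' @param matrix Gene x sample log2 matrix.
#' @param sampleA,sampleB Column names to compare.
#' @param fold Fold-change threshold (> 1, default 2).
#' @return List with `up`, `down` (character vectors), `nUp`, `nDown`,
#'   `n` (combined count).
#' @examples
#' m <- cbind(a = c(g1 = 3, g2 = 0, g3 = -2), b = c(0, 0, 0))
#' foldChangeCounts(m, "a", "b")$n  # 2
#' @export
foldChangeCounts <- function(matrix, sampleA, sampleB, fold = 2) {
  stopifnot(fold > 1)
  miss <- setdiff(c(sampleA, sampleB), colnames(matrix))
  if (length(miss)) stop("unknown sample label(s): ", paste(miss, collapse = ", "))
  d <- matrix[, sampleA] - matrix[, sampleB]
  lf <- log2(fold)
  up <- d[d >= lf]
  down <- d[d <= -lf]
  list(up = names(sort(abs(up), decreasing = TRUE)),
       down = names(sort(abs(down), decreasing = TRUE)),
       nUp = length(up), nDown = length(down),
       n = length(up) + length(down))
}

#' Exact Venn partition of gene sets
#'
#' Partitions the union of `k >= 2` named sets into the `2^k - 1` disjoint
#' membership regions.  Region names join the member set names with `&`;
#' counts always sum to the size of the union.
#'
#' @param sets Named list of character vectors (empty sets allowed).
#' @return Named list of character vectors, one per region (regions with
#'   no genes are empty vectors).
#' @examples
#' vennPartition(list(A = c("a", "b"), B = c("b", "c")))
#' @export
vennPartition <- function(sets) {
  stopifnot(length(sets) >= 2, !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, unique)
  un <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) un %in% s, logical(length(un)))
  if (length(un) == 1L) memb <- matrix(memb, 1L, length(sets),
                                       dimnames = list(NULL, names(sets)))
  k <- length(sets)
  regions <- list()
  for (i in seq_len(2^k - 1)) {
    inset <- as.logical(intToBits(i))[seq_len(k)]
    name <- paste(names(sets)[inset], collapse = "&")
    sel <- if (length(un)) apply(memb, 1, function(r) all(r == inset)) else logical()
    regions[[name]] <- un[sel]
  }
  regions
}

## leaf-label splits (one per internal node) of an hclust tree
hclustSplits <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    m <- hc$merge[i, ]
    members[[i]] <- c(if (m[1] < 0) hc$labels[-m[1]] else members[[m[1]]],
                      if (m[2] < 0) hc$labels[-m[2]] else members[[m[2]]])
  }
  lapply(members, function(x) paste(sort(x), collapse = "|"))
}

#' Correlation clustering of samples with bootstrap support
#'
#' Pairwise Pearson correlation of samples over genes, distance
#' `1 - correlation`, average-linkage agglomeration.  For each internal
#' edge the ordinary bootstrap probability (bp) is the fraction of
#' gene-resampled trees containing the same leaf split.
#'
#' @param matrix Gene x sample log2 matrix (>= 3 samples).
#' @param bootstraps Number of gene resamples (0 skips bp).
#' @param seed Integer seed.
#' @return List with `correlation` (matrix), `hclust` (the tree), `splits`
#'   (leaf sets per internal node), `bp` (numeric per internal node, NA if
#'   `bootstraps = 0`) and `newick` (the tree with bp annotations).
#' @export
correlationAndCluster <- function(matrix, bootstraps = 1000, seed = 1L) {
  stopifnot(ncol(matrix) >= 3, bootstraps >= 0)
  v <- apply(matrix, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance sample(s): ",
         paste(colnames(matrix)[v == 0], collapse = ", "))
  C <- cor(matrix)
  hc <- hclust(as.dist(1 - C), method = "average")
  splits <- unlist(hclustSplits(hc))
  bp <- rep(NA_real_, length(splits))
  if (bootstraps > 0) {
    set.seed(as.integer(seed))
    hits <- numeric(length(splits))
    n <- nrow(matrix)
    for (b in seq_len(bootstraps)) {
      idx <- sample.int(n, n, replace = TRUE)
      mb <- matrix[idx, , drop = FALSE]
      vb <- apply(mb, 2, stats::var)
      if (any(vb == 0)) next
      hb <- hclust(as.dist(1 - cor(mb)), method = "average")
      hits <- hits + (splits %in% unlist(hclustSplits(hb)))
    }
    bp <- hits / bootstraps
  }
  phy <- ape::as.phylo(hc)
  if (bootstraps > 0) {
    ## attach bp (percent) to the matching internal nodes
    phySplit <- vapply(seq_len(phy$Nnode) + length(phy$tip.label), function(nd) {
      paste(sort(ape::extract.clade(phy, nd)$tip.label), collapse = "|")
    }, "")
    phy$node.label <- round(100 * bp[match(phySplit, splits)], 1)
  }
  list(correlation = C, hclust = hc, splits = splits, bp = bp,
       newick = ape::write.tree(phy))
}

#' Xenograft tumour area from palpation
#'
#' `(length / 2) * (width / 2) * pi` in mm^2; symmetric in length and
#' width.
#'
#' @param length,width Tumour dimensions in mm (> 0).
#' @return Area(s) in mm^2.
#' @examples
#' xenograftArea(20, 10)  # 50 * pi ~ 157.08
#' @export
xenograftArea <- function(length, width) {
  if (any(length <= 0) || any(width <= 0))
    stop("length and width must be positive")
  (length / 2) * (width / 2) * pi
}
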