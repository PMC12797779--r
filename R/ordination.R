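#' Principal component analysis with cos2 and contributions
#'
#' Centred (optionally scaled) PCA via singular value decomposition.
#' Beyond scores and explained variance fractions it reports, per input
#' variable, the squared correlation with each retained component (`cos2`,
#' the correlation-circle quality of representation) and per-component
#' normalised contributions. Intended both for population-level frequency
#' matrices and individual-level dosage matrices; missing dosages are
#' mean-imputed per variable before decomposition.
#'
#' @param x numeric matrix, entities x features.
#' @param standardize scale features to unit variance (default `TRUE`).
#'   Zero-variance features are dropped with a warning.
#' @param k number of components to retain (default: all).
#' @return list of class `ordination`: `coordinates` (entity scores),
#'   `explained` (variance fractions), `cos2` (features x components),
#'   `contrib` (features x components, columns summing to 1), `method`.
#' @export
pca_ordination <- function(x, standardize = TRUE, k = NULL) {
  x <- as.matrix(x)
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- mean(x[, j], na.rm = TRUE)
  }
  if (standardize) {
    v <- apply(x, 2, stats::var)
    if (any(v == 0)) {
      warning("dropping ", sum(v == 0), " zero-variance feature(s): ",
              paste(utils::head(colnames(x)[v == 0]), collapse = ", "))
      x <- x[, v > 0, drop = FALSE]
    }
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  if (is.null(k)) k <- ncol(pc$x)
  k <- min(k, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  cos2 <- suppressWarnings(stats::cor(x, pc$x))^2
  cos2[is.na(cos2)] <- 0
  load2 <- (pc$rotation * rep(pc$sdev, each = nrow(pc$rotation)))^2
  contrib <- sweep(load2, 2, colSums(load2), "/")
  structure(list(coordinates = scores,
                 explained = expl[seq_len(k)],
                 cos2 = cos2[, seq_len(k), drop = FALSE],
                 contrib = contrib[, seq_len(k), drop = FALSE],
                 method = "pca"),
            class = "ordination")
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centres the squared distance matrix and embeds on the top
#' eigenpairs; components with non-positive eigenvalues are truncated
#' (with a warning if fewer than `k` remain).
#'
#' @param d symmetric distance matrix (e.g. from [distance_matrix()]).
#' @param k number of components requested (default 2).
#' @return list of class `ordination` with `coordinates`, `explained`
#'   (positive-eigenvalue fractions) and `method = "mds"`.
#' @export
classical_mds <- function(d, k = 2) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  n <- nrow(d)
  fit <- suppressWarnings(stats::cmdscale(d, k = min(k, n - 1), eig = TRUE))
  pos <- fit$eig[fit$eig > 1e-12]
  got <- ncol(as.matrix(fit$points))
  if (length(fit$points) == 0 || got < k) {
    warning("only ", max(got, 0), " positive-eigenvalue component(s) available")
  }
  coords <- as.matrix(fit$points)
  if (nrow(coords) == 0) coords <- matrix(0, n, 1, dimnames = list(rownames(d)))
  structure(list(coordinates = coords,
                 explained = if (length(pos)) (pos / sum(pos))[seq_len(min(k, length(pos)))]
                             else numeric(0),
                 method = "mds"),
            class = "ordination")
}

#' Neighbor-joining tree from a population distance matrix
#'
#' Saitou-Nei agglomeration (as implemented in `ape::nj`) followed by a
#' negative-branch-length adjustment: any negative edge is set to zero and
#' its length excess moved to the adjacent edge toward the other child of
#' the same node, preserving path lengths between the leaves on either
#' side (the usual tree-display convention).
#'
#' @param d symmetric distance matrix with zero diagonal, >= 3 labels.
#' @return an `ape::phylo` tree; write with `ape::write.tree` for Newick.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (nrow(d) < 3) stop("need at least 3 labels")
  tree <- ape::nj(stats::as.dist(d))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    excess <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1]
    sib <- which(tree$edge[, 1] == parent & seq_len(nrow(tree$edge)) != e)
    if (length(sib)) {
      s <- sib[1]
      tree$edge.length[s] <- max(0, tree$edge.length[s] + excess)
    }
  }
  tree
}

#' Hierarchical clustering orderings for a heatmap
#'
#' Average-linkage (UPGMA) clustering on Euclidean distances of the matrix
#' rows, and of the columns, yielding the leaf orderings used to arrange a
#' population x locus frequency heatmap.
#'
#' @param x numeric matrix (e.g. populations x loci insertion frequencies).
#' @return list with `row_order`, `col_order` (integer orders),
#'   `row_hclust`, `col_hclust` (`hclust` objects; `NULL` for a single
#'   row/column).
#' @export
hclust_order <- function(x) {
  x <- as.matrix(x)
  side <- function(m) {
    if (nrow(m) < 2) return(list(order = seq_len(nrow(m)), hc = NULL))
    hc <- stats::hclust(stats::dist(m), method = "average")
    list(order = hc$order, hc = hc)
  }
  r <- side(x)
  cl <- side(t(x))
  list(row_order = r$order, col_order = cl$order,
       row_hclust = r$hc, col_hclust = cl$hc)
}
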