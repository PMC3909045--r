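#' Remove (near-)constant descriptor columns
#'
#' @param x compound x descriptor numeric matrix.
#' @param tol variance tolerance; columns with variance <= `tol` are
#'   dropped. Default `1e-12` absorbs numeric noise.
#' @return The pruned matrix (column order preserved) with attribute
#'   `removed` naming the dropped descriptors.
#' @export
prune_constant_descriptors <- function(x, tol = 1e-12) {
  stopifnot(is.matrix(x), nrow(x) >= 1L, ncol(x) >= 1L)
  v <- apply(x, 2L, stats::var)
  keep <- v > tol
  if (!any(keep)) stop("all descriptor columns are constant at tol = ", tol)
  out <- x[, keep, drop = FALSE]
  attr(out, "removed") <- colnames(x)[!keep]
  out
}

#' Unit-variance (UV) autoscale a descriptor matrix
#'
#' Column-centers and scales to unit standard deviation, the chemometrics
#' convention before PCA/PLS. Scaling metadata is attached for applying the
#' same transform to new compounds.
#'
#' @param x numeric matrix without constant columns.
#' @return Scaled matrix with `center` and `scale` attributes.
#' @export
uv_scale <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  if (any(sd == 0)) stop("constant column(s) cannot be UV-scaled: ",
                         paste(colnames(x)[sd == 0], collapse = ", "))
  out <- sweep(sweep(x, 2L, mu), 2L, sd, "/")
  attr(out, "center") <- mu
  attr(out, "scale") <- sd
  out
}

#' Principal component scores of the chemical space
#'
#' Singular-value decomposition of the column-centered (and optionally
#' UV-scaled) matrix. Component signs follow a deterministic convention:
#' the largest-magnitude loading of each component is positive.
#'
#' @param x compound x descriptor matrix.
#' @param n_components number of components to return.
#' @param scale UV-scale before decomposition (default `TRUE`).
#' @return A `pca_result` list: `scores` (compounds x components, named
#'   `t1, t2, ...`), `loadings` (descriptors x components),
#'   `explained` (fraction of variance per component), `center`, `scale`.
#' @export
pca_scores <- function(x, n_components = 2L, scale = TRUE) {
  stopifnot(is.matrix(x))
  kmax <- min(nrow(x) - 1L, ncol(x))
  if (n_components > kmax)
    stop("n_components must be <= min(rows - 1, cols) = ", kmax)
  xs <- if (scale) uv_scale(x) else {
    out <- sweep(x, 2L, colMeans(x))
    attr(out, "center") <- colMeans(x); attr(out, "scale") <- rep(1, ncol(x))
    out
  }
  sv <- svd(xs, nu = n_components, nv = n_components)
  flip <- vapply(seq_len(n_components), function(k) {
    v <- sv$v[, k]
    sign(v[which.max(abs(v))])
  }, 0)
  flip[flip == 0] <- 1
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(n_components)], n_components), 2L, flip, "*")
  loadings <- sweep(sv$v, 2L, flip, "*")
  dimnames(scores) <- list(rownames(x), paste0("t", seq_len(n_components)))
  dimnames(loadings) <- list(colnames(x), paste0("p", seq_len(n_components)))
  structure(list(scores = scores, loadings = loadings,
                 explained = (sv$d^2 / sum(sv$d^2))[seq_len(n_components)],
                 center = attr(xs, "center"), scale = attr(xs, "scale")),
            class = "pca_result")
}

#' Average-linkage (UPGMA) hierarchical clustering of compounds
#'
#' Agglomerative clustering with average linkage on Euclidean (or
#' squared-Euclidean) distances over the UV-scaled descriptor matrix.
#' Average linkage is monotone, so merge heights are non-decreasing.
#'
#' @param x compound x descriptor matrix.
#' @param metric `"euclidean"` (default) or `"squared"`.
#' @param scale UV-scale first (default `TRUE`).
#' @return An object of class `hclust` (merge/height/order/labels).
#' @export
hca_average_linkage <- function(x, metric = c("euclidean", "squared"), scale = TRUE) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(x))
  if (nrow(x) < 2L) stop("clustering needs at least 2 compounds")
  xs <- if (scale) uv_scale(x) else x
  d <- stats::dist(xs, method = "euclidean")
  if (metric == "squared") d <- d^2
  stats::hclust(d, method = "average")
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths encode merge heights (ultrametric tree).
#'
#' @param hc an `hclust` object.
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_dendrogram_newick <- function(hc, file) {
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = file)
  invisible(file)
}

#' Flat merge table of a dendrogram
#'
#' @param hc an `hclust` object.
#' @return data.frame `(step, node_a, node_b, height, size)`; negative node
#'   ids are leaves, positive ids refer to earlier merges (the `hclust`
#'   convention).
#' @export
merge_table <- function(hc) {
  sizes <- integer(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    sz <- function(j) if (j < 0) 1L else sizes[j]
    sizes[i] <- sz(hc$merge[i, 1L]) + sz(hc$merge[i, 2L])
  }
  data.frame(step = seq_len(nrow(hc$merge)),
             node_a = hc$merge[, 1L], node_b = hc$merge[, 2L],
             height = hc$height, size = sizes)
}
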