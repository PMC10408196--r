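#' Distance matrix container
#'
#' @param values symmetric non-negative matrix with zero diagonal; dimnames
#'   are sample ids.
#' @param metric metric name.
#' @return object of class `dist_matrix`.
#' @export
dist_matrix <- function(values, metric) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("distance matrix needs sample ids")
  if (max(abs(values - t(values))) > 1e-12)
    stop("distance matrix is not symmetric")
  diag(values) <- 0
  if (any(values < 0)) stop("negative distances")
  structure(list(values = values, sample_ids = rownames(values),
                 metric = metric), class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix (%s): %d samples\n", x$metric, nrow(x$values)))
  invisible(x)
}

#' Alpha diversity
#'
#' Shannon (natural log), Simpson (1 - sum p^2), or bias-corrected Chao1
#' richness per sample. Chao1 requires integer counts because it is built on
#' singleton/doubleton frequencies.
#'
#' @param table an [abundance_table()]; relative or counts for
#'   shannon/simpson, counts for chao1.
#' @param index one of `"shannon"`, `"simpson"`, `"chao1"`.
#' @return named numeric vector, one value per sample.
#' @export
alpha_diversity <- function(table, index = c("shannon", "simpson", "chao1")) {
  index <- match.arg(index)
  keep <- !table$stratified & !table$nonbiological
  m <- t(table$values[keep, , drop = FALSE])  # samples x features for vegan
  if (index == "chao1") {
    if (table$unit != "counts")
      stop("chao1 requires integer counts (singletons/doubletons), not ",
           table$unit, " abundances")
    est <- vegan::estimateR(round(m))
    out <- est["S.chao1", ]
  } else {
    out <- vegan::diversity(m, index = if (index == "shannon") "shannon" else "simpson")
  }
  stats::setNames(as.numeric(out), rownames(m))
}

#' Bray-Curtis dissimilarity
#'
#' `BC(x, y) = sum |x_j - y_j| / sum (x_j + y_j)` over shared features; on
#' relative abundances the values lie in `[0, 1]`.
#'
#' @param table an [abundance_table()] with unit `"relative"` (enforced).
#' @return a [dist_matrix()].
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$unit != "relative")
    stop("bray_curtis requires relative abundances; call normalize_abundance()")
  keep <- !table$stratified & !table$nonbiological
  d <- vegan::vegdist(t(table$values[keep, , drop = FALSE]), method = "bray")
  dist_matrix(as.matrix(d), metric = "bray_curtis")
}

#' UniFrac distance
#'
#' Unweighted UniFrac is the fraction of total branch length unique to either
#' sample's observed leaf set; weighted UniFrac is
#' `sum b_i |A_i - B_i| / sum b_i (A_i + B_i)` over branches, with `A_i`,
#' `B_i` the abundance fractions descending from branch `i`.
#'
#' @param table an [abundance_table()] whose terminal clades all map to tree
#'   tips (unmapped features are an error listing them).
#' @param tree an `ape::phylo` tree; unrooted trees are midpoint-rooted with
#'   a warning.
#' @param weighted logical.
#' @return a [dist_matrix()].
#' @export
unifrac <- function(table, tree, weighted = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) {
    warning("unrooted tree: rooting at midpoint")
    tree <- phangorn::midpoint(tree)
  }
  keep <- !table$stratified & !table$nonbiological
  vals <- table$values[keep, , drop = FALSE]
  term <- terminal_clade(rownames(vals))
  unmapped <- setdiff(term, tree$tip.label)
  if (length(unmapped))
    stop("features not on the tree: ", paste(unmapped, collapse = ", "))
  # per-sample abundance fraction on each tip, tree tip order
  p <- matrix(0, length(tree$tip.label), ncol(vals),
              dimnames = list(tree$tip.label, colnames(vals)))
  frac <- sweep(vals, 2, pmax(colSums(vals), .Machine$double.eps), "/")
  p[term, ] <- frac
  # per-edge descendant-tip abundance, postorder accumulation
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  node_ab <- matrix(0, nnode, ncol(p))
  node_ab[seq_len(ntip), ] <- p
  ord <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(ord$edge))) {
    par <- ord$edge[i, 1]; child <- ord$edge[i, 2]
    node_ab[par, ] <- node_ab[par, ] + node_ab[child, ]
  }
  edge_ab <- node_ab[tree$edge[, 2], , drop = FALSE]  # one row per edge
  b <- tree$edge.length
  ns <- ncol(p)
  d <- matrix(0, ns, ns, dimnames = list(colnames(p), colnames(p)))
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    A <- edge_ab[, i]; B <- edge_ab[, j]
    if (weighted) {
      den <- sum(b * (A + B))
      d[i, j] <- d[j, i] <- if (den > 0) sum(b * abs(A - B)) / den else 0
    } else {
      pa <- A > 0; pb <- B > 0
      den <- sum(b[pa | pb])
      d[i, j] <- d[j, i] <- if (den > 0) sum(b[xor(pa, pb)]) / den else 0
    }
  }
  dist_matrix(d, metric = if (weighted) "weighted_unifrac" else "unweighted_unifrac")
}

#' Principal coordinates analysis
#'
#' Classical scaling: eigendecomposition of the Gower double-centered
#' `-0.5 * D^2` matrix. Coordinates are returned for positive-eigenvalue axes
#' only; negative eigenvalues are reported separately and excluded from the
#' proportion-explained denominator.
#'
#' @param dist a [dist_matrix()].
#' @param n_axes number of axes to retain (default 5, the number carried into
#'   downstream stability analyses).
#' @return list with `coordinates` (samples x axes), `eigenvalues` (retained,
#'   non-increasing), `proportion_explained`, and `negative_eigenvalues`.
#' @export
pcoa <- function(dist, n_axes = 5) {
  stopifnot(inherits(dist, "dist_matrix"))
  n <- nrow(dist$values)
  D2 <- dist$values^2
  G <- -0.5 * (sweep(sweep(D2, 1, rowMeans(D2)), 2, colMeans(D2)) + mean(D2))
  G <- (G + t(G)) / 2
  ev <- eigen(G, symmetric = TRUE)
  tol <- max(abs(ev$values)) * 1e-9
  pos <- which(ev$values > tol)
  k <- min(n_axes, length(pos))
  if (k < n_axes)
    warning("only ", length(pos), " positive eigenvalues; returning ", k, " axes")
  coords <- matrix(0, n, k,
                   dimnames = list(dist$sample_ids,
                                   if (k > 0) paste0("PCo", seq_len(k))))
  if (k > 0)
    coords[, ] <- ev$vectors[, pos[seq_len(k)], drop = FALSE] %*%
      diag(sqrt(ev$values[pos[seq_len(k)]]), k)
  list(coordinates = coords,
       eigenvalues = ev$values[pos[seq_len(k)]],
       proportion_explained = ev$values[pos[seq_len(k)]] / sum(ev$values[pos]),
       negative_eigenvalues = ev$values[ev$values < -tol])
}
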