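# Core SparCC basis solve on a log-transformed composition matrix.
# L: features x samples matrix of log relative abundances.
# Returns the correlation matrix implied by the sparsity assumption with
# iterative exclusion of the strongest pairs.
sparcc_basis <- function(L, n_iter = 20, exclusion_threshold = 0.1) {
  p <- nrow(L)
  vlog <- apply(L, 1, stats::var)
  C <- stats::cov(t(L))
  # variation matrix T_ij = var(log x_i - log x_j)
  Tm <- outer(vlog, vlog, "+") - 2 * C
  diag(Tm) <- 0
  M <- matrix(1, p, p) + diag(p - 2, p)
  Tw <- Tm
  excluded <- matrix(FALSE, p, p)
  rho <- matrix(NA_real_, p, p)
  for (iter in seq_len(n_iter + 1L)) {
    t_i <- rowSums(Tw)
    omega <- tryCatch(solve(M, t_i), error = function(e) rep(NA_real_, p))
    if (anyNA(omega)) break
    omega <- pmax(omega, 1e-12)
    denom <- 2 * sqrt(outer(omega, omega))
    rho <- (outer(omega, omega, "+") - Tm) / denom
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    if (iter > n_iter) break
    # exclude the single strongest still-included pair above the threshold
    cand <- abs(rho)
    cand[excluded] <- -Inf
    diag(cand) <- -Inf
    mx <- which.max(cand)
    if (cand[mx] <= exclusion_threshold) break
    ij <- arrayInd(mx, dim(cand))
    i <- ij[1]; j <- ij[2]
    excluded[i, j] <- excluded[j, i] <- TRUE
    Tw[i, j] <- Tw[j, i] <- 0
    M[i, j] <- M[j, i] <- 0
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    if (any(diag(M) < 2)) break  # solvable minimum reached
  }
  unest <- rowSums(excluded) >= p - 2
  if (any(unest)) {
    rho[unest, ] <- NA_real_
    rho[, unest] <- NA_real_
    diag(rho) <- 1
  }
  rho
}

#' SparCC compositional correlations
#'
#' Sparse compositional correlation estimation: basis variances are solved
#' from the log-ratio variation matrix `T_ij = var(log(x_i / x_j))` under the
#' sparsity assumption, with up to `n_iter` rounds of excluding the strongest
#' correlated pair above `exclusion_threshold`. A pseudo-count of 0.5 is
#' added to counts before forming log-ratios. Pseudo p-values come from null
#' datasets in which each feature's values are resampled independently
#' across samples (breaking cross-feature association):
#' `p = (1 + #(|rho_null| >= |rho_obs|)) / (1 + n_boot)`.
#'
#' @param counts a counts [abundance_table()] (>= 4 features, >= 10
#'   samples).
#' @param n_iter exclusion rounds (default 20).
#' @param exclusion_threshold |rho| above which a pair is excluded from the
#'   basis solve (default 0.1).
#' @param n_boot null datasets for p-values (default 100; 0 skips them).
#' @param pseudo_count added to counts before log-ratios (default 0.5).
#' @param seed RNG seed.
#' @return list with `rho` and `p` matrices (feature x feature; `p` NA when
#'   `n_boot = 0`).
#' @export
sparcc_correlations <- function(counts, n_iter = 20, exclusion_threshold = 0.1,
                                n_boot = 100, pseudo_count = 0.5, seed = NULL) {
  stopifnot(inherits(counts, "abundance_table"))
  keep <- !counts$stratified & !counts$nonbiological
  m <- counts$values[keep, , drop = FALSE]
  if (nrow(m) < 4) stop("need at least 4 features")
  if (ncol(m) < 10) stop("need at least 10 samples")
  logfrac <- function(mm) {
    mm <- mm + pseudo_count
    log(sweep(mm, 2, colSums(mm), "/"))
  }
  rho <- sparcc_basis(logfrac(m), n_iter, exclusion_threshold)
  dimnames(rho) <- list(rownames(m), rownames(m))
  pmat <- matrix(NA_real_, nrow(m), nrow(m), dimnames = dimnames(rho))
  if (n_boot > 0) {
    exceed <- matrix(0, nrow(m), nrow(m))
    with_seed(seed, {
      for (b in seq_len(n_boot)) {
        mb <- t(apply(m, 1, sample, size = ncol(m), replace = TRUE))
        rb <- sparcc_basis(logfrac(mb), n_iter, exclusion_threshold)
        exceed <- exceed + (abs(rb) >= abs(rho))
      }
    })
    pmat <- (1 + exceed) / (1 + n_boot)
    diag(pmat) <- NA_real_
  }
  list(rho = rho, p = pmat)
}

#' Build a significance-filtered correlation network
#'
#' BH-adjusts the off-diagonal upper-triangle p-values and keeps edges with
#' `q < edge_threshold`; nodes without a surviving edge are retained as
#' isolates.
#'
#' @param rho,p symmetric matrices from [sparcc_correlations()].
#' @param edge_threshold adjusted-p cutoff (default 0.1).
#' @param group optional group label (e.g. responder / non_responder).
#' @return a `correlation_network`: `graph` (igraph), `edges` data.frame
#'   (`from`, `to`, `rho`, `p`, `q`), `nodes`, `group`.
#' @export
build_network <- function(rho, p, edge_threshold = 0.1, group = NA_character_) {
  if (max(abs(rho - t(rho)), na.rm = TRUE) > 1e-8) stop("asymmetric rho matrix")
  nodes <- rownames(rho) %||% as.character(seq_len(nrow(rho)))
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  pv <- p[ut]
  qv <- rep(NA_real_, length(pv))
  ok <- !is.na(pv)
  qv[ok] <- fdr_adjust(pv[ok])
  keep <- ok & qv < edge_threshold
  edges <- data.frame(from = nodes[ut[keep, 1]], to = nodes[ut[keep, 2]],
                      rho = rho[ut][keep], p = pv[keep], q = qv[keep],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  structure(list(graph = g, edges = edges, nodes = nodes, group = group,
                 edge_threshold = edge_threshold),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("correlation_network (%s): %d nodes, %d edges (q < %g)\n",
              x$group, length(x$nodes), nrow(x$edges), x$edge_threshold))
  invisible(x)
}

#' Degree and closeness centrality of a correlation network
#'
#' Degree is the incident-edge count. Closeness is component-normalized:
#' within a node's connected component of size `c`,
#' `closeness = (c - 1) / sum(shortest-path lengths)` over unweighted edges;
#' isolates get 0.
#'
#' @param net a [build_network()] result.
#' @return data.frame with `node`, `degree`, `closeness`.
#' @export
network_centrality <- function(net) {
  g <- net$graph
  if (length(net$nodes) == 0)
    return(data.frame(node = character(0), degree = numeric(0),
                      closeness = numeric(0)))
  deg <- igraph::degree(g)
  comp <- igraph::components(g)
  d <- igraph::distances(g)
  clo <- vapply(seq_along(net$nodes), function(i) {
    members <- which(comp$membership == comp$membership[i])
    if (length(members) < 2) return(0)
    (length(members) - 1) / sum(d[i, members])
  }, numeric(1))
  data.frame(node = net$nodes, degree = as.numeric(deg), closeness = clo,
             stringsAsFactors = FALSE)
}

#' Compare centralities of two group networks
#'
#' Student t tests on the per-node degree and closeness values of the two
#' networks (e.g. responders vs non-responders).
#'
#' @param net_a,net_b [build_network()] results.
#' @return data.frame with `measure`, `mean_a`, `mean_b`, `t`, `p`.
#' @export
compare_centrality <- function(net_a, net_b) {
  ca <- network_centrality(net_a); cb <- network_centrality(net_b)
  do.call(rbind, lapply(c("degree", "closeness"), function(mm) {
    tt <- stats::t.test(ca[[mm]], cb[[mm]])
    data.frame(measure = mm, mean_a = mean(ca[[mm]]), mean_b = mean(cb[[mm]]),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  }))
}

#' Write a network edge list TSV
#' @param net a [build_network()] result.
#' @param path output file.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
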