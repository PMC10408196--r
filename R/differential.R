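#' PERMANOVA on a distance matrix
#'
#' One-way permutational multivariate analysis of variance (Anderson's
#' pseudo-F from among/within sums of squared distances). Sample labels are
#' permuted freely; `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`.
#'
#' @param dist a [dist_matrix()].
#' @param groups group label per sample (>= 2 groups, each with >= 2
#'   samples).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return list with `pseudo_F`, `R2`, `p`, `n_perm`.
#' @export
permanova <- function(dist, groups, n_perm = 999, seed = NULL) {
  stopifnot(inherits(dist, "dist_matrix"))
  groups <- as.factor(groups)
  n <- nrow(dist$values)
  stopifnot(length(groups) == n)
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2))
    stop("every group needs at least 2 samples (offending: ",
         paste(names(which(table(groups) < 2)), collapse = ", "), ")")
  D2 <- dist$values^2
  a <- nlevels(droplevels(groups))
  ss_total <- sum(D2[upper.tri(D2)]) / n
  ss_within <- function(g) {
    s <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      s <- s + sum(D2[idx, idx][upper.tri(D2[idx, idx])]) / length(idx)
    }
    s
  }
  f_stat <- function(g) {
    ssw <- ss_within(g)
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_stat(groups)
  r2 <- (ss_total - ss_within(groups)) / ss_total
  p <- NA_real_
  if (n_perm > 0) {
    exceed <- with_seed(seed, {
      sum(vapply(seq_len(n_perm),
                 function(b) f_stat(sample(groups)) >= f_obs, logical(1)))
    })
    p <- (1 + exceed) / (1 + n_perm)
  }
  list(pseudo_F = f_obs, R2 = r2, p = p, n_perm = n_perm)
}

po_loglik <- function(par, x, y, K) {
  theta <- par[seq_len(K - 1)]; beta <- par[K]
  eta <- outer(-beta * x, rep(1, K - 1)) + matrix(theta, length(x), K - 1,
                                                  byrow = TRUE)
  cum <- cbind(0, stats::plogis(eta), 1)
  pr <- cum[cbind(seq_along(y), y + 1L)] - cum[cbind(seq_along(y), y)]
  sum(log(pmax(pr, 1e-300)))
}

po_gradient <- function(par, x, y, K) {
  theta <- par[seq_len(K - 1)]; beta <- par[K]
  n <- length(x)
  eta <- outer(-beta * x, rep(1, K - 1)) + matrix(theta, n, K - 1, byrow = TRUE)
  Fm <- cbind(0, stats::plogis(eta), 1)
  fm <- cbind(0, stats::dlogis(eta), 0)
  pr <- pmax(Fm[cbind(1:n, y + 1L)] - Fm[cbind(1:n, y)], 1e-300)
  g <- numeric(K)
  fy <- fm[cbind(1:n, y + 1L)]   # density at upper threshold of category
  fy1 <- fm[cbind(1:n, y)]       # density at lower threshold
  for (j in seq_len(K - 1)) {
    dj <- (fy * (y == j) - fy1 * (y == j + 1L)) / pr
    g[j] <- sum(dj)
  }
  g[K] <- sum(-x * (fy - fy1) / pr)
  g
}

#' Proportional-odds ordinal regression for one feature
#'
#' Cumulative-logit model `P(Y <= j) = logistic(theta_j - beta x)` for the
#' ordered response groups, maximized by Newton iteration with step halving
#' (Hessian by central differences of the analytic gradient). Wald p-value
#' from the observed information; when monotone separation is detected
#' (diverging slope) the fit is flagged and the p-value falls back to a
#' likelihood-ratio test against the intercept-only model.
#'
#' @param x feature values (already transformed upstream, e.g. arcsine
#'   square-root abundances).
#' @param labels ordered factor (non_responder < partial_responder <
#'   responder) or anything coercible to one; at least 2 distinct labels.
#' @param feature id carried into the result.
#' @return an `ordinal_fit` list: `feature`, `beta`, `thresholds`, `se`,
#'   `p`, `direction`, `separation`, `converged`, `valid`, `loglik`,
#'   `max_gradient`.
#' @export
fit_ordinal_regression <- function(x, labels, feature = NA_character_) {
  if (!is.ordered(labels)) labels <- factor(labels, ordered = TRUE)
  labels <- droplevels(labels)
  K <- nlevels(labels)
  if (K < 2) stop("all labels identical: ordinal fit undefined")
  y <- as.integer(labels)
  invalid <- function(reason) structure(
    list(feature = feature, beta = NA_real_, thresholds = rep(NA_real_, K - 1),
         se = NA_real_, p = NA_real_, direction = NA_character_,
         separation = FALSE, converged = FALSE, valid = FALSE,
         loglik = NA_real_, max_gradient = NA_real_, reason = reason),
    class = "ordinal_fit")
  if (stats::sd(x) == 0) return(invalid("constant feature"))
  xs <- (x - mean(x)) / stats::sd(x)   # fit on standardized scale
  cumprop <- cumsum(tabulate(y, K) / length(y))[seq_len(K - 1)]
  cumprop <- pmin(pmax(cumprop, 1e-6), 1 - 1e-6)
  par <- c(stats::qlogis(cumprop), 0)
  ll <- po_loglik(par, xs, y, K)
  ll_null <- ll
  separation <- FALSE
  converged <- FALSE
  num_hess <- function(p0) {
    h <- 1e-5
    H <- matrix(0, K, K)
    for (m in seq_len(K)) {
      e <- rep(0, K); e[m] <- h
      H[, m] <- (po_gradient(p0 + e, xs, y, K) -
                 po_gradient(p0 - e, xs, y, K)) / (2 * h)
    }
    (H + t(H)) / 2
  }
  for (it in seq_len(100)) {
    g <- po_gradient(par, xs, y, K)
    if (max(abs(g)) < 1e-8) { converged <- TRUE; break }
    H <- num_hess(par)
    step <- tryCatch(solve(H, g), error = function(e) g / max(1, max(abs(g))))
    sc <- 1
    repeat {
      cand <- par - sc * step
      ok <- all(diff(cand[seq_len(K - 1)]) > 0)
      if (ok && po_loglik(cand, xs, y, K) >= ll - 1e-12) break
      sc <- sc / 2
      if (sc < 1e-8) { cand <- par; break }
    }
    par <- cand
    ll <- po_loglik(par, xs, y, K)
    if (abs(par[K]) > 15) { separation <- TRUE; break }
  }
  g <- po_gradient(par, xs, y, K)
  H <- num_hess(par)
  se_s <- tryCatch({
    v <- solve(-H)[K, K]
    if (v > 0) sqrt(v) else NA_real_
  }, error = function(e) NA_real_)
  beta_s <- par[K]
  if (!separation && (is.na(se_s) || se_s > 50)) separation <- TRUE
  if (separation) {
    lr <- 2 * (ll - ll_null)
    p <- stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
  } else {
    p <- 2 * stats::pnorm(-abs(beta_s / se_s))
  }
  sdx <- stats::sd(x)
  structure(list(feature = feature,
                 beta = beta_s / sdx,
                 thresholds = par[seq_len(K - 1)] + beta_s * mean(x) / sdx,
                 se = se_s / sdx, p = p,
                 direction = if (beta_s > 0) "enriched_in_responders"
                             else "enriched_in_non_responders",
                 separation = separation, converged = converged || separation,
                 valid = TRUE, loglik = ll, max_gradient = max(abs(g))),
            class = "ordinal_fit")
}

#' Ordinal differential abundance across the three response groups
#'
#' Applies the arcsine square-root transform per feature and fits the
#' proportional-odds model of [fit_ordinal_regression()], with BH adjustment
#' across features.
#'
#' @param table relative-abundance [abundance_table()] (baseline samples).
#' @param labels ordered response labels aligned to the table's samples.
#' @param transform apply arcsine sqrt before fitting (default TRUE; set
#'   FALSE when values are already transformed or are CPM units).
#' @return data.frame with `feature`, `beta`, `p`, `q`, `direction`,
#'   `separation`, `valid`.
#' @export
ordinal_da <- function(table, labels, transform = TRUE) {
  keep <- !table$stratified & !table$nonbiological
  vals <- table$values[keep, , drop = FALSE]
  if (transform && table$unit != "relative")
    stop("arcsine sqrt transform requires relative abundances")
  rows <- lapply(seq_len(nrow(vals)), function(j) {
    x <- vals[j, ]
    if (transform) x <- transform_measurements(x, "arcsine_sqrt")
    ft <- if (stats::sd(x) == 0)
      list(feature = rownames(vals)[j], beta = NA_real_, p = NA_real_,
           direction = NA_character_, separation = FALSE, valid = FALSE)
    else fit_ordinal_regression(x, labels, feature = rownames(vals)[j])
    data.frame(feature = ft$feature, beta = ft$beta, p = ft$p,
               direction = ft$direction %||% NA_character_,
               separation = ft$separation, valid = ft$valid,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  out$q[out$valid] <- fdr_adjust(out$p[out$valid])
  out
}

#' Wilcoxon rank-sum differential abundance (responders vs non-responders)
#'
#' Rank-sum test with normal approximation and tie correction per feature,
#' plus `log2FC = log2((mean_R + eps) / (mean_NR + eps))` with `eps` half the
#' smallest nonzero value of the table (pseudo-count tied to the data scale).
#'
#' @param table an [abundance_table()].
#' @param labels per-sample labels; `positive` and `negative` name the two
#'   groups compared.
#' @param positive,negative group labels (default responder vs
#'   non_responder).
#' @return data.frame with `feature`, `log2FC`, `p`, `q`.
#' @export
wilcoxon_da <- function(table, labels, positive = "responder",
                        negative = "non_responder") {
  keep <- !table$stratified & !table$nonbiological
  vals <- table$values[keep, , drop = FALSE]
  gpos <- labels == positive; gneg <- labels == negative
  if (!any(gpos) || !any(gneg)) stop("both groups must be non-empty")
  nz <- vals[vals > 0]
  eps <- if (length(nz)) min(nz) * 0.5 else .Machine$double.eps
  rows <- lapply(seq_len(nrow(vals)), function(j) {
    a <- vals[j, gpos]; b <- vals[j, gneg]
    p <- if (stats::sd(c(a, b)) == 0) 1 else
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    data.frame(feature = rownames(vals)[j],
               log2FC = log2((mean(a) + eps) / (mean(b) + eps)),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- fdr_adjust(out$p)
  out
}

#' Chi-square enrichment of annotation hits between two groups
#'
#' 2x2 Pearson chi-square without continuity correction on the hit/non-hit
#' contingency table; a warning is raised when any expected count is below 5.
#'
#' @param k_hit_a,k_tot_a hits and total in group A.
#' @param k_hit_b,k_tot_b hits and total in group B.
#' @return list with `chi2`, `p`, `table`.
#' @export
chi_square_enrichment <- function(k_hit_a, k_tot_a, k_hit_b, k_tot_b) {
  if (k_tot_a <= 0 || k_tot_b <= 0) stop("group totals must be positive")
  if (k_hit_a > k_tot_a || k_hit_b > k_tot_b)
    stop("hit counts exceed group totals")
  tab <- matrix(c(k_hit_a, k_tot_a - k_hit_a, k_hit_b, k_tot_b - k_hit_b),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("hit", "nonhit")))
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ht$expected < 5))
    warning("expected count below 5: chi-square approximation is inaccurate")
  list(chi2 = unname(ht$statistic), p = ht$p.value, table = tab)
}

#' Spearman association matrix between two feature sets
#'
#' Spearman rho (mean ranks on ties) over shared samples, p from the
#' t-approximation, BH adjustment across the full matrix. Constant vectors
#' yield `NA` and are flagged.
#'
#' @param table_a,table_b [abundance_table()]s sharing >= 4 samples (matched
#'   by sample id).
#' @return list of matrices `rho`, `p`, `q` (rows: features of `table_a`).
#' @export
spearman_assoc <- function(table_a, table_b) {
  shared <- intersect(sample_ids(table_a), sample_ids(table_b))
  if (length(shared) < 4) stop("need at least 4 shared samples")
  ka <- !table_a$stratified & !table_a$nonbiological
  kb <- !table_b$stratified & !table_b$nonbiological
  A <- table_a$values[ka, shared, drop = FALSE]
  B <- table_b$values[kb, shared, drop = FALSE]
  n <- length(shared)
  ra <- t(apply(A, 1, rank)); rb <- t(apply(B, 1, rank))
  consta <- apply(A, 1, stats::sd) == 0
  constb <- apply(B, 1, stats::sd) == 0
  rho <- suppressWarnings(stats::cor(t(ra), t(rb)))
  rho[consta, ] <- NA; rho[, constb] <- NA
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1 - 1e-12] <- 0
  q <- matrix(fdr_adjust(as.vector(p)), nrow(p), ncol(p),
              dimnames = dimnames(p))
  list(rho = rho, p = p, q = q)
}

#' Link species to the functions they contribute to
#'
#' A species contributes to a function when its stratified row is nonzero in
#' at least `min_prevalence` of the samples; the contribution fraction is the
#' mean of stratified/unstratified over samples with positive community
#' abundance.
#'
#' @param stratified a stratified functional [abundance_table()].
#' @param species_list species ids (full lineage or terminal clade).
#' @param function_list unstratified function ids.
#' @param min_prevalence prevalence threshold (default 0.1).
#' @return data.frame with `species`, `fun`, `contributes`,
#'   `contribution_fraction`.
#' @export
link_contributions <- function(stratified, species_list, function_list,
                               min_prevalence = 0.1) {
  ids <- feature_ids(stratified)
  vals <- stratified$values
  term_sp <- terminal_clade(species_list)
  rows <- list()
  for (fn in function_list) {
    unstrat <- vals[ids == fn, , drop = FALSE]
    if (nrow(unstrat) == 0) stop("function not in table: ", fn)
    tot <- unstrat[1, ]
    for (si in seq_along(species_list)) {
      pat <- paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", fn),
                    "\\|.*", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                                  term_sp[si]), "$")
      hit <- grep(pat, ids)
      if (length(hit) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          species = species_list[si], fun = fn, contributes = FALSE,
          contribution_fraction = 0, stringsAsFactors = FALSE)
        next
      }
      sv <- colSums(vals[hit, , drop = FALSE])
      prev <- mean(sv > 0)
      posi <- tot > 0
      frac <- if (any(posi)) mean(sv[posi] / tot[posi]) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        species = species_list[si], fun = fn,
        contributes = prev >= min_prevalence,
        contribution_fraction = frac, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH with monotonicity enforcement (delegates to
#' [stats::p.adjust()]); `NA`s are propagated.
#'
#' @param pvals p-values in `[0, 1]`.
#' @return adjusted q-values.
#' @export
fdr_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}
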