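#' Measurement transforms for stability analysis
#'
#' `arcsine_sqrt` maps proportions through `asin(sqrt(p))`, the classical
#' variance-stabilizing transform for relative abundances. `gaussianize` is
#' the rank-based inverse-normal transform with Blom offsets
#' (`qnorm((r - 3/8) / (n + 1/4))`), ties sharing their mean rank; it is
#' deterministic and invariant to monotone re-expressions of the input.
#'
#' @param values numeric vector; `arcsine_sqrt` requires values in `[0, 1]`.
#' @param kind `"gaussianize"` or `"arcsine_sqrt"`.
#' @return transformed numeric vector (NAs propagated).
#' @export
transform_measurements <- function(values, kind = c("gaussianize", "arcsine_sqrt")) {
  kind <- match.arg(kind)
  if (kind == "arcsine_sqrt") {
    if (any(values < 0 | values > 1, na.rm = TRUE))
      stop("arcsine_sqrt requires proportions in [0, 1]")
    return(asin(sqrt(values)))
  }
  ok <- !is.na(values)
  n <- sum(ok)
  r <- rank(values[ok], ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

icc_from_ms <- function(msr, msc, mse, n) {
  denom <- msr + (msc - mse) / n
  if (!is.finite(denom) || denom <= 0) return(NA_real_)
  min(1, max(0, (msr - mse) / denom))
}

anova_ms <- function(m) {
  # two-way crossed design, subjects x occasions, one observation per cell
  n <- nrow(m); k <- ncol(m)
  g <- mean(m)
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  ssr <- k * sum((rm_ - g)^2)
  ssc <- n * sum((cm_ - g)^2)
  sst <- sum((m - g)^2)
  sse <- sst - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), sst = sst)
}

#' Intraclass correlation of repeated measurements
#'
#' Two-way random-effects, absolute-agreement, mean-of-k-ratings ICC:
#' `ICC(A,k) = (MS_R - MS_E) / (MS_R + (MS_C - MS_E) / n)` from the
#' subjects-by-occasions ANOVA mean squares. Negative estimates are truncated
#' to 0 (the stability scale runs from 0, no stability, to 1, perfect
#' stability). The 95% confidence interval is a percentile bootstrap over
#' subjects — the exchangeable unit of a repeatability design.
#'
#' @param measurements numeric matrix, subjects in rows, the k repeated
#'   measurements in columns; rows with missing cells are dropped and
#'   reported in the result.
#' @param n_boot bootstrap resamples for the CI (0 skips the CI).
#' @param seed RNG seed for the bootstrap (global RNG state is restored).
#' @param target identifier carried into the result.
#' @param transformation label of the transform already applied upstream.
#' @return an `icc_result` list: `target`, `icc`, `ci_low`, `ci_high`,
#'   `n_subjects`, `k`, `transformation`, `ms_r`, `ms_c`, `ms_e`, `valid`,
#'   `n_dropped`. `valid` is `FALSE` (and `icc` `NA`) when the estimate is
#'   undefined: fewer than 3 complete subjects, k < 2, or zero total
#'   variance.
#' @export
estimate_icc <- function(measurements, n_boot = 1000, seed = NULL,
                         target = NA_character_, transformation = "none") {
  m <- as.matrix(measurements)
  complete <- stats::complete.cases(m)
  n_dropped <- sum(!complete)
  m <- m[complete, , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  invalid <- function() structure(
    list(target = target, icc = NA_real_, ci_low = NA_real_,
         ci_high = NA_real_, n_subjects = n, k = k,
         transformation = transformation, ms_r = NA_real_, ms_c = NA_real_,
         ms_e = NA_real_, valid = FALSE, n_dropped = n_dropped),
    class = "icc_result")
  if (k < 2 || n < 3) return(invalid())
  ms <- anova_ms(m)
  if (!is.finite(ms$sst) || ms$sst <= .Machine$double.eps * n * k)
    return(invalid())
  icc <- icc_from_ms(ms$msr, ms$msc, ms$mse, n)
  if (is.na(icc)) return(invalid())
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        mb <- m[sample.int(n, n, replace = TRUE), , drop = FALSE]
        msb <- anova_ms(mb)
        if (msb$sst <= .Machine$double.eps * n * k) return(NA_real_)
        icc_from_ms(msb$msr, msb$msc, msb$mse, n)
      }, numeric(1))
    })
    ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    ci[1] <- min(ci[1], icc); ci[2] <- max(ci[2], icc)
  }
  structure(list(target = target, icc = icc, ci_low = ci[1], ci_high = ci[2],
                 n_subjects = n, k = k, transformation = transformation,
                 ms_r = ms$msr, ms_c = ms$msc, ms_e = ms$mse, valid = TRUE,
                 n_dropped = n_dropped),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  if (x$valid)
    cat(sprintf("ICC(A,%d) [%s] = %.3f (95%% CI %.3f-%.3f), n = %d\n",
                x$k, x$target, x$icc, x$ci_low, x$ci_high, x$n_subjects))
  else cat(sprintf("ICC [%s]: non-valid (n = %d, k = %d)\n",
                   x$target, x$n_subjects, x$k))
  invisible(x)
}

#' Stability call from an ICC estimate
#'
#' @param icc numeric ICC value(s) or an `icc_result`.
#' @param threshold stability cutoff (default 0.5).
#' @param strict if `TRUE` (default), stable means `icc > threshold`;
#'   otherwise `>=`.
#' @return logical vector (`NA` for non-valid estimates).
#' @export
stability_call <- function(icc, threshold = 0.5, strict = TRUE) {
  if (inherits(icc, "icc_result")) icc <- icc$icc
  if (strict) icc > threshold else icc >= threshold
}

# build subjects x k matrix of a per-sample measurement using metadata,
# visits ordered by day; subjects with a different number of samples than k
# are excluded (ids recorded in the "excluded" attribute)
subject_visit_matrix <- function(values, metadata, k = NULL) {
  stopifnot(length(values) == nrow(metadata))
  ord <- order(metadata$subject_id, metadata$day)
  metadata <- metadata[ord, , drop = FALSE]
  values <- values[ord]
  counts <- table(metadata$subject_id)
  if (is.null(k)) k <- as.integer(names(sort(table(counts), decreasing = TRUE))[1])
  keep_subj <- names(counts)[counts == k]
  excluded <- setdiff(names(counts), keep_subj)
  m <- matrix(NA_real_, length(keep_subj), k,
              dimnames = list(keep_subj, paste0("visit", seq_len(k))))
  for (s in keep_subj)
    m[s, ] <- values[metadata$subject_id == s]
  attr(m, "excluded") <- excluded
  m
}

#' Per-feature ICC profile of a cohort
#'
#' Applies the arcsine square-root transform to each feature's relative
#' abundances, resolves per-subject repeated visits from the metadata, and
#' estimates the ICC feature by feature. Features absent from the cohort
#' (all zeros) are returned as non-valid. Subjects whose sample count
#' differs from `k` are excluded and reported in the `excluded_subjects`
#' attribute.
#'
#' @param table a relative-abundance [abundance_table()].
#' @param metadata matching [sample_metadata()].
#' @param n_boot,seed bootstrap control, see [estimate_icc()].
#' @param k visits per subject (default: the modal per-subject sample count).
#' @return data.frame of [estimate_icc()] fields, one row per feature.
#' @export
feature_icc_profile <- function(table, metadata, n_boot = 1000, seed = NULL,
                                k = NULL) {
  metadata <- align_samples(table, metadata)
  keep <- !table$stratified & !table$nonbiological
  vals <- table$values[keep, , drop = FALSE]
  excluded <- NULL
  res <- lapply(seq_len(nrow(vals)), function(j) {
    feat <- rownames(vals)[j]
    if (all(vals[j, ] == 0))
      return(estimate_icc(matrix(NA_real_, 0, 2), n_boot = 0, target = feat,
                          transformation = "arcsine_sqrt"))
    x <- transform_measurements(vals[j, ], "arcsine_sqrt")
    m <- subject_visit_matrix(x, metadata, k = k)
    excluded <<- attr(m, "excluded")
    estimate_icc(m, n_boot = n_boot,
                 seed = if (is.null(seed)) NULL else derive_seed(seed, j),
                 target = feat, transformation = "arcsine_sqrt")
  })
  out <- do.call(rbind, lapply(res, function(r)
    data.frame(target = r$target, icc = r$icc, ci_low = r$ci_low,
               ci_high = r$ci_high, n_subjects = r$n_subjects, k = r$k,
               valid = r$valid, stringsAsFactors = FALSE)))
  attr(out, "excluded_subjects") <- excluded
  out
}

#' Diversity-level ICC profile of a cohort
#'
#' Computes the three alpha indexes (gaussianized before ICC estimation) and
#' the top PCoA axes of each requested beta metric, then estimates the ICC of
#' each measurement.
#'
#' @param table relative-abundance [abundance_table()] (counts table needed
#'   for chao1 can be supplied via `counts_table`).
#' @param metadata matching [sample_metadata()].
#' @param counts_table optional counts [abundance_table()] for chao1.
#' @param tree optional phylogeny enabling the UniFrac metrics.
#' @param n_axes PCoA axes carried per beta metric (default 5).
#' @param n_boot,seed,k see [feature_icc_profile()].
#' @return data.frame of ICC fields, one row per diversity measurement.
#' @export
diversity_icc_profile <- function(table, metadata, counts_table = NULL,
                                  tree = NULL, n_axes = 5, n_boot = 1000,
                                  seed = NULL, k = NULL) {
  metadata <- align_samples(table, metadata)
  meas <- list(shannon = alpha_diversity(table, "shannon"),
               simpson = alpha_diversity(table, "simpson"))
  if (!is.null(counts_table))
    meas$chao1 <- alpha_diversity(counts_table, "chao1")
  dists <- list(bray_curtis = bray_curtis(table))
  if (!is.null(tree)) {
    dists$unweighted_unifrac <- unifrac(table, tree, weighted = FALSE)
    dists$weighted_unifrac <- unifrac(table, tree, weighted = TRUE)
  }
  for (nm in names(dists)) {
    pc <- suppressWarnings(pcoa(dists[[nm]], n_axes = n_axes))
    for (a in seq_len(ncol(pc$coordinates)))
      meas[[sprintf("%s_PCo%d", nm, a)]] <- pc$coordinates[, a]
  }
  res <- lapply(names(meas), function(nm) {
    x <- transform_measurements(meas[[nm]], "gaussianize")
    m <- subject_visit_matrix(x, metadata, k = k)
    r <- estimate_icc(m, n_boot = n_boot,
                      seed = if (is.null(seed)) NULL else derive_seed(seed, nm),
                      target = nm, transformation = "gaussianize")
    data.frame(target = r$target, icc = r$icc, ci_low = r$ci_low,
               ci_high = r$ci_high, n_subjects = r$n_subjects, k = r$k,
               valid = r$valid, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Compare ICC sets across cohorts or cohort types
#'
#' Pairwise Student t tests (Welch, or paired when `paired = TRUE`) between
#' named sets of ICC values, with Benjamini-Hochberg adjustment across the
#' comparisons.
#'
#' @param icc_sets named list of numeric ICC vectors. For paired comparisons
#'   the vectors must be named by target id and cover identical targets.
#' @param paired logical.
#' @return data.frame with `group1`, `group2`, `t`, `p`, `q`.
#' @export
compare_icc_groups <- function(icc_sets, paired = FALSE) {
  stopifnot(is.list(icc_sets), length(icc_sets) >= 2, !is.null(names(icc_sets)))
  combs <- utils::combn(names(icc_sets), 2)
  rows <- apply(combs, 2, function(pr) {
    a <- icc_sets[[pr[1]]]; b <- icc_sets[[pr[2]]]
    if (paired) {
      if (is.null(names(a)) || is.null(names(b)) ||
          !setequal(names(a), names(b)))
        stop("paired comparison requires identical target ids; difference: ",
             paste(union(setdiff(names(a), names(b)),
                         setdiff(names(b), names(a))), collapse = ", "))
      b <- b[names(a)]
      d <- a - b
      if (stats::sd(d) == 0) {
        tt <- list(statistic = c(t = 0), p.value = if (all(d == 0)) 1 else 0)
        if (any(d != 0)) tt <- list(statistic = c(t = sign(mean(d)) * Inf),
                                    p.value = 0)
      } else tt <- stats::t.test(a, b, paired = TRUE)
    } else tt <- stats::t.test(a, b)
    data.frame(group1 = pr[1], group2 = pr[2],
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
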