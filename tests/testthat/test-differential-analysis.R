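euclid_dm <- function(X) {
  D <- as.matrix(dist(X))
  dimnames(D) <- list(paste0("s", seq_len(nrow(X))),
                      paste0("s", seq_len(nrow(X))))
  dist_matrix(D, "euclidean")
}

test_that("permanova equals coordinate-space ANOVA on euclidean input", {
  set.seed(8)
  X <- matrix(rnorm(60), 20, 3)
  g <- rep(c("a", "b"), each = 10)
  pm <- permanova(euclid_dm(X), g, n_perm = 99, seed = 1)
  # one-way multivariate ANOVA F on the coordinates (trace form)
  sst <- sum(scale(X, scale = FALSE)^2)
  ssw <- sum(vapply(split(as.data.frame(X), g), function(d)
    sum(scale(as.matrix(d), scale = FALSE)^2), numeric(1)))
  f_anova <- (sst - ssw) / (ssw / (20 - 2))
  expect_equal(pm$pseudo_F, f_anova, tolerance = 1e-8)
  expect_equal(pm$R2, (sst - ssw) / sst, tolerance = 1e-8)
  # and agrees with the community-ecology reference implementation
  ad <- vegan::adonis2(dist(X) ~ g, permutations = 10)
  expect_equal(pm$pseudo_F, ad$F[1], tolerance = 1e-8)
  expect_equal(pm$R2, ad$R2[1], tolerance = 1e-8)
})

test_that("permanova handles perfect separation and degenerate groups", {
  set.seed(2)
  X <- rbind(matrix(0, 8, 2), matrix(10, 8, 2)) + 1e-9 * matrix(rnorm(32), 16)
  pm <- permanova(euclid_dm(X), rep(c("a", "b"), each = 8), n_perm = 199,
                  seed = 2)
  expect_gt(pm$R2, 0.999)
  # minimal attainable p, allowing for the rare random permutation that
  # redraws the separating split itself
  expect_lte(pm$p, 2 / 200)
  expect_error(permanova(euclid_dm(X), c(rep("a", 15), "b")), "at least 2")
  expect_error(permanova(euclid_dm(X), rep("a", 16)), "2 groups")
})

test_that("ordinal fit agrees with the reference polr implementation", {
  set.seed(2)
  for (i in 1:5) {
    x <- rnorm(90)
    z <- x + rnorm(90, sd = 2)
    y <- cut(z, quantile(z, c(0, 0.4, 0.7, 1)), include.lowest = TRUE,
             labels = c("non", "part", "resp"), ordered_result = TRUE)
    f <- fit_ordinal_regression(x, y)
    ref <- MASS::polr(y ~ x, Hess = TRUE)
    expect_equal(f$beta, unname(coef(ref)), tolerance = 1e-3)
    expect_equal(f$thresholds, unname(ref$zeta), tolerance = 1e-3)
    expect_lt(f$max_gradient, 1e-6)
    expect_true(f$converged)
  }
})

test_that("ordinal fit flags separation, nulls and degenerate inputs", {
  y <- factor(rep(c("non", "part", "resp"), each = 2),
              levels = c("non", "part", "resp"), ordered = TRUE)
  f <- fit_ordinal_regression(c(1, 1, 2, 2, 3, 3), y)
  expect_true(f$separation)
  expect_gt(f$beta, 0)
  expect_lt(f$p, 0.05)   # likelihood-ratio fallback
  # group-independent feature: slope near zero, p large
  set.seed(9)
  x0 <- rep(c(1, 2, 3, 4), 6)
  y0 <- factor(rep(c("non", "part", "resp"), 8), ordered = TRUE)
  f0 <- fit_ordinal_regression(x0, y0)
  expect_lt(abs(f0$beta), 0.2)
  expect_gt(f0$p, 0.5)
  expect_error(fit_ordinal_regression(rnorm(5),
                                      factor(rep("non", 5), ordered = TRUE)),
               "identical")
  expect_false(fit_ordinal_regression(rep(1, 6), y)$valid)
})

test_that("ordinal DA recovers planted monotone effects under BH control", {
  set.seed(30)
  n <- 120; p <- 200; n_sig <- 20
  labels <- factor(rep(c("non_responder", "partial_responder", "responder"),
                       each = n / 3),
                   levels = c("non_responder", "partial_responder",
                              "responder"), ordered = TRUE)
  shift <- as.integer(labels) - 2   # -1, 0, 1
  # observed FDR is an expectation, so average the false-discovery
  # proportion over replicate draws
  one_run <- function() {
    # independent per-feature proportions (no compositional closure, so
    # null features really are null)
    vals <- matrix(rbeta(p * n, 2, 40), p, n)
    vals[seq_len(n_sig), ] <- plogis(qlogis(vals[seq_len(n_sig), ]) +
                                       rep(0.9 * shift, each = n_sig))
    dimnames(vals) <- list(paste0("f", 1:p), paste0("s", 1:n))
    tab <- abundance_table(vals, unit = "relative", level = "species",
                           validate = FALSE)
    da <- ordinal_da(tab, labels)
    hits <- da$feature[!is.na(da$q) & da$q < 0.2]
    c(recovery = mean(paste0("f", seq_len(n_sig)) %in% hits),
      fdp = if (length(hits))
        mean(!hits %in% paste0("f", seq_len(n_sig))) else 0,
      dir_ok = mean(da$direction[match(paste0("f", 1:n_sig), da$feature)] ==
                      "enriched_in_responders"))
  }
  runs <- replicate(8, one_run())
  expect_gte(mean(runs["recovery", ]), 0.8)
  expect_lte(mean(runs["fdp", ]), 0.25)
  expect_gte(mean(runs["dir_ok", ]), 0.95)
})

test_that("wilcoxon DA reports tie-corrected p and scale-aware log2FC", {
  set.seed(14)
  labels <- rep(c("responder", "non_responder"), each = 10)
  vals <- matrix(rexp(50 * 20), 50, 20)
  dimnames(vals) <- list(paste0("f", 1:50), paste0("s", 1:20))
  vals <- sweep(vals, 2, colSums(vals), "/")
  tab <- abundance_table(vals, unit = "relative", level = "species")
  da <- wilcoxon_da(tab, labels)
  expect_equal(da$q, p.adjust(da$p, "BH"))
  # equal group means give log2FC 0
  v2 <- vals; v2[1, ] <- rep(c(0.1, 0.2), 10)
  tab2 <- abundance_table(v2, unit = "relative", level = "species",
                          validate = FALSE)
  da2 <- wilcoxon_da(tab2, labels)
  expect_equal(da2$log2FC[1], 0, tolerance = 1e-10)
  # disjoint ranges attain the minimal normal-approximation p for n=10 vs 10
  v3 <- vals
  v3[2, labels == "responder"] <- 0.5 + seq(0, 0.009, length.out = 10)
  v3[2, labels == "non_responder"] <- 0.1 + seq(0, 0.009, length.out = 10)
  tab3 <- abundance_table(v3, unit = "relative", level = "species",
                          validate = FALSE)
  da3 <- wilcoxon_da(tab3, labels)
  pmin_ref <- wilcox.test(1:10 + 100, 1:10, exact = FALSE)$p.value
  expect_equal(da3$p[2], pmin_ref, tolerance = 1e-12)
  expect_error(wilcoxon_da(tab, rep("responder", 20)), "non-empty")
})

test_that("null wilcoxon p-values are uniform", {
  set.seed(71)
  labels <- rep(c("responder", "non_responder"), each = 15)
  vals <- matrix(rexp(800 * 30), 800, 30)
  dimnames(vals) <- list(paste0("f", 1:800), paste0("s", 1:30))
  tab <- abundance_table(sweep(vals, 2, colSums(vals), "/"),
                         unit = "relative", level = "species")
  da <- wilcoxon_da(tab, labels)
  ks <- suppressWarnings(ks.test(da$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("chi-square enrichment matches the Pearson formula", {
  null <- chi_square_enrichment(5, 50, 10, 100)
  expect_equal(null$chi2, 0)
  expect_equal(null$p, 1)
  res <- chi_square_enrichment(20, 100, 5, 100)
  # independent oracle: Pearson chi-square written out longhand
  O <- c(20, 80, 5, 95)
  E <- c(25 * 100 / 200, 175 * 100 / 200, 25 * 100 / 200, 175 * 100 / 200)
  expect_equal(res$chi2, sum((O - E)^2 / E), tolerance = 1e-10)
  expect_equal(res$chi2, 10.28571, tolerance = 1e-5)
  expect_warning(chi_square_enrichment(3, 11, 43, 384), "below 5")
  expect_error(chi_square_enrichment(10, 5, 1, 10), "exceed")
  expect_error(chi_square_enrichment(0, 0, 1, 10), "positive")
})

test_that("spearman association handles monotonicity, sign and ties", {
  set.seed(26)
  n <- 30
  x <- matrix(rexp(2 * n), 2, n,
              dimnames = list(c("sp1", "sp2"), paste0("s", 1:n)))
  y <- rbind(pwyA = exp(x[1, ]), pwyB = -x[1, ], pwyC = rep(1, n))
  colnames(y) <- paste0("s", 1:n)
  ta <- abundance_table(x, unit = "cpm", level = "species")
  tb <- abundance_table(y - min(y) + 1, unit = "cpm", level = "pathway")
  res <- spearman_assoc(ta, tb)
  expect_equal(res$rho["sp1", "pwyA"], 1)
  expect_equal(res$rho["sp1", "pwyB"], -1)
  expect_true(is.na(res$rho["sp1", "pwyC"]))   # constant vector flagged
  expect_equal(res$p["sp1", "pwyA"], 0)
  expect_error(spearman_assoc(
    abundance_table(x[, 1:3], unit = "cpm", level = "species"), tb),
    "4 shared samples")
  # null critical value: 95th percentile of |rho| for independent pairs
  set.seed(27)
  rhos <- replicate(1000, cor(rnorm(100), rnorm(100), method = "spearman"))
  expect_lt(abs(quantile(abs(rhos), 0.95) - 0.196), 0.025)
})

test_that("BH adjustment matches hand computation and rejects bad input", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.42), 0.42)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.1, 1.4)), "\\[0, 1\\]")
  set.seed(3)
  p <- runif(50)
  q <- fdr_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in p-rank
})

test_that("contribution linking respects prevalence and fractions", {
  # two contributors at constant 2:1, one absent species
  mat <- rbind("PWY-1" = rep(300, 6),
               "PWY-1|g__A.s__A_sp" = rep(200, 6),
               "PWY-1|g__B.s__B_sp" = rep(100, 6))
  colnames(mat) <- paste0("s", 1:6)
  tab <- abundance_table(mat, unit = "cpm", level = "pathway")
  links <- link_contributions(tab, c("s__A_sp", "s__B_sp", "s__C_sp"),
                              "PWY-1")
  expect_equal(links$contribution_fraction[1:2], c(2 / 3, 1 / 3))
  expect_true(all(links$contributes[1:2]))
  expect_false(links$contributes[3])      # absent species: no link, no error
  expect_equal(links$contribution_fraction[3], 0)
  # all-zero stratified row fails the prevalence gate
  mat0 <- rbind(mat, "PWY-1|g__D.s__D_sp" = rep(0, 6))
  tab0 <- abundance_table(mat0, unit = "cpm", level = "pathway")
  l0 <- link_contributions(tab0, "s__D_sp", "PWY-1")
  expect_false(l0$contributes)
})
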