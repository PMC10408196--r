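# Small in-code fixtures shared across test files.

# features x samples matrix with ids filled in
make_mat <- function(v, nr, nc, fids = NULL, sids = NULL) {
  m <- matrix(v, nr, nc)
  rownames(m) <- fids %||% paste0("k__Bacteria|g__G", seq_len(nr),
                                  "|s__G", seq_len(nr), "_sp")
  colnames(m) <- sids %||% paste0("S", seq_len(nc))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

rel_table <- function(m, level = "species") {
  m <- sweep(m, 2, colSums(m), "/")
  abundance_table(m, unit = "relative", level = level)
}

# minimal control-style metadata: each subject sampled on the given days
make_metadata <- function(subjects, days, cohort_id = "CTL",
                          cohort_type = "control") {
  df <- expand.grid(subject = subjects, day = days,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[order(df$subject, df$day), ]
  sample_metadata(data.frame(
    sample_id = sprintf("%s_%s_d%d", cohort_id, df$subject, df$day),
    subject_id = paste0(cohort_id, "_", df$subject),
    cohort_id = cohort_id, cohort_type = cohort_type, day = df$day,
    phase = if (cohort_type == "control") "baseline" else
      ifelse(df$day == min(days), "baseline", "post"),
    stringsAsFactors = FALSE))
}

# direct two-variance-component repeatability data (subjects x k), the
# analytic oracle scale for the ICC estimator
sim_repeatability <- function(n, k = 2, sigma_b2 = 1, sigma_w2 = 1) {
  m <- rnorm(n, 0, sqrt(sigma_b2))
  matrix(m, n, k) + matrix(rnorm(n * k, 0, sqrt(sigma_w2)), n, k)
}
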