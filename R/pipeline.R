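#' Read a pipeline configuration from YAML
#'
#' One YAML file with per-stage blocks; unknown keys are errors (silent
#' typos corrupt analyses).
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "out_dir", "simulate", "icc", "classify", "diff",
             "network", "ml")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$simulate)) {
    sim_known <- names(formals(simulation_config))
    bad <- setdiff(names(cfg$simulate), sim_known)
    if (length(bad))
      stop("unknown simulate key(s): ", paste(bad, collapse = ", "))
  }
  cfg
}

manifest_entry <- function(paths) {
  data.frame(file = unname(paths),
             md5 = unname(tools::md5sum(unname(paths))),
             stringsAsFactors = FALSE)
}

write_manifest <- function(out_dir, seed, config, files) {
  man <- list(seed = seed,
              config = config,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              versions = list(microresist = as.character(
                utils::packageVersion("microresist")),
                R = R.version.string),
              files = manifest_entry(files))
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  man
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the stability (ICC) analysis over one or more cohorts
#'
#' Per cohort: the three alpha-diversity ICCs and the top PCoA-axis ICCs of
#' Bray-Curtis (plus the UniFrac metrics when a tree is available), the
#' per-species ICC profile with stability calls, and a cross-cohort
#' comparison of the species ICC sets. Outputs are written as TSV under
#' `out_dir` together with a JSON run manifest of file digests.
#'
#' @param cohorts named list; each element a list with `table` (relative
#'   [abundance_table()]), `metadata`, and optionally `counts_table` and
#'   `tree`.
#' @param out_dir output directory.
#' @param n_boot,seed bootstrap control for the ICC estimates.
#' @param n_axes PCoA axes per beta metric.
#' @return list with `diversity_icc`, `species_icc`, `stability`,
#'   `comparisons`, `manifest`.
#' @export
run_stability_analysis <- function(cohorts, out_dir, n_boot = 200, seed = 1,
                                   n_axes = 5) {
  stopifnot(length(cohorts) >= 1, !is.null(names(cohorts)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  div_icc <- list(); sp_icc <- list(); files <- character(0)
  for (nm in names(cohorts)) {
    co <- cohorts[[nm]]
    n_subj <- length(unique(co$metadata$subject_id))
    if (n_subj < 3)
      stop("cohort '", nm, "' has ", n_subj,
           " subject(s); ICC needs at least 3")
    stage_log("icc", "cohort %s: %d samples, %d subjects", nm,
              ncol(co$table$values), n_subj)
    div <- diversity_icc_profile(co$table, co$metadata,
                                 counts_table = co$counts_table,
                                 tree = co$tree, n_axes = n_axes,
                                 n_boot = n_boot,
                                 seed = derive_seed(seed, paste0(nm, "_div")))
    div$cohort <- nm
    sp <- feature_icc_profile(co$table, co$metadata, n_boot = n_boot,
                              seed = derive_seed(seed, paste0(nm, "_sp")))
    sp$cohort <- nm
    sp$stable <- stability_call(sp$icc)
    div_icc[[nm]] <- div; sp_icc[[nm]] <- sp
    f1 <- file.path(out_dir, paste0("diversity_icc_", nm, ".tsv"))
    f2 <- file.path(out_dir, paste0("species_icc_", nm, ".tsv"))
    utils::write.table(div, f1, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sp, f2, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f1, f2)
  }
  comparisons <- NULL
  if (length(cohorts) >= 2) {
    sets <- lapply(sp_icc, function(d)
      stats::setNames(d$icc, d$target)[d$valid])
    shared <- Reduce(intersect, lapply(sets, names))
    comparisons <- if (length(shared) >= 3)
      compare_icc_groups(lapply(sets, function(s) s[shared]), paired = TRUE)
    else compare_icc_groups(sets, paired = FALSE)
    fc <- file.path(out_dir, "icc_comparisons.tsv")
    utils::write.table(comparisons, fc, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, fc)
  }
  man <- write_manifest(out_dir, seed, list(n_boot = n_boot, n_axes = n_axes),
                        files)
  list(diversity_icc = do.call(rbind, div_icc),
       species_icc = do.call(rbind, sp_icc),
       comparisons = comparisons, manifest = man)
}

#' Run the full response pipeline
#'
#' Control fluctuation baseline, per-subject response classification,
#' PERMANOVA on the baseline Bray-Curtis among the three groups, ordinal
#' differential abundance of species (and pathways when supplied),
#' stratified contribution links, per-group SparCC networks with centrality
#' comparison, and the repeated-split machine-learning report. When one of
#' the responder/non-responder classes is absent the ML stage is skipped
#' with an explicit notice.
#'
#' @param control list with `table`, `metadata` of the control cohort.
#' @param intervention list with `table` (relative abundances), `metadata`,
#'   and optionally `counts_table` (for SparCC) and `pathways` (stratified
#'   functional [abundance_table()]).
#' @param out_dir output directory.
#' @param seed master seed for every stochastic stage.
#' @param max_gap_days control pairing window (default 2).
#' @param ml_config a [model_config()] for the ML stage.
#' @param n_perm PERMANOVA permutations.
#' @param sparcc_boot bootstrap datasets for SparCC p-values.
#' @param ordinal_q species ordinal-regression significance threshold
#'   (default 0.2, pathway table uses 0.1).
#' @return list with `baseline`, `assessment`, `permanova`, `species_da`,
#'   `pathway_da`, `links`, `networks`, `centrality_comparison`,
#'   `ml_report`, `manifest`.
#' @export
run_response_pipeline <- function(control, intervention, out_dir, seed = 1,
                                  max_gap_days = 2,
                                  ml_config = model_config(seed = seed),
                                  n_perm = 999, sparcc_boot = 100,
                                  ordinal_q = 0.2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  baseline <- estimate_daily_fluctuation(control$table, control$metadata,
                                         max_gap_days = max_gap_days)
  stage_log("classify", "baseline: mean %.4f sd %.4f from %d pairs",
            baseline$mean, baseline$sd, baseline$n_pairs)
  assessment <- classify_cohort(intervention$table, intervention$metadata,
                                baseline)
  f <- file.path(out_dir, "response_assessment.tsv")
  utils::write.table(assessment, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  stage_log("classify", "labels: %s",
            paste(names(table(assessment$label)), table(assessment$label),
                  sep = "=", collapse = ", "))

  # baseline samples of classified subjects only
  md <- intervention$metadata
  base_md <- md[md$phase == "baseline" &
                  md$subject_id %in% assessment$subject_id, , drop = FALSE]
  base_md <- base_md[!duplicated(base_md$subject_id), , drop = FALSE]
  bt <- intervention$table
  base_vals <- bt$values[, base_md$sample_id, drop = FALSE]
  base_tab <- abundance_table(base_vals, unit = bt$unit, level = bt$level,
                              stratified = bt$stratified,
                              nonbiological = bt$nonbiological,
                              validate = FALSE)
  labels <- assessment$label[match(base_md$subject_id,
                                   assessment$subject_id)]

  groups_ok <- nlevels(droplevels(labels)) >= 2 &&
    all(table(droplevels(labels)) >= 2)
  perma <- NULL; species_da <- NULL
  if (groups_ok) {
    perma <- permanova(bray_curtis(base_tab), labels, n_perm = n_perm,
                       seed = derive_seed(seed, "permanova"))
    stage_log("diff", "PERMANOVA: F=%.2f R2=%.3f p=%.4f", perma$pseudo_F,
              perma$R2, perma$p)
    species_da <- ordinal_da(base_tab, labels)
    f <- file.path(out_dir, "species_ordinal_da.tsv")
    utils::write.table(species_da, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  } else {
    stage_log("diff", "skipped: fewer than 2 response groups at baseline")
  }

  pathway_da <- NULL; links <- NULL
  if (!is.null(intervention$pathways) && groups_ok) {
    pw <- intervention$pathways
    pw_base <- abundance_table(pw$values[, base_md$sample_id, drop = FALSE],
                               unit = pw$unit, level = pw$level,
                               stratified = pw$stratified,
                               nonbiological = pw$nonbiological,
                               validate = FALSE)
    pathway_da <- ordinal_da(pw_base, labels, transform = FALSE)
    sig_sp <- species_da$feature[!is.na(species_da$q) &
                                   species_da$q < ordinal_q]
    sig_pw <- pathway_da$feature[!is.na(pathway_da$q) & pathway_da$q < 0.1]
    if (length(sig_sp) && length(sig_pw))
      links <- link_contributions(pw_base, sig_sp, sig_pw)
    f <- file.path(out_dir, "pathway_ordinal_da.tsv")
    utils::write.table(pathway_da, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }

  networks <- NULL; cent_cmp <- NULL
  counts <- intervention$counts_table
  if (!is.null(counts)) {
    networks <- list(); cents <- list()
    for (grp in c("responder", "non_responder")) {
      subj <- assessment$subject_id[assessment$label == grp]
      sids <- base_md$sample_id[base_md$subject_id %in% subj]
      if (length(sids) < 10) {
        stage_log("network", "group %s: only %d baseline samples, skipped",
                  grp, length(sids))
        next
      }
      ct <- abundance_table(counts$values[, sids, drop = FALSE],
                            unit = "counts", level = counts$level)
      sc <- sparcc_correlations(ct, n_boot = sparcc_boot,
                                seed = derive_seed(seed, paste0("sparcc_", grp)))
      net <- build_network(sc$rho, sc$p, group = grp)
      networks[[grp]] <- net
      cents[[grp]] <- network_centrality(net)
      f <- file.path(out_dir, paste0("network_", grp, ".tsv"))
      write_edge_list(net, f)
      files <- c(files, f)
    }
    if (length(networks) == 2)
      cent_cmp <- compare_centrality(networks$responder,
                                     networks$non_responder)
  }

  ml_report <- NULL
  two <- assessment$label %in% c("responder", "non_responder")
  n_r <- sum(assessment$label == "responder")
  n_nr <- sum(assessment$label == "non_responder")
  if (n_r >= 5 && n_nr >= 5) {
    keep_subj <- assessment$subject_id[two]
    keep_md <- base_md[base_md$subject_id %in% keep_subj, , drop = FALSE]
    xm <- t(base_tab$values[!base_tab$stratified & !base_tab$nonbiological,
                            keep_md$sample_id, drop = FALSE])
    yl <- as.character(assessment$label[match(keep_md$subject_id,
                                              assessment$subject_id)])
    ml_report <- repeated_split_eval(xm, yl, ml_config)
    f <- file.path(out_dir, "ml_splits.tsv")
    utils::write.table(ml_report$splits, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  } else {
    stage_log("ml", paste0("skipped: %d responders / %d non-responders ",
                           "(need >= 5 each)"), n_r, n_nr)
  }

  man <- write_manifest(out_dir, seed,
                        list(max_gap_days = max_gap_days, n_perm = n_perm),
                        files)
  list(baseline = baseline, assessment = assessment, permanova = perma,
       species_da = species_da, pathway_da = pathway_da, links = links,
       networks = networks, centrality_comparison = cent_cmp,
       ml_report = ml_report, manifest = man)
}
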