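#' Simulation configuration for synthetic longitudinal studies
#'
#' The generative law is logistic-normal + multinomial: per subject `i` and
#' species `j`, a subject-specific log-abundance mean
#' `m_ij ~ Normal(mu_j, sigma_b2)`; per visit, `m_ij + Normal(0, sigma_w2)`;
#' a softmax across species gives the composition and counts are multinomial
#' at the configured depth. Between/within variance therefore decomposes
#' additively on the log scale and every species has the closed-form true
#' intra-visit correlation `rho = sigma_b2 / (sigma_b2 + sigma_w2)`.
#'
#' @param n_subjects subjects per arm.
#' @param n_species,n_genera,n_pathways feature counts.
#' @param timepoints strictly increasing integer days, at least 2.
#' @param sigma_b2 between-subject variance of log-abundance (>= 0).
#' @param sigma_w2 within-subject visit-to-visit variance (> 0).
#' @param depth multinomial read depth per sample.
#' @param responder_fraction proportion of intervention subjects planted as
#'   responders, in `[0, 1]`.
#' @param effect_size post-intervention log-abundance shift magnitude applied
#'   to affected taxa of responders.
#' @param affected_fraction fraction of taxa shifted per responder (default
#'   0.3: community-wide displacement without single-taxon artifacts).
#' @param n_informative planted discriminative taxa whose baseline means
#'   differ between responder and non-responder subjects.
#' @param informative_offset baseline log-abundance offset of informative
#'   taxa in responders (log units; default 2, a strong planted effect of
#'   twice the between-subject SD at the default `sigma_b2`).
#' @param mu_sd spread of the species log-mean profile `mu_j` (rank-abundance
#'   realism; ~2 orders of magnitude at the default 1).
#' @param seed master seed; per-cohort streams are derived deterministically.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_subjects = 50, n_species = 100, n_genera = 25,
                              n_pathways = 30, timepoints = c(0L, 1L),
                              sigma_b2 = 1, sigma_w2 = 0.5, depth = 50000,
                              responder_fraction = 0.5, effect_size = 5,
                              affected_fraction = 0.3, n_informative = 10,
                              informative_offset = 2, mu_sd = 1, seed = 1) {
  cfg <- list(n_subjects = n_subjects, n_species = n_species,
              n_genera = n_genera, n_pathways = n_pathways,
              timepoints = as.integer(timepoints), sigma_b2 = sigma_b2,
              sigma_w2 = sigma_w2, depth = depth,
              responder_fraction = responder_fraction,
              effect_size = effect_size, affected_fraction = affected_fraction,
              n_informative = n_informative,
              informative_offset = informative_offset, mu_sd = mu_sd,
              seed = seed)
  num <- unlist(cfg[setdiff(names(cfg), "timepoints")])
  if (!all(is.finite(num))) stop("non-finite simulation config values")
  if (cfg$sigma_b2 < 0 || cfg$sigma_w2 <= 0)
    stop("sigma_b2 must be >= 0 and sigma_w2 > 0")
  if (cfg$depth < 1) stop("depth must be >= 1")
  if (cfg$responder_fraction < 0 || cfg$responder_fraction > 1)
    stop("responder_fraction must lie in [0, 1]")
  if (length(cfg$timepoints) < 2 || any(diff(cfg$timepoints) <= 0))
    stop("timepoints must be strictly increasing with at least 2 entries")
  if (cfg$n_informative > cfg$n_species)
    stop("n_informative exceeds n_species")
  structure(cfg, class = "simulation_config")
}

sim_feature_ids <- function(cfg) {
  genus <- sprintf("Genus%02d", (seq_len(cfg$n_species) - 1L) %% cfg$n_genera + 1L)
  species <- sprintf("%s_species%03d", genus, seq_len(cfg$n_species))
  sprintf("k__Bacteria|g__%s|s__%s", genus, species)
}

# shared machinery: draw one cohort given per-subject/visit shift matrix hook
sim_cohort <- function(cfg, cohort_id, cohort_type, seed,
                       subject_offset = NULL, visit_shift = NULL) {
  ids <- sim_feature_ids(cfg)
  tp <- cfg$timepoints
  n <- cfg$n_subjects
  with_seed(seed, {
    mu <- stats::rnorm(cfg$n_species, 0, cfg$mu_sd)
    subj_mean <- matrix(stats::rnorm(n * cfg$n_species, mu,
                                     sd = sqrt(cfg$sigma_b2)),
                        n, cfg$n_species, byrow = TRUE)
    if (!is.null(subject_offset)) subj_mean <- subj_mean + subject_offset
    counts <- matrix(0L, cfg$n_species, n * length(tp))
    sample_id <- character(n * length(tp))
    meta <- vector("list", n * length(tp))
    k <- 0L
    for (i in seq_len(n)) {
      for (t in seq_along(tp)) {
        k <- k + 1L
        la <- subj_mean[i, ] + stats::rnorm(cfg$n_species, 0, sqrt(cfg$sigma_w2))
        if (!is.null(visit_shift)) la <- la + visit_shift(i, t)
        comp <- exp(la - max(la)); comp <- comp / sum(comp)
        counts[, k] <- stats::rmultinom(1, cfg$depth, comp)[, 1]
        sample_id[k] <- sprintf("%s_S%03d_d%02d", cohort_id, i, tp[t])
        meta[[k]] <- data.frame(
          sample_id = sample_id[k],
          subject_id = sprintf("%s_S%03d", cohort_id, i),
          cohort_id = cohort_id, cohort_type = cohort_type,
          day = tp[t],
          phase = if (cohort_type == "control" || t == 1L) "baseline" else "post",
          stringsAsFactors = FALSE)
      }
    }
    dimnames(counts) <- list(ids, sample_id)
    list(counts = counts, metadata = sample_metadata(do.call(rbind, meta)))
  })
}

#' Simulate a no-intervention (control) cohort
#'
#' Dense or paired time series with no perturbation; used to estimate the
#' natural day-to-day fluctuation of the community and as a high-stability
#' reference. Deterministic given the config seed.
#'
#' @param config a [simulation_config()].
#' @return a `simulated_study` list: `counts` (species x samples integer
#'   matrix with lineage rownames), `metadata`, `truth` (per-feature true
#'   intra-visit correlation `rho`), `responder_labels` (NULL),
#'   `informative_features`, `contribution_map`, `tree` (random coalescent
#'   tree over the species, for exercising UniFrac).
#' @export
simulate_control_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  seed <- derive_seed(config$seed, "control")
  cohort <- sim_cohort(config, "CTL", "control", seed)
  finish_study(config, cohort, responder_labels = NULL,
               informative = character(0))
}

#' Simulate an intervention cohort with planted responders
#'
#' A `responder_fraction` share of subjects is planted as responders: their
#' post-intervention samples receive a log-abundance shift of magnitude
#' `effect_size` (random sign) on a per-subject random `affected_fraction` of
#' taxa. Planted discriminative taxa additionally differ in baseline mean
#' between responder and non-responder subjects so the machine-learning stage
#' has recoverable signal. Non-responders receive no shift.
#'
#' @param config a [simulation_config()]; `timepoints[1]` is the baseline
#'   visit, later timepoints are post-intervention.
#' @param baseline optional [fluctuation_baseline()] from a control cohort,
#'   recorded in the study for reference.
#' @return a `simulated_study` (see [simulate_control_cohort()]) with
#'   `responder_labels` and `informative_features` filled in.
#' @export
simulate_intervention_cohort <- function(config, baseline = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  seed <- derive_seed(config$seed, "intervention")
  n <- config$n_subjects
  p <- config$n_species
  setup <- with_seed(seed, {
    n_resp <- round(config$responder_fraction * n)
    resp <- sample(rep(c(TRUE, FALSE), c(n_resp, n - n_resp)))
    informative <- sample.int(p, config$n_informative)
    off <- matrix(0, n, p)
    off[resp, informative] <- config$informative_offset
    n_aff <- max(1L, round(config$affected_fraction * p))
    shift <- matrix(0, n, p)
    for (i in which(resp)) {
      aff <- sample.int(p, n_aff)
      shift[i, aff] <- config$effect_size * sample(c(-1, 1), n_aff, replace = TRUE)
    }
    list(resp = resp, informative = informative, off = off, shift = shift)
  })
  cohort <- sim_cohort(config, "INT", "lifestyle",
                       seed = derive_seed(seed, "draw"),
                       subject_offset = setup$off,
                       visit_shift = function(i, t) {
                         if (t == 1L) rep(0, p) else setup$shift[i, ]
                       })
  labels <- stats::setNames(ifelse(setup$resp, "responder", "non_responder"),
                            sprintf("INT_S%03d", seq_len(n)))
  st <- finish_study(config, cohort, responder_labels = labels,
                     informative = sim_feature_ids(config)[setup$informative])
  st$baseline_used <- baseline
  st
}

finish_study <- function(config, cohort, responder_labels, informative) {
  ids <- rownames(cohort$counts)
  rho <- if (config$sigma_b2 == 0) 0 else
    config$sigma_b2 / (config$sigma_b2 + config$sigma_w2)
  truth <- data.frame(feature = ids, rho = rho, stringsAsFactors = FALSE)
  cmap <- with_seed(derive_seed(config$seed, "pathways"), {
    lapply(stats::setNames(seq_len(config$n_pathways),
                           sprintf("PWY-%04d", seq_len(config$n_pathways))),
           function(k) {
             nc <- sample(2:min(5, config$n_species), 1)
             data.frame(species = sample(ids, nc),
                        weight = exp(stats::rnorm(nc, 0, 0.5)),
                        stringsAsFactors = FALSE)
           })
  })
  tree <- with_seed(derive_seed(config$seed, "tree"), {
    tr <- ape::rcoal(config$n_species)
    tr$tip.label <- terminal_clade(ids)
    tr
  })
  structure(list(counts = cohort$counts, metadata = cohort$metadata,
                 truth = truth, responder_labels = responder_labels,
                 informative_features = informative,
                 contribution_map = cmap, tree = tree, config = config),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("simulated_study: %d species x %d samples, %d subjects\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$metadata$subject_id))))
  if (!is.null(x$responder_labels))
    cat("  planted responders:", sum(x$responder_labels == "responder"), "\n")
  invisible(x)
}

#' Species counts of a study as an abundance table
#' @param study a `simulated_study`.
#' @param unit `"counts"` or `"relative"` (total-sum scaled).
#' @return an [abundance_table()].
#' @export
study_species_table <- function(study, unit = c("relative", "counts")) {
  unit <- match.arg(unit)
  tab <- abundance_table(study$counts, unit = "counts", level = "species")
  if (unit == "relative") normalize_abundance(tab, "tss") else tab
}

#' Simulate a stratified functional profile from a study
#'
#' Each pathway's community abundance is the weighted sum of its contributing
#' species' relative abundances (weights from the study's contribution map),
#' rescaled per sample to copies per million. One stratified row is emitted
#' per contributing species; the unstratified row is the exact sum of its
#' stratified rows.
#'
#' @param study a `simulated_study` with a `contribution_map`.
#' @param config the study's [simulation_config()] (defaults to the one
#'   recorded in the study).
#' @return an [abundance_table()] (unit `"cpm"`, level `"pathway"`).
#' @export
simulate_stratified_functions <- function(study, config = study$config) {
  cmap <- study$contribution_map
  if (is.null(cmap)) stop("study carries no contribution_map")
  if (any(vapply(cmap, function(d) any(d$weight < 0), logical(1))))
    stop("negative contribution weight")
  rel <- study_species_table(study, "relative")$values
  ns <- ncol(rel)
  rows <- list()
  for (pwy in names(cmap)) {
    contr <- cmap[[pwy]]
    strat <- rel[contr$species, , drop = FALSE] * contr$weight
    rownames(strat) <- paste0(pwy, "|",
                              gsub("|", ".", sub("^k__[^|]*\\|", "", contr$species),
                                   fixed = TRUE))
    rows[[pwy]] <- rbind(matrix(colSums(strat), 1, ns,
                                dimnames = list(pwy, colnames(rel))), strat)
  }
  mat <- do.call(rbind, rows)
  strat_flag <- grepl("\\|", rownames(mat))
  # per-sample rescale so unstratified rows sum to 1e6
  tot <- colSums(mat[!strat_flag, , drop = FALSE])
  mat <- sweep(mat, 2, tot / 1e6, "/")
  abundance_table(mat, unit = "cpm", level = "pathway",
                  stratified = strat_flag,
                  nonbiological = rep(FALSE, nrow(mat)))
}

#' Write a simulated study to the pipeline's file dialects
#'
#' Emits the merged species table (relative abundances), the stratified
#' pathway table (CPM), the metadata TSV, and a Newick tree.
#'
#' @param study a `simulated_study`.
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_simulated_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(species = file.path(dir, "species_profile.tsv"),
             pathways = file.path(dir, "pathway_profile.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             tree = file.path(dir, "tree.nwk"))
  write_taxonomic_profile(study_species_table(study, "relative"), paths["species"])
  write_function_profile(simulate_stratified_functions(study), paths["pathways"])
  write_sample_metadata(study$metadata, paths["metadata"])
  ape::write.tree(study$tree, paths["tree"])
  invisible(paths)
}
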