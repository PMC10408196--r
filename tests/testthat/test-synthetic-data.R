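test_that("simulation config rejects invalid study conditions", {
  expect_error(simulation_config(sigma_w2 = 0), "sigma_w2")
  expect_error(simulation_config(sigma_b2 = -1), "sigma_b2")
  expect_error(simulation_config(responder_fraction = 1.2), "responder_fraction")
  expect_error(simulation_config(timepoints = c(3, 1)), "strictly increasing")
  expect_error(simulation_config(timepoints = 5), "at least 2")
  expect_error(simulation_config(sigma_b2 = NaN), "non-finite")
  expect_error(simulation_config(depth = 0), "depth")
})

test_that("control cohorts respect depth, closure, truth and determinism", {
  cfg <- simulation_config(n_subjects = 8, n_species = 30, depth = 2000,
                           seed = 3)
  st <- simulate_control_cohort(cfg)
  expect_true(all(colSums(st$counts) == 2000))
  expect_setequal(colnames(st$counts), st$metadata$sample_id)
  expect_equal(st$truth$rho, rep(1 / 1.5, 30))  # sigma_b2=1, sigma_w2=0.5
  rel <- study_species_table(st, "relative")
  expect_equal(unname(colSums(rel$values)), rep(1, ncol(rel$values)))
  # bit-identical regeneration from the same seed
  st2 <- simulate_control_cohort(cfg)
  expect_identical(st$counts, st2$counts)
  expect_identical(st$metadata, st2$metadata)
  # forced-ratio and zero-variance truth cases
  expect_equal(simulate_control_cohort(
    simulation_config(n_subjects = 4, n_species = 5, sigma_b2 = 1,
                      sigma_w2 = 1, n_informative = 2,
                      seed = 1))$truth$rho, rep(0.5, 5))
  st0 <- simulate_control_cohort(
    simulation_config(n_subjects = 4, n_species = 5, sigma_b2 = 0,
                      n_informative = 2, seed = 1))
  expect_equal(st0$truth$rho, rep(0, 5))
})

test_that("visit-to-visit correlation tracks the planted variance ratio", {
  # Monte-Carlo oracle on the generator's own output: mean per-species
  # Pearson correlation of the two visits' arcsine-sqrt abundances. The
  # nonlinear transform attenuates the log-scale rho (3/4 here), so the
  # frozen band comes from the oracle runs, and a low-stability
  # configuration must sit clearly below a high-stability one.
  visit_cor <- function(sigma_b2, sigma_w2, seed) {
    cfg <- simulation_config(n_subjects = 50, n_species = 40,
                             sigma_b2 = sigma_b2, sigma_w2 = sigma_w2,
                             depth = 50000, seed = seed)
    st <- simulate_control_cohort(cfg)
    v <- study_species_table(st)$values
    md <- st$metadata
    a <- asin(sqrt(v[, md$sample_id[md$day == 0]]))
    b <- asin(sqrt(v[, md$sample_id[md$day == 1]]))
    mean(vapply(seq_len(nrow(a)), function(j) cor(a[j, ], b[j, ]),
                numeric(1)))
  }
  hi <- visit_cor(3, 1, seed = 1)
  expect_gt(hi, 0.58)   # oracle range 0.64-0.69 across seeds
  expect_lt(hi, 0.78)
  expect_gt(hi, visit_cor(1, 3, seed = 1) + 0.2)
})

test_that("intervention cohorts plant responders and discriminative taxa", {
  cfg <- simulation_config(n_subjects = 20, n_species = 40,
                           timepoints = c(0, 14), seed = 9)
  st <- simulate_intervention_cohort(cfg)
  expect_equal(sum(st$responder_labels == "responder"), 10)
  expect_length(st$informative_features, cfg$n_informative)
  expect_true(all(st$informative_features %in% rownames(st$counts)))
  # responder_fraction = 0: no subject shifted, all labels non_responder
  cfg0 <- simulation_config(n_subjects = 10, n_species = 40,
                            timepoints = c(0, 14), responder_fraction = 0,
                            seed = 9)
  st0 <- simulate_intervention_cohort(cfg0)
  expect_true(all(st0$responder_labels == "non_responder"))
})

test_that("zero effect size is indistinguishable from control fluctuation", {
  ctl <- simulate_control_cohort(simulation_config(n_subjects = 60, seed = 21))
  bl <- estimate_daily_fluctuation(study_species_table(ctl), ctl$metadata)
  tail_mass <- mean(attr(bl, "values") > bl$cutoff2)  # empirical control tail
  int <- simulate_intervention_cohort(
    simulation_config(n_subjects = 100, timepoints = c(0, 14),
                      effect_size = 0, seed = 22))
  asmt <- classify_cohort(study_species_table(int), int$metadata, bl)
  frac_resp <- mean(asmt$label == "responder")
  expect_lt(abs(frac_resp - tail_mass), 0.08)
})

test_that("stratified pathway tables are exact weighted sums of species", {
  cfg <- simulation_config(n_subjects = 6, n_species = 20, n_pathways = 8,
                           seed = 4)
  st <- simulate_control_cohort(cfg)
  fn <- simulate_stratified_functions(st)
  ids <- rownames(fn$values)
  parent <- sub("\\|.*$", "", ids)
  for (pwy in unique(parent[fn$stratified])) {
    unstrat <- fn$values[ids == pwy & !fn$stratified, ]
    strat_sum <- colSums(fn$values[fn$stratified & parent == pwy, ,
                                   drop = FALSE])
    expect_equal(unname(strat_sum), unname(unstrat), tolerance = 1e-10)
  }
  expect_equal(unname(colSums(fn$values[!fn$stratified, ])),
               rep(1e6, ncol(fn$values)))
  # hand-built contribution map: weights 2:1 on equal abundances give
  # stratified rows in ratio 2:1; a single weight-1 contributor is
  # proportional to its species
  st$contribution_map <- list(
    "PWY-X" = data.frame(species = rownames(st$counts)[1:2],
                         weight = c(2, 1)),
    "PWY-Y" = data.frame(species = rownames(st$counts)[3], weight = 1))
  st$counts[1, ] <- st$counts[2, ]  # force equal abundances for the 2:1 check
  fn2 <- simulate_stratified_functions(st)
  s1 <- fn2$values[grep("^PWY-X\\|.*species001", rownames(fn2$values)), ]
  s2 <- fn2$values[grep("^PWY-X\\|.*species002", rownames(fn2$values)), ]
  expect_equal(unname(s1 / s2), rep(2, length(s1)))
  # single weight-1 contributor: pathway abundance proportional to the
  # species within every sample (the CPM rescale is shared across pathways)
  y <- fn2$values[rownames(fn2$values) == "PWY-Y", ]
  x <- fn2$values[rownames(fn2$values) == "PWY-X", ]
  rel2 <- study_species_table(st)$values
  scale_y <- y / rel2[3, ]                      # per-sample CPM factor
  scale_x <- x / (2 * rel2[1, ] + rel2[2, ])    # same factor via PWY-X
  expect_equal(unname(scale_y), unname(scale_x), tolerance = 1e-10)
  # negative weights are rejected
  st$contribution_map[["PWY-X"]]$weight[1] <- -1
  expect_error(simulate_stratified_functions(st), "negative contribution")
})

test_that("written study files round-trip through the io readers", {
  st <- simulate_control_cohort(
    simulation_config(n_subjects = 4, n_species = 15, n_pathways = 5,
                      seed = 6))
  dir <- withr::local_tempdir()
  paths <- write_simulated_study(st, dir)
  tab <- read_taxonomic_profile(paths["species"], level = "species")
  expect_equal(tab$values, study_species_table(st)$values, tolerance = 1e-12)
  md <- read_sample_metadata(paths["metadata"])
  expect_equal(md$sample_id, st$metadata$sample_id)
  fn <- read_stratified_function_profile(paths["pathways"])
  expect_gt(sum(fn$stratified), 0)
  tree <- ape::read.tree(paths["tree"])
  expect_setequal(tree$tip.label,
                  microresist:::terminal_clade(rownames(st$counts)))
})
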