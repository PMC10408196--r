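#' Control-cohort fluctuation baseline
#'
#' @param mean,sd mean and (sample) standard deviation of pooled control
#'   day-to-day Bray-Curtis values.
#' @param n_pairs number of contributing pairs.
#' @param max_gap_days pairing window used.
#' @return a `fluctuation_baseline` with `cutoff1 = mean + sd` and
#'   `cutoff2 = mean + 2 sd`.
#' @export
fluctuation_baseline <- function(mean, sd, n_pairs, max_gap_days = 2) {
  if (!is.finite(sd) || sd <= 0)
    stop("degenerate fluctuation baseline: sd must be > 0")
  if (n_pairs < 2) stop("need at least 2 contributing pairs")
  structure(list(mean = mean, sd = sd, cutoff1 = mean + sd,
                 cutoff2 = mean + 2 * sd, n_pairs = n_pairs,
                 max_gap_days = max_gap_days),
            class = "fluctuation_baseline")
}

#' @export
print.fluctuation_baseline <- function(x, ...) {
  cat(sprintf(paste0("fluctuation_baseline: mean %.4f, sd %.4f ",
                     "(cutoffs %.4f / %.4f; %d pairs, gap <= %d d)\n"),
              x$mean, x$sd, x$cutoff1, x$cutoff2, x$n_pairs, x$max_gap_days))
  invisible(x)
}

#' Estimate the day-to-day fluctuation of an undisturbed microbiome
#'
#' For every control subject, all sample pairs whose collection days differ
#' by 1 to `max_gap_days` contribute one Bray-Curtis dissimilarity. The
#' pooled values' mean and SD define the two response cutoffs
#' (`mean + SD`, `mean + 2 SD`).
#'
#' @param control_table relative-abundance [abundance_table()] of the control
#'   cohort.
#' @param control_metadata matching [sample_metadata()].
#' @param max_gap_days maximum day gap of an eligible pair (default 2).
#' @return a [fluctuation_baseline()]; the pooled values are attached as the
#'   `"values"` attribute.
#' @export
estimate_daily_fluctuation <- function(control_table, control_metadata,
                                       max_gap_days = 2) {
  md <- align_samples(control_table, control_metadata)
  bc <- bray_curtis(control_table)$values
  vals <- numeric(0)
  for (s in unique(md$subject_id)) {
    sub <- md[md$subject_id == s, , drop = FALSE]
    if (nrow(sub) < 2) next
    for (i in seq_len(nrow(sub) - 1)) for (j in (i + 1):nrow(sub)) {
      gap <- abs(sub$day[j] - sub$day[i])
      if (gap >= 1 && gap <= max_gap_days)
        vals <- c(vals, bc[sub$sample_id[i], sub$sample_id[j]])
    }
  }
  if (length(vals) < 2)
    stop("no eligible control pairs within max_gap_days = ", max_gap_days)
  if (length(unique(md$subject_id[md$sample_id %in% rownames(bc)])) < 2)
    stop("need pairs from at least 2 control subjects")
  out <- fluctuation_baseline(mean(vals), stats::sd(vals), length(vals),
                              max_gap_days)
  attr(out, "values") <- vals
  out
}

#' Select the first-peak response time point
#'
#' Given a subject's ordered post-intervention Bray-Curtis-to-baseline
#' trajectory, returns the earliest local maximum: runs of equal consecutive
#' values are compressed, and a run counts as a peak when it is not below its
#' predecessor and strictly above its successor (or is the final run). The
#' selected day is the first day of the peak run; a monotone increasing
#' trajectory therefore yields the last time point and a single observation
#' yields itself.
#'
#' @param days post-intervention days, strictly increasing.
#' @param bc_values Bray-Curtis to baseline at those days.
#' @return list with `selected_day` and `bc_value`.
#' @export
select_response_timepoint <- function(days, bc_values) {
  stopifnot(length(days) == length(bc_values), length(days) >= 1)
  if (length(days) > 1 && any(diff(days) <= 0))
    stop("days must be strictly increasing")
  r <- rle(bc_values)
  run_start <- cumsum(c(1, utils::head(r$lengths, -1)))
  nr <- length(r$values)
  for (i in seq_len(nr)) {
    up <- i == 1 || r$values[i] >= r$values[i - 1]
    down <- i == nr || r$values[i] > r$values[i + 1]
    if (up && down) {
      idx <- run_start[i]
      return(list(selected_day = days[idx], bc_value = bc_values[idx]))
    }
  }
  # non-increasing start followed by rises only: fall back to global max
  idx <- which.max(bc_values)
  list(selected_day = days[idx], bc_value = bc_values[idx])
}

#' Classify a response magnitude against the control fluctuation cutoffs
#'
#' `bc < mean + SD` is a non-responder; `bc` in the closed interval
#' `[mean + SD, mean + 2 SD]` is a partial responder; `bc > mean + 2 SD` is a
#' responder.
#'
#' @param bc_value Bray-Curtis dissimilarity in `[0, 1]` (vectorized).
#' @param baseline a [fluctuation_baseline()].
#' @return factor with ordered levels non_responder < partial_responder <
#'   responder.
#' @export
classify_response <- function(bc_value, baseline) {
  stopifnot(inherits(baseline, "fluctuation_baseline"))
  if (any(bc_value < 0 | bc_value > 1, na.rm = TRUE))
    stop("Bray-Curtis values must lie in [0, 1]")
  lab <- ifelse(bc_value < baseline$cutoff1, "non_responder",
                ifelse(bc_value <= baseline$cutoff2, "partial_responder",
                       "responder"))
  factor(lab, levels = c("non_responder", "partial_responder", "responder"),
         ordered = TRUE)
}

#' Classify every subject of an intervention cohort
#'
#' For each subject: Bray-Curtis between the baseline sample and every
#' post-intervention sample, first-peak time-point selection, then
#' classification against the control cutoffs.
#'
#' @param table relative-abundance [abundance_table()] of the intervention
#'   cohort (baseline and post samples).
#' @param metadata matching [sample_metadata()].
#' @param baseline a [fluctuation_baseline()].
#' @return data.frame `response_assessment`: `subject_id`, `selected_day`,
#'   `bc_value`, `label`.
#' @export
classify_cohort <- function(table, metadata, baseline) {
  md <- align_samples(table, metadata)
  bc <- bray_curtis(table)$values
  subjects <- unique(md$subject_id)
  rows <- lapply(subjects, function(s) {
    sub <- md[md$subject_id == s, , drop = FALSE]
    base <- sub[sub$phase == "baseline", , drop = FALSE]
    post <- sub[sub$phase == "post", , drop = FALSE]
    if (nrow(base) == 0 || nrow(post) == 0) return(NULL)
    base_id <- base$sample_id[which.min(base$day)]
    post <- post[order(post$day), , drop = FALSE]
    sel <- select_response_timepoint(post$day, bc[base_id, post$sample_id])
    data.frame(subject_id = s, selected_day = sel$selected_day,
               bc_value = sel$bc_value,
               label = as.character(classify_response(sel$bc_value, baseline)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$label <- factor(out$label, levels = c("non_responder",
                                            "partial_responder", "responder"),
                      ordered = TRUE)
  out
}
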