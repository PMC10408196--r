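#' Sample metadata constructor
#'
#' Validates the per-sample study metadata: sample id, subject id, cohort id,
#' cohort type, integer collection day, and study phase.
#'
#' @param df data.frame with columns `sample_id`, `subject_id`, `cohort_id`,
#'   `cohort_type` (one of control/antibiotic/lifestyle), `day` (integer),
#'   `phase` (baseline/post).
#' @return the validated data.frame with class `sample_metadata` prepended.
#' @export
sample_metadata <- function(df) {
  req <- c("sample_id", "subject_id", "cohort_id", "cohort_type", "day", "phase")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$subject_id <- as.character(df$subject_id)
  df$cohort_id <- as.character(df$cohort_id)
  df$day <- as.integer(df$day)
  if (!all(df$cohort_type %in% c("control", "antibiotic", "lifestyle")))
    stop("cohort_type must be control, antibiotic or lifestyle")
  if (!all(df$phase %in% c("baseline", "post")))
    stop("phase must be baseline or post")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata")
  dup <- duplicated(df[, c("cohort_id", "subject_id", "day")])
  if (any(dup))
    stop("duplicate (subject, day) pairs within a cohort: ",
         paste(df$sample_id[dup][seq_len(min(5, sum(dup)))], collapse = ", "))
  nonctl <- df[df$cohort_type != "control", ]
  if (nrow(nonctl)) {
    nb <- tapply(nonctl$phase == "baseline", nonctl$subject_id, any)
    if (!all(nb))
      stop("subject(s) without a baseline sample: ",
           paste(names(nb)[!nb], collapse = ", "))
  }
  class(df) <- unique(c("sample_metadata", class(df)))
  df
}

#' Check sample alignment between a table and its metadata
#'
#' Any sample present in one but not the other is a hard error naming the
#' offending ids; subject pairing is load-bearing for the ICC stage, so
#' silent drops are not allowed.
#'
#' @param table an [abundance_table()].
#' @param metadata a [sample_metadata()] data.frame.
#' @return invisibly, the metadata reordered to the table's sample order.
#' @export
align_samples <- function(table, metadata) {
  s_tab <- sample_ids(table)
  s_met <- metadata$sample_id
  only_tab <- setdiff(s_tab, s_met)
  only_met <- setdiff(s_met, s_tab)
  if (length(only_tab) || length(only_met))
    stop("sample mismatch between table and metadata.",
         if (length(only_tab)) paste0(" Only in table: ",
                                      paste(only_tab, collapse = ", "), "."),
         if (length(only_met)) paste0(" Only in metadata: ",
                                      paste(only_met, collapse = ", "), "."))
  invisible(metadata[match(s_tab, s_met), , drop = FALSE])
}

rank_prefix <- c(species = "s__", genus = "g__", family = "f__",
                 order = "o__", class = "c__", phylum = "p__", kingdom = "k__")

#' Read a merged taxonomic profile
#'
#' Parses the merged-table dialect written by shotgun taxonomic profilers:
#' tab-separated, first column a pipe-delimited clade lineage
#' (`k__...|p__...|...`), one column per sample. Only rows terminating at the
#' requested taxonomic level are returned. Percent-scaled tables (columns
#' summing to ~100) are auto-detected and divided by 100.
#'
#' @param path file path.
#' @param level taxonomic level to extract (`"species"` or `"genus"`).
#' @return an [abundance_table()] with unit `"relative"`.
#' @export
read_taxonomic_profile <- function(path, level = c("species", "genus")) {
  level <- match.arg(level)
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("no sample columns in ", path)
  lineage <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat))
    stop("non-numeric abundance cells in ", path, " (first bad column: ",
         colnames(mat)[which(!apply(df[, -1, drop = FALSE], 2, is.numeric))[1]], ")")
  term <- terminal_clade(lineage)
  keep <- startsWith(term, rank_prefix[[level]])
  if (!any(keep)) {
    warning("no rows at level '", level, "' in ", path)
    mat0 <- mat[0, , drop = FALSE]
    rownames(mat0) <- character(0)
    return(abundance_table(mat0, unit = "relative", level = level,
                           validate = FALSE))
  }
  mat <- mat[keep, , drop = FALSE]
  rownames(mat) <- lineage[keep]
  if (anyDuplicated(rownames(mat)))
    stop("duplicate clades in ", path, ": ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  cs <- colSums(mat)
  pct <- abs(cs - 100) < 1     # percent dialect
  prop <- abs(cs - 1) < 0.01   # proportion dialect
  if (any(pct) && any(prop) && !all(pct | prop))
    stop("mixed percent/proportion units across columns in ", path)
  if (mean(pct) > 0.5) mat <- mat / 100
  abundance_table(mat, unit = "relative", level = level)
}

#' Write a merged taxonomic profile
#'
#' @param table an [abundance_table()] at species or genus level.
#' @param path output file.
#' @export
write_taxonomic_profile <- function(table, path) {
  df <- data.frame(clade_name = feature_ids(table), table$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a stratified functional profile
#'
#' Tab-separated functional abundance table in which a feature column entry is
#' either an unstratified community total (`PWY-101`) or a per-taxon
#' contribution (`PWY-101|g__X.s__Y`, `PWY-101|unclassified`). `UNMAPPED` /
#' `UNINTEGRATED` rows are retained for copies-per-million bookkeeping but
#' flagged non-biological. Stratified rows without an unstratified parent, or
#' exceeding their parent's total beyond tolerance, are rejected.
#'
#' @param path file path.
#' @param level `"pathway"` or `"ko"`.
#' @param unit unit of the stored values, default `"cpm"`.
#' @return an [abundance_table()] with `stratified` / `nonbiological` flags.
#' @export
read_stratified_function_profile <- function(path, level = c("pathway", "ko"),
                                             unit = "cpm") {
  level <- match.arg(level)
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- ids
  nonbio <- grepl("^(UNMAPPED|UNINTEGRATED)", ids)
  strat <- grepl("\\|", ids) & !nonbio
  parent <- sub("\\|.*$", "", ids)
  orphans <- setdiff(unique(parent[strat]), ids[!strat & !nonbio])
  if (length(orphans))
    stop("stratified rows without an unstratified parent: ",
         paste(orphans, collapse = ", "))
  for (p in unique(parent[strat])) {
    tot <- mat[ids == p & !strat, , drop = FALSE]
    ssum <- colSums(mat[strat & parent == p, , drop = FALSE])
    if (any(ssum - tot > 1e-6 * pmax(1, tot)))
      stop("stratified rows of ", p, " exceed the unstratified total")
  }
  abundance_table(mat, unit = unit, level = level,
                  stratified = strat, nonbiological = nonbio)
}

#' Write a (stratified) functional profile
#' @param table an [abundance_table()] at pathway or ko level.
#' @param path output file.
#' @export
write_function_profile <- function(table, path) {
  df <- data.frame(feature = feature_ids(table), table$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata TSV
#' @param path file path.
#' @return a [sample_metadata()] data.frame.
#' @export
read_sample_metadata <- function(path) {
  sample_metadata(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_sample_metadata
#' @param metadata a [sample_metadata()] data.frame.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate a species table to genus level
#'
#' Sums species sharing the genus clade of their lineage. Mirrors the
#' taxonomy aggregation used by the machine-learning stage.
#'
#' @param table a species-level [abundance_table()].
#' @return a genus-level [abundance_table()].
#' @export
aggregate_to_genus <- function(table) {
  stopifnot(table$level == "species")
  parts <- strsplit(feature_ids(table), "|", fixed = TRUE)
  genus <- vapply(parts, function(p) {
    g <- grep("^g__", p, value = TRUE)
    if (length(g)) paste(p[seq_len(which(p == g[length(g)]))], collapse = "|")
    else "g__unclassified"
  }, character(1))
  agg <- rowsum(table$values, group = genus)
  abundance_table(agg[order(rownames(agg)), , drop = FALSE],
                  unit = table$unit, level = "genus")
}
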