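#' Abundance table container
#'
#' A features x samples matrix of microbial feature abundances together with
#' its unit semantics. Feature identifiers are pipe-delimited clade lineages
#' for taxa (`k__...|g__...|s__...`) or `PATHWAY` / `PATHWAY|g__X.s__Y` style
#' identifiers for (stratified) functional features.
#'
#' @param values non-negative numeric matrix, features in rows, samples in
#'   columns; `rownames` are feature ids, `colnames` sample ids.
#' @param unit one of `"relative"`, `"counts"`, `"cpm"`.
#' @param level one of `"species"`, `"genus"`, `"pathway"`, `"ko"`.
#' @param stratified logical per-feature flag; `TRUE` for per-taxon
#'   contribution rows of a functional table. Default: detected from the
#'   feature id (`"|g__"` / `"|unclassified"` suffix) for pathway/ko levels.
#' @param nonbiological logical per-feature flag for bookkeeping rows
#'   (`UNMAPPED`, `UNINTEGRATED`). Default: detected from the feature id.
#' @param validate check invariants (non-negativity, id uniqueness, column
#'   closure for relative tables).
#'
#' @return an object of class `abundance_table` with elements `values`,
#'   `unit`, `level`, `stratified`, `nonbiological`.
#' @export
abundance_table <- function(values, unit = c("relative", "counts", "cpm"),
                            level = c("species", "genus", "pathway", "ko"),
                            stratified = NULL, nonbiological = NULL,
                            validate = TRUE) {
  unit <- match.arg(unit)
  level <- match.arg(level)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("`values` must carry feature ids (rownames) and sample ids (colnames)")
  ids <- rownames(values)
  if (is.null(nonbiological))
    nonbiological <- grepl("^(UNMAPPED|UNINTEGRATED)", ids)
  if (is.null(stratified)) {
    stratified <- if (level %in% c("pathway", "ko"))
      grepl("\\|(g__|unclassified)", ids) else rep(FALSE, length(ids))
  }
  out <- structure(
    list(values = values, unit = unit, level = level,
         stratified = stratified, nonbiological = nonbiological),
    class = "abundance_table")
  if (validate) validate_abundance_table(out)
  out
}

validate_abundance_table <- function(x) {
  v <- x$values
  if (anyNA(v) || any(v < 0))
    stop("abundance values must be finite and non-negative")
  if (anyDuplicated(rownames(v)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", "))
  if (anyDuplicated(colnames(v)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", "))
  if (x$unit == "relative") {
    keep <- !x$stratified & !x$nonbiological
    cs <- colSums(v[keep, , drop = FALSE])
    bad <- abs(cs - 1) > 1e-6 & cs > 0
    if (any(bad))
      stop("relative-abundance columns must sum to 1 (off: ",
           paste(colnames(v)[bad][seq_len(min(5, sum(bad)))], collapse = ", "), ")")
  }
  invisible(x)
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d features x %d samples [%s, %s]\n",
              nrow(x$values), ncol(x$values), x$level, x$unit))
  if (any(x$stratified))
    cat(sprintf("  %d stratified contribution rows\n", sum(x$stratified)))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

feature_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Normalize an abundance table
#'
#' Total-sum scaling (columns sum to 1) or copies-per-million (columns sum to
#' 1e6). All-zero columns are left at zero with a warning. Stratified and
#' bookkeeping rows share the column's scaling factor so contribution ratios
#' are preserved.
#'
#' @param table an [abundance_table()] with unit `"counts"` or `"cpm"`.
#' @param scheme `"tss"` or `"cpm"`.
#' @return an [abundance_table()] in the requested unit.
#' @export
normalize_abundance <- function(table, scheme = c("tss", "cpm")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(table, "abundance_table"))
  if (any(table$values < 0)) stop("negative abundance values")
  keep <- !table$stratified & !table$nonbiological
  cs <- colSums(table$values[keep, , drop = FALSE])
  zero <- cs == 0
  if (any(zero)) {
    warning("all-zero sample column(s) left as zeros: ",
            paste(colnames(table$values)[zero], collapse = ", "))
    cs[zero] <- 1
  }
  target <- if (scheme == "tss") 1 else 1e6
  vals <- sweep(table$values, 2, cs / target, "/")
  abundance_table(vals, unit = if (scheme == "tss") "relative" else "cpm",
                  level = table$level, stratified = table$stratified,
                  nonbiological = table$nonbiological)
}
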