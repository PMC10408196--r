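#' @keywords internal
"_PACKAGE"

# Derive a reproducible child seed from a master seed and a stream label.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(master) + 7919 * h) %% (.Machine$integer.max - 1L)) + 1L
}

# Run code under a seed without disturbing the caller's RNG state.
# seed = NULL runs under the current RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# terminal clade of a pipe-delimited lineage string, e.g.
# "k__Bacteria|g__Gx|s__Gx_sp" -> "s__Gx_sp"
terminal_clade <- function(lineage) {
  vapply(strsplit(lineage, "|", fixed = TRUE),
         function(p) p[[length(p)]], character(1))
}

# rank-based AUC (Mann-Whitney); scores for the positive class
rank_auc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  pos <- as.logical(positive)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
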