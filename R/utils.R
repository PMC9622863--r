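# internal helpers shared across modules

# deterministic sub-seed derivation: keeps every derived seed a positive
# 32-bit integer so reruns of any benchmark subset are reproducible
derive_seed <- function(master, counter) {
  as.integer((as.double(master) %% 2147483629) * 48271 %% 2147483629 +
               997 * as.double(counter)) %% 2147483629L + 1L
}

stop_if_not_square <- function(F, what = "F") {
  if (!is.matrix(F) || nrow(F) != ncol(F))
    stop(sprintf("'%s' must be a square matrix, got %s", what,
                 paste(dim(as.matrix(F)), collapse = "x")), call. = FALSE)
  if (!all(is.finite(F)))
    stop(sprintf("'%s' contains non-finite entries", what), call. = FALSE)
  invisible(F)
}

check_length <- function(x, n, what) {
  if (length(x) != n)
    stop(sprintf("'%s' must have length %d, got %d", what, n, length(x)),
         call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("'%s' contains non-finite entries", what), call. = FALSE)
  invisible(x)
}

# parameter names used consistently by coef(), truth tables and classifiers:
# edge weights F_ij (row i = target, column j = source) in column-major order,
# then basal production, then external stimulus
param_names <- function(n) {
  fn <- as.vector(outer(seq_len(n), seq_len(n), function(i, j) sprintf("F%d%d", i, j)))
  c(fn, sprintf("S%db", seq_len(n)), sprintf("S%dex", seq_len(n)))
}
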