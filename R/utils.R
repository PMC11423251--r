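# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# stop with a classed condition so callers/tests can target pgnet errors
pg_abort <- function(msg, class = "pgnet_error", ...) {
  rlang::abort(msg, class = class, ...)
}

pg_warn <- function(msg, class = "pgnet_warning") {
  rlang::warn(msg, class = class)
}

# informational logging used by the pipeline; quiet by default in tests
pg_log <- function(...) {
  if (isTRUE(getOption("pgnet.verbose", TRUE))) {
    message(sprintf(...))
  }
}

assert_matrix_like <- function(x, what = "matrix") {
  if (is.data.frame(x)) {
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    pg_abort(sprintf("`%s` must be a numeric matrix or data frame.", what))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    pg_abort(sprintf("`%s` must have row names (genes) and column names (samples).", what))
  }
  x
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    pg_abort(sprintf("`%s` must be a single value in [0, 1].", name))
  }
  invisible(x)
}

# deterministic gene namespace used by all simulators (G00001, G00002, ...)
gene_names <- function(n, prefix = "G") {
  sprintf("%s%05d", prefix, seq_len(n))
}
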