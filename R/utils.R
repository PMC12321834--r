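# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sum rows of `x` into `n` bins given by integer index `idx` (length nrow(x)).
# Bins with no contributing rows are zero. Workhorse for message aggregation.
scatter_add <- function(x, idx, n) {
  out <- matrix(0, n, ncol(x))
  if (length(idx)) {
    s <- rowsum(x, idx)
    out[as.integer(rownames(s)), ] <- s
  }
  out
}

# abort with a class so callers/tests can condition on the failure kind
stop_cmpnntox <- function(msg, class) {
  rlang::abort(msg, class = c(class, "cmpnntox_error"))
}

inform_quiet <- function(...) {
  if (!isTRUE(getOption("cmpnntox.quiet", FALSE))) rlang::inform(paste0(...))
}

is_binary_label <- function(x) {
  is.numeric(x) && all(x %in% c(0, 1))
}
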