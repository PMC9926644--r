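# Typed conditions: every error carries a subclass so callers and tests can
# distinguish degenerate variance from input problems etc.
stop_mlsize <- function(class, message, call = sys.call(-1)) {
  cond <- structure(
    class = c(paste0("mlsize_", class), "mlsize_error", "error", "condition"),
    list(message = message, call = call))
  stop(cond)
}

warn_mlsize <- function(class, message) {
  cond <- structure(
    class = c(paste0("mlsize_", class), "mlsize_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1)))
  warning(cond)
}

# Deterministic child seeds from one master seed.  Every stochastic stage
# draws its own seed from this stream so stages are reproducible
# independently of execution order (and of parallel scheduling).
derive_seeds <- function(master_seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master_seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# Stable fingerprint of a dataset for lineage checks between effect-size
# summaries and evaluation curves (no digest dependency; sums are cheap and
# adequate to catch accidental mixing of datasets).
dataset_fingerprint <- function(dataset) {
  v <- dataset$values
  sprintf("%dx%d:%.10g:%.10g", nrow(v), ncol(v), sum(v), sum(v^2))
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
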