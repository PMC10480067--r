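#' @keywords internal
"_PACKAGE"

## Deterministic sub-seed derivation: every stochastic stage draws its own
## seed from the master seed and a stage name, so stages are reproducible
## independently of execution order. Kept below 2^31 (R integers).
sub_seed <- function(seed, stage, i = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) %% 2147483647 * 69069 + h * 2654435 + i * 1013) %%
    2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
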