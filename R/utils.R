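#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Deterministic 31-bit hash of a label, used to key per-experiment
## seed sub-streams so that set-level results do not depend on the order
## in which experiments are listed.
label_hash <- function(label) {
  codes <- utf8ToInt(enc2utf8(as.character(label)))
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

## Sub-seed for one experiment under a master seed; stays below 2^31.
sub_seed <- function(seed, label) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + label_hash(label)) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
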