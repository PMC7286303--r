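# Internal helpers shared across modules.

# Derive a reproducible 32-bit substream seed from a master seed and an
# integer stream index. Arithmetic kept in doubles (< 2^53) before the
# final modulus so no overflow occurs.
substream_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 48271 + abs(as.numeric(index)) * 16807) %%
               2147483629)
}

# Stable small integer stream index for a character id.
string_stream <- function(x) {
  v <- utf8ToInt(as.character(x))
  as.integer(sum(v * seq_along(v) * 131) %% 1000003)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_binary_kind <- function(kind) {
  kind %in% c("struct_binary", "func_binary", "binary")
}
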