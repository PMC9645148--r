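# Shared small numerics.

# Reflect-pad a matrix by k pixels on every side (edge mirror without
# repeating the border pixel would need k < dim; we use symmetric padding
# "abc|cba" truncated to available size, which is safe for k < dim).
.padReflect <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  ri <- c(rev(seq_len(k)), seq_len(h), h - seq_len(k) + 1L)
  ci <- c(rev(seq_len(k)), seq_len(w), w - seq_len(k) + 1L)
  m[ri, ci, drop = FALSE]
}

.padZero <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h + 2L * k, w + 2L * k)
  out[k + seq_len(h), k + seq_len(w)] <- m
  out
}

# Numerically stable softmax over all entries of x (any shape preserved).
.softmaxAll <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# 2x box-downsample of a matrix (H, W even).
.downsample2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  (m[seq(1L, h, 2L), seq(1L, w, 2L)] + m[seq(2L, h, 2L), seq(1L, w, 2L)] +
   m[seq(1L, h, 2L), seq(2L, w, 2L)] + m[seq(2L, h, 2L), seq(2L, w, 2L)]) / 4
}

# Deterministic small-int sub-seed derived from a base seed and a tag,
# kept below 2^31.
.subSeed <- function(seed, tag) {
  (as.numeric(seed) * 1009 + tag * 9973) %% 2147483647
}
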