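# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. Keeps every exported operation deterministic
# given its seed argument without clobbering the global stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic per-individual sub-seed so adding individuals never perturbs
# the streams of existing ones
sub_seed <- function(seed, i) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(i)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# 2-D convolution of equal-sized matrices via FFT with zero padding.
# Returns a matrix the size of `a`; `k` is treated as centered.
conv2d_fft <- function(a, k) {
  na <- nrow(a); ma <- ncol(a)
  nk <- nrow(k); mk <- ncol(k)
  n <- na + nk - 1L; m <- ma + mk - 1L
  pa <- matrix(0, n, m); pa[seq_len(na), seq_len(ma)] <- a
  pk <- matrix(0, n, m); pk[seq_len(nk), seq_len(mk)] <- k
  out <- Re(fft(fft(pa) * fft(pk), inverse = TRUE)) / (n * m)
  # center of kernel maps to offset (ceiling(nk/2), ceiling(mk/2))
  r0 <- ceiling(nk / 2); c0 <- ceiling(mk / 2)
  out[r0 + seq_len(na) - 1L, c0 + seq_len(ma) - 1L]
}

# Gaussian smoothing kernel truncated at 3 sd (sd in cells)
gauss_kernel <- function(sd_cells) {
  r <- max(1L, ceiling(3 * sd_cells))
  ax <- (-r):r
  k1 <- exp(-ax^2 / (2 * sd_cells^2))
  k <- outer(k1, k1)
  k / sum(k)
}
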