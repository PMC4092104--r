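# Straight-loop reference implementations, kept deliberately independent of
# the package internals (no shared helpers).

# Explicit GVF diffusion, scalar loops, reflected boundaries.
gvf_oracle <- function(f, mu, n_iter, dt) {
  H <- nrow(f); W <- ncol(f)
  cl <- function(i, n) min(max(i, 1L), n)
  fx <- matrix(0, H, W); fy <- matrix(0, H, W)
  for (i in 1:H) {
    for (j in 1:W) {
      fx[i, j] <- (f[cl(i + 1L, H), j] - f[cl(i - 1L, H), j]) / 2
      fy[i, j] <- (f[i, cl(j + 1L, W)] - f[i, cl(j - 1L, W)]) / 2
    }
  }
  u <- fx; v <- fy
  b <- fx^2 + fy^2
  for (it in seq_len(n_iter)) {
    un <- u; vn <- v
    for (i in 1:H) {
      for (j in 1:W) {
        lu <- u[cl(i - 1L, H), j] + u[cl(i + 1L, H), j] +
          u[i, cl(j - 1L, W)] + u[i, cl(j + 1L, W)] - 4 * u[i, j]
        lv <- v[cl(i - 1L, H), j] + v[cl(i + 1L, H), j] +
          v[i, cl(j - 1L, W)] + v[i, cl(j + 1L, W)] - 4 * v[i, j]
        un[i, j] <- u[i, j] + dt * (mu * lu - b[i, j] * (u[i, j] - fx[i, j]))
        vn[i, j] <- v[i, j] + dt * (mu * lv - b[i, j] * (v[i, j] - fy[i, j]))
      }
    }
    u <- un; v <- vn
  }
  list(u = u, v = v)
}

# Textbook paired t on differences.
paired_t_oracle <- function(pre, post) {
  d <- post - pre
  n <- length(d)
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  list(t = t_stat, p = 2 * stats::pt(-abs(t_stat), df = n - 1))
}
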