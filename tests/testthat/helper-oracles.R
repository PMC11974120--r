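# Independent oracles used to pin expected values. These deliberately use
# naive, transparent algorithms (brute-force double loops, full
# enumeration) and stay independent of the package implementations.

# O(N^2) brute-force approximate entropy (Pincus definition, self-matches
# included, Chebyshev distance, r = r_factor * sd)
apen_brute <- function(x, m = 2, r_factor = 0.2) {
  n <- length(x)
  r <- r_factor * stats::sd(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    X <- matrix(0, nt, mm)
    for (k in seq_len(mm)) X[, k] <- x[k:(k + nt - 1)]
    logC <- numeric(nt)
    for (i in seq_len(nt)) {
      d <- abs(X[, 1] - X[i, 1])
      if (mm > 1) {
        for (k in 2:mm) d <- pmax(d, abs(X[, k] - X[i, k]))
      }
      logC[i] <- log(sum(d <= r) / nt)
    }
    mean(logC)
  }
  phi(m) - phi(m + 1)
}

# exact Mann-Whitney p by enumerating all C(nx+ny, nx) group assignments;
# U counts (x > y) pairs with ties worth 1/2; inclusive tail convention
mwu_enum <- function(x, y, tail = c("right", "left")) {
  tail <- match.arg(tail)
  nx <- length(x)
  pooled <- c(x, y)
  u_stat <- function(ix) {
    xx <- pooled[ix]
    yy <- pooled[-ix]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  obs <- u_stat(seq_len(nx))
  us <- utils::combn(length(pooled), nx, u_stat)
  if (tail == "right") mean(us >= obs - 1e-9) else mean(us <= obs + 1e-9)
}

# exact Wilcoxon signed-rank p by enumerating all 2^n sign patterns
# (midranks for tied |differences|; inclusive tail convention)
wsr_enum <- function(pre, post, tail = c("right", "left")) {
  tail <- match.arg(tail)
  d <- pre - post
  d <- d[d != 0]
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.numeric(signs %*% r)
  if (tail == "right") mean(ws >= obs - 1e-9) else mean(ws <= obs + 1e-9)
}

# log-log periodogram regression slope over mid-band frequencies
psd_slope <- function(x, fs) {
  n <- length(x)
  p <- Mod(stats::fft(x))[2:(n %/% 2)]^2
  f <- (1:(n %/% 2 - 1)) * fs / n
  sel <- f >= 10 * fs / n & f <= fs / 8 & p > 0
  unname(stats::coef(stats::lm(log(p[sel]) ~ log(f[sel])))[2])
}

# frequency and amplitude of the dominant spectral peak
dominant_peak <- function(x, fs) {
  n <- length(x)
  sp <- Mod(stats::fft(x))[seq_len(n %/% 2)]
  k <- which.max(sp[-1])  # skip DC
  list(freq = k * fs / n, amp = 2 * sp[k + 1] / n)
}

rms <- function(x) sqrt(mean(x^2))
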