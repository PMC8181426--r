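# Straight-line, loop-based reimplementations of every handcrafted
# feature formula, used as independent oracles against the package's
# vectorized implementations. Deliberately naive: explicit loops and
# the formulas exactly as documented, nothing shared with the package
# code.

oracleChannel <- function(x, set, zcThr = 0, sscThr = 0, wampThr = 0,
                          logFloor = -20) {
  n <- length(x)
  mav <- 0
  for (v in x) mav <- mav + abs(v)
  mav <- mav / n
  zc <- 0
  for (i in 1:(n - 1))
    if (x[i] * x[i + 1] < 0 && abs(x[i] - x[i + 1]) >= zcThr) zc <- zc + 1
  ssc <- 0
  if (n >= 3)
    for (i in 2:(n - 1)) {
      d1 <- x[i] - x[i - 1]; d2 <- x[i] - x[i + 1]
      if (d1 * d2 > 0 && max(abs(d1), abs(d2)) >= sscThr) ssc <- ssc + 1
    }
  wl <- 0
  for (i in 1:(n - 1)) wl <- wl + abs(x[i + 1] - x[i])
  glog <- function(v, base = exp(1)) {
    out <- log(abs(v), base = base)
    if (!is.finite(out)) logFloor else out
  }
  if (set == "TD") return(c(mav, zc, ssc, wl))
  if (set == "TDAR") {
    # Levinson-Durbin on the biased autocorrelation, polynomial sign
    p <- 4
    if (max(x) == min(x)) return(c(mav, zc, ssc, wl, rep(0, p)))
    r <- numeric(p + 1)
    for (k in 0:p) {
      s <- 0
      for (i in 1:(n - k)) s <- s + x[i] * x[i + k]
      r[k + 1] <- s / n
    }
    phi <- numeric(p); e <- r[1]
    for (m in 1:p) {
      acc <- r[m + 1]
      if (m > 1) for (j in 1:(m - 1)) acc <- acc - phi[j] * r[m - j + 1]
      kk <- acc / e
      new <- phi
      new[m] <- kk
      if (m > 1) for (j in 1:(m - 1)) new[j] <- phi[j] - kk * phi[m - j]
      phi <- new
      e <- e * (1 - kk^2)
    }
    return(c(mav, zc, ssc, wl, -phi))
  }
  if (set == "TDPSD") {
    six <- function(y) {
      m <- length(y)
      dy <- numeric(m - 1); for (i in 1:(m - 1)) dy[i] <- y[i + 1] - y[i]
      ddy <- numeric(m - 2); for (i in 1:(m - 2)) ddy[i] <- dy[i + 1] - dy[i]
      m0 <- sqrt(sum(y^2))^0.1 / 0.1
      m2 <- sqrt(sum(dy^2))^0.1 / 0.1
      m4 <- sqrt(sum(ddy^2))^0.1 / 0.1
      sparse <- m0 / sqrt(abs((m0 - m2) * (m0 - m4)))
      irr <- m2 / sqrt(m0 * m4)
      wlr <- sum(abs(dy)) / sum(abs(ddy))
      vapply(c(m0, m0 - m2, m0 - m4, sparse, irr, wlr), glog, numeric(1))
    }
    a <- six(x)
    b <- six(log(x^2 + .Machine$double.eps))
    out <- -2 * a * b / (a^2 + b^2)
    out[!is.finite(out)] <- 0
    return(out)
  }
  # LSF4 block
  sdsum <- 0
  for (i in 1:(n - 1)) sdsum <- sdsum + (x[i + 1] - x[i])^2
  mfl <- glog(sqrt(sdsum), base = 10)
  xs <- sort(x)
  b0 <- mean(xs)
  b1 <- 0
  for (i in 1:n) b1 <- b1 + ((i - 1) / (n - 1)) * xs[i]
  b1 <- b1 / n
  ls <- 2 * b1 - b0
  msr <- 0
  for (v in x) msr <- msr + sign(v) * sqrt(abs(v))
  msr <- abs(msr) / n
  wamp <- 0
  for (i in 1:(n - 1)) if (abs(x[i + 1] - x[i]) > wampThr) wamp <- wamp + 1
  lsf4 <- c(mfl, ls, msr, wamp)
  if (set == "LSF4") return(lsf4)
  rms <- sqrt(sum(x^2) / n)
  iemg <- sum(abs(x))
  dasdv <- sqrt(sdsum / (n - 1))
  vr <- sum(x^2) / (n - 1)
  c(lsf4, zc, rms, iemg, dasdv, vr)
}

oracleWindow <- function(w, set, ...) {
  # sapply returns features x channels; column-major unlisting gives
  # per-channel blocks, matching the package layout
  as.numeric(sapply(seq_len(nrow(w)), function(c)
    oracleChannel(w[c, ], set, ...)))
}
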