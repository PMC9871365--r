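# Brute-force sums-of-squares oracle, coded directly from the textbook
# definitions with explicit loops -- deliberately independent of the
# implementation's marginal-mean algebra.
oracle_2way <- function(y) {
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  g <- mean(y)
  ss <- function(fun) { s <- 0
    for (i in 1:n) for (c1 in 1:a) for (t1 in 1:b)
      s <- s + fun(i, c1, t1)^2
    s }
  mS <- sapply(1:n, function(i) mean(y[i, , ]))
  mC <- sapply(1:a, function(c1) mean(y[, c1, ]))
  mT <- sapply(1:b, function(t1) mean(y[, , t1]))
  mSC <- outer(1:n, 1:a, Vectorize(function(i, c1) mean(y[i, c1, ])))
  mST <- outer(1:n, 1:b, Vectorize(function(i, t1) mean(y[i, , t1])))
  mCT <- outer(1:a, 1:b, Vectorize(function(c1, t1) mean(y[, c1, t1])))
  ss_C <- ss(function(i, c1, t1) mC[c1] - g)
  ss_SC <- ss(function(i, c1, t1) mSC[i, c1] - mS[i] - mC[c1] + g)
  ss_T <- ss(function(i, c1, t1) mT[t1] - g)
  ss_ST <- ss(function(i, c1, t1) mST[i, t1] - mS[i] - mT[t1] + g)
  ss_CT <- ss(function(i, c1, t1) mCT[c1, t1] - mC[c1] - mT[t1] + g)
  ss_E <- ss(function(i, c1, t1) y[i, c1, t1] - mSC[i, c1] - mST[i, t1] -
               mCT[c1, t1] + mS[i] + mC[c1] + mT[t1] - g)
  c(condition = (ss_C / (a - 1)) / (ss_SC / ((a - 1) * (n - 1))),
    trial = (ss_T / (b - 1)) / (ss_ST / ((b - 1) * (n - 1))),
    interaction = (ss_CT / ((a - 1) * (b - 1))) /
      (ss_E / ((a - 1) * (b - 1) * (n - 1))))
}


# beat times with sinusoidal RR modulation of amplitude a_ms at freq f
modulated_beats <- function(a_ms, f = 0.25, rr = 1, total = 195) {
  t <- 0; times <- numeric(0)
  while (t < total) {
    times <- c(times, t)
    t <- t + rr + a_ms / 1000 * sin(2 * pi * f * t)
  }
  times
}

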