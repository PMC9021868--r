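# Independent straight-line oracles. These transcribe each published
# formula directly (scalar recursions, sum formulas), deliberately sharing
# no code with the package implementations they check.

# two-step dynamic model: literal transcription of the canonical recursion
dyn_oracle <- function(temp_c, x0 = 0) {
  slp <- 1.6; tetmlt <- 277; e0 <- 4153.5; e1 <- 12888.8
  a0 <- 1.395e5; a1 <- 2.567e18
  tk <- temp_c + 273
  # per-hour quantities are pure functions of temperature (vectorised);
  # only the pool state is sequential
  xs <- (a0 / a1) * exp((e1 - e0) / tk)
  ak1 <- a1 * exp(-e1 / tk)
  sr <- exp(slp * tetmlt * (tk - tetmlt) / tk)
  xi <- sr / (1 + sr)
  x <- x0
  delta <- numeric(length(temp_c))
  for (i in seq_along(temp_c)) {
    inter_e <- xs[i] - (xs[i] - x) * exp(-ak1[i])
    d <- if (inter_e >= 1) xi[i] * inter_e else 0
    x <- inter_e - d
    delta[i] <- d
  }
  list(cumulative = cumsum(delta), state = x)
}

# Utah weights via an explicit per-element if-chain
utah_oracle <- function(temp_c) {
  vapply(temp_c, function(t) {
    if (t <= 1.4) 0
    else if (t <= 2.4) 0.5
    else if (t <= 9.1) 1
    else if (t <= 12.4) 0.5
    else if (t <= 15.9) 0
    else if (t <= 18) -0.5
    else -1
  }, numeric(1))
}

# Pearson correlation via the direct sum formula
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# NIPALS PLS1 + VIP: independent transcription of the textbook algorithm
nipals_oracle <- function(X, y, ncomp) {
  Xs <- scale(X)
  yc <- y - mean(y)
  p <- ncol(Xs); n <- nrow(Xs)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  qv <- numeric(ncomp); ssy <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- t(Xs) %*% yc
    w <- w / sqrt(sum(w * w))
    tt <- Xs %*% w
    t2 <- sum(tt * tt)
    pa <- t(Xs) %*% tt / t2
    qa <- sum(yc * tt) / t2
    Xs <- Xs - tt %*% t(pa)
    yc <- yc - qa * tt
    W[, a] <- w; P[, a] <- pa; qv[a] <- qa; ssy[a] <- qa^2 * t2
  }
  b <- W %*% solve(t(P) %*% W) %*% qv
  vip <- sqrt(p * (W^2 %*% ssy) / sum(ssy))
  list(coefficients = as.numeric(b), vip = as.numeric(vip))
}

# Bland-Altman quantities from first principles
ba_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  md <- sum(d) / n
  sdd <- sqrt(sum((d - md)^2) / (n - 1))
  lo <- md - 1.96 * sdd; hi <- md + 1.96 * sdd
  list(mean_diff = md, loa = c(lo, hi),
       inside = sum(d >= lo & d <= hi) / n)
}

# helper: hourly series of given temps starting at a fixed timestamp
make_series <- function(temp_c, start = "2016-11-01 00:00:00") {
  temperature_series(
    seq(as.POSIXct(start, tz = "UTC"), by = 3600,
        length.out = length(temp_c)),
    temp_c)
}

# helper: a full synthetic season of hourly weather (smooth + reproducible)
season_series <- function(first_year = 2016, mean_c = 10, amp_c = 8,
                          diurnal_c = 4) {
  s <- season(first_year)
  tt <- seq(as.POSIXct(paste(s$start, "00:00:00"), tz = "UTC"),
            as.POSIXct(paste(s$end, "23:00:00"), tz = "UTC"), by = 3600)
  doy <- as.numeric(format(tt, "%j", tz = "UTC"))
  hr <- as.numeric(format(tt, "%H", tz = "UTC"))
  temperature_series(tt, mean_c - amp_c * cos(2 * pi * (doy - 15) / 365.25) +
                       diurnal_c * cos(2 * pi * (hr - 14) / 24))
}
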