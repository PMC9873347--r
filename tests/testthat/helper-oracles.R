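# Independent naive reference implementations used to validate the fast
# estimators.  These deliberately share no code with the package: plain
# double loops / order()-based constructions, straight from the defining
# formulas.

oracle_sampen <- function(x, m = 2, r_coeff = 0.15) {
  r <- r_coeff * sqrt(mean((x - mean(x))^2))
  N <- length(x); nt <- N - m
  A <- 0; B <- 0
  for (i in 1:(nt - 1)) for (j in (i + 1):nt) {
    if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
      B <- B + 1
      if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
    }
  }
  if (A == 0 || B == 0) return(log(nt * (nt - 1) / 2))
  -log(A / B)
}

oracle_fuzzen <- function(x, m = 2, r = 0.0077, n = 3, variant = "local") {
  N <- length(x); nt <- N - m
  if (variant == "global") x <- x - mean(x)
  phi <- function(mm) {
    tpl <- sapply(0:(mm - 1), function(k) x[(1:nt) + k])
    if (variant == "local") tpl <- tpl - rowMeans(tpl)
    tot <- 0
    for (i in 1:(nt - 1)) for (j in (i + 1):nt)
      tot <- tot + exp(-(max(abs(tpl[i, ] - tpl[j, ])) / r)^n)
    tot / (nt * (nt - 1) / 2)
  }
  log(phi(m)) - log(phi(m + 1))
}

oracle_peren <- function(x, order = 3, delay = 2, normalize = TRUE) {
  n_vec <- length(x) - (order - 1) * delay
  pats <- character(n_vec)
  for (i in 1:n_vec) {
    v <- x[i + (0:(order - 1)) * delay]
    pats[i] <- paste(order(v), collapse = "")  # stable: ties by position
  }
  p <- table(pats) / n_vec
  h <- -sum(p * log(p))
  if (normalize) h / log(factorial(order)) else h
}

oracle_dispen <- function(x, m = 2, cc = 3) {
  rng <- max(x) - min(x)
  if (rng == 0) return(0)
  cls <- pmin(floor((x - min(x)) / rng * cc) + 1, cc)
  n_vec <- length(x) - m + 1
  pats <- character(n_vec)
  for (i in 1:n_vec) pats[i] <- paste(cls[i:(i + m - 1)], collapse = ",")
  p <- table(pats) / n_vec
  -sum(p * log(p)) / log(cc^m)
}

oracle_ben <- function(x, m = 10) {
  swaps <- function(mm) {
    nt <- length(x) - mm + 1
    out <- integer(nt)
    for (i in 1:nt) {
      v <- x[i:(i + mm - 1)]
      # literal bubble sort, counting swaps
      cnt <- 0
      repeat {
        done <- TRUE
        for (a in 1:(mm - 1)) if (v[a] > v[a + 1]) {
          tmp <- v[a]; v[a] <- v[a + 1]; v[a + 1] <- tmp
          cnt <- cnt + 1; done <- FALSE
        }
        if (done) break
      }
      out[i] <- cnt
    }
    out
  }
  renyi2 <- function(cnts) {
    p <- table(cnts) / length(cnts)
    -log(sum(p^2))
  }
  (renyi2(swaps(m + 1)) - renyi2(swaps(m))) / log((m + 1) / (m - 1))
}

oracle_phen <- function(x, k) {
  d <- diff(x)
  X <- d[-length(d)]; Y <- d[-1]
  keep <- !(X == 0 & Y == 0)
  ang <- atan2(Y[keep], X[keep])
  ang[ang < 0] <- ang[ang < 0] + 2 * pi
  sec <- floor(ang / (2 * pi / k)) + 1
  sec[sec > k] <- k
  p <- table(sec) / sum(keep)
  -sum(p * log(p)) / log(k)
}

# exact two-sided Mann-Whitney p-value by full enumeration of label
# arrangements (small n only)
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  u_stat <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_stat(seq_len(na))
  combs <- utils::combn(n, na)
  us <- apply(combs, 2, u_stat)
  mu <- na * (n - na) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# small synthetic windows for feature tests: a z-scored, F1-band-passed
# record segment at 20 Hz
make_test_window <- function(seed = 1, n_rec = 36000, band = "F1") {
  set.seed(seed)
  bandpass(zscore(rnorm(n_rec)), ehg_band(band), 20)[1:2400]
}
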