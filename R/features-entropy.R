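#' Default entropy parameter set
#'
#' The internal parameters used for the per-window entropy features:
#' SampEn (m=2, relative tolerance r=0.15*SD), FuzzEn (m=2, absolute
#' r=0.0077, exponential membership power n=3, local and global variants),
#' PerEn (order pi=3, delay d=2, normalized), DispEn (m=2, c=3 classes,
#' linear min-max mapping), bubble entropy (embedding order m=10) and PhEn
#' (k = 2, 4, ..., 24 sectors, twelve separate features).
#'
#' @return a named list of parameter blocks.
#' @export
entropy_params <- function() {
  list(sampen = list(m = 2, r_coeff = 0.15),
       fuzzen = list(m = 2, r = 0.0077, n = 3),
       peren = list(order = 3, delay = 2),
       dispen = list(m = 2, c = 3),
       ben = list(m = 10),
       phen = list(ks = seq(2, 24, by = 2)))
}

#' Sample entropy
#'
#' Negative log conditional probability that template vectors matching for
#' `m` points (Chebyshev distance within `r = r_coeff * SD(x)`, self-matches
#' excluded) also match for `m + 1` points.  A constant window returns 0
#' (every template matches); when no `(m+1)`-matches exist the estimate
#' saturates at `log(number of template pairs)` and carries attribute
#' `saturated = TRUE`.
#'
#' @param x numeric series of length >= `m + 2`.
#' @param m embedding dimension.
#' @param r_coeff tolerance as a fraction of the population SD of `x`.
#' @return entropy in nats.
#' @export
sample_entropy <- function(x, m = 2, r_coeff = 0.15) {
  if (length(x) < m + 2) stop_ehg("series too short for sample entropy")
  r <- r_coeff * sd_pop(x)
  ab <- sampen_counts_cpp(as.numeric(x), as.integer(m), r)
  A <- ab[1]; B <- ab[2]
  if (B == 0 || A == 0) {
    nt <- length(x) - m
    return(structure(log(nt * (nt - 1) / 2), saturated = TRUE))
  }
  -log(A / B)
}

#' Fuzzy entropy (local and global variants)
#'
#' Like sample entropy but with a soft membership `exp(-(d/r)^n)` instead of
#' a hard tolerance: `ln(phi_m) - ln(phi_(m+1))` where `phi` is the mean
#' membership over template pairs.  The `local` variant removes each
#' template's own mean before computing distances (sensitive to shape, not
#' level); the `global` variant removes only the whole-window mean.  The
#' tolerance `r` is absolute, so FuzzEn is the one entropy here that is not
#' invariant to rescaling the signal.
#'
#' @param x numeric series of length >= `m + 2`.
#' @param m embedding dimension.
#' @param r absolute tolerance.
#' @param n membership exponent.
#' @param variant `"local"` or `"global"`.
#' @return entropy in nats.
#' @export
fuzzy_entropy <- function(x, m = 2, r = 0.0077, n = 3,
                          variant = c("local", "global")) {
  variant <- match.arg(variant)
  if (length(x) < m + 2) stop_ehg("series too short for fuzzy entropy")
  x <- as.numeric(x)
  if (variant == "global") x <- x - mean(x)
  phi <- fuzzen_phi_cpp(x, as.integer(m), r, n, variant == "local")
  if (phi[1] == 0 || phi[2] == 0) {
    nt <- length(x) - m
    return(structure(log(nt * (nt - 1) / 2), saturated = TRUE))
  }
  log(phi[1]) - log(phi[2])
}

# ordinal pattern ids for embedded vectors; ties broken by order of
# appearance (an earlier element ranks below an equal later one).  The
# rank of element k inside its vector is computed from vectorized pairwise
# comparisons, which encodes the same pattern classes as a stable sort.
ordinal_patterns <- function(x, order, delay) {
  n_vec <- length(x) - (order - 1) * delay
  cols <- lapply(0:(order - 1), function(k) x[(1:n_vec) + k * delay])
  id <- numeric(n_vec)
  for (k in seq_len(order)) {
    rk <- 1
    for (l in seq_len(order)) {
      if (l == k) next
      rk <- rk + if (l < k) (cols[[l]] <= cols[[k]]) else (cols[[l]] < cols[[k]])
    }
    id <- id * order + (rk - 1)
  }
  match(id, sort(unique(id)))
}

#' Permutation entropy
#'
#' Shannon entropy of the relative frequencies of ordinal (rank-order)
#' patterns of embedded vectors; ties are broken by order of appearance.
#'
#' @param x numeric series.
#' @param order pattern length (pi).
#' @param delay embedding delay (d).
#' @param normalize divide by `log(order!)` so the value lies in `[0, 1]`.
#' @return entropy (nats if `normalize = FALSE`).
#' @export
permutation_entropy <- function(x, order = 3, delay = 2, normalize = TRUE) {
  if (length(x) < (order - 1) * delay + 2)
    stop_ehg("series too short for permutation entropy")
  pat <- ordinal_patterns(as.numeric(x), order, delay)
  p <- tabulate(pat, nbins = factorial(order))
  p <- p[p > 0] / length(pat)
  h <- -sum(p * log(p))
  if (normalize) h / log(factorial(order)) else h
}

#' Dispersion entropy
#'
#' Samples are mapped to `c` discrete classes by linear min-max binning,
#' embedded with dimension `m` (delay 1), and the Shannon entropy of the
#' dispersion-pattern frequencies is normalized by `log(c^m)`.  A
#' zero-range window has a single class and a single pattern and returns 0.
#'
#' @param x numeric series of length >= `m + 1`.
#' @param m embedding dimension.
#' @param c number of classes.
#' @return normalized entropy in `[0, 1]`.
#' @export
dispersion_entropy <- function(x, m = 2, c = 3) {
  if (length(x) < m + 1) stop_ehg("series too short for dispersion entropy")
  x <- as.numeric(x)
  rng <- max(x) - min(x)
  if (rng == 0) return(0)
  cls <- pmin(floor((x - min(x)) / rng * c) + 1, c)
  n_vec <- length(x) - m + 1
  id <- numeric(n_vec)
  for (k in 0:(m - 1)) id <- id * c + (cls[(1:n_vec) + k] - 1)
  p <- tabulate(id + 1, nbins = c^m)
  p <- p[p > 0] / n_vec
  -sum(p * log(p)) / log(c^m)
}

#' Bubble entropy
#'
#' Renyi-2 entropy of the distribution of bubble-sort swap counts of
#' embedded vectors, differenced across embedding orders `m + 1` and `m`
#' and normalized: `(H_(m+1) - H_m) / log((m+1)/(m-1))`.  Monotone series
#' give 0 at both orders (all swap counts identical).
#'
#' @param x numeric series of length >= `m + 2`.
#' @param m embedding order (>= 2).
#' @return the normalized entropy difference.
#' @export
bubble_entropy <- function(x, m = 10) {
  if (m < 2) stop_ehg("bubble entropy needs m >= 2")
  if (length(x) < m + 2) stop_ehg("series too short for bubble entropy")
  renyi2 <- function(counts) {
    p <- tabulate(counts + 1L)
    p <- p[p > 0] / sum(p)
    -log(sum(p^2))
  }
  x <- as.numeric(x)
  h_m <- renyi2(swap_counts_cpp(x, as.integer(m)))
  h_m1 <- renyi2(swap_counts_cpp(x, as.integer(m + 1)))
  (h_m1 - h_m) / log((m + 1) / (m - 1))
}

#' Phase entropy
#'
#' Entropy of the angular distribution of the second-order difference plot:
#' points `(x[i+1] - x[i], x[i+2] - x[i+1])` are binned into `k` equal
#' angular sectors starting at angle 0 (points at the origin are dropped),
#' and the Shannon entropy of the sector occupancies is normalized by
#' `log(k)` to `[0, 1]`.
#'
#' @param x numeric series of length >= 4.
#' @param k even number of sectors (>= 2).
#' @return normalized entropy in `[0, 1]`.
#' @export
phase_entropy <- function(x, k) {
  if (length(x) < 4) stop_ehg("series too short for phase entropy")
  if (k < 2 || k %% 2 != 0) stop_ehg("k must be even and >= 2")
  d <- diff(as.numeric(x))
  X <- d[-length(d)]
  Y <- d[-1]
  keep <- !(X == 0 & Y == 0)
  if (!any(keep)) stop_ehg("degenerate signal: all difference points at origin")
  ang <- atan2(Y[keep], X[keep]) %% (2 * pi)
  sector <- pmin(floor(ang / (2 * pi / k)) + 1, k)
  p <- tabulate(sector, nbins = k)
  p <- p[p > 0] / sum(p)
  -sum(p * log(p)) / log(k)
}

#' Phase entropy profile over sector counts
#'
#' Evaluates [phase_entropy()] for each `k` in `ks` and returns the twelve
#' (by default) values as named features `PhEn_k2 ... PhEn_k24`, each used
#' as an individual characteristic downstream.
#'
#' @param x numeric series.
#' @param ks distinct even sector counts.
#' @return named numeric vector, one value in `[0, 1]` per `k`.
#' @export
phen_profile <- function(x, ks = seq(2, 24, by = 2)) {
  if (anyDuplicated(ks)) stop_ehg("duplicate k in ks")
  out <- vapply(ks, function(k) phase_entropy(x, k), 0)
  names(out) <- paste0("PhEn_k", ks)
  out
}
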