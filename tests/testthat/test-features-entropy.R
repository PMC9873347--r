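test_that("trivial entropy identities hold exactly", {
  expect_equal(as.numeric(sample_entropy(rep(3, 100))), 0)
  expect_equal(as.numeric(sample_entropy(rep(c(1, 2, 3), 50))), 0)
  expect_equal(as.numeric(fuzzy_entropy(rep(2, 60), variant = "local")), 0)
  expect_equal(as.numeric(fuzzy_entropy(rep(2, 60), variant = "global")), 0)
  expect_equal(permutation_entropy(seq_len(100)), 0)
  expect_equal(bubble_entropy(seq_len(100), 10), 0)
  expect_equal(bubble_entropy(rev(seq_len(100)), 10), 0)
  expect_equal(dispersion_entropy(rep(1, 50)), 0)
  # convex increasing series: all difference-plot points in one sector
  expect_equal(phase_entropy(exp(seq(0, 3, length.out = 60)), 4), 0)
})

test_that("hand-computed examples are reproduced", {
  # 4 ascents, 2 descents among the 6 ordinal pairs of this series
  x <- c(4, 7, 9, 10, 6, 11, 3)
  expect_equal(permutation_entropy(x, order = 2, delay = 1, normalize = FALSE),
               -(4 / 6) * log(4 / 6) - (2 / 6) * log(2 / 6),
               tolerance = 1e-4)
  # linear ramp, m = 2, c = 3: only the five monotone dispersion patterns
  ramp <- seq_len(300)
  expect_equal(dispersion_entropy(ramp, 2, 3), oracle_dispen(ramp, 2, 3),
               tolerance = 1e-12)
  cls <- pmin(floor((ramp - 1) / 299 * 3) + 1, 3)
  pats <- unique(paste(cls[-length(cls)], cls[-1]))
  expect_setequal(pats, c("1 1", "1 2", "2 2", "2 3", "3 3"))
  # first differences cycling (+,+,-,-) occupy the four quadrants equally
  d <- c(rep(c(1, 1, -1, -1), 10), 1)
  expect_equal(phase_entropy(cumsum(c(0, d)), 4), 1)
})

test_that("white-noise windows approach maximal normalized entropies", {
  set.seed(31); w <- rnorm(2400)
  expect_gte(permutation_entropy(w), 0.99)
  expect_gte(dispersion_entropy(w * 0 + runif(2400)), 0.97)
})

test_that("entropy estimators match naive oracles on 50 seeded series", {
  for (s in 1:50) {
    set.seed(1000 + s)
    # mixture of scales/smoothness so tolerances and recurrences vary;
    # amplitude ~0.05 keeps the absolute-tolerance FuzzEn non-degenerate
    x <- if (s %% 2 == 0) 0.05 * rnorm(300)
         else 0.05 * bandpass(zscore(rnorm(1500)), ehg_band("F1"), 20)[301:600]
    expect_equal(as.numeric(sample_entropy(x)), oracle_sampen(x),
                 tolerance = 1e-10, label = sprintf("SampEn s=%d", s))
    expect_equal(as.numeric(fuzzy_entropy(x, variant = "local")),
                 oracle_fuzzen(x, variant = "local"),
                 tolerance = 1e-10, label = sprintf("FuzzEnLoc s=%d", s))
    expect_equal(as.numeric(fuzzy_entropy(x, variant = "global")),
                 oracle_fuzzen(x, variant = "global"),
                 tolerance = 1e-10, label = sprintf("FuzzEnGlob s=%d", s))
    expect_equal(permutation_entropy(x), oracle_peren(x),
                 tolerance = 1e-10, label = sprintf("PerEn s=%d", s))
    expect_equal(dispersion_entropy(x), oracle_dispen(x),
                 tolerance = 1e-10, label = sprintf("DispEn s=%d", s))
    expect_equal(bubble_entropy(x, 10), oracle_ben(x, 10),
                 tolerance = 1e-10, label = sprintf("bEn s=%d", s))
    expect_equal(phase_entropy(x, 8), oracle_phen(x, 8),
                 tolerance = 1e-10, label = sprintf("PhEn s=%d", s))
  }
})

test_that("local and global fuzzy variants differ on trending series", {
  set.seed(77)
  x <- 0.03 * rnorm(150) + seq(0, 0.5, length.out = 150)
  loc <- fuzzy_entropy(x, variant = "local")
  glo <- fuzzy_entropy(x, variant = "global")
  expect_gt(abs(loc - glo), 1e-3)
  expect_equal(as.numeric(loc), oracle_fuzzen(x, variant = "local"),
               tolerance = 1e-10)
  expect_equal(as.numeric(glo), oracle_fuzzen(x, variant = "global"),
               tolerance = 1e-10)
})

test_that("entropies are invariant to positive affine rescaling except FuzzEn", {
  for (s in 1:5) {
    set.seed(400 + s)
    x <- rnorm(300)
    y <- 1.7 * x + 0.4
    expect_equal(as.numeric(sample_entropy(y)), as.numeric(sample_entropy(x)),
                 tolerance = 1e-8)
    expect_equal(permutation_entropy(y), permutation_entropy(x),
                 tolerance = 1e-12)
    expect_equal(dispersion_entropy(y), dispersion_entropy(x),
                 tolerance = 1e-12)
    expect_equal(bubble_entropy(y, 10), bubble_entropy(x, 10),
                 tolerance = 1e-12)
    expect_equal(phase_entropy(y, 8), phase_entropy(x, 8), tolerance = 1e-12)
    expect_gt(abs(fuzzy_entropy(0.02 * x, variant = "local") -
                  fuzzy_entropy(0.08 * x, variant = "local")), 1e-4)
  }
})

test_that("normalized entropies stay in [0, 1] and counts are sane", {
  for (s in 1:10) {
    set.seed(500 + s)
    x <- rnorm(300) * runif(1, 0.01, 2)
    expect_gte(permutation_entropy(x), 0); expect_lte(permutation_entropy(x), 1)
    expect_gte(dispersion_entropy(x), 0); expect_lte(dispersion_entropy(x), 1)
    ph <- phen_profile(x)
    expect_length(ph, 12)
    expect_identical(names(ph), paste0("PhEn_k", seq(2, 24, 2)))
    expect_true(all(ph >= 0 & ph <= 1))
    expect_gte(as.numeric(sample_entropy(x)), 0)
    expect_gte(bubble_entropy(x, 10), -1e-10)
  }
  expect_error(phen_profile(rnorm(100), ks = c(2, 4, 4)), "duplicate")
  expect_error(phase_entropy(rnorm(100), 5), "even")
  expect_error(permutation_entropy(rnorm(5)), "short")
  expect_error(bubble_entropy(rnorm(100), 1), "m >= 2")
  expect_error(phase_entropy(rep(1, 100), 4), "degenerate")
})

test_that("regular bursts are less entropic than irregular ones at matched RMS", {
  # single-burst records; the window centred on the annotated burst carries
  # the carrier, so the regularity knob is what differs between the pair
  # (SampEn uses a relative tolerance, so RMS matching is inherent)
  eval_pair <- function(s) {
    cfg <- sim_config(n_P = 1, n_T = 1, duration_s = 600, seed = s)
    mk <- function(lab, regl) generate_record(
      class_profile(lab, burst_rate = 3, burst_duration_s = c(240, 0),
                    burst_gain = 8, regularity = regl,
                    ecg_interference_gain = 0), cfg, 1)
    reg <- mk("P", 1); irr <- mk("T", 0)
    if (nrow(reg$annotations) != 1 || nrow(irr$annotations) != 1) return(NULL)
    win_of <- function(r) {
      mid <- r$annotations$midpoint_s[1]
      wins <- segment_windows(bandpass(zscore(r$channels$S1), ehg_band("F1"), 20), 20)
      wins[[max(1, min(length(wins), round((mid * 20 - 1200) / 1200) + 1))]]
    }
    c(sample_entropy(win_of(reg)), sample_entropy(win_of(irr)))
  }
  hits <- 0; n <- 0; s <- 0
  while (n < 20 && s < 200) {
    s <- s + 1
    v <- eval_pair(700 + s)
    if (is.null(v)) next
    n <- n + 1
    if (v[1] < v[2]) hits <- hits + 1
  }
  expect_equal(n, 20)
  expect_gte(hits, 19)
})
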