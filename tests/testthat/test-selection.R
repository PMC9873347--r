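# feature tables with a known informative structure: noise features named
# after the canonical registry, a subset carrying the class signal
make_selection_data <- function(n = 200, informative = "RMS", shift = 1,
                                seed = 1) {
  set.seed(seed)
  y <- rep(c("P", "T"), each = n / 2)
  X <- as.data.frame(matrix(rnorm(n * 10), n, 10))
  colnames(X) <- feature_names()[1:10]
  for (f in informative)
    X[[f]] <- X[[f]] * 0.1 + ifelse(y == "P", shift, 0)
  list(X = X, y = y)
}

test_that("F-test ranking puts the informative feature first", {
  d <- make_selection_data(informative = "RMS", shift = 1, seed = 2)
  r <- rank_ftest(d$X, d$y)
  expect_identical(r[1], "RMS")
  expect_lte(length(r), 10)
  # fewer features than requested: all returned
  expect_length(rank_ftest(d$X[, 1:5], d$y), 5)
  # identical features tie and keep name order
  X2 <- d$X; X2$Amp <- X2$RMS
  r2 <- rank_ftest(X2, d$y)
  expect_identical(r2[1:2], c("Amp", "RMS"))
  # zero within-class variance with distinct means gets an infinite F
  # statistic and ranks first
  X3 <- d$X; X3$ZCR <- ifelse(d$y == "P", 1, 0)
  expect_identical(rank_ftest(X3, d$y)[1], "ZCR")
  expect_true("ZCR" %in% rank_chi2(X3, d$y)[1:2])
})

test_that("chi-square ranking detects label association after binning", {
  d <- make_selection_data(informative = "MedFreq", shift = 1.5, seed = 3)
  expect_identical(rank_chi2(d$X, d$y)[1], "MedFreq")
  # constant feature scores 0 and ranks last
  X2 <- d$X; X2$Amp <- 1
  r <- rank_chi2(X2, d$y)
  st <- attr(rank_chi2(X2, d$y, top = 10), "statistic")
  expect_false("Amp" %in% r[1:9])
  # perfectly separating binary feature on a 10+10 sample: chi2 = 20
  Xb <- data.frame(RMS = rep(c(0, 1), each = 10))
  yb <- rep(c("T", "P"), each = 10)
  expect_equal(unname(attr(rank_chi2(Xb, yb), "statistic")["RMS"]), 20)
})

test_that("regression selection keeps small-p features ascending", {
  d <- make_selection_data(informative = "SampEn", shift = 1, seed = 4)
  r <- select_regression(d$X, d$y)
  expect_true("SampEn" %in% r)
  expect_false(attr(r, "fallback"))
  p <- attr(r, "p_value")
  expect_true(all(diff(p) >= 0) && all(p < 0.05))
  # p >= n triggers the univariate fallback
  d2 <- make_selection_data(n = 8, seed = 5)
  r2 <- suppressWarnings(select_regression(d2$X, d2$y))
  expect_true(attr(r2, "fallback"))
})

test_that("all-noise regression selects about alpha * p features", {
  counts <- integer(40)
  for (s in 1:40) {
    set.seed(7000 + s)
    X <- as.data.frame(matrix(rnorm(200 * 10), 200, 10))
    colnames(X) <- feature_names()[1:10]
    y <- rep(c("P", "T"), each = 100)
    counts[s] <- length(select_regression(X, y))
  }
  # binomial(10, 0.05): mean 0.5; the mean of 40 runs stays well below 1.5
  expect_lt(mean(counts), 1.5)
  expect_gte(mean(counts), 0)
})

test_that("sequential forward selection finds separating features and stops", {
  d <- make_selection_data(informative = "DispEn", shift = 4, seed = 6)
  s <- sequential_forward_selection(d$X, d$y, seed = 1)
  expect_identical(s[1], "DispEn")
  expect_lte(length(s), 3)
  # pure noise: stops almost immediately
  dn <- make_selection_data(informative = character(0), seed = 7)
  sn <- sequential_forward_selection(dn$X, dn$y, seed = 1)
  expect_lte(length(sn), 2)
  # deterministic under a fixed seed
  expect_identical(s, sequential_forward_selection(d$X, d$y, seed = 1))
})

test_that("the combination rule merges, pads and truncates to 7-13", {
  fn <- feature_names()
  ftest <- c("a1" = fn[1], fn[2:10])  # names irrelevant, values canonical
  out <- combine_selections(ftest = c(fn[1], fn[4:12]),
                            chi2 = c(fn[3], fn[13:21]),
                            regression = c(fn[2], fn[3]),
                            seqsel = c(fn[1], fn[2], fn[30]))
  # seqsel/ftest overlap fn[1], seqsel/regression overlap fn[2],
  # regression/chi2 overlap fn[3]
  expect_true(all(fn[c(1, 2, 3)] %in% out))
  expect_gte(length(out), 7); expect_lte(length(out), 13)
  prov <- attr(out, "provenance")
  expect_true(all(prov$padded[!prov$feature %in% fn[1:3]] |
                  prov$from_ftest[!prov$feature %in% fn[1:3]] |
                  prov$from_chi2[!prov$feature %in% fn[1:3]]))
  # four disjoint lists: pure padding
  out2 <- combine_selections(fn[1:3], fn[4:6], fn[7:9], fn[10:12])
  expect_length(out2, 7)
  expect_true(all(attr(out2, "provenance")$padded))
  # an oversized rule output is truncated to 13
  out3 <- combine_selections(ftest = fn[1:10], chi2 = fn[6:15],
                             regression = fn[1:10], seqsel = fn[6:15])
  expect_lte(length(out3), 13)
  expect_error(combine_selections(character(0), character(0),
                                  character(0), character(0)), "empty")
})

test_that("select_features is deterministic and respects the size range", {
  d <- make_selection_data(informative = c("RMS", "SampEn"), shift = 0.8,
                           seed = 8)
  s1 <- select_features(d$X, d$y, seed = 5)
  s2 <- select_features(d$X, d$y, seed = 5)
  expect_identical(s1$final_features, s2$final_features)
  expect_gte(length(s1$final_features), 7)
  expect_lte(length(s1$final_features), 13)
  expect_true(all(s1$final_features %in% feature_names()))
  expect_true(all(c("RMS", "SampEn") %in% s1$final_features))
})

test_that("informative trio is recovered across seeded replicates", {
  hits <- 0
  for (s in 1:20) {
    d <- make_selection_data(informative = c("RMS", "ZCR", "PerEn"),
                             shift = 1.2, seed = 900 + s)
    sel <- select_features(d$X, d$y, seed = s)
    if (all(c("RMS", "ZCR", "PerEn") %in% sel$final_features)) hits <- hits + 1
  }
  expect_gte(hits, 18)
})
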