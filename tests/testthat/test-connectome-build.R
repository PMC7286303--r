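# Structural/functional connectome construction: hand-checked weights,
# support identity, strict thresholding, time-series preprocessing and
# partial-correlation estimation.

make_atlas4 <- function() {
  atl <- generate_atlas(4, 3, seed = 1)
  atl$volume <- c(10, 10, 20, 5)  # known volumes for hand checks
  atl
}

test_that("structural weights reproduce hand-computed FA and FD values", {
  atl <- make_atlas4()
  st <- data.frame(
    region_a = atl$name[c(1, 2, 1, 3)],
    region_b = atl$name[c(2, 1, 3, 1)],
    length_mm = c(2, 4, 5, 5),
    mean_fa = c(0.4, 0.6, 0.5, 0.7)
  )
  cs <- build_structural(st, atl)
  # (a, b) and (b, a) are one connection: mean FA = 0.5
  expect_equal(cs$fa_w$weights[1, 2], 0.5)
  # FD with lengths 2 and 4, volumes 10 + 10: (1/2 + 1/4) / 20
  expect_equal(cs$fd_w$weights[1, 2], 0.0375)
  # pair (1, 3): (1/5 + 1/5) / (10 + 20)
  expect_equal(cs$fd_w$weights[1, 3], 0.4 / 30)
  expect_equal(cs$fa_w$weights[1, 3], 0.6)
  expect_equal(cs$struct_binary$weights[1, 2], 1)
  # alternative normalization by the mean of the volumes
  cs2 <- build_structural(st, atl, volume_normalization = "mean")
  expect_equal(cs2$fd_w$weights[1, 2], 0.075)
})

test_that("self-loops are ignored, unknown labels and bad values error", {
  atl <- make_atlas4()
  st <- data.frame(region_a = atl$name[1], region_b = atl$name[1],
                   length_mm = 3, mean_fa = 0.5)
  cs <- build_structural(st, atl)
  expect_equal(sum(cs$struct_binary$weights), 0)
  expect_error(
    build_structural(data.frame(region_a = "nope", region_b = atl$name[2],
                                length_mm = 3, mean_fa = 0.5), atl),
    "unknown region")
  expect_error(
    build_structural(data.frame(region_a = atl$name[1],
                                region_b = atl$name[2],
                                length_mm = -1, mean_fa = 0.5), atl),
    "lengths")
})

test_that("empty streamline table gives all-zero connectomes with density 0", {
  atl <- make_atlas4()
  cs <- build_structural(atl[0, c(1, 2)] |>
                           (\(x) data.frame(region_a = character(0),
                                            region_b = character(0),
                                            length_mm = numeric(0),
                                            mean_fa = numeric(0)))(), atl)
  expect_equal(connectome_density(cs$fa_w), 0)
  expect_equal(connectome_density(cs$struct_binary), 0)
})

test_that("the three structural connectomes share one support set", {
  atl <- generate_atlas(15, 10, seed = 3)
  coh <- generate_cohort(2, c(6, 9), dropout_prob = 0, seed = 1)
  st <- generate_streamline_table(atl, coh[1, ], effect_spec(), seed = 4)
  cs <- build_structural(st, atl)
  supp <- cs$struct_binary$weights != 0
  expect_identical(cs$fa_w$weights != 0, supp)
  expect_identical(cs$fd_w$weights != 0, supp)
  # FA bounds wherever an edge exists
  expect_true(all(cs$fa_w$weights[supp] > 0 & cs$fa_w$weights[supp] <= 1))
})

test_that("region relabeling permutes every structural output identically", {
  atl <- generate_atlas(8, 5, seed = 11)
  coh <- generate_cohort(1, c(6), dropout_prob = 0, seed = 1)
  st <- generate_streamline_table(atl, coh[1, ], effect_spec(), seed = 2)
  cs <- build_structural(st, atl)
  perm <- sample(8)
  atl_p <- atl[perm, ]
  cs_p <- build_structural(st, atl_p)
  for (k in names(cs))
    expect_equal(cs_p[[k]]$weights,
                 cs[[k]]$weights[perm, perm])
})

test_that("density arithmetic matches the edge-count formula", {
  # 76 nodes with 1773 edges: 100 * 1773 / 2850
  n <- 76
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  w[sample(ut, 1773)] <- 1
  w <- pmax(w, t(w))
  x <- connectome(w, sprintf("r%02d", 1:n), "struct_binary")
  expect_equal(connectome_density(x), 100 * 1773 / 2850, tolerance = 1e-12)
})

test_that("filter_edges applies a strict threshold and keeps the kind", {
  w <- sym_from_edges(3, rbind(c(1, 2), c(1, 3), c(2, 3)),
                      c(0.2, 0.3, 0.31))
  x <- connectome(w, letters[1:3], "fa_w")
  f <- filter_edges(x, 0.3)
  expect_equal(sum(f$weights[upper.tri(f$weights)] > 0), 1)
  expect_equal(f$weights[2, 3], 0.31)
  expect_identical(f$kind, "fa_w")
  # threshold 0 keeps the support of a non-negative graph
  expect_identical(filter_edges(x, 0)$weights != 0, x$weights != 0)
})

# ---- time-series preprocessing ----

test_that("constant series come out all-zero", {
  ts <- rbind(rep(3.5, 100), rnorm(100))
  out <- preprocess_timeseries(ts, tr = 2)
  expect_equal(out[1, ], rep(0, 100))
  expect_gt(sd(out[2, ]), 0)
})

test_that("out-of-band sinusoid is suppressed (spectral power check)", {
  tr <- 2
  n <- 600
  tt <- (seq_len(n) - 1) * tr
  x <- rbind(sin(2 * pi * 0.2 * tt))   # 0.2 Hz, above the 0.1 Hz band edge
  out <- preprocess_timeseries(x, band = c(0.01, 0.1), tr = tr)
  pow <- function(v) sum(Mod(fft(v))^2)
  expect_lt(pow(out[1, ]), 0.01 * pow(as.numeric(scale(x[1, ]))))
  # in-band sinusoid passes essentially intact
  xin <- rbind(sin(2 * pi * 0.05 * tt))
  outin <- preprocess_timeseries(xin, band = c(0.01, 0.1), tr = tr)
  expect_gt(pow(outin[1, ]), 0.8 * pow(as.numeric(scale(xin[1, ]))))
})

test_that("output is orthogonal to the nuisance regressors", {
  set.seed(12)
  n <- 300
  nuis <- cbind(rnorm(n), cumsum(rnorm(n, 0, 0.1)))
  ts <- rbind(nuis[, 1] + rnorm(n, 0, 0.1), rnorm(n))
  out <- preprocess_timeseries(ts, nuis, tr = 2)
  expect_lt(abs(sum(out[1, ] * nuis[, 1])), 1e-8)
  expect_lt(abs(sum(out[2, ] * nuis[, 2])), 1e-8)
})

test_that("preprocessing is shape-idempotent on its own output", {
  set.seed(13)
  ts <- matrix(rnorm(4 * 400), 4, 400)
  nuis <- matrix(rnorm(400 * 3), 400, 3)
  once <- preprocess_timeseries(ts, nuis, tr = 2)
  twice <- preprocess_timeseries(once, nuis, tr = 2)
  # a recursive band-pass re-applied keeps shaving the band edges, so
  # the signal shape is preserved (high correlation) but not the exact
  # values; see the methods vignette
  for (r in 1:4)
    expect_gt(cor(once[r, ], twice[r, ]), 0.97)
})

test_that("band above Nyquist is rejected", {
  expect_error(preprocess_timeseries(matrix(rnorm(300), 1), tr = 2,
                                     band = c(0.01, 0.3)),
               "Nyquist")
})

# ---- functional connectome ----

test_that("independent regions give near-half density and small z", {
  set.seed(21)
  ts <- matrix(rnorm(10 * 600), 10, 600,
               dimnames = list(sprintf("g%02d", 1:10), NULL))
  fc <- build_functional(ts)
  d <- connectome_density(fc$func_w)
  expect_gt(d, 30); expect_lt(d, 70)      # sign of noise
  expect_lt(max(fc$func_w$weights), 0.25) # all |z| small at n = 600
  # binary functional connectome marks exactly the z > 0 support
  expect_identical(fc$func_binary$weights, (fc$func_w$weights > 0) * 1)
})

test_that("a planted partial correlation of 0.5 is recovered near atanh(0.5)", {
  set.seed(22)
  p <- 8
  P <- diag(p)
  P[1, 2] <- P[2, 1] <- -0.5   # unit-diagonal precision: pcor(1,2) = 0.5
  Sigma <- solve(P)
  zs <- replicate(40, {
    X <- crossprod(chol(Sigma), matrix(rnorm(p * 600), p, 600))
    rownames(X) <- sprintf("g%d", 1:p)
    build_functional(X)$func_w$weights[1, 2]
  })
  expect_equal(mean(zs), atanh(0.5), tolerance = 0.05)
})

test_that("negative partial correlations are excluded exactly", {
  set.seed(23)
  p <- 6
  P <- diag(p)
  P[1, 2] <- P[2, 1] <- 0.4    # positive precision entry => negative pcor
  X <- crossprod(chol(solve(P)), matrix(rnorm(p * 500), p, 500))
  rownames(X) <- sprintf("g%d", 1:p)
  fc <- build_functional(X)
  expect_identical(fc$func_w$weights[1, 2], 0)
  expect_identical(fc$func_binary$weights[1, 2], 0)
  expect_true(all(fc$func_w$weights >= 0))
})

test_that("singular covariance errors with a shrinkage hint; shrinkage rescues", {
  ts <- matrix(rnorm(10 * 8), 10, 8)   # volumes < regions
  expect_error(build_functional(ts), "shrinkage")
  fc <- build_functional(ts, shrinkage = 0.5)
  expect_s3_class(fc$func_w, "connectome")
})

test_that("partial-correlation RMSE shrinks as volumes grow", {
  set.seed(24)
  p <- 10
  P <- diag(p)
  P[1, 2] <- P[2, 1] <- -0.3
  P[3, 4] <- P[4, 3] <- -0.2
  Sigma <- solve(P)
  d <- sqrt(diag(solve(Sigma)))
  truth <- -solve(Sigma) / tcrossprod(d); diag(truth) <- 0
  rmse <- function(nvol) {
    errs <- replicate(25, {
      X <- crossprod(chol(Sigma), matrix(rnorm(p * nvol), p, nvol))
      S <- cov(t(X)); Pd <- solve(S)
      dd <- sqrt(diag(Pd))
      est <- -Pd / tcrossprod(dd); diag(est) <- 0
      sqrt(mean((est - truth)[upper.tri(truth)]^2))
    })
    mean(errs)
  }
  expect_lt(rmse(1200), rmse(300))
})
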