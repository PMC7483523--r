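test_that("binned_trace validates its invariants", {
  expect_s3_class(binned_trace(0:3, c(0, 1, 0, 2), 1e-3), "binned_trace")
  expect_error(binned_trace(0:3, 0:2, 1e-3), "same length")
  expect_error(binned_trace(c(-1, 0), c(0, 0), 1e-3), "non-negative")
  expect_error(binned_trace(c(0.5, 1), c(0, 0), 1e-3), "integer")
  expect_error(binned_trace(0:1, 0:1, 0), "positive")
})

test_that("rebin sums consecutive bins, drops the remainder, conserves counts", {
  tr <- binned_trace(donor = c(1, 2, 3, 4), acceptor = c(4, 3, 2, 1),
                     bin_width = 1e-3)
  expect_identical(rebin(tr, 1)$donor, tr$donor)
  r2 <- rebin(tr, 2)
  expect_identical(r2$donor, c(3L, 7L))
  expect_identical(r2$acceptor, c(7L, 3L))
  expect_equal(r2$bin_width, 2e-3)
  # remainder dropped, conservation up to the dropped tail
  tr5 <- binned_trace(donor = c(1, 2, 3, 4, 9), acceptor = rep(0L, 5),
                      bin_width = 1e-3)
  r <- rebin(tr5, 2)
  expect_identical(length(r), 2L)
  expect_equal(sum(r$donor) + 9, sum(tr5$donor))
  expect_error(rebin(tr, 0), "positive integer")
})

test_that("detect_bursts finds maximal above-threshold runs with channel sums", {
  zero <- binned_trace(rep(0L, 50), rep(0L, 50), 1e-3)
  expect_identical(nrow(detect_bursts(zero, 1)), 0L)

  one <- binned_trace(c(0L, 30L, 0L), c(0L, 70L, 0L), 1e-3)
  b <- detect_bursts(one, 50)
  expect_identical(nrow(b), 1L)
  expect_equal(b$e_app, 0.70)
  expect_identical(c(b$start_bin, b$end_bin), c(2L, 2L))

  # runs and sums on a hand-built trace
  d <- c(0L, 5L, 6L, 0L, 0L, 7L, 0L)
  a <- c(0L, 5L, 4L, 0L, 0L, 3L, 0L)
  b <- detect_bursts(binned_trace(d, a, 1e-3), 10)
  expect_identical(b$start_bin, c(2L, 6L))
  expect_identical(b$donor_sum, c(11L, 7L))
  expect_identical(b$acceptor_sum, c(9L, 3L))
})

test_that("raising the threshold never adds burst bins (monotone selection)", {
  set.seed(5)
  d <- rpois(3000, 0.6) + rpois(3000, 0.02) * 30L
  a <- rpois(3000, 0.6)
  tr <- binned_trace(d, a, 1e-3)
  burst_bins <- function(th) {
    b <- detect_bursts(tr, th)
    if (nrow(b) == 0L) return(integer())
    unlist(Map(seq, b$start_bin, b$end_bin))
  }
  for (th in c(2, 5, 10, 20)) {
    expect_true(all(burst_bins(th + 1) %in% burst_bins(th)))
  }
  # burst bins + background bins partition the trace
  b <- detect_bursts(tr, 5)
  bg <- setdiff(seq_len(length(tr)), burst_bins(5))
  expect_identical(sort(c(burst_bins(5), bg)), seq_len(length(tr)))
})

test_that("estimate_background averages over non-burst bins", {
  tr <- binned_trace(rep(2L, 100), rep(0L, 100), 1e-3)
  none <- detect_bursts(tr, 100)
  bg <- estimate_background(tr, none)
  expect_equal(bg$donor_rate, 2)
  expect_equal(bg$acceptor_rate, 0)

  all_burst <- detect_bursts(tr, 0)
  expect_error(estimate_background(tr, all_burst), "no background")

  # Poisson consistency: rate recovered within 3 standard errors
  set.seed(11)
  lam <- 0.05
  n <- 2e5
  tr <- binned_trace(rpois(n, lam), rpois(n, lam), 1e-3)
  bg <- estimate_background(tr, detect_bursts(tr, 1e6))
  expect_lt(abs(bg$donor_rate - lam), 3 * sqrt(lam / n))
})

test_that("poisson_masked_trace keeps selected bins verbatim and is seeded", {
  set.seed(3)
  tr <- binned_trace(rpois(5000, 1), rpois(5000, 1), 1e-3)
  bg <- background_model(1, 1)

  all_win <- data.frame(start_bin = 1L, end_bin = length(tr))
  expect_identical(poisson_masked_trace(tr, all_win, bg, seed = 1)$donor,
                   tr$donor)

  none <- data.frame(start_bin = integer(), end_bin = integer())
  zero <- poisson_masked_trace(tr, none, background_model(0, 0), seed = 1)
  expect_true(all(zero$donor == 0L) && all(zero$acceptor == 0L))

  # replacement noise has the requested Poisson mean
  m1 <- poisson_masked_trace(tr, none, bg, seed = 7)
  expect_lt(abs(mean(m1$donor) - 1), 3 * sqrt(1 / length(tr)))

  # deterministic under the seed, kept windows bit-exact
  win <- data.frame(start_bin = c(10L, 100L), end_bin = c(20L, 150L))
  a <- poisson_masked_trace(tr, win, bg, seed = 42)
  b <- poisson_masked_trace(tr, win, bg, seed = 42)
  expect_identical(a$donor, b$donor)
  expect_identical(a$acceptor[100:150], tr$acceptor[100:150])

  overlapping <- data.frame(start_bin = c(10L, 15L), end_bin = c(20L, 25L))
  expect_error(poisson_masked_trace(tr, overlapping, bg, seed = 1), "overlap")
})

test_that("map_windows converts burst intervals across binnings and merges", {
  b <- data.frame(start_bin = c(2L, 4L), end_bin = c(2L, 5L))
  w <- map_windows(b, coarse_bin_width = 1e-3, fine_bin_width = 1e-4,
                   n_fine = 100)
  # bin 2 covers (1 ms, 2 ms] -> fine bins 11..20; bins 4..5 -> 31..50
  expect_equal(w$start_bin, c(11, 31))
  expect_equal(w$end_bin, c(20, 50))
  # touching windows merge
  b2 <- data.frame(start_bin = c(1L, 2L), end_bin = c(1L, 3L))
  w2 <- map_windows(b2, 1e-3, 1e-4, 100)
  expect_identical(nrow(w2), 1L)
  expect_equal(c(w2$start_bin, w2$end_bin), c(1, 30))
})

test_that("traces round-trip through the delimited text format", {
  tr <- binned_trace(c(0L, 3L, 1L), c(2L, 0L, 5L), 0.96e-6,
                     direct_acceptor = c(1L, 1L, 0L), origin_time = 2.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, path)
  rt <- read_trace(path)
  expect_identical(rt$donor, tr$donor)
  expect_identical(rt$acceptor, tr$acceptor)
  expect_identical(rt$direct_acceptor, tr$direct_acceptor)
  expect_equal(rt$bin_width, tr$bin_width)
  expect_equal(rt$origin_time, 2.5)
  expect_error(read_trace(file.path(tempdir(), "absent.tsv")), "not found")
})
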