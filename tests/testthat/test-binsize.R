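test_that("cost reduces to mean(k)/delta^2 for ideal Poisson counts", {
  # when var(k) = mean(k) exactly, cost = mean(k)/delta^2, decreasing in delta
  set.seed(1)
  # construct a series whose counts in width-10 bins are a prescribed vector
  k <- c(4, 6, 5, 5, 3, 7, 5, 5)   # var != mean in general; compute both
  times <- unlist(lapply(seq_along(k), function(i)
    sort(runif(k[i], (i - 1) * 10, i * 10 - 1e-9))))
  es <- event_series(times, T = 80)
  kbar <- mean(k); v <- mean((k - kbar)^2)
  expect_equal(binsize_cost(es, 10), (2 * kbar - v) / 100)
})

test_that("trailing partial bin is discarded, not folded into the last bin", {
  # 3 events per unit on [0,10]; with delta = 4 only bins [0,4) and [4,8) count
  times <- seq(0.05, 9.95, length.out = 30)
  es <- event_series(times, T = 10)
  k <- c(sum(times < 4), sum(times >= 4 & times < 8))
  kbar <- mean(k)
  expect_equal(binsize_cost(es, 4), (2 * kbar - mean((k - kbar)^2)) / 16)
})

test_that("homogeneous Poisson series yield a diverging optimal bin size", {
  set.seed(42)
  for (rate in c(0.6, 5)) {
    es <- event_series(sort(runif(rpois(1, rate * 1000), 0, 1000)), T = 1000)
    expect_true(optimal_binsize(es)$diverging)
  }
})

test_that("a sinusoidally modulated rate gives a finite bin size near the oracle", {
  # lambda(t) = 5 (1 + 0.9 sin 2 pi t / 50), T = 5000
  set.seed(7)
  T <- 5000; dtg <- 0.002
  tg <- seq(0, T - dtg, by = dtg)
  lam <- 5 * (1 + 0.9 * sin(2 * pi * tg / 50))
  times <- tg[runif(length(tg)) < lam * dtg]
  res <- optimal_binsize(event_series(times, T = T))
  expect_false(res$diverging)
  # order of the modulation period (50), not of T
  expect_lt(res$delta_star, 50)
  expect_gt(res$delta_star, 0.5)
  # oracle: direct MSE between histogram and the known generating rate
  oracle_mse <- vapply(res$delta_grid, function(d) {
    nb <- floor(T / d)
    if (nb < 2) return(Inf)
    k <- tabulate(floor(times[times < nb * d] / d) + 1L, nbins = nb)
    hist_rate <- rep(k / d, each = round(d / dtg))[seq_len(round(nb * d / dtg))]
    mean((hist_rate - lam[seq_along(hist_rate)])^2)
  }, numeric(1))
  dstar_oracle <- res$delta_grid[which.min(oracle_mse)]
  expect_lt(abs(log(res$delta_star / dstar_oracle)), log(3))
})

test_that("grid argmin matches a 10x finer brute-force argmin", {
  set.seed(3)
  T <- 3000
  tg <- seq(0, T - 0.005, 0.005)
  lam <- 2 * (1 + 0.8 * sin(2 * pi * tg / 80))
  times <- tg[runif(length(tg)) < lam * 0.005]
  es <- event_series(times, T = T)
  coarse <- optimal_binsize(es, n_grid = 100)
  fine <- optimal_binsize(es, n_grid = 1000,
                          delta_range = range(coarse$delta_grid))
  # within one coarse-grid step (log spacing ratio)
  step <- coarse$delta_grid[2] / coarse$delta_grid[1]
  expect_lt(abs(log(coarse$delta_star / fine$delta_star)), 1.5 * log(step))
})

test_that("rescaling time rescales the optimal bin size identically", {
  set.seed(5)
  tg <- seq(0, 2000, 0.01)
  lam <- 1.5 * (1 + 0.9 * sin(2 * pi * tg / 40))
  times <- tg[runif(length(tg)) < lam * 0.01]
  r1 <- optimal_binsize(event_series(times, T = 2000))
  r2 <- optimal_binsize(event_series(times * 7, T = 14000))
  expect_equal(r2$delta_star, 7 * r1$delta_star, tolerance = 1e-10)
  expect_equal(r2$diverging, r1$diverging)
})

test_that("degenerate series are handled explicitly", {
  expect_error(optimal_binsize(event_series(numeric(0), T = 10)), "empty")
  expect_warning(res <- optimal_binsize(event_series(c(1, 2, 3), T = 10)),
                 "fewer than 10")
  expect_true(res$diverging)
  es <- event_series(runif(100, 0, 100), T = 100)
  expect_error(binsize_cost(es, 60), "fewer than 2")
})

test_that("the univariate analytic SN condition has its boundary at 1 - 1/sqrt(2)", {
  expect_false(sn_condition_univariate(0.2))   # 1/0.64 = 1.5625 < 2
  expect_true(sn_condition_univariate(0.5))    # 4 > 2
  # the verdict flips at the boundary (exact boundary itself is below
  # double-precision resolution)
  Rc <- 1 - 1 / sqrt(2)
  expect_false(sn_condition_univariate(Rc - 1e-9))
  expect_true(sn_condition_univariate(Rc + 1e-9))
  expect_error(sn_condition_univariate(1), "\\[0, 1\\)")
})
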