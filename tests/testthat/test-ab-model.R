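# The latent GP allele-balance model: covariance function, Laplace
# approximation, grid-search fitting and posterior prediction.

test_that("covariance function matches its closed form and is symmetric", {
  p <- cov_params(0, 1, 0, 1)
  expect_equal(ab_covariance(5, 5, p), 2)
  expect_equal(ab_covariance(0, 1, p), 2 * exp(-1))
  p2 <- cov_params(-1, 10000, -2, 150)
  withr::with_seed(1, {
    x1 <- runif(50, 0, 1e6); x2 <- runif(50, 0, 1e6)
    expect_equal(ab_covariance(x1, x2, p2), ab_covariance(x2, x1, p2))
    # depends on |x1 - x2| only
    expect_equal(ab_covariance(x1 + 777, x2 + 777, p2),
                 ab_covariance(x1, x2, p2))
  })
  # decays to zero at long range; e^a + e^c at zero
  expect_lt(ab_covariance(0, 1e7, p2), 1e-12)
  expect_equal(ab_covariance(3, 3, p2), exp(-1) + exp(-2))
  expect_error(cov_params(NA, 1, 0, 1), "finite")
})

test_that("cov_params orders components so d <= b", {
  p <- cov_params(a = -2, b = 100, c = 0, d = 5000)
  expect_equal(p$b, 5000); expect_equal(p$a, 0)
  expect_equal(p$d, 100); expect_equal(p$c, -2)
})

test_that("Laplace block matches an exact 1-D Laplace and finds the symmetric mode", {
  # balanced single site: likelihood and prior both maximized at B = 0
  p1 <- cov_params(0, 1000, 0, 100)
  f0 <- laplace_block(data.frame(pos = 1, allele1_reads = 5, depth = 10), p1)
  expect_equal(f0$b_hat, 0, tolerance = 1e-8)
  # evidence equals the independently optimized 1-D Laplace (k(0) = 1)
  ph <- cov_params(log(0.5), 1000, log(0.5), 100)
  for (case in list(c(9, 10), c(27, 30), c(3, 25))) {
    fit <- laplace_block(data.frame(pos = 1, allele1_reads = case[1],
                                    depth = case[2]), ph, jitter = 0)
    expect_equal(fit$log_marginal, oracle_laplace_1d(case[1], case[2], 1),
                 tolerance = 1e-5)
  }
  # w_diag is the binomial information at the mode, nonnegative
  fit <- laplace_block(data.frame(pos = c(1, 400), allele1_reads = c(8, 2),
                                  depth = c(10, 12)), ph)
  expect_true(all(fit$w_diag >= 0))
  expect_equal(fit$w_diag,
               fit$b_hat |> plogis() |> (\(p) c(10, 12) * p * (1 - p))())
})

test_that("Laplace evidence approximates the true integral for small blocks", {
  # blocks of 1-2 hSNPs at study-like depth: |Laplace - integral| <= 1e-2
  truth <- default_truth()
  withr::with_seed(12, {
    for (n in 1:2) {
      for (rep in 1:4) {
        pos <- cumsum(c(1000, round(rexp(n - 1, 1 / 1500)) + 1))[1:n]
        B <- simulate_ab(pos, truth)
        d <- pmax(1, rpois(n, 30))
        y <- rbinom(n, d, plogis(B))
        blk <- data.frame(pos = pos, allele1_reads = y, depth = d)
        lz <- laplace_block(blk, truth)$log_marginal
        oz <- oracle_logz_grid(pos, y, d, truth)
        expect_lt(abs(lz - oz), 1e-2)
      }
    }
  })
})

test_that("chromosomes split into blocks of 100 with a trailing remainder", {
  idx <- abcall:::block_indices(150, 100)
  expect_length(idx, 2)
  expect_length(idx[[1]], 100)
  expect_length(idx[[2]], 50)
  expect_equal(unlist(idx, use.names = FALSE), 1:150)
  expect_length(abcall:::block_indices(100, 100), 1)
})

test_that("grid fit recovers the long length scale and ignores row order", {
  hs <- sim_hsnps(1500, seed = 21)
  grid <- ab_param_grid(a = c(-2, -1, 0), b = c(2000, 10000, 50000),
                        c = c(-2, -1), d = c(50, 150))
  fit <- fit_ab_params(hs, grid = grid)
  expect_s3_class(fit, "ab_fit")
  expect_lte(fit$params$b / 10000, 2)
  expect_gte(fit$params$b / 10000, 0.5)
  # likelihood at selected point >= likelihood at the true parameters
  ll_true <- fit$grid$log_lik[fit$grid$a == -1 & fit$grid$b == 10000 &
                              fit$grid$c == -2 & fit$grid$d == 150]
  expect_gte(max(fit$grid$log_lik), ll_true)
  # shuffling input rows (re-sorted internally) leaves the answer unchanged
  fit2 <- fit_ab_params(hs[sample.int(nrow(hs)), ], grid = grid)
  expect_equal(glance(fit2), glance(fit))
  # tidy/glance expose the full grid and the winner
  expect_equal(nrow(tidy(fit)), nrow(grid))
  expect_equal(tidy(fit)$log_lik[1], max(fit$grid$log_lik))
})

test_that("prediction returns the prior far from data and tracks dense data", {
  truth <- default_truth()
  hs1 <- tibble::tibble(pos = 5000, allele1_reads = 9000, depth = 10000)
  # co-located, very deep hSNP at VAF 0.9 pins the posterior
  pr <- predict_ab(5000, hs1, truth)
  expect_equal(pr$ab, 0.9, tolerance = 0.01)
  expect_false(pr$ab_uninformed)
  # far outside the window: GP prior, flagged uninformed
  far <- predict_ab(5e7, hs1, truth)
  expect_equal(far$mu, 0)
  expect_equal(far$sigma2, exp(-1) + exp(-2))
  expect_true(far$ab_uninformed)
})

test_that("posterior variance never exceeds the prior and shrinks with data", {
  truth <- default_truth()
  prior_var <- exp(truth$a) + exp(truth$c)
  hs <- sim_hsnps(50, seed = 31)
  withr::with_seed(32, {
    x <- sort(runif(20, min(hs$pos), max(hs$pos)))
    pr <- predict_ab(x, hs, truth)
    expect_true(all(pr$sigma2 <= prior_var + 1e-8))
    # adding an hSNP at a position never increases sigma2 there
    xq <- hs$pos[25]
    without <- predict_ab(xq, hs[-25, ], truth)
    with_it <- predict_ab(xq, hs, truth)
    expect_lte(with_it$sigma2, without$sigma2 + 1e-10)
  })
})

test_that("AB estimation error decreases with hSNP density", {
  truth <- default_truth()
  err_at_density <- function(spacing, seed) {
    withr::with_seed(seed, {
      n <- 600
      pos <- cumsum(round(rexp(n, 1 / spacing)) + 1)
      B <- simulate_ab(pos, truth)
      d <- pmax(1L, rpois(n, 30))
      y <- rbinom(n, d, plogis(B))
      hold <- seq(5, n, by = 10) # held-out positions
      hs <- tibble::tibble(pos = pos[-hold], allele1_reads = y[-hold],
                           depth = d[-hold])
      pr <- predict_ab(pos[hold], hs, truth)
      mean(abs(pr$ab - plogis(B[hold])))
    })
  }
  expect_lt(err_at_density(500, 41), err_at_density(4000, 41))
})

test_that("covariance matrices factorize across the default grid", {
  withr::with_seed(51, {
    pos <- cumsum(round(rexp(40, 1 / 1500)) + 1)
    g <- ab_param_grid()
    some <- g[round(seq(1, nrow(g), length.out = 60)), ]
    for (i in seq_len(nrow(some))) {
      p <- cov_params(some$a[i], some$b[i], some$c[i], some$d[i])
      expect_no_error(chol(abcall:::cov_matrix(pos, p)))
    }
  })
})
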