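test_that("aridity index is the radiation/precipitation ratio with guards", {
  out <- aridity_index(c(800, 500, 300), c(400, 500, 0))
  expect_equal(out$aridity, c(2, 1, NA))
  expect_equal(out$flagged, c(FALSE, FALSE, TRUE))
})

test_that("zone medians equal a sort-and-pick-middle oracle", {
  z <- zone_median(c(-3, -1, 5), rep("a", 3))
  expect_equal(z$median_sensitivity, -1)
  z1 <- zone_median(0.7, "solo")
  expect_equal(z1$median_sensitivity, 0.7)
  set.seed(2)
  vals <- rnorm(60)
  zones <- sample(letters[1:4], 60, replace = TRUE)
  zm <- zone_median(vals, zones)
  for (zz in unique(zones)) {
    v <- sort(vals[zones == zz])
    n <- length(v)
    oracle <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
    expect_equal(zm$median_sensitivity[zm$zone == zz], oracle)
  }
})

test_that("bin means honor the minimum-significant-cells rule", {
  mk <- function(n_sig) {
    sens <- rep(-0.5, 12)
    sig <- c(rep(TRUE, n_sig), rep(FALSE, 12 - n_sig))
    bin_means(sens, sig, aridity = rep(1, 12), temperature = rep(10, 12),
              min_cells = 10)
  }
  b9 <- mk(9)
  expect_true(b9$suppressed)
  expect_true(is.na(b9$mean_sensitivity))
  b10 <- mk(10)
  expect_false(b10$suppressed)
  expect_equal(b10$mean_sensitivity, -0.5)
  expect_error(bin_means(1, TRUE, 1, 1, aridity_edges = c(1, 1)),
               "strictly increasing")
})

test_that("bin partitions conserve cell counts", {
  set.seed(4)
  n <- 300
  sens <- rnorm(n)
  sig <- runif(n) < 0.5
  aridity <- runif(n, 0.1, 6)
  temperature <- runif(n, -5, 32)
  b <- bin_means(sens, sig, aridity, temperature)
  expect_equal(sum(b$n_cells) + attr(b, "n_unbinned"), n)
  expect_equal(sum(b$n_significant_cells), sum(sig))
})

test_that("partial Spearman reduces to Spearman for constant controls", {
  set.seed(5)
  x <- rnorm(30); y <- 0.6 * x + rnorm(30)
  ps <- partial_spearman(x, y, data.frame(c1 = rep(2, 30)))
  expect_equal(ps$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
})

test_that("partial Spearman recovers monotone links and matches the residual oracle", {
  set.seed(6)
  x <- rnorm(50)
  y <- exp(x)  # strictly increasing
  ctrl <- data.frame(a = rnorm(50), t = rnorm(50))
  expect_gt(partial_spearman(x, y, ctrl)$rho, 0.9)
  # residual-based rank-regression oracle
  y2 <- 0.5 * x + 0.3 * ctrl$a + rnorm(50)
  ps <- partial_spearman(x, y2, ctrl)
  rx <- rank(x); ry <- rank(y2); ra <- rank(ctrl$a); rt <- rank(ctrl$t)
  oracle <- cor(resid(lm(rx ~ ra + rt)), resid(lm(ry ~ ra + rt)))
  expect_lt(abs(ps$rho - oracle), 1e-10)
  # invariance to strictly monotone transforms
  ps_t <- partial_spearman(exp(x), y2^3 + 10 * y2, ctrl)
  expect_equal(ps_t$rho, ps$rho, tolerance = 1e-12)
})

test_that("degenerate partial-Spearman inputs are flagged", {
  out <- partial_spearman(rep(1, 10), rnorm(10),
                          data.frame(a = rnorm(10)))
  expect_true(out$degenerate)
  out2 <- partial_spearman(rnorm(3), rnorm(3), data.frame(a = rnorm(3)))
  expect_true(out2$degenerate)
})

test_that("Benjamini-Hochberg equals the brute-force step-up definition", {
  out <- benjamini_hochberg(c(0.01, 0.02, 0.04, 0.8), q = 0.05)
  expect_equal(out$significant, c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(benjamini_hochberg(rep(0.001, 8))$significant))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
  set.seed(7)
  for (i in 1:200) {
    m <- sample(3:40, 1)
    p <- runif(m)^sample(1:3, 1)
    got <- benjamini_hochberg(p, q = 0.05)$significant
    expect_identical(got, bh_bruteforce(p, 0.05))
  }
  # adjusted p is monotone after sorting and >= raw
  p <- runif(50)
  out <- benjamini_hochberg(p)
  expect_true(all(out$p_adjusted >= out$p_raw))
  expect_true(!is.unsorted(out$p_adjusted[order(out$p_raw)]))
})

test_that("covariate analysis disregards thin bins and flags degenerate ones", {
  set.seed(8)
  mk_cells <- function(n, bio) tibble::tibble(
    sensitivity = rnorm(n), biodiversity = bio,
    rootzone_storage = rnorm(n, 200, 20),
    aridity = runif(n, 0.55, 0.75), temperature = runif(n, 11, 14))
  out19 <- covariate_analysis(mk_cells(19, rnorm(19, 400, 50)))
  expect_true(all(out19$suppressed))
  expect_true(all(is.na(out19$partial_rho)))
  out25 <- covariate_analysis(mk_cells(25, rnorm(25, 400, 50)))
  expect_true(all(!out25$suppressed))
  # all-identical covariate: undefined, flagged degenerate
  outdeg <- covariate_analysis(mk_cells(25, rep(400, 25)))
  deg <- outdeg[outdeg$covariate == "biodiversity", ]
  expect_true(all(deg$degenerate))
  expect_true(all(is.na(deg$partial_rho)))
})

test_that("planted covariate links are recovered and null worlds stay quiet", {
  set.seed(9)
  n <- 400
  aridity <- runif(n, 0.2, 1.1)
  temperature <- runif(n, 2, 14)
  bio <- rnorm(n, 400, 80)
  sens <- 0.004 * bio + 0.3 * temperature + rnorm(n, sd = 0.4)
  cells <- tibble::tibble(sensitivity = sens, biodiversity = bio,
                          rootzone_storage = rnorm(n, 200, 30),
                          aridity = aridity, temperature = temperature)
  out <- covariate_analysis(cells, aridity_edges = c(0, 0.6, 1.2),
                            temp_edges = c(0, 8, 16))
  pop <- out[!out$suppressed & out$covariate == "biodiversity", ]
  expect_true(all(pop$partial_rho > 0))
  expect_gt(sum(pop$significant_bh), 0)
  # null: no link anywhere
  cells$sensitivity <- rnorm(n)
  out0 <- covariate_analysis(cells, aridity_edges = c(0, 0.6, 1.2),
                             temp_edges = c(0, 8, 16))
  expect_lte(mean(out0$significant_bh[!out0$suppressed]), 0.1)
})
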