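test_that("zscore standardizes exactly with the population divisor", {
  expect_equal(zscore(c(1, 2, 3)),
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  z <- zscore(rnorm(50))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(mean(z^2), 1, tolerance = 1e-12)
  expect_equal(zscore(z), z, tolerance = 1e-12)    # idempotence
  expect_error(zscore(c(5, 5, 5)), "constant")
  expect_error(zscore(3), "length")
  # optional sample-variance divisor matches scale()
  x <- rnorm(20)
  expect_equal(zscore(x, sample_var = TRUE), as.numeric(scale(x)),
               tolerance = 1e-12)
})

test_that("pearson agrees with the textbook covariance formula", {
  expect_equal(pearson(1:5, 1:5), 1, tolerance = 1e-12)
  expect_equal(pearson(1:5, -(1:5)), -1, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(30); y <- rnorm(30)
    expect_equal(pearson(x, y), cor(x, y), tolerance = 1e-12)
  }
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 4)),
               cor(c(1, 2, 3), c(1, 2, 4)), tolerance = 1e-12)
})

test_that("Van der Waerden transform maps ranks to normal quantiles", {
  expect_equal(van_der_waerden(c(10, 20, 30)),
               qnorm(c(1, 2, 3) / 4), tolerance = 1e-12)
  set.seed(4)
  w <- rnorm(25)
  tw <- van_der_waerden(w)
  perm <- sample(25)
  expect_equal(van_der_waerden(w[perm]), tw[perm])  # rank equivariance
  expect_equal(van_der_waerden(-w), -tw, tolerance = 1e-12)
  expect_equal(mean(tw), 0, tolerance = 1e-12)      # rank symmetry, no ties
  expect_true(all(diff(tw[order(w)]) > 0))          # strictly monotone
  # midranks keep tied values equal and the mean at zero
  tt <- van_der_waerden(c(1, 2, 2, 3))
  expect_equal(tt[2], tt[3])
  expect_equal(mean(tt), 0, tolerance = 1e-12)
})

test_that("shared profiles sum the shared microRNA rows", {
  mic <- matrix(c(1, 0, 0, 1, 2, 2), 3, 2, byrow = TRUE,
                dimnames = list(c("m1", "m2", "m3"), c("s1", "s2")))
  map <- target_map(c("gA", "gA", "gB", "gB", "gC"),
                    c("m1", "m2", "m1", "m2", "m3"))
  p <- shared_profile("gA", "gB", map, mic)
  expect_equal(unname(p$raw_sum), c(1, 1))          # (1,0) + (0,1)
  expect_setequal(p$shared_mirnas, c("m1", "m2"))
  p2 <- shared_profile("gB", "gA", map, mic)
  expect_equal(p$raw_sum, p2$raw_sum)               # symmetry
  expect_error(shared_profile("gA", "gC", map, mic), "not a candidate")
  # single shared microRNA: sum equals that row
  map1 <- target_map(c("gA", "gB"), c("m3", "m3"))
  expect_equal(shared_profile("gA", "gB", map1, mic)$raw_sum,
               mic["m3", ])
})

test_that("liquid association matches hand-evaluated triple products", {
  # symmetric configuration: products cancel about the median
  expect_equal(liquid_association(c(1, 2, 3), c(1, 2, 3), c(10, 20, 30)),
               0, tolerance = 1e-12)
  # independent arithmetic for the one non-zero term
  zx <- zscore(c(1, 2, 3)); zy <- zscore(c(3, 1, 2))
  wt <- qnorm(c(1, 2, 3) / 4)
  expect_equal(liquid_association(c(1, 2, 3), c(3, 1, 2), c(10, 20, 30)),
               sum(zx * zy * wt) / 3, tolerance = 1e-12)
  expect_equal(sum(zx * zy * wt) / 3, 0.3372449, tolerance = 1e-6)
  # symmetries
  set.seed(9)
  x <- rnorm(40); y <- rnorm(40); w <- rnorm(40)
  expect_equal(liquid_association(x, y, w), liquid_association(y, x, w))
  expect_equal(liquid_association(x, -y, w),
               -liquid_association(x, y, w), tolerance = 1e-12)
  expect_error(liquid_association(x, y[-1], w), "equal length")
})

test_that("liquid association is near zero for independent triples", {
  n <- 10000
  set.seed(12)
  la <- liquid_association(rnorm(n), rnorm(n), rnorm(n))
  expect_lt(abs(la), 4 / sqrt(n))
})

test_that("partial correlation matches the regression-residual oracle", {
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(30); y <- rnorm(30); w <- rnorm(30)
    oracle <- cor(resid(lm(x ~ w)), resid(lm(y ~ w)))
    expect_equal(partial_correlation(x, y, w), oracle, tolerance = 1e-10)
  }
  # formula collapse when w is uncorrelated with both
  x <- c(1, -1, 1, -1); w <- c(1, 1, -1, -1); y <- c(2, -2, 2, -2)
  expect_equal(partial_correlation(x, y, w), pearson(x, y))
  expect_equal(partial_correlation(x, x, w), 1)
  expect_error(partial_correlation(w, y, w), "undefined")
})

test_that("sensitivity correlation is PCC minus partial correlation", {
  set.seed(10)
  x <- rnorm(30); y <- x + rnorm(30); w <- rnorm(30)
  expect_equal(sensitivity_correlation(x, y, w),
               pearson(x, y) - partial_correlation(x, y, w))
  x2 <- c(1, -1, 1, -1); w2 <- c(1, 1, -1, -1)
  expect_equal(sensitivity_correlation(x2, x2, w2), 0)
})

test_that("hypergeometric MS-P equals exhaustive enumeration", {
  expect_equal(msp_hypergeometric(4, 3, 0, 10), 1)
  expect_equal(msp_hypergeometric(4, 3, 2, 10), 1 / 3, tolerance = 1e-12)
  expect_equal(msp_hypergeometric(4, 3, 2, 10),
               enum_shared_tail(4, 3, 2, 10), tolerance = 1e-12)
  for (Q in c(5, 8)) for (T in 0:Q) for (b in 0:Q)
    for (q in 0:min(T, b))
      expect_equal(msp_hypergeometric(T, b, q, Q),
                   enum_shared_tail(T, b, q, Q), tolerance = 1e-12)
  # monotone non-increasing in q
  ps <- sapply(0:3, function(q) msp_hypergeometric(4, 3, q, 10))
  expect_true(all(diff(ps) <= 0))
  expect_error(msp_hypergeometric(11, 3, 1, 10), "infeasible")
})

test_that("score_pair fills all statistics and is symmetric", {
  set.seed(21)
  n <- 40
  mic <- matrix(rexp(3 * n), 3, n,
                dimnames = list(c("m1", "m2", "m3"), sprintf("s%02d", 1:n)))
  genes <- matrix(rnorm(2 * n), 2, n,
                  dimnames = list(c("gA", "gB"), colnames(mic)))
  genes["gB", ] <- genes["gA", ]      # identical rows
  map <- target_map(c("gA", "gA", "gB", "gB"),
                    c("m1", "m2", "m2", "m3"))
  st <- score_pair("gA", "gB", genes, mic, map)
  expect_equal(st$pcc, 1)
  expect_equal(st$q_shared, 1L)
  expect_equal(st$msp, msp_hypergeometric(2, 2, 1, 3))
  st_rev <- score_pair("gB", "gA", genes, mic, map)
  expect_equal(st, st_rev)
  genes["gB", ] <- 5
  expect_error(score_pair("gA", "gB", genes, mic, map), "constant")
})

test_that("a simulated ceRNA pair scores positive on both PCC and LA", {
  cfg <- simulation_config(n_samples = 2000, cerna_effect = 1,
                           noise_sd = 0.05, seed = 42)
  tri <- simulate_cerna_triples(cfg)
  expect_gt(pearson(tri$x, tri$y), 0)
  expect_gt(liquid_association(tri$x, tri$y, tri$w), 0)
})

test_that("score_all_pairs returns lexicographic candidate pairs", {
  set.seed(33)
  n <- 30
  mic <- matrix(rexp(4 * n), 4, n,
                dimnames = list(paste0("m", 1:4), sprintf("s%02d", 1:n)))
  genes <- matrix(rnorm(3 * n), 3, n,
                  dimnames = list(c("gC", "gA", "gB"), colnames(mic)))
  map <- target_map(c("gA", "gA", "gB", "gB", "gC"),
                    c("m1", "m2", "m2", "m3", "m4"))
  st <- score_all_pairs(genes, mic, map)
  # only gA-gB shares a microRNA
  expect_identical(nrow(st), 1L)
  expect_identical(c(st$rna1, st$rna2), c("gA", "gB"))
  expect_equal(st[1, ], score_pair("gA", "gB", genes, mic, map),
               ignore_attr = TRUE)
})
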