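test_that("zone boundaries split the disc into exact equal areas", {
  b <- zone_boundaries(1)
  expect_equal(unname(b["r1"]), sqrt(2 / 3))
  expect_equal(unname(b["r2"]), sqrt(1 / 3))
  # analytic area fractions of the three rings are exactly 1/3
  expect_equal(1 - b[["r1"]]^2, 1 / 3)
  expect_equal(b[["r1"]]^2 - b[["r2"]]^2, 1 / 3)
  expect_equal(b[["r2"]]^2, 1 / 3)
  expect_equal(zone_boundaries(5), 5 * zone_boundaries(1))
  expect_error(zone_boundaries(0), class = "invalid_parameter")
})

test_that("zone assignment matches brute-force radius comparisons", {
  expect_equal(assign_zone(0.9, 1), 1L)
  expect_equal(assign_zone(0, 1), 3L)
  b <- zone_boundaries(1)
  expect_equal(assign_zone(b[["r1"]], 1), 1L)  # tie -> peripheral
  expect_equal(assign_zone(b[["r2"]], 1), 2L)
  set.seed(17)
  r <- runif(500)
  z <- assign_zone(r, 1)
  oracle <- vapply(r, function(ri) {
    if (ri >= b[["r1"]]) 1L else if (ri >= b[["r2"]]) 2L else 3L
  }, integer(1))
  expect_identical(unname(z), oracle)
  expect_equal(sum(tabulate(z, 3)), 500L)  # every spot in exactly one zone
  expect_error(assign_zone(1.1, 1), class = "outside_disc")
  # uniform-area spots fall ~33% in each zone
  set.seed(18)
  zu <- assign_zone(sqrt(runif(1e5)), 1)
  expect_true(all(abs(tabulate(zu, 3) / 1e5 - 1 / 3) < 0.01))
})

test_that("decile bins follow the edge-to-periphery convention", {
  expect_equal(assign_decile(0.05), 0L)  # closest to the nucleolus edge
  expect_equal(assign_decile(1.0), 9L)   # closed last bin
  expect_equal(assign_decile(seq(0.05, 0.95, 0.1)), 0:9)
  expect_warning(na <- assign_decile(c(-0.2, 0.5)), "inside the nucleolus")
  expect_identical(na, c(NA_integer_, 5L))
  expect_error(assign_decile(1.2), class = "invalid_parameter")
  set.seed(19)
  bins <- assign_decile(runif(2e4))
  expect_true(all(abs(tabulate(bins + 1L, 10) / 2e4 - 0.1) < 0.02))
  expect_equal(relative_edge_position(1.5, 1, 3), 0.25)
  expect_error(relative_edge_position(1, 2, 2), class = "invalid_parameter")
})

test_that("chi-squared on zone tables matches the Pearson formula", {
  same <- chi_squared_zones(c(40, 30, 30), c(40, 30, 30))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  a <- c(50, 25, 25); b <- c(25, 25, 50)
  out <- chi_squared_zones(a, b)
  # explicit sum((O - E)^2 / E) over the 2 x 3 table
  tab <- rbind(a, b)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(out$statistic, sum((tab - E)^2 / E))
  expect_equal(out$df, 2)
  expect_equal(out$p_value, pchisq(out$statistic, 2, lower.tail = FALSE))
  expect_error(chi_squared_zones(c(10, 0), c(5, 0)), class = "zero_expected")
  expect_error(chi_squared_zones(c(1, 2), c(1, 2, 3)),
               class = "invalid_input")
})

test_that("permutation p-values: identity, exhaustive equality, floor", {
  prof <- matrix(rep(seq(0.1, 1, length.out = 20), 4), nrow = 4,
                 byrow = TRUE)
  p_same <- permutation_bin_test(prof[1:2, ], prof[3:4, ], n_perm = 199,
                                 seed = 1)
  expect_true(all(p_same == 1))
  # 2 vs 2: exact enumeration equals an independent brute-force loop
  set.seed(23)
  A <- matrix(runif(40), 2); B <- matrix(runif(40) + 0.3, 2)
  p_exact <- permutation_bin_test(A, B, exact = TRUE)
  pool <- rbind(A, B)
  obs <- abs(colMeans(A) - colMeans(B))
  combs <- combn(4, 2)
  p_oracle <- vapply(1:20, function(bin) {
    stats <- apply(combs, 2, function(ia) {
      abs(mean(pool[ia, bin]) - mean(pool[setdiff(1:4, ia), bin]))
    })
    mean(stats >= obs[bin] - 1e-12)
  }, numeric(1))
  expect_equal(as.numeric(p_exact), p_oracle)
  # add-one estimator keeps p in [1/(n_perm+1), 1] even for extreme groups
  p <- permutation_bin_test(A + 5, B, n_perm = 99, seed = 2)
  expect_true(all(p >= 1 / 100 & p <= 1))
  expect_error(permutation_bin_test(A[1, , drop = FALSE], B),
               class = "invalid_input")
  expect_error(permutation_bin_test(A, B, n_perm = 50),
               class = "invalid_input")
  # seeded reproducibility
  expect_identical(
    as.numeric(permutation_bin_test(A, B, n_perm = 199, seed = 7)),
    as.numeric(permutation_bin_test(A, B, n_perm = 199, seed = 7)))
})

test_that("Bonferroni and region combination behave as documented", {
  expect_equal(bonferroni_adjust(0.01), 0.2)
  expect_equal(bonferroni_adjust(0.2), 1.0)
  set.seed(27)
  p <- runif(20)
  expect_equal(bonferroni_adjust(p), pmin(1, 20 * p))
  expect_error(bonferroni_adjust(1.5), class = "invalid_parameter")
  # combined probability: null aggregation and k = 1 identity
  expect_equal(as.numeric(combine_region(rep(1, 6))), 1)
  expect_equal(as.numeric(combine_region(0.37)), 0.37, tolerance = 1e-12)
  expect_equal(as.numeric(combine_region(0.37, method = "pearson")), 0.37,
               tolerance = 1e-12)
  # (0.1, 0.2): chi2 = -2(log .1 + log .2) vs 4-df upper tail,
  # independent closed form exp(-x/2) (1 + x/2)
  x2 <- -2 * (log(0.1) + log(0.2))
  expect_equal(x2, 7.824046, tolerance = 1e-6)
  expect_equal(as.numeric(combine_region(c(0.1, 0.2))),
               exp(-x2 / 2) * (1 + x2 / 2))
  # monotone: decreasing any input never increases the combined p
  base <- c(0.3, 0.5, 0.7)
  for (i in 1:3) {
    dec <- base; dec[i] <- dec[i] / 2
    expect_lte(as.numeric(combine_region(dec)),
               as.numeric(combine_region(base)))
  }
  expect_warning(z <- combine_region(c(0, 0.5), n_perm = 999), "clamped")
  expect_lte(as.numeric(z), 1)
  expect_error(combine_region(numeric(0)), class = "invalid_input")
})

test_that("region membership is 6 + 6 + 6 bins with two excluded", {
  prof <- matrix(runif(80), nrow = 4)
  cmp <- compare_condition_profiles(prof[1:2, ], prof[3:4, ], exact = TRUE)
  expect_equal(lengths(cmp$regions), c("0-30%" = 6L, "35-65%" = 6L,
                                       "70-100%" = 6L))
  centers <- seq(2.5, 97.5, 5)
  excluded <- setdiff(seq_len(20), unlist(cmp$regions))
  expect_equal(centers[excluded], c(32.5, 67.5))
  # identical groups: every region p-value is 1
  same <- rbind(prof[1:2, ], prof[1:2, ])
  cmp1 <- compare_condition_profiles(same[c(1, 2), ], same[c(3, 4), ],
                                     exact = TRUE)
  expect_equal(unname(cmp1$region_p), rep(1, 3))
  expect_equal(cmp1$p_adjusted, pmin(1, 20 * cmp1$p_raw))
})
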