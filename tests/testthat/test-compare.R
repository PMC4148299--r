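test_that("Friedman hand cases", {
  # identical columns: no rank differences
  same <- matrix(rep(1:5, 3), 5, 3)
  fr <- friedman_rank_test(same)
  expect_equal(fr$chi_square, 0)
  expect_equal(fr$p_value, 1)
  # strictly ordered 3x3 rows: chi-square = 6 with df = 2
  ordered <- rbind(c(1, 2, 3), c(4, 5, 6), c(0.1, 0.5, 0.9))
  fr2 <- friedman_rank_test(ordered)
  expect_equal(fr2$chi_square, 6)
  expect_equal(fr2$df, 2)
  expect_equal(fr2$p_value, pchisq(6, 2, lower.tail = FALSE))
  expect_error(friedman_rank_test(ordered[, 1, drop = FALSE]), "2 treatments")
})

test_that("Friedman agrees with the reference implementation without ties", {
  withr::with_seed(1, {
    for (rep in 1:10) {
      m <- matrix(rnorm(8 * 4), 8, 4)
      ours <- friedman_rank_test(m)
      ref <- stats::friedman.test(m)
      expect_equal(ours$chi_square, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-10)
    }
  })
})

test_that("Friedman is invariant to monotone within-block transforms and block shifts", {
  withr::with_seed(2, {
    m <- matrix(rnorm(30), 10, 3)
    base <- friedman_rank_test(m)$chi_square
    expect_equal(friedman_rank_test(exp(m))$chi_square, base)
    expect_equal(friedman_rank_test(m^3)$chi_square, base)
    shifted <- m
    shifted[4, ] <- shifted[4, ] + 100
    expect_equal(friedman_rank_test(shifted)$chi_square, base)
  })
})

test_that("tie correction matches the closed form on a known tied table", {
  # one block fully tied, two ordered blocks, k = 3
  m <- rbind(c(1, 1, 1), c(1, 2, 3), c(1, 2, 3))
  fr <- friedman_rank_test(m)
  # ranks: (2,2,2), (1,2,3), (1,2,3); S = sum (Rj - n(k+1)/2)^2 = 8
  # uncorrected chi2 = 12*8/(3*3*4) = 8/3; tie correction 1 - 24/(3*3*8) = 2/3
  expect_equal(fr$chi_square, (12 * 8 / 36) / (1 - 24 / (3 * 3 * 8)))
})

test_that("Friedman chi-square approximation matches the exact permutation law", {
  # exact null distribution for n = 6 blocks, k = 3: all 6^6 equally likely
  # within-block rank assignments, enumerated directly from the rank formula
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  n <- 6
  grid <- as.matrix(expand.grid(rep(list(1:6), n)))
  rj <- sapply(1:3, function(j) rowSums(matrix(perms[grid, j], ncol = n)))
  chi_all <- 12 / (n * 3 * 4) * rowSums((rj - n * 2)^2)
  # the discreteness limit: the largest atom of the exact distribution
  atom <- max(table(round(chi_all, 9))) / length(chi_all)
  withr::with_seed(3, {
    for (rep in 1:5) {
      m <- matrix(rnorm(n * 3), n, 3)
      obs <- friedman_rank_test(m)
      # the implemented statistic is one of the enumerated values
      expect_true(any(abs(chi_all - obs$chi_square) < 1e-9))
      p_exact <- mean(chi_all >= obs$chi_square - 1e-9)
      expect_lt(abs(obs$p_value - p_exact), atom)
    }
  })
})

test_that("Nemenyi post-hoc behaves on degenerate and ordered inputs", {
  same <- matrix(rep(1:6, 4), 6, 4, dimnames = list(NULL, letters[1:4]))
  nm <- nemenyi_test(same)
  expect_equal(unname(nm$p_values[upper.tri(nm$p_values)]), rep(1, 6))
  expect_equal(unname(diag(nm$p_values)), rep(1, 4))
  expect_error(nemenyi_test(same[, 1:2]), "3 treatments")

  ordered <- matrix(rep(1:4, each = 40), 40, 4) +
    withr::with_seed(4, matrix(rnorm(160, 0, 0.01), 40, 4))
  nm2 <- nemenyi_test(ordered)
  # wider rank gaps give smaller p-values
  expect_lt(nm2$p_values[1, 4], nm2$p_values[1, 2])
  expect_lt(nm2$p_values[1, 4], nm2$p_values[2, 3])
  expect_equal(nm2$p_values, t(nm2$p_values))
})

test_that("Nemenyi family-wise error is controlled under the null", {
  withr::with_seed(5, {
    any_rej <- replicate(2000, {
      m <- matrix(rnorm(50 * 4), 50, 4)
      nm <- nemenyi_test(m)
      any(nm$p_values[upper.tri(nm$p_values)] < 0.05)
    })
  })
  expect_lte(mean(any_rej), 0.07)
})

test_that("compare_pipelines assembles matched blocks and guards k", {
  withr::with_seed(6, {
    stats4 <- list(default = rnorm(60), flexhrf = rnorm(60),
                   mcompcor = rnorm(60) + 1, combined = rnorm(60) + 1)
  })
  cmp <- compare_pipelines(stats4, stat_kind = "t_value")
  expect_s3_class(cmp$friedman, "friedman_test")
  expect_s3_class(cmp$nemenyi, "nemenyi_test")
  expect_equal(cmp$summary$pipeline[1:2] %in% c("mcompcor", "combined"),
               c(TRUE, TRUE))
  # two pipelines: Friedman runs, Nemenyi refuses
  cmp2 <- compare_pipelines(stats4[1:2])
  expect_s3_class(cmp2$friedman, "friedman_test")
  expect_null(cmp2$nemenyi)
  expect_error(compare_pipelines(list(a = rnorm(10), b = rnorm(11))),
               "different numbers of blocks")
})
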