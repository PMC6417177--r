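test_that("Mann-Whitney exact branch matches hand enumeration", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)    # 2 * (1/20) over all 20 rank assignments
  expect_equal(res$method, "exact")

  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p, 0.9)
})

test_that("exact p agrees with the enumeration oracle over random small cases", {
  withr::with_seed(19, {
    for (i in 1:50) {
      n <- sample(2:7, 1); m <- sample(2:7, 1)
      x <- sample(seq_len(100), n)   # distinct values: no ties
      y <- sample(setdiff(seq_len(100), x), m)
      got <- mann_whitney(x, y)
      want <- oracle_mw_exact(x, y)
      expect_equal(got$U, want$U)
      expect_equal(got$p, want$p, tolerance = 1e-12)
    }
  })
})

test_that("ties or large groups switch to the corrected normal approximation", {
  res <- mann_whitney(c(1, 1, 2, 3), c(2, 3, 3, 4))
  expect_equal(res$method, "normal")
  res2 <- mann_whitney(rnorm(20), rnorm(20))
  expect_equal(res2$method, "normal")
  expect_error(mann_whitney(numeric(0), 1:3), class = "vitapath_input_error")
})

test_that("Kruskal-Wallis H matches the direct formula and is symmetric", {
  gs <- list(c(1, 2), c(3, 4), c(5, 6))
  res <- kruskal_wallis(gs)
  expect_equal(res$H, oracle_kw_H(gs), tolerance = 1e-12)
  expect_equal(res$df, 2)

  ident <- kruskal_wallis(list(c(5, 5), c(5, 5), c(5, 5)))
  expect_equal(ident$H, 0)
  expect_equal(ident$p, 1)

  perm <- kruskal_wallis(gs[c(3, 1, 2)])
  expect_equal(perm$H, res$H)

  expect_error(kruskal_wallis(list(1:3, 4:6)), "mann_whitney",
               class = "vitapath_input_error")
})

test_that("Bonferroni multiplies by the family size and caps at one", {
  expect_equal(bonferroni(0.01), 0.01)
  expect_equal(bonferroni(c(0.01, 0.2, 0.5)), c(0.03, 0.6, 1.0))
  expect_equal(bonferroni(c(1, 1)), c(1, 1))
  expect_error(bonferroni(c(0.5, 1.2)), class = "vitapath_input_error")
  # monotone in the input
  p <- sort(runif(10))
  expect_true(all(diff(bonferroni(p)) >= 0))
})

test_that("star labels follow the printed thresholds with inclusive bounds", {
  expect_equal(stars(0.03), "*")
  expect_equal(stars(0.05), "*")
  expect_equal(stars(0.2), "ns")
  expect_equal(stars(c(0.051, 0.01, 0.001, 0.0001, 0.00009)),
               c("ns", "**", "***", "****", "****"))
})

test_that("two-group comparisons use Mann-Whitney and Bonferroni-adjust", {
  withr::with_seed(37, {
    profile <- tidyr::expand_grid(sample = sprintf("s%02d", 1:20),
                                  vitamin = c("BIO", "THI"),
                                  category = "biosynthesis") |>
      dplyr::mutate(abundance = runif(dplyr::n()))
    # plant a clear shift for BIO only
    g2 <- sprintf("s%02d", 11:20)
    profile$abundance[profile$vitamin == "BIO" & profile$sample %in% g2] <-
      profile$abundance[profile$vitamin == "BIO" & profile$sample %in% g2] + 5
  })
  md <- tibble::tibble(sample = sprintf("s%02d", 1:20),
                       group = rep(c("healthy", "diseased"), each = 10))
  cmp <- compare_groups(profile, md)
  expect_equal(unique(cmp$test), "Mann-Whitney-Wilcoxon")
  expect_equal(cmp$p_adj, pmin(1, cmp$p * 2))
  expect_lt(cmp$p[cmp$vitamin == "BIO"], 0.001)
  expect_gt(cmp$p[cmp$vitamin == "THI"], 0.05)
  expect_equal(cmp$stars, stars(cmp$p))
})

test_that("three groups route to Kruskal-Wallis", {
  withr::with_seed(41, {
    profile <- tibble::tibble(sample = sprintf("s%02d", 1:30), vitamin = "RIB",
                              category = "biosynthesis", abundance = runif(30))
  })
  md <- tibble::tibble(sample = sprintf("s%02d", 1:30),
                       group = rep(c("CHN", "USA", "ESP"), each = 10))
  cmp <- compare_groups(profile, md)
  expect_equal(cmp$test, "Kruskal-Wallis")
})

test_that("rejection rates are calibrated under null and shift alternatives", {
  # type-I at alpha = 0.05 under a shared null, n = 25/25
  withr::with_seed(53, {
    p_null <- replicate(400, mann_whitney(rnorm(25), rnorm(25))$p)
  })
  expect_gt(mean(p_null < 0.05), 0.02)
  expect_lt(mean(p_null < 0.05), 0.09)

  # power at alpha = 0.01 with a 1-SD location shift, n = 50/50
  withr::with_seed(59, {
    p_shift <- replicate(200, mann_whitney(rnorm(50), rnorm(50) + 1)$p)
  })
  expect_gte(mean(p_shift < 0.01), 0.95)
})

test_that("indicator association reports OLS slope and F, F equals t squared", {
  withr::with_seed(61, {
    ab <- c(rnorm(30, 1, 0.1), rnorm(30, 2, 0.1))
  })
  profile <- tibble::tibble(sample = sprintf("s%02d", 1:60), vitamin = "BIO",
                            category = "biosynthesis", abundance = ab)
  md <- tibble::tibble(sample = sprintf("s%02d", 1:60),
                       country = rep(c("USA", "CHN"), each = 30))
  res <- indicator_association(profile, md, "country", "CHN")
  expect_lt(res$p, 0.01)
  expect_gt(res$statistic, 0)
  tt <- t.test(ab[31:60], ab[1:30], var.equal = TRUE)
  expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-9)

  # identical distributions in both groups: slope 0, p = 1
  flat <- profile
  flat$abundance <- rep(c(1, 2, 3), 20)
  res0 <- indicator_association(flat, md, "country", "CHN")
  expect_equal(res0$slope, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1, tolerance = 1e-6)

  expect_error(indicator_association(profile, md, "country", "FRA"),
               class = "vitapath_input_error")
})

test_that("the logistic direction reports a likelihood-ratio statistic", {
  withr::with_seed(67, {
    ab <- c(rnorm(30, 1, 0.2), rnorm(30, 3, 0.2))
  })
  profile <- tibble::tibble(sample = sprintf("s%02d", 1:60), vitamin = "BIO",
                            category = "biosynthesis", abundance = ab)
  md <- tibble::tibble(sample = sprintf("s%02d", 1:60),
                       status = rep(c("healthy", "diseased"), each = 30))
  res <- suppressWarnings(
    indicator_association(profile, md, "status", "diseased", direction = "logistic")
  )
  expect_gt(res$statistic, 0)
  expect_lt(res$p, 0.01)
})
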