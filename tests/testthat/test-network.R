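test_that("spearman handles perfect monotone and constant inputs", {
  expect_equal(spearman(c(1, 2, 3), c(3, 2, 1))$rho, -1)
  expect_equal(spearman(c(1, 2, 3, 4), c(10, 20, 30, 40))$rho, 1)
  res <- spearman(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_true(is.na(res$rho) && is.na(res$p))
  expect_error(spearman(c(1, 2), c(2, 1)), class = "vitapath_insufficient_data_error")
})

test_that("rho equals the mid-rank-then-Pearson oracle on tied vectors", {
  withr::with_seed(3, {
    for (i in 1:30) {
      n <- sample(5:40, 1)
      x <- sample(1:6, n, replace = TRUE)   # heavy ties
      y <- sample(1:6, n, replace = TRUE)
      if (length(unique(x)) == 1 || length(unique(y)) == 1) next
      expect_equal(spearman(x, y)$rho, oracle_spearman_rho(x, y), tolerance = 1e-12)
    }
  })
})

test_that("large-sample p matches the t-approximation of cor.test", {
  withr::with_seed(9, {
    for (i in 1:10) {
      x <- rnorm(25); y <- rnorm(25)
      ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
      expect_equal(spearman(x, y)$p, ct$p.value, tolerance = 1e-10)
    }
  })
})

# independent permutation generator (insertion construction)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- combinat_perms(n - 1)
  out <- list()
  for (p in sub) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}

test_that("small-sample p comes from the exact permutation distribution", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  got <- spearman(x, y)
  rhos <- vapply(combinat_perms(5), function(idx) oracle_spearman_rho(x, y[idx]),
                 numeric(1))
  expect_equal(got$p, mean(abs(rhos) >= abs(got$rho) - 1e-12), tolerance = 1e-12)
})

test_that("build_network enumerates all unordered pairs and classifies them", {
  withr::with_seed(21, {
    abund <- dplyr::bind_cols(
      tibble::tibble(species = sprintf("sp%d", 1:4)),
      tibble::as_tibble(matrix(runif(4 * 20), nrow = 4,
                               dimnames = list(NULL, sprintf("s%02d", 1:20))))
    )
  })
  net <- build_network(abund)
  expect_equal(nrow(net$edges), 6)
  expect_equal(sum(net$summary$n), 6)
  expect_equal(sum(net$summary$pct), 100)
  expect_true(all(net$edges$species_a != net$edges$species_b))
  expect_error(build_network(abund[, 1:3]), class = "vitapath_insufficient_data_error")
})

test_that("classification follows the rho and significance thresholds", {
  withr::with_seed(2, {
    s <- sort(runif(30))
    abund <- tibble::tibble(species = c("up1", "up2", "down"),
                            !!!setNames(as.data.frame(rbind(
                              s + rnorm(30, 0, 0.01),
                              s + rnorm(30, 0, 0.01),
                              rev(s) + rnorm(30, 0, 0.01)
                            )), sprintf("s%02d", 1:30)))
  })
  net <- build_network(abund, alpha = 0.01, rho_cutoff = 0.4)
  e <- net$edges
  cls <- function(a, b) e$classification[(e$species_a == a & e$species_b == b) |
                                           (e$species_a == b & e$species_b == a)]
  expect_equal(cls("up1", "up2"), "positive")
  expect_equal(cls("up1", "down"), "negative")
  # positive needs rho >= 0.4, negative needs rho < 0
  expect_true(all(e$rho[e$classification == "positive"] >= 0.4))
  expect_true(all(e$rho[e$classification == "negative"] < 0))
})

test_that("species relabeling permutes but does not change rho values", {
  withr::with_seed(13, {
    abund <- dplyr::bind_cols(
      tibble::tibble(species = sprintf("sp%d", 1:6)),
      tibble::as_tibble(matrix(rlnorm(6 * 15), nrow = 6,
                               dimnames = list(NULL, sprintf("s%02d", 1:15))))
    )
  })
  net1 <- build_network(abund)
  relabeled <- abund
  relabeled$species <- sprintf("taxon_%d", 6:1)
  net2 <- build_network(relabeled)
  expect_equal(sort(round(net1$edges$rho, 12)), sort(round(net2$edges$rho, 12)))
  expect_equal(net1$summary$n, net2$summary$n)
})

test_that("phenotype pairs label edges unordered per vitamin", {
  abund <- dplyr::bind_cols(
    tibble::tibble(species = c("spA", "spB")),
    tibble::as_tibble(matrix(c(1, 2, 3, 4, 3, 2, 1, 4), nrow = 2, byrow = TRUE,
                             dimnames = list(NULL, sprintf("s%d", 1:4))))
  )
  ph <- tibble::tibble(species = c("spA", "spB"), vitamin = "BIO",
                       phenotype = c("PC", "P"))
  net <- build_network(abund, ph, vitamins = "BIO")
  expect_equal(net$edges$pheno_BIO, "P-PC")
  expect_equal(net$phenotype_tally$n, 1L)
})

test_that("a planted high-correlation pair is classified positive", {
  b <- generate_synthetic(synthetic_spec(seed = 101))
  ph <- assign_phenotypes(b$annotation, b$gene_species, b$catalog)
  net <- build_network(b$species_abund, ph)
  e <- net$edges
  tr <- b$truth$edges
  pos <- e[(e$species_a == tr$species_a[1] & e$species_b == tr$species_b[1]) |
             (e$species_a == tr$species_b[1] & e$species_b == tr$species_a[1]), ]
  expect_equal(pos$classification, "positive")
  neg <- e[(e$species_a == tr$species_a[2] & e$species_b == tr$species_b[2]) |
             (e$species_a == tr$species_b[2] & e$species_b == tr$species_a[2]), ]
  expect_equal(neg$classification, "negative")
})

test_that("summarize_network reproduces reported pair-count arithmetic", {
  edges <- tibble::tibble(classification = rep(
    c("positive", "negative", "unclassified"), c(2030, 590, 7021 - 2030 - 590)
  ))
  s <- summarize_network(edges)
  expect_equal(round(s$pct[s$classification == "positive"], 1), 28.9)
  expect_equal(round(s$pct[s$classification == "negative"]), 8)
  expect_equal(sum(s$n), 7021)
})

test_that("tidy and glance expose edges and the one-row summary", {
  withr::with_seed(31, {
    abund <- dplyr::bind_cols(
      tibble::tibble(species = sprintf("sp%d", 1:5)),
      tibble::as_tibble(matrix(runif(5 * 12), nrow = 5,
                               dimnames = list(NULL, sprintf("s%02d", 1:12))))
    )
  })
  net <- build_network(abund)
  expect_equal(tidy(net), net$edges)
  g <- glance(net)
  expect_equal(g$n_pairs, 10)
  expect_equal(g$n_positive + g$n_negative + g$n_unclassified, 10)
})
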