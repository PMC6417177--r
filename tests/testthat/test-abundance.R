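test_that("normalize_gene divides reads by the sample total", {
  counts <- tibble::tibble(gene = c("g1", "g2"), s1 = c(10L, 0L))
  totals <- tibble::tibble(sample = "s1", total_reads = 1000)
  expect_equal(normalize_gene(counts, "s1", "g1", totals), 0.01)
  expect_equal(normalize_gene(counts, "s1", "g2", totals), 0)
  expect_error(
    suppressWarnings(
      normalize_gene(counts, "s1", "g1", tibble::tibble(sample = "s1", total_reads = 0))
    ),
    "s1", class = "vitapath_degenerate_sample_error"
  )
})

test_that("missing totals fall back to annotated column sums with a warning", {
  counts <- tibble::tibble(gene = c("g1", "g2"), s1 = c(10L, 30L))
  expect_warning(tot <- sample_totals(counts), class = "vitapath_totals_fallback")
  expect_equal(tot$total_reads, 40)
})

test_that("total normalized abundance sums category genes once each", {
  cat <- tiny_catalog()
  counts <- tibble::tibble(gene = c("g1", "g2", "g3"), s1 = c(10L, 30L, 500L))
  # g1 and g2 both BIO biosynthesis (sibling KOs); g3 unannotated
  annotation <- tibble::tibble(gene = c("g1", "g2"), ko = c("K00652", "K01012"))
  totals <- tibble::tibble(sample = "s1", total_reads = 1000)
  prof <- total_pathway_abundance(counts, annotation, cat, totals)
  expect_equal(prof$abundance[prof$vitamin == "BIO" & prof$category == "biosynthesis"], 0.04)
  # categories with no annotated gene are present with value 0
  expect_equal(prof$abundance[prof$vitamin == "FOL" & prof$category == "transport"], 0)
  expect_true(all(prof$abundance >= 0 & prof$abundance <= 1))

  # a gene annotated to two KOs of the same category counts once
  annot2 <- tibble::tibble(gene = c("g1", "g1"), ko = c("K00652", "K01012"))
  prof2 <- total_pathway_abundance(counts, annot2, cat, totals)
  expect_equal(prof2$abundance[prof2$vitamin == "BIO" & prof2$category == "biosynthesis"], 0.01)
})

test_that("pathway abundance equals the gene-by-gene double-loop oracle", {
  cat <- tiny_catalog()
  fx <- random_count_fixture(20, 200, cat, seed = 42)
  got <- total_pathway_abundance(fx$counts, fx$annotation, cat, fx$totals)
  want <- oracle_pathway_abundance(fx$counts, fx$annotation, cat, fx$totals)
  merged <- dplyr::inner_join(got, want, by = c("sample", "vitamin", "category"))
  expect_equal(nrow(merged), nrow(got))
  expect_equal(merged$abundance.x, merged$abundance.y, tolerance = 1e-12)
})

test_that("profiles are invariant to row/column order and count rescaling", {
  cat <- tiny_catalog()
  fx <- random_count_fixture(6, 50, cat, seed = 7)
  base <- total_pathway_abundance(fx$counts, fx$annotation, cat, fx$totals)

  perm <- fx$counts[sample(nrow(fx$counts)), c("gene", sample(setdiff(names(fx$counts), "gene")))]
  shuffled <- total_pathway_abundance(perm, fx$annotation, cat, fx$totals)
  expect_equal(dplyr::arrange(shuffled, sample, vitamin, category),
               dplyr::arrange(base, sample, vitamin, category))

  doubled <- fx$counts
  for (s in setdiff(names(doubled), "gene")) doubled[[s]] <- doubled[[s]] * 2L
  tot2 <- dplyr::mutate(fx$totals, total_reads = total_reads * 2)
  expect_equal(total_pathway_abundance(doubled, fx$annotation, cat, tot2)$abundance,
               base$abundance, tolerance = 1e-12)
})

test_that("raising one annotated gene's count raises its category total", {
  cat <- tiny_catalog()
  counts <- tibble::tibble(gene = c("g1", "g2"), s1 = c(10L, 5L))
  annotation <- tibble::tibble(gene = c("g1", "g2"), ko = c("K00652", "K03523"))
  totals <- tibble::tibble(sample = "s1", total_reads = 1000)
  before <- total_pathway_abundance(counts, annotation, cat, totals)
  counts$s1[1] <- 20L
  after <- total_pathway_abundance(counts, annotation, cat, totals)
  pick <- function(p) p$abundance[p$vitamin == "BIO" & p$category == "biosynthesis"]
  expect_gt(pick(after), pick(before))
})

test_that("EC grouping sums catalog enzymes and reports ignored features", {
  cat <- tiny_catalog()
  feats <- tibble::tibble(feature = c("1.1.1.1: not in catalog", "2.8.1.6"),
                          s1 = c(0.2, 0.3))
  expect_message(prof <- group_ec_abundance(feats, cat, "biosynthetic"),
                 "ignored 1 feature")
  expect_equal(prof$abundance[prof$vitamin == "BIO"], 0.3)

  empty <- tibble::tibble(feature = character(), s1 = numeric())
  expect_equal(unique(group_ec_abundance(empty, cat, "dependent")$abundance), 0)
})

test_that("EC grouping matches a feature-wise oracle on random tables", {
  cat <- tiny_catalog()
  withr::with_seed(11, {
    ecs <- c(cat$enzymes$ec, "9.9.9.9", "5.5.5.5")
    feats <- dplyr::bind_cols(
      tibble::tibble(feature = sample(ecs, 50, replace = TRUE)),
      tibble::as_tibble(matrix(stats::runif(50 * 10), nrow = 50,
                               dimnames = list(NULL, sprintf("s%02d", 1:10))))
    )
  })
  suppressMessages(got <- group_ec_abundance(feats, cat, "dependent"))
  dep <- cat$enzymes[cat$enzymes$role == "dependent", ]
  for (v in unique(dep$vitamin)) {
    keep <- feats$feature %in% dep$ec[dep$vitamin == v]
    for (s in sprintf("s%02d", 1:10)) {
      want <- sum(feats[[s]][keep])
      expect_equal(got$abundance[got$vitamin == v & got$sample == s], want,
                   tolerance = 1e-12)
    }
  }
})
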