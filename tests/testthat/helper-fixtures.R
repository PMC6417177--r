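# Small fixtures built in code.

tiny_catalog <- function() {
  vita_catalog(
    entries = tibble::tibble(
      vitamin = c("BIO", "BIO", "BIO", "FOL", "FOL", "THI", "THI"),
      category = c("biosynthesis", "biosynthesis", "transport",
                   "biosynthesis", "transport", "biosynthesis", "transport"),
      ko = c("K00652", "K01012", "K03523", "K01495", "K16923", "K03147", "K02064")
    ),
    enzymes = tibble::tibble(
      vitamin = c("BIO", "BIO", "THI"),
      role = c("biosynthetic", "dependent", "dependent"),
      ec = c("2.8.1.6", "6.4.1.1", "2.2.1.1")
    )
  )
}

write_tmp_catalog <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("vitamin\tcategory\tid_type\tidentifier", lines), path)
  path
}

# Random gene-count fixture with annotation and explicit totals.
random_count_fixture <- function(n_samples, n_genes, catalog, seed = 1) {
  withr::with_seed(seed, {
    samples <- sprintf("s%02d", seq_len(n_samples))
    genes <- sprintf("g%03d", seq_len(n_genes))
    kos <- unique(catalog$entries$ko)
    annotation <- tibble::tibble(
      gene = sample(genes, ceiling(n_genes * 0.6)),
      ko = sample(kos, ceiling(n_genes * 0.6), replace = TRUE)
    )
    counts <- dplyr::bind_cols(
      tibble::tibble(gene = genes),
      tibble::as_tibble(matrix(stats::rpois(n_genes * n_samples, 40),
                               nrow = n_genes, dimnames = list(NULL, samples)))
    )
    totals <- tibble::tibble(
      sample = samples,
      total_reads = vapply(samples, function(s) sum(counts[[s]]), numeric(1)) + 1000
    )
    list(counts = counts, annotation = annotation, totals = totals)
  })
}
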