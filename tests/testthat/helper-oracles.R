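# Independent brute-force oracles used to pin expected values. These stay
# deliberately naive (double loops, exhaustive enumeration, direct formulas)
# and never call the package code paths they check.

# Mid-ranks computed from first principles: r_i = #(x < x_i) + (#(x == x_i)+1)/2.
oracle_midrank <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
}

# Textbook Pearson correlation formula.
oracle_pearson <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

oracle_spearman_rho <- function(x, y) {
  oracle_pearson(oracle_midrank(x), oracle_midrank(y))
}

# Exact two-sided Mann-Whitney p by enumerating all C(n+m, n) assignments of
# the pooled ranks to group x. Valid without ties.
oracle_mw_exact <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  sets <- utils::combn(n + m, n)
  Ud <- apply(sets, 2, function(idx) sum(r[idx])) - n * (n + 1) / 2
  p <- 2 * min(mean(Ud <= U_obs), mean(Ud >= U_obs))
  list(U = U_obs, p = min(1, p))
}

# Kruskal-Wallis H from the direct rank-sum formula with tie correction.
oracle_kw_H <- function(groups) {
  all_v <- unlist(groups)
  N <- length(all_v)
  r <- rank(all_v)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, idx, sum)^2 / lengths(groups)) - 3 * (N + 1)
  tie_sizes <- table(all_v)
  H / (1 - sum(tie_sizes^3 - tie_sizes) / (N^3 - N))
}

# Gene-by-gene double-loop pathway abundance, plain arithmetic.
oracle_pathway_abundance <- function(counts, annotation, catalog, totals) {
  samples <- setdiff(names(counts), "gene")
  sets <- unique(catalog$entries[c("vitamin", "category")])
  out <- NULL
  for (s in samples) {
    tot <- totals$total_reads[totals$sample == s]
    for (i in seq_len(nrow(sets))) {
      kos <- catalog$entries$ko[catalog$entries$vitamin == sets$vitamin[i] &
                                  catalog$entries$category == sets$category[i]]
      genes <- unique(annotation$gene[annotation$ko %in% kos])
      acc <- 0
      for (g in genes) {
        acc <- acc + counts[[s]][counts$gene == g] / tot
      }
      out <- rbind(out, data.frame(sample = s, vitamin = sets$vitamin[i],
                                   category = sets$category[i], abundance = acc))
    }
  }
  tibble::as_tibble(out)
}

# Random boolean expression trees in the test's own representation
# (list(gene=) leaves, list(op=, args=) nodes), with an independent renderer
# and recursive evaluator.
random_tree <- function(genes, depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.35) {
    return(list(gene = sample(genes, 1)))
  }
  op <- sample(c("and", "or"), 1)
  k <- sample(2:3, 1)
  list(op = op, args = lapply(seq_len(k), function(i) random_tree(genes, depth - 1)))
}

render_tree <- function(node) {
  if (!is.null(node$gene)) return(node$gene)
  inner <- vapply(node$args, render_tree, character(1))
  paste0("(", paste(inner, collapse = paste0(" ", toupper(node$op), " ")), ")")
}

oracle_eval_tree <- function(node, present) {
  if (!is.null(node$gene)) return(node$gene %in% present)
  vals <- vapply(node$args, oracle_eval_tree, logical(1), present = present)
  if (node$op == "and") all(vals) else any(vals)
}
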