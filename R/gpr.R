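#' Parse a gene-protein-reaction (GPR) boolean rule
#'
#' GPR rules from genome-scale metabolic models state which gene products a
#' reaction requires: `AND` joins subunits of a complex, `OR` joins
#' isozymes. The grammar accepts gene tokens, case-insensitive `and`/`or`,
#' parentheses and arbitrary whitespace; `not` is rejected (negation does
#' not occur in these reconstructions). `or` binds loosest:
#' `a and b or c` parses as `(a and b) or c`.
#'
#' @param rule_text Non-empty rule string, e.g. `"(g1 and g2) or g3"`.
#' @return A `gpr` expression tree: a leaf `list(gene = <id>)` or a node
#'   `list(op = "and"|"or", args = list(<gpr>, ...))`.
#' @export
parse_gpr <- function(rule_text) {
  if (!is.character(rule_text) || length(rule_text) != 1 || !nzchar(trimws(rule_text))) {
    abort("GPR rule must be a non-empty string.", class = "vitapath_gpr_parse_error")
  }
  toks <- gpr_tokenize(rule_text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$i <- 1L
  tree <- gpr_parse_or(st)
  if (st$i <= nrow(st$toks)) {
    gpr_parse_fail(st, "unexpected trailing token")
  }
  structure(tree, class = "gpr")
}

gpr_tokenize <- function(text) {
  pat <- "\\(|\\)|[A-Za-z0-9_.:-]+"
  m <- gregexpr(pat, text)[[1]]
  covered <- logical(nchar(text))
  toks <- regmatches(text, gregexpr(pat, text))[[1]]
  if (length(toks) > 0) {
    for (k in seq_along(m)) {
      covered[m[k]:(m[k] + attr(m, "match.length")[k] - 1)] <- TRUE
    }
  }
  chars <- strsplit(text, "")[[1]]
  stray <- which(!covered & !grepl("\\s", chars))
  if (length(stray) > 0) {
    abort(sprintf("GPR parse error at position %d: unexpected character '%s'.",
                  stray[1], chars[stray[1]]),
          class = "vitapath_gpr_parse_error")
  }
  type <- dplyr::case_when(
    toks == "(" ~ "lparen",
    toks == ")" ~ "rparen",
    tolower(toks) == "and" ~ "and",
    tolower(toks) == "or" ~ "or",
    tolower(toks) == "not" ~ "not",
    TRUE ~ "gene"
  )
  if (any(type == "not")) {
    abort(sprintf("GPR parse error at position %d: 'not' is not supported.",
                  as.integer(m[which(type == "not")[1]])),
          class = "vitapath_gpr_parse_error")
  }
  tibble::tibble(token = toks, type = type, pos = as.integer(m))
}

gpr_parse_fail <- function(st, why) {
  pos <- if (st$i <= nrow(st$toks)) st$toks$pos[st$i] else NA_integer_
  at <- if (is.na(pos)) "at end of rule" else sprintf("at position %d", pos)
  abort(sprintf("GPR parse error %s: %s.", at, why), class = "vitapath_gpr_parse_error")
}

gpr_peek <- function(st) if (st$i <= nrow(st$toks)) st$toks$type[st$i] else NA_character_

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(gpr_peek(st)) && gpr_peek(st) == "or") {
    st$i <- st$i + 1L
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1) args[[1]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (!is.na(gpr_peek(st)) && gpr_peek(st) == "and") {
    st$i <- st$i + 1L
    args <- c(args, list(gpr_parse_atom(st)))
  }
  if (length(args) == 1) args[[1]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  tp <- gpr_peek(st)
  if (is.na(tp)) gpr_parse_fail(st, "expected a gene or '('")
  if (tp == "gene") {
    g <- st$toks$token[st$i]
    st$i <- st$i + 1L
    return(list(gene = g))
  }
  if (tp == "lparen") {
    st$i <- st$i + 1L
    inner <- gpr_parse_or(st)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != "rparen") {
      gpr_parse_fail(st, "unbalanced parentheses, expected ')'")
    }
    st$i <- st$i + 1L
    return(inner)
  }
  gpr_parse_fail(st, sprintf("unexpected token '%s'", st$toks$token[st$i]))
}

#' Canonical string form of a GPR tree
#'
#' Parsing the returned string reproduces an identical tree (round trip).
#'
#' @param tree A `gpr` tree from [parse_gpr()].
#' @return A single string, fully parenthesized below the top level.
#' @export
gpr_to_string <- function(tree) {
  render <- function(node, parent_op = NULL) {
    if (!is.null(node$gene)) return(node$gene)
    inner <- vapply(node$args, render, character(1), parent_op = node$op)
    joined <- paste(inner, collapse = paste0(" ", node$op, " "))
    if (is.null(parent_op)) joined else paste0("(", joined, ")")
  }
  render(unclass(tree))
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", gpr_to_string(x), "\n", sep = "")
  invisible(x)
}

#' Evaluate a GPR rule against a set of present genes
#'
#' Standard boolean semantics: a leaf is true iff its gene is in
#' `present_genes`; `and`/`or` combine as usual. Evaluation is monotone —
#' adding genes never flips a reaction from present to absent.
#'
#' @param tree A `gpr` tree (or a rule string, parsed on the fly).
#' @param present_genes Character vector of present gene identifiers.
#' @return Logical scalar: is the reaction catalyzable?
#' @export
evaluate_gpr <- function(tree, present_genes) {
  if (is.character(tree)) tree <- parse_gpr(tree)
  evl <- function(node) {
    if (!is.null(node$gene)) return(node$gene %in% present_genes)
    vals <- vapply(node$args, evl, logical(1))
    if (node$op == "and") all(vals) else any(vals)
  }
  evl(unclass(tree))
}

#' Read GPR models from TSV
#'
#' Dialect: `species<TAB>reaction<TAB>vitamin<TAB>rule`, one reaction per
#' row. An empty rule field marks a reaction whose gene annotation is
#' missing; it still belongs to the pathway (it counts in coverage
#' denominators) but can never evaluate present.
#'
#' @param path Path to the model TSV.
#' @return Tibble `species`, `reaction`, `vitamin`, `rule` (rule `NA` for
#'   annotation-missing reactions). Every rule is checked to parse.
#' @export
read_gpr_models <- function(path) {
  models <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                            progress = FALSE)
  stopifnot(all(c("species", "reaction", "vitamin", "rule") %in% names(models)))
  check_vitamin(unique(models$vitamin))
  models <- dplyr::mutate(models, rule = dplyr::if_else(
    is.na(.data$rule) | !nzchar(trimws(.data$rule)), NA_character_, .data$rule))
  purrr::walk(models$rule[!is.na(models$rule)], parse_gpr)
  models
}

#' Vitamin-pathway coverage of one species
#'
#' Coverage is the fraction of the vitamin's reactions whose GPR rule
#' evaluates true given the species' present genes. Reactions with missing
#' gene annotation count as absent, stay in the denominator, and are
#' reported separately.
#'
#' @param models Model tibble (`species`, `reaction`, `vitamin`, `rule`),
#'   e.g. from [read_gpr_models()] or a synthetic bundle.
#' @param species Species name to score.
#' @param present_genes Character vector of the species' present genes.
#' @param vitamin Vitamin label; the species' model must contain at least
#'   one reaction for it.
#' @return List: `coverage` (fraction in `[0, 1]`), `reactions` (tibble
#'   `reaction`, `present`, `annotation_missing`), `n_missing_annotation`.
#' @export
pathway_coverage <- function(models, species, present_genes, vitamin) {
  check_vitamin(vitamin)
  sub <- models[models$species == species & models$vitamin == vitamin, , drop = FALSE]
  if (nrow(sub) == 0) {
    abort(sprintf("Species '%s' has no %s reactions in the model set.", species, vitamin),
          class = "vitapath_undefined_pathway_error")
  }
  reactions <- tibble::tibble(
    reaction = sub$reaction,
    annotation_missing = is.na(sub$rule),
    present = vapply(seq_len(nrow(sub)), function(i) {
      if (is.na(sub$rule[i])) FALSE else evaluate_gpr(sub$rule[i], present_genes)
    }, logical(1))
  )
  list(
    coverage = mean(reactions$present),
    reactions = reactions,
    n_missing_annotation = sum(reactions$annotation_missing)
  )
}
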