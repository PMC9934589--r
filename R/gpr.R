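# Gene-protein-reaction (GPR) boolean rules.
#
# A rule is a tree of nodes: GENE leaves, and AND/OR internal nodes with at
# least two children after normalization. AND models an enzyme complex
# (limited by its scarcest subunit), OR models isozymes (best available
# alternative), so numeric evaluation is min over AND and max over OR. The
# empty rule is a distinguished sentinel used for reactions with no gene
# association (most exchange and biomass reactions).

gpr_empty <- function() structure(list(kind = "empty"), class = "gpr_rule")

gpr_gene <- function(gene) {
  stopifnot(is.character(gene), length(gene) == 1L, nzchar(gene))
  structure(list(kind = "gene", gene = gene), class = "gpr_rule")
}

# Build an AND/OR node, flattening nested nodes of the same kind and
# collapsing single-child nodes, so normalization invariants hold by
# construction.
gpr_node <- function(kind, children) {
  stopifnot(kind %in% c("and", "or"))
  flat <- list()
  for (ch in children) {
    stopifnot(inherits(ch, "gpr_rule"))
    if (ch$kind == kind) flat <- c(flat, ch$children) else flat <- c(flat, list(ch))
  }
  if (length(flat) == 1L) return(flat[[1L]])
  structure(list(kind = kind, children = flat), class = "gpr_rule")
}

#' Test whether a GPR rule is the empty sentinel
#' @param rule A `gpr_rule`.
#' @return Logical scalar.
#' @export
gpr_is_empty <- function(rule) {
  stopifnot(inherits(rule, "gpr_rule"))
  identical(rule$kind, "empty")
}

#' Genes referenced by a GPR rule
#' @param rule A `gpr_rule`.
#' @return Character vector of unique gene identifiers (empty for the empty
#'   rule).
#' @export
gpr_genes <- function(rule) {
  stopifnot(inherits(rule, "gpr_rule"))
  switch(rule$kind,
    empty = character(0),
    gene  = rule$gene,
    unique(unlist(lapply(rule$children, gpr_genes)))
  )
}

#' Parse a GPR string into a rule tree
#'
#' Grammar: `expr := term ("or" term)*`, `term := factor ("and" factor)*`,
#' `factor := "(" expr ")" | gene`. Keywords are case-insensitive and `and`
#' binds tighter than `or`. Gene tokens are maximal runs of characters other
#' than whitespace and parentheses. Empty or all-whitespace input yields the
#' empty rule.
#'
#' @param text GPR string (may be `NA`, `NULL` or empty).
#' @return A normalized `gpr_rule` tree.
#' @export
#' @examples
#' parse_gpr("g1 and (g2 or g3)")
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0L) return(gpr_empty())
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(gpr_empty())

  # tokenize, keeping source positions for error messages
  toks <- list(); pos <- integer(0)
  i <- 1L; n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- ch; pos <- c(pos, i); i <- i + 1L; next
    }
    j <- i
    while (j <= n && !grepl("^[\\s()]$", substr(text, j, j), perl = TRUE)) j <- j + 1L
    toks[[length(toks) + 1L]] <- substr(text, i, j - 1L)
    pos <- c(pos, i)
    i <- j
  }
  toks <- unlist(toks)
  kind <- ifelse(tolower(toks) == "and", "and",
          ifelse(tolower(toks) == "or", "or",
          ifelse(toks == "(", "lpar", ifelse(toks == ")", "rpar", "gene"))))

  k <- 1L
  peek <- function() if (k <= length(toks)) kind[k] else "eof"
  fail <- function(msg) {
    at <- if (k <= length(toks)) pos[k] else nchar(text) + 1L
    abort_("GPR parse error at position %d: %s (in \"%s\")", at, msg, text,
           class = "tidegem_gpr_parse_error")
  }
  parse_factor <- function() {
    if (peek() == "lpar") {
      k <<- k + 1L
      e <- parse_expr()
      if (peek() != "rpar") fail("expected ')'")
      k <<- k + 1L
      e
    } else if (peek() == "gene") {
      g <- gpr_gene(toks[k]); k <<- k + 1L; g
    } else fail("expected gene or '('")
  }
  parse_term <- function() {
    parts <- list(parse_factor())
    while (peek() == "and") {
      k <<- k + 1L
      parts[[length(parts) + 1L]] <- parse_factor()
    }
    gpr_node("and", parts)
  }
  parse_expr <- function() {
    parts <- list(parse_term())
    while (peek() == "or") {
      k <<- k + 1L
      parts[[length(parts) + 1L]] <- parse_term()
    }
    gpr_node("or", parts)
  }
  out <- parse_expr()
  if (peek() != "eof") fail("unexpected token")
  out
}

#' Render a GPR rule back to a string
#'
#' Inverse of [parse_gpr()] up to normalization: parsing the output
#' reproduces the same tree.
#'
#' @param rule A `gpr_rule`.
#' @return Character scalar ("" for the empty rule).
#' @export
gpr_to_string <- function(rule) {
  stopifnot(inherits(rule, "gpr_rule"))
  switch(rule$kind,
    empty = "",
    gene  = rule$gene,
    and   = paste(vapply(rule$children, function(ch) {
              s <- gpr_to_string(ch)
              if (ch$kind == "or") paste0("(", s, ")") else s
            }, character(1)), collapse = " and "),
    or    = paste(vapply(rule$children, gpr_to_string, character(1)),
                  collapse = " or ")
  )
}

#' Evaluate a GPR rule over per-gene numeric values
#'
#' OR nodes take the maximum of their children, AND nodes the minimum: with
#' log2 fold changes this selects the most extreme isozyme and the limiting
#' complex member; with abundances it gives the capacity of the best isozyme
#' and the scarcest complex subunit.
#'
#' @param rule A `gpr_rule`.
#' @param gene_values Named numeric vector of per-gene values.
#' @param missing One of `"skip"` (drop absent genes from their node; a node
#'   whose children are all absent propagates as missing), `"zero"` (absent
#'   genes count as 0), or `"error"`.
#' @return A numeric scalar, or `NA_real_` when the rule is empty or all its
#'   genes are missing under the skip policy.
#' @export
#' @examples
#' evaluate_gpr(parse_gpr("g1 or g2"), c(g1 = 2, g2 = -1))  # 2
#' evaluate_gpr(parse_gpr("g1 and g2"), c(g1 = 2, g2 = -1)) # -1
evaluate_gpr <- function(rule, gene_values, missing = c("skip", "zero", "error")) {
  missing <- match.arg(missing)
  stopifnot(inherits(rule, "gpr_rule"))
  eval_node <- function(node) {
    if (node$kind == "empty") return(NA_real_)
    if (node$kind == "gene") {
      g <- node$gene
      if (g %in% names(gene_values)) return(unname(gene_values[[g]]))
      return(switch(missing,
        skip  = NA_real_,
        zero  = 0,
        error = abort_("gene '%s' has no value", g,
                       class = "tidegem_missing_gene_error")))
    }
    vals <- vapply(node$children, eval_node, numeric(1))
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) return(NA_real_)
    if (node$kind == "and") min(vals) else max(vals)
  }
  eval_node(rule)
}

#' @export
print.gpr_rule <- function(x, ...) {
  if (gpr_is_empty(x)) cat("<empty GPR>\n") else cat(gpr_to_string(x), "\n")
  invisible(x)
}

#' @export
format.gpr_rule <- function(x, ...) gpr_to_string(x)
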