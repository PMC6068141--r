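# Gene-protein-reaction boolean rules: parsing, serialization, evaluation.
# Grammar (case-insensitive connectives, parentheses bind tightest, "and"
# binds tighter than "or"):
#   expr   := term ("or" term)*
#   term   := factor ("and" factor)*
#   factor := gene | "(" expr ")"

gpr_gene <- function(id) list(kind = "gene", gene = id)

gpr_node <- function(kind, children) {
  # flatten nested nodes of the same kind so AND/OR are n-ary
  flat <- list()
  for (ch in children) {
    if (identical(ch$kind, kind)) flat <- c(flat, ch$children)
    else flat <- c(flat, list(ch))
  }
  if (length(flat) == 1L) return(flat[[1]])
  list(kind = kind, children = flat)
}

gpr_tokenize <- function(rule) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, rule)[[1]]
  if (m[1] == -1L) return(character())
  regmatches(rule, gregexpr(pat, rule))[[1]]
}

#' Parse a gene-association rule string into a boolean tree
#'
#' @param rule string over gene identifiers, parentheses, and the
#'   connectives \code{and}/\code{or} (case-insensitive; the symbolic
#'   forms \code{&}/\code{|} are also accepted).  Empty or all-whitespace
#'   rules give `NULL` (no gene association).
#' @return a GPR tree: `NULL`, a gene leaf, or an n-ary
#'   \code{and}/\code{or} node with at least two children.
#' @examples
#' parse_gpr("(g1 and g2) or g3")
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- gpr_tokenize(rule)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  is_conn <- function(t, what)
    !is.na(t) && (tolower(t) == what || t == switch(what, and = "&", or = "|"))
  err <- function(msg) stop("GPR parse error at token ", pos, " ('",
                            if (is.na(peek())) "<end>" else peek(), "'): ",
                            msg, call. = FALSE)
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) err("expected gene or '('")
    if (t == "(") {
      take()
      e <- parse_expr()
      if (!identical(peek(), ")")) err("expected ')'")
      take()
      return(e)
    }
    if (t == ")" || is_conn(t, "and") || is_conn(t, "or"))
      err("dangling connective or misplaced token")
    gpr_gene(take())
  }
  parse_term <- function() {
    kids <- list(parse_factor())
    while (is_conn(peek(), "and")) { take(); kids <- c(kids, list(parse_factor())) }
    gpr_node("and", kids)
  }
  parse_expr <- function() {
    kids <- list(parse_term())
    while (is_conn(peek(), "or")) { take(); kids <- c(kids, list(parse_term())) }
    gpr_node("or", kids)
  }
  tree <- parse_expr()
  if (!is.na(peek())) err("unexpected trailing input (unbalanced parentheses?)")
  tree
}

#' Serialize a GPR tree back to a rule string
#'
#' Inverse of [parse_gpr()] up to whitespace and redundant parentheses:
#' \code{parse_gpr(serialize_gpr(tree))} reproduces \code{tree}.
#' @param tree a GPR tree (`NULL` gives the empty string).
#' @export
serialize_gpr <- function(tree) {
  if (is.null(tree)) return("")
  if (tree$kind == "gene") return(tree$gene)
  parts <- vapply(tree$children, function(ch) {
    s <- serialize_gpr(ch)
    if (ch$kind != "gene") paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", tree$kind, " "))
}

#' Genes referenced by a GPR tree
#' @param tree a GPR tree.
#' @return character vector of gene ids (unique, in appearance order).
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character())
  if (tree$kind == "gene") return(tree$gene)
  unique(unlist(lapply(tree$children, gpr_genes)))
}

#' Evaluate a GPR tree over per-gene weights
#'
#' AND nodes take the minimum of their children, OR nodes the maximum —
#' an enzyme complex is limited by its least active subunit while
#' isozymes provide the activity of the most active alternative.  An
#' empty rule evaluates to 1 (the reaction is not gene-limited).
#'
#' @param tree a GPR tree.
#' @param weights named numeric vector of gene weights \eqn{W_G \in [0,1]}.
#' @return the reaction weight \eqn{W_R \in [0,1]}.
#' @export
reaction_weight <- function(tree, weights) {
  if (is.null(tree)) return(1)
  if (tree$kind == "gene") {
    if (!tree$gene %in% names(weights))
      stop("no weight for gene '", tree$gene, "'")
    return(unname(weights[[tree$gene]]))
  }
  vals <- vapply(tree$children, reaction_weight, numeric(1),
                 weights = weights)
  if (tree$kind == "and") min(vals) else max(vals)
}
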