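#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene ids with `and` (enzyme
#' complexes) and `or` (isozymes), case-insensitive, with parentheses.
#' An empty or all-whitespace rule yields `NULL` (no gene association).
#'
#' @param rule GPR rule string, e.g. `"(g1 or g2) and g3"`.
#' @return a GPR abstract syntax tree: either `NULL`, a leaf
#'   `list(gene = "id")`, or a node `list(op = "and"|"or", args = list(...))`.
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  cached <- .gpr_cache[[rule]]
  if (!is.null(cached)) return(cached)
  txt <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(txt), "[[:space:]]+")[[1]]
  pos <- 1L

  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }

  parse_atom <- function() {
    t <- take()
    if (is.na(t)) stop("GPR parse error: unexpected end of rule in '", rule, "'")
    if (t == "(") {
      e <- parse_or()
      if (!identical(take(), ")"))
        stop("GPR parse error: unbalanced parentheses in '", rule, "'")
      return(e)
    }
    if (t %in% c(")", "and", "AND", "or", "OR", "And", "Or"))
      stop("GPR parse error: unexpected token '", t, "' in '", rule, "'")
    list(gene = t)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      args <- c(args, list(parse_atom()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      args <- c(args, list(parse_and()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }

  ast <- parse_or()
  if (!is.na(peek()))
    stop("GPR parse error: trailing token '", peek(), "' in '", rule, "'")
  .gpr_cache[[rule]] <- ast
  ast
}

# memoisation cache: rules are re-parsed constantly during network surgery
.gpr_cache <- new.env(parent = emptyenv())

#' Render a GPR tree back to rule text
#'
#' `parse_gpr(render_gpr(ast))` reproduces `ast` exactly.
#'
#' @param ast a GPR tree from [parse_gpr()].
#' @return rule string ("" for `NULL`).
#' @export
render_gpr <- function(ast) {
  if (is.null(ast)) return("")
  if (!is.null(ast$gene)) return(ast$gene)
  parts <- vapply(ast$args, function(a) {
    s <- render_gpr(a)
    if (is.null(a$gene)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", ast$op, " "))
}

#' Genes appearing in a GPR tree
#'
#' @param ast a GPR tree from [parse_gpr()].
#' @return character vector of unique gene ids.
#' @export
gpr_genes <- function(ast) {
  if (is.null(ast)) return(character(0))
  if (!is.null(ast$gene)) return(ast$gene)
  unique(unlist(lapply(ast$args, gpr_genes)))
}

#' Evaluate a GPR tree against numeric gene values
#'
#' The standard reaction-expression mapping: `and` takes the minimum of its
#' children, `or` the maximum. Children without data (`NA`) are ignored as
#' long as at least one child is scored; a rule with no scored leaf at all
#' evaluates to `NA`.
#'
#' @param ast a GPR tree from [parse_gpr()].
#' @param values named numeric vector of gene values; missing genes are `NA`.
#' @param and_fun,or_fun aggregation functions (defaults `min` / `max`).
#' @return a single numeric value or `NA`.
#' @export
eval_gpr_value <- function(ast, values, and_fun = min, or_fun = max) {
  if (is.null(ast)) return(NA_real_)
  if (!is.null(ast$gene)) {
    v <- unname(values[ast$gene])
    return(if (length(v) == 0 || is.na(v)) NA_real_ else v)
  }
  kids <- vapply(ast$args, eval_gpr_value, numeric(1),
                 values = values, and_fun = and_fun, or_fun = or_fun)
  kids <- kids[!is.na(kids)]
  if (!length(kids)) return(NA_real_)
  if (ast$op == "and") and_fun(kids) else or_fun(kids)
}

#' Evaluate a GPR tree as a boolean under gene knockouts
#'
#' Every gene is available (`TRUE`) unless listed in `knocked`. A `NULL`
#' tree (no gene association) evaluates to `TRUE`: reactions without GPR are
#' not silenced by any knockout.
#'
#' @param ast a GPR tree from [parse_gpr()].
#' @param knocked character vector of deleted gene ids.
#' @return logical: can the reaction still be catalyzed?
#' @export
eval_gpr_bool <- function(ast, knocked) {
  if (is.null(ast)) return(TRUE)
  if (!is.null(ast$gene)) return(!(ast$gene %in% knocked))
  kids <- vapply(ast$args, eval_gpr_bool, logical(1), knocked = knocked)
  if (ast$op == "and") all(kids) else any(kids)
}
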