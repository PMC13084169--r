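#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene ids with `and` / `or`
#' (case-insensitive) and parentheses; `and` binds tighter than `or`,
#' the community convention for FBC models. `and` encodes an enzyme
#' complex (all subunits required), `or` isozymes (any suffices).
#'
#' @param text rule string, e.g. `"g1 and (g2 or g3)"`.
#' @return an object of class `"gpr_rule"` with elements `expression`
#'   (nested list tree; leaves are gene-id strings, internal nodes
#'   `list(op = "and"|"or", args = ...)`) and `source_text`.
#' @export
#' @examples
#' parse_gpr("ENSG00000010404")
#' parse_gpr("g1 and (g2 or g3)")
parse_gpr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) stop("empty GPR rule string")
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L
  expr <- gpr_parse_or(st, text)
  if (st$pos <= length(st$toks))
    stop("GPR parse error in '", text, "': unexpected token '",
         st$toks[[st$pos]]$val, "' at position ", st$toks[[st$pos]]$at)
  structure(list(expression = expr, source_text = text),
            class = "gpr_rule")
}

gpr_tokenize <- function(text) {
  toks <- list()
  i <- 1L; n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch, val = ch, at = i)
      i <- i + 1L; next
    }
    m <- regmatches(substr(text, i, n),
                    regexpr("^[^()[:space:]]+", substr(text, i, n)))
    word <- m[[1]]
    type <- switch(tolower(word), "and" = "and", "or" = "or", "gene")
    toks[[length(toks) + 1L]] <- list(type = type, val = word, at = i)
    i <- i + nchar(word)
  }
  toks
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]] else NULL

gpr_parse_or <- function(st, text) {
  args <- list(gpr_parse_and(st, text))
  while (!is.null(tk <- gpr_peek(st)) && tk$type == "or") {
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- gpr_parse_and(st, text)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st, text) {
  args <- list(gpr_parse_atom(st, text))
  while (!is.null(tk <- gpr_peek(st)) && tk$type == "and") {
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- gpr_parse_atom(st, text)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st, text) {
  tk <- gpr_peek(st)
  if (is.null(tk))
    stop("GPR parse error in '", text, "': unexpected end of rule")
  if (tk$type == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st, text)
    cl <- gpr_peek(st)
    if (is.null(cl) || cl$type != ")")
      stop("GPR parse error in '", text,
           "': unbalanced parenthesis opened at position ", tk$at)
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk$type == "gene") {
    st$pos <- st$pos + 1L
    return(tk$val)
  }
  stop("GPR parse error in '", text, "': dangling operator '", tk$val,
       "' at position ", tk$at)
}

#' Genes referenced by a GPR rule
#'
#' @param rule a `gpr_rule` or a raw expression tree.
#' @return character vector of distinct gene ids (leaf order).
#' @export
gpr_genes <- function(rule) {
  expr <- if (inherits(rule, "gpr_rule")) rule$expression else rule
  walk <- function(e) {
    if (is.character(e)) return(e)
    unlist(lapply(e$args, walk))
  }
  unique(walk(expr))
}

#' Evaluate a GPR rule under a gene deletion
#'
#' Leaves evaluate to `FALSE` iff the gene is in `deleted`, `TRUE`
#' otherwise; `and` / `or` are evaluated bottom-up. A `NULL`/empty rule
#' is `TRUE`: a reaction without a GPR is never disabled by a knockout.
#'
#' @param rule a `gpr_rule`, or `NULL` for a reaction without a rule.
#' @param deleted character vector of deleted gene ids.
#' @return logical: is the reaction still catalysable?
#' @export
#' @examples
#' rule_active(parse_gpr("g1 or g2"), "g1")   # isozyme survives
#' rule_active(parse_gpr("g1 and g2"), "g2")  # complex broken
rule_active <- function(rule, deleted) {
  if (is.null(rule)) return(TRUE)
  expr <- if (inherits(rule, "gpr_rule")) rule$expression else rule
  ev <- function(e) {
    if (is.character(e)) return(!(e %in% deleted))
    vals <- vapply(e$args, ev, TRUE)
    if (e$op == "and") all(vals) else any(vals)
  }
  ev(expr)
}

#' Serialize a GPR rule back to text
#'
#' Fully parenthesised, logically equivalent to the source rule.
#'
#' @param rule a `gpr_rule` or raw expression tree.
#' @return rule string.
#' @export
gpr_to_string <- function(rule) {
  expr <- if (inherits(rule, "gpr_rule")) rule$expression else rule
  ser <- function(e) {
    if (is.character(e)) return(e)
    paste0("(", paste(vapply(e$args, ser, ""), collapse = paste0(" ", e$op, " ")), ")")
  }
  ser(expr)
}

#' @export
print.gpr_rule <- function(x, ...) {
  cat("<gpr_rule> ", x$source_text, "\n", sep = "")
  invisible(x)
}
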