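#' Selection mini-language over site tables
#'
#' Selections are boolean expressions over the static site metadata.
#' Supported fields: `site_name`, `residue_name`, `polarity_class`,
#' `chain_label` (string-valued) and `molecule_id`, `chain_position`
#' (integer-valued). Operators: `==`, `!=` for both kinds, `<`, `<=`,
#' `>`, `>=` for integers, `in (v1, v2, ...)` for membership,
#' combined with `&`/`and`, `|`/`or`, `!`/`not` and parentheses. The bare
#' words `all` and `none` select everything / nothing. Values may be bare
#' words (`phosphate`), quoted strings (`"PO4"`), or integers.
#'
#' Parsing is total: every expression either yields an index set or a
#' syntax error naming the character position. Results are returned in
#' ascending `site_id` order, so selections depend on row content only
#' through `site_id`.
#'
#' @param tab a `site_table`.
#' @param expr selection expression string, e.g.
#'   `"polarity_class == phosphate & residue_name != RL"`.
#' @return integer vector of matching `site_id` values (0-based),
#'   ascending; possibly empty.
#' @examples
#' tab <- site_table(c("PO4", "C1"), "PL", 1,
#'                   polarity_class = c("phosphate", "apolar"))
#' select_sites(tab, "polarity_class == phosphate")
#' @export
select_sites <- function(tab, expr) {
  validate_site_table(tab)
  ast <- parse_selection(expr)
  mask <- eval_selection(ast, tab)
  sort(tab$site_id[mask])
}

#' Parse a selection expression
#'
#' @param expr expression string.
#' @return an AST (nested lists); errors carry the offending character
#'   position.
#' @export
parse_selection <- function(expr) {
  if (!is.character(expr) || length(expr) != 1L || is.na(expr))
    stop("selection expression must be a single string")
  toks <- sel_tokenize(expr)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$i <- 1L; st$src <- expr
  ast <- sel_parse_or(st)
  tk <- sel_peek(st)
  if (tk$type != "eof")
    sel_err(st, tk, "unexpected token '", tk$text, "'")
  ast
}

SEL_STR_FIELDS <- c("site_name", "residue_name", "polarity_class",
                    "chain_label")
SEL_INT_FIELDS <- c("molecule_id", "chain_position")

sel_tokenize <- function(expr) {
  toks <- list()
  i <- 1L; n <- nchar(expr)
  push <- function(type, text, pos)
    toks[[length(toks) + 1L]] <<- list(type = type, text = text, pos = pos)
  while (i <= n) {
    ch <- substr(expr, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    rest <- substr(expr, i, n)
    if (ch %in% c("(", ")", ",")) {
      push(ch, ch, i); i <- i + 1L
    } else if (grepl("^(==|!=|<=|>=|<|>)", rest)) {
      op <- regmatches(rest, regexpr("^(==|!=|<=|>=|<|>)", rest))
      push("op", op, i); i <- i + nchar(op)
    } else if (ch == "&") { push("and", "&", i); i <- i + 1L
    } else if (ch == "|") { push("or", "|", i); i <- i + 1L
    } else if (ch == "!") { push("not", "!", i); i <- i + 1L
    } else if (ch == '"' || ch == "'") {
      m <- regexpr(paste0("^", ch, "[^", ch, "]*", ch), rest)
      if (m == -1L)
        stop("selection syntax error at position ", i,
             ": unterminated string")
      s <- regmatches(rest, m)
      push("value", substr(s, 2, nchar(s) - 1L), i)
      i <- i + nchar(s)
    } else if (grepl("^[A-Za-z0-9_.-]", ch)) {
      w <- regmatches(rest, regexpr("^[A-Za-z0-9_.*'-]+", rest))
      lw <- tolower(w)
      if (lw == "and") push("and", w, i)
      else if (lw == "or") push("or", w, i)
      else if (lw == "not") push("not", w, i)
      else if (lw == "in") push("in", w, i)
      else if (lw == "all") push("all", w, i)
      else if (lw == "none") push("none", w, i)
      else if (w %in% c(SEL_STR_FIELDS, SEL_INT_FIELDS)) push("field", w, i)
      else push("value", w, i)
      i <- i + nchar(w)
    } else {
      stop("selection syntax error at position ", i,
           ": unexpected character '", ch, "'")
    }
  }
  push("eof", "", n + 1L)
  toks
}

sel_peek <- function(st) st$toks[[st$i]]
sel_next <- function(st) { tk <- st$toks[[st$i]]; st$i <- st$i + 1L; tk }
sel_err <- function(st, tk, ...)
  stop("selection syntax error at position ", tk$pos, ": ", ...)

sel_parse_or <- function(st) {
  left <- sel_parse_and(st)
  while (sel_peek(st)$type == "or") {
    sel_next(st)
    left <- list(op = "or", left = left, right = sel_parse_and(st))
  }
  left
}

sel_parse_and <- function(st) {
  left <- sel_parse_not(st)
  while (sel_peek(st)$type == "and") {
    sel_next(st)
    left <- list(op = "and", left = left, right = sel_parse_not(st))
  }
  left
}

sel_parse_not <- function(st) {
  if (sel_peek(st)$type == "not") {
    sel_next(st)
    return(list(op = "not", arg = sel_parse_not(st)))
  }
  sel_parse_primary(st)
}

sel_parse_primary <- function(st) {
  tk <- sel_peek(st)
  if (tk$type == "(") {
    sel_next(st)
    inner <- sel_parse_or(st)
    cl <- sel_next(st)
    if (cl$type != ")") sel_err(st, cl, "expected ')'")
    return(inner)
  }
  if (tk$type == "all") { sel_next(st); return(list(op = "all")) }
  if (tk$type == "none") { sel_next(st); return(list(op = "none")) }
  if (tk$type == "field") return(sel_parse_comparison(st))
  if (tk$type == "value")
    sel_err(st, tk, "unknown field '", tk$text, "'")
  sel_err(st, tk, "expected a field, 'all', 'none', '!' or '('")
}

sel_parse_comparison <- function(st) {
  field <- sel_next(st)
  tk <- sel_next(st)
  if (tk$type == "in") {
    op <- sel_next(st)
    if (op$type != "(") sel_err(st, op, "expected '(' after 'in'")
    vals <- list()
    repeat {
      v <- sel_next(st)
      if (!v$type %in% c("value", "field", "all", "none"))
        sel_err(st, v, "expected a value")
      vals[[length(vals) + 1L]] <- v$text
      sep <- sel_next(st)
      if (sep$type == ")") break
      if (sep$type != ",") sel_err(st, sep, "expected ',' or ')'")
    }
    return(list(op = "in", field = field$text, values = unlist(vals),
                pos = field$pos))
  }
  if (tk$type != "op")
    sel_err(st, tk, "expected a comparison operator after '", field$text, "'")
  if (tk$text %in% c("<", "<=", ">", ">=") &&
      !field$text %in% SEL_INT_FIELDS)
    sel_err(st, tk, "ordering comparison not defined for string field '",
            field$text, "'")
  v <- sel_next(st)
  if (!v$type %in% c("value", "field", "all", "none"))
    sel_err(st, v, "expected a value after '", tk$text, "'")
  list(op = "cmp", field = field$text, cmp = tk$text, value = v$text,
       pos = field$pos)
}

sel_field_vals <- function(node, tab) {
  col <- tab[[node$field]]
  if (node$field %in% SEL_INT_FIELDS) {
    val <- suppressWarnings(as.numeric(
      if (is.null(node$values)) node$value else node$values))
    if (any(is.na(val)))
      stop("selection syntax error at position ", node$pos,
           ": field '", node$field, "' needs numeric value(s)")
    list(col = as.numeric(col), val = val)
  } else {
    list(col = as.character(col),
         val = if (is.null(node$values)) node$value else node$values)
  }
}

eval_selection <- function(node, tab) {
  n <- nrow(tab)
  switch(node$op,
    all = rep(TRUE, n),
    none = rep(FALSE, n),
    and = eval_selection(node$left, tab) & eval_selection(node$right, tab),
    or = eval_selection(node$left, tab) | eval_selection(node$right, tab),
    not = !eval_selection(node$arg, tab),
    "in" = {
      fv <- sel_field_vals(node, tab)
      res <- fv$col %in% fv$val
      res & !is.na(fv$col)
    },
    cmp = {
      fv <- sel_field_vals(node, tab)
      res <- switch(node$cmp,
        "==" = fv$col == fv$val,
        "!=" = fv$col != fv$val,
        "<"  = fv$col < fv$val,
        "<=" = fv$col <= fv$val,
        ">"  = fv$col > fv$val,
        ">=" = fv$col >= fv$val)
      # NA metadata (e.g. chain_label on headgroups) never matches
      res[is.na(res)] <- FALSE
      res
    },
    stop("internal: unknown AST node '", node$op, "'")
  )
}
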