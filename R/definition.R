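#' Formal definitions of syntaxa
#'
#' A formal definition is a boolean expression over cover and presence
#' conditions, written in a small formula language:
#'
#' ```
#' expr  := or
#' or    := and ("OR" and)*
#' and   := unary ("AND" unary)*
#' unary := "NOT" unary | "(" expr ")" | atom
#' atom  := ("TC" | "SC") "(" name ")" (">" | ">=") number
#'        | "COV" "(" taxon ")" (">" | ">=") number
#'        | "SOC" "(" name ")"
#' ```
#'
#' `TC`/`SC`/`SOC` reference named [species_group()]s of matching kind;
#' `COV` compares the cover of a single taxon. Thresholds are percentages in
#' `[0, 100]`. Keywords are case-insensitive; group and taxon names run to
#' the closing parenthesis.
#'
#' @param text formula string.
#' @param groups named list of [species_group()]s ([read_species_groups()]).
#' @return an object of class `cocktail_definition` (the parsed expression
#'   tree with all group references resolved).
#' @examples
#' reg <- list(Ref = species_group("Ref", "TC", c("Carex bohemica")))
#' d <- parse_definition("TC(Ref) > 25 AND NOT COV(Juncus bufonius) >= 50",
#'                       reg)
#' @export
parse_definition <- function(text, groups) {
  stopifnot(is.character(text), length(text) == 1L)
  st <- new.env(parent = emptyenv())
  st$s <- text
  st$pos <- 1L
  ast <- p_expr(st, groups)
  p_skip_ws(st)
  if (st$pos <= nchar(st$s)) {
    stop("syntax error at position ", st$pos, " in formula: unexpected '",
         substr(st$s, st$pos, min(nchar(st$s), st$pos + 15L)), "'")
  }
  structure(ast, class = "cocktail_definition")
}

# --- recursive-descent parser ------------------------------------------------

p_skip_ws <- function(st) {
  while (st$pos <= nchar(st$s) &&
         grepl("^\\s$", substr(st$s, st$pos, st$pos))) {
    st$pos <- st$pos + 1L
  }
}

p_peek_word <- function(st) {
  p_skip_ws(st)
  m <- regmatches(substr(st$s, st$pos, nchar(st$s)),
                  regexpr("^[A-Za-z]+", substr(st$s, st$pos, nchar(st$s))))
  if (length(m)) toupper(m) else ""
}

p_take_word <- function(st) {
  w <- p_peek_word(st)
  st$pos <- st$pos + nchar(w)
  w
}

p_expect <- function(st, ch) {
  p_skip_ws(st)
  if (substr(st$s, st$pos, st$pos + nchar(ch) - 1L) != ch) {
    stop("syntax error at position ", st$pos, ": expected '", ch, "'")
  }
  st$pos <- st$pos + nchar(ch)
}

p_expr <- function(st, groups) {
  left <- p_and(st, groups)
  args <- list(left)
  while (p_peek_word(st) == "OR") {
    p_take_word(st)
    args <- c(args, list(p_and(st, groups)))
  }
  if (length(args) == 1L) left else list(op = "or", args = args)
}

p_and <- function(st, groups) {
  left <- p_unary(st, groups)
  args <- list(left)
  while (p_peek_word(st) == "AND") {
    p_take_word(st)
    args <- c(args, list(p_unary(st, groups)))
  }
  if (length(args) == 1L) left else list(op = "and", args = args)
}

p_unary <- function(st, groups) {
  w <- p_peek_word(st)
  if (w == "NOT") {
    p_take_word(st)
    return(list(op = "not", args = list(p_unary(st, groups))))
  }
  p_skip_ws(st)
  if (substr(st$s, st$pos, st$pos) == "(") {
    p_expect(st, "(")
    e <- p_expr(st, groups)
    p_expect(st, ")")
    return(e)
  }
  p_atom(st, groups)
}

p_name <- function(st) {
  p_expect(st, "(")
  rest <- substr(st$s, st$pos, nchar(st$s))
  close <- regexpr(")", rest, fixed = TRUE)
  if (close < 0) stop("syntax error at position ", st$pos, ": missing ')'")
  nm <- trimws(substr(rest, 1L, close - 1L))
  if (!nchar(nm)) stop("syntax error at position ", st$pos, ": empty name")
  st$pos <- st$pos + close
  nm
}

p_cmp <- function(st) {
  p_skip_ws(st)
  two <- substr(st$s, st$pos, st$pos + 1L)
  if (two == ">=") {
    st$pos <- st$pos + 2L
    return(">=")
  }
  if (substr(st$s, st$pos, st$pos) == ">") {
    st$pos <- st$pos + 1L
    return(">")
  }
  stop("syntax error at position ", st$pos, ": expected '>' or '>='")
}

p_number <- function(st) {
  p_skip_ws(st)
  rest <- substr(st$s, st$pos, nchar(st$s))
  m <- regmatches(rest, regexpr("^[0-9]+(\\.[0-9]+)?", rest))
  if (!length(m)) {
    stop("syntax error at position ", st$pos, ": expected a number")
  }
  st$pos <- st$pos + nchar(m)
  v <- as.numeric(m)
  if (v < 0 || v > 100) stop("threshold must be in [0, 100]: ", v)
  v
}

p_atom <- function(st, groups) {
  w <- p_take_word(st)
  if (w %in% c("TC", "SC")) {
    nm <- p_name(st)
    grp <- find_group(groups, nm)
    if (grp$kind != w) {
      stop("group '", nm, "' has kind ", grp$kind, ", not ", w)
    }
    cmp <- p_cmp(st)
    thr <- p_number(st)
    return(list(op = tolower(w), group = grp, cmp = cmp, threshold = thr))
  }
  if (w == "COV") {
    nm <- p_name(st)
    cmp <- p_cmp(st)
    thr <- p_number(st)
    return(list(op = "cov", taxon = nm, norm_taxon = normalize_name(nm),
                cmp = cmp, threshold = thr))
  }
  if (w == "SOC") {
    nm <- p_name(st)
    grp <- find_group(groups, nm)
    if (grp$kind != "SOC") {
      stop("group '", nm, "' has kind ", grp$kind, ", not SOC")
    }
    return(list(op = "soc", group = grp))
  }
  stop("syntax error at position ", st$pos,
       ": expected TC, SC, COV, SOC, NOT or '('")
}

# --- evaluation --------------------------------------------------------------

#' Evaluate a formal definition on a releve
#'
#' @param defn a [parse_definition()] result.
#' @param cover named cover-fraction vector of one plot
#'   ([releve_cover()] / [plot_covers()]).
#' @return logical: does the releve satisfy the definition?
#' @export
evaluate <- function(defn, cover) {
  eval_node(unclass(defn), cover)
}

eval_node <- function(node, cover) {
  switch(node$op,
    and = all(vapply(node$args, eval_node, logical(1), cover = cover)),
    or  = any(vapply(node$args, eval_node, logical(1), cover = cover)),
    not = !eval_node(node$args[[1]], cover),
    tc  = cmp_apply(total_cover(cover, node$group), node$cmp, node$threshold),
    sc  = cmp_apply(max_single_cover(cover, node$group), node$cmp,
                    node$threshold),
    cov = {
      v <- cover[node$norm_taxon]
      v <- if (is.na(v)) 0 else 100 * unname(v)
      cmp_apply(v, node$cmp, node$threshold)
    },
    soc = sociological_presence(cover, node$group),
    stop("unknown node op: ", node$op)
  )
}

cmp_apply <- function(value, cmp, threshold) {
  if (cmp == ">") value > threshold else value >= threshold
}

#' @export
format.cocktail_definition <- function(x, ...) {
  fmt_node(unclass(x), top = TRUE)
}

fmt_node <- function(node, top = FALSE) {
  wrap <- function(s) if (top) s else paste0("(", s, ")")
  switch(node$op,
    and = wrap(paste(vapply(node$args, fmt_node, character(1)),
                     collapse = " AND ")),
    or  = wrap(paste(vapply(node$args, fmt_node, character(1)),
                     collapse = " OR ")),
    not = paste0("NOT ", fmt_node(node$args[[1]])),
    tc  = sprintf("TC(%s) %s %g", node$group$name, node$cmp, node$threshold),
    sc  = sprintf("SC(%s) %s %g", node$group$name, node$cmp, node$threshold),
    cov = sprintf("COV(%s) %s %g", node$taxon, node$cmp, node$threshold),
    soc = sprintf("SOC(%s)", node$group$name)
  )
}

#' @export
print.cocktail_definition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
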