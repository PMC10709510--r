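#' Parse a decision-tree rule table
#'
#' Rules map a cell's cover vector to a vegetation type.  Each rule is a
#' boolean expression over species covers in a small grammar:
#'
#' ```
#' expr     := term { OR term }
#' term     := atom { AND atom }
#' atom     := '(' expr ')' | condition
#' condition:= species_id comparator number
#' comparator := '<' | '>' | '<=' | '>='
#' ```
#'
#' Species IDs may contain letters, digits, dots and underscores; thresholds
#' are percent cover in `[0,100]`.  Rules are evaluated in order and the first
#' satisfied rule assigns its type; the ruleset ends with a default type for
#' cells matching no rule.  Comparators are exactly as written — no implicit
#' tolerance, so `A > 50` is not satisfied at `A = 50`.
#'
#' @param table data.frame with columns `order`, `expression`, `type_id`.
#' @param default_type type assigned when no rule matches.
#' @param species_ids optional character vector of known species for
#'   validation.
#' @return object of class `veg_ruleset`.
#' @export
parse_ruleset <- function(table, default_type, species_ids = NULL) {
  if (!nrow(table)) stop("empty rule table (and no default rule)")
  req <- c("order", "expression", "type_id")
  if (length(setdiff(req, names(table))))
    stop("rule table needs columns ", paste(req, collapse = ", "))
  if (anyDuplicated(table$order))
    stop("duplicate order keys in rule table")
  table <- table[order(table$order), , drop = FALSE]
  rules <- vector("list", nrow(table))
  for (i in seq_len(nrow(table))) {
    expr <- tryCatch(parse_rule_expression(table$expression[i]),
                     error = function(e)
                       stop("rule ", table$order[i], " (line ", i, "): ",
                            conditionMessage(e), call. = FALSE))
    if (!is.null(species_ids)) {
      used <- rule_species(expr)
      unknown <- setdiff(used, species_ids)
      if (length(unknown))
        stop("rule ", table$order[i], " references unknown species: ",
             paste(unknown, collapse = ", "))
    }
    rules[[i]] <- list(order = table$order[i], expr = expr,
                       text = table$expression[i],
                       type_id = as.character(table$type_id[i]))
  }
  structure(list(rules = rules, default_type = as.character(default_type)),
            class = "veg_ruleset")
}

# Recursive-descent parser for the rule mini-grammar.
parse_rule_expression <- function(text) {
  toks <- tokenize_rule(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_expr <- function() {
    node <- parse_term()
    while (!is.null(peek()) && identical(peek()$type, "OR")) {
      take()
      node <- list(op = "OR", lhs = node, rhs = parse_term())
    }
    node
  }
  parse_term <- function() {
    node <- parse_atom()
    while (!is.null(peek()) && identical(peek()$type, "AND")) {
      take()
      node <- list(op = "AND", lhs = node, rhs = parse_atom())
    }
    node
  }
  parse_atom <- function() {
    t <- peek()
    if (is.null(t)) stop("unexpected end of expression")
    if (t$type == "LPAR") {
      take()
      node <- parse_expr()
      if (is.null(peek()) || peek()$type != "RPAR")
        stop("missing closing parenthesis")
      take()
      return(node)
    }
    if (t$type != "ID") stop("expected species name, got '", t$value, "'")
    take()
    cmp <- take()
    if (is.null(cmp) || cmp$type != "CMP")
      stop("expected comparator after '", t$value, "'")
    num <- take()
    if (is.null(num) || num$type != "NUM")
      stop("expected numeric threshold after '", cmp$value, "'")
    thr <- as.numeric(num$value)
    if (thr < 0 || thr > 100) stop("threshold out of [0,100]: ", thr)
    list(op = "cond", species = t$value, cmp = cmp$value, threshold = thr)
  }
  node <- parse_expr()
  if (!is.null(peek())) stop("trailing input: '", peek()$value, "'")
  node
}

tokenize_rule <- function(text) {
  pat <- "\\s*(<=|>=|<|>|\\(|\\)|AND|OR|[A-Za-z][A-Za-z0-9._]*|[0-9]+\\.?[0-9]*)"
  toks <- list()
  rest <- text
  while (nchar(trimws(rest))) {
    m <- regmatches(rest, regexpr(paste0("^", pat), rest))[[1]]
    if (!length(m)) stop("syntax error near '", substr(trimws(rest), 1, 12), "'")
    v <- trimws(m)
    type <- if (v %in% c("AND", "OR")) v
      else if (v %in% c("<", ">", "<=", ">=")) "CMP"
      else if (v == "(") "LPAR" else if (v == ")") "RPAR"
      else if (grepl("^[0-9]", v)) "NUM" else "ID"
    toks[[length(toks) + 1L]] <- list(type = type, value = v)
    rest <- substr(rest, nchar(m) + 1, nchar(rest))
  }
  toks
}

rule_species <- function(node) {
  if (node$op == "cond") return(node$species)
  c(rule_species(node$lhs), rule_species(node$rhs))
}

# Evaluate one rule node against a cover matrix (cells x species).
eval_rule <- function(node, cover) {
  if (node$op == "cond") {
    v <- if (node$species %in% colnames(cover)) cover[, node$species] else
      rep(0, nrow(cover))
    return(switch(node$cmp,
                  "<" = v < node$threshold, ">" = v > node$threshold,
                  "<=" = v <= node$threshold, ">=" = v >= node$threshold))
  }
  l <- eval_rule(node$lhs, cover)
  r <- eval_rule(node$rhs, cover)
  if (node$op == "AND") l & r else l | r
}

#' Classify a cover vector
#'
#' Returns the type of the first satisfied rule, or the default type.  Pure
#' function of the cover vector and the ruleset.
#'
#' @param cover named numeric of percent cover (absent species count as 0).
#' @param ruleset a `veg_ruleset`.
#' @return a type ID.
#' @export
classify_cover <- function(cover, ruleset) {
  mat <- matrix(cover, 1, dimnames = list(NULL, names(cover)))
  for (rule in ruleset$rules)
    if (eval_rule(rule$expr, mat)) return(rule$type_id)
  ruleset$default_type
}

#' Classify all modeled cells of a grid
#'
#' @param grid a `veg_grid`.
#' @param ruleset a `veg_ruleset`.
#' @return the grid with refreshed `veg_type` for modeled cells.
#' @export
classify_grid <- function(grid, ruleset) {
  m <- grid$modeled
  assigned <- rep(NA_character_, grid$n_cells)
  open <- m
  for (rule in ruleset$rules) {
    if (!any(open)) break
    hit <- open
    hit[open] <- eval_rule(rule$expr, grid$cover[open, , drop = FALSE])
    assigned[hit] <- rule$type_id
    open <- open & !hit
  }
  assigned[open] <- ruleset$default_type
  grid$veg_type[m] <- assigned[m]
  grid
}

#' Serialise a ruleset back to its table form
#'
#' Round-trips through [parse_ruleset()].
#'
#' @param ruleset a `veg_ruleset`.
#' @return data.frame with columns `order`, `expression`, `type_id`.
#' @export
format_ruleset <- function(ruleset) {
  data.frame(order = vapply(ruleset$rules, function(r) r$order, numeric(1)),
             expression = vapply(ruleset$rules, function(r)
               deparse_rule(r$expr), character(1)),
             type_id = vapply(ruleset$rules, function(r) r$type_id,
                              character(1)),
             stringsAsFactors = FALSE)
}

deparse_rule <- function(node, parent = "") {
  if (node$op == "cond")
    return(paste0(node$species, " ", node$cmp, " ", node$threshold))
  s <- paste(deparse_rule(node$lhs, node$op), node$op,
             deparse_rule(node$rhs, node$op))
  if (parent != "" && parent != node$op) paste0("(", s, ")") else s
}
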