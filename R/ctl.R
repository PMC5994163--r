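#' Computation Tree Logic formulas
#'
#' CTL formulas are represented as abstract syntax trees built from atoms
#' comparing an entity's level against a constant, boolean connectives, and
#' the eight path-state quantifier combinations \code{EX AX EF AF EG AG}
#' and \code{E[. U .]}, \code{A[. U .]}. Construct them with the
#' \code{ctl_*} helpers or parse them from text with \code{\link{parse_ctl}}.
#'
#' @param entity entity name the atom refers to.
#' @param rel one of \code{"="}, \code{"!="}, \code{"<="}, \code{">="}.
#' @param level integer level compared against.
#' @param f,g sub-formulas.
#' @return an object of class \code{ctl_formula}.
#' @name ctl_formula
NULL

ctl_node <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "ctl_formula")
}

#' @rdname ctl_formula
#' @export
ctl_atom <- function(entity, rel = "=", level = 1L) {
  stopifnot(rel %in% c("=", "!=", "<=", ">="))
  ctl_node("atom", entity = entity, rel = rel, level = as.integer(level))
}

#' @rdname ctl_formula
#' @export
ctl_true <- function() ctl_node("true")

#' @rdname ctl_formula
#' @export
ctl_false <- function() ctl_node("false")

#' @rdname ctl_formula
#' @export
ctl_not <- function(f) ctl_node("not", sub = f)

#' @rdname ctl_formula
#' @export
ctl_and <- function(f, g) ctl_node("and", lhs = f, rhs = g)

#' @rdname ctl_formula
#' @export
ctl_or <- function(f, g) ctl_node("or", lhs = f, rhs = g)

#' @rdname ctl_formula
#' @export
ctl_implies <- function(f, g) ctl_node("implies", lhs = f, rhs = g)

#' @rdname ctl_formula
#' @export
ctl_EX <- function(f) ctl_node("EX", sub = f)

#' @rdname ctl_formula
#' @export
ctl_AX <- function(f) ctl_node("AX", sub = f)

#' @rdname ctl_formula
#' @export
ctl_EF <- function(f) ctl_node("EF", sub = f)

#' @rdname ctl_formula
#' @export
ctl_AF <- function(f) ctl_node("AF", sub = f)

#' @rdname ctl_formula
#' @export
ctl_EG <- function(f) ctl_node("EG", sub = f)

#' @rdname ctl_formula
#' @export
ctl_AG <- function(f) ctl_node("AG", sub = f)

#' @rdname ctl_formula
#' @export
ctl_EU <- function(f, g) ctl_node("EU", lhs = f, rhs = g)

#' @rdname ctl_formula
#' @export
ctl_AU <- function(f, g) ctl_node("AU", lhs = f, rhs = g)

#' Render a CTL formula as text
#'
#' @param f a \code{ctl_formula}.
#' @return a single string in the grammar accepted by \code{\link{parse_ctl}}.
#' @export
ctl_text <- function(f) {
  switch(f$kind,
    true = "TRUE",
    false = "FALSE",
    atom = paste0(f$entity, f$rel, f$level),
    not = paste0("!(", ctl_text(f$sub), ")"),
    and = paste0("(", ctl_text(f$lhs), " & ", ctl_text(f$rhs), ")"),
    or = paste0("(", ctl_text(f$lhs), " | ", ctl_text(f$rhs), ")"),
    implies = paste0("(", ctl_text(f$lhs), " -> ", ctl_text(f$rhs), ")"),
    EX = , AX = , EF = , AF = , EG = , AG =
      paste0(f$kind, "(", ctl_text(f$sub), ")"),
    EU = paste0("E[", ctl_text(f$lhs), " U ", ctl_text(f$rhs), "]"),
    AU = paste0("A[", ctl_text(f$lhs), " U ", ctl_text(f$rhs), "]"),
    stop("unknown CTL node kind: ", f$kind))
}

#' @export
print.ctl_formula <- function(x, ...) {
  cat(ctl_text(x), "\n")
  invisible(x)
}

check_atom <- function(graph, f) {
  i <- match(f$entity, colnames(graph$states))
  if (is.na(i))
    stop("formula atom references unknown entity: ", f$entity)
  ml <- graph$entities$max_level[match(f$entity, graph$entities$name)]
  if (f$level < 0L || f$level > ml)
    stop("atom level out of range for ", f$entity, ": ", f$level)
  lev <- graph$states[, i]
  switch(f$rel,
         "=" = lev == f$level,
         "!=" = lev != f$level,
         "<=" = lev <= f$level,
         ">=" = lev >= f$level)
}

#' Model-check a CTL formula on a state graph
#'
#' Standard explicit-state fixed-point labelling: existential/universal
#' next-state operators are evaluated over the successor lists, \code{EF AF
#' EU AU} as least fixed points and \code{EG AG} as greatest fixed points.
#' The transition relation is total (deadlocks carry self-loops), so all
#' operators are well defined.
#'
#' @param graph a \code{state_graph}.
#' @param formula a \code{ctl_formula}.
#' @return logical vector, one entry per state row, \code{TRUE} where the
#'   formula holds.
#' @examples
#' toy <- toy_fixture()
#' g <- build_state_graph(toy$network, toy$params)
#' ctl_check(g, ctl_EF(ctl_and(ctl_atom("X", "=", 0), ctl_atom("Y", "=", 0))))
#' @export
ctl_check <- function(graph, formula) {
  adj <- graph$adj
  some_succ <- function(set) vapply(adj, function(s) any(set[s]), logical(1))
  all_succ <- function(set) vapply(adj, function(s) all(set[s]), logical(1))
  lfp <- function(base, grow) {
    cur <- base
    repeat {
      nxt <- cur | grow(cur)
      if (identical(nxt, cur)) return(cur)
      cur <- nxt
    }
  }
  gfp <- function(base, keep) {
    cur <- base
    repeat {
      nxt <- cur & keep(cur)
      if (identical(nxt, cur)) return(cur)
      cur <- nxt
    }
  }
  ev <- function(f) {
    switch(f$kind,
      true = rep(TRUE, nrow(graph$states)),
      false = rep(FALSE, nrow(graph$states)),
      atom = check_atom(graph, f),
      not = !ev(f$sub),
      and = ev(f$lhs) & ev(f$rhs),
      or = ev(f$lhs) | ev(f$rhs),
      implies = !ev(f$lhs) | ev(f$rhs),
      EX = some_succ(ev(f$sub)),
      AX = all_succ(ev(f$sub)),
      EF = lfp(ev(f$sub), some_succ),
      AF = lfp(ev(f$sub), all_succ),
      EG = gfp(ev(f$sub), some_succ),
      AG = gfp(ev(f$sub), all_succ),
      EU = {
        a <- ev(f$lhs); b <- ev(f$rhs)
        lfp(b, function(cur) a & some_succ(cur))
      },
      AU = {
        a <- ev(f$lhs); b <- ev(f$rhs)
        lfp(b, function(cur) a & all_succ(cur))
      },
      stop("unknown CTL node kind: ", f$kind))
  }
  ev(formula)
}

#' Does a model satisfy a formula in every state?
#'
#' Model acceptance follows the all-states convention used when selecting
#' parameter tables: a state graph satisfies a formula iff the formula holds
#' in every state (equivalently, checking with every state initial).
#'
#' @inheritParams ctl_check
#' @return single logical.
#' @export
ctl_satisfies <- function(graph, formula) {
  all(ctl_check(graph, formula))
}

## ---- formula parser -------------------------------------------------------

ctl_tokenize <- function(text) {
  pats <- c(ws = "\\s+", op = "->|!=|<=|>=|=|!|&|\\||\\(|\\)|\\[|\\]",
            num = "[0-9]+", id = "[A-Za-z_][A-Za-z0-9_.-]*")
  toks <- list()
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    hit <- FALSE
    for (k in names(pats)) {
      m <- regexpr(paste0("^(", pats[[k]], ")"), substr(text, pos, n))
      if (m == 1L) {
        len <- attr(m, "match.length")
        if (k != "ws")
          toks[[length(toks) + 1L]] <-
            list(kind = k, text = substr(text, pos, pos + len - 1L))
        pos <- pos + len
        hit <- TRUE
        break
      }
    }
    if (!hit)
      stop("CTL syntax error at position ", pos, ": ",
           substr(text, pos, min(n, pos + 10L)))
  }
  toks
}

#' Parse a CTL formula from text
#'
#' Grammar: atoms \code{name=level} (also \code{!=}, \code{<=}, \code{>=});
#' connectives \code{!}, \code{&}, \code{|}, \code{->} (right-associative,
#' loosest); quantifiers \code{EX AX EF AF EG AG} and
#' \code{E[f U g]}, \code{A[f U g]}; parentheses; \code{TRUE}/\code{FALSE}.
#'
#' @param text formula string.
#' @return a \code{ctl_formula}.
#' @examples
#' parse_ctl("EF(AG(Myc=1))")
#' parse_ctl("X=0 & Y=0 -> EX(EF(X=0 & Y=0))")
#' @export
parse_ctl <- function(text) {
  toks <- ctl_tokenize(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  take <- function(txt = NULL) {
    t <- peek()
    if (is.null(t)) stop("CTL syntax error: unexpected end of formula")
    if (!is.null(txt) && t$text != txt)
      stop("CTL syntax error: expected '", txt, "' but found '", t$text, "'")
    pos <<- pos + 1L
    t
  }
  parse_implies <- function() {
    lhs <- parse_or()
    if (!is.null(peek()) && peek()$text == "->") {
      take("->")
      return(ctl_implies(lhs, parse_implies()))  # right-associative
    }
    lhs
  }
  parse_or <- function() {
    lhs <- parse_and()
    while (!is.null(peek()) && peek()$text == "|") {
      take("|")
      lhs <- ctl_or(lhs, parse_and())
    }
    lhs
  }
  parse_and <- function() {
    lhs <- parse_unary()
    while (!is.null(peek()) && peek()$text == "&") {
      take("&")
      lhs <- ctl_and(lhs, parse_unary())
    }
    lhs
  }
  quantifiers <- c("EX", "AX", "EF", "AF", "EG", "AG")
  parse_unary <- function() {
    t <- peek()
    if (is.null(t)) stop("CTL syntax error: unexpected end of formula")
    if (t$text == "!") {
      take("!")
      return(ctl_not(parse_unary()))
    }
    if (t$kind == "id" && t$text %in% quantifiers) {
      take()
      return(ctl_node(t$text, sub = parse_unary()))
    }
    if (t$kind == "id" && t$text %in% c("E", "A") &&
        pos < length(toks) && toks[[pos + 1L]]$text == "[") {
      take(); take("[")
      lhs <- parse_implies()
      u <- take()
      if (u$text != "U")
        stop("CTL syntax error: expected 'U' inside ", t$text, "[ ... ]")
      rhs <- parse_implies()
      take("]")
      return(if (t$text == "E") ctl_EU(lhs, rhs) else ctl_AU(lhs, rhs))
    }
    parse_primary()
  }
  parse_primary <- function() {
    t <- take()
    if (t$text == "(") {
      f <- parse_implies()
      take(")")
      return(f)
    }
    if (t$kind == "id") {
      if (t$text %in% c("TRUE", "true")) return(ctl_true())
      if (t$text %in% c("FALSE", "false")) return(ctl_false())
      rel <- take()
      if (!rel$text %in% c("=", "!=", "<=", ">="))
        stop("CTL syntax error: expected a relation after '", t$text, "'")
      lv <- take()
      if (lv$kind != "num")
        stop("CTL syntax error: expected a level after '", rel$text, "'")
      return(ctl_atom(t$text, rel$text, as.integer(lv$text)))
    }
    stop("CTL syntax error: unexpected token '", t$text, "'")
  }
  f <- parse_implies()
  if (!is.null(peek()))
    stop("CTL syntax error: trailing input at '", peek()$text, "'")
  f
}

## ---- the shipped property library ----------------------------------------

#' The five circadian/cell-cycle CTL properties
#'
#' Named library of the temporal-logic observations used to select the
#' K-parameters of the clock/MYC/p53 model:
#' \describe{
#'   \item{psi1}{homeostasis: from the initial resting state
#'     (\code{CB=0, PC=0, Rev=0, Myc=0, p53=0}; \code{Bmal} is left free)
#'     every immediate successor can return to it.}
#'   \item{psi2}{the clock keeps revisiting its trough while \code{Myc} can
#'     become persistently high with \code{p53} off.}
#'   \item{psi3}{if \code{p53} can reach its normal level and \code{Myc} can
#'     be shut off, then along some path \code{p53} stays at 0 until it
#'     rises to 1 (the until is the existential \code{E[. U .]}).}
#'   \item{psi4}{\code{Myc} over-expression is reachable:
#'     \code{EF(EG Myc=1)}.}
#'   \item{psi5}{\code{p53} suppression is reachable: \code{EF(EG p53=0)}.}
#' }
#'
#' Persistent (over-)expression is encoded with the existential globally
#' operator \code{EG} — the same idiom psi2 uses for the identical
#' condition on Myc and p53 — because asynchronous dynamics always keep a
#' path on which a poised antagonist fires, so the universal \code{AG}
#' variant of a persistence claim is unsatisfiable in this network for
#' every admissible parameter table. Set \code{universal = TRUE} to obtain
#' that \code{AG} variant of psi4/psi5 anyway (useful to verify the
#' unsatisfiability).
#'
#' @param universal logical; use \code{AG} instead of \code{EG} in
#'   psi4/psi5.
#' @return named list of five \code{ctl_formula} objects plus
#'   \code{psi_all}, their conjunction.
#' @export
psi_library <- function(universal = FALSE) {
  a <- function(e, l) ctl_atom(e, "=", l)
  init <- Reduce(ctl_and, list(a("CB", 0), a("PC", 0), a("Rev", 0),
                               a("Myc", 0), a("p53", 0)))
  clock0 <- Reduce(ctl_and, list(a("Bmal", 0), a("CB", 0), a("PC", 0),
                                 a("Rev", 0)))
  G <- if (universal) ctl_AG else ctl_EG
  psi1 <- ctl_implies(init, ctl_AX(ctl_EF(init)))
  psi2 <- ctl_implies(
    ctl_EF(clock0),
    ctl_and(ctl_EX(ctl_EF(clock0)),
            ctl_EF(ctl_EG(ctl_and(a("Myc", 1), a("p53", 0))))))
  psi3 <- ctl_implies(
    ctl_EF(a("p53", 1)),
    ctl_implies(ctl_EF(a("Myc", 0)),
                ctl_EU(a("p53", 0), a("p53", 1))))
  psi4 <- ctl_EF(G(a("Myc", 1)))
  psi5 <- ctl_EF(G(a("p53", 0)))
  psi_all <- Reduce(ctl_and, list(psi1, psi2, psi3, psi4, psi5))
  list(psi1 = psi1, psi2 = psi2, psi3 = psi3, psi4 = psi4, psi5 = psi5,
       psi_all = psi_all)
}
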