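#' Parse a temporal-logic formula
#'
#' Grammar (precedence low to high: `|`, `&`, prefixes):
#' \preformatted{
#' formula  := conj ('|' conj)*
#' conj     := unary ('&' unary)*
#' unary    := '!' unary
#'           | 'EF' '(' formula ')'   # some reachable state satisfies
#'           | 'AG' '(' formula ')'   # all reachable states satisfy
#'           | 'EX' '(' formula ')'   # some immediate successor satisfies
#'           | '<' labels '>' unary   # some transition in the label set
#'           | '[' labels ']' unary   # all transitions in the label set
#'           | 'tt' | 'ff' | '(' formula ')'
#' labels   := label (',' label)*
#' }
#' Labels are action names such as `H_contrast` and may use `*` wildcards
#' over the level or feature part (`H_*`, `*_contrast`). They are resolved
#' against the model alphabet at check time, not at parse time.
#'
#' @param text A formula string, e.g.
#'   `"EF(<H_contrast>tt & <L_id>tt)"`.
#' @return An object of class `acdx_formula` (an AST).
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  toks <- tokenize_formula(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L; st$text <- text
  f <- p_formula(st)
  if (st$pos <= length(st$toks))
    stop("syntax error at position ", st$toks[[st$pos]]$at,
         ": unexpected `", st$toks[[st$pos]]$v, "`", call. = FALSE)
  structure(f, class = "acdx_formula")
}

tokenize_formula <- function(text) {
  toks <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")", "<", ">", "[", "]", "&", "|", "!", ",")) {
      toks[[length(toks) + 1L]] <- list(t = ch, v = ch, at = i)
      i <- i + 1L
      next
    }
    m <- regmatches(substr(text, i, n),
                    regexpr("^[A-Za-z*][A-Za-z0-9_*]*", substr(text, i, n)))
    if (length(m) == 0)
      stop("syntax error at position ", i, ": unexpected `", ch, "`",
           call. = FALSE)
    toks[[length(toks) + 1L]] <- list(t = "name", v = m, at = i)
    i <- i + nchar(m)
  }
  toks
}

peek <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]] else NULL
advance <- function(st) { t <- peek(st); st$pos <- st$pos + 1L; t }
expect <- function(st, type) {
  t <- peek(st)
  if (is.null(t) || t$t != type)
    stop("syntax error at position ",
         if (is.null(t)) nchar(st$text) + 1 else t$at,
         ": expected `", type, "`", call. = FALSE)
  advance(st)
}

p_formula <- function(st) {
  f <- p_conj(st)
  while (!is.null(peek(st)) && peek(st)$t == "|") {
    advance(st)
    f <- list(op = "or", lhs = f, rhs = p_conj(st))
  }
  f
}

p_conj <- function(st) {
  f <- p_unary(st)
  while (!is.null(peek(st)) && peek(st)$t == "&") {
    advance(st)
    f <- list(op = "and", lhs = f, rhs = p_unary(st))
  }
  f
}

p_labels <- function(st) {
  labs <- expect(st, "name")$v
  while (!is.null(peek(st)) && peek(st)$t == ",") {
    advance(st)
    labs <- c(labs, expect(st, "name")$v)
  }
  labs
}

p_unary <- function(st) {
  t <- peek(st)
  if (is.null(t))
    stop("syntax error at position ", nchar(st$text) + 1,
         ": unexpected end of formula", call. = FALSE)
  if (t$t == "!") { advance(st); return(list(op = "not", arg = p_unary(st))) }
  if (t$t == "<") {
    advance(st)
    labs <- p_labels(st)
    expect(st, ">")
    return(list(op = "dia", labels = labs, arg = p_unary(st)))
  }
  if (t$t == "[") {
    advance(st)
    labs <- p_labels(st)
    expect(st, "]")
    return(list(op = "box", labels = labs, arg = p_unary(st)))
  }
  if (t$t == "(") {
    advance(st)
    f <- p_formula(st)
    expect(st, ")")
    return(f)
  }
  if (t$t == "name") {
    advance(st)
    if (t$v == "tt") return(list(op = "tt"))
    if (t$v == "ff") return(list(op = "ff"))
    if (t$v %in% c("EF", "AG", "EX")) {
      expect(st, "(")
      f <- p_formula(st)
      expect(st, ")")
      return(list(op = t$v, arg = f))
    }
    stop("syntax error at position ", t$at, ": unexpected name `", t$v, "`",
         call. = FALSE)
  }
  stop("syntax error at position ", t$at, ": unexpected `", t$v, "`",
       call. = FALSE)
}

#' @export
print.acdx_formula <- function(x, ...) {
  cat("<acdx_formula>", deparse_formula(x), "\n")
  invisible(x)
}

#' Render a formula AST back to text
#' @param f An `acdx_formula`.
#' @return A string in the [parse_formula()] grammar.
#' @export
deparse_formula <- function(f) {
  switch(f$op,
    tt = "tt",
    ff = "ff",
    not = paste0("!", deparse_formula(f$arg)),
    and = paste0("(", deparse_formula(f$lhs), " & ", deparse_formula(f$rhs), ")"),
    or = paste0("(", deparse_formula(f$lhs), " | ", deparse_formula(f$rhs), ")"),
    dia = paste0("<", paste(f$labels, collapse = ","), ">",
                 deparse_formula(f$arg)),
    box = paste0("[", paste(f$labels, collapse = ","), "]",
                 deparse_formula(f$arg)),
    EF = paste0("EF(", deparse_formula(f$arg), ")"),
    AG = paste0("AG(", deparse_formula(f$arg), ")"),
    EX = paste0("EX(", deparse_formula(f$arg), ")"),
    stop("unknown operator ", f$op)
  )
}

# resolve a label set (possibly with wildcards) against the alphabet
resolve_labels <- function(labels, alphabet, quiet = FALSE) {
  out <- character()
  for (l in labels) {
    if (grepl("*", l, fixed = TRUE)) {
      out <- c(out, grep(utils::glob2rx(l), alphabet, value = TRUE))
    } else if (l %in% alphabet) {
      out <- c(out, l)
    } else if (!quiet) {
      warning("label `", l, "` not in model alphabet; treated as empty",
              call. = FALSE)
    }
  }
  unique(out)
}

#' Model-check a formula on an LTS
#'
#' Evaluates the formula bottom-up as state sets over the finite LTS; `EF` is
#' the least fixpoint of backward reachability and `AG` the greatest fixpoint
#' of invariance, both iterated to stabilization (at most one round per
#' state). The verdict is the truth value at the initial state: `TRUE` means
#' the model satisfies the property. For a satisfied formula whose root is
#' `EF`, a shortest witness path (action sequence from the initial state to a
#' state satisfying the `EF` body) is attached.
#'
#' Labels absent from the alphabet (and not wildcards) raise a warning and
#' resolve to the empty set, so `<>` becomes false and `[]` true there; set
#' `quiet = TRUE` to silence the warning (used by the classifier, whose
#' compiled label sets routinely mention levels a given exam never shows).
#'
#' @param lts An `acdx_lts`.
#' @param formula An `acdx_formula` or a formula string.
#' @param quiet Suppress unresolved-label warnings.
#' @return An object of class `acdx_verdict`: list with `value` (logical) and
#'   `witness` (character vector of actions, or `NULL`).
#' @examples
#' lts <- lts_from_model(new_ccs_from_levels(list(c("H_contrast", "L_id"))))
#' check_formula(lts, "EF(<H_contrast>tt & <L_id>tt)")$value
#' @export
check_formula <- function(lts, formula, quiet = FALSE) {
  stopifnot(inherits(lts, "acdx_lts"))
  if (is.character(formula)) formula <- parse_formula(formula)
  n <- nrow(lts$states)
  tr <- lts$transitions
  sat <- eval_formula(formula, lts, n, tr, quiet)
  value <- sat[lts$initial]
  witness <- NULL
  if (isTRUE(value) && identical(formula$op, "EF")) {
    target <- eval_formula(formula$arg, lts, n, tr, quiet = TRUE)
    witness <- shortest_path_to(lts, which(target))
  }
  structure(list(value = value, witness = witness), class = "acdx_verdict")
}

eval_formula <- function(f, lts, n, tr, quiet) {
  switch(f$op,
    tt = rep(TRUE, n),
    ff = rep(FALSE, n),
    not = !eval_formula(f$arg, lts, n, tr, quiet),
    and = eval_formula(f$lhs, lts, n, tr, quiet) &
          eval_formula(f$rhs, lts, n, tr, quiet),
    or = eval_formula(f$lhs, lts, n, tr, quiet) |
         eval_formula(f$rhs, lts, n, tr, quiet),
    dia = {
      A <- resolve_labels(f$labels, lts$alphabet, quiet)
      phi <- eval_formula(f$arg, lts, n, tr, quiet)
      keep <- tr$label %in% A & phi[tr$to]
      s <- rep(FALSE, n); s[unique(tr$from[keep])] <- TRUE
      s
    },
    box = {
      A <- resolve_labels(f$labels, lts$alphabet, quiet)
      phi <- eval_formula(f$arg, lts, n, tr, quiet)
      viol <- tr$label %in% A & !phi[tr$to]
      s <- rep(TRUE, n); s[unique(tr$from[viol])] <- FALSE
      s
    },
    EX = {
      phi <- eval_formula(f$arg, lts, n, tr, quiet)
      s <- rep(FALSE, n); s[unique(tr$from[phi[tr$to]])] <- TRUE
      s
    },
    EF = {
      y <- eval_formula(f$arg, lts, n, tr, quiet)
      repeat {
        grow <- tr$from[y[tr$to] & !y[tr$from]]
        if (length(grow) == 0) break
        y[grow] <- TRUE
      }
      y
    },
    AG = {
      phi <- eval_formula(f$arg, lts, n, tr, quiet)
      y <- phi
      repeat {
        viol <- tr$from[!y[tr$to] & y[tr$from]]
        if (length(viol) == 0) break
        y[viol] <- FALSE
      }
      y
    },
    stop("unknown operator ", f$op)
  )
}

# BFS shortest action path from the initial state to any target state
shortest_path_to <- function(lts, targets) {
  if (lts$initial %in% targets) return(character())
  n <- nrow(lts$states)
  prev <- rep(NA_integer_, n)
  via <- rep(NA_character_, n)
  seen <- rep(FALSE, n)
  seen[lts$initial] <- TRUE
  frontier <- lts$initial
  tr <- lts$transitions
  while (length(frontier) > 0) {
    step <- tr[tr$from %in% frontier & !seen[tr$to], ]
    if (nrow(step) == 0) return(NULL)
    step <- step[!duplicated(step$to), ]
    seen[step$to] <- TRUE
    prev[step$to] <- step$from
    via[step$to] <- step$label
    hit <- intersect(step$to, targets)
    if (length(hit) > 0) {
      s <- hit[1]
      path <- character()
      while (!is.na(prev[s])) {
        path <- c(via[s], path)
        s <- prev[s]
      }
      return(path)
    }
    frontier <- step$to
  }
  NULL
}

#' @export
print.acdx_verdict <- function(x, ...) {
  cat("<acdx_verdict>", if (x$value) "TRUE" else "FALSE", "\n")
  if (!is.null(x$witness))
    cat("  witness:", paste(x$witness, collapse = "."), "\n")
  invisible(x)
}

#' Read formulas from a property file
#'
#' Plain text, one formula per line; blank lines and `#` comments ignored.
#'
#' @param path File path.
#' @return A list of `acdx_formula`.
#' @export
read_formulas <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lapply(lines[nzchar(lines)], parse_formula)
}
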