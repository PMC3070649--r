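#' Boolean regulatory rules in disjunctive normal form
#'
#' A `dnf_rule` is a disjunction (OR) of conjunctive clauses; every clause is a
#' set of polarized literals over regulator node ids. Internally a clause is a
#' named integer vector with values `+1` (the regulator must be present) or
#' `-1` (it must be absent), names sorted; clauses are stored sorted by their
#' canonical key so that equal rules compare identical. Construction enforces
#' irredundancy: contradictory clauses (a literal and its negation) are
#' dropped, duplicate clauses merged, and any clause that is a superset of
#' another clause is absorbed. A rule with no satisfiable clause is rejected:
#' a node that can never activate cannot take part in signal transduction and
#' almost always indicates a curation mistake.
#'
#' @param clauses list of named integer vectors (values +1/-1).
#' @return A canonical `dnf_rule` object.
#' @examples
#' dnf_rule(list(c(A = 1L, B = -1L)))           # A and not B
#' parse_rule_expr("A or (B and C)")
#' @export
dnf_rule <- function(clauses) {
  stopifnot(is.list(clauses))
  cl <- list()
  for (c0 in clauses) {
    if (length(c0) == 0L) {
      stop("rule reduces to a constant (TRUE); constant rules are only allowed for inputs",
           call. = FALSE)
    }
    v <- as.integer(c0)
    names(v) <- names(c0)
    if (is.null(names(v)) || any(!nzchar(names(v)))) {
      stop("clause literals must be named by node id", call. = FALSE)
    }
    # collapse repeated literals; drop the clause if contradictory
    agg <- tapply(v, names(v), function(x) if (length(unique(x)) == 1L) x[[1L]] else NA_integer_)
    if (anyNA(agg)) next
    lit <- as.integer(agg[sort(names(agg))])
    names(lit) <- sort(names(agg))
    cl[[length(cl) + 1L]] <- lit
  }
  cl <- unique(cl)
  if (length(cl) == 0L) {
    stop("rule is unsatisfiable (reduces to FALSE)", call. = FALSE)
  }
  cl <- absorb_clauses(cl)
  cl <- cl[order(vapply(cl, clause_key, character(1)))]
  structure(list(clauses = cl), class = "dnf_rule")
}

clause_key <- function(cl) {
  paste(paste0(names(cl), ifelse(cl > 0L, "+", "-")), collapse = ",")
}

# remove every clause that is a (proper or equal, later-index) superset of another
absorb_clauses <- function(cl) {
  n <- length(cl)
  if (n <= 1L) return(cl)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    for (j in seq_len(n)) {
      if (i == j || !keep[j]) next
      # clause j subset of clause i => absorb i
      if (length(cl[[j]]) <= length(cl[[i]]) &&
          all(names(cl[[j]]) %in% names(cl[[i]])) &&
          all(cl[[i]][names(cl[[j]])] == cl[[j]])) {
        if (length(cl[[j]]) < length(cl[[i]]) || j < i) {
          keep[i] <- FALSE
          break
        }
      }
    }
  }
  cl[keep]
}

#' @export
print.dnf_rule <- function(x, ...) {
  cat(deparse_rule(x), "\n")
  invisible(x)
}

#' @export
format.dnf_rule <- function(x, ...) deparse_rule(x)

#' Variables mentioned by a rule
#' @param rule a `dnf_rule`.
#' @return character vector of node ids, sorted.
#' @export
rule_vars <- function(rule) {
  sort(unique(unlist(lapply(rule$clauses, names), use.names = FALSE)))
}

#' Evaluate a DNF rule against a logical state
#' @param rule a `dnf_rule`.
#' @param state named logical vector covering at least `rule_vars(rule)`.
#' @return logical scalar.
#' @export
eval_rule <- function(rule, state) {
  for (cl in rule$clauses) {
    s <- state[names(cl)]
    if (!anyNA(s) && all(s == (cl > 0L))) return(TRUE)
  }
  FALSE
}

#' Parse a Boolean rule expression into DNF
#'
#' Accepts `and`, `or`, `not` (case-insensitive) and parentheses over word
#' identifiers, e.g. `"A and not (B or C)"`. The expression is converted to
#' irredundant DNF; correctness criterion is truth-table equivalence.
#'
#' @param text expression string (right-hand side of a rule).
#' @return a `dnf_rule`.
#' @export
parse_rule_expr <- function(text) {
  s <- text
  s <- gsub("\\b[Aa][Nn][Dd]\\b", "&", s)
  s <- gsub("\\b[Oo][Rr]\\b", "|", s)
  s <- gsub("\\b[Nn][Oo][Tt]\\b", "!", s)
  e <- tryCatch(str2lang(s), error = function(err) {
    stop("syntax error in rule expression: ", text, call. = FALSE)
  })
  dnf_rule(expr_to_clauses(e, neg = FALSE))
}

expr_to_clauses <- function(e, neg) {
  if (is.symbol(e)) {
    nm <- as.character(e)
    return(list(stats::setNames(if (neg) -1L else 1L, nm)))
  }
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (op == "(") return(expr_to_clauses(e[[2L]], neg))
    if (op == "!") return(expr_to_clauses(e[[2L]], !neg))
    if (op %in% c("&", "&&")) {
      if (!neg) return(cross_clauses(expr_to_clauses(e[[2L]], FALSE),
                                     expr_to_clauses(e[[3L]], FALSE)))
      return(c(expr_to_clauses(e[[2L]], TRUE), expr_to_clauses(e[[3L]], TRUE)))
    }
    if (op %in% c("|", "||")) {
      if (!neg) return(c(expr_to_clauses(e[[2L]], FALSE),
                         expr_to_clauses(e[[3L]], FALSE)))
      return(cross_clauses(expr_to_clauses(e[[2L]], TRUE),
                           expr_to_clauses(e[[3L]], TRUE)))
    }
  }
  stop("unsupported construct in rule expression: ", deparse(e), call. = FALSE)
}

# AND-distribution of two clause lists, dropping contradictions
cross_clauses <- function(a, b) {
  out <- list()
  for (ca in a) {
    for (cb in b) {
      m <- merge_clause(ca, cb)
      if (!is.null(m)) out[[length(out) + 1L]] <- m
    }
  }
  out
}

merge_clause <- function(a, b) {
  common <- intersect(names(a), names(b))
  if (length(common) && any(a[common] != b[common])) return(NULL)
  v <- c(a, b[setdiff(names(b), names(a))])
  v[sort(names(v))]
}

#' Logical negation of a DNF rule
#'
#' Returns an irredundant DNF whose truth table is the complement of the
#' input's. Used to derive the rule that governs a complementary node from the
#' rule of its original node.
#'
#' @param rule a `dnf_rule`.
#' @return a `dnf_rule`.
#' @examples
#' negate_rule(parse_rule_expr("A and B"))  # not A or not B
#' @export
negate_rule <- function(rule) {
  # negation of an OR of clauses = AND over clauses of (OR of negated literals);
  # distribute back to DNF, pruning contradictions as they appear
  acc <- list(stats::setNames(integer(0), character(0)))
  for (cl in rule$clauses) {
    nxt <- list()
    for (partial in acc) {
      for (k in seq_along(cl)) {
        lit <- stats::setNames(-cl[[k]], names(cl)[k])
        m <- merge_clause(partial, lit)
        if (!is.null(m)) nxt[[length(nxt) + 1L]] <- m
      }
    }
    nxt <- unique(nxt)
    if (length(nxt) > 2048L) nxt <- absorb_clauses(nxt)
    acc <- nxt
    if (length(acc) == 0L) {
      stop("rule is unsatisfiable (reduces to FALSE)", call. = FALSE)
    }
  }
  dnf_rule(acc)
}

#' Serialize a DNF rule to rule-file syntax
#' @param rule a `dnf_rule`.
#' @return a string such as `"A and not B or C"`.
#' @export
deparse_rule <- function(rule) {
  one <- function(cl) {
    lits <- paste0(ifelse(cl > 0L, "", "not "), names(cl))
    s <- paste(lits, collapse = " and ")
    if (length(rule$clauses) > 1L && length(cl) > 1L) paste0("(", s, ")") else s
  }
  paste(vapply(rule$clauses, one, character(1)), collapse = " or ")
}

#' Parse a block of rule lines
#'
#' One rule per line, syntax `TARGET = EXPR`; `#` starts a comment; blank
#' lines ignored. Returns the rule map only — roles and headers are handled by
#' [read_network()]/[parse_network()].
#'
#' @param text character scalar or vector of lines.
#' @param inputs node ids that may not carry a rule.
#' @return named list of `dnf_rule`.
#' @export
parse_rules <- function(text, inputs = character(0)) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  rules <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^(INPUT|OUTPUT)\\s*:", ln)) next
    if (!grepl("=", ln, fixed = TRUE)) {
      stop(sprintf("line %d: expected 'TARGET = EXPR', got: %s", i, lines[i]), call. = FALSE)
    }
    target <- trimws(sub("=.*$", "", ln))
    expr <- trimws(sub("^[^=]*=", "", ln))
    if (!grepl("^\\w+$", target)) {
      stop(sprintf("line %d: invalid target identifier '%s'", i, target), call. = FALSE)
    }
    if (target %in% inputs) {
      stop(sprintf("line %d: rule given for declared input '%s'", i, target), call. = FALSE)
    }
    if (!is.null(rules[[target]])) {
      stop(sprintf("line %d: duplicate rule for '%s'", i, target), call. = FALSE)
    }
    r <- tryCatch(parse_rule_expr(expr), error = function(e) {
      stop(sprintf("line %d: %s", i, conditionMessage(e)), call. = FALSE)
    })
    if (target %in% rule_vars(r)) {
      stop(sprintf("line %d: self-regulation in rule for '%s' is not supported", i, target),
           call. = FALSE)
    }
    rules[[target]] <- r
  }
  rules
}
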