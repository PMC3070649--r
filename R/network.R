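#' Signed signaling networks
#'
#' A `signed_network` holds the original directed graph of a signaling system:
#' nodes tagged as input / intermediate / output, signed edges (activating or
#' inhibitory), and one DNF Boolean rule per non-input node describing how its
#' regulators combine. Edges are derived from the rules so the two views can
#' never disagree: a positive literal `u` in the rule of `v` is the activating
#' edge u -> v, a negated literal the inhibitory edge u -| v.
#'
#' @param rules named list of [dnf_rule] objects (one per non-input node).
#' @param inputs,outputs character vectors of node ids.
#' @param nodes optional character vector of node ids (defaults to everything
#'   mentioned); extra isolated nodes are allowed.
#' @return a `signed_network` object.
#' @export
signed_network <- function(rules, inputs, outputs, nodes = NULL) {
  stopifnot(length(inputs) >= 1L, length(outputs) >= 1L)
  mentioned <- union(names(rules), unlist(lapply(rules, rule_vars), use.names = FALSE))
  ids <- sort(unique(c(nodes, mentioned, inputs, outputs)))
  if (any(inputs %in% names(rules))) {
    stop("input nodes may not carry a rule: ",
         paste(intersect(inputs, names(rules)), collapse = ", "), call. = FALSE)
  }
  ruleless <- setdiff(ids, c(inputs, names(rules)))
  if (length(ruleless)) {
    stop("non-input node(s) without a rule: ", paste(ruleless, collapse = ", "),
         call. = FALSE)
  }
  for (v in names(rules)) {
    if (v %in% rule_vars(rules[[v]])) {
      stop("self-regulation in rule for '", v, "' is not supported", call. = FALSE)
    }
  }
  role <- ifelse(ids %in% inputs, "input", ifelse(ids %in% outputs, "output", "intermediate"))
  edges <- edges_from_rules(rules)
  structure(
    list(
      nodes = tibble::tibble(id = ids, role = role),
      edges = edges,
      rules = rules[sort(names(rules))],
      inputs = sort(inputs),
      outputs = sort(outputs)
    ),
    class = "signed_network"
  )
}

edges_from_rules <- function(rules) {
  from <- character(0); to <- character(0); sign <- character(0)
  for (v in names(rules)) {
    lits <- list()
    for (cl in rules[[v]]$clauses) {
      for (k in seq_along(cl)) {
        key <- paste0(names(cl)[k], if (cl[[k]] > 0L) "+" else "-")
        lits[[key]] <- c(names(cl)[k], if (cl[[k]] > 0L) "+" else "-")
      }
    }
    for (l in lits) {
      from <- c(from, l[1L]); to <- c(to, v); sign <- c(sign, l[2L])
    }
  }
  ord <- order(to, from, sign)
  tibble::tibble(from = from[ord], to = to[ord], sign = sign[ord])
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("signed_network: %d nodes, %d edges (%d inhibitory)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$sign == "-")))
  cat("  inputs: ", paste(x$inputs, collapse = ", "), "\n", sep = "")
  cat("  outputs:", paste(x$outputs, collapse = ", "), "\n")
  invisible(x)
}

#' Parse a rule-file text into a signed network
#'
#' Format: UTF-8 text, `#` comments, header lines `INPUT: id[, id...]` and
#' `OUTPUT: id[, id...]`, then one `node = expr` rule per line with operators
#' `and`, `or`, `not` and parentheses.
#'
#' @param text character scalar or vector of lines.
#' @return a [signed_network].
#' @export
parse_network <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  hdr <- function(tag) {
    got <- character(0)
    for (ln in lines) {
      ln <- sub("#.*$", "", ln)
      m <- regmatches(ln, regexec(paste0("^\\s*", tag, "\\s*:\\s*(.*)$"), ln))[[1L]]
      if (length(m)) got <- c(got, trimws(strsplit(m[2L], ",", fixed = TRUE)[[1L]]))
    }
    got[nzchar(got)]
  }
  inputs <- hdr("INPUT")
  outputs <- hdr("OUTPUT")
  if (!length(inputs)) stop("rule file declares no INPUT", call. = FALSE)
  if (!length(outputs)) stop("rule file declares no OUTPUT", call. = FALSE)
  rules <- parse_rules(lines, inputs = inputs)
  signed_network(rules, inputs = inputs, outputs = outputs)
}

#' Read / write rule files
#' @param path file path.
#' @return `read_network()` a [signed_network]; `write_network()` the path,
#'   invisibly. Writing emits the canonical serialization, so
#'   read -> write -> read is the identity.
#' @export
read_network <- function(path) {
  parse_network(readLines(path, warn = FALSE))
}

#' @rdname read_network
#' @param net a [signed_network].
#' @export
write_network <- function(net, path) {
  writeLines(serialize_network(net), path)
  invisible(path)
}

#' @rdname read_network
#' @export
serialize_network <- function(net) {
  c(paste0("INPUT: ", paste(net$inputs, collapse = ", ")),
    paste0("OUTPUT: ", paste(net$outputs, collapse = ", ")),
    vapply(sort(names(net$rules)),
           function(v) paste0(v, " = ", deparse_rule(net$rules[[v]])),
           character(1)))
}

#' Read a SIF-like signed edge list
#'
#' Tab-separated lines `source<TAB>(+|-)<TAB>target`. The result carries no
#' rules; pass it through [synthesize_rules()] to obtain a full network.
#'
#' @param path file path.
#' @param inputs,outputs node role declarations.
#' @return list with `edges` (tibble: from, sign, to), `inputs`, `outputs`.
#' @export
read_sif <- function(path, inputs, outputs) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 3L |
                 !vapply(parts, function(p) p[2L] %in% c("+", "-"), logical(1)))
  if (length(bad)) {
    stop("malformed SIF line ", bad[1L], ": expected 'source\\t(+|-)\\ttarget'",
         call. = FALSE)
  }
  m <- do.call(rbind, parts)
  list(edges = tibble::tibble(from = m[, 1L], sign = m[, 2L], to = m[, 3L]),
       inputs = inputs, outputs = outputs)
}

#' Synthesize Boolean rules from signed edges and partial synergy evidence
#'
#' Applies the field's default reading of converging regulation: independent
#' activators of the same target are OR-ed; activators listed together in a
#' synergy group form a single AND clause; each inhibitor X contributes
#' `and not X` to every clause when inhibition is dominant, otherwise an
#' alternative clause `not X` (its absence acts like an activator).
#'
#' @param edgelist result of [read_sif()], or a list with `edges`
#'   (tibble from/sign/to), `inputs`, `outputs`.
#' @param synergy list of groups; each group is
#'   `list(target = "C", sources = c("A", "B"))` declaring that the activating
#'   edges sources -> target act synergistically.
#' @param dominant_inhibition logical; `TRUE` uses AND NOT, `FALSE` OR NOT.
#' @return a [signed_network] with synthesized rules.
#' @export
synthesize_rules <- function(edgelist, synergy = list(), dominant_inhibition = TRUE) {
  edges <- edgelist$edges
  inputs <- edgelist$inputs
  outputs <- edgelist$outputs
  for (g in synergy) {
    if (is.null(g$target) || is.null(g$sources) || length(g$sources) < 2L) {
      stop("each synergy group needs a single target and >= 2 sources", call. = FALSE)
    }
    if (length(g$target) != 1L) {
      stop("synergy group mixes targets: ", paste(g$target, collapse = ", "), call. = FALSE)
    }
    ok <- g$sources %in% edges$from[edges$to == g$target & edges$sign == "+"]
    if (!all(ok)) {
      stop("synergy group for '", g$target, "' references missing activating edge(s): ",
           paste(g$sources[!ok], collapse = ", "), call. = FALSE)
    }
  }
  targets <- sort(unique(edges$to))
  rules <- list()
  for (v in targets) {
    act <- sort(edges$from[edges$to == v & edges$sign == "+"])
    inh <- sort(edges$from[edges$to == v & edges$sign == "-"])
    grouped <- list()
    used <- character(0)
    for (g in synergy) {
      if (identical(g$target, v)) {
        grouped[[length(grouped) + 1L]] <- stats::setNames(rep(1L, length(g$sources)),
                                                           sort(g$sources))
        used <- union(used, g$sources)
      }
    }
    for (a in setdiff(act, used)) {
      grouped[[length(grouped) + 1L]] <- stats::setNames(1L, a)
    }
    if (length(inh)) {
      if (dominant_inhibition) {
        negs <- stats::setNames(rep(-1L, length(inh)), inh)
        if (length(grouped)) {
          grouped <- lapply(grouped, function(cl) merge_clause(cl, negs))
          grouped <- grouped[!vapply(grouped, is.null, logical(1))]
        } else {
          grouped <- list(negs)
        }
      } else {
        for (x in inh) grouped[[length(grouped) + 1L]] <- stats::setNames(-1L, x)
      }
    }
    if (!length(grouped)) next
    rules[[v]] <- dnf_rule(grouped)
  }
  signed_network(rules, inputs = inputs, outputs = outputs,
                 nodes = unique(c(edges$from, edges$to)))
}

#' Tidy views of networks
#'
#' `tidy()` on a `signed_network` returns its signed edge list as a tibble;
#' on an `expanded_network` the unsigned edge list with node kinds attached.
#'
#' @param x a network object.
#' @param ... unused.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
tidy.signed_network <- function(x, ...) x$edges

#' @export
tidy.default <- function(x, ...) {
  stop("no tidy() method for class ", paste(class(x), collapse = "/"), call. = FALSE)
}
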