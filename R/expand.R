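#' All-activating expanded representation of a signed network
#'
#' Expansion removes the two ambiguities of signed graphs. Inhibition:
#' a complementary node `~v` is introduced for every component with a direct
#' inhibitory role (it appears negated in some rule, or its own rule contains
#' negated literals), governed by the logical negation of v's rule; negating
#' rules can demand further complements and those are created transitively.
#' Synergy: every AND clause with two or more literals becomes a composite
#' node whose in-edges (one per literal) are jointly required and whose single
#' out-edge activates the clause's owner. Every edge of the result means
#' activation; edges converging on an ordinary node are independent
#' alternatives, edges converging on a composite node are all required.
#'
#' When rule negation demands the complement of an input node, that complement
#' is created as a source with no rule (the constitutive absence of the input)
#' and reported in `$notes`; under sustained-input semantics it can never lie
#' on an input-output path and pruning removes it.
#'
#' @param net a [signed_network] with rules.
#' @param prune prune input-output-irrelevant nodes (default `TRUE`).
#' @param deep_negation also preserve overall-activating input-output paths of
#'   the original graph whose inhibitory edges are separated by more than one
#'   activating edge, by adding the complements those paths need. Off by
#'   default, mirroring the focus on direct inhibitory effects.
#' @return an `expanded_network`: tibbles `nodes` (id, kind) and `edges`,
#'   role vectors `inputs`/`outputs`, `composite_req` (required regulators per
#'   composite), `origin` maps, `notes`, and a `transduces` flag.
#' @examples
#' net <- parse_network(c("INPUT: A", "OUTPUT: B", "B = not A"))
#' expand(net, prune = FALSE)   # the two-complement inhibition motif
#' @export
expand <- function(net, prune = TRUE, deep_negation = FALSE) {
  stopifnot(inherits(net, "signed_network"))
  notes <- character(0)

  # which components need complements: direct inhibitory role first
  negated_somewhere <- sort(unique(unlist(lapply(net$rules, function(r) {
    unlist(lapply(r$clauses, function(cl) names(cl)[cl < 0L]), use.names = FALSE)
  }), use.names = FALSE)))
  negatively_regulated <- names(net$rules)[vapply(net$rules, function(r) {
    any(vapply(r$clauses, function(cl) any(cl < 0L), logical(1)))
  }, logical(1))]
  seeds <- sort(unique(c(negated_somewhere, negatively_regulated)))
  if (deep_negation) {
    seeds <- sort(unique(c(seeds, deep_negation_complements(net))))
  }

  # transitive closure: negating a rule can demand further complements
  comp_rules <- list()       # original id -> dnf_rule of its complement
  constitutive <- character(0)
  dead <- character(0)
  queue <- seeds
  seen <- character(0)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    if (v %in% seen) next
    seen <- c(seen, v)
    if (v %in% net$inputs) {
      constitutive <- c(constitutive, v)
      notes <- c(notes, sprintf(
        "complement of input '%s' demanded by negation; created as a constitutive source",
        v))
      next
    }
    neg <- tryCatch(negate_rule(net$rules[[v]]), error = function(e) NULL)
    if (is.null(neg)) {
      dead <- c(dead, v)
      notes <- c(notes, sprintf(
        "complement of '%s' is unsatisfiable (its rule is a tautology); omitted", v))
      next
    }
    comp_rules[[v]] <- neg
    demands <- unlist(lapply(neg$clauses, function(cl) names(cl)[cl < 0L]),
                      use.names = FALSE)
    queue <- c(queue, setdiff(unique(demands), seen))
  }

  comp_id <- function(v) paste0("~", v, recycle0 = TRUE)
  node_id <- character(0); node_kind <- character(0)
  add_node <- function(id, kind) {
    if (!id %in% node_id) {
      node_id <<- c(node_id, id); node_kind <<- c(node_kind, kind)
    }
  }
  for (v in net$nodes$id) add_node(v, "original")
  for (v in c(names(comp_rules), constitutive)) add_node(comp_id(v), "complementary")

  e_from <- character(0); e_to <- character(0)
  composite_req <- list()
  origin_composite <- list()
  available <- c(net$nodes$id, comp_id(c(names(comp_rules), constitutive)))

  add_rule_edges <- function(owner, rule) {
    ks <- seq_along(rule$clauses)
    for (k in ks) {
      cl <- rule$clauses[[k]]
      src <- ifelse(cl > 0L, names(cl), comp_id(names(cl)))
      if (!all(src %in% available)) next  # clause needs an unsatisfiable complement
      if (length(src) == 1L) {
        e_from <<- c(e_from, src); e_to <<- c(e_to, owner)
      } else {
        cid <- sprintf("cmp:%s:%d", owner, k)
        add_node(cid, "composite")
        composite_req[[cid]] <<- sort(src)
        origin_composite[[cid]] <<- list(owner = owner, clause = cl)
        e_from <<- c(e_from, src, cid); e_to <<- c(e_to, rep(cid, length(src)), owner)
      }
    }
  }
  for (v in sort(names(net$rules))) add_rule_edges(v, net$rules[[v]])
  for (v in sort(names(comp_rules))) add_rule_edges(comp_id(v), comp_rules[[v]])

  origin_complement <- stats::setNames(c(names(comp_rules), constitutive),
                                       comp_id(c(names(comp_rules), constitutive)))
  xnet <- new_expanded_network(
    nodes = tibble::tibble(id = node_id, kind = node_kind),
    edges = tibble::tibble(from = e_from, to = e_to),
    inputs = net$inputs, outputs = net$outputs,
    composite_req = composite_req,
    origin = list(complement = origin_complement, composite = origin_composite),
    notes = notes
  )
  if (prune) prune_expanded(xnet) else xnet
}

new_expanded_network <- function(nodes, edges, inputs, outputs, composite_req,
                                 origin, notes = character(0), transduces = TRUE) {
  ord <- order(nodes$id)
  nodes <- nodes[ord, , drop = FALSE]
  if (nrow(edges)) {
    edges <- unique(edges[order(edges$to, edges$from), , drop = FALSE])
  }
  x <- structure(
    list(nodes = nodes, edges = edges,
         inputs = intersect(sort(inputs), nodes$id),
         outputs = intersect(sort(outputs), nodes$id),
         composite_req = composite_req[intersect(names(composite_req), nodes$id)],
         origin = origin, notes = notes, transduces = transduces),
    class = "expanded_network"
  )
  x$in_nb <- adjacency_list(x, "in")
  x$out_nb <- adjacency_list(x, "out")
  x
}

adjacency_list <- function(xnet, dir = c("in", "out")) {
  dir <- match.arg(dir)
  nb <- stats::setNames(vector("list", nrow(xnet$nodes)), xnet$nodes$id)
  for (i in seq_along(nb)) nb[[i]] <- character(0)
  if (nrow(xnet$edges)) {
    key <- if (dir == "in") xnet$edges$to else xnet$edges$from
    val <- if (dir == "in") xnet$edges$from else xnet$edges$to
    sp <- split(val, key)
    nb[names(sp)] <- lapply(sp, sort)
  }
  nb
}

node_kinds <- function(xnet) stats::setNames(xnet$nodes$kind, xnet$nodes$id)

#' @export
print.expanded_network <- function(x, ...) {
  k <- table(factor(x$nodes$kind, levels = c("original", "complementary", "composite")))
  cat(sprintf(
    "expanded_network: %d nodes (%d original, %d complementary, %d composite), %d edges\n",
    nrow(x$nodes), k[["original"]], k[["complementary"]], k[["composite"]],
    nrow(x$edges)))
  if (!x$transduces) cat("  NO TRANSDUCTION: no output reachable from any input\n")
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.expanded_network <- function(x, ...) {
  kinds <- node_kinds(x)
  dplyr::mutate(x$edges,
                from_kind = unname(kinds[.data$from]),
                to_kind = unname(kinds[.data$to]))
}

# AND-aware forward closure: a composite activates only when all its required
# regulators have; an ordinary node when any in-neighbour has.
activatable_set <- function(xnet, roots = xnet$inputs) {
  roots <- intersect(roots, xnet$nodes$id)
  act <- stats::setNames(rep(FALSE, nrow(xnet$nodes)), xnet$nodes$id)
  need <- vapply(xnet$composite_req, length, integer(1))
  got <- stats::setNames(rep(0L, length(need)), names(need))
  queue <- roots
  act[queue] <- TRUE
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (u in xnet$out_nb[[v]]) {
      if (act[[u]]) next
      if (!is.null(xnet$composite_req[[u]])) {
        got[[u]] <- got[[u]] + 1L
        if (got[[u]] == need[[u]]) { act[[u]] <- TRUE; queue <- c(queue, u) }
      } else {
        act[[u]] <- TRUE; queue <- c(queue, u)
      }
    }
  }
  names(act)[act]
}

coreachable_set <- function(xnet, targets = xnet$outputs) {
  seen <- stats::setNames(rep(FALSE, nrow(xnet$nodes)), xnet$nodes$id)
  queue <- intersect(targets, xnet$nodes$id)
  seen[queue] <- TRUE
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    fresh <- xnet$in_nb[[v]][!seen[xnet$in_nb[[v]]]]
    seen[fresh] <- TRUE
    queue <- c(queue, fresh)
  }
  names(seen)[seen]
}

subnetwork <- function(xnet, keep) {
  keep <- intersect(xnet$nodes$id, keep)
  nodes <- xnet$nodes[xnet$nodes$id %in% keep, , drop = FALSE]
  edges <- xnet$edges[xnet$edges$from %in% keep & xnet$edges$to %in% keep, , drop = FALSE]
  new_expanded_network(nodes, edges, xnet$inputs, xnet$outputs,
                       xnet$composite_req, xnet$origin, xnet$notes,
                       transduces = xnet$transduces)
}

#' Prune input-output-irrelevant parts of an expanded network
#'
#' Keeps only nodes that are both activatable from the inputs (under
#' AND-semantics at composite nodes) and able to reach an output, iterating
#' with removal of composite nodes that lose a required regulator until a
#' fixpoint. A network whose outputs become unreachable is returned with
#' `transduces = FALSE` rather than raising an error.
#'
#' @param xnet an `expanded_network`.
#' @return the pruned `expanded_network`.
#' @export
prune_expanded <- function(xnet) {
  repeat {
    keep <- intersect(activatable_set(xnet), coreachable_set(xnet))
    # a kept composite must keep every required regulator
    repeat {
      bad <- names(xnet$composite_req)[vapply(names(xnet$composite_req), function(cid) {
        cid %in% keep && !all(xnet$composite_req[[cid]] %in% keep)
      }, logical(1))]
      if (!length(bad)) break
      keep <- setdiff(keep, bad)
    }
    if (length(keep) == nrow(xnet$nodes)) break
    xnet <- subnetwork(xnet, keep)
    if (!nrow(xnet$nodes)) break
  }
  xnet$transduces <- length(xnet$outputs) > 0L &&
    any(xnet$outputs %in% activatable_set(xnet))
  xnet
}

# Complements needed to preserve overall-activating original-graph paths whose
# inhibitory edges are separated by more than one activating edge: walk every
# such simple input->output path and collect the nodes traversed while the
# running sign parity is negative.
deep_negation_complements <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     vertices = net$nodes$id)
  sign_of <- stats::setNames(net$edges$sign, paste(net$edges$from, net$edges$to))
  extra <- character(0)
  for (i in net$inputs) {
    for (o in net$outputs) {
      paths <- igraph::all_simple_paths(g, from = i, to = o, mode = "out")
      for (p in paths) {
        ids <- names(p)
        signs <- sign_of[paste(ids[-length(ids)], ids[-1L])]
        negpos <- which(signs == "-")
        if (length(negpos) < 2L) next
        if (sum(signs == "-") %% 2L != 0L) next            # not overall activating
        if (all(diff(negpos) <= 2L)) next                  # separations of <= 1 activating edge
        parity <- cumsum(signs == "-") %% 2L
        extra <- c(extra, ids[-1L][parity == 1L])
      }
    }
  }
  sort(unique(extra))
}

#' Convert networks to igraph
#'
#' @param x a [signed_network] or `expanded_network`.
#' @return an [igraph::igraph] with a `kind` (expanded) or `role` plus edge
#'   `sign` (signed) attribute.
#' @export
as_igraph <- function(x) UseMethod("as_igraph")

#' @export
as_igraph.signed_network <- function(x) {
  g <- igraph::graph_from_data_frame(x$edges[, c("from", "to")],
                                     vertices = data.frame(name = x$nodes$id,
                                                           role = x$nodes$role))
  igraph::E(g)$sign <- x$edges$sign
  g
}

#' @export
as_igraph.expanded_network <- function(x) {
  igraph::graph_from_data_frame(
    x$edges,
    vertices = data.frame(name = x$nodes$id, kind = x$nodes$kind))
}
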