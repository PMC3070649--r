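# Independent oracles and small builders shared by the test files.
# Each oracle deliberately re-derives its result by a different route than the
# implementation it checks (R's own parser/evaluator for Boolean rules,
# exhaustive subset search for ESMs, from-scratch fixpoints for cascades).

# Evaluate a raw rule expression string with R's evaluator (truth-table oracle)
tt_eval <- function(expr_text, state) {
  s <- gsub("\\b[Aa][Nn][Dd]\\b", "&", expr_text)
  s <- gsub("\\b[Oo][Rr]\\b", "|", s)
  s <- gsub("\\b[Nn][Oo][Tt]\\b", "!", s)
  isTRUE(eval(str2lang(s), envir = as.list(state)))
}

# All 2^n assignments over vars, as a list of named logical vectors
all_states <- function(vars) {
  if (!length(vars)) return(list(stats::setNames(logical(0), character(0))))
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(vars)))
  names(grid) <- vars
  lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, , drop = FALSE]))
}

# Does a dnf_rule match a raw expression on every assignment?
tt_equivalent <- function(rule, expr_text, vars = NULL) {
  vars <- sort(unique(c(vars, esmnet::rule_vars(rule))))
  all(vapply(all_states(vars), function(st) {
    esmnet::eval_rule(rule, st) == tt_eval(expr_text, st)
  }, logical(1)))
}

# --- expanded-network oracles (index-based, independent of package internals) --

xnet_index <- function(xnet) {
  ids <- xnet$nodes$id
  idx <- stats::setNames(seq_along(ids), ids)
  list(
    ids = ids,
    n = length(ids),
    in_nb = lapply(ids, function(v) unname(idx[xnet$edges$from[xnet$edges$to == v]])),
    out_nb = lapply(ids, function(v) unname(idx[xnet$edges$to[xnet$edges$from == v]])),
    is_comp = xnet$nodes$kind == "composite",
    roots = unname(idx[xnet$inputs]),
    outs = unname(idx[xnet$outputs])
  )
}

# transduction of a node subset: repeated-sweep activation closure
bf_transduces <- function(ix, member) {
  act <- logical(ix$n)
  act[intersect(ix$roots, which(member))] <- TRUE
  repeat {
    changed <- FALSE
    for (i in which(member & !act)) {
      ins <- ix$in_nb[[i]]
      ok <- if (ix$is_comp[i]) {
        length(ins) > 0 && all(member[ins]) && all(act[ins])
      } else {
        any(act[ins[member[ins]]])
      }
      if (ok) { act[i] <- TRUE; changed <- TRUE }
    }
    if (!changed) break
  }
  any(act[ix$outs])
}

# exact ESM enumeration by exhaustive search over global in-edge choice
# functions: assign every non-input ordinary node one of its in-edges, close
# the support of each output under those choices (composites pull in all
# regulators), reject cyclic or input-less supports, and deduplicate by edge
# set. Independent of the package's backtracking enumerator.
bf_esm_supports <- function(xnet) {
  ix <- xnet_index(xnet)
  choosers <- which(!ix$is_comp & !(seq_len(ix$n) %in% ix$roots) &
                      lengths(ix$in_nb) > 0L)
  grids <- ix$in_nb[choosers]
  stopifnot(prod(lengths(grids)) <= 5e5)
  combos <- if (length(grids)) do.call(expand.grid, grids) else data.frame(row = 1)
  found <- list()
  keys <- character(0)
  for (r in seq_len(nrow(combos))) {
    f <- if (length(grids)) stats::setNames(as.integer(combos[r, ]), choosers) else integer(0)
    for (o in ix$outs) {
      visited <- integer(0)
      stack <- o
      edges <- matrix(integer(0), ncol = 2)
      ok <- TRUE
      while (length(stack) && ok) {
        v <- stack[[1L]]; stack <- stack[-1L]
        if (v %in% visited) next
        visited <- c(visited, v)
        if (v %in% ix$roots) next
        parents <- if (ix$is_comp[v]) {
          ix$in_nb[[v]]
        } else if (as.character(v) %in% names(f)) {
          f[[as.character(v)]]
        } else NULL
        if (is.null(parents) || !length(parents)) { ok <- FALSE; break }
        edges <- rbind(edges, cbind(parents, v))
        stack <- c(stack, setdiff(parents, visited))
      }
      if (!ok || !nrow(edges)) next
      # acyclicity of the collected support
      g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2))
      if (!igraph::is_dag(g)) next
      ord <- order(edges[, 2L], edges[, 1L])
      key <- paste(edges[ord, 1L], edges[ord, 2L], collapse = ";")
      if (key %in% keys) next
      keys <- c(keys, key)
      found[[length(found) + 1L]] <- list(
        members = sort(ix$ids[visited]),
        edge_key = paste(ix$ids[edges[ord, 1L]], ix$ids[edges[ord, 2L]],
                         sep = "->", collapse = ";"))
    }
  }
  found
}

# from-scratch cascade fixpoint: repeatedly delete unsupported nodes
bf_cascade <- function(xnet, seeds) {
  ids <- xnet$nodes$id
  alive <- !(ids %in% seeds)
  names(alive) <- ids
  is_comp <- stats::setNames(xnet$nodes$kind == "composite", ids)
  is_root <- stats::setNames(ids %in% xnet$inputs, ids)
  full_in <- lapply(stats::setNames(ids, ids),
                    function(v) xnet$edges$from[xnet$edges$to == v])
  repeat {
    changed <- FALSE
    for (v in ids[alive]) {
      ins <- full_in[[v]]
      bad <- if (is_comp[[v]]) {
        !all(alive[ins])
      } else if (!is_root[[v]]) {
        !any(alive[ins])
      } else FALSE
      if (bad) { alive[[v]] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  sort(ids[!alive])
}

# simple-path count via igraph (independent of the package's DFS)
bf_simple_paths <- function(xnet) {
  if (!nrow(xnet$edges)) return(0L)
  g <- igraph::graph_from_data_frame(xnet$edges, vertices = xnet$nodes$id)
  total <- 0L
  for (i in intersect(xnet$inputs, xnet$nodes$id)) {
    for (o in intersect(xnet$outputs, xnet$nodes$id)) {
      total <- total + length(igraph::all_simple_paths(g, from = i, to = o, mode = "out"))
    }
  }
  total
}

# check the ESM minimality invariant: within the ESM's own subnetwork,
# cascade-removal of any single member destroys transduction
esm_is_minimal <- function(xnet, esm) {
  members <- esm$nodes$id
  subnet <- local({
    keep <- members
    nodes <- xnet$nodes[xnet$nodes$id %in% keep, , drop = FALSE]
    edges <- esm$edges
    esmnet:::new_expanded_network(nodes, edges, xnet$inputs, xnet$outputs,
                                  xnet$composite_req, xnet$origin)
  })
  perturbable <- setdiff(members, names(which(esmnet:::node_kinds(subnet) == "composite")))
  all(vapply(perturbable, function(w) {
    !esmnet::residual_transduces(esmnet::cascade_remove(subnet, w))
  }, logical(1)))
}

# deterministic battery of small random networks whose expansion has at most
# `max_expanded` nodes
small_battery <- function(n_nets, seed0 = 100L, max_expanded = 14L,
                          n_nodes = 8L, inhibitory_frac = 0.2, and_frac = 0.3) {
  nets <- list()
  seed <- seed0
  while (length(nets) < n_nets) {
    seed <- seed + 1L
    net <- tryCatch(
      esmnet::generate_network(esmnet::generator_spec(
        n_nodes = n_nodes, density = 1.6, inhibitory_frac = inhibitory_frac,
        and_frac = and_frac, seed = seed)),
      error = function(e) NULL)
    if (is.null(net)) next
    x <- esmnet::expand(net)
    if (nrow(x$nodes) <= max_expanded && x$transduces) {
      nets[[length(nets) + 1L]] <- list(net = net, xnet = x, seed = seed)
    }
  }
  nets
}
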