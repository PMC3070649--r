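#' Elementary signaling modes
#'
#' An elementary signaling mode (ESM) is a minimal set of expanded-network
#' components that can transduce signal from input(s) to output(s) on its
#' own: every non-input member is supported from within the set, composite
#' members carry all of their required regulators, and removing any member
#' destroys transduction. An ESM without composite nodes is exactly a simple
#' path.
#'
#' Formally an ESM is a minimal self-contained support subgraph: the output
#' is included, every ordinary (original or complementary) member carries
#' exactly one in-edge of the ESM, every composite member all of its
#' expanded-network in-edges, the subgraph is acyclic and every source is an
#' input. Minimality is relative to the ESM's own edges: cascade-removing any
#' member from the ESM subgraph destroys its transduction. Two ESMs may share
#' nodes, and one ESM's node set may even contain another's (a path with a
#' chord), but no ESM's edge set can contain another's.
#'
#' `enumerate_esms()` performs exact, complete enumeration by backtracking
#' over that constraint system, branching on the chosen in-edge of each
#' ordinary node and rejecting support cycles; distinct supports are reported
#' once (identity = edge set). Intended for networks up to a few dozen
#' expanded nodes; at scale use the [count_esms()] estimators.
#'
#' @param xnet a pruned `expanded_network`.
#' @param max_count stop after this many ESMs (result flagged via
#'   `attr(, "incomplete")`).
#' @return list of `esm` objects, sorted by size then node ids; zero-length
#'   when the network does not transduce.
#' @examples
#' length(enumerate_esms(expand(fixtures()$diamond)))  # 2
#' @export
enumerate_esms <- function(xnet, max_count = Inf) {
  stopifnot(inherits(xnet, "expanded_network"))
  if (!nrow(xnet$nodes) || !length(xnet$outputs)) {
    return(structure(list(), incomplete = FALSE))
  }
  roots <- xnet$inputs
  kinds <- node_kinds(xnet)
  raw_cap <- max(5000, if (is.finite(max_count)) 50 * max_count else 0)
  env <- new.env(parent = emptyenv())
  env$supports <- list()
  env$keys <- character(0)
  env$hit_cap <- FALSE

  reach_from <- function(v, sup_out) {
    seen <- v
    stack <- v
    while (length(stack)) {
      x <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      nxt <- setdiff(sup_out[[x]], seen)
      seen <- c(seen, nxt); stack <- c(stack, nxt)
    }
    seen
  }

  rec <- function(need, members, sup_out) {
    if (env$hit_cap) return(invisible())
    if (!length(need)) {
      used <- names(sup_out)[lengths(sup_out) > 0L]
      from <- rep(used, lengths(sup_out[used]))
      to <- unlist(sup_out[used], use.names = FALSE)
      ord <- order(to, from)
      key <- paste(from[ord], to[ord], collapse = ";")
      if (!key %in% env$keys) {
        env$keys <- c(env$keys, key)
        env$supports[[length(env$supports) + 1L]] <-
          list(members = sort(members),
               edges = tibble::tibble(from = from[ord], to = to[ord]))
        if (length(env$supports) >= raw_cap) env$hit_cap <- TRUE
      }
      return(invisible())
    }
    v <- need[[1L]]; rest <- need[-1L]
    if (v %in% roots) return(rec(rest, members, sup_out))
    ins <- xnet$in_nb[[v]]
    if (!length(ins)) return(invisible())           # unsupported: dead branch
    down_of_v <- reach_from(v, sup_out)             # support-descendants of v
    if (kinds[[v]] == "composite") {
      if (any(ins %in% down_of_v)) return(invisible())
      new_out <- sup_out
      for (u in ins) new_out[[u]] <- c(new_out[[u]], v)
      fresh <- setdiff(ins, members)
      rec(c(fresh, rest), c(members, fresh), new_out)
    } else {
      for (u in ins) {
        if (u %in% down_of_v) next                  # would close a support cycle
        new_out <- sup_out
        new_out[[u]] <- c(new_out[[u]], v)
        fresh <- setdiff(u, members)
        rec(c(fresh, rest), c(members, fresh), new_out)
      }
    }
    invisible()
  }

  empty_out <- stats::setNames(vector("list", nrow(xnet$nodes)), xnet$nodes$id)
  for (o in xnet$outputs) {
    rec(o, o, empty_out)
  }

  supports <- env$supports
  truncated <- is.finite(max_count) && length(supports) > max_count
  if (truncated) supports <- supports[seq_len(max_count)]
  esms <- lapply(supports, function(s) make_esm(xnet, s$members, edges = s$edges))
  ord <- order(vapply(esms, function(e) nrow(e$nodes), integer(1)),
               vapply(esms, function(e) paste(e$nodes$id, collapse = ","), character(1)),
               vapply(esms, function(e) paste(e$edges$from, e$edges$to, collapse = ";"),
                      character(1)))
  structure(esms[ord], incomplete = env$hit_cap || truncated)
}

make_esm <- function(xnet, members, edges = NULL) {
  nodes <- xnet$nodes[xnet$nodes$id %in% members, , drop = FALSE]
  if (is.null(edges)) {
    edges <- xnet$edges[xnet$edges$from %in% members & xnet$edges$to %in% members, ,
                        drop = FALSE]
  }
  sub <- subnetwork(xnet, members)
  d <- shortest_distances(sub)
  fin <- d[intersect(xnet$outputs, members)]
  len <- if (length(fin) && any(is.finite(fin))) min(fin[is.finite(fin)]) else Inf
  structure(
    list(nodes = nodes, edges = edges, length = len,
         size_all = nrow(nodes),
         size_noncomposite = sum(nodes$kind != "composite")),
    class = "esm"
  )
}

#' @export
print.esm <- function(x, ...) {
  cat(sprintf("esm: %d nodes (%d non-composite), length %s\n",
              x$size_all, x$size_noncomposite, format(x$length)))
  cat(" ", paste(x$nodes$id, collapse = ", "), "\n")
  invisible(x)
}

#' Estimate the number of ESMs by depth-first search
#'
#' Traverses from each output toward the inputs, forbidding revisits of
#' on-stack nodes (so only acyclic supports are counted). The count at an
#' ordinary node is the sum over its in-neighbours; at a composite node the
#' product (`"multiplication"` mode, an upper-bound-style estimate counting
#' branch combinations) or the maximum (`"max"` mode, a lower-bound-style
#' estimate) of its in-neighbours, and zero if any required regulator is
#' unreachable; at an input, one. Deterministic; on composite-free networks
#' both modes equal the exact simple-path count.
#'
#' @param xnet a pruned `expanded_network`.
#' @param mode `"multiplication"` or `"max"`.
#' @return a numeric count estimate.
#' @export
count_esms <- function(xnet, mode = c("multiplication", "max")) {
  mode <- match.arg(mode)
  stopifnot(inherits(xnet, "expanded_network"))
  if (!nrow(xnet$nodes)) return(0)
  kinds <- node_kinds(xnet)
  roots <- xnet$inputs
  cnt <- function(v, stack) {
    if (v %in% roots) return(1)
    ins <- xnet$in_nb[[v]]
    if (kinds[[v]] == "composite") {
      vals <- numeric(length(ins))
      for (k in seq_along(ins)) {
        if (ins[[k]] %in% stack) return(0)
        vals[[k]] <- cnt(ins[[k]], c(stack, v))
        if (vals[[k]] == 0) return(0)
      }
      if (mode == "multiplication") prod(vals) else max(vals)
    } else {
      total <- 0
      for (u in ins) {
        if (u %in% stack) next
        total <- total + cnt(u, c(stack, v))
      }
      total
    }
  }
  sum(vapply(xnet$outputs, function(o) cnt(o, character(0)), numeric(1)))
}

#' Signal propagation distances in an expanded network
#'
#' The distance of a node from the input(s) follows activation timing: an
#' ordinary (original or complementary) node activates with its earliest
#' regulator, `d(v) = 1 + min(d(u))`; a composite node with its latest,
#' `d(c) = max(d(u))` (the composite hop itself adds no step). Computed by
#' monotone relaxation from `+Inf`; finite exactly on nodes activatable from
#' the inputs over a cycle-free support.
#'
#' @param xnet an `expanded_network`.
#' @return named numeric vector of distances (`Inf` = not activatable).
#' @export
shortest_distances <- function(xnet) {
  ids <- xnet$nodes$id
  d <- stats::setNames(rep(Inf, length(ids)), ids)
  if (!length(ids)) return(d)
  d[xnet$inputs] <- 0
  kinds <- node_kinds(xnet)
  nonroot <- setdiff(ids, xnet$inputs)
  cap <- length(ids)^2 + 2L
  for (sweep in seq_len(cap)) {
    changed <- FALSE
    for (v in nonroot) {
      ins <- xnet$in_nb[[v]]
      if (!length(ins)) next
      nd <- if (kinds[[v]] == "composite") max(d[ins]) else 1 + min(d[ins])
      if (nd < d[[v]]) { d[[v]] <- nd; changed <- TRUE }
    }
    if (!changed) break
  }
  d
}

#' The shortest elementary signaling mode
#'
#' Backtracks from the closest output through the distance map of
#' [shortest_distances()]: at an ordinary node one argmin in-neighbour is
#' chosen (lexicographic tie-break, so the result is deterministic), at a
#' composite node all in-neighbours are required. The ESM's `length` equals
#' the output's distance (edges into ordinary nodes only; the composite hop
#' is free) and both size conventions are reported (`size_all`,
#' `size_noncomposite`).
#'
#' @param xnet a pruned `expanded_network`.
#' @return an `esm` object.
#' @export
shortest_esm <- function(xnet) {
  d <- shortest_distances(xnet)
  outs <- xnet$outputs[is.finite(d[xnet$outputs])]
  if (!length(outs)) stop("no transduction: no output is reachable from an input",
                          call. = FALSE)
  o <- outs[order(d[outs], outs)][1L]
  kinds <- node_kinds(xnet)
  members <- character(0)
  e_from <- character(0); e_to <- character(0)
  queue <- o
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    if (v %in% members) next
    members <- c(members, v)
    if (v %in% xnet$inputs) next
    ins <- xnet$in_nb[[v]]
    if (kinds[[v]] == "composite") {
      sel <- ins
    } else {
      best <- ins[d[ins] == d[[v]] - 1]
      sel <- sort(best)[1L]
    }
    e_from <- c(e_from, sel); e_to <- c(e_to, rep(v, length(sel)))
    queue <- c(queue, setdiff(sel, members))
  }
  make_esm(xnet, sort(members),
           edges = tibble::tibble(from = e_from, to = e_to)[order(e_to, e_from), ])
}

# number of ESMs under a counting mode; "exact" enumerates
n_esms <- function(xnet, mode = c("exact", "multiplication", "max")) {
  mode <- match.arg(mode)
  if (mode == "exact") length(enumerate_esms(xnet)) else count_esms(xnet, mode)
}

#' Write an ESM list as TSV
#'
#' One row per ESM with columns `esm_index`, `size`, `length`, `nodes`
#' (comma-joined sorted ids).
#'
#' @param esms list of `esm` objects as returned by [enumerate_esms()].
#' @param path output file path.
#' @export
write_esms <- function(esms, path) {
  df <- data.frame(
    esm_index = seq_along(esms),
    size = vapply(esms, function(e) e$size_all, integer(1)),
    length = vapply(esms, function(e) e$length, numeric(1)),
    nodes = vapply(esms, function(e) paste(e$nodes$id, collapse = ","), character(1))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
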