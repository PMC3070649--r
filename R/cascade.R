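#' Cascading effect of removing components from an expanded network
#'
#' Removing an original node simulates a knockout; removing a complementary
#' node simulates constitutive activation of its original component. The
#' disruption propagates through the three indispensability rules: a regulator
#' v is indispensable for its target u when (1) v is u's sole regulator,
#' (2) u is a composite node (all regulators jointly required), or (3) v is
#' the only regulator of u still remaining. The worklist algorithm touches
#' each edge at most once, so total work is O(|E|).
#'
#' @param xnet an `expanded_network`.
#' @param remove character vector of node ids to delete (the perturbation
#'   seed). Composite nodes may not be perturbed directly.
#' @param order worklist discipline, `"fifo"` or `"random"`; the disrupted
#'   set is provably order-independent, the option exists to exercise that.
#' @return a `cascade_result`: `disrupted` (node ids, including the seeds)
#'   and `residual` (the surviving `expanded_network`).
#' @examples
#' net <- fixtures()$diamond
#' res <- cascade_remove(expand(net), "A")
#' res$disrupted
#' @export
cascade_remove <- function(xnet, remove, order = c("fifo", "random")) {
  order <- match.arg(order)
  stopifnot(inherits(xnet, "expanded_network"))
  missing_ids <- setdiff(remove, xnet$nodes$id)
  if (length(missing_ids)) {
    stop("node(s) not in the expanded network: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  kinds <- node_kinds(xnet)
  if (any(kinds[remove] == "composite")) {
    stop("composite nodes cannot be perturbed directly; perturb their regulators",
         call. = FALSE)
  }

  ids <- xnet$nodes$id
  indeg <- stats::setNames(vapply(xnet$in_nb, length, integer(1)), ids)
  is_composite <- stats::setNames(kinds == "composite", ids)
  is_root <- stats::setNames(ids %in% xnet$inputs, ids)
  disrupted <- stats::setNames(rep(FALSE, length(ids)), ids)

  # a non-input ordinary node with no activation source is disrupted outright
  seeds <- unique(c(remove, ids[indeg == 0L & !is_root & !is_composite]))
  disrupted[seeds] <- TRUE
  work <- seeds
  while (length(work)) {
    i <- if (order == "random" && length(work) > 1L) sample.int(length(work), 1L) else 1L
    v <- work[[i]]; work <- work[-i]
    for (u in xnet$out_nb[[v]]) {
      if (disrupted[[u]]) next
      indeg[[u]] <- indeg[[u]] - 1L
      if (is_composite[[u]] || (indeg[[u]] == 0L && !is_root[[u]])) {
        disrupted[[u]] <- TRUE
        work <- c(work, u)
      }
    }
  }
  out <- names(disrupted)[disrupted]
  structure(
    list(disrupted = sort(out),
         residual = subnetwork(xnet, setdiff(ids, out)),
         seed = sort(remove)),
    class = "cascade_result"
  )
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("cascade_result: seed {%s} disrupts %d node(s)\n",
              paste(x$seed, collapse = ", "), length(x$disrupted)))
  cat("  disrupted:", paste(x$disrupted, collapse = ", "), "\n")
  invisible(x)
}

#' Does a damaged network still transduce signal?
#'
#' `TRUE` iff some output is activatable from some input in the residual
#' network, under AND-semantics at composite nodes.
#'
#' @param res a `cascade_result` or an `expanded_network`.
#' @return logical scalar.
#' @export
residual_transduces <- function(res) {
  xnet <- if (inherits(res, "cascade_result")) res$residual else res
  length(xnet$outputs) > 0L && any(xnet$outputs %in% activatable_set(xnet))
}
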