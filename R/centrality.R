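#' Count input-to-output simple paths
#'
#' Exact number of simple directed paths from any input to any output of the
#' expanded network, by depth-first search with on-stack exclusion. Paths that
#' pass through one output on the way to another are counted for each output
#' they end at.
#'
#' @param xnet an `expanded_network`.
#' @param cap abort threshold; exceeding it flags the result via
#'   `attr(, "overflow")`.
#' @return numeric path count.
#' @export
count_simple_paths <- function(xnet, cap = 1e9) {
  stopifnot(inherits(xnet, "expanded_network"))
  if (!nrow(xnet$nodes)) return(structure(0, overflow = FALSE))
  outs <- xnet$outputs
  total <- 0
  overflow <- FALSE
  dfs <- function(v, stack) {
    if (overflow) return(invisible())
    here <- 0
    if (v %in% outs) here <- here + 1
    for (u in xnet$out_nb[[v]]) {
      if (u %in% stack) next
      here <- here + dfs(u, c(stack, v))
    }
    if (total + here > cap) overflow <<- TRUE
    here
  }
  for (i in xnet$inputs) total <- total + dfs(i, character(0))
  structure(total, overflow = overflow)
}

importance_score <- function(base, damaged) {
  if (base <= 0) stop("importance undefined: the intact network has zero count",
                      call. = FALSE)
  (base - damaged) / base
}

#' ESM-based importance of a component
#'
#' The relative reduction in the number of elementary signaling modes caused
#' by the cascading disruption that follows removal of `v`:
#' `(N_ESM(G) - N_ESM(G_dv)) / N_ESM(G)`, in `[0, 1]`; 1 means every ESM is
#' destroyed (transduction lost). Removing an original node scores its
#' knockout, removing a complementary node the constitutive activation of its
#' original component.
#'
#' @param xnet a pruned `expanded_network`.
#' @param v node id (or ids, perturbed jointly) present in `xnet`; composite
#'   nodes are not perturbable.
#' @param mode ESM counting mode: `"exact"` (enumeration),
#'   `"multiplication"` or `"max"` (DFS estimators). In `"max"` mode a zero
#'   estimate on a transducing network falls back to reachability: 1 if
#'   transduction is destroyed, else the multiplication-mode score.
#' @return numeric score in `[0, 1]`.
#' @examples
#' esm_importance(expand(fixtures()$diamond), "A")   # 0.5
#' @export
esm_importance <- function(xnet, v, mode = c("exact", "multiplication", "max")) {
  mode <- match.arg(mode)
  res <- cascade_remove(xnet, v)
  base <- n_esms(xnet, mode)
  if (mode == "max" && base == 0 && residual_transduces(xnet)) {
    return(esm_importance(xnet, v, mode = "multiplication"))
  }
  if (base == 0) {
    return(if (residual_transduces(res)) stop(
      "importance undefined: zero ESMs in a transducing network", call. = FALSE) else 1)
  }
  importance_score(base, n_esms(res$residual, mode))
}

#' Simple-path importance (with and without cascading)
#'
#' `sp_importance()` measures the relative reduction of the input-output
#' simple-path count after the full cascading disruption of removing `v`.
#' `sigflux_importance()` is the no-cascade baseline: only `v` and its
#' incident edges are deleted. The cascade can only remove additional paths,
#' so `sp_importance(v) >= sigflux_importance(v)` always.
#'
#' @inheritParams esm_importance
#' @return numeric score in `[0, 1]`.
#' @export
sp_importance <- function(xnet, v) {
  base <- as.numeric(count_simple_paths(xnet))
  res <- cascade_remove(xnet, v)
  importance_score(base, as.numeric(count_simple_paths(res$residual)))
}

#' @rdname sp_importance
#' @export
sigflux_importance <- function(xnet, v) {
  missing_ids <- setdiff(v, xnet$nodes$id)
  if (length(missing_ids)) {
    stop("node(s) not in the expanded network: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  base <- as.numeric(count_simple_paths(xnet))
  naive <- subnetwork(xnet, setdiff(xnet$nodes$id, v))
  importance_score(base, as.numeric(count_simple_paths(naive)))
}

#' Betweenness centrality of the original signed graph
#'
#' Standard directed shortest-path betweenness computed on the original graph
#' with signs ignored (the classical baseline), normalized by the maximum raw
#' betweenness in the graph so scores lie in `[0, 1]` and the most central
#' vertex scores 1.
#'
#' @param net a [signed_network].
#' @return named numeric vector over original node ids.
#' @export
betweenness_scores <- function(net) {
  g <- as_igraph(net)
  b <- igraph::betweenness(g, directed = TRUE, normalized = FALSE)
  m <- max(b)
  if (m > 0) b <- b / m
  b[order(names(b))]
}

delta_shortest_len <- function(xnet, residual) {
  d0 <- shortest_distances(xnet)
  base <- suppressWarnings(min(d0[xnet$outputs][is.finite(d0[xnet$outputs])]))
  if (!is.finite(base)) return(NA_real_)
  d1 <- shortest_distances(residual)
  fin <- d1[intersect(xnet$outputs, residual$nodes$id)]
  fin <- fin[is.finite(fin)]
  if (!length(fin)) return(Inf)
  (min(fin) - base) / base
}

#' Screen every component with all importance measures
#'
#' Performs single-node (and optionally two-node) deletions of every original
#' and complementary node of the expanded network and reports, per
#' perturbation: the ESM measure, the simple-path measure, the no-cascade
#' simple-path (SigFlux-equivalent) measure, betweenness centrality of the
#' original graph (originals only), the relative change of the shortest-ESM
#' length (`Inf` when transduction is destroyed), and whether the residual
#' network still transduces. Pair screening excludes the contradictory pair
#' `{v, ~v}` and pairs where one member already lies in the cascade shadow of
#' the other; exclusions are reported in `attr(, "excluded")`.
#'
#' @param net a [signed_network].
#' @param pairs also screen two-node combinations.
#' @param mode ESM counting mode, see [esm_importance()].
#' @param xnet optionally a pre-computed pruned expansion of `net`.
#' @return a tibble of class `esm_report` with columns `perturbed`, `kind`,
#'   `e_esm`, `e_sp`, `e_sigflux`, `betweenness`, `delta_shortest`,
#'   `transduces_after`.
#' @examples
#' rank_components(fixtures()$and_gate)
#' @export
rank_components <- function(net, pairs = FALSE,
                            mode = c("exact", "multiplication", "max"),
                            xnet = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "signed_network"))
  if (is.null(xnet)) xnet <- expand(net)
  if (!xnet$transduces) {
    stop("no transduction in the intact network; importance is undefined", call. = FALSE)
  }
  kinds <- node_kinds(xnet)
  singles <- sort(names(kinds)[kinds != "composite"])
  bc <- betweenness_scores(net)

  score_one <- function(ids) {
    res <- cascade_remove(xnet, ids)
    tr <- residual_transduces(res)
    list(
      e_esm = esm_importance(xnet, ids, mode = mode),
      e_sp = sp_importance(xnet, ids),
      e_sigflux = sigflux_importance(xnet, ids),
      delta_shortest = delta_shortest_len(xnet, res$residual),
      transduces_after = tr
    )
  }
  kind_of <- function(id) if (kinds[[id]] == "original") "knockout" else "constitutive"

  rows <- lapply(singles, function(v) {
    s <- score_one(v)
    tibble::tibble(
      perturbed = v, kind = kind_of(v),
      e_esm = s$e_esm, e_sp = s$e_sp, e_sigflux = s$e_sigflux,
      betweenness = if (kinds[[v]] == "original") unname(bc[v]) else NA_real_,
      delta_shortest = s$delta_shortest, transduces_after = s$transduces_after
    )
  })
  excluded <- tibble::tibble(a = character(0), b = character(0), reason = character(0))
  if (pairs && length(singles) >= 2L) {
    combs <- utils::combn(singles, 2L, simplify = FALSE)
    shadow <- lapply(stats::setNames(singles, singles),
                     function(v) cascade_remove(xnet, v)$disrupted)
    for (p in combs) {
      a <- p[[1L]]; b <- p[[2L]]
      if (identical(paste0("~", a), b) || identical(paste0("~", b), a)) {
        excluded <- dplyr::bind_rows(excluded,
          tibble::tibble(a = a, b = b, reason = "contradictory pair {v, ~v}"))
        next
      }
      if (b %in% shadow[[a]] || a %in% shadow[[b]]) {
        excluded <- dplyr::bind_rows(excluded,
          tibble::tibble(a = a, b = b, reason = "one member in cascade shadow of the other"))
        next
      }
      s <- score_one(c(a, b))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        perturbed = paste0(a, "+", b),
        kind = paste(kind_of(a), kind_of(b), sep = "+"),
        e_esm = s$e_esm, e_sp = s$e_sp, e_sigflux = s$e_sigflux,
        betweenness = NA_real_,
        delta_shortest = s$delta_shortest, transduces_after = s$transduces_after
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "excluded") <- excluded
  attr(out, "mode") <- mode
  class(out) <- c("esm_report", class(out))
  out
}

#' Write an importance report as TSV
#' @param report an `esm_report` tibble.
#' @param path output file path.
#' @export
write_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' One-row summary of an importance screen
#'
#' @param x an `esm_report`.
#' @param ... unused.
#' @return a tibble with the number of perturbations screened, the number
#'   that destroy transduction, and the counting mode used.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname glance
#' @export
glance.esm_report <- function(x, ...) {
  tibble::tibble(
    n_perturbations = nrow(x),
    n_essential_esm = sum(x$e_esm >= 1),
    n_transduction_destroyed = sum(!x$transduces_after),
    mode = attr(x, "mode") %||% "exact"
  )
}

#' @importFrom rlang %||% .data
NULL

#' Plot an importance screen
#'
#' Dot plot of all importance measures per perturbed component, mirroring the
#' per-node comparison figures used for this family of measures.
#'
#' @param object an `esm_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.esm_report <- function(object, ...) {
  long <- tidyr_pivot(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$perturbed, y = .data$value,
                                     shape = .data$measure, colour = .data$measure)) +
    ggplot2::geom_point(size = 2, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "importance") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

# minimal long-format pivot (avoids a tidyr dependency for one call)
tidyr_pivot <- function(report) {
  measures <- c("e_esm", "e_sp", "e_sigflux", "betweenness")
  dplyr::bind_rows(lapply(measures, function(m) {
    tibble::tibble(perturbed = report$perturbed, measure = m, value = report[[m]])
  }))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
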