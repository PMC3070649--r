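#' Canned toy signaling motifs
#'
#' Small frozen networks exercising every structural feature: plain chains
#' and diamonds, the two-complement inhibition motif, AND gates, a mixed
#' presence/absence gate, a synergy-bypass motif where the synergistic hub is
#' essential yet has lower betweenness than a non-essential relay, an
#' inhibitor-hub motif where a high-betweenness inhibitor is structurally
#' irrelevant to transduction, and a 10-node network combining one composite
#' and one surviving complement. These are regression anchors for the whole
#' pipeline.
#'
#' @return named list of [signed_network] objects: `chain`, `diamond`,
#'   `and_gate`, `not_motif`, `mixed_gate`, `fig1a_like`, `fig1b_like`,
#'   `fig3_like`.
#' @examples
#' names(fixtures())
#' @export
fixtures <- function() {
  nets <- list(
    chain = c(
      "INPUT: I", "OUTPUT: O",
      "A = I",
      "O = A"),
    diamond = c(
      "INPUT: I", "OUTPUT: O",
      "A = I",
      "B = I",
      "O = A or B"),
    and_gate = c(
      "INPUT: I", "OUTPUT: O",
      "A = I",
      "B = I",
      "O = A and B"),
    not_motif = c(
      "INPUT: A", "OUTPUT: B",
      "B = not A"),
    mixed_gate = c(
      # inhibitor B sits behind intermediate S so its absence (~B) is reachable
      "INPUT: I", "OUTPUT: C",
      "A = I",
      "S = I",
      "B = not S",
      "C = A and not B"),
    fig1a_like = c(
      # E and F independently activate O but both need the synergy of D;
      # relay C has the higher betweenness, hub D is the essential one
      "INPUT: I", "OUTPUT: O",
      "C = I",
      "D = I",
      "E = C",
      "F = C",
      "O = (E and D) or (F and D)"),
    fig1b_like = c(
      # inhibitor C collects convergent regulation and sits on the shortest
      # original-graph route, but transduction runs through B alone
      "INPUT: I", "OUTPUT: O",
      "A = I",
      "B = I",
      "C = A or B",
      "D = B or not C",
      "O = D"),
    fig3_like = c(
      "INPUT: I", "OUTPUT: O",
      "A = I",
      "B = I",
      "S = A",
      "F = not S",
      "C = A and B",
      "G = B",
      "D = C or G",
      "E = B and not F",
      "O = D or E")
  )
  lapply(nets, parse_network)
}

#' Specification for the random network generator
#'
#' @param n_nodes total number of original nodes (including inputs/outputs).
#' @param density expected number of regulators per non-input node.
#' @param inhibitory_frac fraction of edges that are inhibitory.
#' @param and_frac fraction of multi-activator nodes whose activators form an
#'   AND clause.
#' @param max_clause_width maximum literals per AND clause.
#' @param n_inputs,n_outputs role counts.
#' @param dominant_inhibition inhibitors combine as AND NOT (else OR NOT).
#' @param seed RNG seed; identical specs with identical seeds generate
#'   identical networks.
#' @return a `generator_spec` list.
#' @export
generator_spec <- function(n_nodes = 12L, density = 1.8, inhibitory_frac = 0.2,
                           and_frac = 0.3, max_clause_width = 3L,
                           n_inputs = 1L, n_outputs = 1L,
                           dominant_inhibition = TRUE, seed = NULL) {
  stopifnot(n_nodes >= n_inputs + n_outputs + 1L,
            inhibitory_frac >= 0, inhibitory_frac <= 1,
            and_frac >= 0, and_frac <= 1,
            max_clause_width >= 2L, density > 0)
  structure(list(n_nodes = as.integer(n_nodes), density = density,
                 inhibitory_frac = inhibitory_frac, and_frac = and_frac,
                 max_clause_width = as.integer(max_clause_width),
                 n_inputs = as.integer(n_inputs), n_outputs = as.integer(n_outputs),
                 dominant_inhibition = isTRUE(dominant_inhibition), seed = seed),
            class = "generator_spec")
}

#' Generate a random signaling network
#'
#' Draws a layered random digraph (inputs first, outputs last, regulators
#' always upstream in a random topological order, so the graph is acyclic
#' with every node on an input-to-output route), then synthesizes each
#' node's rule: activators OR-ed by default, an AND clause with probability
#' `and_frac` when a node has several activators, inhibitors attached per the
#' dominance convention. Candidates whose expansion fails to transduce are
#' rejection-sampled.
#'
#' @param spec a [generator_spec].
#' @param max_tries rejection-sampling cap.
#' @return a [signed_network].
#' @examples
#' net <- generate_network(generator_spec(n_nodes = 8, seed = 1))
#' @export
generate_network <- function(spec, max_tries = 200L) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  for (try in seq_len(max_tries)) {
    net <- try_generate(spec)
    if (is.null(net)) next
    x <- tryCatch(expand(net), error = function(e) NULL)
    if (!is.null(x) && x$transduces) return(net)
  }
  stop("generator failed to produce a transducing network after ", max_tries,
       " tries; spec: n_nodes=", spec$n_nodes, " density=", spec$density,
       " inhibitory_frac=", spec$inhibitory_frac, " and_frac=", spec$and_frac,
       call. = FALSE)
}

try_generate <- function(spec) {
  n <- spec$n_nodes
  ids <- sprintf("n%02d", seq_len(n))
  inputs <- ids[seq_len(spec$n_inputs)]
  outputs <- ids[(n - spec$n_outputs + 1L):n]
  # position i may be regulated by any position < i; inputs occupy the front
  regulators <- list()
  for (i in seq_along(ids)) {
    v <- ids[[i]]
    if (v %in% inputs) next
    pool <- ids[seq_len(i - 1L)]
    k <- max(1L, min(length(pool), stats::rpois(1L, spec$density)))
    regulators[[v]] <- sample(pool, k)
  }
  # every non-output must regulate something downstream
  regulated <- unique(unlist(regulators, use.names = FALSE))
  for (i in seq_along(ids)) {
    v <- ids[[i]]
    if (v %in% outputs || v %in% regulated) next
    later <- setdiff(ids[seq(i + 1L, n)], inputs)
    if (!length(later)) return(NULL)
    tgt <- sample(later, 1L)
    regulators[[tgt]] <- union(regulators[[tgt]], v)
  }
  rules <- list()
  for (v in names(regulators)) {
    regs <- regulators[[v]]
    inh <- regs[stats::runif(length(regs)) < spec$inhibitory_frac]
    act <- setdiff(regs, inh)
    clauses <- list()
    if (length(act) >= 2L && stats::runif(1L) < spec$and_frac) {
      w <- min(length(act), spec$max_clause_width)
      grp <- sort(sample(act, w))
      clauses[[1L]] <- stats::setNames(rep(1L, w), grp)
      for (a in setdiff(act, grp)) {
        clauses[[length(clauses) + 1L]] <- stats::setNames(1L, a)
      }
    } else {
      for (a in act) clauses[[length(clauses) + 1L]] <- stats::setNames(1L, a)
    }
    if (length(inh)) {
      if (spec$dominant_inhibition) {
        negs <- stats::setNames(rep(-1L, length(inh)), sort(inh))
        clauses <- if (length(clauses)) {
          lapply(clauses, function(cl) merge_clause(cl, negs))
        } else list(negs)
      } else {
        for (x in inh) clauses[[length(clauses) + 1L]] <- stats::setNames(-1L, x)
      }
    }
    if (!length(clauses)) return(NULL)
    rules[[v]] <- dnf_rule(clauses)
  }
  tryCatch(signed_network(rules, inputs = inputs, outputs = outputs, nodes = ids),
           error = function(e) NULL)
}
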