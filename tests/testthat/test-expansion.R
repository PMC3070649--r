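test_that("inhibition expands to the two-complement motif", {
  net <- parse_network(c("INPUT: A", "OUTPUT: B", "B = not A"))
  x <- expand(net, prune = FALSE)
  expect_setequal(x$nodes$id, c("A", "~A", "B", "~B"))
  expect_setequal(x$nodes$id[x$nodes$kind == "complementary"], c("~A", "~B"))
  expect_setequal(paste(x$edges$from, x$edges$to), c("~A B", "A ~B"))
  expect_true(any(grepl("constitutive source", x$notes)))

  # under sustained-input semantics the pruned motif cannot transduce
  expect_false(expand(net)$transduces)
})

test_that("synergy expands to a composite node with jointly required in-edges", {
  x <- expand(fixtures()$and_gate)
  comp <- x$nodes$id[x$nodes$kind == "composite"]
  expect_length(comp, 1L)
  expect_setequal(x$edges$from[x$edges$to == comp], c("A", "B"))
  expect_equal(x$edges$to[x$edges$from == comp], "O")
  expect_equal(sum(x$edges$from == comp), 1L)  # out-degree exactly one
})

test_that("presence/absence gates combine both operations", {
  x <- expand(fixtures()$mixed_gate)
  comp <- x$nodes$id[x$nodes$kind == "composite"]
  expect_length(comp, 1L)
  expect_setequal(x$edges$from[x$edges$to == comp], c("A", "~B"))
  # the complement's rule is the negation of the original's:
  # B = not S  =>  ~B governed by S
  expect_true(all(c("~B") %in% x$nodes$id))
  expect_true(any(x$edges$from == "S" & x$edges$to == "~B"))
  # and the negation itself is truth-table-correct
  net <- fixtures()$mixed_gate
  nr <- negate_rule(net$rules$B)
  for (st in all_states("S")) expect_equal(eval_rule(nr, st), !eval_rule(net$rules$B, st))
})

test_that("pruning keeps exactly the input-output-relevant subgraph", {
  # dangling node reachable only from the output side is removed
  net <- parse_network(c("INPUT: I", "OUTPUT: O", "A = I", "O = A", "D = O"))
  x <- expand(net)
  expect_false("D" %in% x$nodes$id)
  expect_setequal(x$nodes$id, c("I", "A", "O"))

  # a composite losing a regulator takes its downstream-only dependents with it
  net <- parse_network(c("INPUT: I", "OUTPUT: O",
                         "A = I", "B = not I", "C = A and B", "O = A or C"))
  x <- expand(net)
  # B depends on ~I (constitutive source, pruned), so C's clause is unsatisfiable
  expect_false(any(grepl("^cmp:", x$nodes$id)))
  expect_setequal(x$nodes$id, c("I", "A", "O"))
  expect_true(x$transduces)

  # every surviving node lies on an input->output route
  for (fx in fixtures()) {
    x <- expand(fx)
    if (!x$transduces) next
    act <- esmnet:::activatable_set(x)
    cor <- esmnet:::coreachable_set(x)
    expect_setequal(x$nodes$id, intersect(act, cor))
  }
})

test_that("expansion of a purely activating, synergy-free network is isomorphic to it", {
  for (seed in 1:5) {
    net <- generate_network(generator_spec(n_nodes = 9, inhibitory_frac = 0,
                                           and_frac = 0, seed = seed))
    x <- expand(net)
    expect_true(all(x$nodes$kind == "original"))
    g0 <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                        vertices = net$nodes$id)
    expect_true(igraph::isomorphic(g0, as_igraph(x)))
  }
})

test_that("expanded size is bounded and prune is idempotent", {
  for (seed in 1:8) {
    net <- generate_network(generator_spec(n_nodes = 9, inhibitory_frac = 0.3,
                                           and_frac = 0.4, seed = seed))
    x_raw <- expand(net, prune = FALSE)
    multi <- function(rules) sum(vapply(rules, function(r) {
      sum(lengths(r$clauses) >= 2L)
    }, integer(1)))
    neg_rules <- lapply(names(net$rules), function(v) {
      tryCatch(negate_rule(net$rules[[v]]), error = function(e) NULL)
    })
    neg_rules <- neg_rules[!vapply(neg_rules, is.null, logical(1))]
    bound <- 2L * nrow(net$nodes) + multi(net$rules) +
      multi(stats::setNames(neg_rules, seq_along(neg_rules)))
    expect_lte(nrow(x_raw$nodes), bound)

    once <- prune_expanded(x_raw)
    twice <- prune_expanded(once)
    expect_equal(once$nodes, twice$nodes)
    expect_equal(once$edges, twice$edges)
  }
})

test_that("deep negation is opt-in and only ever adds nodes", {
  net <- parse_network(c("INPUT: I", "OUTPUT: O",
                         "A = I", "B = not A", "C = B", "D = C", "E = not D",
                         "O = E"))
  x0 <- expand(net, prune = FALSE)
  x1 <- expand(net, prune = FALSE, deep_negation = TRUE)
  expect_true(all(x0$nodes$id %in% x1$nodes$id))
  # the transitive complement closure already preserves this two-inhibition path
  x <- expand(net)
  expect_true(x$transduces)
  expect_true(all(c("~B", "~C", "~D") %in% x$nodes$id))
})

test_that("networks without rules for non-input nodes are rejected", {
  expect_error(parse_network(c("INPUT: I", "OUTPUT: O", "O = A")), "without a rule")
  expect_error(parse_network(c("OUTPUT: O", "O = A")), "no INPUT")
  expect_error(signed_network(list(I = parse_rule_expr("A")),
                              inputs = "I", outputs = "O"), "input nodes may not")
})
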