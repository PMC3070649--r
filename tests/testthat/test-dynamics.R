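test_that("synchronous dynamics reach the expected attractors on motifs", {
  f <- fixtures()
  tr <- simulate_boolean(f$chain)
  expect_false(is.null(tr$steady))
  expect_true(tr$steady[["O"]])

  tr <- simulate_boolean(f$and_gate, clamp = c(A = FALSE))
  expect_false(is.null(tr$steady))
  expect_false(tr$steady[["O"]])
  expect_equal(tr$on_frequency[["O"]], 0)

  # negative feedback through a relay oscillates (no fixed point)
  osc <- parse_network(c("INPUT: I", "OUTPUT: O",
                         "O = I and not B", "B = O"))
  tr <- simulate_boolean(osc)
  expect_null(tr$steady)
  expect_true(tr$attractor_period > 1L)
  # oracle: exhaustive transition table over the 4 free-node states shows the
  # cycle (O,B): 10 -> 11 -> 01 -> 00 -> 10, period 4
  expect_equal(tr$attractor_period, 4L)
  expect_equal(unname(tr$on_frequency[c("O", "B")]), c(0.5, 0.5))
})

test_that("the update functions agree with R's evaluator on every state", {
  # the engine updates each node with eval_rule() on the canonical DNF; the
  # oracle re-evaluates the serialized rule text with R's own parser, so the
  # whole parse -> DNF -> eval pipeline is checked exhaustively (2^n states)
  f <- fixtures()
  for (nm in c("chain", "and_gate", "diamond", "mixed_gate", "fig1a_like", "fig3_like")) {
    net <- f[[nm]]
    free <- names(net$rules)
    raw <- stats::setNames(
      vapply(free, function(v) deparse_rule(net$rules[[v]]), character(1)), free)
    mismatch <- 0L
    for (st in all_states(net$nodes$id)) {
      for (v in free) {
        if (eval_rule(net$rules[[v]], st) != tt_eval(raw[[v]], st)) {
          mismatch <- mismatch + 1L
        }
      }
    }
    expect_equal(mismatch, 0L, info = nm)
  }
})

test_that("the engine's transition function matches exhaustive enumeration", {
  # drive the engine from every state for one step and compare against the
  # independently evaluated rule expressions
  f <- fixtures()
  for (nm in c("and_gate", "mixed_gate", "fig3_like")) {
    net <- f[[nm]]
    free <- names(net$rules)
    raw <- stats::setNames(
      vapply(free, function(v) deparse_rule(net$rules[[v]]), character(1)), free)
    step_engine <- function(st) {
      # horizon-1 synchronous run starting exactly at st; inputs hold st's value
      tr <- simulate_boolean(net, initial = st, horizon = 1L)
      tr
    }
    for (st in all_states(net$nodes$id)) {
      tr <- step_engine(st)
      nxt_oracle <- st
      for (v in free) nxt_oracle[[v]] <- tt_eval(raw[[v]], st)
      if (identical(unname(nxt_oracle[order(names(nxt_oracle))]),
                    unname(st[order(names(st))]))) {
        # st is a fixed point: the engine must report it as steady
        expect_false(is.null(tr$steady), info = paste(nm, "fp"))
        expect_equal(tr$steady[order(names(tr$steady))],
                     st[order(names(st))], info = nm)
      }
    }
  }
})

test_that("dynamic essentiality classification matches the motif truths", {
  f <- fixtures()
  ce <- classify_essential(f$chain)
  expect_true(ce$essential[ce$node == "A" & ce$kind == "knockout"])

  ce <- classify_essential(f$diamond)
  expect_false(ce$essential[ce$node == "A" & ce$kind == "knockout"])
  expect_true(ce$essential[ce$node == "I" & ce$kind == "knockout"])

  ce <- classify_essential(f$and_gate)
  expect_true(all(ce$essential[ce$node %in% c("A", "B") & ce$kind == "knockout"]))
})

test_that("asynchronous updating is reproducible under a seed", {
  net <- fixtures()$fig3_like
  t1 <- simulate_boolean(net, scheme = "asynchronous", replicates = 20,
                         horizon = 20, seed = 5)
  t2 <- simulate_boolean(net, scheme = "asynchronous", replicates = 20,
                         horizon = 20, seed = 5)
  expect_identical(t1$on_frequency, t2$on_frequency)
})

test_that("ROC sweeps behave for perfect, constant and anti-perfect scorers", {
  truth <- stats::setNames(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                           paste0("v", 1:6))
  mkrep <- function(scores) {
    r <- tibble::tibble(perturbed = names(truth), kind = "knockout",
                        e_esm = scores, e_sp = NA_real_, e_sigflux = NA_real_,
                        betweenness = NA_real_, delta_shortest = 0,
                        transduces_after = TRUE)
    class(r) <- c("esm_report", class(r))
    r
  }
  perfect <- roc_validation(mkrep(as.numeric(truth)), truth)
  best <- attr(perfect, "best")
  expect_equal(best$sensitivity[best$measure == "e_esm"], 1)
  expect_equal(best$specificity[best$measure == "e_esm"], 1)

  constant <- roc_validation(mkrep(rep(0.5, 6)), truth)
  cs <- constant[constant$measure == "e_esm", ]
  expect_true(all(cs$sensitivity + cs$specificity == 1))

  anti <- roc_validation(mkrep(1 - as.numeric(truth)), truth)
  as_ <- anti[anti$measure == "e_esm", ]
  expect_true(all(as_$sensitivity + as_$specificity <= 1))

  # degenerate truth is flagged, not crashed on
  deg <- roc_validation(mkrep(as.numeric(truth)),
                        stats::setNames(rep(TRUE, 6), names(truth)))
  expect_true(any(!deg$defined))
})

test_that("structurally omnipresent nodes are dynamically essential on fixtures", {
  f <- fixtures()
  for (nm in c("chain", "and_gate", "fig1a_like")) {
    net <- f[[nm]]
    x <- expand(net)
    esms <- enumerate_esms(x)
    in_all <- Reduce(intersect, lapply(esms, function(e) e$nodes$id))
    knockouts <- intersect(in_all, setdiff(net$nodes$id, net$outputs))
    ce <- classify_essential(net)
    for (v in knockouts) {
      expect_true(ce$essential[ce$node == v & ce$kind == "knockout"],
                  info = paste(nm, v))
    }
  }
})
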