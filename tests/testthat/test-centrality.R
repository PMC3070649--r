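# 3x3 grid DAG, edges right and down, corner to corner: choose(4, 2) = 6 paths
grid3_net <- function() {
  parse_network(c(
    "INPUT: g11", "OUTPUT: g33",
    "g12 = g11", "g21 = g11",
    "g13 = g12", "g22 = g12 or g21", "g31 = g21",
    "g23 = g13 or g22", "g32 = g22 or g31",
    "g33 = g23 or g32"))
}

test_that("simple-path counting is exact", {
  f <- fixtures()
  expect_equal(as.numeric(count_simple_paths(expand(f$chain))), 1)
  expect_equal(as.numeric(count_simple_paths(expand(f$diamond))), 2)
  x <- expand(grid3_net())
  expect_equal(as.numeric(count_simple_paths(x)), 6)
  expect_equal(as.numeric(count_simple_paths(x)), bf_simple_paths(x))
})

test_that("importance measures reproduce the motif values", {
  f <- fixtures()
  xd <- expand(f$diamond)
  expect_equal(esm_importance(xd, "A"), 0.5)
  expect_equal(sp_importance(xd, "A"), 0.5)
  expect_equal(sigflux_importance(xd, "A"), 0.5)

  xa <- expand(f$and_gate)
  expect_equal(esm_importance(xa, "A"), 1.0)
  expect_equal(sp_importance(xa, "A"), 1.0)       # cascade kills the composite
  expect_equal(sigflux_importance(xa, "A"), 0.5)  # naive deletion leaves one path

  xc <- expand(f$chain)
  expect_equal(sp_importance(xc, "A"), 1.0)
  expect_equal(sigflux_importance(xc, "A"), 1.0)

  # synergy hub: every route to the output needs D
  expect_equal(esm_importance(expand(f$fig1a_like), "D"), 1.0)

  expect_error(esm_importance(xd, "nope"), "not in the expanded network")
})

test_that("estimator modes are recorded and fall back sanely", {
  xd <- expand(fixtures()$diamond)
  expect_equal(esm_importance(xd, "A", mode = "multiplication"), 0.5)
  expect_equal(esm_importance(xd, "A", mode = "max"), 0.5)
})

test_that("betweenness is the classical baseline on the original graph", {
  bc <- betweenness_scores(fixtures()$chain)
  expect_equal(bc[["A"]], 1)                       # only interior vertex
  bc <- betweenness_scores(fixtures()$diamond)
  expect_equal(bc[["A"]], bc[["B"]])               # symmetric branches
  # star hub: hub scores the maximum
  star <- parse_network(c("INPUT: I1, I2", "OUTPUT: O1, O2",
                          "H = I1 or I2", "O1 = H", "O2 = H"))
  bc <- betweenness_scores(star)
  expect_equal(bc[["H"]], 1)
  expect_true(all(bc[setdiff(names(bc), "H")] < 1))
})

test_that("the component screen reports all perturbations with bounded scores", {
  f <- fixtures()
  rep <- rank_components(f$and_gate)
  expect_equal(nrow(rep), 4L)
  expect_setequal(rep$perturbed, c("I", "A", "B", "O"))
  expect_true(all(rep$e_esm == 1.0))

  rep <- rank_components(f$diamond)
  ess <- rep$perturbed[rep$e_esm == 1.0]
  expect_setequal(ess, c("I", "O"))

  for (m in c("e_esm", "e_sp", "e_sigflux")) {
    expect_true(all(rep[[m]] >= 0 & rep[[m]] <= 1))
  }
  # a full cascade-aware score is exactly the loss of transduction
  for (m in c("e_esm", "e_sp")) {
    expect_equal(rep[[m]] == 1, !rep$transduces_after)
  }
  expect_equal(glance(rep)$n_perturbations, nrow(rep))
})

test_that("pair screening scores combinations and reports exclusions", {
  rep <- rank_components(fixtures()$diamond, pairs = TRUE)
  ab <- rep[rep$perturbed == "A+B", ]
  expect_equal(nrow(ab), 1L)
  expect_equal(ab$e_esm, 1.0)
  expect_false(ab$transduces_after)
  exc <- attr(rep, "excluded")
  # I's cascade shadows everything, so pairs with I are excluded as duplicates
  expect_true(all(c("reason") %in% names(exc)))
  expect_true(any(grepl("shadow", exc$reason)))
})

test_that("the cascade only removes paths: sp >= sigflux pointwise", {
  nets <- small_battery(8, seed0 = 600L)
  for (item in nets) {
    x <- item$xnet
    for (v in x$nodes$id[x$nodes$kind != "composite"]) {
      expect_gte(sp_importance(x, v), sigflux_importance(x, v))
    }
  }
})

test_that("scores are invariant under node relabeling", {
  net <- generate_network(generator_spec(n_nodes = 8, inhibitory_frac = 0.2,
                                         and_frac = 0.4, seed = 9))
  rep1 <- rank_components(net)
  # relabel by serializing with renamed identifiers
  txt <- serialize_network(net)
  ids <- net$nodes$id
  relab <- stats::setNames(sprintf("z%02d", rev(seq_along(ids))), ids)
  for (old in names(relab)) {
    txt <- gsub(paste0("\\b", old, "\\b"), relab[[old]], txt)
  }
  rep2 <- rank_components(parse_network(txt))
  key1 <- rep1[order(rep1$perturbed), ]
  key2 <- rep2[order(chartr("z", "n", rep2$perturbed)), ]
  # the multisets of scores coincide measure by measure
  for (m in c("e_esm", "e_sp", "e_sigflux", "betweenness")) {
    expect_equal(sort(key1[[m]]), sort(key2[[m]]), info = m)
  }
})

test_that("without synergy or inhibition all three structural measures agree", {
  for (seed in 1:5) {
    net <- generate_network(generator_spec(n_nodes = 8, inhibitory_frac = 0,
                                           and_frac = 0, seed = seed))
    x <- expand(net)
    rep <- rank_components(net, xnet = x)
    expect_equal(rep$e_esm, rep$e_sp)
    expect_equal(rep$e_sp, rep$e_sigflux)
  }
})
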