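test_that("interacting-chain trajectories obey the embedding rules", {
  tail <- tail_spec(gain = 1.2, loss = 0.8)
  armor <- armor_spec(gain = 1, loss = 0.5)
  # bd mode: never a direct jump from absent to both-present
  set.seed(3)
  for (i in 1:200) {
    tr <- simulate_interacting_chains(tail, armor, "bd", duration = 2, init = "aa1")
    if (nrow(tr) < 2) next
    from <- paste0(tr$controller[-nrow(tr)], tr$dependent[-nrow(tr)])
    to <- paste0(tr$controller[-1], tr$dependent[-1])
    expect_false(any(from == "a-" & to == "pp1"))
  }
  # beta = 0: the controller, once born, is never lost
  tail0 <- char_bd("tail", gain = 2, loss = 0)
  tr <- simulate_interacting_chains(tail0, color_spec(), "ql", duration = 50,
                                    seed = 9, init = "a")
  born <- which(tr$controller == "p")[1]
  expect_false(any(tr$controller[born:nrow(tr)] == "a"))
  expect_error(simulate_interacting_chains(tail, armor, "bd", duration = -1),
               "positive")
})

test_that("interacting chains match the amalgamated CTMC (equivalence)", {
  # the tip-state distribution of the duet equals a row of exp(Qt) of the
  # ED-amalgamated matrix, for both flavours
  tail <- tail_spec(gain = 1, loss = 1)
  col <- color_spec(phi = c(0.3, 0.7), r12 = 1.5, r21 = 0.7)
  armor <- armor_spec(gain = 0.9, loss = 0.4)
  cases <- list(
    list(dep = col, mode = "ql", Q = ed_ql(tail, col), init = "a"),
    list(dep = armor, mode = "bd", Q = ed_bd(tail, armor), init = "aa1"))
  nrep <- 12000
  for (cs in cases) {
    set.seed(17)
    finals <- character(nrep)
    for (i in seq_len(nrep))
      finals[i] <- attr(simulate_interacting_chains(tail, cs$dep, cs$mode,
                                                    duration = 1, init = cs$init),
                        "final_state")
    states <- rownames(cs$Q)
    counts <- as.numeric(table(factor(finals, levels = states)))
    theory <- as.numeric(transition_probabilities(cs$Q, 1)[cs$init, ])
    p <- suppressWarnings(stats::chisq.test(counts, p = theory)$p.value)
    expect_gt(p, 0.001)
  }
})

test_that("tree simulation matches pruning-computed pattern probabilities", {
  tree <- read_newick("((A:0.4,B:0.4):0.6,C:1);")
  m <- make_model("QTC1")
  n <- 6000
  sim <- simulate_ctmc_on_tree(tree, m, n_columns = n, seed = 21)
  pats <- apply(unclass(sim), 2, paste, collapse = "")
  states <- rownames(m$Q)
  grid <- expand.grid(A = states, B = states, C = states, stringsAsFactors = FALSE)
  probs <- apply(grid, 1, function(g)
    exp(pruning_loglik(tree, m, setNames(unname(g), c("A", "B", "C")))))
  expect_equal(sum(probs), 1, tolerance = 1e-9)
  keys <- apply(grid, 1, paste, collapse = "")
  counts <- as.numeric(table(factor(pats, levels = keys)))
  p <- suppressWarnings(stats::chisq.test(counts, p = probs)$p.value)
  expect_gt(p, 0.001)
  # reproducibility and the variable-only retry cap
  sim2 <- simulate_ctmc_on_tree(tree, m, n_columns = 5, seed = 33)
  sim3 <- simulate_ctmc_on_tree(tree, m, n_columns = 5, seed = 33)
  expect_identical(unclass(sim2), unclass(sim3))
  slow <- rate_matrix(rbind(c(-1e-9, 1e-9), c(1e-9, -1e-9)), c("0", "1"))
  expect_error(simulate_ctmc_on_tree(tree, slow, n_columns = 1, seed = 1,
                                     variable_only = TRUE, max_tries = 50),
               "variable_only")
})

test_that("Yule simulation has the right cherry law and reproducibility", {
  # n = 2: split age ~ Exponential(2 * birth)
  set.seed(8)
  ages <- replicate(4000, max(ape::node.depth.edgelength(simulate_yule_tree(2, 0.5))))
  ks <- suppressWarnings(stats::ks.test(ages, stats::pexp, rate = 2 * 0.5))
  expect_gt(ks$p.value, 0.001)
  t1 <- simulate_yule_tree(10, 0.3, seed = 4)
  t2 <- simulate_yule_tree(10, 0.3, seed = 4)
  expect_equal(write_newick(t1), write_newick(t2))
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
  t3 <- simulate_yule_tree(6, 0.1, seed = 2, root_age = 1)
  expect_equal(max(ape::node.depth.edgelength(t3)), 1, tolerance = 1e-12)
  expect_error(simulate_yule_tree(1, 1), ">= 2")
})

test_that("benchmark fixtures match their published descriptions", {
  tca <- make_tca_fixture()
  expect_equal(dim(tca), c(4, 50))
  expect_true(all(apply(unclass(tca), 1, function(r) length(unique(r)) == 1)))
  expect_setequal(tca[, 1], c("aa1", "pa1", "pp1r", "pp1b"))

  for (nsyn in c(1, 11)) {
    tcp <- make_tcp_fixture(nsyn)
    expect_equal(nrow(tcp$data), 14)
    part <- attr(tcp$data, "partition")
    expect_equal(sum(part == "col"), 50)
    expect_equal(sum(part == "bin"), 9 + nsyn)
    colpart <- tcp$data[, part == "col"]
    expect_true(all(apply(colpart, 1, function(r) length(unique(r)) == 1)))
    expect_setequal(unique(as.vector(colpart)), c("a", "r", "b"))
    # every resolved clade of the true tree is supported by a synapomorphy
    splits <- edmorph:::tree_splits(tcp$true_tree, rooted = TRUE)
    bins <- tcp$data[, part == "bin"]
    supported <- apply(bins, 2, function(b)
      paste(sort(rownames(tcp$data)[b == "1"]), collapse = "|"))
    expect_setequal(intersect(splits, supported), splits)
  }
  expect_error(make_tcp_fixture(3), "1 or 11")
})
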