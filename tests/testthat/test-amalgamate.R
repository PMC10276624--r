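test_that("SMM amalgamation is the independent joint chain", {
  Qa <- mk2q(c("0", "1"), 0.7, 1.3)
  Qb <- mk2q(c("x", "y"), 0.4, 2.0)
  Q <- smm_amalgamate(Qa, Qb)
  expect_equal(rownames(Q), c("0x", "0y", "1x", "1y"))
  expect_true(validate_rate_matrix(Q)$valid)
  # simultaneous double transitions are impossible
  expect_equal(Q["0x", "1y"], 0)
  expect_equal(Q["1x", "0y"], 0)
  # P_amalg(t) = P_a(t) (x) P_b(t)
  for (t in c(0.1, 1)) {
    P <- transition_probabilities(Q, t)
    Pk <- kronecker(unclass(transition_probabilities(Qa, t)),
                    unclass(transition_probabilities(Qb, t)))
    expect_equal(unname(unclass(P)), unname(Pk), tolerance = 1e-9)
  }
  # 1-state chain is the identity element
  one <- matrix(0, 1, 1, dimnames = list("z", "z"))
  Q1 <- smm_amalgamate(Qa, one)
  expect_equal(unname(unclass(Q1))[, ], unname(unclass(Qa))[, ])
  expect_error(smm_amalgamate(mk2q(c("a", "ab")), mk2q(c("b", ""))), "collision")
})

test_that("ED amalgamation reproduces the tail-colour and tail-armour matrices", {
  # ED-ql: lambda_i = phi_i * alpha, both loss entries = beta
  alpha <- 1.7; beta <- 0.6; phi <- c(0.3, 0.7)
  Q <- ed_ql(char_bd("tail", alpha, beta), color_spec(phi = phi, r12 = 2, r21 = 0.5))
  expect_equal(rownames(Q), c("a", "pr", "pb"))
  expect_equal(Q["a", "pr"], phi[1] * alpha)
  expect_equal(Q["a", "pb"], phi[2] * alpha)
  expect_equal(unname(Q["pr", "a"]), beta)
  expect_equal(unname(Q["pb", "a"]), beta)
  expect_equal(Q["pr", "pb"], 2)
  expect_true(validate_rate_matrix(Q)$valid)

  # ED-bd: embedded vector (1, 0) prohibits the direct jump to "both present"
  Qbd <- ed_bd(char_bd("tail", alpha, beta), armor_spec(gain = 0.9, loss = 0.2))
  expect_equal(rownames(Qbd), c("aa1", "pa1", "pp1"))
  expect_equal(unname(Qbd["aa1", "pa1"]), alpha)   # lambda1 = alpha
  expect_equal(unname(Qbd["aa1", "pp1"]), 0)       # lambda2 = 0
  expect_equal(unname(Qbd["pp1", "aa1"]), beta)    # same loss from every state
  expect_equal(unname(Qbd["pp1", "pa1"]), 0.2)

  # alpha = 0 makes the absent state absorbing
  Qabs <- ed_ql(char_bd("tail", 0, beta), color_spec())
  P <- transition_probabilities(Qabs, 5)
  expect_equal(unname(P["a", ]), c(1, 0, 0), tolerance = 1e-12)

  # dimension law and validity for dependent blocks of 2..6 states
  for (k in 2:6) {
    Qd <- random_valid_Q(k)
    phi_k <- rep(1 / k, k)
    Qe <- ed_amalgamate(char_bd("c", 1, 1), Qd, phi = phi_k)
    expect_equal(nrow(Qe), k + 1)
    expect_true(validate_rate_matrix(Qe)$valid)
  }
  expect_error(ed_amalgamate(char_bd("c", 1, 1), random_valid_Q(3), phi = c(0.5, 0.5)),
               "one entry per state")
  expect_warning(ed_amalgamate(char_bd("c", 1, 1), random_valid_Q(2),
                               phi = c(1, 0), beta = c(0.1, 0.9)),
                 "canonical")
})

test_that("root vectors compose in product form", {
  d <- dependency_diagram(
    list(tail_spec(pi = c(0.5, 0.5)), color_spec(pi = c(0.4, 0.6))),
    data.frame(from = "tail", to = "color"))
  expect_equal(as.numeric(compose_root_vector(d)), c(0.5, 0.2, 0.3), tolerance = 1e-12)

  d2 <- dependency_diagram(
    list(tail_spec(pi = c(0, 1)), color_spec(pi = c(0.4, 0.6))),
    data.frame(from = "tail", to = "color"))
  expect_equal(as.numeric(compose_root_vector(d2))[1], 0)

  # the TCA composition pi_TA
  d3 <- tca_diagram()
  expect_equal(as.numeric(compose_root_vector(d3)),
               c(0.5, 0.25, 0.125, 0.125), tolerance = 1e-12)
})

test_that("hidden-state expansion is lumpable and congruent", {
  Q <- make_model("QTCA2")$Q
  E <- expand_with_hidden_states(Q, c(4, 2, 1, 1))
  expect_equal(nrow(E), 8)
  obs <- attr(E, "observable")
  L <- lump_states(E, obs)
  expect_equal(unclass(L)[rownames(Q), rownames(Q)], unclass(Q)[, ], tolerance = 1e-12)

  # a 2-state Mk expanded into identical copies lumps back
  Q2 <- mk2q(c("0", "1"))
  E2 <- expand_with_hidden_states(Q2, c(2, 2))
  expect_equal(unclass(lump_states(E2, attr(E2, "observable")))[, ],
               unclass(Q2)[, ], tolerance = 1e-12)

  # congruence: identical pruning likelihood on the quartet data
  tree <- quartet_tree()
  col <- c(A = "aa1", B = "pa1", C = "pp1r", D = "pp1b")
  rv <- rep(1 / 4, 4)
  ll0 <- pruning_loglik(tree, Q, col, root_vector = prob_vector(rv, rownames(Q)))
  amb <- vapply(col, function(s) paste(names(obs)[obs == s], collapse = "/"), "")
  rvE <- vapply(seq_along(obs), function(i) rv[match(obs[i], rownames(Q))] / sum(obs == obs[i]), 0)
  llE <- pruning_loglik(tree, E, amb, root_vector = prob_vector(rvE, rownames(E)))
  expect_equal(ll0, llE, tolerance = 1e-10)

  # non-lumpable partition errors with the offending blocks
  set.seed(7)
  Qr <- random_valid_Q(4)
  expect_error(lump_states(Qr, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")),
               "not lumpable")
  # symmetric Mk4 lumped 2+2 is a symmetric 2-state matrix
  mk4 <- rate_matrix(matrix(1, 4, 4) - diag(4, 4), fix_diagonal = TRUE)
  L4 <- lump_states(mk4, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
  expect_equal(unname(unclass(L4)), rbind(c(-2, 2), c(2, -2)), tolerance = 1e-12)
})

test_that("molecular scaling law: N sites plus a birth-death gene gives 4^N + 1 states", {
  mk4 <- function(i) rate_matrix(matrix(1, 4, 4) - diag(4, 4),
                                 labels = paste0(c("A", "C", "G", "T"), i),
                                 fix_diagonal = TRUE)
  for (N in 1:3) {
    block <- Reduce(smm_amalgamate, lapply(seq_len(N), mk4))
    Qg <- ed_amalgamate(char_bd("gene", 1, 1), block,
                        phi = rep(1 / 4^N, 4^N), absent_label = "absent")
    expect_equal(nrow(Qg), 4^N + 1)
    expect_true(validate_rate_matrix(Qg)$valid)
  }
})
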