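test_that("named factories reproduce the printed matrices", {
  # QTCA2: equal diagonals, rows rescaled uniformly
  q2 <- make_model("QTCA2")
  expect_equal(unname(unclass(q2$Q)["pa1", ]), c(1 / 3, -1, 1 / 3, 1 / 3))
  expect_equal(unname(unclass(q2$Q)["aa1", ]), c(-1, 1, 0, 0))

  # QTCA1: all non-zero rates equal; row-sum-zero fixes the diagonals
  q1 <- make_model("QTCA1")
  expect_equal(unname(unclass(q1$Q)["aa1", ]), c(-1, 1, 0, 0))
  expect_equal(unclass(q1$Q)["pa1", "pa1"], -3)
  expect_equal(unclass(q1$Q)["pp1r", "pp1b"], 1)

  # QTCA3: growth q2 (split over the coloured states), loss q1, quality q3
  q3 <- make_model("QTCA3", params = c(q1 = 0.2, q2 = 0.5))
  expect_equal(unclass(q3$Q)["pa1", "pp1r"], 0.25)
  expect_equal(unclass(q3$Q)["pa1", "pp1b"], 0.25)
  expect_equal(unclass(q3$Q)["pp1r", "pp1b"], 0.3)   # q3 = 1 - q1 - q2
  expect_equal(unname(unclass(q3$Q)["aa1", ]), c(-0.5, 0.5, 0, 0))
  expect_error(make_model("QTCA3", params = c(q1 = 0.7, q2 = 0.5)), "simplex")
  expect_error(make_model("nope"), "unknown model")
  expect_error(make_model("Mk-SMM-sw"), "not implemented")
})

test_that("free-parameter counting honours the published maxima", {
  expect_equal(count_free_parameters(make_model("ED-ql-general")), 5)
  expect_equal(count_free_parameters(make_model("ED-bd-general")), 4)
  expect_equal(count_free_parameters(make_model("TCA-general")), 7)
  expect_equal(count_free_parameters(make_model("QTC2")), 2)
  # ED5 = QTCA1 + inferred root + clock: 0 + 3 + 1 = 4
  expect_equal(count_free_parameters(make_model("ED5"), include_root = TRUE,
                                     include_clock = TRUE), 4)
  # the full grid matches the published parameter counts
  counts <- c(ED1 = 3, ED2 = 3, ED3 = 1, ED4 = 1, ED5 = 4, ED6 = 1, ED7 = 1, ED8 = 4)
  for (nm in names(counts))
    expect_equal(count_free_parameters(make_model(nm), include_root = TRUE,
                                       include_clock = TRUE),
                 unname(counts[nm]), info = nm)
})

test_that("root-vector policies resolve correctly", {
  m <- make_model("QTC1")
  expect_equal(as.numeric(resolve_root_vector(m, "equal")),
               as.numeric(resolve_root_vector(m, "equilibrium")), tolerance = 1e-12)
  q2 <- make_model("QTCA2")
  eq <- resolve_root_vector(q2, "equilibrium")
  # left-null-space oracle
  pi0 <- as.numeric(stationary_distribution(q2$Q))
  expect_equal(as.numeric(eq), pi0, tolerance = 1e-12)
  expect_lt(max(abs(as.numeric(eq) %*% unclass(q2$Q))), 1e-12)
  lat <- resolve_root_vector(q2, "inferred")
  expect_s3_class(lat, "latent_root")
  expect_equal(lat$n_free, 3)
})

rdirich_test <- function(k) { g <- rexp(k); g / sum(g) }

test_that("factories yield valid generators across random admissible draws", {
  set.seed(5)
  for (i in 1:100) {
    fam <- sample(c("QTC2", "QTCA3", "ED-ql-general", "ED-bd-general", "TCA-general"), 1)
    p <- switch(fam,
      "QTC2" = { x <- rdirich_test(3); c(beta = x[1], lambda = x[2]) },
      "QTCA3" = { x <- rdirich_test(3); c(q1 = x[1], q2 = x[2]) },
      "ED-ql-general" = c(alpha = rexp(1), beta = rexp(1), phi1 = runif(1),
                          g_rb = rexp(1), g_br = rexp(1)),
      "ED-bd-general" = c(alpha1 = rexp(1), beta1 = rexp(1), alphaA = rexp(1),
                          betaA = rexp(1)),
      "TCA-general" = c(alpha1 = rexp(1), beta1 = rexp(1), alpha2 = rexp(1),
                        phiC1 = runif(1), beta2 = rexp(1), g_rb = rexp(1),
                        g_br = rexp(1)))
    m <- make_model(fam, params = p)
    expect_true(validate_rate_matrix(m$Q)$valid, info = fam)
  }
})

test_that("QTC1 is time-reversible and the TCA parametrizations are not", {
  m <- make_model("QTC1")
  pi <- as.numeric(resolve_root_vector(m, "equal"))
  Q <- unclass(m$Q)
  expect_equal(pi * Q, t(pi * Q), tolerance = 1e-15)  # detailed balance, exact
  # the structural zeros of the TCA matrices (aa1 -> pp1* prohibited, but the
  # reverse allowed) break detailed balance outright
  for (nm in c("QTCA1", "QTCA2", "QTCA3")) {
    mm <- make_model(nm)
    pim <- as.numeric(stationary_distribution(mm$Q))
    F <- pim * unclass(mm$Q)
    expect_gt(max(abs(F - t(F))), 1e-6)  # at least one violated balance condition
  }
  # QTC2's stationary vector differs from the equal root vector, so rooted
  # inference still matters even though its flows balance
  q2 <- make_model("QTC2", params = c(beta = 0.5, lambda = 0.2))
  expect_gt(max(abs(as.numeric(stationary_distribution(q2$Q)) - 1 / 3)), 0.05)
})

test_that("Mk-SMM-ind is the eight-state independent-chain baseline", {
  m <- make_model("Mk-SMM-ind")
  expect_equal(nrow(m$Q), 8)
  obs <- m$observable
  expect_setequal(unique(obs), c("aa1", "pa1", "pp1r", "pp1b"))
  # uniform observable initial vector, split within hidden blocks
  rv <- as.numeric(m$root_vector)
  agg <- tapply(rv, obs, sum)
  expect_equal(as.numeric(agg[c("aa1", "pa1", "pp1r", "pp1b")]), rep(0.25, 4),
               tolerance = 1e-12)
  # hidden states simulate the dependency: the observable partition is NOT
  # strongly lumpable (unlike the ED construction, which needs no hidden states)
  expect_error(lump_states(m$Q, obs), "not lumpable")
})


test_that("model configurations load from JSON", {
  m <- read_model_config('{"family": "QTCA3", "params": {"q1": 0.2, "q2": 0.5},
                           "root_policy": "equilibrium"}')
  expect_equal(unclass(m$Q)["pa1", "pp1r"], 0.25)
  expect_equal(m$root_policy, "equilibrium")
  expect_equal(as.numeric(m$root_vector),
               as.numeric(stationary_distribution(m$Q)), tolerance = 1e-12)
})
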