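test_that("RF distance equals the bipartition-set oracle", {
  t1 <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- read_newick("((A:1,C:1):1,(B:1,D:1):1);")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), 2)
  expect_error(rf_distance(t1, read_newick("((A:1,B:1):1,(C:1,E:1):1);")),
               "taxon sets")
  skip_if_not_installed("phangorn")
  set.seed(12)
  for (i in 1:10) {
    a <- simulate_yule_tree(8, 1)
    b <- simulate_yule_tree(8, 1)
    b$tip.label <- a$tip.label[match(b$tip.label, sort(b$tip.label))]
    expect_equal(rf_distance(a, b), as.integer(phangorn::RF.dist(a, b)))
  }
})

test_that("Bayes factors are marginal log-likelihood differences", {
  expect_equal(bayes_factor(-292.29, -313.42), 21.13, tolerance = 1e-12)
  expect_equal(bayes_factor(-292.29, -296.13), 3.84, tolerance = 1e-12)
  expect_equal(bayes_factor(-5, -5), 0)
})

test_that("proportion-differential bootstrap matches the exact resampling law", {
  # identical vectors: pd = 0 and the tie-heavy p lands high
  r <- proportion_differential_bootstrap(rep(1, 30), rep(1, 30), reps = 500, seed = 1)
  expect_equal(r$pd, 0)
  expect_gte(r$p_value, 0.5)
  r2 <- proportion_differential_bootstrap(rep(1, 100), rep(0, 100), reps = 500, seed = 1)
  expect_equal(r2$pd, 1)
  expect_lt(r2$p_value, 0.01)
  expect_error(proportion_differential_bootstrap(1:3, 1:2), "paired")

  # exact oracle: pd* is the mean of n iid draws of d = a - b from the
  # empirical difference distribution; P(sum <= 0) by convolution
  a <- c(rep(1, 12), rep(0, 8)); b <- c(rep(1, 7), rep(0, 5), rep(1, 2), rep(0, 6))
  n <- 20
  d <- a - b
  pr <- table(factor(d, levels = -1:1)) / n
  pmf <- c(1)                      # distribution of the running sum, offset n
  for (i in seq_len(n)) {
    new <- numeric(length(pmf) + 2)
    new[1:length(pmf)] <- new[1:length(pmf)] + pmf * pr[[1]]
    new[2:(length(pmf) + 1)] <- new[2:(length(pmf) + 1)] + pmf * pr[[2]]
    new[3:(length(pmf) + 2)] <- new[3:(length(pmf) + 2)] + pmf * pr[[3]]
    pmf <- new
  }
  exact <- sum(pmf[seq_len(n + 1)])  # P(sum <= 0): offsets -n..0
  reps <- 20000
  rb <- proportion_differential_bootstrap(a, b, reps = reps, seed = 42)
  mc_err <- sqrt(exact * (1 - exact) / reps)
  expect_lt(abs(rb$p_value - exact), 4 * mc_err)
})

test_that("consensus and MCC trees summarise posterior samples", {
  taxa <- c("A", "B", "C", "D")
  snap <- function(nwk) {
    pt <- edmorph:::phylo_to_ptree(edmorph:::read_newick(nwk))
    pt <- edmorph:::reindex_ptree_taxa(pt, taxa)
    list(parent = pt$parent, age = pt$age)
  }
  fake_fit <- function(snaps) {
    structure(list(runs = list(list(trace = data.frame(gen = seq_along(snaps)),
                                    trees = snaps, accept = c(psi = 0.5))),
                   config = mcmc_config(generations = 10, n_runs = 1),
                   taxa = taxa), class = "ed_mcmc")
  }
  s1 <- snap("((A:0.3,B:0.3):0.7,(C:0.5,D:0.5):0.5);")
  fit_same <- fake_fit(rep(list(s1), 10))
  mj <- consensus_tree(fit_same, burnin = 0)
  mcc <- mcc_tree(fit_same, burnin = 0)
  expect_equal(rf_distance(mj, mcc), 0)
  expect_true(all(as.numeric(mj$node.label) == 1))
  expect_equal(clade_posterior(fit_same, c("A", "B"), burnin = 0), 1)

  # 50/50 split on one clade becomes a polytomy in the majority-rule tree
  s2 <- snap("((A:0.3,C:0.3):0.7,(B:0.5,D:0.5):0.5);")
  fit_split <- fake_fit(c(rep(list(s1), 5), rep(list(s2), 5)))
  mj2 <- consensus_tree(fit_split, burnin = 0)
  expect_equal(mj2$Nnode, 1)  # star: no clade above 50%
})

test_that("prior-only MCMC recovers the Yule and Exponential priors", {
  taxa <- paste0("t", 1:4)
  nodata <- character_matrix(matrix(character(0), 4, 0,
                                    dimnames = list(taxa, NULL)))
  cfg <- mcmc_config(generations = 150000, n_runs = 1, seed = 11, thin = 150)
  fit <- ed_mcmc(nodata, make_model("QTC1"), cfg)
  tr <- edmorph:::pooled_trace(fit, 0.1)
  ks_psi <- suppressWarnings(stats::ks.test(unique(tr$psi), stats::pexp, rate = 10))
  expect_gt(ks_psi$p.value, 0.001)
  snaps <- edmorph:::pooled_snapshots(fit, 0.1)
  set.seed(77)
  ages <- vapply(snaps, function(s) s$age[sample(6:7, 1)], 0)
  m <- length(ages)
  lam <- stats::rexp(m, 1); u <- stats::runif(m)
  direct <- -log(1 - u * (1 - exp(-lam))) / lam
  ks_age <- suppressWarnings(stats::ks.test(ages, direct))
  expect_gt(ks_age$p.value, 0.001)
  # topology frequencies match the forward Yule simulator (uniform over
  # ranked histories: balanced shapes are half as probable as caterpillars)
  key_of <- function(s) paste(sort(edmorph:::snapshot_clades(s, taxa)$keys),
                              collapse = ";")
  keys_mcmc <- vapply(snaps, key_of, "")
  keys_yule <- replicate(3000, {
    phy <- simulate_yule_tree(4, 1)
    pt <- edmorph:::phylo_to_ptree(phy)
    pt$tip.label <- sample(taxa)
    paste(sort(edmorph:::ptree_clades(pt)), collapse = ";")
  })
  lv <- sort(unique(c(keys_mcmc, keys_yule)))
  tab <- rbind(as.numeric(table(factor(keys_mcmc, lv))),
               as.numeric(table(factor(keys_yule, lv))))
  p <- suppressWarnings(stats::chisq.test(tab)$p.value)
  expect_gt(p, 0.001)
})

test_that("clock rate recovery: psi falls in its 95% interval", {
  # data simulated under ED6 with known psi on a fixed tree; the credible
  # interval should cover the truth in nearly all replicates
  set.seed(99)
  tree <- simulate_yule_tree(14, 0.1, seed = 31, root_age = 1)
  m6 <- make_model("ED6")
  psi_true <- 0.5
  hits <- 0; nrep <- 12
  for (i in seq_len(nrep)) {
    dat <- simulate_ctmc_on_tree(tree, m6, n_columns = 200, seed = 500 + i,
                                 variable_only = TRUE, psi = psi_true)
    cfg <- mcmc_config(generations = 3000, n_runs = 1, seed = i,
                       fixed_tree = TRUE, thin = 3)
    fit <- ed_mcmc(dat, m6, cfg, tree = tree)
    s <- summary(fit, burnin = 0.3)$params
    ci <- s[s$parameter == "psi", c("lower95", "upper95")]
    if (psi_true >= ci$lower95 && psi_true <= ci$upper95) hits <- hits + 1
  }
  expect_gte(hits / nrep, 0.9)
})

test_that("stepping-stone matches direct integration on a fixed-tree toy", {
  tree <- read_newick("((A:0.3,B:0.3):0.7,C:1);")
  dat <- character_matrix(rbind(A = c("0", "0", "1", "0", "1"),
                                B = c("1", "0", "1", "0", "1"),
                                C = c("1", "1", "0", "1", "0")))
  mod <- mk_model(2)
  integrand <- function(psi) vapply(psi, function(p)
    tryCatch(exp(variable_only_loglik(tree, mod, dat, psi = p)) *
               stats::dexp(p, 10), error = function(e) 0), 0)
  oracle <- log(stats::integrate(integrand, 1e-7, 50, rel.tol = 1e-9)$value)
  cfg <- mcmc_config(n_runs = 2, seed = 5, fixed_tree = TRUE)
  ss <- stepping_stone_mln(dat, mod, cfg, tree = tree,
                           n_stones = 24, gens_per_stone = 1200)
  expect_lt(abs(ss$mln - oracle), 0.05)
  # more stones cannot hurt: estimator spread across runs stays small
  expect_lt(abs(ss$runs[1] - ss$runs[2]), 0.2)
})

test_that("posterior-predictive simulation reproduces data dimensions and states", {
  tca <- make_tca_fixture()
  fit <- ed_mcmc(tca, make_model("ED6"),
                 mcmc_config(generations = 2000, n_runs = 1, seed = 13, thin = 10))
  reps <- simulate(fit, nsim = 2, seed = 5)
  expect_length(reps, 2)
  for (r in reps) {
    expect_equal(dim(r), dim(tca))
    expect_true(all(as.vector(r) %in% c("aa1", "pa1", "pp1r", "pp1b")))
    # Mkv world: no constant columns
    expect_false(any(apply(unclass(r), 2, function(cl) length(unique(cl)) == 1)))
  }
  expect_identical(simulate(fit, nsim = 1, seed = 9), simulate(fit, nsim = 1, seed = 9))
})
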