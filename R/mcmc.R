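#' MCMC configuration
#'
#' Settings for the Bayesian clock analysis: Metropolis-Hastings over
#' (rooted topology, node ages, clock rate psi, Yule birth rate, model
#' simplex parameters, inferred root frequencies). Priors follow the dating
#' framework used throughout: psi ~ Exponential(10), Yule prior on ranked
#' labelled topologies and node ages with the root age fixed at 1.0 (birth
#' rate given an Exponential(1) hyperprior and sampled), flat Dirichlet
#' priors on rate simplices and inferred root frequencies. Likelihoods are
#' conditioned on variable characters (Mkv) by default.
#'
#' @param generations MCMC generations per run.
#' @param burnin fraction of initial samples discarded by summaries.
#' @param n_runs independent runs (distinct seeds).
#' @param thin record every `thin` generations (default: about 2000 samples).
#' @param seed integer seed; run r uses `seed + r - 1`.
#' @param fixed_tree if TRUE, topology and node ages are held at the
#'   supplied tree (only psi and model parameters are sampled).
#' @param mkv condition the likelihood on variable characters.
#' @param tune list of proposal tunings: `psi_eps`, `lambda_eps`
#'   (multiplier widths), `dirichlet_conc` (simplex proposal concentration).
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(generations = 20000, burnin = 0.3, n_runs = 2,
                        thin = NULL, seed = 1, fixed_tree = FALSE, mkv = TRUE,
                        tune = list()) {
  stopifnot(generations > 0, burnin >= 0, burnin < 1, n_runs >= 1)
  if (is.null(thin)) thin <- max(1L, as.integer(generations %/% 2000))
  tn <- utils::modifyList(list(psi_eps = 1.0, lambda_eps = 1.2, dirichlet_conc = 100),
                          tune)
  structure(list(generations = as.integer(generations), burnin = burnin,
                 n_runs = as.integer(n_runs), thin = as.integer(thin),
                 seed = as.integer(seed), fixed_tree = fixed_tree, mkv = mkv,
                 tune = tn),
            class = "mcmc_config")
}

# ---- engine construction ---------------------------------------------------

build_engine <- function(data, model, config, tree = NULL, constraints = NULL) {
  data <- as.matrix(data)
  taxa <- rownames(data)
  n <- length(taxa)
  if (n < 2) stop("need at least two taxa")
  models <- if (inherits(model, "amalgamated_model")) {
    setNames(list(model), attr(data, "partition")[1] %||% "all")
  } else model
  part <- attr(data, "partition") %||% rep(names(models)[1], ncol(data))
  if (!all(part %in% names(models)))
    stop("partition(s) without a model: ",
         paste(setdiff(unique(part), names(models)), collapse = ", "))
  parts <- lapply(setNames(nm = unique(part)), function(p) {
    mod <- models[[p]]
    states <- rownames(mod$Q)
    cols <- data[, part == p, drop = FALSE]
    key <- apply(cols, 2, paste, collapse = "\r")
    uk <- unique(key)
    patterns <- cols[, match(uk, key), drop = FALSE]
    weights <- as.numeric(table(factor(key, levels = uk)))
    k <- length(states)
    # appended constant patterns feed the Mkv correction
    pats <- cbind(patterns, matrix(rep(states, each = n), n))
    tipL <- lapply(seq_len(n), function(i) tokens_to_indicators(pats[i, ], states))
    free_simplex <- !is.null(mod$simplex)
    if (length(mod$free) && !free_simplex)
      stop("ed_mcmc supports models whose free rate parameters form a simplex (",
           mod$name, " has unconstrained free rates); fix them via make_model(params=...)")
    list(name = p, model = mod, states = states, k = k,
         npat = ncol(patterns), weights = weights, ncols = ncol(cols),
         tipL = tipL, free_simplex = free_simplex,
         inferred = mod$root_policy == "inferred")
  })
  constr <- lapply(constraints, function(cl) {
    idx <- match(cl, taxa)
    if (anyNA(idx)) stop("constraint names unknown taxa: ",
                         paste(cl[is.na(idx)], collapse = ", "))
    sort(idx)
  })
  list(taxa = taxa, n = n, parts = parts, config = config, tree = tree,
       constraints = constr)
}

# random ultrametric starting tree honouring monophyly constraints
ptree_from_constraints <- function(taxa, constraints) {
  n <- length(taxa)
  sets <- lapply(constraints, sort)
  sets <- sets[order(-lengths(sets))]
  node <- function(tipset) {
    inner <- Filter(function(s) length(s) < length(tipset) && all(s %in% tipset), sets)
    used <- integer(0); kids <- list()
    for (s in inner) {
      if (!any(s %in% used)) { kids <- c(kids, list(node(s))); used <- c(used, s) }
    }
    for (t in setdiff(tipset, used)) kids <- c(kids, list(t))
    while (length(kids) > 2) {       # random binarisation of polytomies
      pick <- sample(seq_along(kids), 2)
      kids <- c(kids[-pick], list(list(kids[[pick[1]]], kids[[pick[2]]])))
    }
    if (length(kids) == 1) kids[[1]] else list(kids[[1]], kids[[2]])
  }
  top <- node(seq_len(n))
  parent <- integer(2L * n - 1L); children <- vector("list", 2L * n - 1L)
  age <- numeric(2L * n - 1L)
  nxt <- n + 1L
  place <- function(nd, id) {
    kid_ids <- integer(2)
    for (j in 1:2) {
      if (is.numeric(nd[[j]]) && length(nd[[j]]) == 1 && nd[[j]] <= n) {
        kid_ids[j] <- nd[[j]]
      } else {
        nxt <<- nxt + 1L
        kid_ids[j] <- nxt
        place(nd[[j]], kid_ids[j])
      }
    }
    parent[kid_ids] <<- id
    children[[id]] <<- kid_ids
    age[id] <<- max(age[kid_ids]) + stats::runif(1, 0.5, 1)
  }
  place(top, n + 1L)
  scale <- age[n + 1L]
  age[(n + 1L):(2L * n - 1L)] <- age[(n + 1L):(2L * n - 1L)] / scale
  list(n = n, parent = parent, children = children, age = age, tip.label = taxa)
}

part_state_of <- function(part) {
  mod <- part$model
  out <- list()
  if (part$free_simplex) {
    k3 <- length(mod$simplex)
    full <- c(mod$params, 1 - sum(mod$params))
    out$simplex <- setNames(full, mod$simplex)
  }
  if (part$inferred) out$rootfreq <- rep(1 / part$k, part$k)
  out$spectral <- spectral_of(mod$Q)
  out$rootvec <- part_root_vec(part, out)
  out
}

part_root_vec <- function(part, ps) {
  mod <- part$model
  if (part$inferred) return(ps$rootfreq)
  if (mod$root_policy == "equilibrium") {
    Q <- rate_matrix(ps$spectral$Q, labels = part$states)
    return(as.numeric(stationary_distribution(Q)))
  }
  as.numeric(resolve_root_vector(mod, mod$root_policy))
}

rebuild_part_Q <- function(part, simplex) {
  mod <- part$model
  pars <- simplex[mod$free]
  m2 <- update_model(mod, pars)
  m2$Q
}

part_loglik <- function(part, pt, psi, ps, mkv = TRUE) {
  ll <- prune_patterns(pt, durations_of(pt, psi), ps$spectral, part$tipL, ps$rootvec)
  obs <- seq_len(part$npat)
  datall <- sum(part$weights * ll[obs])
  if (!mkv) return(datall)
  p_const <- sum(exp(ll[part$npat + seq_len(part$k)]))
  # cancellation guard: at psi -> 0 the conditioned ratio stays finite, so
  # clamp rather than return -Inf (the region has ~zero prior mass anyway)
  if (p_const >= 1) p_const <- 1 - 1e-15
  datall - part$ncols * log1p(-p_const)
}

# ---- priors ----------------------------------------------------------------

log_tree_prior <- function(pt, lambda) {
  n <- pt$n
  if (n == 2) return(0)
  internal <- (n + 2L):(2L * n - 1L)
  s <- pt$age[internal]
  if (any(s <= 0) || any(s >= 1)) return(-Inf)
  dens <- sum(log(lambda) - lambda * s - log1p(-exp(-lambda)))
  # uniform over ranked labelled topologies + order statistics factor
  logH <- lfactorial(n) + lfactorial(n - 1) - (n - 1) * log(2)
  dens + lfactorial(n - 2) - logH
}

ldirichlet <- function(x, alpha) {
  if (any(x <= 0)) return(-Inf)
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

log_prior_of <- function(state, engine) {
  lp <- stats::dexp(state$psi, 10, log = TRUE) +
    stats::dexp(state$lambda, 1, log = TRUE) +
    log_tree_prior(state$pt, state$lambda)
  for (i in seq_along(engine$parts)) {
    ps <- state$parts[[i]]
    if (!is.null(ps$simplex)) lp <- lp + ldirichlet(ps$simplex, rep(1, length(ps$simplex)))
    if (!is.null(ps$rootfreq)) lp <- lp + ldirichlet(ps$rootfreq, rep(1, length(ps$rootfreq)))
  }
  lp
}

# ---- state initialisation --------------------------------------------------
# (constraints restrict the topology support; moves proposing a violating
# topology are rejected, which preserves detailed balance on the subspace)

random_ranked_ptree <- function(taxa, lambda = 1) {
  n <- length(taxa)
  m <- 2L * n - 1L
  parent <- integer(m); children <- vector("list", m)
  age <- numeric(m)
  if (n > 2) {
    s <- sort(-log(1 - stats::runif(n - 2) * (1 - exp(-lambda))) / lambda)
    s <- pmin(pmax(s, 1e-6), 1 - 1e-6)
  } else s <- numeric(0)
  ages_internal <- c(s, 1)                 # ascending; root last
  active <- seq_len(n)
  # ape numbering: root must be n+1; assign ids so the LAST join is n+1
  ids <- c((n + 2L):(2L * n - 1L), n + 1L)
  if (n == 2) ids <- n + 1L
  for (j in seq_len(n - 1L)) {
    pick <- sample(seq_along(active), 2)
    a <- active[pick[1]]; b <- active[pick[2]]
    nd <- ids[j]
    parent[a] <- nd; parent[b] <- nd
    children[[nd]] <- c(a, b)
    age[nd] <- ages_internal[j]
    active <- c(active[-pick], nd)
  }
  list(n = n, parent = parent, children = children, age = age, tip.label = taxa)
}

init_state <- function(engine, seed) {
  set.seed(seed)
  cfg <- engine$config
  if (!is.null(engine$tree)) {
    pt <- phylo_to_ptree(engine$tree)
    pt <- reindex_ptree_taxa(pt, engine$taxa)
  } else {
    if (cfg$fixed_tree) stop("fixed_tree requires a tree")
    pt <- if (length(engine$constraints))
      ptree_from_constraints(engine$taxa, engine$constraints)
    else random_ranked_ptree(engine$taxa)
  }
  if (!satisfies_constraints(pt, engine$constraints))
    stop("starting tree violates the monophyly constraints")
  state <- list(pt = pt, psi = 0.1, lambda = 1,
                parts = lapply(engine$parts, part_state_of))
  state$partll <- vapply(seq_along(engine$parts), function(i)
    part_loglik(engine$parts[[i]], state$pt, state$psi, state$parts[[i]], cfg$mkv),
    0)
  state$prior <- log_prior_of(state, engine)
  state
}

# make tip indices of the ptree match engine$taxa order
reindex_ptree_taxa <- function(pt, taxa) {
  perm <- match(pt$tip.label, taxa)
  if (anyNA(perm)) stop("tree taxa do not match data taxa")
  m <- length(pt$parent)
  map <- seq_len(m); map[seq_len(pt$n)] <- perm
  parent2 <- integer(m); children2 <- vector("list", m); age2 <- numeric(m)
  for (v in seq_len(m)) {
    parent2[map[v]] <- if (pt$parent[v] > 0) map[pt$parent[v]] else 0L
    age2[map[v]] <- pt$age[v]
    if (v > pt$n) children2[[map[v]]] <- map[pt$children[[v]]]
  }
  list(n = pt$n, parent = parent2, children = children2, age = age2,
       tip.label = taxa)
}

# ---- moves -----------------------------------------------------------------
# each returns NULL (unavailable) or list(state, logH, affected): affected is
# integer vector of partition indices to recompute, or 0 for prior-only.

# sample() treats a scalar first argument as 1:x; this never does
sample1 <- function(x) x[sample.int(length(x), 1L)]

move_age <- function(state, engine) {
  pt <- state$pt; n <- pt$n
  if (n <= 2) return(NULL)
  v <- sample1((n + 2L):(2L * n - 1L))
  lo <- max(pt$age[pt$children[[v]]])
  hi <- pt$age[pt$parent[v]]
  pt$age[v] <- stats::runif(1, lo, hi)
  state$pt <- pt
  list(state = state, logH = 0, affected = seq_along(engine$parts))
}

move_nni <- function(state, engine) {
  pt <- state$pt; n <- pt$n
  if (n <= 2) return(NULL)
  cands <- (n + 2L):(2L * n - 1L)
  c1 <- sample1(cands)
  p <- pt$parent[c1]
  sib <- setdiff(pt$children[[p]], c1)
  g <- pt$children[[c1]][sample.int(2, 1)]
  if (pt$age[sib] >= pt$age[c1]) return(list(state = state, logH = -Inf,
                                             affected = integer(0)))
  pt$children[[c1]] <- c(setdiff(pt$children[[c1]], g), sib)
  pt$children[[p]] <- c(c1, g)
  pt$parent[sib] <- c1
  pt$parent[g] <- p
  if (!satisfies_constraints(pt, engine$constraints))
    return(list(state = state, logH = -Inf, affected = integer(0)))
  state$pt <- pt
  list(state = state, logH = 0, affected = seq_along(engine$parts))
}

subtree_nodes <- function(pt, v) {
  out <- integer(0); stack <- v
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, x)
    if (x > pt$n) stack <- c(stack, pt$children[[x]])
  }
  out
}

spr_candidates <- function(pt) {
  root <- pt$n + 1L
  which(pt$parent > 0L & pt$parent != root)
}

move_spr <- function(state, engine) {
  pt <- state$pt; n <- pt$n; root <- n + 1L
  cands <- spr_candidates(pt)
  if (!length(cands)) return(NULL)
  v <- sample1(cands)
  Nv <- length(cands)
  p <- pt$parent[v]; q <- pt$parent[p]
  o <- setdiff(pt$children[[p]], v)
  # prune: connect o to q
  pt$children[[q]] <- c(setdiff(pt$children[[q]], p), o)
  pt$parent[o] <- q
  pt$parent[p] <- 0L
  sub <- subtree_nodes(pt, v)
  len_r <- pt$age[q] - max(pt$age[v], pt$age[o])   # reverse interval
  # eligible target edges (u,w) in the pruned tree
  nodes <- setdiff(which(pt$parent > 0L), sub)
  elig <- nodes[vapply(nodes, function(w)
    pt$age[pt$parent[w]] > max(pt$age[v], pt$age[w]), TRUE)]
  if (!length(elig)) return(NULL)
  w <- sample1(elig)
  u <- pt$parent[w]
  lo <- max(pt$age[v], pt$age[w]); hi <- pt$age[u]
  newage <- stats::runif(1, lo, hi)
  # regraft p on edge (u, w)
  pt$children[[u]] <- c(setdiff(pt$children[[u]], w), p)
  pt$parent[p] <- u
  pt$children[[p]] <- c(v, w)
  pt$parent[w] <- p
  pt$age[p] <- newage
  if (!satisfies_constraints(pt, engine$constraints))
    return(list(state = state, logH = -Inf, affected = integer(0)))
  state$pt <- pt
  Nv2 <- length(spr_candidates(pt))
  logH <- log(Nv) - log(Nv2) + log(hi - lo) - log(len_r)
  list(state = state, logH = logH, affected = seq_along(engine$parts))
}

move_psi <- function(state, engine) {
  eps <- engine$config$tune$psi_eps
  f <- exp(eps * (stats::runif(1) - 0.5))
  state$psi <- state$psi * f
  list(state = state, logH = log(f), affected = seq_along(engine$parts))
}

move_lambda <- function(state, engine) {
  eps <- engine$config$tune$lambda_eps
  f <- exp(eps * (stats::runif(1) - 0.5))
  state$lambda <- state$lambda * f
  list(state = state, logH = log(f), affected = integer(0))
}

rdirich <- function(alpha) {
  g <- stats::rgamma(length(alpha), alpha, 1)
  g / sum(g)
}

propose_simplex <- function(x, conc) {
  a_fwd <- conc * x + 1
  y <- rdirich(a_fwd)
  a_rev <- conc * y + 1
  logH <- ldirichlet(x, a_rev) - ldirichlet(y, a_fwd)
  list(y = y, logH = logH)
}

move_simplex <- function(state, engine, i, what) {
  conc <- engine$config$tune$dirichlet_conc
  ps <- state$parts[[i]]
  if (what == "q") {
    pr <- propose_simplex(ps$simplex, conc)
    ps$simplex[] <- pr$y
    Q <- tryCatch(rebuild_part_Q(engine$parts[[i]], ps$simplex),
                  error = function(e) NULL)
    if (is.null(Q)) return(list(state = state, logH = -Inf, affected = integer(0)))
    ps$spectral <- spectral_of(Q)
    ps$rootvec <- part_root_vec(engine$parts[[i]], ps)
  } else {
    pr <- propose_simplex(ps$rootfreq, conc)
    ps$rootfreq <- pr$y
    ps$rootvec <- pr$y
  }
  state$parts[[i]] <- ps
  list(state = state, logH = pr$logH, affected = i)
}

# ---- chain runner ----------------------------------------------------------

make_moves <- function(engine, state0) {
  cfg <- engine$config
  moves <- list(); weights <- numeric(0)
  if (!cfg$fixed_tree && engine$n > 2) {
    moves <- c(moves, list(age = move_age, nni = move_nni, spr = move_spr))
    weights <- c(weights, 0.25, 0.20, 0.15)
  }
  moves <- c(moves, list(psi = move_psi, lambda = move_lambda))
  weights <- c(weights, 0.18, 0.05)
  for (i in seq_along(engine$parts)) {
    if (engine$parts[[i]]$free_simplex) {
      nm <- paste0("q_", engine$parts[[i]]$name)
      moves[[nm]] <- local({ ii <- i; function(s, e) move_simplex(s, e, ii, "q") })
      weights <- c(weights, 0.12)
    }
    if (engine$parts[[i]]$inferred) {
      nm <- paste0("root_", engine$parts[[i]]$name)
      moves[[nm]] <- local({ ii <- i; function(s, e) move_simplex(s, e, ii, "root") })
      weights <- c(weights, 0.12)
    }
  }
  list(moves = moves, weights = weights / sum(weights))
}

run_chain <- function(engine, state, gens, power = 1, record_every = 1,
                      record_trees = TRUE) {
  cfg <- engine$config
  mv <- make_moves(engine, state)
  nm <- names(mv$moves)
  acc <- setNames(numeric(length(nm)), nm)
  try_ <- setNames(numeric(length(nm)), nm)
  nrec <- gens %/% record_every
  par_names <- trace_par_names(engine)
  trace <- matrix(NA_real_, nrec, 4 + length(par_names))
  colnames(trace) <- c("gen", "loglik", "logprior", "psi", par_names)
  trees <- if (record_trees) vector("list", nrec) else NULL
  r <- 0L
  for (g in seq_len(gens)) {
    mi <- sample.int(length(nm), 1, prob = mv$weights)
    try_[mi] <- try_[mi] + 1
    prop <- mv$moves[[mi]](state, engine)
    if (!is.null(prop) && is.finite(prop$logH)) {
      cand <- prop$state
      aff <- prop$affected
      newll <- state$partll
      for (i in aff) newll[i] <- part_loglik(engine$parts[[i]], cand$pt, cand$psi,
                                             cand$parts[[i]], cfg$mkv)
      newprior <- log_prior_of(cand, engine)
      lldiff <- sum(newll) - sum(state$partll)
      logr <- (if (power == 0) 0 else power * lldiff) +
        (newprior - state$prior) + prop$logH
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        cand$partll <- newll
        cand$prior <- newprior
        state <- cand
        acc[mi] <- acc[mi] + 1
      }
    }
    if (g %% record_every == 0L) {
      r <- r + 1L
      trace[r, ] <- c(g, sum(state$partll), state$prior, state$psi,
                      trace_par_values(engine, state))
      if (record_trees) trees[[r]] <- list(parent = state$pt$parent,
                                           age = state$pt$age)
    }
  }
  list(trace = as.data.frame(trace), trees = trees, state = state,
       accept = ifelse(try_ > 0, acc / pmax(try_, 1), NA))
}

trace_par_names <- function(engine) {
  out <- "lambda"
  for (p in engine$parts) {
    if (p$free_simplex) out <- c(out, paste0(p$name, ".", p$model$simplex))
    if (p$inferred) out <- c(out, paste0(p$name, ".pi.", p$states))
  }
  out
}

trace_par_values <- function(engine, state) {
  out <- state$lambda
  for (i in seq_along(engine$parts)) {
    ps <- state$parts[[i]]
    if (!is.null(ps$simplex)) out <- c(out, ps$simplex)
    if (!is.null(ps$rootfreq)) out <- c(out, ps$rootfreq)
  }
  out
}

#' Bayesian clock MCMC under amalgamated models
#'
#' The central fitting function: Metropolis-Hastings sampling of rooted
#' ultrametric time trees (root age fixed at 1.0), the global clock rate
#' psi, the Yule birth rate, and any model simplex parameters or inferred
#' root frequencies, targeting prior x variable-only likelihood. Data may be
#' partitioned (columns of `data` carry a partition attribute) with one
#' model per partition sharing the tree and clock. Runs `config$n_runs`
#' independent chains from distinct seeds.
#'
#' @param data `character_matrix`; cells must use the model's amalgamated
#'   state labels (recode hierarchies first, see [recode_characters()]). A
#'   zero-column matrix samples the prior.
#' @param model an `amalgamated_model`, or a named list of models matching
#'   the data's partition names.
#' @param config an [mcmc_config()].
#' @param tree optional starting tree (`phylo`); required (and held fixed)
#'   when `config$fixed_tree = TRUE`.
#' @param constraints optional list of taxon-label vectors that must remain
#'   monophyletic (topology proposals violating them are rejected); used
#'   e.g. to hold a reference backbone resolved while free clades are
#'   sampled.
#' @return object of class `ed_mcmc` with per-run traces, sampled trees and
#'   acceptance rates; see [summary.ed_mcmc()], [consensus_tree()],
#'   [mcc_tree()], [clade_posterior()].
#' @export
ed_mcmc <- function(data, model, config = mcmc_config(), tree = NULL,
                    constraints = NULL) {
  engine <- build_engine(data, model, config, tree, constraints)
  runs <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    state <- init_state(engine, config$seed + r - 1L)
    runs[[r]] <- run_chain(engine, state, config$generations, power = 1,
                           record_every = config$thin)
  }
  structure(list(runs = runs, config = config, engine = engine,
                 taxa = engine$taxa),
            class = "ed_mcmc")
}
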