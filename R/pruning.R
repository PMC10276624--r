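# Spectral cache for fast P(t) = exp(Qt) along many branches.
# P(t) = sum_m C_m e^{d_m t} with C_m = V[,m] %o% Vinv[m,]; all branches are
# obtained with one complex matrix product. Falls back to dense Pade expm
# when Q is (numerically) non-diagonalizable.
spectral_of <- function(Q) {
  k <- nrow(Q)
  sp <- tryCatch({
    e <- eigen(unclass(Q))
    Vinv <- solve(e$vectors)
    Cflat <- matrix(0i, k * k, k)
    for (m in seq_len(k)) Cflat[, m] <- as.vector(e$vectors[, m] %o% Vinv[m, ])
    list(method = "eigen", Cflat = Cflat, d = e$values, k = k, Q = unclass(Q))
  }, error = function(e) NULL)
  P2 <- as.matrix(Matrix::expm(Matrix::Matrix(unclass(Q) * 0.7)))
  if (!is.null(sp)) {
    # accept only if it reproduces expm at a representative time
    P1 <- Re(matrix(sp$Cflat %*% exp(sp$d * 0.7), k, k))
    if (max(abs(P1 - P2)) < 1e-9) return(sp)
  }
  # defective/ill-conditioned generators (e.g. repeated eigenvalues): use
  # uniformization, P(t) = sum_n dpois(n, qt) M^n with M = I + Q/q, which
  # needs no diagonalizability and vectorizes across branches
  q <- max(-diag(unclass(Q)))
  if (q <= 0) q <- 1e-12
  N <- 150L
  M <- diag(k) + unclass(Q) / q
  Mpow <- matrix(0, k * k, N + 1L)
  Pw <- diag(k)
  Mpow[, 1] <- as.vector(Pw)
  for (n in seq_len(N)) { Pw <- Pw %*% M; Mpow[, n + 1L] <- as.vector(Pw) }
  sp <- list(method = "unif", Mpow = Mpow, q = q, N = N, k = k, Q = unclass(Q))
  P1 <- matrix(sp$Mpow %*% stats::dpois(0:N, q * 0.7), k, k)
  if (max(abs(P1 - P2)) < 1e-9) return(sp)
  list(method = "expm", k = k, Q = unclass(Q))
}

# P matrices for a vector of durations -> array k x k x length(t)
spectral_P <- function(sp, tvec) {
  k <- sp$k
  if (sp$method == "eigen") {
    E <- exp(outer(sp$d, tvec))
    Parr <- array(Re(sp$Cflat %*% E), dim = c(k, k, length(tvec)))
  } else if (sp$method == "unif") {
    a <- sp$q * tvec
    long <- a > sp$N - 8 * sqrt(sp$N + 1)    # Poisson tail would be truncated
    Nn <- min(sp$N, ceiling(max(a[!long], 0) + 10 * sqrt(max(a[!long], 0) + 1) + 10))
    W <- matrix(0, Nn + 1L, length(a))
    w <- exp(-a)
    W[1L, ] <- w
    for (n in seq_len(Nn)) { w <- w * a / n; W[n + 1L, ] <- w }
    Parr <- array(sp$Mpow[, seq_len(Nn + 1L), drop = FALSE] %*% W,
                  dim = c(k, k, length(tvec)))
    for (i in which(long))
      Parr[, , i] <- as.matrix(Matrix::expm(Matrix::Matrix(sp$Q * tvec[i])))
  } else {
    Parr <- array(0, dim = c(k, k, length(tvec)))
    for (i in seq_along(tvec))
      Parr[, , i] <- as.matrix(Matrix::expm(Matrix::Matrix(sp$Q * tvec[i])))
  }
  Parr[Parr < 0] <- 0
  Parr
}

# Felsenstein pruning over a ptree for a set of site patterns.
# tipL: list over tips of k x npat indicator matrices.
# Returns per-pattern log-likelihoods (log-space column scaling throughout).
prune_patterns <- function(pt, durations, sp, tipL, root_vec) {
  k <- sp$k
  npat <- ncol(tipL[[1]])
  m <- length(pt$parent)
  root <- pt$n + 1L
  Parr <- spectral_P(sp, durations)  # durations indexed by node id (root slot unused)
  L <- vector("list", m)
  logscale <- rep(0, npat)
  for (v in postorder_nodes(pt)) {
    if (v <= pt$n) { L[[v]] <- tipL[[v]]; next }
    acc <- matrix(1, k, npat)
    for (ch in pt$children[[v]]) {
      acc <- acc * (Parr[, , ch] %*% L[[ch]])
    }
    if (v == root) { L[[v]] <- acc; break }
    sc <- apply(acc, 2, max)
    sc[sc <= 0] <- 1
    L[[v]] <- acc / rep(sc, each = k)
    logscale <- logscale + log(sc)
  }
  lik <- as.numeric(root_vec %*% L[[root]])
  ifelse(lik > 0, log(lik) + logscale, -Inf)
}

# convert observed tokens to a k x npat indicator matrix
tokens_to_indicators <- function(tokens, states) {
  k <- length(states)
  sapply(tokens, function(tok) {
    if (tok == "?") return(rep(1, k))
    if (tok == "-")
      stop("inapplicable cell '-' encountered: hierarchy columns must be recoded before likelihood computation (see recode_characters)")
    parts <- strsplit(tok, "/", fixed = TRUE)[[1]]
    idx <- match(parts, states)
    if (anyNA(idx)) stop("tip symbol '", tok, "' not in model state set {",
                         paste(states, collapse = ","), "}")
    v <- rep(0, k); v[idx] <- 1; v
  })
}

durations_of <- function(pt, psi) {
  dur <- rep(0, length(pt$parent))
  nz <- which(pt$parent > 0L)
  dur[nz] <- (pt$age[pt$parent[nz]] - pt$age[nz]) * psi
  if (any(dur < -1e-12)) stop("negative branch duration: ages inconsistent with topology")
  pmax(dur, 0)
}

#' Pruning log-likelihood of one character on a rooted tree
#'
#' Computes the log-likelihood of a single column by Felsenstein's pruning
#' algorithm with matrix exponentiation, summing the root conditional
#' likelihoods against the root vector. Branch durations are the tree's
#' branch lengths (time) multiplied by the global clock rate `psi`.
#' Ambiguity sets and "?" become indicator vectors over the permitted
#' states; inapplicable "-" cells are only legal after recoding and raise an
#' error here.
#'
#' @param tree rooted `phylo` with branch lengths, or an internal ptree.
#' @param model an `amalgamated_model`, or a bare `rate_matrix`.
#' @param column named character vector of tip tokens (names = taxa), or a
#'   1-column `character_matrix`.
#' @param root_vector optional `prob_vector`; defaults to the model's
#'   resolved root vector (error if the model's policy is "inferred" and no
#'   vector is supplied).
#' @param psi global clock rate multiplier (default 1: branch lengths are
#'   already in expected-change units).
#' @return log-likelihood (numeric scalar).
#' @export
pruning_loglik <- function(tree, model, column, root_vector = NULL, psi = 1) {
  Q <- if (inherits(model, "amalgamated_model")) model$Q else model
  states <- rownames(Q)
  if (is.null(root_vector)) {
    rv <- if (inherits(model, "amalgamated_model")) model$root_vector
          else prob_vector(rep(1 / nrow(Q), nrow(Q)), states)
    if (inherits(rv, "latent_root"))
      stop("model has inferred root frequencies; supply root_vector explicitly")
    root_vector <- rv
  }
  pt <- if (inherits(tree, "phylo")) phylo_to_ptree(tree) else tree
  if (is.matrix(column)) column <- setNames(column[, 1], rownames(column))
  tokens <- column[pt$tip.label]
  if (anyNA(tokens)) stop("column is missing tips: ",
                          paste(setdiff(pt$tip.label, names(column)), collapse = ", "))
  tipL <- lapply(seq_len(pt$n), function(i)
    matrix(tokens_to_indicators(tokens[i], states), ncol = 1))
  sp <- spectral_of(Q)
  prune_patterns(pt, durations_of(pt, psi), sp, tipL, as.numeric(root_vector))
}

#' Variable-only (Mkv) conditioned log-likelihood of a character matrix
#'
#' Sums per-column pruning log-likelihoods and applies the Lewis Mkv
#' ascertainment correction: each column's likelihood is divided by the
#' probability of observing a variable character, 1 - sum_s P(all tips in
#' state s), computed over the model's own state set. Constant columns
#' trigger a warning (they cannot occur in variable-only data).
#'
#' Rate heterogeneity across characters (several hierarchies, each its own
#' column, may evolve at different speeds) can be modelled with a discrete
#' gamma multiplier: `gamma_alpha` switches on a `n_rate_categories`-category
#' equal-probability mixture of rate scalers (quantile-median
#' discretisation, mean 1); both the per-column likelihood and the Mkv
#' constant-pattern mass are averaged over categories. Off by default.
#'
#' @inheritParams pruning_loglik
#' @param data `character_matrix` (all columns share the model's state set).
#' @param gamma_alpha optional shape of the discrete-gamma rate mixture.
#' @param n_rate_categories categories for the gamma mixture (default 4).
#' @return conditioned log-likelihood (numeric scalar).
#' @export
variable_only_loglik <- function(tree, model, data, root_vector = NULL, psi = 1,
                                 gamma_alpha = NULL, n_rate_categories = 4) {
  Q <- if (inherits(model, "amalgamated_model")) model$Q else model
  states <- rownames(Q)
  k <- length(states)
  if (is.null(root_vector)) {
    rv <- if (inherits(model, "amalgamated_model")) model$root_vector
          else prob_vector(rep(1 / k, k), states)
    if (inherits(rv, "latent_root"))
      stop("model has inferred root frequencies; supply root_vector explicitly")
    root_vector <- rv
  }
  pt <- if (inherits(tree, "phylo")) phylo_to_ptree(tree) else tree
  m <- as.matrix(data)[pt$tip.label, , drop = FALSE]
  is_const <- apply(m, 2, function(cl) length(unique(cl)) == 1L && !any(cl %in% c("?", "-")))
  if (any(is_const))
    warning("constant column(s) in variable-only data: ",
            paste(which(is_const), collapse = ", "))
  # patterns: observed columns plus the k constant patterns for the correction
  pats <- cbind(m, matrix(rep(states, each = nrow(m)), nrow(m)))
  tipL <- lapply(seq_len(pt$n), function(i) tokens_to_indicators(pats[i, ], states))
  sp <- spectral_of(Q)
  nobs <- ncol(m)
  if (is.null(gamma_alpha)) {
    ll <- prune_patterns(pt, durations_of(pt, psi), sp, tipL,
                         as.numeric(root_vector))
  } else {
    mcat <- n_rate_categories
    r <- stats::qgamma((seq_len(mcat) - 0.5) / mcat, gamma_alpha, gamma_alpha)
    r <- r / mean(r)
    lmat <- vapply(r, function(rm)
      prune_patterns(pt, durations_of(pt, psi * rm), sp, tipL,
                     as.numeric(root_vector)),
      numeric(nobs + k))
    ll <- apply(matrix(lmat, nobs + k), 1, logmeanexp)
  }
  p_const <- sum(exp(ll[nobs + seq_len(k)]))
  if (p_const >= 1) stop("Mkv conditioning denominator <= 0 (numerically degenerate tree)")
  sum(ll[seq_len(nobs)]) - nobs * log1p(-p_const)
}

#' Check likelihood (in)variance under rerooting
#'
#' A time-reversible model with its stationary root vector gives the same
#' likelihood wherever a tree is rooted along its unrooted shape; the
#' time-irreversible amalgamated models generally do not, which is why their
#' inference requires rooted trees. This diagnostic computes the pruning
#' log-likelihood of one column under every rerooting of the tree (rooting
#' at the midpoint of each internal/terminal edge of the unrooted shape,
#' preserving branch lengths) and reports the spread.
#'
#' @inheritParams pruning_loglik
#' @return list with `loglik` (per-rerooting values, named by the edge), and
#'   `invariant` (TRUE iff max spread < 1e-10).
#' @export
reroot_invariance_check <- function(tree, model, column, root_vector = NULL, psi = 1) {
  ut <- ape::unroot(tree)
  lls <- numeric(0)
  for (e in seq_len(nrow(ut$edge))) {
    rt <- tryCatch(phangorn_free_reroot(ut, e), error = function(err) NULL)
    if (is.null(rt)) next
    lls <- c(lls, setNames(pruning_loglik(rt, model, column, root_vector, psi),
                           paste0("edge", e)))
  }
  list(loglik = lls, invariant = (max(lls) - min(lls)) < 1e-10)
}

# root an unrooted tree at the midpoint of edge e (no external deps)
phangorn_free_reroot <- function(ut, e) {
  child <- ut$edge[e, 2]
  len <- ut$edge.length[e]
  rooted <- ape::root(ut, node = if (child > length(ut$tip.label)) child else NULL,
                      outgroup = if (child <= length(ut$tip.label)) ut$tip.label[child] else NULL,
                      resolve.root = TRUE)
  # split the root edge evenly so total path lengths are preserved
  n <- length(rooted$tip.label)
  root_node <- n + 1L
  re <- which(rooted$edge[, 1] == root_node)
  if (length(re) == 2 && any(rooted$edge.length[re] == 0)) {
    z <- re[rooted$edge.length[re] == 0][1]
    o <- setdiff(re, z)[1]
    half <- rooted$edge.length[o] / 2
    rooted$edge.length[o] <- half
    rooted$edge.length[z] <- rooted$edge.length[z] + half
  }
  rooted
}
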