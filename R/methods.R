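#' @export
print.ed_mcmc <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Bayesian clock MCMC: %d run(s) x %d generations (thin %d)\n",
              cfg$n_runs, cfg$generations, cfg$thin))
  cat(sprintf("  %d taxa; partitions: %s\n", length(x$taxa),
              paste(vapply(x$engine$parts, function(p)
                sprintf("%s[%s, %d cols]", p$name, p$model$name, p$ncols), ""),
                collapse = ", ")))
  ll <- unlist(lapply(x$runs, function(r) r$trace$loglik))
  cat(sprintf("  log-likelihood range: [%.2f, %.2f]\n", min(ll), max(ll)))
  invisible(x)
}

#' Summarise an MCMC fit
#'
#' Posterior means, 95% credible intervals and effective acceptance rates,
#' computed from the pooled post-burn-in samples of all runs, plus the most
#' frequent clades.
#'
#' @param object an `ed_mcmc` fit.
#' @param burnin burn-in fraction (default: configured value).
#' @param ... unused.
#' @return list of class `summary.ed_mcmc` with elements `params`
#'   (data.frame), `accept`, `clades` (top clades with posterior support),
#'   `ess` (effective sample sizes of the log-likelihood and clock traces)
#'   and `max_split_freq_diff` (largest clade-frequency disagreement across
#'   runs, the basic non-mixing report).
#' @export
summary.ed_mcmc <- function(object, burnin = object$config$burnin, ...) {
  tr <- pooled_trace(object, burnin)
  pars <- setdiff(colnames(tr), c("gen"))
  params <- data.frame(
    parameter = pars,
    mean = vapply(pars, function(p) mean(tr[[p]]), 0),
    lower95 = vapply(pars, function(p) unname(stats::quantile(tr[[p]], 0.025)), 0),
    upper95 = vapply(pars, function(p) unname(stats::quantile(tr[[p]], 0.975)), 0),
    row.names = NULL)
  accept <- Reduce(`+`, lapply(object$runs, function(r) r$accept)) / length(object$runs)
  clades <- tryCatch({
    tab <- clade_table(object, burnin)
    utils::head(tab[order(-tab$freq), c("clade", "freq", "mean_age")], 10)
  }, error = function(e) NULL)
  ess <- c(loglik = ess_of(tr$loglik), psi = ess_of(tr$psi))
  # basic convergence report: largest clade-frequency disagreement across runs
  split_diff <- NA_real_
  if (length(object$runs) >= 2 && !is.null(object$runs[[1]]$trees)) {
    freqs <- lapply(seq_along(object$runs), function(r) {
      one <- object
      one$runs <- object$runs[r]
      tab <- clade_table(one, burnin)
      setNames(tab$freq, tab$clade)
    })
    keys <- unique(unlist(lapply(freqs, names)))
    fm <- vapply(freqs, function(f) ifelse(keys %in% names(f), f[keys], 0),
                 numeric(length(keys)))
    fm <- matrix(fm, nrow = length(keys))
    split_diff <- max(apply(fm, 1, function(x) max(x) - min(x)))
  }
  structure(list(params = params, accept = accept, clades = clades,
                 ess = ess, max_split_freq_diff = split_diff),
            class = "summary.ed_mcmc")
}

# autocorrelation-time effective sample size (initial positive sequence)
ess_of <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(ac < 0)[1]
  if (!is.na(pos)) ac <- ac[seq_len(pos - 1)]
  max(1, n / (1 + 2 * sum(ac)))
}

#' @export
print.summary.ed_mcmc <- function(x, ...) {
  cat("posterior summaries (pooled post-burn-in samples):\n")
  print(transform(x$params, mean = signif(mean, 4), lower95 = signif(lower95, 4),
                  upper95 = signif(upper95, 4)), row.names = FALSE)
  cat("\nmove acceptance rates:\n")
  print(round(x$accept, 3))
  cat(sprintf("\nESS: loglik %.0f, psi %.0f", x$ess["loglik"], x$ess["psi"]))
  if (!is.na(x$max_split_freq_diff))
    cat(sprintf("; max split-frequency difference across runs: %.3f",
                x$max_split_freq_diff))
  cat("\n")
  if (!is.null(x$clades)) {
    cat("\ntop clades:\n")
    print(transform(x$clades, freq = round(freq, 3), mean_age = signif(mean_age, 3)),
          row.names = FALSE)
  }
  invisible(x)
}

pooled_trace <- function(fit, burnin) {
  do.call(rbind, lapply(fit$runs, function(r) {
    nrec <- nrow(r$trace)
    r$trace[seq_len(nrec) > floor(burnin * nrec), , drop = FALSE]
  }))
}

#' @export
coef.ed_mcmc <- function(object, burnin = object$config$burnin, ...) {
  tr <- pooled_trace(object, burnin)
  pars <- setdiff(colnames(tr), c("gen", "loglik", "logprior"))
  vapply(pars, function(p) mean(tr[[p]]), 0)
}

#' @export
logLik.ed_mcmc <- function(object, burnin = object$config$burnin, ...) {
  tr <- pooled_trace(object, burnin)
  structure(mean(tr$loglik), df = NA, class = "logLik")
}

#' Posterior-predictive simulation from an MCMC fit
#'
#' Draws `nsim` replicate datasets: for each, a posterior sample (tree,
#' clock rate, model parameters, root frequencies) is picked at random from
#' the pooled post-burn-in samples and a character matrix of the original
#' dimensions is simulated under it.
#'
#' @param object an `ed_mcmc` fit.
#' @param nsim number of replicate datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a list of `character_matrix` objects (length `nsim`).
#' @export
simulate.ed_mcmc <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  burnin <- object$config$burnin
  tr <- pooled_trace(object, burnin)
  snaps <- pooled_snapshots(object, burnin)
  engine <- object$engine
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    i <- sample.int(nrow(tr), 1)
    snap <- snaps[[i]]
    pt <- list(n = engine$n, parent = snap$parent,
               children = children_of_parent(snap$parent),
               age = snap$age, tip.label = engine$taxa)
    phy <- ptree_to_phylo(pt)
    cols <- list()
    for (p in engine$parts) {
      mod <- p$model
      if (p$free_simplex) {
        vals <- unlist(tr[i, paste0(p$name, ".", mod$simplex[seq_along(mod$free)])])
        mod <- update_model(mod, setNames(vals, mod$free))
      }
      rv <- if (p$inferred)
        prob_vector(unlist(tr[i, paste0(p$name, ".pi.", p$states)]), p$states)
      else mod$root_vector
      cols[[p$name]] <- unclass(simulate_ctmc_on_tree(
        phy, mod$Q, root_vector = rv, n_columns = p$ncols,
        psi = tr$psi[i], variable_only = object$config$mkv))
    }
    m <- do.call(cbind, cols)
    out[[s]] <- character_matrix(m, partition = rep(names(cols),
                                                    vapply(cols, ncol, 0L)))
  }
  out
}

#' Trace plots for an MCMC fit
#'
#' Log-likelihood and clock-rate traces per run (base graphics), the basic
#' convergence eyeball check.
#'
#' @param x an `ed_mcmc` fit.
#' @param ... passed to [plot()].
#' @export
plot.ed_mcmc <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  for (what in c("loglik", "psi")) {
    first <- TRUE
    for (i in seq_along(x$runs)) {
      tr <- x$runs[[i]]$trace
      if (first) {
        plot(tr$gen, tr[[what]], type = "l", col = i, xlab = "generation",
             ylab = what, ...)
        first <- FALSE
      } else graphics::lines(tr$gen, tr[[what]], col = i)
    }
  }
  invisible(x)
}
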