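#' Simulate a duet of interacting chains (the ED process)
#'
#' Exact (Gillespie) event-time simulation of the embedded-dependency
#' process: the controlling BD character gains and loses at its own rates,
#' and the dependent chain evolves only while the controller is present. On
#' each birth of the controller the dependent state is drawn from the
#' embedded vector — the dependent's own `phi` under `mode = "ql"`, or its
#' "absent" state under `mode = "bd"` (the macroevolutionary lag). The final
#' state maps onto the states of the corresponding ED-amalgamated CTMC,
#' which describes exactly the same process.
#'
#' @param controlling BD `character_spec`.
#' @param dependent `character_spec` (qualitative or BD).
#' @param mode "ql" or "bd".
#' @param duration total simulated time (> 0).
#' @param seed optional integer seed.
#' @param init optional initial amalgamated state label; by default drawn
#'   from the composed initial vector.
#' @return data.frame of events (`time`, `controller`, `dependent`) with the
#'   final amalgamated state label in attribute `final_state` and the
#'   amalgamated state labels in attribute `states`.
#' @export
simulate_interacting_chains <- function(controlling, dependent, mode = c("ql", "bd"),
                                        duration, seed = NULL, init = NULL) {
  mode <- match.arg(mode)
  if (duration <= 0) stop("duration must be positive")
  if (!is.null(seed)) set.seed(seed)
  dl <- dependent$labels
  amalg_states <- if (mode == "bd")
    c(paste0(controlling$labels[1], dl[1]),
      paste0(controlling$labels[2], dl))
  else c(controlling$labels[1], paste0(controlling$labels[2], dl))
  dep_label <- function(ctrl, dep) {
    if (ctrl == 1L) amalg_states[1] else amalg_states[1 + dep]
  }
  phi <- if (mode == "bd") c(1, rep(0, length(dl) - 1)) else as.numeric(dependent$phi)
  # initial state
  if (is.null(init)) {
    p2 <- as.numeric(controlling$pi)[2]
    if (stats::runif(1) < p2) {
      ctrl <- 2L; dep <- sample.int(length(dl), 1, prob = as.numeric(dependent$pi))
    } else { ctrl <- 1L; dep <- NA_integer_ }
  } else {
    i <- match(init, amalg_states)
    if (is.na(i)) stop("unknown initial state: ", init)
    if (i == 1L) { ctrl <- 1L; dep <- NA_integer_ } else { ctrl <- 2L; dep <- i - 1L }
  }
  t <- 0
  ev <- list(list(time = 0, controller = controlling$labels[ctrl],
                  dependent = if (ctrl == 1L) "-" else dl[dep]))
  Qd <- unclass(dependent$Q)
  repeat {
    if (ctrl == 1L) {
      rates <- c(gain = controlling$gain)
    } else {
      out_rates <- Qd[dep, ]; out_rates[dep] <- 0
      rates <- c(loss = controlling$loss, setNames(out_rates, paste0("dep_", seq_along(out_rates))))
    }
    tot <- sum(rates)
    if (tot <= 0) break
    t <- t + stats::rexp(1, tot)
    if (t > duration) break
    which_ev <- sample.int(length(rates), 1, prob = rates)
    if (ctrl == 1L) {
      ctrl <- 2L
      dep <- sample.int(length(dl), 1, prob = phi)
    } else if (which_ev == 1L) {
      ctrl <- 1L; dep <- NA_integer_
    } else {
      dep <- which_ev - 1L
    }
    ev[[length(ev) + 1L]] <- list(time = t, controller = controlling$labels[ctrl],
                                  dependent = if (ctrl == 1L) "-" else dl[dep])
  }
  out <- do.call(rbind.data.frame, ev)
  attr(out, "final_state") <- dep_label(ctrl, dep)
  attr(out, "states") <- amalg_states
  out
}

#' Simulate characters along a rooted tree under a CTMC
#'
#' Draws the root state from `root_vector` and evolves it along each branch
#' by sampling from the exact transition probabilities P(t) = exp(Qt)
#' (branch lengths in time, optionally scaled by a clock rate). With
#' `variable_only`, constant columns are redrawn, emulating data in which
#' invariant characters are never collected (the situation the Mkv
#' correction conditions on).
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param Q `rate_matrix` (or `amalgamated_model`).
#' @param root_vector `prob_vector` over the states; default uniform.
#' @param n_columns number of characters to simulate.
#' @param seed optional integer seed (byte-identical matrices per seed).
#' @param variable_only resample constant columns.
#' @param psi clock multiplier applied to branch lengths.
#' @param max_tries resampling cap per column before erroring.
#' @return `character_matrix` (taxa x n_columns).
#' @export
simulate_ctmc_on_tree <- function(tree, Q, root_vector = NULL, n_columns = 1,
                                  seed = NULL, variable_only = FALSE, psi = 1,
                                  max_tries = 10000) {
  if (inherits(Q, "amalgamated_model")) {
    if (is.null(root_vector) && !inherits(Q$root_vector, "latent_root"))
      root_vector <- Q$root_vector
    Q <- Q$Q
  }
  k <- nrow(Q)
  if (is.null(root_vector)) root_vector <- rep(1 / k, k)
  if (!is.null(seed)) set.seed(seed)
  pt <- phylo_to_ptree(tree)
  sp <- spectral_of(Q)
  Parr <- spectral_P(sp, durations_of(pt, psi))
  pre <- order_nodes_preorder(pt$parent, pt$children, pt$n + 1L)
  draw_col <- function() {
    st <- integer(length(pt$parent))
    st[pt$n + 1L] <- sample.int(k, 1, prob = as.numeric(root_vector))
    for (v in pre[-1]) {
      p <- Parr[st[pt$parent[v]], , v]
      st[v] <- sample.int(k, 1, prob = p)
    }
    rownames(Q)[st[seq_len(pt$n)]]
  }
  cols <- matrix(NA_character_, pt$n, n_columns, dimnames = list(pt$tip.label, NULL))
  for (j in seq_len(n_columns)) {
    tries <- 0
    repeat {
      cl <- draw_col(); tries <- tries + 1
      if (!variable_only || length(unique(cl)) > 1L) break
      if (tries >= max_tries)
        stop("variable_only: could not draw a variable column in ", max_tries,
             " tries (rates too small?)")
    }
    cols[, j] <- cl
  }
  character_matrix(cols)
}

#' Simulate a Yule (pure-birth) time tree
#'
#' Forward simulation from a single lineage: each lineage splits
#' independently at `birth_rate`; the process is stopped when the next split
#' after reaching `n_taxa` lineages would occur, so for `n_taxa = 2` the
#' root age (the single cherry's split time) is Exponential with rate
#' `2 * birth_rate`.
#'
#' @param n_taxa number of tips (>= 2).
#' @param birth_rate speciation rate per lineage per unit time.
#' @param seed optional integer seed.
#' @param root_age optional: rescale the tree so the root has this age.
#' @return ultrametric rooted `phylo`.
#' @export
simulate_yule_tree <- function(n_taxa, birth_rate = 0.1, seed = NULL, root_age = NULL) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  t <- stats::rexp(1, birth_rate)             # first split = root
  node_time <- c(root = t)
  node_children <- list(root = character(0))
  active <- c("L1", "L2")                      # lineage id -> parent node
  active_parent <- c(L1 = "root", L2 = "root")
  next_lin <- 3L; next_node <- 2L
  while (length(active) < n_taxa) {
    t <- t + stats::rexp(1, birth_rate * length(active))
    i <- sample.int(length(active), 1)
    lin <- active[i]
    nd <- paste0("n", next_node); next_node <- next_node + 1L
    node_time[nd] <- t
    node_children[[active_parent[lin]]] <- c(node_children[[active_parent[lin]]], nd)
    node_children[[nd]] <- character(0)
    l1 <- paste0("L", next_lin); l2 <- paste0("L", next_lin + 1L)
    next_lin <- next_lin + 2L
    active <- c(active[-i], l1, l2)
    active_parent <- c(active_parent[names(active_parent) != lin],
                       setNames(c(nd, nd), c(l1, l2)))
  }
  t_stop <- t + stats::rexp(1, birth_rate * n_taxa)
  # assemble newick recursively
  tip_ix <- 0L
  build <- function(node) {
    kids <- node_children[[node]]
    lins <- names(active_parent)[active_parent == node]
    parts <- character(0)
    for (k in kids)
      parts <- c(parts, paste0(build(k), ":", node_time[k] - node_time[node]))
    for (l in lins) {
      tip_ix <<- tip_ix + 1L
      parts <- c(parts, paste0("t", tip_ix, ":", t_stop - node_time[node]))
    }
    paste0("(", paste(parts, collapse = ","), ")")
  }
  phy <- read_newick(paste0(build("root"), ";"))
  if (!is.null(root_age)) {
    h <- max(ape::node.depth.edgelength(phy))
    phy$edge.length <- phy$edge.length * root_age / h
  }
  phy
}
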