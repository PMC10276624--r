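# shared builders for the toy tail hierarchies

mk2q <- function(lab, r12 = 1, r21 = 1) {
  rate_matrix(rbind(c(-r12, r12), c(r21, -r21)), labels = lab)
}

tail_spec <- function(gain = 1, loss = 1, pi = c(0.5, 0.5)) {
  char_bd("tail", gain, loss, pi = pi)
}

color_spec <- function(phi = c(0.5, 0.5), pi = c(0.5, 0.5), r12 = 1, r21 = 1) {
  char_ql("color", mk2q(c("r", "b"), r12, r21), pi = pi, phi = phi)
}

armor_spec <- function(gain = 1, loss = 1, pi = c(0.5, 0.5)) {
  char_bd("armor", gain, loss, pi = pi, labels = c("a1", "p1"))
}

tca_diagram <- function() {
  dependency_diagram(
    list(tail_spec(), armor_spec(), color_spec()),
    data.frame(from = c("tail", "armor"), to = c("armor", "color")))
}

# the complex seven-character hierarchy (three BD, four qualitative)
complex_diagram <- function() {
  dependency_diagram(
    list(char_bd("T", 1, 1),
         char_bd("B1", 1, 1, labels = c("a1", "p1")),
         char_bd("B2", 1, 1, labels = c("a2", "p2")),
         char_ql("c1", mk2q(c("r", "b"))),
         char_ql("c2", mk2q(c("x", "y"))),
         char_ql("c3", mk2q(c("u", "v"))),
         char_ql("c4", mk2q(c("m", "n")))),
    data.frame(from = c("T", "T", "T", "B1", "B1", "B2"),
               to = c("B1", "B2", "c4", "c1", "c2", "c3")))
}

random_valid_Q <- function(k, scale = 1) {
  m <- matrix(stats::runif(k * k) * scale, k, k)
  rate_matrix(m, labels = paste0("s", seq_len(k)), fix_diagonal = TRUE)
}

quartet_tree <- function() read_newick("((A:0.3,B:0.3):0.7,(C:0.6,D:0.6):0.4);")

# brute-force pruning oracle: enumerate all internal-node state assignments
enumeration_loglik <- function(tree, Q, column, root_vector, psi = 1) {
  pt <- edmorph:::phylo_to_ptree(tree)
  k <- nrow(Q)
  states <- rownames(Q)
  Plist <- lapply(seq_along(pt$parent), function(v) {
    if (pt$parent[v] == 0) return(NULL)
    transition_probabilities(Q, (pt$age[pt$parent[v]] - pt$age[v]) * psi)
  })
  internals <- (pt$n + 1L):(2L * pt$n - 1L)
  tipidx <- lapply(seq_len(pt$n), function(i) {
    tok <- column[[pt$tip.label[i]]]
    if (tok == "?") seq_len(k) else match(strsplit(tok, "/", fixed = TRUE)[[1]], states)
  })
  grid <- do.call(expand.grid, c(rep(list(seq_len(k)), length(internals)),
                                 lapply(tipidx, function(x) x)))
  colnames(grid) <- c(internals, seq_len(pt$n))
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    st <- integer(length(pt$parent))
    st[as.integer(colnames(grid))] <- as.integer(grid[r, ])
    p <- root_vector[st[pt$n + 1L]]
    for (v in seq_along(pt$parent)) {
      if (pt$parent[v] == 0) next
      p <- p * Plist[[v]][st[pt$parent[v]], st[v]]
    }
    tot <- tot + p
  }
  log(tot)
}
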