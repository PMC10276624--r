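# ---- posterior tree summaries ---------------------------------------------

# pooled post-burn-in tree snapshots across runs, as (parent, age) lists
pooled_snapshots <- function(fit, burnin) {
  out <- list()
  for (run in fit$runs) {
    nrec <- length(run$trees)
    keep <- seq_len(nrec) > floor(burnin * nrec)
    out <- c(out, run$trees[keep])
  }
  if (!length(out)) stop("empty post-burn-in sample")
  out
}

snapshot_clades <- function(snap, taxa) {
  n <- length(taxa)
  m <- length(snap$parent)
  sets <- vector("list", m)
  ord <- order(snap$age[(n + 1L):m]) + n       # youngest internal first = postorder-safe
  for (v in seq_len(n)) sets[[v]] <- v
  for (v in ord) {
    kids <- which(snap$parent == v)
    sets[[v]] <- sort(unlist(sets[kids]))
  }
  list(keys = vapply((n + 1L):m, function(v) paste(sort(taxa[sets[[v]]]), collapse = "|"), ""),
       ages = snap$age[(n + 1L):m])
}

clade_table <- function(fit, burnin) {
  taxa <- fit$taxa
  snaps <- pooled_snapshots(fit, burnin)
  freq <- new.env(hash = TRUE)
  agesum <- new.env(hash = TRUE)
  for (s in snaps) {
    cl <- snapshot_clades(s, taxa)
    for (i in seq_along(cl$keys)) {
      k <- cl$keys[i]
      freq[[k]] <- (freq[[k]] %||% 0) + 1
      agesum[[k]] <- (agesum[[k]] %||% 0) + cl$ages[i]
    }
  }
  keys <- ls(freq)
  data.frame(clade = keys,
             freq = vapply(keys, function(k) freq[[k]], 0) / length(snaps),
             mean_age = vapply(keys, function(k) agesum[[k]] / freq[[k]], 0),
             stringsAsFactors = FALSE)
}

#' Posterior probability of a clade
#'
#' Frequency of the exact clade (as a monophyletic group) in the pooled
#' post-burn-in posterior sample of an [ed_mcmc()] fit.
#'
#' @param fit an `ed_mcmc` object.
#' @param tips character vector of taxon labels forming the clade.
#' @param burnin burn-in fraction (default: the fit's configured burn-in).
#' @return numeric in `[0, 1]`.
#' @export
clade_posterior <- function(fit, tips, burnin = fit$config$burnin) {
  key <- paste(sort(tips), collapse = "|")
  tab <- clade_table(fit, burnin)
  f <- tab$freq[match(key, tab$clade)]
  if (is.na(f)) 0 else f
}

#' Majority-rule consensus tree of a posterior sample
#'
#' Builds the 50% (or stricter) majority-rule consensus from the pooled
#' post-burn-in samples: every clade with frequency above the threshold is
#' included (clades above 0.5 are mutually compatible); unresolved parts
#' become polytomies. Node labels carry the clade posterior probabilities
#' and node ages are posterior means conditional on the clade.
#'
#' @param fit an `ed_mcmc` object.
#' @param threshold clade-frequency threshold (default 0.5).
#' @param burnin burn-in fraction (default 0.3, the reporting convention).
#' @return a `phylo` with `node.label` = clade support.
#' @export
consensus_tree <- function(fit, threshold = 0.5, burnin = 0.3) {
  taxa <- fit$taxa
  tab <- clade_table(fit, burnin)
  keep <- tab[tab$freq > threshold, , drop = FALSE]
  build_clade_tree(taxa, keep)
}

build_clade_tree <- function(taxa, tab) {
  tips_of <- strsplit(tab$clade, "|", fixed = TRUE)
  sizes <- lengths(tips_of)
  ord <- order(-sizes)
  tips_of <- tips_of[ord]; tab <- tab[ord, , drop = FALSE]
  root_i <- which(sizes[ord] == length(taxa))[1]
  assemble <- function(i) {
    mytips <- tips_of[[i]]
    # maximal kept clades strictly inside this one
    inner <- which(vapply(seq_along(tips_of), function(j)
      length(tips_of[[j]]) < length(mytips) && all(tips_of[[j]] %in% mytips), TRUE))
    used <- character(0); children <- integer(0)
    for (j in inner) {
      if (!any(tips_of[[j]] %in% used)) { children <- c(children, j); used <- c(used, tips_of[[j]]) }
    }
    singles <- setdiff(mytips, used)
    parts <- c(vapply(children, function(j)
      paste0(assemble(j), ":", max(tab$mean_age[i] - tab$mean_age[j], 0)), ""),
      vapply(singles, function(s) paste0(s, ":", tab$mean_age[i]), ""))
    paste0("(", paste(parts, collapse = ","), ")", signif(tab$freq[i], 3))
  }
  nk <- if (length(root_i)) assemble(root_i) else
    paste0("(", paste(paste0(taxa, ":1"), collapse = ","), ")1")
  read_newick(paste0(nk, ";"))
}

#' Maximum clade credibility (MCC) tree
#'
#' Among the sampled trees, returns the one maximising the product of its
#' clades' posterior probabilities (computed from the pooled post-burn-in
#' sample). Node labels carry the clade supports.
#'
#' @inheritParams consensus_tree
#' @return a `phylo`.
#' @export
mcc_tree <- function(fit, burnin = 0.3) {
  taxa <- fit$taxa
  snaps <- pooled_snapshots(fit, burnin)
  tab <- clade_table(fit, burnin)
  lookup <- setNames(tab$freq, tab$clade)
  best <- NULL; best_score <- -Inf; best_keys <- NULL
  for (s in snaps) {
    cl <- snapshot_clades(s, taxa)
    sc <- sum(log(lookup[cl$keys]))
    if (sc > best_score) { best <- s; best_score <- sc; best_keys <- cl$keys }
  }
  pt <- list(n = length(taxa), parent = best$parent,
             children = children_of_parent(best$parent),
             age = best$age, tip.label = taxa)
  phy <- ptree_to_phylo(pt)
  supp <- lookup[snapshot_clades(best, taxa)$keys]
  # node order in ptree_to_phylo follows node ids n+1..m
  phy$node.label <- signif(as.numeric(supp), 3)
  phy
}

children_of_parent <- function(parent) {
  m <- length(parent)
  ch <- vector("list", m)
  for (v in which(parent > 0L)) ch[[parent[v]]] <- c(ch[[parent[v]]], v)
  ch
}

#' Robinson-Foulds distance
#'
#' Symmetric difference of the unrooted bipartition sets of two trees on the
#' same taxa (trees are unrooted first; use `rooted = TRUE` for rooted-clade
#' RF). Zero means identical (unrooted) topologies.
#'
#' @param t1,t2 `phylo` objects with identical taxon sets.
#' @param rooted compare rooted clades instead of unrooted bipartitions.
#' @return integer distance.
#' @export
rf_distance <- function(t1, t2, rooted = FALSE) {
  if (!setequal(t1$tip.label, t2$tip.label)) stop("taxon sets differ")
  s1 <- tree_splits(t1, rooted)
  s2 <- tree_splits(t2, rooted)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

tree_splits <- function(phy, rooted = FALSE) {
  taxa <- sort(phy$tip.label)
  n <- length(taxa)
  po <- ape::reorder.phylo(phy, "postorder")
  m <- max(po$edge)
  sets <- vector("list", m)
  for (i in seq_len(n)) sets[[i]] <- phy$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    a <- po$edge[e, 1]; b <- po$edge[e, 2]
    sets[[a]] <- c(sets[[a]], sets[[b]])
  }
  internal <- setdiff(unique(po$edge[, 1]), seq_len(n))
  keys <- character(0)
  for (v in internal) {
    s <- sort(unlist(sets[[v]]))
    if (rooted) {
      if (length(s) >= 2 && length(s) < n) keys <- c(keys, paste(s, collapse = "|"))
    } else {
      if (length(s) < 2 || length(s) > n - 2) next
      if (taxa[1] %in% s) s <- setdiff(taxa, s)
      keys <- c(keys, paste(sort(s), collapse = "|"))
    }
  }
  unique(keys)
}
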