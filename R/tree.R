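#' Read and write rooted trees in Newick format
#'
#' Thin wrappers over \pkg{ape} that add the validation this package needs:
#' parse failures raise errors (rather than returning NULL) and duplicate
#' taxon labels are rejected. Branch lengths are in time units; trees
#' produced by the clock machinery are ultrametric with tip age 0.
#'
#' @param text Newick string (or file path for `read_newick`).
#' @return `read_newick`: an \pkg{ape} `phylo`; `write_newick`: a Newick
#'   string.
#' @export
read_newick <- function(text) {
  phy <- tryCatch({
    if (length(text) == 1 && !grepl("\\(", text) && file.exists(text))
      ape::read.tree(text)
    else ape::read.tree(text = text)
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("Newick parse error")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate taxon labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  phy
}

#' @rdname read_newick
#' @param tree an \pkg{ape} `phylo`.
#' @param digits significant digits for branch lengths (write).
#' @export
write_newick <- function(tree, digits = 15) {
  ape::write.tree(tree, digits = digits)
}

# --- internal rooted-time-tree representation used by the MCMC -------------
# tips 1..n (age 0), internal nodes n+1..2n-1, root = n+1 (age fixed).
# ptree: list(n, parent, children, age, tip.label)

phylo_to_ptree <- function(phy) {
  n <- length(phy$tip.label)
  m <- n + phy$Nnode
  parent <- integer(m)
  children <- vector("list", m)
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1]; b <- phy$edge[i, 2]
    parent[b] <- a
    children[[a]] <- c(children[[a]], b)
  }
  depth <- numeric(m)
  ord <- order_nodes_preorder(parent, children, n + 1L)
  for (v in ord[-1]) {
    e <- which(phy$edge[, 2] == v)
    depth[v] <- depth[parent[v]] + phy$edge.length[e]
  }
  h <- max(depth[seq_len(n)])
  age <- h - depth
  age[seq_len(n)] <- pmax(age[seq_len(n)], 0)
  list(n = n, parent = parent, children = children, age = age,
       tip.label = phy$tip.label)
}

ptree_to_phylo <- function(pt) {
  m <- length(pt$parent)
  keep <- which(pt$parent > 0L)
  edge <- cbind(pt$parent[keep], keep)
  len <- pt$age[pt$parent[keep]] - pt$age[keep]
  phy <- list(edge = edge, edge.length = len, tip.label = pt$tip.label,
              Nnode = m - pt$n)
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  ape::reorder.phylo(phy, "cladewise")
}

order_nodes_preorder <- function(parent, children, root) {
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, children[[v]])
  }
  out
}

postorder_nodes <- function(pt) rev(order_nodes_preorder(pt$parent, pt$children, pt$n + 1L))

# integer tip sets below every internal node
ptree_tipsets <- function(pt) {
  post <- postorder_nodes(pt)
  m <- length(pt$parent)
  sets <- vector("list", m)
  for (v in post) {
    if (v <= pt$n) { sets[[v]] <- v; next }
    sets[[v]] <- sort(unlist(lapply(pt$children[[v]], function(c) sets[[c]])))
  }
  sets[(pt$n + 1L):m]
}

# TRUE iff every constraint (list of integer tip vectors) is a clade of pt
satisfies_constraints <- function(pt, constraints) {
  if (!length(constraints)) return(TRUE)
  keys <- vapply(ptree_tipsets(pt), paste, "", collapse = ",")
  all(vapply(constraints, function(s) paste(s, collapse = ",") %in% keys, TRUE))
}

# clade keys (sorted tip label strings) for every internal node
ptree_clades <- function(pt) {
  post <- postorder_nodes(pt)
  sets <- vector("list", length(pt$parent))
  keys <- character(0)
  for (v in post) {
    if (v <= pt$n) { sets[[v]] <- pt$tip.label[v]; next }
    s <- sort(unlist(lapply(pt$children[[v]], function(c) sets[[c]])))
    sets[[v]] <- s
    keys <- c(keys, paste(s, collapse = "|"))
  }
  keys
}
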