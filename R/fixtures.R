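#' The fixed TCA benchmark dataset
#'
#' Four species with 50 identical four-state characters referring to the
#' tail-colour-and-armour (TCA) case: each taxon is fixed to one of the
#' amalgamated states aa1 / pa1 / pp1r / pp1b (one taxon per state — the
#' minimal informative configuration consistent with the published
#' description; recorded as an assumption in the package vignette). The
#' replication provides enough information for marginal-likelihood model
#' comparison despite the trivial size.
#'
#' @return `character_matrix`, 4 taxa x 50 columns.
#' @export
make_tca_fixture <- function() {
  states <- .tca_states
  taxa <- paste0("t_", states)
  m <- matrix(rep(states, 50), nrow = 4, ncol = 50,
              dimnames = list(taxa, paste0("tca", 1:50)))
  character_matrix(m, partition = rep("tca", 50))
}

#' The tail-colour-problem (TCP) benchmark dataset
#'
#' Fourteen species: tailed species with red and blue tails are nested
#' within the left and right clades of the tailless species. The backbone is
#' fully resolved except within the left-tailed clade (LTC: two red-tailed
#' and two blue-tailed species); every resolved clade is supported by
#' exactly one binary synapomorphy (avoiding zero-length branches) and the
#' LTC itself by 1 or 11 binary synapomorphies. The tail-colour character
#' (states a / r / b) is replicated fifty times. The question the fixture
#' poses: does a model resolve the LTC into the red pair plus the blue pair?
#'
#' @param n_ltc_synapomorphies 1 or 11 binary characters supporting the LTC.
#' @return list with `data` (a partitioned `character_matrix`: partition
#'   "bin" = binary backbone characters, "col" = colour columns),
#'   `true_tree` (reference `phylo`; LTC internal relationships collapsed),
#'   `constraints` (the resolved clades, to be held monophyletic so that
#'   only the LTC interior is sampled, mirroring the published setup), and
#'   `red_clade` / `blue_clade` (taxon vectors for the monophyly queries).
#' @export
make_tcp_fixture <- function(n_ltc_synapomorphies = 1) {
  if (!n_ltc_synapomorphies %in% c(1, 11))
    stop("n_ltc_synapomorphies must be 1 or 11")
  taxa <- c("L1", "L2", "L3", "R1", "R2", "B1", "B2",
            "X1", "X2", "X3", "RR1", "RR2", "BB1", "BB2")
  ltc <- c("R1", "R2", "B1", "B2")
  clades <- list(
    left7  = c("L1", "L2", "L3", ltc),
    left6  = c("L2", "L3", ltc),
    left5  = c("L3", ltc),
    right7 = c("X1", "X2", "X3", "RR1", "RR2", "BB1", "BB2"),
    right6 = c("X2", "X3", "RR1", "RR2", "BB1", "BB2"),
    right5 = c("X3", "RR1", "RR2", "BB1", "BB2"),
    rtc    = c("RR1", "RR2", "BB1", "BB2"),
    rr     = c("RR1", "RR2"),
    bb     = c("BB1", "BB2"))
  bin_clades <- c(clades, rep(list(ltc), n_ltc_synapomorphies))
  bin <- vapply(bin_clades, function(cl) ifelse(taxa %in% cl, "1", "0"),
                character(length(taxa)))
  rownames(bin) <- taxa
  colnames(bin) <- paste0("bin", seq_len(ncol(bin)))
  col_state <- ifelse(taxa %in% c("R1", "R2", "RR1", "RR2"), "r",
                      ifelse(taxa %in% c("B1", "B2", "BB1", "BB2"), "b", "a"))
  col <- matrix(rep(col_state, 50), nrow = length(taxa),
                dimnames = list(taxa, paste0("col", 1:50)))
  data <- character_matrix(cbind(bin, col),
                           partition = c(rep("bin", ncol(bin)), rep("col", 50)))
  true_tree <- read_newick(paste0(
    "((L1:0.9,(L2:0.8,(L3:0.7,(R1:0.5,R2:0.5,B1:0.5,B2:0.5):0.2):0.1):0.1):0.1,",
    "(X1:0.9,(X2:0.8,(X3:0.7,((RR1:0.3,RR2:0.3):0.2,(BB1:0.3,BB2:0.3):0.2):0.2):0.1):0.1):0.1);"))
  list(data = data, true_tree = true_tree,
       constraints = unname(c(clades, list(ltc = ltc))),
       red_clade = c("R1", "R2"), blue_clade = c("B1", "B2"))
}
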