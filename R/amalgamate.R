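#' SMM amalgamation of two independent CTMCs
#'
#' Combines two chains evolving independently into one chain over the product
#' state space (the Kronecker sum Qa (+) Qb). Simultaneous double transitions
#' have rate zero; the marginal dynamics of each factor are unchanged, so
#' P(t) of the amalgam is the Kronecker product of the factor P(t)s.
#'
#' @param Qa,Qb valid `rate_matrix` objects (a 1-state "matrix" is accepted
#'   as an identity element).
#' @param sep separator inserted between state tokens in composite labels
#'   (default "" to reproduce labels like "pa1").
#' @return amalgamated `rate_matrix` of dimension `na * nb`.
#' @export
smm_amalgamate <- function(Qa, Qb, sep = "") {
  la <- rownames(Qa); lb <- rownames(Qb)
  na <- nrow(Qa); nb <- nrow(Qb)
  if (na > 1) stopifnot_valid_Q(Qa)
  if (nb > 1) stopifnot_valid_Q(Qb)
  Q <- kronecker(unclass(Qa), diag(nb)) + kronecker(diag(na), unclass(Qb))
  labels <- as.vector(t(outer(la, lb, function(a, b) paste0(a, sep, b))))
  if (anyDuplicated(labels)) stop("label collision after concatenation: ",
                                  paste(unique(labels[duplicated(labels)]), collapse = ", "))
  out <- rate_matrix(Q, labels = labels)
  attr(out, "steps") <- c(attr(Qa, "steps"), attr(Qb, "steps"),
                          sprintf("SMM(%dx%d -> %d)", na, nb, na * nb))
  out
}

#' ED amalgamation (general form)
#'
#' Embeds a dependent block `Qd` within the "present" state of a controlling
#' birth-death character. The amalgamated generator is
#' \deqn{ED(Qc, Qd) = \begin{pmatrix} -\alpha & \phi_d \alpha \\
#'        \beta^T & Q_d - I\beta \end{pmatrix}}
#' with dimension `dim(Qd) + 1`: one "controller absent" state followed by the
#' dependent states. The first row sends mass from "absent" to the dependent
#' states in proportion to the embedded initial vector `phi`; the first column
#' returns every dependent state to "absent" at the loss rate `beta`. The type
#' of embedded dependency is determined entirely by `phi`: a free simplex
#' gives ED-ql, the point mass (1,0,...) gives ED-bd (the macroevolutionary
#' lag).
#'
#' The canonical models use a single scalar `beta` (the same parameter for
#' every dependent-state -> absent transition); a per-state vector is allowed
#' but breaks the basic ED assumptions and triggers a warning.
#'
#' @param controlling a BD `character_spec` (supplies `gain`, and `loss`
#'   unless `beta` is given).
#' @param Qd `rate_matrix` of the dependent block.
#' @param phi embedded initial vector over `Qd`'s states.
#' @param beta loss rate: scalar (canonical) or per-state vector (relaxed).
#' @param absent_label label for the new "absent" state; defaults to the
#'   controller's absent token suffixed to make composite labels.
#' @return `rate_matrix` of dimension `nrow(Qd) + 1`.
#' @export
ed_amalgamate <- function(controlling, Qd, phi = NULL, beta = NULL,
                          absent_label = NULL) {
  stopifnot(inherits(controlling, "character_spec"), controlling$kind == "bd")
  Qd <- if (inherits(Qd, "rate_matrix")) Qd else rate_matrix(Qd)
  stopifnot_valid_Q(Qd)
  k <- nrow(Qd)
  if (is.null(phi)) phi <- rep(1 / k, k)
  phi <- as.numeric(phi)
  if (length(phi) != k) stop("phi must have one entry per state of Qd")
  if (any(phi < 0) || abs(sum(phi) - 1) > .TOL_CONSTRUCT)
    stop("phi must be a probability vector over Qd's states")
  alpha <- controlling$gain
  if (is.null(beta)) beta <- controlling$loss
  if (any(beta < 0) || alpha < 0) stop("rates must be nonnegative")
  if (length(beta) == 1L) {
    beta <- rep(beta, k)
  } else {
    if (length(beta) != k) stop("beta must be scalar or one rate per dependent state")
    if (length(unique(beta)) > 1L)
      warning("per-state loss rates break the canonical ED assumptions")
  }
  Q <- matrix(0, k + 1, k + 1)
  Q[1, 1] <- -alpha
  Q[1, -1] <- phi * alpha
  Q[-1, 1] <- beta
  Q[-1, -1] <- unclass(Qd) - diag(beta, k)
  if (is.null(absent_label)) absent_label <- controlling$labels[1]
  labels <- c(absent_label, rownames(Qd))
  out <- rate_matrix(Q, labels = labels)
  attr(out, "steps") <- c(attr(Qd, "steps"),
                          sprintf("ED(%s; %d -> %d)", controlling$name, k, k + 1))
  out
}

#' ED-ql amalgamation of a controller and a qualitative dependent
#'
#' On each birth of the controller the dependent state is drawn from the
#' dependent's own embedded vector `phi` (a free parameter of the model).
#'
#' @param controlling BD `character_spec`.
#' @param dependent qualitative `character_spec`.
#' @return amalgamated `rate_matrix` with composite labels.
#' @export
ed_ql <- function(controlling, dependent) {
  stopifnot(inherits(dependent, "character_spec"))
  Qd <- relabel_states(dependent$Q, paste0(controlling$labels[2], rownames(dependent$Q)))
  out <- ed_amalgamate(controlling, Qd, phi = as.numeric(dependent$phi),
                       absent_label = controlling$labels[1])
  out
}

#' ED-bd amalgamation of a controller and a BD dependent
#'
#' Forces the embedded vector to (1, 0, ...): the dependent is reborn in its
#' "absent" state whenever the controller is born, so the direct change from
#' "controller absent" to "controller and dependent both present" is
#' penalised (rate exactly 0) — the macroevolutionary lag.
#'
#' @inheritParams ed_ql
#' @export
ed_bd <- function(controlling, dependent) {
  stopifnot(inherits(dependent, "character_spec"))
  Qd <- relabel_states(dependent$Q, paste0(controlling$labels[2], rownames(dependent$Q)))
  ed_amalgamate(controlling, Qd, phi = c(1, rep(0, nrow(Qd) - 1)),
                absent_label = paste0(controlling$labels[1], dependent$labels[1]))
}

relabel_states <- function(Q, labels) {
  out <- rate_matrix(unclass(Q), labels = labels)
  attr(out, "steps") <- attr(Q, "steps")
  out
}

#' Hidden-state expansion of a rate matrix
#'
#' Expands each state into one or more hidden copies so that the expanded
#' chain is strongly lumpable back onto the original: from any copy of state
#' i, the total rate into the copies of state j equals Q[i, j] (split
#' uniformly among the copies). The expanded and original models are
#' congruent — they return the same pruning likelihood on identical
#' observable data — which allows a fair marginal-likelihood comparison
#' against structured Markov models (SMMs) whose hidden-state spaces are
#' larger.
#'
#' @param Q a valid `rate_matrix`.
#' @param copies integer vector: number of hidden copies per original state
#'   (in `Q`'s state order). States with 1 copy keep their label; others get
#'   suffixes `.1`, `.2`, ...
#' @return expanded `rate_matrix` with attribute `observable` mapping each
#'   expanded state to its original label.
#' @export
expand_with_hidden_states <- function(Q, copies) {
  stopifnot_valid_Q(Q)
  k <- nrow(Q)
  copies <- as.integer(copies)
  if (length(copies) != k || any(copies < 1L))
    stop("copies must give a positive count for every state")
  obs <- rep(seq_len(k), copies)
  n <- length(obs)
  lab <- unlist(lapply(seq_len(k), function(i) {
    if (copies[i] == 1L) rownames(Q)[i]
    else paste0(rownames(Q)[i], ".", seq_len(copies[i]))
  }))
  E <- matrix(0, n, n)
  for (x in seq_len(n)) {
    i <- obs[x]
    for (j in seq_len(k)) {
      tgt <- which(obs == j)
      if (j == i) {
        # within-block: no hidden switching; diagonal fixed below
        next
      }
      E[x, tgt] <- Q[i, j] / copies[j]
    }
  }
  diag(E) <- -rowSums(E)
  out <- rate_matrix(E, labels = lab)
  attr(out, "observable") <- setNames(rownames(Q)[obs], lab)
  out
}

#' Lump states of a rate matrix
#'
#' Aggregates states by a partition, checking the strong-lumpability
#' condition: for every pair of blocks (B, C) the total rate from each member
#' of B into C must be identical (within 1e-10). If it holds the collapsed
#' chain is Markov with the returned generator; otherwise an error names the
#' offending block pair.
#'
#' @param Q a valid `rate_matrix`.
#' @param partition list of character vectors of state labels (the blocks),
#'   or a vector mapping each state to a block name (e.g. the `observable`
#'   attribute from [expand_with_hidden_states()]).
#' @return lumped `rate_matrix` labelled by block names.
#' @export
lump_states <- function(Q, partition) {
  stopifnot_valid_Q(Q)
  lab <- rownames(Q)
  if (!is.list(partition)) {
    if (is.null(names(partition))) names(partition) <- lab
    blocks <- split(names(partition), factor(partition, levels = unique(partition)))
  } else {
    blocks <- partition
    if (is.null(names(blocks))) names(blocks) <- paste0("B", seq_along(blocks))
  }
  if (!setequal(unlist(blocks), lab) || length(unlist(blocks)) != length(lab))
    stop("partition must cover every state exactly once")
  m <- length(blocks)
  L <- matrix(0, m, m, dimnames = list(names(blocks), names(blocks)))
  for (b in seq_len(m)) {
    ib <- match(blocks[[b]], lab)
    for (cc in seq_len(m)) {
      if (b == cc) next
      ic <- match(blocks[[cc]], lab)
      sums <- rowSums(Q[ib, ic, drop = FALSE])
      if (max(sums) - min(sums) > 1e-10)
        stop(sprintf("not lumpable: unequal rates from block '%s' into block '%s'",
                     names(blocks)[b], names(blocks)[cc]))
      L[b, cc] <- sums[1]
    }
  }
  diag(L) <- -rowSums(L)
  rate_matrix(L)
}

#' Compose the root vector of an amalgamated chain
#'
#' Builds the product-form initial vector over amalgamated states: a state is
#' reached by "controller present with probability pi2" times the dependent
#' state's own initial probability, while all combinations with an absent
#' controller collapse onto the single absent state. For the tail-colour case
#' this gives pi_ql = (1 - piT2, piT2*piC1, piT2*piC2); for the
#' tail-colour-and-armour case pi_TA = (1 - piT2, piT2*piA1, piT2*piA2*piC1,
#' piT2*piA2*piC2).
#'
#' @param diagram a `dependency_diagram` (see [dependency_diagram()]); the
#'   per-character `pi` vectors are taken from its `character_spec`s.
#' @return `prob_vector` over the amalgamated states of [dda_traverse()].
#' @export
compose_root_vector <- function(diagram) {
  res <- dda_traverse(diagram)
  res$root_vector
}
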