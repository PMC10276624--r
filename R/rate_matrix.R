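#' Construct a labelled CTMC rate matrix
#'
#' A `rate_matrix` is a square generator matrix Q of a continuous-time Markov
#' chain over a set of labelled states: off-diagonal entries are nonnegative
#' transition intensities (events per unit time) and every row sums to zero.
#' All amalgamated models in this package are plain `rate_matrix` objects, so
#' they work with standard machinery (matrix exponentiation, pruning).
#'
#' @param rates square numeric matrix of transition intensities; the diagonal
#'   may be supplied or left as anything — it is always recomputed so rows sum
#'   to zero when `fix_diagonal = TRUE` (the default keeps the given diagonal
#'   and validates it).
#' @param labels character vector of unique state labels; defaults to existing
#'   dimnames or `s1..sk`.
#' @param fix_diagonal if TRUE, overwrite the diagonal with minus the
#'   off-diagonal row sums.
#' @return an object of class `rate_matrix` (a numeric matrix with dimnames).
#' @examples
#' rate_matrix(rbind(c(-1, 1), c(2, -2)), labels = c("a", "p"))
#' @export
rate_matrix <- function(rates, labels = NULL, fix_diagonal = FALSE) {
  rates <- as.matrix(rates)
  if (nrow(rates) != ncol(rates)) stop("rate matrix must be square")
  if (is.null(labels)) {
    labels <- rownames(rates)
    if (is.null(labels)) labels <- paste0("s", seq_len(nrow(rates)))
  }
  if (length(labels) != nrow(rates)) stop("labels length must match dimension")
  if (anyDuplicated(labels)) stop("duplicate state labels: ",
                                  paste(labels[duplicated(labels)], collapse = ", "))
  if (fix_diagonal) diag(rates) <- 0
  storage.mode(rates) <- "double"
  if (fix_diagonal) diag(rates) <- -rowSums(rates)
  dimnames(rates) <- list(labels, labels)
  structure(rates, class = c("rate_matrix", "matrix", "array"))
}

#' @export
print.rate_matrix <- function(x, digits = 4, ...) {
  cat("CTMC rate matrix (", nrow(x), " states)\n", sep = "")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

state_labels <- function(Q) rownames(Q)

# construction-time tolerance: separates modelling errors from fp noise
.TOL_CONSTRUCT <- 1e-12
.TOL_EXPM <- 1e-10

#' Validate a rate matrix
#'
#' Checks the generator invariants: square, unique labels, nonnegative
#' off-diagonal entries, zero row sums (to 1e-12), dimension >= 2.
#'
#' @param Q matrix to check.
#' @return list with `valid` (logical) and `violations` (character vector, one
#'   entry per offending cell/row).
#' @export
validate_rate_matrix <- function(Q) {
  viol <- character(0)
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) {
    return(list(valid = FALSE, violations = "not a square matrix"))
  }
  lab <- rownames(Q)
  if (is.null(lab)) lab <- paste0("s", seq_len(nrow(Q)))
  if (anyDuplicated(lab)) viol <- c(viol, "duplicate state labels")
  if (nrow(Q) < 2) viol <- c(viol, "dimension must be >= 2")
  off <- Q; diag(off) <- 0
  bad <- which(off < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    viol <- c(viol, sprintf("negative off-diagonal rate %s -> %s",
                            lab[bad[, 1]], lab[bad[, 2]]))
  }
  rs <- rowSums(Q)
  badrow <- which(abs(rs) > .TOL_CONSTRUCT)
  if (length(badrow)) {
    viol <- c(viol, sprintf("row %s sums to %.3e (not 0)", lab[badrow], rs[badrow]))
  }
  list(valid = length(viol) == 0L, violations = viol)
}

stopifnot_valid_Q <- function(Q) {
  v <- validate_rate_matrix(Q)
  if (!v$valid) stop("invalid rate matrix: ", paste(v$violations, collapse = "; "))
  invisible(TRUE)
}

#' Construct a probability vector over labelled states
#'
#' @param probs nonnegative numeric vector summing to 1 (within 1e-12).
#' @param labels state labels, same order as its companion rate matrix.
#' @return named numeric vector of class `prob_vector`.
#' @export
prob_vector <- function(probs, labels = names(probs)) {
  if (is.null(labels)) labels <- paste0("s", seq_along(probs))
  if (length(labels) != length(probs)) stop("labels length must match probs")
  if (any(probs < 0)) stop("probabilities must be nonnegative")
  if (abs(sum(probs) - 1) > .TOL_CONSTRUCT) stop("probabilities must sum to 1")
  structure(setNames(as.numeric(probs), labels), class = "prob_vector")
}

#' @export
print.prob_vector <- function(x, ...) {
  print(setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

#' Stationary distribution of a CTMC
#'
#' Solves pi Q = 0 with sum(pi) = 1 by a dense linear solve. Needed by the
#' "equilibrium" root-vector policy. For a reducible chain with a single
#' closed communicating class the mass is confined to that class; with more
#' than one closed class the stationary distribution is not unique and an
#' error names the classes.
#'
#' @param Q a valid `rate_matrix`.
#' @return a `prob_vector`.
#' @export
stationary_distribution <- function(Q) {
  stopifnot_valid_Q(Q)
  k <- nrow(Q)
  cls <- closed_classes(Q)
  if (length(cls) > 1L) {
    stop("chain has multiple closed classes: ",
         paste(vapply(cls, function(i) paste0("{", paste(rownames(Q)[i], collapse = ","), "}"),
                      ""), collapse = " "))
  }
  A <- rbind(t(Q), rep(1, k))
  b <- c(rep(0, k), 1)
  pi <- qr.solve(A, b)
  pi[abs(pi) < 1e-14] <- 0
  pi <- pmax(pi, 0)
  pi <- pi / sum(pi)
  prob_vector(pi, rownames(Q))
}

# closed communicating classes of the embedded jump graph
closed_classes <- function(Q) {
  k <- nrow(Q)
  adj <- (Q > 0); diag(adj) <- FALSE
  # reachability by repeated squaring of boolean adjacency
  reach <- adj | diag(TRUE, k)
  for (i in seq_len(ceiling(log2(max(k, 2))))) {
    reach <- reach | (reach %*% reach > 0)
  }
  comm <- reach & t(reach)          # mutual reachability -> classes
  classes <- unique(apply(comm, 1, which, simplify = FALSE))
  Filter(function(cl) {
    # closed iff nothing escapes the class
    all(!reach[cl, -cl, drop = FALSE]) || length(cl) == k
  }, classes)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Dense scaling-and-squaring Pade exponential (via \pkg{Matrix}); no
#' eigendecomposition is assumed, since amalgamated generators are generally
#' non-symmetric and time-irreversible.
#'
#' @param Q a valid `rate_matrix`.
#' @param t nonnegative elapsed time.
#' @return row-stochastic matrix with the same labels.
#' @export
transition_probabilities <- function(Q, t) {
  stopifnot_valid_Q(Q)
  if (t < 0) stop("t must be >= 0")
  P <- as.matrix(Matrix::expm(Matrix::Matrix(unclass(Q) * t)))
  P[P < 0] <- 0
  P[P > 1] <- 1
  dimnames(P) <- dimnames(Q)
  P
}

#' Read / write a rate matrix as TSV
#'
#' Plain TSV with a header row of state labels; row labels in the first
#' column. Amalgamation provenance (attribute `steps`), when present, is
#' stored in comment lines starting with `#`.
#'
#' @param Q a `rate_matrix`.
#' @param path file path.
#' @export
write_rate_matrix_tsv <- function(Q, path) {
  con <- file(path, "w")
  on.exit(close(con))
  steps <- attr(Q, "steps")
  if (!is.null(steps)) {
    for (s in steps) writeLines(paste0("# step\t", s), con)
  }
  writeLines(paste(c("state", rownames(Q)), collapse = "\t"), con)
  for (i in seq_len(nrow(Q))) {
    writeLines(paste(c(rownames(Q)[i], format(Q[i, ], digits = 17)), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_rate_matrix_tsv
#' @export
read_rate_matrix_tsv <- function(path) {
  lines <- readLines(path)
  steps <- sub("^# step\t", "", grep("^# step\t", lines, value = TRUE))
  lines <- grep("^#", lines, value = TRUE, invert = TRUE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  labels <- fields[[1]][-1]
  rows <- do.call(rbind, lapply(fields[-1], function(f) as.numeric(f[-1])))
  Q <- rate_matrix(rows, labels = labels)
  if (length(steps)) attr(Q, "steps") <- steps
  Q
}

#' Format a rate matrix as a RevBayes-style text block
#'
#' @param Q a `rate_matrix`.
#' @return character scalar, e.g. for pasting into a Rev script.
#' @export
format_revbayes <- function(Q) {
  rows <- apply(unclass(Q), 1, function(r) paste0("[", paste(format(r, trim = TRUE), collapse = ", "), "]"))
  paste0("# states: ", paste(rownames(Q), collapse = " "), "\nQ := [",
         paste(rows, collapse = ",\n      "), "]\n")
}
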