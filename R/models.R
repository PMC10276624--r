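#' Model factories for the named ED parametrizations
#'
#' Builds an `amalgamated_model`: a rate matrix over amalgamated states
#' together with its free-parameter bindings and a root-vector policy. The
#' named families cover the tail-colour case (3 states a/r/b) and the
#' tail-colour-and-armour (TCA) case (4 states aa1/pa1/pp1r/pp1b):
#'
#' \describe{
#'   \item{QTC1}{symmetric 3-state Mk; the single rate is fixed to 1 (the
#'     free rate is the clock psi), trivially time-reversible with equal or
#'     equilibrium root frequencies.}
#'   \item{QTC2}{tail gain `lambda` split equally between the colours, loss
#'     `beta`, colour change `gamma`, constrained `beta+lambda+gamma = 1`
#'     (2 free parameters).}
#'   \item{QTCA1}{TCA matrix with all non-zero rates equal (fixed to 1).}
#'   \item{QTCA2}{TCA matrix with all diagonal elements equal to -1 and
#'     off-diagonal rates rescaled uniformly within each row.}
#'   \item{QTCA3}{TCA rates grouped into hierarchy growth `q2`, hierarchy
#'     loss `q1` and qualitative change `q3`, with `q3 = 1 - q1 - q2`
#'     (2 free parameters); the aa1 row grows only to pa1 and the pa1 row
#'     splits q2 as q2/2 to each coloured-armour state.}
#'   \item{ED-ql-general}{tail-colour with all 5 admissible parameters
#'     (`alpha`, `beta`, `phi1`, `g_rb`, `g_br`).}
#'   \item{ED-bd-general}{tail-armour with all 4 admissible parameters
#'     (`alpha1`, `beta1`, `alphaA`, `betaA`); aa1 -> pp1 is structurally 0.}
#'   \item{TCA-general}{the 7-parameter TCA mixture (`alpha1`, `beta1`,
#'     `alpha2`, `phiC1`, `beta2`, `g_rb`, `g_br`).}
#'   \item{Mk-SMM-ind}{SMM amalgamation of three independent binary Mk
#'     chains (tail, armour, colour): 8 states, 4 observable, uniform
#'     observable initial vector. Used as the structured-Markov-model
#'     baseline.}
#'   \item{ED1..ED8}{the Table-style grid: QTCA3/QTCA1/QTCA2 crossed with
#'     equal / equilibrium / inferred root frequencies.}
#' }
#'
#' @param name model family name (see Details).
#' @param params named list/vector of free parameters where the family has
#'   any (e.g. `c(q1 = .2, q2 = .3)` for QTCA3).
#' @param root_policy one of "equal", "equilibrium", "inferred"; the grid
#'   names ED1..ED8 fix their own policy.
#' @return object of class `amalgamated_model`.
#' @export
make_model <- function(name, params = NULL, root_policy = c("equal", "equilibrium", "inferred")) {
  grid <- list(ED1 = c("QTCA3", "equal"),       ED2 = c("QTCA3", "equilibrium"),
               ED3 = c("QTCA1", "equal"),       ED4 = c("QTCA1", "equilibrium"),
               ED5 = c("QTCA1", "inferred"),    ED6 = c("QTCA2", "equal"),
               ED7 = c("QTCA2", "equilibrium"), ED8 = c("QTCA2", "inferred"))
  if (name %in% names(grid)) {
    fam <- grid[[name]]
    m <- make_model(fam[1], params = params, root_policy = fam[2])
    m$name <- name
    return(m)
  }
  root_policy <- match.arg(root_policy)
  if (name == "Mk-SMM-sw")
    stop("Mk-SMM-sw is not implemented here; see the source describing the switch-type SMM construction")
  spec <- switch(name,
    "QTC1" = list(
      free = character(0),
      build = function(p) rate_matrix(matrix(1, 3, 3) - diag(3, 3),
                                      labels = c("a", "r", "b"), fix_diagonal = TRUE),
      equal = rep(1 / 3, 3)),
    "QTC2" = list(
      free = c("beta", "lambda"),           # gamma = 1 - beta - lambda
      default = c(beta = 1 / 3, lambda = 1 / 3),
      simplex = c("beta", "lambda", "gamma"),
      build = function(p) {
        g <- 1 - p[["beta"]] - p[["lambda"]]
        check_simplex(c(p[["beta"]], p[["lambda"]], g))
        rate_matrix(rbind(
          c(0, p[["lambda"]] / 2, p[["lambda"]] / 2),
          c(p[["beta"]], 0, g),
          c(p[["beta"]], g, 0)), labels = c("a", "r", "b"), fix_diagonal = TRUE)
      },
      equal = rep(1 / 3, 3)),
    "QTCA1" = list(
      free = character(0),
      build = function(p) rate_matrix(rbind(
        c(0, 1, 0, 0),
        c(1, 0, 1, 1),
        c(1, 1, 0, 1),
        c(1, 1, 1, 0)), labels = .tca_states, fix_diagonal = TRUE),
      equal = rep(1 / 4, 4)),
    "QTCA2" = list(
      free = character(0),
      build = function(p) rate_matrix(rbind(
        c(-1, 1, 0, 0),
        c(1 / 3, -1, 1 / 3, 1 / 3),
        c(1 / 3, 1 / 3, -1, 1 / 3),
        c(1 / 3, 1 / 3, 1 / 3, -1)), labels = .tca_states),
      equal = rep(1 / 4, 4)),
    "QTCA3" = list(
      free = c("q1", "q2"),                  # q3 = 1 - q1 - q2
      default = c(q1 = 1 / 3, q2 = 1 / 3),
      simplex = c("q1", "q2", "q3"),
      build = function(p) {
        q1 <- p[["q1"]]; q2 <- p[["q2"]]; q3 <- 1 - q1 - q2
        check_simplex(c(q1, q2, q3))
        rate_matrix(rbind(
          c(0, q2, 0, 0),
          c(q1, 0, q2 / 2, q2 / 2),
          c(q1, q1, 0, q3),
          c(q1, q1, q3, 0)), labels = .tca_states, fix_diagonal = TRUE)
      },
      equal = rep(1 / 4, 4)),
    "ED-ql-general" = list(
      free = c("alpha", "beta", "phi1", "g_rb", "g_br"),
      default = c(alpha = 1, beta = 1, phi1 = 0.5, g_rb = 1, g_br = 1),
      build = function(p) {
        tail <- char_bd("T", gain = p[["alpha"]], loss = p[["beta"]])
        col <- char_ql("C", rate_matrix(rbind(c(-p[["g_rb"]], p[["g_rb"]]),
                                              c(p[["g_br"]], -p[["g_br"]])),
                                        labels = c("r", "b")),
                       phi = c(p[["phi1"]], 1 - p[["phi1"]]))
        ed_ql(tail, col)
      },
      relabel = c("a", "r", "b"),
      equal = rep(1 / 3, 3)),
    "ED-bd-general" = list(
      free = c("alpha1", "beta1", "alphaA", "betaA"),
      default = c(alpha1 = 1, beta1 = 1, alphaA = 1, betaA = 1),
      build = function(p) {
        tail <- char_bd("T", gain = p[["alpha1"]], loss = p[["beta1"]])
        armor <- char_bd("A", gain = p[["alphaA"]], loss = p[["betaA"]],
                         labels = c("a1", "p1"))
        Q <- ed_bd(tail, armor)
        # armour loss is a within-block event, not a loss of the controller
        Q
      },
      equal = rep(1 / 3, 3)),
    "TCA-general" = list(
      free = c("alpha1", "beta1", "alpha2", "phiC1", "beta2", "g_rb", "g_br"),
      default = c(alpha1 = 1, beta1 = 1, alpha2 = 1, phiC1 = 0.5, beta2 = 1,
                  g_rb = 1, g_br = 1),
      build = function(p) {
        tca_general_Q(p)
      },
      equal = rep(1 / 4, 4)),
    "Mk-SMM-ind" = list(
      free = character(0),
      build = function(p) {
        mk2 <- function(lab) rate_matrix(rbind(c(-1, 1), c(1, -1)), labels = lab)
        smm_amalgamate(smm_amalgamate(mk2(c("a", "p")), mk2(c("a1", "p1"))),
                       mk2(c("r", "b")))
      },
      observable = function(labels) {
        vapply(labels, function(l) {
          if (startsWith(l, "a")) "aa1"
          else if (grepl("a1", l, fixed = TRUE)) "pa1"
          else if (endsWith(l, "r")) "pp1r" else "pp1b"
        }, "")
      }),
    stop("unknown model name: ", name)
  )
  pars <- spec$default %||% setNames(numeric(0), character(0))
  if (!is.null(params)) {
    params <- unlist(params)
    bad <- setdiff(names(params), names(pars))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    pars[names(params)] <- params
  }
  if (any(pars < 0)) stop("parameters must be nonnegative")
  Q <- spec$build(pars)
  if (!is.null(spec$relabel)) Q <- relabel_states(Q, spec$relabel)
  obs <- NULL
  if (!is.null(spec$observable)) {
    obs <- spec$observable(rownames(Q))
    # equal policy = uniform over observable states, split within blocks
    tab <- table(obs)
    spec$equal <- as.numeric(1 / (length(tab) * tab[obs]))
  }
  model <- structure(list(
    name = name, Q = Q, params = pars, free = spec$free,
    simplex = spec$simplex, build = spec$build, relabel = spec$relabel,
    root_policy = root_policy, equal_root = spec$equal, observable = obs),
    class = "amalgamated_model")
  model$root_vector <- resolve_root_vector(model, root_policy)
  model
}

.tca_states <- c("aa1", "pa1", "pp1r", "pp1b")

#' Plain symmetric Mk model
#'
#' The k-state Mk matrix with all rates fixed to 1 (the free rate being the
#' clock), used e.g. for the binary backbone characters of the tail-colour
#' problem. Time-reversible with equal root frequencies.
#'
#' @param k number of states.
#' @param labels state labels (default `0..k-1`).
#' @param root_policy as in [make_model()].
#' @return an `amalgamated_model`.
#' @export
mk_model <- function(k = 2, labels = as.character(seq_len(k) - 1),
                     root_policy = "equal") {
  stopifnot(k >= 2, length(labels) == k)
  build <- function(p) rate_matrix(matrix(1, k, k) - diag(k, k),
                                   labels = labels, fix_diagonal = TRUE)
  model <- structure(list(name = paste0("Mk", k), Q = build(NULL),
                          params = setNames(numeric(0), character(0)),
                          free = character(0), simplex = NULL, build = build,
                          relabel = NULL, root_policy = root_policy,
                          equal_root = rep(1 / k, k), observable = NULL),
                     class = "amalgamated_model")
  model$root_vector <- resolve_root_vector(model, root_policy)
  model
}

tca_general_Q <- function(p) {
  tail <- char_bd("T", gain = p[["alpha1"]], loss = p[["beta1"]])
  armor <- char_bd("A", gain = p[["alpha2"]], loss = p[["beta2"]],
                   labels = c("a1", "p1"))
  col <- char_ql("C", rate_matrix(rbind(c(-p[["g_rb"]], p[["g_rb"]]),
                                        c(p[["g_br"]], -p[["g_br"]])),
                                  labels = c("r", "b")),
                 phi = c(p[["phiC1"]], 1 - p[["phiC1"]]))
  inner <- ed_ql(armor, col)                      # states a1, p1r, p1b
  Qd <- relabel_states(inner, paste0("p", rownames(inner)))
  ed_amalgamate(tail, Qd, phi = c(1, 0, 0), absent_label = "aa1")
}

#' Read a model configuration from JSON
#'
#' Schema: `{"family": "QTCA3", "params": {"q1": 0.2, "q2": 0.5},
#' "root_policy": "equilibrium"}`.
#'
#' @param config path to a JSON file, or a JSON string.
#' @return an `amalgamated_model`.
#' @export
read_model_config <- function(config) {
  txt <- if (length(config) == 1 && file.exists(config))
    paste(readLines(config), collapse = "\n") else config
  s <- jsonlite::fromJSON(txt, simplifyDataFrame = FALSE)
  make_model(s$family, params = s$params,
             root_policy = s$root_policy %||% "equal")
}

check_simplex <- function(x) {
  if (any(x < 0) || any(x > 1)) stop("simplex constraint violated (rates must lie in [0,1] and sum to 1)")
  invisible(TRUE)
}

#' @export
print.amalgamated_model <- function(x, ...) {
  cat(sprintf("amalgamated model '%s': %d states, %d free Q parameter(s), root policy '%s'\n",
              x$name, nrow(x$Q), length(x$free), x$root_policy))
  print(x$Q, ...)
  invisible(x)
}

#' Rebuild a model's rate matrix for new parameter values
#'
#' @param model `amalgamated_model`.
#' @param params named vector of the model's free parameters.
#' @return the model with updated `Q`, `params` and resolved root vector.
#' @export
update_model <- function(model, params) {
  pars <- model$params
  pars[names(params)] <- unlist(params)
  Q <- model$build(pars)
  if (!is.null(model$relabel)) Q <- relabel_states(Q, model$relabel)
  model$Q <- Q
  model$params <- pars
  model$root_vector <- resolve_root_vector(model, model$root_policy)
  model
}

#' Count the free parameters of a model
#'
#' Honours simplex constraints (a k-rate simplex counts k-1) and linked
#' rates. With `include_root`, an inferred root vector over k states adds
#' k-1; with `include_clock`, the global branch rate psi adds 1 (the
#' convention used to label the grid models, e.g. ED5 has 0 + 3 + 1 = 4).
#'
#' @param model `amalgamated_model`.
#' @param include_root count root-frequency parameters for the "inferred"
#'   policy.
#' @param include_clock count the clock rate psi.
#' @return integer.
#' @export
count_free_parameters <- function(model, include_root = FALSE, include_clock = FALSE) {
  n <- length(model$free)
  if (include_root && model$root_policy == "inferred") n <- n + nrow(model$Q) - 1L
  if (include_clock) n <- n + 1L
  as.integer(n)
}

#' Resolve the root-vector policy of a model
#'
#' `equal` gives uniform frequencies (uniform over observable states, split
#' within hidden blocks, for hidden-state models); `equilibrium` the
#' stationary distribution of Q; `inferred` declares k-1 latent simplex
#' parameters with a flat Dirichlet(1,...,1) prior, to be sampled by
#' [ed_mcmc()].
#'
#' @param model `amalgamated_model`.
#' @param policy "equal", "equilibrium" or "inferred".
#' @return a `prob_vector`, or a `latent_root` declaration for "inferred".
#' @export
resolve_root_vector <- function(model, policy = model$root_policy) {
  policy <- match.arg(policy, c("equal", "equilibrium", "inferred"))
  k <- nrow(model$Q)
  switch(policy,
    equal = prob_vector(model$equal_root %||% rep(1 / k, k), rownames(model$Q)),
    equilibrium = stationary_distribution(model$Q),
    inferred = structure(list(k = k, n_free = k - 1L, prior = "Dirichlet(1,...,1)",
                              labels = rownames(model$Q)),
                         class = "latent_root"))
}

#' @export
print.latent_root <- function(x, ...) {
  cat(sprintf("inferred root frequencies over %d states (%d free, prior %s)\n",
              x$k, x$n_free, x$prior))
  invisible(x)
}
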