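#' Declare a birth-death (BD) character
#'
#' A BD character records the absence/presence of an anatomical structure
#' (e.g. a tail). It is the only character type that can control others: its
#' "present" state licenses the evolution of dependent characters.
#'
#' @param name character name (used in composite state labels).
#' @param gain gain rate (absent -> present), per unit time.
#' @param loss loss rate (present -> absent).
#' @param pi length-2 initial probability vector (absent, present).
#' @param labels the two state tokens, default `c("a", "p")`; these tokens are
#'   concatenated when characters are amalgamated.
#' @return object of class `character_spec`.
#' @export
char_bd <- function(name, gain, loss, pi = c(0.5, 0.5), labels = c("a", "p")) {
  stopifnot(length(labels) == 2, gain >= 0, loss >= 0)
  Q <- rate_matrix(rbind(c(-gain, gain), c(loss, -loss)), labels = labels)
  structure(list(name = name, kind = "bd", labels = labels,
                 gain = gain, loss = loss, Q = Q,
                 pi = prob_vector(pi, labels),
                 phi = prob_vector(c(1, 0), labels)),  # lag rule: reborn absent
            class = "character_spec")
}

#' Declare a qualitative character
#'
#' A qualitative character describes a quality (colour, shape) of a
#' structure. It is always the dependent member of a hierarchy: it evolves
#' only while its controlling structure is present, and on each birth of the
#' controller its state is drawn afresh from the embedded vector `phi`.
#'
#' @param name character name.
#' @param Q `rate_matrix` of within-character transitions (>= 2 states).
#' @param pi initial probability vector over the states.
#' @param phi embedded initial vector: probabilities of the states at the
#'   instant the controlling structure is born. Defaults to `pi`.
#' @return object of class `character_spec`.
#' @export
char_ql <- function(name, Q, pi = NULL, phi = NULL) {
  Q <- if (inherits(Q, "rate_matrix")) Q else rate_matrix(Q)
  stopifnot_valid_Q(Q)
  k <- nrow(Q)
  if (is.null(pi)) pi <- rep(1 / k, k)
  if (is.null(phi)) phi <- as.numeric(pi)
  structure(list(name = name, kind = "qualitative", labels = rownames(Q),
                 Q = Q,
                 pi = prob_vector(as.numeric(pi), rownames(Q)),
                 phi = prob_vector(as.numeric(phi), rownames(Q))),
            class = "character_spec")
}

#' @export
print.character_spec <- function(x, ...) {
  cat(sprintf("%s character '%s': states {%s}\n",
              x$kind, x$name, paste(x$labels, collapse = ",")))
  invisible(x)
}
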