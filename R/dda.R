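#' Build a dependency diagram
#'
#' A dependency diagram is an acyclic graph of characters in which every
#' dependency arrow originates at the p-node ("present" state) of a BD
#' character and points to a dependent character (BD or qualitative). It is
#' the input to the dependency diagram amalgamation (DDA) algorithm.
#'
#' @param characters list of [char_bd()] / [char_ql()] objects.
#' @param arrows two-column data.frame or matrix (`from`, `to`) of character
#'   names; `from` must name a BD character.
#' @return object of class `dependency_diagram`.
#' @export
dependency_diagram <- function(characters, arrows = NULL) {
  names(characters) <- vapply(characters, `[[`, "", "name")
  if (anyDuplicated(names(characters))) stop("duplicate character names")
  if (is.null(arrows) || NROW(arrows) == 0) {
    arrows <- data.frame(from = character(0), to = character(0))
  } else {
    arrows <- as.data.frame(arrows, stringsAsFactors = FALSE)
    names(arrows) <- c("from", "to")
  }
  for (i in seq_len(nrow(arrows))) {
    f <- arrows$from[i]; t <- arrows$to[i]
    if (!f %in% names(characters)) stop("unknown parent character: ", f)
    if (!t %in% names(characters)) stop("unknown dependent character: ", t)
    if (characters[[f]]$kind != "bd")
      stop("dependency arrow from qualitative character '", f,
           "': only BD characters (p-nodes) can control")
  }
  if (anyDuplicated(arrows$to)) stop("character with more than one controller: ",
                                     arrows$to[duplicated(arrows$to)][1])
  # cycle detection by repeated leaf-stripping
  deps <- split(arrows$to, arrows$from)
  remaining <- names(characters)
  repeat {
    leaves <- remaining[!remaining %in% arrows$from[arrows$to %in% remaining] &
                          vapply(remaining, function(n)
                            !length(intersect(deps[[n]], remaining)), TRUE)]
    if (!length(leaves)) break
    remaining <- setdiff(remaining, leaves)
  }
  if (length(remaining)) stop("dependency cycle involving: ",
                              paste(remaining, collapse = ", "))
  roots <- setdiff(names(characters), arrows$to)
  structure(list(characters = characters, arrows = arrows, roots = roots),
            class = "dependency_diagram")
}

#' @export
print.dependency_diagram <- function(x, ...) {
  cat(sprintf("dependency diagram: %d characters, %d arrows, %d top-level hierarch%s\n",
              length(x$characters), nrow(x$arrows), length(x$roots),
              if (length(x$roots) == 1) "y" else "ies"))
  for (i in seq_len(nrow(x$arrows)))
    cat(sprintf("  %s(p) -> %s\n", x$arrows$from[i], x$arrows$to[i]))
  invisible(x)
}

#' Parse a dependency-diagram configuration file
#'
#' JSON schema: an array of character objects with fields `name`,
#' `kind` ("bd"/"qualitative"), and optionally `parent` (name of the
#' controlling BD character). BD characters take `gain`, `loss`, `labels`
#' (default `["a","p"]`), `pi`. Qualitative characters take `states`,
#' `rates` (square matrix; default symmetric rate 1), `pi`, `phi`.
#'
#' @param config path to a JSON file, or a JSON string.
#' @return a `dependency_diagram`.
#' @export
parse_diagram <- function(config) {
  txt <- if (length(config) == 1 && file.exists(config)) paste(readLines(config), collapse = "\n") else config
  spec <- jsonlite::fromJSON(txt, simplifyDataFrame = FALSE)
  chars <- lapply(spec, function(s) {
    kind <- match.arg(s$kind, c("bd", "qualitative"))
    if (kind == "bd") {
      char_bd(s$name,
              gain = s$gain %||% 1, loss = s$loss %||% 1,
              pi = unlist(s$pi %||% c(0.5, 0.5)),
              labels = unlist(s$labels %||% c("a", "p")))
    } else {
      states <- unlist(s$states)
      k <- length(states)
      Q <- if (!is.null(s$rates)) {
        rate_matrix(do.call(rbind, lapply(s$rates, unlist)), labels = states)
      } else {
        rate_matrix(matrix(1, k, k) - diag(k, k), labels = states, fix_diagonal = TRUE)
      }
      char_ql(s$name, Q, pi = unlist(s$pi) %||% NULL, phi = unlist(s$phi) %||% NULL)
    }
  })
  parents <- lapply(spec, function(s) s$parent)
  has_parent <- !vapply(parents, is.null, TRUE)
  arrows <- data.frame(from = unlist(parents[has_parent]),
                       to = vapply(spec[has_parent], `[[`, "", "name"))
  dependency_diagram(chars, arrows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dependency diagram amalgamation (DDA)
#'
#' Traverses the diagram from the tips towards the root in topological
#' order. At each p-node all child blocks are combined: multiple children
#' are first SMM-amalgamated pairwise (independent joint evolution), and the
#' combined block is then ED-amalgamated into its controller. The embedded
#' vector of a combined block is the product of the child embedded vectors,
#' where a BD-rooted child contributes the lag vector (1, 0, ...) and a
#' qualitative child its free phi. The amalgamation at the root of the
#' diagram yields the final rate matrix; the trace records one step per
#' pairwise SMM and per ED amalgamation with input and output dimensions.
#'
#' @param diagram a `dependency_diagram`.
#' @param combine_independent if TRUE and the diagram has several top-level
#'   hierarchies, SMM-amalgamate them into one matrix; by default each
#'   hierarchy keeps its own matrix (it should be its own recoded column).
#' @return object of class `dda_result`: list with `Q` (final
#'   `rate_matrix`), `root_vector`, `trace` (data.frame of steps), `states`
#'   (decode table), and `models` (per-hierarchy results when there are
#'   several roots).
#' @export
dda_traverse <- function(diagram, combine_independent = FALSE) {
  stopifnot(inherits(diagram, "dependency_diagram"))
  if (!length(diagram$characters)) stop("empty diagram")
  kids <- split(diagram$arrows$to, factor(diagram$arrows$from,
                                          levels = names(diagram$characters)))
  trace <- list()
  add_step <- function(node, type, dims_in, dim_out) {
    trace[[length(trace) + 1L]] <<- data.frame(
      node = node, type = type, dims_in = paste(dims_in, collapse = "x"),
      dim_out = dim_out, stringsAsFactors = FALSE)
  }

  # returns list(Q, phi, pi, bd_rooted, decode) for the block rooted at `nm`
  block <- function(nm) {
    ch <- diagram$characters[[nm]]
    children <- kids[[nm]]
    if (ch$kind == "qualitative") {
      decode <- lapply(ch$labels, function(s) setNames(list(s), nm))
      return(list(Q = ch$Q, phi = as.numeric(ch$phi), pi = as.numeric(ch$pi),
                  bd_rooted = FALSE, decode = decode))
    }
    if (!length(children)) {
      decode <- lapply(ch$labels, function(s) setNames(list(s), nm))
      return(list(Q = ch$Q, phi = c(1, 0), pi = as.numeric(ch$pi),
                  bd_rooted = TRUE, decode = decode))
    }
    blocks <- lapply(children, block)
    comb <- blocks[[1]]
    for (i in seq_along(blocks)[-1]) {
      b <- blocks[[i]]
      d1 <- nrow(comb$Q); d2 <- nrow(b$Q)
      Qc <- smm_amalgamate(comb$Q, b$Q)
      add_step(nm, "SMM", c(d1, d2), nrow(Qc))
      comb <- list(Q = Qc,
                   phi = as.vector(outer(comb$phi, b$phi))[smm_order(d1, d2)],
                   pi = as.vector(outer(comb$pi, b$pi))[smm_order(d1, d2)],
                   bd_rooted = comb$bd_rooted || b$bd_rooted,
                   decode = merge_decode(comb$decode, b$decode))
    }
    # ED amalgamation of the combined child block into this controller
    dep_labels <- paste0(ch$labels[2], rownames(comb$Q))
    Qd <- relabel_states(comb$Q, dep_labels)
    absent_label <- paste0(ch$labels[1], absent_token(blocks))
    type <- if (any(vapply(blocks, `[[`, TRUE, "bd_rooted"))) "ED-bd" else "ED-ql"
    Qe <- ed_amalgamate(ch, Qd, phi = comb$phi, absent_label = absent_label)
    add_step(nm, type, c(2, nrow(comb$Q)), nrow(Qe))
    pi2 <- as.numeric(ch$pi)[2]
    decode_abs <- c(setNames(list(ch$labels[1]), nm),
                    lapply(setNames(nm = all_names(comb$decode)), function(x) NA))
    decode <- c(list(decode_abs),
                lapply(comb$decode, function(d) c(setNames(list(ch$labels[2]), nm), d)))
    list(Q = Qe, phi = c(1, rep(0, nrow(comb$Q))),
         pi = c(1 - pi2, pi2 * comb$pi),
         bd_rooted = TRUE, decode = decode)
  }

  results <- lapply(setNames(nm = diagram$roots), function(r) {
    n0 <- length(trace)
    b <- block(r)
    if (nrow(b$Q) > 12)
      warning("hierarchy '", r, "' amalgamates to ", nrow(b$Q),
              " states; the approach targets moderate-size hierarchies ",
              "(matrix exponentiation cost grows fast)")
    list(Q = b$Q, root_vector = prob_vector(b$pi, rownames(b$Q)),
         phi = b$phi, decode = b$decode,
         trace = do.call(rbind, trace[seq_along(trace) > n0] %||% list()))
  })
  if (length(results) > 1L && combine_independent) {
    comb <- results[[1]]
    for (i in seq_along(results)[-1]) {
      d1 <- nrow(comb$Q); d2 <- nrow(results[[i]]$Q)
      Qc <- smm_amalgamate(comb$Q, results[[i]]$Q)
      add_step("<virtual root>", "SMM", c(d1, d2), nrow(Qc))
      comb <- list(Q = Qc,
                   root_vector = prob_vector(
                     as.vector(outer(as.numeric(comb$root_vector),
                                     as.numeric(results[[i]]$root_vector)))[smm_order(d1, d2)],
                     rownames(Qc)),
                   decode = merge_decode(comb$decode, results[[i]]$decode))
    }
    comb$trace <- do.call(rbind, trace)
    results <- c(results, list(`<virtual root>` = comb))
    main <- comb
  } else {
    main <- results[[1]]
  }
  structure(list(Q = main$Q, root_vector = main$root_vector,
                 trace = do.call(rbind, trace), states = main$decode,
                 models = results, diagram = diagram),
            class = "dda_result")
}

# kronecker-compatible ordering of the outer product of two state vectors
smm_order <- function(d1, d2) as.vector(t(matrix(seq_len(d1 * d2), d2, d1)))

merge_decode <- function(da, db) {
  out <- vector("list", length(da) * length(db))
  k <- 1L
  for (i in seq_along(da)) for (j in seq_along(db)) {
    out[[k]] <- c(da[[i]], db[[j]]); k <- k + 1L
  }
  out
}

all_names <- function(decode) unique(unlist(lapply(decode, names)))

# label token of the all-absent child state for BD-rooted children only
absent_token <- function(blocks) {
  paste(vapply(blocks, function(b) {
    if (b$bd_rooted) rownames(b$Q)[1] else ""
  }, ""), collapse = "")
}

#' @export
print.dda_result <- function(x, ...) {
  cat(sprintf("DDA result: final rate matrix with %d states in %d steps\n",
              nrow(x$Q), NROW(x$trace)))
  if (NROW(x$trace)) print(x$trace)
  invisible(x)
}

#' Recode hierarchy columns into a single amalgamated character
#'
#' Converts the per-character columns of a hierarchy into one column whose
#' states match the amalgamated ED rate matrix. Cell semantics: a dependent
#' scored "-" requires the controller to be absent; "?" is compatible with
#' any state; a dependent scored with an applicable state while its
#' controller is absent is a contradiction and raises an error with the
#' taxon/character coordinates. Partially missing rows become ambiguity sets
#' over the compatible amalgamated states.
#'
#' @param data `character_matrix` (or plain matrix) whose columns include the
#'   hierarchy's characters.
#' @param diagram a `dependency_diagram`.
#' @param columns named character vector mapping character names to column
#'   names of `data`; defaults to identity (columns named as the characters).
#' @return `character_matrix` with one column per top-level hierarchy; the
#'   DDA result is attached as attribute `dda`.
#' @export
recode_characters <- function(data, diagram, columns = NULL) {
  res <- dda_traverse(diagram)
  if (is.null(columns))
    columns <- setNames(nm = names(diagram$characters))
  out <- matrix(NA_character_, nrow(data), length(res$models),
                dimnames = list(rownames(data), names(res$models)))
  for (h in names(res$models)) {
    hres <- res$models[[h]]
    labels <- rownames(hres$Q)
    decode <- hres$decode
    chars <- all_names(decode)
    for (tx in seq_len(nrow(data))) {
      compat <- rep(TRUE, length(labels))
      for (ch in chars) {
        obs <- data[tx, columns[[ch]]]
        if (obs == "?") next
        ok <- vapply(decode, function(d) {
          val <- d[[ch]]
          if (obs == "-") is.na(val) else (!is.na(val) && val == obs)
        }, TRUE)
        compat <- compat & ok
      }
      if (!any(compat))
        stop(sprintf("contradictory scoring for taxon '%s' in hierarchy '%s' (e.g. dependent applicable while controller absent)",
                     rownames(data)[tx], h))
      out[tx, h] <- paste(labels[compat], collapse = "/")
    }
  }
  m <- character_matrix(out)
  attr(m, "dda") <- res
  m
}

#' Decode an amalgamated state back into per-character scores
#'
#' Inverse of [recode_characters()] for a single fully resolved state label.
#'
#' @param state a state label of the amalgamated matrix.
#' @param dda a `dda_result`.
#' @return named character vector of per-character tokens, `"-"` where
#'   inapplicable.
#' @export
decode_state <- function(state, dda) {
  hres <- if (length(dda$models) == 1L) dda$models[[1]] else dda
  i <- match(state, rownames(hres$Q))
  if (is.na(i)) stop("unknown amalgamated state: ", state)
  d <- hres$decode[[i]]
  vapply(d, function(v) if (is.na(v[1])) "-" else as.character(v), "")
}
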