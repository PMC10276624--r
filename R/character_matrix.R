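#' Character matrix container
#'
#' A taxa-by-characters matrix of state tokens. Cells hold a single symbol,
#' an ambiguity set written `"s1/s2"`, `"?"` (missing: any state), or `"-"`
#' (inapplicable: the controlling structure is absent). Columns may carry a
#' partition assignment (e.g. binary backbone characters vs an amalgamated
#' hierarchy character) used by [ed_mcmc()].
#'
#' @param x character matrix (rownames = taxa).
#' @param partition optional vector (length = ncol) naming the partition of
#'   each column.
#' @return object of class `character_matrix`.
#' @export
character_matrix <- function(x, partition = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "character"
  if (is.null(rownames(x))) rownames(x) <- paste0("t", seq_len(nrow(x)))
  if (is.null(colnames(x)) && ncol(x) > 0) colnames(x) <- paste0("c", seq_len(ncol(x)))
  if (!is.null(partition)) {
    stopifnot(length(partition) == ncol(x))
    attr(x, "partition") <- as.character(partition)
  }
  class(x) <- c("character_matrix", "matrix", "array")
  x
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character matrix: %d taxa x %d characters\n", nrow(x), ncol(x)))
  p <- attr(x, "partition")
  if (!is.null(p)) cat("partitions:", paste(sprintf("%s (%d)", names(table(p)), table(p)),
                                            collapse = ", "), "\n")
  if (ncol(x) > 8) {
    print(unclass(x)[, 1:8, drop = FALSE], quote = FALSE)
    cat("... (", ncol(x) - 8, " more columns)\n", sep = "")
  } else print(unclass(x), quote = FALSE)
  invisible(x)
}

#' Write / read a character matrix as a NEXUS DATA block
#'
#' Minimal morphological NEXUS (STANDARD datatype): symbols per matrix, "-"
#' for inapplicable ("gap"), "?" for missing, curly braces for ambiguity
#' sets. Multi-character state tokens (amalgamated states such as "pp1r") are
#' mapped to single symbols and the mapping written as a state-key comment
#' block; the reader applies the key in reverse.
#'
#' @param x a `character_matrix`.
#' @param path file path.
#' @export
write_character_nexus <- function(x, path) {
  tokens <- sort(setdiff(unique(unlist(strsplit(as.vector(x), "/", fixed = TRUE))),
                         c("?", "-")))
  pool <- c(0:9, letters, LETTERS)
  if (length(tokens) > length(pool)) stop("too many distinct state tokens for NEXUS symbols")
  key <- setNames(as.character(pool[seq_along(tokens)]), tokens)
  enc <- function(cell) {
    if (cell %in% c("?", "-")) return(cell)
    parts <- key[strsplit(cell, "/", fixed = TRUE)[[1]]]
    if (anyNA(parts)) stop("unknown state token in cell: ", cell)
    if (length(parts) > 1) paste0("{", paste(parts, collapse = ""), "}") else parts
  }
  rows <- apply(x, 1, function(r) paste(vapply(r, enc, ""), collapse = ""))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines(sprintf("[ state key: %s ]",
                     paste(sprintf("%s=%s", key, names(key)), collapse = " ")), con)
  writeLines("BEGIN DATA;", con)
  writeLines(sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(x), ncol(x)), con)
  writeLines(sprintf("  FORMAT DATATYPE=STANDARD GAP=- MISSING=? SYMBOLS=\"%s\";",
                     paste(key, collapse = "")), con)
  writeLines("  MATRIX", con)
  for (i in seq_len(nrow(x))) writeLines(sprintf("    %s  %s", rownames(x)[i], rows[i]), con)
  writeLines("  ;", con)
  writeLines("END;", con)
  invisible(path)
}

#' @rdname write_character_nexus
#' @export
read_character_nexus <- function(path) {
  lines <- readLines(path)
  keyline <- grep("^\\[ state key:", lines, value = TRUE)
  key <- NULL
  if (length(keyline)) {
    spec <- strsplit(sub("^\\[ state key: (.*) \\]$", "\\1", keyline[1]), " ", fixed = TRUE)[[1]]
    kv <- strsplit(spec, "=", fixed = TRUE)
    key <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  }
  i0 <- grep("^\\s*MATRIX\\s*$", lines)
  if (!length(i0)) stop("no MATRIX block found")
  i1 <- i0[1] + 1
  taxa <- character(0); rows <- character(0)
  while (!grepl("^\\s*;\\s*$", lines[i1])) {
    f <- strsplit(trimws(lines[i1]), "\\s+")[[1]]
    if (length(f) >= 2) { taxa <- c(taxa, f[1]); rows <- c(rows, f[2]) }
    i1 <- i1 + 1
  }
  dec <- function(row) {
    cells <- character(0); i <- 1; chars <- strsplit(row, "")[[1]]
    while (i <= length(chars)) {
      ch <- chars[i]
      if (ch == "{") {
        j <- i + 1; grp <- character(0)
        while (chars[j] != "}") { grp <- c(grp, chars[j]); j <- j + 1 }
        syms <- if (is.null(key)) grp else unname(key[grp])
        cells <- c(cells, paste(syms, collapse = "/")); i <- j + 1
      } else {
        cells <- c(cells, if (ch %in% c("?", "-") || is.null(key)) ch else unname(key[ch]))
        i <- i + 1
      }
    }
    cells
  }
  m <- do.call(rbind, lapply(rows, dec))
  rownames(m) <- taxa
  character_matrix(m)
}

#' Write / read a character matrix as CSV
#'
#' Plain CSV with taxa in the first column; cells use the package's token
#' conventions ("/" ambiguity, "?", "-").
#'
#' @param x a `character_matrix`.
#' @param path file path.
#' @export
write_character_csv <- function(x, path) {
  df <- data.frame(taxon = rownames(x), unclass(x), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_character_csv
#' @export
read_character_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  character_matrix(m)
}
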