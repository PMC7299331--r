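#' Signed regulatory networks
#'
#' A `regnet` is a signed directed graph over gene identifiers. Edges carry a
#' sign: `"activator"`, `"repressor"` or `"unknown"`. At most one edge is
#' allowed per ordered (source, target) pair; self-loops (autoregulation) are
#' permitted, as are isolated genes.
#'
#' @param edges a data frame with columns `source`, `target`, `sign`
#'   (character). May have zero rows.
#' @param genes character vector of gene identifiers. Defaults to the union of
#'   edge endpoints; may list additional isolated genes.
#' @return An object of class `regnet`: a list with elements `genes`
#'   (character) and `edges` (data frame with columns source, target, sign).
#' @examples
#' ffl <- regnet(data.frame(source = c("X", "X", "Y"),
#'                          target = c("Y", "Z", "Z"),
#'                          sign   = "activator"))
#' n_edges(ffl)
#' @export
regnet <- function(edges = NULL, genes = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        sign = character(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("source", "target", "sign") %in% names(edges)))
  edges <- edges[, c("source", "target", "sign")]
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$sign <- as.character(edges$sign)

  bad <- setdiff(unique(edges$sign), c("activator", "repressor", "unknown"))
  if (length(bad) > 0) {
    stop("invalid edge sign(s): ", paste(bad, collapse = ", "))
  }

  # collapse exact duplicates, reject sign conflicts on an ordered pair
  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    full <- paste(key, edges$sign, sep = "\r")
    edges <- edges[!duplicated(full), , drop = FALSE]
    key <- paste(edges$source, edges$target, sep = "\r")
    if (anyDuplicated(key)) {
      dupe <- key[duplicated(key)][1]
      pair <- strsplit(dupe, "\r", fixed = TRUE)[[1]]
      stop("conflicting signs for edge ", pair[1], " -> ", pair[2])
    }
  }

  endpoint <- unique(c(edges$source, edges$target))
  if (is.null(genes)) {
    genes <- endpoint
  } else {
    genes <- unique(as.character(genes))
    missing <- setdiff(endpoint, genes)
    if (length(missing) > 0) {
      stop("edge endpoint(s) not in gene set: ", paste(missing, collapse = ", "))
    }
  }
  rownames(edges) <- NULL
  structure(list(genes = genes, edges = edges), class = "regnet")
}

#' @export
print.regnet <- function(x, ...) {
  tab <- table(factor(x$edges$sign,
                      levels = c("activator", "repressor", "unknown")))
  cat(sprintf("regnet: %d genes, %d edges (%d activator, %d repressor, %d unknown)\n",
              length(x$genes), nrow(x$edges),
              tab[["activator"]], tab[["repressor"]], tab[["unknown"]]))
  invisible(x)
}

#' @rdname regnet
#' @param x a `regnet`.
#' @export
n_genes <- function(x) length(x$genes)

#' @rdname regnet
#' @export
n_edges <- function(x) nrow(x$edges)

#' @export
`==.regnet` <- function(e1, e2) {
  same_genes <- setequal(e1$genes, e2$genes)
  k1 <- sort(paste(e1$edges$source, e1$edges$target, e1$edges$sign))
  k2 <- sort(paste(e2$edges$source, e2$edges$target, e2$edges$sign))
  same_genes && identical(k1, k2)
}

# fast lookup of in-edges, keyed by target
in_edges_index <- function(net) {
  split(net$edges[, c("source", "sign")], factor(net$edges$target, levels = net$genes))
}

#' Sign token dictionary
#'
#' Maps raw sign tokens from edge-list files onto the canonical sign values.
#' Tokens `+`, `activator`, `activation`, `act`, `positive`, `1` map to
#' `"activator"`; `-`, `repressor`, `repression`, `rep`, `negative`, `-1` to
#' `"repressor"`; `?` and `unknown` to `"unknown"`. Any other token maps to
#' `"unknown"` with a warning.
#'
#' @param tokens character vector of raw tokens.
#' @return character vector of canonical signs.
#' @export
canonical_sign <- function(tokens) {
  tk <- tolower(as.character(tokens))
  out <- rep("unknown", length(tk))
  out[tk %in% c("+", "activator", "activation", "act", "positive", "1")] <- "activator"
  out[tk %in% c("-", "repressor", "repression", "rep", "negative", "-1")] <- "repressor"
  known <- out != "unknown" | tk %in% c("?", "unknown")
  if (any(!known)) {
    warning("unrecognized sign token(s) treated as unknown: ",
            paste(unique(tokens[!known]), collapse = ", "))
  }
  out
}

#' Read a regulatory network from a plain-text edge list
#'
#' The format is whitespace- or tab-separated columns `source target [sign]`,
#' with `#` starting a comment. Lines with only two fields get
#' `sign = "unknown"`. Duplicate identical lines collapse to one edge;
#' conflicting signs for the same ordered pair are an error. A structured
#' comment `# isolated: g1 g2 ...` (as written by [write_edge_list]) restores
#' isolated genes.
#'
#' @param path file path.
#' @param comment_char character that starts a comment line.
#' @return a [regnet].
#' @export
read_edge_list <- function(path, comment_char = "#") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  src <- character(0); tgt <- character(0); tok <- character(0)
  iso <- character(0)
  for (i in seq_along(lines)) {
    # the writer records isolated genes in a structured comment
    if (grepl(paste0("^", comment_char, "\\s*isolated:"), lines[i])) {
      iso <- c(iso, strsplit(trimws(sub(paste0("^", comment_char,
                                               "\\s*isolated:"), "",
                                        lines[i])), "\\s+")[[1]])
      next
    }
    ln <- sub(paste0(comment_char, ".*$"), "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    fields <- strsplit(ln, "[ \t]+")[[1]]
    if (length(fields) < 2) {
      stop("malformed line ", i, " in ", path, ": ", lines[i])
    }
    src <- c(src, fields[1])
    tgt <- c(tgt, fields[2])
    tok <- c(tok, if (length(fields) >= 3) fields[3] else "?")
  }
  edges <- if (length(src) == 0) NULL else {
    data.frame(source = src, target = tgt,
               sign = canonical_sign(tok), stringsAsFactors = FALSE)
  }
  regnet(edges, genes = unique(c(src, tgt, iso)))
}

#' Write a regulatory network as a plain-text edge list
#'
#' Signs are serialized as `+`, `-` and `?`; isolated genes are recorded in a
#' header comment so that `read_edge_list(write_edge_list(n))` round-trips.
#'
#' @param net a [regnet].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "regnet"))
  sym <- c(activator = "+", repressor = "-", unknown = "?")
  lines <- c("# source\ttarget\tsign")
  iso <- setdiff(net$genes, unique(c(net$edges$source, net$edges$target)))
  if (length(iso) > 0) {
    lines <- c(lines, paste0("# isolated: ", paste(iso, collapse = " ")))
  }
  if (nrow(net$edges) > 0) {
    lines <- c(lines, paste(net$edges$source, net$edges$target,
                            sym[net$edges$sign], sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Per-gene degree profile split by edge sign
#'
#' @param net a [regnet].
#' @return a data frame with one row per gene and columns
#'   `in_activator`, `in_repressor`, `in_unknown`, `out_activator`,
#'   `out_repressor`, `out_unknown`.
#' @export
degree_profile <- function(net) {
  stopifnot(inherits(net, "regnet"))
  genes <- net$genes
  signs <- c("activator", "repressor", "unknown")
  prof <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (s in signs) {
    e <- net$edges[net$edges$sign == s, , drop = FALSE]
    prof[[paste0("in_", s)]] <- as.integer(table(factor(e$target, levels = genes)))
    prof[[paste0("out_", s)]] <- as.integer(table(factor(e$source, levels = genes)))
  }
  rownames(prof) <- NULL
  prof
}
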