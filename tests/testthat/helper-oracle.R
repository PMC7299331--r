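# Independent oracles used across test files.

# Random signed digraph: each ordered pair (self-loops allowed) is an edge
# with probability p, with a sign drawn from `signs`.
random_signed_net <- function(n_nodes, p = 0.25,
                              signs = c("activator", "repressor", "unknown")) {
  genes <- paste0("g", seq_len(n_nodes))
  pairs <- expand.grid(source = genes, target = genes,
                       stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(pairs)) < p
  e <- pairs[keep, , drop = FALSE]
  e$sign <- sample(signs, nrow(e), replace = TRUE)
  regnet(e, genes = genes)
}

# Brute-force fiber partition: group genes by pairwise input-tree isomorphism
# at depth = number of genes (canonical-form comparison). Independent of the
# refinement algorithm.
oracle_fiber_groups <- function(net) {
  depth <- max(length(net$genes), 2)
  canons <- vapply(net$genes, function(g) {
    input_tree(net, g, depth, build_canon = TRUE)$canon
  }, character(1))
  unname(split(net$genes, match(canons, unique(canons))))
}

as_partition_key <- function(groups) {
  paste(sort(vapply(groups, function(g) paste(sort(g), collapse = ","),
                    character(1))), collapse = ";")
}

# Brute-force pattern matchers: enumerate every injective role assignment and
# keep those realizing the required signed adjacency. De-duplication mirrors
# the documented conventions (unordered replica pair + unordered input set).
oracle_edge_ok <- function(net, src, tgt, sign = NULL) {
  hit <- net$edges$source == src & net$edges$target == tgt
  if (!any(hit)) return(FALSE)
  is.null(sign) || net$edges$sign[hit][1] == sign
}

oracle_sr <- function(net) {
  g <- net$genes
  keys <- character(0)
  if (length(g) < 4) return(keys)
  for (y in g) for (yp in g) {
    if (y >= yp) next
    if (!oracle_edge_ok(net, y, yp, "repressor")) next
    if (!oracle_edge_ok(net, yp, y, "repressor")) next
    for (s in setdiff(g, c(y, yp))) for (r in setdiff(g, c(y, yp, s))) {
      if (oracle_edge_ok(net, s, y) && oracle_edge_ok(net, r, yp)) {
        keys <- c(keys, paste(y, yp, paste(sort(c(s, r)), collapse = "+")))
      }
    }
  }
  sort(unique(keys))
}

oracle_clocked_sr <- function(net) {
  g <- net$genes
  keys <- character(0)
  if (length(g) < 7) return(keys)
  for (y in g) for (yp in g) {
    if (y >= yp) next
    if (!oracle_edge_ok(net, y, yp, "repressor") ||
        !oracle_edge_ok(net, yp, y, "repressor")) next
    rest0 <- setdiff(g, c(y, yp))
    for (x in rest0) for (xp in setdiff(rest0, x)) {
      if (!oracle_edge_ok(net, x, y) || !oracle_edge_ok(net, xp, yp)) next
      for (clk in setdiff(rest0, c(x, xp))) {
        if (!oracle_edge_ok(net, clk, x) || !oracle_edge_ok(net, clk, xp)) next
        for (s in setdiff(rest0, c(x, xp, clk))) {
          for (r in setdiff(rest0, c(x, xp, clk, s))) {
            if (oracle_edge_ok(net, s, x) && oracle_edge_ok(net, r, xp)) {
              keys <- c(keys, paste(y, yp, x, xp, clk,
                                    paste(sort(c(s, r)), collapse = "+")))
            }
          }
        }
      }
    }
  }
  sort(unique(keys))
}

oracle_jk <- function(net, chiral = FALSE) {
  g <- net$genes
  keys <- character(0)
  if (length(g) < 6) return(keys)
  variants <- if (chiral) c("parity", "chiral") else "parity"
  for (y in g) for (yp in g) {
    if (y >= yp) next
    if (!oracle_edge_ok(net, y, yp, "repressor") ||
        !oracle_edge_ok(net, yp, y, "repressor")) next
    rest0 <- setdiff(g, c(y, yp))
    for (x in rest0) for (xp in setdiff(rest0, x)) {
      if (!oracle_edge_ok(net, x, y) || !oracle_edge_ok(net, xp, yp)) next
      for (v in variants) {
        ok <- if (v == "parity") {
          oracle_edge_ok(net, y, xp) && oracle_edge_ok(net, yp, x)
        } else {
          oracle_edge_ok(net, y, x) && oracle_edge_ok(net, yp, xp)
        }
        if (!ok) next
        for (j in setdiff(rest0, c(x, xp))) {
          for (k in setdiff(rest0, c(x, xp, j))) {
            if (oracle_edge_ok(net, j, x) && oracle_edge_ok(net, k, xp)) {
              keys <- c(keys, paste(v, y, yp, x, xp,
                                    paste(sort(c(j, k)), collapse = "+")))
            }
          }
        }
      }
    }
  }
  sort(unique(keys))
}

# canonical keys of the package finders, for comparison with the oracles
match_key_sr <- function(m) {
  r <- m$roles
  paste(min(r["Y"], r["Yp"]), max(r["Y"], r["Yp"]),
        paste(sort(c(r["S"], r["R"])), collapse = "+"))
}
match_key_csr <- function(m) {
  r <- m$roles
  if (r["Y"] < r["Yp"]) {
    paste(r["Y"], r["Yp"], r["X"], r["Xp"], r["CLK"],
          paste(sort(c(r["S"], r["R"])), collapse = "+"))
  } else {
    paste(r["Yp"], r["Y"], r["Xp"], r["X"], r["CLK"],
          paste(sort(c(r["S"], r["R"])), collapse = "+"))
  }
}
match_key_jk <- function(m, variant = NULL) {
  r <- m$roles
  if (is.null(variant)) variant <- if (is.null(m$variant)) "parity" else m$variant
  if (r["Y"] < r["Yp"]) {
    paste(variant, r["Y"], r["Yp"], r["X"], r["Xp"],
          paste(sort(c(r["J"], r["K"])), collapse = "+"))
  } else {
    paste(variant, r["Yp"], r["Y"], r["Xp"], r["X"],
          paste(sort(c(r["J"], r["K"])), collapse = "+"))
  }
}
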