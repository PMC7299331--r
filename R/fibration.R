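#' Minimal balanced coloring (fibers) of a signed network
#'
#' Computes the coarsest balanced coloring: the partition in which two genes
#' share a class iff they receive identical multisets of (regulator class,
#' edge sign) over their in-edges. Classes of the coarsest balanced coloring
#' are the fibers of the graph fibration: genes with isomorphic input trees,
#' whose dynamics synchronize. Computed by iterative refinement from the
#' all-in-one partition; stabilizes in at most `n_genes` rounds.
#'
#' @param net a [regnet]. Edge signs (including `"unknown"`) are part of the
#'   balance condition.
#' @return an object of class `fiber_partition`: list with `coloring` (named
#'   integer vector gene -> fiber id), `fibers` (list fiber id -> gene
#'   vector), and `n_rounds` (refinement rounds used).
#' @examples
#' fp <- minimal_balanced_coloring(make_circuit("SAT_FFF"))
#' fp$fibers  # {X} and {Y, Z}
#' @export
minimal_balanced_coloring <- function(net) {
  stopifnot(inherits(net, "regnet"))
  genes <- net$genes
  n <- length(genes)
  if (n == 0) {
    return(structure(list(coloring = stats::setNames(integer(0), character(0)),
                          fibers = list(), n_rounds = 0L),
                     class = "fiber_partition"))
  }
  src_i <- match(net$edges$source, genes)
  tgt_i <- match(net$edges$target, genes)
  sgn <- net$edges$sign
  color <- rep(1L, n)
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    if (length(src_i) > 0) {
      lab <- paste0(color[src_i], "/", sgn)
      sig <- vapply(seq_len(n), function(i) {
        mine <- lab[tgt_i == i]
        if (length(mine) == 0) "" else paste(sort(mine), collapse = ",")
      }, character(1))
    } else {
      sig <- rep("", n)
    }
    key <- paste(color, sig, sep = "|")
    new_color <- match(key, unique(key))
    if (identical(new_color, color)) break
    color <- new_color
    if (rounds > n + 1L) stop("refinement failed to stabilize")  # cannot happen
  }
  coloring <- stats::setNames(as.integer(color), genes)
  structure(list(coloring = coloring,
                 fibers = split(genes, coloring),
                 n_rounds = rounds),
            class = "fiber_partition")
}

#' @export
print.fiber_partition <- function(x, ...) {
  sizes <- lengths(x$fibers)
  cat(sprintf("fiber_partition: %d fibers over %d genes (%d non-trivial)\n",
              length(x$fibers), length(x$coloring), sum(sizes > 1)))
  invisible(x)
}

# occurrence-count recursion: counts[t+1][h] = sum_g counts[t][g] * (#edges h->g)
input_layer_counts <- function(net, root, depth) {
  genes <- net$genes
  n <- length(genes)
  src_i <- match(net$edges$source, genes)
  tgt_i <- match(net$edges$target, genes)
  cnt <- numeric(n)
  cnt[match(root, genes)] <- 1
  Q <- numeric(depth)
  Q[1] <- 1
  layers <- vector("list", depth)
  layers[[1]] <- cnt
  if (depth > 1) {
    for (t in 2:depth) {
      nxt <- numeric(n)
      for (e in seq_along(src_i)) {
        nxt[src_i[e]] <- nxt[src_i[e]] + cnt[tgt_i[e]]
      }
      cnt <- nxt
      Q[t] <- sum(cnt)
      layers[[t]] <- cnt
    }
  }
  list(Q = Q, layer_counts = layers)
}

# canonical string of the depth-d truncated input tree rooted at gene i,
# memoized on (gene, depth); edge signs are part of the labels
input_tree_canon <- function(net, root, depth) {
  genes <- net$genes
  inx <- in_edges_index(net)
  memo <- new.env(parent = emptyenv())
  rec <- function(g, d) {
    key <- paste0(g, "\r", d)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (d == 1) {
      "."
    } else {
      ine <- inx[[g]]
      if (is.null(ine) || nrow(ine) == 0) {
        "."
      } else {
        kids <- vapply(seq_len(nrow(ine)), function(j) {
          paste0(substr(ine$sign[j], 1, 1), rec(ine$source[j], d - 1))
        }, character(1))
        paste0("(", paste(sort(kids), collapse = ""), ")")
      }
    }
    memo[[key]] <- val
    val
  }
  rec(root, depth)
}

#' Input tree of a gene
#'
#' The rooted tree of all reversed regulation paths into a gene: the root is
#' the gene itself (layer 1, Q_1 = 1), and layer t + 1 holds one node per
#' in-edge of each layer-t occurrence, labelled by the regulator gene and the
#' edge sign. Q_t is the number of nodes in layer t; its growth rate is the
#' branching ratio.
#'
#' Layer-occurrence counts are tracked per gene, so deep trees (whose explicit
#' node lists grow exponentially) remain cheap. The canonical form used by
#' [trees_isomorphic] is built only when `build_canon = TRUE`.
#'
#' @param net a [regnet].
#' @param root the root gene.
#' @param depth number of layers (>= 1).
#' @param build_canon build the canonical string for isomorphism testing
#'   (suitable for modest depths; memoized per gene x depth).
#' @return an object of class `input_tree`: list with `root`, `depth`, `Q`
#'   (numeric vector of layer sizes), `layer_counts` (per-layer named gene
#'   occurrence counts) and `canon` (canonical string or NULL).
#' @examples
#' fib <- regnet(data.frame(source = c("Y", "X", "Y"),
#'                          target = c("Y", "Y", "X"),
#'                          sign = "repressor"))
#' input_tree(fib, "Y", depth = 6)$Q  # 1 2 3 5 8 13
#' @export
input_tree <- function(net, root, depth, build_canon = FALSE) {
  stopifnot(inherits(net, "regnet"), depth >= 1)
  if (!root %in% net$genes) stop("unknown root gene: ", root)
  lc <- input_layer_counts(net, root, depth)
  layer_counts <- lapply(lc$layer_counts, function(v) {
    stats::setNames(v, net$genes)[v > 0]
  })
  canon <- if (build_canon) input_tree_canon(net, root, depth) else NULL
  structure(list(root = root, depth = depth, Q = lc$Q,
                 layer_counts = layer_counts, canon = canon),
            class = "input_tree")
}

#' @export
print.input_tree <- function(x, ...) {
  qshow <- utils::head(x$Q, 10)
  cat(sprintf("input_tree rooted at %s, depth %d; Q = %s%s\n", x$root, x$depth,
              paste(qshow, collapse = ", "),
              if (x$depth > 10) ", ..." else ""))
  invisible(x)
}

#' Test two input trees for isomorphism
#'
#' Rooted, sign-edge-labelled tree isomorphism by comparison of canonical
#' forms (order-independent recursive multiset encoding). Both trees must
#' have been built with `build_canon = TRUE` and equal depth.
#'
#' @param a,b `input_tree` objects.
#' @return logical.
#' @export
trees_isomorphic <- function(a, b) {
  stopifnot(inherits(a, "input_tree"), inherits(b, "input_tree"))
  if (a$depth != b$depth) stop("input trees have different depths")
  if (is.null(a$canon) || is.null(b$canon)) {
    stop("trees must be built with build_canon = TRUE")
  }
  identical(a$canon, b$canon)
}

#' Branching ratio of an input tree
#'
#' The finite-depth estimate Q_depth / Q_{depth-1} of the asymptotic
#' branching ratio n = lim Q_{t+1} / Q_t, the divergence measure that
#' classifies fiber complexity (1 for the autoregulation loop, the golden
#' ratio for Fibonacci fibers, 2 for the doubly autoregulated fiber).
#'
#' @param net a [regnet].
#' @param root root gene.
#' @param depth layers to build (default 40, which separates 1, phi and 2 far
#'   beyond 4-decimal reporting).
#' @return numeric estimate; 0 with attribute `died_out = TRUE` if the tree
#'   has no layer-(depth-1) nodes.
#' @export
branching_ratio <- function(net, root, depth = 40) {
  stopifnot(depth >= 2)
  Q <- input_tree(net, root, depth)$Q
  if (Q[depth - 1] == 0) {
    return(structure(0, died_out = TRUE))
  }
  structure(Q[depth] / Q[depth - 1], died_out = FALSE)
}

#' Quotient (base) graph of a balanced partition
#'
#' Collapses each fiber to one node. For each target fiber the number of
#' in-edges per member gene from each (source fiber, sign) is the same for
#' every member (that is what balance means); that count is the edge
#' multiplicity in the base.
#'
#' @param net a [regnet].
#' @param partition a `fiber_partition` balanced for `net`.
#' @param name_by `"representative"` (first member gene names the fiber node)
#'   or `"id"` (fiber ids).
#' @return list with `base` (a [regnet] over fiber nodes) and `multiplicity`
#'   (data frame source, target, sign, multiplicity).
#' @export
quotient_base <- function(net, partition, name_by = c("representative", "id")) {
  name_by <- match.arg(name_by)
  stopifnot(inherits(net, "regnet"), inherits(partition, "fiber_partition"))
  col <- partition$coloring
  stopifnot(setequal(names(col), net$genes))
  fid <- sort(unique(col))
  node_name <- if (name_by == "representative") {
    vapply(partition$fibers[as.character(fid)], `[[`, character(1), 1)
  } else paste0("fiber_", fid)
  names(node_name) <- fid

  # per-gene in-edge counts by (source fiber, sign); check balance
  mult <- NULL
  for (f in fid) {
    members <- partition$fibers[[as.character(f)]]
    per_gene <- lapply(members, function(g) {
      ine <- net$edges[net$edges$target == g, , drop = FALSE]
      if (nrow(ine) == 0) return(character(0))
      sort(paste(col[ine$source], ine$sign, sep = "|"))
    })
    if (length(unique(per_gene)) > 1) {
      stop("partition is not balanced: fiber ", f,
           " members have differing in-edge profiles")
    }
    counts <- table(per_gene[[1]])
    if (length(counts) > 0) {
      parts <- strsplit(names(counts), "|", fixed = TRUE)
      mult <- rbind(mult, data.frame(
        source = node_name[vapply(parts, `[[`, character(1), 1)],
        target = node_name[[as.character(f)]],
        sign = vapply(parts, `[[`, character(1), 2),
        multiplicity = as.integer(counts),
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(mult)) {
    mult <- data.frame(source = character(), target = character(),
                       sign = character(), multiplicity = integer(),
                       stringsAsFactors = FALSE)
  }
  rownames(mult) <- NULL
  # the base is in general a signed multigraph: one fiber may feed another
  # through edges of several signs, so the dual-sign check of regnet() does
  # not apply here
  base_edges <- mult[, c("source", "target", "sign")]
  rownames(base_edges) <- NULL
  base <- structure(list(genes = unname(node_name), edges = base_edges),
                    class = "regnet")
  list(base = base, multiplicity = mult)
}

golden_ratio <- (1 + sqrt(5)) / 2

#' Classify a fiber by branching ratio and external regulators
#'
#' Computes the number of distinct external regulator fibers ell feeding the
#' fiber, the branching ratio n of a member's input tree, and assigns the
#' circuit-class label used throughout: `"AR |1,0>"` (autoregulation loop
#' class), `"FFF |1,1>"` (feed-forward fiber), `"Fibonacci"` (n = golden
#' ratio; layer sizes obey Q_t = Q_{t-1} + Q_{t-2}), `"n = 2"` (doubly
#' autoregulated), or a generic `"|n, l>"` label.
#'
#' @param net a [regnet].
#' @param fiber character vector: the member genes (one class of `partition`).
#' @param partition the `fiber_partition` the fiber came from.
#' @param depth input-tree depth for the branching-ratio estimate.
#' @param tol absolute tolerance on n for the named classes.
#' @return an object of class `fiber_class`: list with `n`, `ell`, `loops`
#'   (list(m, d) for the named classes, NULL otherwise), `label` and `genes`.
#' @export
classify_fiber <- function(net, fiber, partition, depth = 40, tol = 1e-3) {
  stopifnot(inherits(net, "regnet"), inherits(partition, "fiber_partition"))
  col <- partition$coloring
  my_fid <- unique(col[fiber])
  stopifnot(length(my_fid) == 1)
  ine <- net$edges[net$edges$target %in% fiber, , drop = FALSE]
  ext_fids <- setdiff(unique(col[ine$source]), my_fid)
  ell <- length(ext_fids)
  n <- as.numeric(branching_ratio(net, fiber[1], depth = depth))
  has_self <- any(net$edges$source == net$edges$target &
                    net$edges$source %in% fiber)
  label <- if (abs(n - 1) < tol && ell == 0) {
    "AR |1,0>"
  } else if (abs(n - 1) < tol && ell == 1) {
    "FFF |1,1>"
  } else if (abs(n - golden_ratio) < tol) {
    "Fibonacci"
  } else if (abs(n - 2) < tol) {
    "n = 2"
  } else {
    sprintf("|n = %.4f, l = %d>", n, ell)
  }
  loops <- switch(label,
                  "AR |1,0>" = list(m = 0L, d = NA_integer_),
                  "FFF |1,1>" = list(m = 0L, d = NA_integer_),
                  "Fibonacci" = list(m = 1L, d = 2L),
                  "n = 2" = list(m = 0L, d = NA_integer_),
                  NULL)
  structure(list(n = n, ell = ell, loops = loops, label = label,
                 genes = fiber, has_self_loop = has_self),
            class = "fiber_class")
}

#' @export
print.fiber_class <- function(x, ...) {
  cat(sprintf("fiber_class %s: n = %.4f, l = %d, genes = {%s}\n",
              x$label, x$n, x$ell, paste(x$genes, collapse = ", ")))
  invisible(x)
}

#' Count unsatisfied interactions of a high/low state
#'
#' With production otherwise available (external drive high), an activator
#' edge is satisfied iff the target state equals the source state, and a
#' repressor edge is satisfied iff the target state is the opposite of the
#' source state. Frustration — a circuit with no fully satisfied state — is
#' what forces oscillation (the repressor autoregulator being the minimal
#' case).
#'
#' @param net a [regnet] with no unknown-sign edges.
#' @param state named logical (or "high"/"low" character) vector per gene.
#' @return integer: the number of unsatisfied edges.
#' @export
frustration_count <- function(net, state) {
  stopifnot(inherits(net, "regnet"))
  if (any(net$edges$sign == "unknown")) {
    stop("frustration counting requires fully signed edges")
  }
  if (is.character(state)) state <- state == "high"
  stopifnot(is.logical(state), setequal(names(state), net$genes))
  if (nrow(net$edges) == 0) return(0L)
  s_src <- state[net$edges$source]
  s_tgt <- state[net$edges$target]
  want <- ifelse(net$edges$sign == "activator", s_src, !s_src)
  sum(s_tgt != want)
}

#' Classify a circuit as satisfiable or frustrated
#'
#' Searches all high/low assignments (genes with no in-edges are pinned high,
#' playing the role of the external drive) for one with zero unsatisfied
#' interactions.
#'
#' @param net a [regnet] with at most `max_genes` free genes.
#' @param max_genes guard on the exhaustive 2^k search (default 20).
#' @return `"SAT"` or `"UNSAT"`.
#' @export
sat_classify <- function(net, max_genes = 20) {
  stopifnot(inherits(net, "regnet"))
  genes <- net$genes
  indeg <- table(factor(net$edges$target, levels = genes))
  pinned <- genes[indeg == 0]
  free <- genes[indeg > 0]
  if (length(free) > max_genes) {
    stop("too many genes for exhaustive SAT search (", length(free), ")")
  }
  base_state <- stats::setNames(rep(TRUE, length(genes)), genes)
  if (length(free) == 0) {
    return(if (frustration_count(net, base_state) == 0) "SAT" else "UNSAT")
  }
  for (m in 0:(2^length(free) - 1)) {
    st <- base_state
    st[free] <- bitwAnd(bitwShiftR(m, seq_along(free) - 1L), 1L) == 1L
    if (frustration_count(net, st) == 0) return("SAT")
  }
  "UNSAT"
}
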