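# edge lookup helpers shared by the pattern finders ------------------------

edge_key_set <- function(net) {
  stats::setNames(net$edges$sign, paste(net$edges$source, net$edges$target,
                                        sep = "\r"))
}

has_edge <- function(keys, src, tgt, sign = NULL) {
  s <- unname(keys[paste(src, tgt, sep = "\r")])
  if (is.na(s)) return(FALSE)
  is.null(sign) || s == sign
}

regulators_of <- function(net) {
  split(net$edges$source, factor(net$edges$target, levels = net$genes))
}

# unordered pairs {a, b} (a < b) with repressor edges both ways
mutual_repression_pairs <- function(net, keys = edge_key_set(net)) {
  rep_e <- net$edges[net$edges$sign == "repressor" &
                       net$edges$source != net$edges$target, , drop = FALSE]
  if (nrow(rep_e) == 0) return(list())
  cand <- rep_e[rep_e$source < rep_e$target, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(cand))) {
    a <- cand$source[i]; b <- cand$target[i]
    if (has_edge(keys, b, a, "repressor")) out[[length(out) + 1]] <- c(a, b)
  }
  out
}

new_match <- function(type, roles, edges_used, sat_state = NA_character_) {
  structure(list(circuit_type = type, roles = roles,
                 edges_used = edges_used, sat_state = sat_state),
            class = "circuit_match")
}

#' @export
print.circuit_match <- function(x, ...) {
  cat(sprintf("circuit_match %s: %s\n", x$circuit_type,
              paste(names(x$roles), x$roles, sep = "=", collapse = " ")))
  invisible(x)
}

match_edges <- function(net, keys, pairs) {
  # pairs: data.frame(source, target); recover signs from the network
  data.frame(source = pairs$source, target = pairs$target,
             sign = vapply(seq_len(nrow(pairs)), function(i) {
               keys[[paste(pairs$source[i], pairs$target[i], sep = "\r")]]
             }, character(1)),
             stringsAsFactors = FALSE)
}

#' Find symmetric fiber building blocks
#'
#' Runs [minimal_balanced_coloring] and classifies every non-trivial fiber
#' (size >= 2, or a singleton with a self-loop) with [classify_fiber].
#' Returns one match per fiber of the four named classes: autoregulation
#' fiber (`AR_fiber`, class |1,0>), feed-forward fiber (`FFF`, class |1,1>),
#' `Fibonacci` (branching ratio = golden ratio) and `n2_fiber` (branching
#' ratio 2). Counting one match per fiber mirrors the per-fiber counting of
#' circuit census tables.
#'
#' @param net a [regnet].
#' @param depth input-tree depth for branching ratios.
#' @return list of `circuit_match` objects. Roles: `Y` (first fiber member
#'   carrying an intra-fiber in-edge, else first member), `Z`/`Z2`/... (other
#'   members), `X`/`X2`/... (one representative gene per external regulator
#'   fiber). The `sat_state` field carries the SAT/UNSAT classification of
#'   the fiber plus its regulators when all involved edges are signed.
#' @export
find_fiber_blocks <- function(net, depth = 40) {
  part <- minimal_balanced_coloring(net)
  keys <- edge_key_set(net)
  out <- list()
  for (f in names(part$fibers)) {
    members <- part$fibers[[f]]
    has_self <- any(vapply(members, function(g) has_edge(keys, g, g), logical(1)))
    intra <- any(net$edges$source %in% members & net$edges$target %in% members)
    if (length(members) < 2 && !has_self) next
    cls <- classify_fiber(net, members, part, depth = depth)
    type <- switch(cls$label,
                   "AR |1,0>" = "AR_fiber",
                   "FFF |1,1>" = "FFF",
                   "Fibonacci" = "Fibonacci",
                   "n = 2" = "n2_fiber",
                   NA_character_)
    if (is.na(type)) next
    # roles: Y = member receiving an intra-fiber edge if any, rest Z,
    # one X per external regulator fiber
    recv_intra <- members[vapply(members, function(g) {
      any(net$edges$target == g & net$edges$source %in% members)
    }, logical(1))]
    y <- if (length(recv_intra) > 0) recv_intra[1] else members[1]
    zs <- setdiff(members, y)
    ine <- net$edges[net$edges$target %in% members, , drop = FALSE]
    ext_f <- setdiff(unique(part$coloring[ine$source]), part$coloring[[y]])
    xs <- vapply(as.character(ext_f), function(ff) part$fibers[[ff]][1],
                 character(1))
    roles <- c(stats::setNames(y, "Y"),
               if (length(zs) > 0) stats::setNames(zs, paste0("Z", ifelse(seq_along(zs) == 1, "", seq_along(zs)))),
               if (length(xs) > 0) stats::setNames(xs, paste0("X", ifelse(seq_along(xs) == 1, "", seq_along(xs)))))
    sub_genes <- unique(c(members, ine$source))
    sub_edges <- net$edges[net$edges$target %in% sub_genes &
                             net$edges$source %in% sub_genes, , drop = FALSE]
    sat <- if (all(sub_edges$sign != "unknown")) {
      sub <- regnet(sub_edges, genes = sub_genes)
      tryCatch(sat_classify(sub), error = function(e) NA_character_)
    } else NA_character_
    out[[length(out) + 1]] <- new_match(type, roles, ine, sat)
  }
  out
}

#' Find SR flip-flop (toggle switch) instances
#'
#' An SR flip-flop analogue is a mutually repressing pair Y -| Y', Y' -| Y
#' whose symmetry is broken by two distinct external inputs: S regulating Y
#' and R regulating Y' (any input sign, including unknown). Matches are
#' de-duplicated by the unordered replica pair plus the unordered input set,
#' so swapping the S/R labels does not create a second match.
#'
#' @param net a [regnet].
#' @return list of `circuit_match` objects with roles Y, Yp, S, R.
#' @export
find_sr_flipflops <- function(net) {
  keys <- edge_key_set(net)
  regs <- regulators_of(net)
  out <- list()
  seen <- character(0)
  for (pr in mutual_repression_pairs(net, keys)) {
    y <- pr[1]; yp <- pr[2]
    a <- setdiff(unique(regs[[y]]), c(y, yp))
    b <- setdiff(unique(regs[[yp]]), c(y, yp))
    for (s in a) for (r in b) {
      if (s == r) next
      key <- paste(y, yp, paste(sort(c(s, r)), collapse = "\r"), sep = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      eu <- match_edges(net, keys, data.frame(
        source = c(y, yp, s, r), target = c(yp, y, y, yp),
        stringsAsFactors = FALSE))
      out[[length(out) + 1]] <-
        new_match("SR_flipflop", c(Y = y, Yp = yp, S = s, R = r), eu)
    }
  }
  out
}

#' Find clocked SR flip-flop instances
#'
#' The clocked variant adds an input layer to the toggle pair: X regulates Y
#' and X' regulates Y', a clock gene CLK regulates both X and X', and the
#' symmetry is broken by distinct inputs S (on X) and R (on X'). All seven
#' roles must be distinct genes; the mutual repression must be repressor,
#' other edges may carry any sign. De-duplicated by the replica pairs, the
#' clock, and the unordered input set.
#'
#' @param net a [regnet].
#' @return list of `circuit_match` objects with roles Y, Yp, X, Xp, CLK, S, R.
#' @export
find_clocked_sr_flipflops <- function(net) {
  keys <- edge_key_set(net)
  regs <- regulators_of(net)
  out <- list()
  seen <- character(0)
  for (pr in mutual_repression_pairs(net, keys)) {
    y <- pr[1]; yp <- pr[2]
    for (x in setdiff(unique(regs[[y]]), c(y, yp))) {
      for (xp in setdiff(unique(regs[[yp]]), c(y, yp, x))) {
        clks <- setdiff(intersect(unique(regs[[x]]), unique(regs[[xp]])),
                        c(y, yp, x, xp))
        for (clk in clks) {
          ss <- setdiff(unique(regs[[x]]), c(y, yp, x, xp, clk))
          rr <- setdiff(unique(regs[[xp]]), c(y, yp, x, xp, clk))
          for (s in ss) for (r in rr) {
            if (s == r) next
            key <- paste(y, yp, x, xp, clk,
                         paste(sort(c(s, r)), collapse = "\r"), sep = "\r")
            if (key %in% seen) next
            seen <- c(seen, key)
            eu <- match_edges(net, keys, data.frame(
              source = c(y, yp, x, xp, clk, clk, s, r),
              target = c(yp, y, y, yp, x, xp, x, xp),
              stringsAsFactors = FALSE))
            out[[length(out) + 1]] <-
              new_match("ClockedSR_flipflop",
                        c(Y = y, Yp = yp, X = x, Xp = xp, CLK = clk,
                          S = s, R = r), eu)
          }
        }
      }
    }
  }
  out
}

#' Find JK flip-flop instances
#'
#' The JK analogue arises from replica duplication of the Fibonacci fiber:
#' a toggle pair Y -| Y', an input layer X regulating Y and X' regulating Y',
#' parity feedback (Y regulates X' and Y' regulates X — the left-right
#' reflection realized in biological circuits), and distinct inputs J (on X)
#' and K (on X'). The chiral wiring (Y regulates X, Y' regulates X') is
#' matched only when `chiral = TRUE`. All six roles distinct; mutual
#' repression must be repressor, other edges any sign.
#'
#' @param net a [regnet].
#' @param chiral also match the chiral feedback variant (default FALSE:
#'   parity only).
#' @return list of `circuit_match` objects with roles Y, Yp, X, Xp, J, K.
#' @export
find_jk_flipflops <- function(net, chiral = FALSE) {
  keys <- edge_key_set(net)
  regs <- regulators_of(net)
  variants <- if (chiral) c("parity", "chiral") else "parity"
  out <- list()
  seen <- character(0)
  for (pr in mutual_repression_pairs(net, keys)) {
    y <- pr[1]; yp <- pr[2]
    for (x in setdiff(unique(regs[[y]]), c(y, yp))) {
      for (xp in setdiff(unique(regs[[yp]]), c(y, yp, x))) {
        for (variant in variants) {
          fb_ok <- if (variant == "parity") {
            has_edge(keys, y, xp) && has_edge(keys, yp, x)
          } else {
            has_edge(keys, y, x) && has_edge(keys, yp, xp)
          }
          if (!fb_ok) next
          jj <- setdiff(unique(regs[[x]]), c(y, yp, x, xp))
          kk <- setdiff(unique(regs[[xp]]), c(y, yp, x, xp))
          for (j in jj) for (k in kk) {
            if (j == k) next
            key <- paste(variant, y, yp, x, xp,
                         paste(sort(c(j, k)), collapse = "\r"), sep = "\r")
            if (key %in% seen) next
            seen <- c(seen, key)
            fb <- if (variant == "parity") {
              data.frame(source = c(y, yp), target = c(xp, x),
                         stringsAsFactors = FALSE)
            } else {
              data.frame(source = c(y, yp), target = c(x, xp),
                         stringsAsFactors = FALSE)
            }
            eu <- match_edges(net, keys, rbind(
              data.frame(source = c(y, yp, x, xp, j, k),
                         target = c(yp, y, y, yp, x, xp),
                         stringsAsFactors = FALSE), fb))
            m <- new_match("JK_flipflop",
                           c(Y = y, Yp = yp, X = x, Xp = xp, J = j, K = k), eu)
            m$variant <- variant
            out[[length(out) + 1]] <- m
          }
        }
      }
    }
  }
  out
}

#' Count circuit instances by type
#'
#' Convenience wrapper running the requested finders and returning one count
#' per circuit type, the observable the null-model Z-scores are computed on.
#'
#' @param net a [regnet].
#' @param types subset of `c("AR_fiber", "FFF", "Fibonacci", "n2_fiber",
#'   "SR_flipflop", "ClockedSR_flipflop", "JK_flipflop")`.
#' @param depth input-tree depth for the fiber classifier.
#' @return named integer vector of counts.
#' @export
circuit_counts <- function(net, types = c("AR_fiber", "FFF", "Fibonacci",
                                          "n2_fiber", "SR_flipflop",
                                          "ClockedSR_flipflop", "JK_flipflop"),
                           depth = 40) {
  types <- match.arg(types, several.ok = TRUE)
  counts <- stats::setNames(integer(length(types)), types)
  fiber_types <- intersect(types, c("AR_fiber", "FFF", "Fibonacci", "n2_fiber"))
  if (length(fiber_types) > 0) {
    fb <- find_fiber_blocks(net, depth = depth)
    for (m in fb) {
      if (m$circuit_type %in% fiber_types) {
        counts[m$circuit_type] <- counts[m$circuit_type] + 1L
      }
    }
  }
  if ("SR_flipflop" %in% types) {
    counts["SR_flipflop"] <- length(find_sr_flipflops(net))
  }
  if ("ClockedSR_flipflop" %in% types) {
    counts["ClockedSR_flipflop"] <- length(find_clocked_sr_flipflops(net))
  }
  if ("JK_flipflop" %in% types) {
    counts["JK_flipflop"] <- length(find_jk_flipflops(net))
  }
  counts
}
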