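#' Canonical threshold circuits
#'
#' Builds the canonical circuit topologies used throughout: the coherent
#' feed-forward loop (FFL), its symmetrized satisfied and frustrated
#' feed-forward fibers (SAT-FFF / UNSAT-FFF), the autoregulation loop (AR),
#' the Fibonacci fiber, the doubly autoregulated n = 2 fiber, and the
#' broken-symmetry memory circuits (SR, clocked SR, JK flip-flop analogues).
#' Gene names carry the conventional roles (X, Y, Z, Yp, S, R, J, K, CLK).
#'
#' Topologies:
#' \itemize{
#'   \item `FFL`: X->Y, X->Z, Y->Z, all activator.
#'   \item `SAT_FFF`: FFL plus activator autoregulation Y->Y.
#'   \item `UNSAT_FFF`: X->Y, X->Z activator; Y-|Y, Y-|Z repressor.
#'   \item `AR`: a single gene Y with a self-loop (repressor by default).
#'   \item `Fibonacci`: the feed-forward fiber plus feedback to the
#'     regulator — X->Y, X->Z, Y->Y, Y->Z, Y->X — all repressor by default
#'     (the uxuR/exuR/lgoR wiring). The fiber is \{Y, Z\}; X stays outside
#'     the base.
#'   \item `n2`: self-loops on X and Y plus mutual X->Y, Y->X, and output
#'     Y->Z (activator by default).
#'   \item `SR`: mutual repression Y-|Yp, Yp-|Y with distinct inputs S->Y,
#'     R->Yp.
#'   \item `ClockedSR`: mutual repression Y-|Yp plus input layer X->Y,
#'     Xp->Yp, clock CLK->X, CLK->Xp, and inputs S->X, R->Xp.
#'   \item `JK`: mutual repression Y-|Yp, input layer X->Y, Xp->Yp, parity
#'     feedback Y->Xp, Yp->X, and inputs J->X, K->Xp.
#' }
#'
#' @param type circuit type, one of `"FFL"`, `"SAT_FFF"`, `"UNSAT_FFF"`,
#'   `"AR"`, `"Fibonacci"`, `"n2"`, `"SR"`, `"ClockedSR"`, `"JK"`.
#' @param sign default sign for edges whose sign the class does not pin down
#'   (self-loop of `AR`; all edges of `Fibonacci`/`n2`; input and X-layer
#'   edges of the flip-flops). Mutual-repression core edges are always
#'   repressor.
#' @param prefix optional prefix prepended to every gene name (used when
#'   planting many instances).
#' @return a [regnet].
#' @export
make_circuit <- function(type = c("FFL", "SAT_FFF", "UNSAT_FFF", "AR",
                                  "Fibonacci", "n2", "SR", "ClockedSR", "JK"),
                         sign = NULL, prefix = "") {
  type <- match.arg(type)
  act <- "activator"; rep_ <- "repressor"
  e <- function(src, tgt, sgn) {
    data.frame(source = src, target = tgt, sign = sgn, stringsAsFactors = FALSE)
  }
  edges <- switch(type,
    FFL = e(c("X", "X", "Y"), c("Y", "Z", "Z"), act),
    SAT_FFF = e(c("X", "X", "Y", "Y"), c("Y", "Z", "Z", "Y"), act),
    UNSAT_FFF = rbind(e(c("X", "X"), c("Y", "Z"), act),
                      e(c("Y", "Y"), c("Y", "Z"), rep_)),
    AR = e("Y", "Y", if (is.null(sign)) rep_ else sign),
    Fibonacci = e(c("X", "X", "Y", "Y", "Y"), c("Y", "Z", "Y", "Z", "X"),
                  if (is.null(sign)) rep_ else sign),
    n2 = e(c("X", "Y", "X", "Y", "Y"), c("X", "Y", "Y", "X", "Z"),
           if (is.null(sign)) act else sign),
    SR = rbind(e(c("Y", "Yp"), c("Yp", "Y"), rep_),
               e(c("S", "R"), c("Y", "Yp"), if (is.null(sign)) act else sign)),
    ClockedSR = rbind(e(c("Y", "Yp"), c("Yp", "Y"), rep_),
                      e(c("X", "Xp", "CLK", "CLK", "S", "R"),
                        c("Y", "Yp", "X", "Xp", "X", "Xp"),
                        if (is.null(sign)) act else sign)),
    JK = rbind(e(c("Y", "Yp"), c("Yp", "Y"), rep_),
               e(c("X", "Xp", "Y", "Yp", "J", "K"),
                 c("Y", "Yp", "Xp", "X", "X", "Xp"),
                 if (is.null(sign)) act else sign)))
  if (nzchar(prefix)) {
    edges$source <- paste0(prefix, edges$source)
    edges$target <- paste0(prefix, edges$target)
  }
  regnet(edges)
}

# core genes whose in-edges must not be touched by background wiring; for
# fiber circuits that is every gene, for flip-flops the whole role set
circuit_core_genes <- function(type, prefix = "") {
  roles <- switch(type,
    FFL = c("X", "Y", "Z"),
    SAT_FFF = c("X", "Y", "Z"),
    UNSAT_FFF = c("X", "Y", "Z"),
    AR = "Y",
    Fibonacci = c("X", "Y", "Z"),
    n2 = c("X", "Y", "Z"),
    SR = c("Y", "Yp", "S", "R"),
    ClockedSR = c("Y", "Yp", "X", "Xp", "CLK", "S", "R"),
    JK = c("Y", "Yp", "X", "Xp", "J", "K"))
  paste0(prefix, roles)
}

#' Plant known circuits in a random background network
#'
#' Builds a synthetic network hosting node-disjoint copies of the requested
#' canonical circuits plus random background edges. Background edges never
#' target a circuit gene (so planted in-trees, hence planted fibers and
#' pattern matches, survive by construction); they may originate anywhere.
#' Background self-loops are not drawn, keeping accidental autoregulation
#' fibers out of the background. Deterministic given `seed`.
#'
#' @param counts named integer vector, e.g. `c(SR = 3, SAT_FFF = 2)`; names
#'   are [make_circuit] types.
#' @param n_background number of background genes.
#' @param n_edges named vector of background edge counts per sign, e.g.
#'   `c(activator = 200, repressor = 100)` (default ratio 2:1 over a total of
#'   about 1.5 edges per background gene).
#' @param seed integer seed.
#' @return an object of class `planted_network`: list with `network` (a
#'   [regnet]), `ground_truth` (list of planted instances, each with
#'   `circuit_type` and `roles`), and `background_spec`.
#' @export
embed_circuits <- function(counts, n_background = 200, n_edges = NULL,
                           seed = 1) {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  if (is.null(n_edges)) {
    total <- round(1.5 * n_background)
    n_edges <- c(activator = round(2 * total / 3),
                 repressor = total - round(2 * total / 3))
  }
  local_seed(seed)
  type_map <- c(FFL = "FFL", SAT_FFF = "FFF", UNSAT_FFF = "FFF",
                AR = "AR_fiber", Fibonacci = "Fibonacci", n2 = "n2_fiber",
                SR = "SR_flipflop", ClockedSR = "ClockedSR_flipflop",
                JK = "JK_flipflop")
  edges <- NULL
  truth <- list()
  core <- character(0)
  idx <- 0
  for (ty in names(counts)) {
    for (i in seq_len(counts[[ty]])) {
      idx <- idx + 1
      prefix <- sprintf("c%d_", idx)
      circ <- make_circuit(ty, prefix = prefix)
      edges <- rbind(edges, circ$edges)
      roles <- stats::setNames(circ$genes,
                               sub(prefix, "", circ$genes, fixed = TRUE))
      truth[[idx]] <- list(circuit_type = unname(type_map[ty]),
                           make_type = ty, roles = roles)
      core <- c(core, circuit_core_genes(ty, prefix))
    }
  }
  bg <- sprintf("bg%03d", seq_len(n_background))
  all_genes <- c(unique(c(edges$source, edges$target)), bg)
  if (n_background < 1 && sum(n_edges) > 0) {
    stop("background has no genes to host edges")
  }
  existing <- paste(edges$source, edges$target)
  for (s in names(n_edges)) {
    placed <- 0
    guard <- 0
    while (placed < n_edges[[s]]) {
      guard <- guard + 1
      if (guard > 50 * sum(n_edges)) stop("cannot place requested background edges")
      src <- sample(all_genes, 1)
      tgt <- sample(bg, 1)
      if (src == tgt) next
      key <- paste(src, tgt)
      if (key %in% existing) next
      existing <- c(existing, key)
      edges <- rbind(edges, data.frame(source = src, target = tgt, sign = s,
                                       stringsAsFactors = FALSE))
      placed <- placed + 1
    }
  }
  structure(list(network = regnet(edges, genes = all_genes),
                 ground_truth = truth,
                 background_spec = list(n_background = n_background,
                                        n_edges = n_edges, seed = seed)),
            class = "planted_network")
}

#' @export
print.planted_network <- function(x, ...) {
  cat(sprintf("planted_network: %d planted circuits in %d genes / %d edges\n",
              length(x$ground_truth), n_genes(x$network), n_edges(x$network)))
  invisible(x)
}
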