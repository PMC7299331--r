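# Seed the RNG for the duration of the calling function, restoring the
# caller's RNG state on exit. Keeps package randomness reproducible without
# clobbering the user's stream.
local_seed <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  restore <- if (is.null(old)) {
    quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  } else {
    bquote(assign(".Random.seed", .(old), globalenv()))
  }
  do.call(on.exit, list(restore, add = TRUE), envir = env)
  set.seed(seed)
  invisible(seed)
}

# Z-score of an observed count against replicate counts, with the census
# conventions: NA when the observed count is 0; 0 when the replicates have no
# spread and equal the observed count; +/- Inf when they have no spread and
# differ, displayed as the bound form "> 3" when in addition the null mean is
# 0. The sd uses the population (divide-by-n) convention.
null_z <- function(n_real, counts) {
  mu <- mean(counts)
  sdv <- sqrt(mean((counts - mu)^2))
  if (n_real == 0) {
    z <- NA_real_; disp <- "N/A"
  } else if (sdv > 0) {
    z <- (n_real - mu) / sdv
    disp <- formatC(z, digits = 4, format = "fg")
  } else if (n_real == mu) {
    z <- 0; disp <- "0"
  } else if (n_real > mu) {
    z <- Inf
    disp <- if (mu == 0) "> 3" else "Inf"
  } else {
    z <- -Inf; disp <- "-Inf"
  }
  list(mean = mu, sd = sdv, z = z, display = disp)
}

#' Degree- and sign-preserving randomization
#'
#' Repeated double-edge swaps within each sign class: two edges (a -> b) and
#' (c -> d) of the same sign are rewired to (a -> d) and (c -> b). A proposal
#' is rejected if it would duplicate an existing ordered pair, or (by
#' default) create or destroy a self-loop — autoregulation is structurally
#' meaningful here, so self-loops form their own invariant class. Every
#' gene's in- and out-degree per sign is exactly preserved, as is the gene
#' set and edge count. Deterministic given `seed`.
#'
#' @param net a [regnet].
#' @param n_swaps attempted swaps; default 10 x edge count, a standard mixing
#'   heuristic.
#' @param seed integer seed.
#' @param preserve_self_loops keep self-loops fixed (default TRUE).
#' @return a randomized [regnet].
#' @export
randomize_network <- function(net, n_swaps = 10 * n_edges(net), seed = 1,
                              preserve_self_loops = TRUE) {
  stopifnot(inherits(net, "regnet"), n_swaps >= 0)
  edges <- net$edges
  if (nrow(edges) < 2 || n_swaps == 0) {
    return(regnet(edges, genes = net$genes))
  }
  local_seed(seed)
  occupied <- new.env(parent = emptyenv())
  for (k in paste(edges$source, edges$target, sep = "\r")) occupied[[k]] <- TRUE
  is_self <- edges$source == edges$target
  by_sign <- split(seq_len(nrow(edges)),
                   factor(edges$sign, levels = unique(edges$sign)))
  for (sw in seq_len(n_swaps)) {
    sgn <- sample(names(by_sign), 1)
    pool <- by_sign[[sgn]]
    if (preserve_self_loops) pool <- pool[!is_self[pool]]
    if (length(pool) < 2) next
    ij <- sample(pool, 2)
    i <- ij[1]; j <- ij[2]
    a <- edges$source[i]; b <- edges$target[i]
    c_ <- edges$source[j]; d <- edges$target[j]
    if (b == d || a == c_) next                    # swap would be a no-op/dup
    if (a == d || c_ == b) next                    # would create a self-loop
    k1 <- paste(a, d, sep = "\r"); k2 <- paste(c_, b, sep = "\r")
    if (!is.null(occupied[[k1]]) || !is.null(occupied[[k2]])) next
    rm(list = c(paste(a, b, sep = "\r"), paste(c_, d, sep = "\r")),
       envir = occupied)
    occupied[[k1]] <- TRUE; occupied[[k2]] <- TRUE
    edges$target[i] <- d
    edges$target[j] <- b
  }
  regnet(edges, genes = net$genes)
}

#' Z-scores of circuit counts against the degree-preserving null
#'
#' Counts the requested circuit types in the observed network and in
#' `n_replicates` randomizations ([randomize_network]), and reports the
#' Z-score (N_real - mean) / sd with the census-table conventions:
#' Z is NA when N_real = 0; when the replicate counts have zero spread,
#' Z is 0 if N_real equals the replicate count, otherwise +/- Inf (the
#' display column shows the bound form "> 3" when in addition the null mean
#' is 0). The standard deviation uses the population (divide-by-n)
#' convention. Fully reproducible given (`seed`, `n_replicates`, `n_swaps`).
#'
#' @param net a [regnet].
#' @param types circuit types, as in [circuit_counts].
#' @param n_replicates number of randomized replicates (>= 2; census-scale
#'   runs use 1000, small tests 50).
#' @param n_swaps swap attempts per replicate (default 10 x edge count).
#' @param seed integer seed; replicate r uses seed + r.
#' @param depth input-tree depth for the fiber classifier.
#' @return a data frame of class `null_stats` with columns `circuit_type`,
#'   `n_real`, `n_rand_mean`, `n_rand_sd`, `z`, `z_display`, `n_replicates`,
#'   `n_swaps`, `seed`.
#' @export
zscores <- function(net, types = c("AR_fiber", "FFF", "Fibonacci", "n2_fiber",
                                   "SR_flipflop", "ClockedSR_flipflop",
                                   "JK_flipflop"),
                    n_replicates = 1000, n_swaps = 10 * n_edges(net),
                    seed = 1, depth = 40) {
  stopifnot(n_replicates >= 2)
  types <- match.arg(types, several.ok = TRUE)
  real <- circuit_counts(net, types, depth = depth)
  rand <- matrix(0L, nrow = n_replicates, ncol = length(types),
                 dimnames = list(NULL, types))
  for (r in seq_len(n_replicates)) {
    rn <- randomize_network(net, n_swaps = n_swaps, seed = seed + r)
    rand[r, ] <- circuit_counts(rn, types, depth = depth)
  }
  stats <- lapply(seq_along(types), function(i) null_z(real[i], rand[, i]))
  out <- data.frame(circuit_type = types,
                    n_real = as.integer(real),
                    n_rand_mean = vapply(stats, `[[`, numeric(1), "mean"),
                    n_rand_sd = vapply(stats, `[[`, numeric(1), "sd"),
                    z = vapply(stats, `[[`, numeric(1), "z"),
                    z_display = vapply(stats, `[[`, character(1), "display"),
                    n_replicates = n_replicates,
                    n_swaps = n_swaps,
                    seed = seed,
                    stringsAsFactors = FALSE)
  class(out) <- c("null_stats", "data.frame")
  out
}
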