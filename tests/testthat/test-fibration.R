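test_that("canonical circuits produce the expected fibers", {
  # FFL: no symmetry, three singleton fibers
  expect_equal(lengths(minimal_balanced_coloring(make_circuit("FFL"))$fibers),
               c(`1` = 1, `2` = 1, `3` = 1), ignore_attr = TRUE)
  # SAT-FFF: {X} and {Y, Z}
  fp <- minimal_balanced_coloring(make_circuit("SAT_FFF"))
  groups <- unname(lapply(fp$fibers, sort))
  expect_true(list(c("Y", "Z")) %in% groups)
  expect_true(list("X") %in% groups)
  # edgeless network: one fiber holding everything
  iso <- regnet(genes = letters[1:5])
  expect_equal(lengths(minimal_balanced_coloring(iso)$fibers),
               c(`1` = 5), ignore_attr = TRUE)
})

test_that("edge signs split fibers", {
  # Y and Z receive from X with different signs: not symmetric
  net <- regnet(data.frame(source = c("X", "X"), target = c("Y", "Z"),
                           sign = c("activator", "repressor")))
  expect_equal(length(minimal_balanced_coloring(net)$fibers), 3)
  # same signs: symmetric
  net2 <- regnet(data.frame(source = c("X", "X"), target = c("Y", "Z"),
                            sign = "repressor"))
  expect_equal(length(minimal_balanced_coloring(net2)$fibers), 2)
  # unknown is a third type, distinct from both
  net3 <- regnet(data.frame(source = c("X", "X"), target = c("Y", "Z"),
                            sign = c("unknown", "repressor")))
  expect_equal(length(minimal_balanced_coloring(net3)$fibers), 3)
})

test_that("input trees carry the canonical layer-count sequences", {
  # AR loop: Q identically 1
  ar <- make_circuit("AR")
  expect_equal(input_tree(ar, "Y", 10)$Q, rep(1, 10))
  # Fibonacci base rooted at Y: 1, 2, 3, 5, 8, ...
  fib <- regnet(data.frame(source = c("Y", "X", "Y"),
                           target = c("Y", "Y", "X"), sign = "repressor"))
  expect_equal(input_tree(fib, "Y", 8)$Q, c(1, 2, 3, 5, 8, 13, 21, 34))
  # no in-edges: the tree dies after the root
  chain <- regnet(data.frame(source = "A", target = "B", sign = "activator"))
  expect_equal(input_tree(chain, "A", 4)$Q, c(1, 0, 0, 0))
  expect_error(input_tree(chain, "nope", 3), "unknown root")
})

test_that("branching ratios separate the fiber hierarchy", {
  ar <- make_circuit("AR")
  expect_equal(round(as.numeric(branching_ratio(ar, "Y", 20)), 4), 1.0000)
  fib <- regnet(data.frame(source = c("Y", "X", "Y"),
                           target = c("Y", "Y", "X"), sign = "repressor"))
  expect_equal(round(as.numeric(branching_ratio(fib, "Y", 41)), 4), 1.6180)
  n2 <- regnet(data.frame(source = c("X", "Y", "X", "Y"),
                          target = c("X", "Y", "Y", "X"), sign = "activator"))
  expect_equal(round(as.numeric(branching_ratio(n2, "Y", 20)), 4), 2.0000)
  # dead tree: ratio 0 with a flag
  chain <- regnet(data.frame(source = "A", target = "B", sign = "activator"))
  br <- branching_ratio(chain, "A", 10)
  expect_equal(as.numeric(br), 0)
  expect_true(attr(br, "died_out"))
})

test_that("layer counts obey the generalized recurrence Q_t = n Q_{t-1} + m Q_{t-d}", {
  # AR: (n, m) = (1, 0); Fibonacci: (1, 1, d = 2); n2: (2, 0)
  ar_q <- input_tree(make_circuit("AR"), "Y", 12)$Q
  expect_equal(ar_q[3:12], ar_q[2:11])
  fib <- regnet(data.frame(source = c("Y", "X", "Y"),
                           target = c("Y", "Y", "X"), sign = "repressor"))
  fq <- input_tree(fib, "Y", 15)$Q
  expect_equal(fq[3:15], fq[2:14] + fq[1:13])
  n2 <- regnet(data.frame(source = c("X", "Y", "X", "Y"),
                          target = c("X", "Y", "Y", "X"), sign = "activator"))
  nq <- input_tree(n2, "Y", 15)$Q
  expect_equal(nq[2:15], 2 * nq[1:14])
})

test_that("input-tree isomorphism mirrors fiber membership on the FFF", {
  fff <- make_circuit("SAT_FFF")
  ty <- input_tree(fff, "Y", 3, build_canon = TRUE)
  tz <- input_tree(fff, "Z", 3, build_canon = TRUE)
  tx <- input_tree(fff, "X", 3, build_canon = TRUE)
  expect_true(trees_isomorphic(ty, tz))
  expect_false(trees_isomorphic(tx, ty))
  expect_true(trees_isomorphic(ty, ty))
  t2 <- input_tree(fff, "Y", 4, build_canon = TRUE)
  expect_error(trees_isomorphic(ty, t2), "different depths")
})

test_that("the quotient base collapses fibers with correct multiplicities", {
  fff <- make_circuit("SAT_FFF")
  q <- quotient_base(fff, minimal_balanced_coloring(fff))
  expect_equal(sort(q$base$genes), c("X", "Y"))
  expect_equal(nrow(q$base$edges), 2)
  expect_true(any(q$base$edges$source == "X" & q$base$edges$target == "Y"))
  expect_true(any(q$base$edges$source == "Y" & q$base$edges$target == "Y"))
  expect_equal(q$multiplicity$multiplicity, c(1, 1))

  # FFL: singleton partition leaves the network unchanged
  ffl <- make_circuit("FFL")
  q2 <- quotient_base(ffl, minimal_balanced_coloring(ffl))
  expect_true(q2$base == ffl)

  # unbalanced partition is rejected
  bad <- minimal_balanced_coloring(ffl)
  bad$coloring[] <- 1L
  bad$fibers <- split(names(bad$coloring), bad$coloring)
  expect_error(quotient_base(ffl, bad), "not balanced")
})

test_that("simulating the base reproduces the synchronized fiber trajectory", {
  for (type in c("SAT_FFF", "UNSAT_FFF")) {
    net <- make_circuit(type)
    spec <- dynamics_spec(alpha = 0.1, gamma = c(X = 0.5, Y = 0.5),
                          k = c(X = 0.5, Y = 0.4))
    tr <- simulate_network(net, spec, initial = c(Y = 0.3, Z = 0.3),
                           drive = list(X = drive_constant(1)), T = 200)
    base <- quotient_base(net, minimal_balanced_coloring(net))$base
    trb <- simulate_network(base, spec, initial = c(Y = 0.3),
                            drive = list(X = drive_constant(1)), T = 200)
    expect_equal(trb$levels[, "Y"], tr$levels[, "Y"], tolerance = 1e-12)
    expect_equal(trb$levels[, "Y"], tr$levels[, "Z"], tolerance = 1e-12)
  }
})

test_that("fiber classification assigns the |n, l> hierarchy labels", {
  # AR |1,0>
  ar <- make_circuit("AR")
  cls <- classify_fiber(ar, "Y", minimal_balanced_coloring(ar))
  expect_equal(cls$label, "AR |1,0>")
  expect_equal(cls$ell, 0)
  # FFF |1,1>
  fff <- make_circuit("SAT_FFF")
  fp <- minimal_balanced_coloring(fff)
  cls2 <- classify_fiber(fff, c("Y", "Z"), fp)
  expect_equal(cls2$label, "FFF |1,1>")
  expect_equal(cls2$ell, 1)
  expect_equal(cls2$n, 1, tolerance = 1e-6)
  # Fibonacci: golden-ratio branching, one loop of length 2
  fib <- make_circuit("Fibonacci")
  fpf <- minimal_balanced_coloring(fib)
  clsf <- classify_fiber(fib, c("Y", "Z"), fpf)
  expect_equal(clsf$label, "Fibonacci")
  expect_equal(clsf$n, (1 + sqrt(5)) / 2, tolerance = 1e-4)
  expect_equal(clsf$loops, list(m = 1L, d = 2L))
  # n = 2
  n2 <- make_circuit("n2")
  fpn <- minimal_balanced_coloring(n2)
  clsn <- classify_fiber(n2, c("X", "Y"), fpn)
  expect_equal(clsn$label, "n = 2")
})

test_that("frustration counting and SAT classification follow the sign rules", {
  uns <- make_circuit("UNSAT_FFF")
  all_high <- c(X = TRUE, Y = TRUE, Z = TRUE)
  expect_equal(frustration_count(uns, all_high), 2)  # Y -| Y and Y -| Z
  expect_equal(sat_classify(uns), "UNSAT")

  sat <- make_circuit("SAT_FFF")
  expect_equal(frustration_count(sat, all_high), 0)
  expect_equal(sat_classify(sat), "SAT")

  expect_equal(sat_classify(make_circuit("AR")), "UNSAT")  # repressor loop
  expect_equal(sat_classify(make_circuit("AR", sign = "activator")), "SAT")
  expect_equal(sat_classify(make_circuit("FFL")), "SAT")

  unk <- regnet(data.frame(source = "A", target = "B", sign = "unknown"))
  expect_error(frustration_count(unk, c(A = TRUE, B = TRUE)), "signed")
})

test_that("refinement stabilizes within |genes| rounds with monotone class counts", {
  set.seed(202)
  for (i in 1:25) {
    net <- random_signed_net(sample(3:10, 1), p = 0.3)
    fp <- minimal_balanced_coloring(net)
    expect_lte(fp$n_rounds, n_genes(net) + 1)
    # balanced: member in-signatures agree within every fiber (via quotient)
    expect_silent(quotient_base(net, fp))
  }
})

test_that("coloring classes coincide with input-tree isomorphism classes", {
  # exhaustive: every 2-node signed digraph (all three sign values)
  states2 <- c("none", "activator", "repressor", "unknown")
  grid2 <- expand.grid(aa = states2, ab = states2, ba = states2, bb = states2,
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid2))) {
    g <- grid2[i, ]
    src <- c("a", "a", "b", "b")[g != "none"]
    tgt <- c("a", "b", "a", "b")[g != "none"]
    sgn <- unlist(g[g != "none"])
    net <- regnet(if (length(src) > 0) {
      data.frame(source = src, target = tgt, sign = sgn,
                 stringsAsFactors = FALSE)
    } else NULL, genes = c("a", "b"))
    expect_equal(as_partition_key(unname(minimal_balanced_coloring(net)$fibers)),
                 as_partition_key(oracle_fiber_groups(net)))
  }

  # sampled: random 3-6-node graphs with all three signs
  set.seed(303)
  for (i in 1:100) {
    net <- random_signed_net(sample(3:6, 1), p = 0.3)
    expect_equal(as_partition_key(unname(minimal_balanced_coloring(net)$fibers)),
                 as_partition_key(oracle_fiber_groups(net)))
  }
})
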