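test_that("modularity matches hand-evaluated cases", {
  g <- toy_graph()
  # one big community: internal edge fraction and null term both equal 1
  expect_equal(modularity_q(g, setNames(rep(1, 6), paste0("v", 1:6))), 0)

  # the true two-module split of the toy graph
  expect_equal(modularity_q(g, toy_truth()), 0.25)

  # two triangles joined by a single bridge, split into the triangles
  tt <- graph_from_edges(c("a", "a", "b", "c", "d", "d", "e"),
                         c("b", "c", "c", "d", "e", "f", "f"))
  p <- as_partition(c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2))
  expect_equal(modularity_q(tt, p), 5 / 14)

  expect_error(
    modularity_q(graph_from_edges(character(0), character(0), nodes = "a"),
                 c(a = 1)),
    "edgeless")
})

test_that("modularity closed forms and igraph cross-check hold", {
  for (i in 1:12) {
    g <- random_gnp(12, 0.35, seed = 2400 + i)
    if (edge_count(g) == 0) next
    nodes <- igraph::V(g)$name
    m <- edge_count(g)
    deg <- igraph::degree(g)
    # all singletons: no internal edges, only the null-model penalty remains
    singles <- setNames(seq_along(nodes), nodes)
    expect_equal(modularity_q(g, singles), -sum(deg^2) / (2 * m)^2)
    # random partition agrees with the independent implementation
    p <- setNames(sample(1:4, length(nodes), replace = TRUE), nodes)
    cp <- as_partition(p)
    expect_equal(modularity_q(g, cp),
                 igraph::modularity(g, unclass(cp)[nodes] + 1L))
  }
})

test_that("pair F-measure matches enumeration and handles degeneracies", {
  truth <- as_partition(c(`1` = "a", `2` = "a", `3` = "b", `4` = "b"))
  pred <- as_partition(c(`1` = 1, `2` = 1, `3` = 1, `4` = 2))
  # S = {12,13,23}, T = {12,34}: precision 1/3, recall 1/2
  expect_equal(f_measure(pred, truth), 0.4)

  expect_equal(f_measure(truth, truth), 1)

  # no retrieved pairs at all
  singles <- as_partition(setNames(1:4, names(truth)))
  expect_equal(f_measure(singles, truth), 0)
  expect_equal(f_measure(singles, singles), 1)

  set.seed(20)
  for (i in 1:25) {
    x <- random_partition(8, 3, seed = 3100 + i)
    y <- random_partition(8, 4, seed = 3200 + i)
    expect_equal(f_measure(x, y), brute_f_measure(x, y))
  }
})

test_that("NMI matches hand cases, symmetry and the reference oracle", {
  x <- as_partition(c(`1` = 1, `2` = 1, `3` = 2, `4` = 2))
  y <- as_partition(c(`1` = 1, `2` = 2, `3` = 1, `4` = 2))
  expect_equal(nmi(x, y), 0)          # every contingency cell is 1
  expect_equal(nmi(x, x), 1)

  for (i in 1:40) {
    a <- random_partition(8, 4, seed = 4100 + i)
    b <- random_partition(8, 4, seed = 4200 + i)
    expect_equal(nmi(a, b), nmi(b, a))
    expect_equal(nmi(a, b), ref_nmi(a, b), tolerance = 1e-12)
    expect_gte(nmi(a, b), 0)
    expect_lte(nmi(a, b), 1 + 1e-12)
  }

  expect_error(nmi(x, as_partition(c(`9` = 1, `8` = 1))), "node set")
})

test_that("NMI degenerate conventions keep '1 iff identical' true", {
  one <- as_partition(c(a = 1, b = 1, c = 1))
  split3 <- as_partition(c(a = 1, b = 2, c = 2))
  expect_equal(nmi(one, one), 1)      # both trivial: identical
  expect_equal(nmi(one, split3), 0)   # exactly one trivial
  expect_equal(nmi(split3, one), 0)
})

test_that("all metrics are invariant under community relabeling", {
  g <- toy_graph()
  set.seed(77)
  for (i in 1:10) {
    p <- random_partition(6, 3, seed = 5000 + i)
    names(p) <- paste0("v", 1:6)          # align to the toy node set
    p <- as_partition(setNames(unclass(p), names(p)))
    shuffled <- as_partition(setNames(sample(10:90, 6)[unclass(p) + 1L],
                                      names(p)))
    expect_identical(p, shuffled)
    expect_equal(modularity_q(g, p), modularity_q(g, shuffled))
    expect_equal(nmi(p, toy_truth()), nmi(shuffled, toy_truth()))
    expect_equal(f_measure(p, toy_truth()), f_measure(shuffled, toy_truth()))
  }
})

test_that("NMI agrees with brute-force contingency on tiny partitions", {
  # exhaustive set partitions of 4 labeled nodes (Bell(4) = 15)
  nodes <- c("w", "x", "y", "z")
  parts <- list()
  gen <- function(assigned, rest) {
    if (!length(rest)) {
      parts[[length(parts) + 1L]] <<- assigned
      return(invisible())
    }
    v <- rest[1]
    for (b in seq_len(max(assigned) + 1L)) {
      gen(c(assigned, setNames(b, v)), rest[-1])
    }
  }
  gen(setNames(1L, nodes[1]), nodes[-1])
  expect_length(parts, 15)
  direct_nmi <- function(px, py) {
    ct <- table(px[nodes], py[nodes])
    n <- sum(ct)
    num <- 0
    for (r in seq_len(nrow(ct))) for (cc in seq_len(ncol(ct))) {
      if (ct[r, cc] > 0) {
        num <- num - 2 * ct[r, cc] *
          log(n * ct[r, cc] / (sum(ct[r, ]) * sum(ct[, cc])))
      }
    }
    den <- sum(rowSums(ct) * log(rowSums(ct) / n)) +
      sum(colSums(ct) * log(colSums(ct) / n))
    if (den == 0) 1 else num / den
  }
  for (px in parts) for (py in parts) {
    expect_equal(nmi(as_partition(px), as_partition(py)),
                 direct_nmi(px, py))
  }
})
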