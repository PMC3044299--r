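fig <- worked_example_fixture()

test_that("concept similarity follows the closed form", {
  h <- fig$hierarchy
  root <- "biological process"
  expect_equal(concept_similarity(h, root, root), 0)  # hc = 0 at the root
  expect_equal(concept_similarity(h, fig$t1, fig$t1),
               tanh(0.6 * concept_depth(h, fig$t1)))
  # worked-example pair: l = 2 + 1, common-ancestor depth 2
  expect_equal(concept_similarity(h, fig$t1, fig$t2),
               exp(-0.2 * 3) * tanh(0.6 * 2))
  expect_equal(concept_similarity(h, fig$t2, fig$t1),
               concept_similarity(h, fig$t1, fig$t2))
})

test_that("similarity is symmetric and in [0, 1] on random DAGs; disjoint
           concepts score 0", {
  set.seed(41)
  for (s in 1:8) {
    h <- random_dag(s)
    pair <- sample(h$ids, 2)
    s12 <- concept_similarity(h, pair[1], pair[2])
    expect_equal(concept_similarity(h, pair[2], pair[1]), s12)
    expect_gte(s12, 0); expect_lte(s12, 1)
  }
  h2 <- concept_hierarchy(
    data.frame(id = c("r1", "r2", "x", "y")),
    data.frame(child = c("x", "y"), parent = c("r1", "r2")))
  expect_equal(concept_similarity(h2, "x", "y"), 0)
})

test_that("weighted edge sets match the worked example and the
           path-enumeration oracle", {
  h <- fig$hierarchy
  expect_identical(nrow(weighted_edge_set(h, fig$t1, fig$t1)), 0L)
  e <- weighted_edge_set(h, fig$t1, fig$t2)
  expect_identical(nrow(e), 3L)  # the 2+1 paths through the common ancestor
  expect_setequal(map_keys(e), oracle_edge_set(h, fig$t1, fig$t2))

  set.seed(43)
  for (s in 1:12) {
    hr <- random_dag(s)
    pair <- sample(hr$ids, 2)
    expect_setequal(map_keys(weighted_edge_set(hr, pair[1], pair[2])),
                    oracle_edge_set(hr, pair[1], pair[2]))
  }
})

test_that("pair weights clamp at the floor when similarity saturates", {
  h <- fig$hierarchy
  # alpha = 0 and a steep beta drive S to 1 for concepts sharing a deep
  # ancestor, so every kept weight hits the eps floor
  ta <- weighted_concept_set(fig$t1)
  tl <- weighted_concept_set(fig$t2)
  m <- edge_weights_for_pair(h, ta, tl, alpha = 0, beta = 50, eps = 0.01)
  expect_true(nrow(m) > 0)
  expect_true(all(m$weight == 0.01))
})

test_that("conflicting candidates on a shared edge resolve to the minimum", {
  # t2 and t2b both route through the same child edge of the ancestor but
  # at different depths, so their similarities to t1 differ
  h <- concept_hierarchy(
    data.frame(id = c("r", "a", "t1", "mid", "t2", "t2b")),
    data.frame(child = c("a", "t1", "mid", "t2", "t2b"),
               parent = c("r", "a", "a", "mid", "t2")))
  ta <- weighted_concept_set("t1")
  tl <- weighted_concept_set(c("t2", "t2b"))
  s_near <- concept_similarity(h, "t1", "t2")
  s_far <- concept_similarity(h, "t1", "t2b")
  m <- edge_weights_for_pair(h, ta, tl)
  shared <- m$weight[m$child == "t1" & m$parent == "a"]
  expect_equal(shared, 1 - max(s_near, s_far))
})

test_that("pair weight maps equal the brute-force union/min oracle and are
           order-invariant", {
  set.seed(47)
  for (s in 1:8) {
    h <- random_dag(s)
    ta <- weighted_concept_set(sample(h$ids, 2))
    tl <- weighted_concept_set(sample(h$ids, 2))
    m <- edge_weights_for_pair(h, ta, tl)
    # oracle: every pair contributes 1 - S on its edge set; min per edge
    cand <- list()
    for (t1 in ta$id) for (t2 in tl$id) {
      keys <- oracle_edge_set(h, t1, t2)
      if (!length(keys)) next
      om <- min(max(1 - concept_similarity(h, t1, t2), 0.01), 1)
      for (k in keys) cand[[k]] <- min(c(cand[[k]], om))
    }
    expect_setequal(map_keys(m), names(cand))
    got <- stats::setNames(m$weight, map_keys(m))[names(cand)]
    expect_equal(unname(got), unname(unlist(cand)))
    # order of concepts within the sets is irrelevant
    m2 <- edge_weights_for_pair(h, ta[rev(seq_len(nrow(ta))), ],
                                tl[rev(seq_len(nrow(tl))), ])
    expect_equal(m2[order(map_keys(m2)), ]$weight,
                 m[order(map_keys(m)), ]$weight)
  }
})

test_that("AND keeps common edges, OR the union, both with the min rule", {
  m1 <- edge_weight_map(c("a", "b"), c("r", "r"), c(0.3, 0.5))
  m2 <- edge_weight_map(c("b", "c"), c("r", "r"), c(0.2, 0.9))
  expect_equal(combine_and(list(m1)), m1)
  expect_equal(combine_or(list(m1)), m1)

  a <- combine_and(list(m1, m2))
  expect_identical(map_keys(a), edge_key("b", "r"))
  expect_equal(a$weight, 0.2)

  o <- combine_or(list(m1, m2))
  expect_setequal(map_keys(o), c(edge_key("a", "r"), edge_key("b", "r"),
                                 edge_key("c", "r")))
  expect_equal(stats::setNames(o$weight, map_keys(o))[[edge_key("b", "r")]],
               0.2)
  # disjoint maps concatenate under OR, empty under AND
  m3 <- edge_weight_map("x", "y", 0.4)
  expect_identical(nrow(combine_and(list(m1, m3))), 0L)
  expect_identical(nrow(combine_or(list(m1, m3))), nrow(m1) + nrow(m3))
})

test_that("map combination matches set-algebra oracles; AND keys are a
           subset of OR keys; both are commutative and associative", {
  set.seed(53)
  for (rep in 1:8) {
    h <- random_dag(rep)
    maps <- lapply(1:3, function(i) random_weight_map(h, frac = 0.4))
    keysets <- lapply(maps, map_keys)
    and <- combine_and(maps); or <- combine_or(maps)
    expect_setequal(map_keys(and), Reduce(intersect, keysets))
    expect_setequal(map_keys(or), Reduce(union, keysets))
    expect_true(all(map_keys(and) %in% map_keys(or)))
    # element-wise minimum oracle
    allw <- do.call(rbind, lapply(maps, as.data.frame))
    allk <- edge_key(allw$child, allw$parent)
    for (k in map_keys(or)) {
      expect_equal(stats::setNames(or$weight, map_keys(or))[[k]],
                   min(allw$weight[allk == k]))
    }
    # commutativity / associativity
    perm <- maps[c(2, 3, 1)]
    reorder <- function(m) as.data.frame(m[order(map_keys(m)), ])
    expect_equal(reorder(combine_or(perm)), reorder(or),
                 ignore_attr = TRUE)
    expect_equal(reorder(combine_and(perm)), reorder(and),
                 ignore_attr = TRUE)
    nested <- combine_or(list(combine_or(maps[1:2]), maps[[3]]))
    expect_equal(reorder(nested), reorder(or), ignore_attr = TRUE)
  }
})

test_that("kept weights stay in [eps, 1] so reweighted relevance never
           drops below the unweighted value", {
  set.seed(59)
  for (s in 1:6) {
    h <- random_dag(s)
    ta <- weighted_concept_set(sample(h$ids, 2))
    tl <- weighted_concept_set(sample(h$ids, 2))
    m <- edge_weights_for_pair(h, ta, tl, eps = 0.01)
    if (nrow(m)) {
      expect_true(all(m$weight >= 0.01 & m$weight <= 1))
    }
    pair <- sample(h$ids, 2)
    expect_gte(concept_relevance(h, pair[1], pair[2], m),
               concept_relevance(h, pair[1], pair[2]))
  }
})
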