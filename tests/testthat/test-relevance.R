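fig <- worked_example_fixture()

test_that("concept relevance reproduces the worked example and its bounds", {
  h <- fig$hierarchy
  expect_equal(concept_relevance(h, fig$t1, fig$t2), 5)
  expect_equal(concept_relevance(h, fig$t1, fig$t1), 8)  # 2 d(H)
  expect_error(concept_relevance(h, fig$t1, "nope"), "unknown concept")
})

test_that("concept relevance matches the exhaustive oracle; unit-weight
           symmetry and range hold", {
  set.seed(17)
  for (s in 1:15) {
    h <- random_dag(s)
    pair <- sample(h$ids, 2)
    r <- concept_relevance(h, pair[1], pair[2])
    expect_equal(r, oracle_relevance(h, pair[1], pair[2]))
    expect_equal(concept_relevance(h, pair[2], pair[1]), r)
    expect_gte(r, 0)
    expect_lte(r, 2 * hierarchy_depth(h))
    expect_equal(concept_relevance(h, pair[1], pair[1]),
                 2 * hierarchy_depth(h))
    w <- random_weight_map(h)
    expect_equal(concept_relevance(h, pair[1], pair[2], w),
                 oracle_relevance(h, pair[1], pair[2], w))
  }
})

test_that("disjoint concepts score zero relevance", {
  h <- concept_hierarchy(
    data.frame(id = c("r1", "r2", "x", "y")),
    data.frame(child = c("x", "y"), parent = c("r1", "r2")))
  expect_equal(concept_relevance(h, "x", "y"), 0)
})

test_that("GO document relevance: degenerate cases and user weights", {
  h <- fig$hierarchy
  one <- weighted_concept_set(fig$t1)
  s <- document_relevance_go(h, one, one)
  expect_equal(s$raw, 2 * hierarchy_depth(h))
  expect_equal(s$normalized, 1)

  d1 <- weighted_concept_set(fig$t1, weight = 2)
  d2 <- weighted_concept_set(fig$t2)
  expect_equal(document_relevance_go(h, d1, d2)$raw,
               2 * concept_relevance(h, fig$t1, fig$t2))

  empty <- document_relevance_go(h, weighted_concept_set(), d2)
  expect_true(empty$empty)
  expect_equal(empty$normalized, 0)

  expect_warning(
    document_relevance_go(h, weighted_concept_set(c(fig$t1, "ghost")), d2),
    "ghost")
})

test_that("document relevance equals the hand-expanded double loop", {
  h <- fig$hierarchy
  set.seed(3)
  ids <- h$ids
  d1 <- weighted_concept_set(sample(ids, 3), weight = c(1, 2, 0.5))
  d2 <- weighted_concept_set(sample(ids, 3))
  w <- random_weight_map(h)
  for (wm in list(NULL, w)) {
    raw <- 0
    for (i in seq_len(3)) {
      raw <- raw + d1$weight[i] *
        max(vapply(d2$id, function(t2)
          concept_relevance(h, d1$id[i], t2, wm), numeric(1)))
    }
    s <- document_relevance_go(h, d1, d2, wm)
    expect_equal(s$raw, raw)
    expect_equal(s$normalized, raw / (sum(d1$weight) * 2 * hierarchy_depth(h)))
  }
})

test_that("SCOP document relevance on the six-level tree", {
  res <- parse_scop_classification(paste(
    "1abc\ta/f/sf/fa/pr/sp1",
    "2xyz\ta/f/sf/fa/pr/sp2",
    "3pqr\ta/f/sf/fa/pr2/sp3", sep = "\n"))
  h <- res$hierarchy
  l1 <- weighted_concept_set(res$pdb_map[["1abc"]])
  l2 <- weighted_concept_set(res$pdb_map[["2xyz"]])
  l3 <- weighted_concept_set(res$pdb_map[["3pqr"]])
  expect_equal(document_relevance_scop(h, l1, l1)$normalized, 1)
  # species sharing a protein: 2*6 - (1+1) = 10 on the six-level tree
  expect_equal(document_relevance_scop(h, l1, l2)$raw, 10)
  # species sharing only the family: 2*6 - (2+2) = 8
  expect_equal(document_relevance_scop(h, l1, l3)$raw, 8)
  # weights are ignored for the structural viewpoint
  lw <- weighted_concept_set(res$pdb_map[["1abc"]], weight = 5)
  expect_equal(document_relevance_scop(h, lw, l2)$raw, 10)
})

test_that("MeSH document relevance applies the Major-Topic factor", {
  h <- fig$hierarchy
  ids <- c(fig$t1, "cell cycle arrest")
  plain <- weighted_concept_set(ids)
  d2 <- weighted_concept_set("cell cycle control")
  base <- document_relevance_mesh(h, plain, d2)
  go_equiv <- document_relevance_go(h, plain, d2)
  expect_equal(base$raw, go_equiv$raw)  # no Major Topics: same as GO form

  onemajor <- weighted_concept_set(ids, major = c(TRUE, FALSE))
  boosted <- document_relevance_mesh(h, onemajor, d2, major_topic_factor = 2)
  contrib <- max(vapply(d2$id, function(t2)
    concept_relevance(h, ids[1], t2), numeric(1)))
  expect_equal(boosted$raw, base$raw + contrib)  # that term exactly doubles
})

test_that("lowering edge weights never decreases relevance scores", {
  set.seed(23)
  for (s in 1:8) {
    h <- random_dag(s)
    w <- random_weight_map(h, frac = 0.6)
    pair <- sample(h$ids, 2)
    expect_gte(concept_relevance(h, pair[1], pair[2], w),
               concept_relevance(h, pair[1], pair[2]))
    d1 <- weighted_concept_set(sample(h$ids, 2))
    d2 <- weighted_concept_set(sample(h$ids, 2))
    expect_gte(document_relevance_go(h, d1, d2, w)$raw,
               document_relevance_go(h, d1, d2)$raw)
  }
})

test_that("an article is most relevant to itself under unit weights", {
  set.seed(29)
  h <- random_dag(4)
  d <- weighted_concept_set(sample(h$ids, 3))
  self <- document_relevance_go(h, d, d)$raw
  for (i in 1:10) {
    other <- weighted_concept_set(sample(h$ids, 3))
    expect_gte(self, document_relevance_go(h, d, other)$raw)
  }
})

test_that("combined score is the renormalized weighted mean over non-empty
           viewpoints", {
  vs <- function(v, norm, empty = FALSE) {
    structure(list(viewpoint = v, raw = norm, normalized = norm,
                   empty = empty), class = "viewpoint_score")
  }
  expect_equal(as.numeric(combined_score(list(vs("GO", 0.7)),
                                         mix = c(GO = 1))), 0.7)
  expect_equal(as.numeric(combined_score(
    list(vs("GO", 1), vs("SCOP", 0), vs("MESH", 0.5)))), 0.5)
  # empty viewpoint excluded, mix renormalized
  expect_equal(as.numeric(combined_score(
    list(vs("GO", 1), vs("SCOP", 0.4, empty = TRUE)),
    mix = c(GO = 1, SCOP = 9))), 1)
  allempty <- combined_score(list(vs("GO", 0.3, empty = TRUE)))
  expect_equal(as.numeric(allempty), 0)
  expect_true(attr(allempty, "empty"))
  # random mixes match the direct weighted mean
  set.seed(37)
  for (i in 1:10) {
    vals <- stats::runif(3)
    mix <- stats::runif(3, 0.1, 2)
    names(mix) <- c("GO", "SCOP", "MESH")
    got <- combined_score(list(vs("GO", vals[1]), vs("SCOP", vals[2]),
                               vs("MESH", vals[3])), mix)
    expect_equal(as.numeric(got), sum(mix * vals) / sum(mix))
  }
})
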