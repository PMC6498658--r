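make_set <- function(df) statement_set(df)

test_that("stance aggregation nets repeated and conflicting mentions", {
  s <- make_set(stance_df(list("A", "x", "+"), list("A", "x", "+"),
                          list("A", "y", "+"), list("A", "y", "-"),
                          list("B", "x", "-")))
  p <- build_stances(s)
  expect_equal(p$stance["A", "x"], 1)      # 2 agree, 0 disagree
  expect_equal(p$stance["A", "y"], 0)      # exact tie -> ambivalent
  expect_equal(p$stance["B", "x"], -1)
  expect_true(is.na(p$stance["B", "y"]))   # never mentioned
  expect_equal(p$n_agree["A", "x"], 2)
  # ambivalent mentions count towards activity by default, not otherwise
  expect_equal(unname(p$activity["A"]), 2)
  p2 <- build_stances(s, count_ambivalent = FALSE)
  expect_equal(unname(p2$activity["A"]), 1)
  expect_equal(unname(p$citation_count[match("A", rownames(p$stance))]), 4)
})

test_that("mention counts equal a brute-force tally on random sets", {
  for (seed in c(2, 9)) {
    df <- rand_statement_df(seed, n_actors = 5, n_concepts = 4, n = 60)
    p <- build_stances(make_set(df))
    for (a in unique(df$organisation)) for (con in unique(df$concept)) {
      rows <- df$organisation == a & df$concept == con
      expect_equal(p$n_agree[a, con], sum(df$agreement[rows]))
      expect_equal(p$n_disagree[a, con], sum(!df$agreement[rows]))
    }
    expect_true(all(p$activity[unique(df$organisation)] >= 1))
  }
})

test_that("congruence and conflict count shared non-ambivalent stances", {
  s <- make_set(stance_df(list("A", "x", "+"), list("A", "y", "+"),
                          list("B", "x", "+"), list("B", "y", "-")))
  cc <- congruence_conflict(build_stances(s))
  expect_equal(cc$congruence["A", "B"], 1L)
  expect_equal(cc$conflict["A", "B"], 1L)
  # disjoint concept sets share nothing
  s2 <- make_set(stance_df(list("A", "x", "+"), list("B", "y", "-")))
  cc2 <- congruence_conflict(build_stances(s2))
  expect_equal(cc2$congruence["A", "B"], 0L)
  expect_equal(cc2$conflict["A", "B"], 0L)
})

test_that("pair counts equal exhaustive enumeration on a random profile", {
  df <- rand_statement_df(31, n_actors = 8, n_concepts = 6, n = 120)
  p <- build_stances(make_set(df))
  cc <- congruence_conflict(p)
  acts <- rownames(p$stance)
  for (i in acts) for (j in acts) {
    if (i == j) next
    c_exp <- 0L; d_exp <- 0L
    for (con in colnames(p$stance)) {
      si <- p$stance[i, con]; sj <- p$stance[j, con]
      if (is.na(si) || is.na(sj) || si == 0 || sj == 0) next
      if (si == sj) c_exp <- c_exp + 1L else d_exp <- d_exp + 1L
    }
    expect_equal(cc$congruence[i, j], c_exp)
    expect_equal(cc$conflict[i, j], d_exp)
  }
})

test_that("subtract transformation with activity normalisation is exact", {
  # identical stances on all 3 concepts both actors mention -> weight 1
  s <- make_set(stance_df(list("A", "x", "+"), list("A", "y", "+"),
                          list("A", "z", "-"),
                          list("B", "x", "+"), list("B", "y", "+"),
                          list("B", "z", "-")))
  n <- subtract_normalise(build_stances(s))
  expect_equal(n$weights["A", "B"], 1)
  expect_equal(n$stage, "normalised")
  # fully opposed on 2 shared concepts -> weight -1
  s2 <- make_set(stance_df(list("A", "x", "+"), list("A", "y", "-"),
                           list("B", "x", "-"), list("B", "y", "+")))
  expect_equal(subtract_normalise(build_stances(s2))$weights["A", "B"], -1)
  # c = 2, d = 1, activities 4 and 6 -> (2 - 1) / 5 = 0.2
  s3 <- make_set(stance_df(
    list("A", "u", "+"), list("A", "v", "+"), list("A", "w", "+"),
    list("A", "x", "+"),
    list("B", "u", "+"), list("B", "v", "+"), list("B", "w", "-"),
    list("B", "p", "+"), list("B", "q", "+"), list("B", "r", "+")))
  expect_equal(subtract_normalise(build_stances(s3))$weights["A", "B"], 0.2)
})

test_that("zero-activity actors are an internal consistency error", {
  s <- make_set(stance_df(list("A", "x", "+"), list("B", "x", "-")))
  p <- build_stances(s)
  p$activity["A"] <- 0L
  expect_error(subtract_normalise(p), "zero activity")
})

test_that("thresholding keeps >= tau inclusively and drops negatives", {
  w <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  w["a", "b"] <- w["b", "a"] <- 0.40
  w["a", "c"] <- w["c", "a"] <- 0.39
  w["b", "c"] <- w["c", "b"] <- -0.8
  w["c", "d"] <- w["d", "c"] <- 0.95
  n <- apply_threshold(actor_network(w, stage = "normalised"))
  expect_equal(n$weights["a", "b"], 0.40)  # inclusive at the cut-off
  expect_equal(n$weights["a", "c"], 0)
  expect_equal(n$weights["b", "c"], 0)
  expect_equal(n$weights["c", "d"], 0.95)
  expect_equal(n$stage, "thresholded")
  expect_equal(n$threshold, 0.4)
  expect_equal(isolates(n), character(0))
  # nodes losing all ties stay as isolates
  w["a", "c"] <- w["c", "a"] <- 0.45
  w["c", "d"] <- w["d", "c"] <- 0.1
  n2 <- apply_threshold(actor_network(w, stage = "normalised"))
  expect_equal(isolates(n2), "d")
  expect_equal(length(actors(n2)), 4)
  expect_error(apply_threshold(actor_network(w, stage = "normalised"),
                               tau = 0), "tau")
  expect_error(apply_threshold(actor_network(w, stage = "normalised"),
                               tau = 1.2), "tau")
})

test_that("normalised weights are bounded and rate-invariant", {
  for (seed in c(4, 17, 40)) {
    df <- rand_statement_df(seed, n_actors = 7, n_concepts = 5, n = 70)
    n <- subtract_normalise(build_stances(statement_set(df)))
    expect_true(all(abs(n$weights) <= 1 + 1e-12))
    # duplicating every statement must not change any weight
    dup <- rbind(df, df)
    n_dup <- subtract_normalise(build_stances(statement_set(dup)))
    expect_equal(n_dup$weights[rownames(n$weights), colnames(n$weights)],
                 n$weights)
  }
})

test_that("the pipeline is invariant under actor relabelling", {
  df <- rand_statement_df(8, n_actors = 6, n_concepts = 4, n = 50)
  net1 <- statements_to_network(statement_set(df))
  perm <- c(org3 = "zz", org1 = "mm", org2 = "aa", org4 = "kk",
            org5 = "bb", org6 = "qq")
  df2 <- df
  df2$organisation <- unname(perm[df$organisation])
  net2 <- statements_to_network(statement_set(df2))
  for (i in names(perm)) for (j in names(perm))
    expect_equal(net2$weights[perm[i], perm[j]], net1$weights[i, j])
})

test_that("pipeline output equals the from-scratch brute-force oracle", {
  for (seed in c(1, 6, 13, 27)) {
    df <- rand_statement_df(seed, n_actors = 10, n_concepts = 6, n = 90)
    got <- statements_to_network(statement_set(df))$weights
    want <- brute_thresholded(df)
    expect_equal(got[rownames(want), colnames(want)], want)
  }
})

test_that("GraphML export carries node and coalition attributes", {
  net <- clique_network(c(4, 4))
  p <- girvan_newman(net)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, path, partition = p)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 8)
  expect_true("coalition" %in% igraph::vertex_attr_names(g))
  expect_equal(length(unique(igraph::V(g)$coalition)), 2)
})
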