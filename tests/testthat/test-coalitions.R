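bridge_cliques <- function(sizes) {
  # disjoint cliques joined in a chain by single bridges
  n <- clique_network(sizes)
  stops <- cumsum(sizes)
  w <- n$weights
  for (b in seq_len(length(sizes) - 1))
    w[stops[b], stops[b] + 1] <- w[stops[b] + 1, stops[b]] <- 1
  actor_network(w, stage = "thresholded", threshold = 0.4)
}

test_that("edge-betweenness clustering splits bridged cliques", {
  net <- bridge_cliques(c(4, 4))
  p <- girvan_newman(net)
  expect_s3_class(p, "coalition_partition")
  expect_equal(p$k, 2)
  expect_equal(unname(sort(as.vector(coalition_sizes(p)))), c(4, 4))
  # members of one clique share a cluster
  expect_equal(length(unique(p$membership[paste0("n0", 1:4)])), 1)
})

test_that("clustering a disconnected graph never merges components", {
  for (seed in 1:5) {
    pl <- planted_network(5, p_in = 0.9, p_out = 0, seed = seed)
    p <- girvan_newman(pl$network)
    g <- as_igraph(pl$network, binarise = TRUE, drop_isolates = TRUE)
    comp <- igraph::components(g)$membership
    shared <- intersect(names(p$membership), names(comp))
    # cluster labels refine component labels
    expect_true(all(tapply(comp[shared], p$membership[shared],
                           function(x) length(unique(x))) == 1))
  }
})

test_that("an edgeless network yields isolates and a warning", {
  w <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  net <- actor_network(w, stage = "thresholded", threshold = 0.4)
  expect_warning(p <- girvan_newman(net), "isolate")
  expect_equal(length(p$membership), 0)
  expect_equal(sort(p$isolates), c("a", "b", "c"))
  p2 <- suppressWarnings(girvan_newman(net, singleton_isolates = TRUE))
  expect_equal(p2$k, 3)
})

test_that("the dendrogram cut agrees with the exhaustive bipartition", {
  # 4-clique and 5-clique joined by one bridge: the best two-way split is
  # also the Girvan-Newman maximum-modularity cut
  net <- bridge_cliques(c(4, 5))
  p <- girvan_newman(net)
  expect_equal(p$k, 2)
  expect_equal(p$modularity, exhaustive_max_q2(net$weights),
               tolerance = 1e-12)
})

test_that("modularity matches its definition and independent routes", {
  # single cluster -> 0
  net <- bridge_cliques(c(3, 3))
  one <- stats::setNames(rep(1L, 6), actors(net))
  expect_equal(modularity_q(net, one), 0)
  # two disconnected equal cliques, component split -> exactly 1/2
  net2 <- clique_network(c(4, 4))
  split <- stats::setNames(rep(1:2, each = 4), actors(net2))
  expect_equal(modularity_q(net2, split), 0.5)
  # random weighted graph, random partition: double-sum oracle and igraph
  for (seed in c(3, 12)) {
    set.seed(seed)
    w <- matrix(stats::runif(100), 10, 10) * (matrix(stats::runif(100), 10) < 0.4)
    w <- (w + t(w)) / 2; diag(w) <- 0
    rownames(w) <- colnames(w) <- paste0("v", 1:10)
    net3 <- actor_network(w, stage = "thresholded", threshold = 0.4)
    keep <- setdiff(actors(net3), isolates(net3))
    memb <- stats::setNames(sample(1:3, length(keep), replace = TRUE), keep)
    q <- modularity_q(net3, memb)
    expect_equal(q, direct_q(net3$weights, memb), tolerance = 1e-12)
    g <- as_igraph(net3, drop_isolates = TRUE)
    expect_equal(q, igraph::modularity(g, memb[igraph::V(g)$name],
                                       weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
    expect_gte(q, -0.5)
    expect_lte(q, 1)
  }
  expect_error(modularity_q(net2, stats::setNames(1L, "ghost")),
               "absent")
})

test_that("every ensemble member recovers two disconnected triangles", {
  net <- clique_network(c(3, 3))
  ens <- cluster_k2_ensemble(net, seed = 42)
  expect_equal(length(ens), length(k2_methods()))
  for (p in ens) {
    expect_equal(p$k, 2)
    expect_equal(p$modularity, 0.5)
    expect_equal(length(unique(p$membership[paste0("n0", 1:3)])), 1)
  }
})

test_that("no bipartition of a complete graph beats the null", {
  net <- clique_network(c(6))
  ens <- suppressWarnings(cluster_k2_ensemble(net, seed = 7))
  expect_gt(length(ens), 0)
  for (p in ens) expect_lte(p$modularity, 0)
})

test_that("the best ensemble member recovers a noisy planted bipartition", {
  pl <- planted_network(6, p_in = 0.9, p_out = 0.05, seed = 8)
  ens <- suppressWarnings(cluster_k2_ensemble(pl$network, seed = 8))
  aris <- vapply(ens, function(p)
    mclust::adjustedRandIndex(pl$block[names(p$membership)], p$membership),
    numeric(1))
  expect_equal(max(aris), 1)
})

test_that("ensemble maximum is monotone in the method list", {
  pl <- planted_network(7, p_in = 0.6, p_out = 0.15, seed = 5)
  all_m <- k2_methods()
  best <- c()
  for (k in c(3, 7, 11)) {
    ens <- suppressWarnings(cluster_k2_ensemble(pl$network, all_m[1:k],
                                                seed = 9))
    best <- c(best, max(vapply(ens, `[[`, 1, "modularity")))
  }
  expect_true(all(diff(best) >= -1e-12))
})

test_that("a failing ensemble member is skipped with a warning", {
  bad <- c(k2_methods()[1:2],
           list(always_fails = function(A, seed) stop("boom")))
  net <- clique_network(c(3, 3))
  expect_warning(ens <- cluster_k2_ensemble(net, bad, seed = 1),
                 "always_fails")
  expect_equal(length(ens), 2)
})

test_that("coalitions are labelled by mean stance on reference concepts", {
  df <- rbind(
    stance_df(list("A", "tax_works", "+"), list("B", "tax_works", "+"),
              list("C", "tax_works", "-"), list("D", "tax_works", "-"),
              list("A", "other", "+"), list("B", "other", "+"),
              list("C", "other", "-"), list("D", "other", "-")))
  s <- statement_set(df)
  prof <- build_stances(s)
  net <- statements_to_network(s)
  p <- girvan_newman(net)
  p <- label_coalitions(p, prof, "tax_works")
  lab <- coalition_labels_vector(p, actors(net))
  expect_equal(unname(lab["A"]), "supportive")
  expect_equal(unname(lab["B"]), "supportive")
  expect_equal(unname(lab["C"]), "sceptical")
  expect_equal(unname(lab["D"]), "sceptical")
  expect_error(label_coalitions(p, prof, character()), "non-empty")
  expect_error(label_coalitions(p, prof, "missing_concept"), "registry")
})

test_that("mixed-cluster labels match the brute-force mean sign", {
  deb <- generate_debate(debate_config(n_actors_per_coalition = c(8, 8),
                                       n_intermediaries = 2,
                                       n_statements = 400, seed = 12))
  prof <- build_stances(deb$statements)
  net <- statements_to_network(deb$statements)
  p <- label_coalitions(girvan_newman(net), prof, pro_concepts(deb$truth))
  for (c_id in unique(p$membership)) {
    members <- names(p$membership)[p$membership == c_id]
    m <- mean(prof$stance[members, pro_concepts(deb$truth)], na.rm = TRUE)
    want <- if (is.nan(m) || m == 0) "other"
            else if (m > 0) "supportive" else "sceptical"
    expect_equal(unname(p$cluster_labels[as.character(c_id)]), want)
  }
})

test_that("partition CSV export lists every actor with its label", {
  net <- clique_network(c(3, 3))
  p <- girvan_newman(net)
  path <- withr::local_tempfile(fileext = ".csv")
  write_partition_csv(p, path, network = net)
  out <- utils::read.csv(path)
  expect_equal(nrow(out), 6)
  expect_equal(length(unique(out$coalition)), 2)
})
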