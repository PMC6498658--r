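# Independent oracles and small fixture builders. The oracles deliberately
# use plain loops over the definitions, sharing no code with the package
# implementation.

# random statement table
rand_statement_df <- function(seed, n_actors = 6, n_concepts = 4, n = 40,
                              start = as.Date("2016-01-01"), span = 120) {
  set.seed(seed)
  data.frame(
    person = "",
    organisation = sample(paste0("org", seq_len(n_actors)), n, replace = TRUE),
    org_type = "type_a",
    concept = sample(paste0("c", seq_len(n_concepts)), n, replace = TRUE),
    agreement = sample(c(TRUE, FALSE), n, replace = TRUE),
    date = start + sample.int(span, n, replace = TRUE) - 1L,
    article_id = sprintf("art%03d", sample.int(20, n, replace = TRUE)),
    stringsAsFactors = FALSE
  )
}

# from-scratch recomputation of the full statement -> thresholded network
# pipeline: per-pair concept loops, no matrix algebra
brute_thresholded <- function(df, tau = 0.4, count_ambivalent = TRUE) {
  acts <- sort(unique(df$organisation))
  cons <- sort(unique(df$concept))
  stance <- function(a, con) {
    rows <- df$organisation == a & df$concept == con
    if (!any(rows)) return(NA_real_)
    sign(sum(df$agreement[rows]) - sum(!df$agreement[rows]))
  }
  S <- matrix(NA_real_, length(acts), length(cons),
              dimnames = list(acts, cons))
  for (a in acts) for (con in cons) S[a, con] <- stance(a, con)
  act_of <- function(a) {
    if (count_ambivalent) sum(!is.na(S[a, ]))
    else sum(!is.na(S[a, ]) & S[a, ] != 0)
  }
  w <- matrix(0, length(acts), length(acts), dimnames = list(acts, acts))
  for (i in acts) for (j in acts) {
    if (i == j) next
    cij <- 0; dij <- 0
    for (con in cons) {
      si <- S[i, con]; sj <- S[j, con]
      if (is.na(si) || is.na(sj) || si == 0 || sj == 0) next
      if (si == sj) cij <- cij + 1 else dij <- dij + 1
    }
    w[i, j] <- (cij - dij) / ((act_of(i) + act_of(j)) / 2)
  }
  w[w < tau] <- 0
  w
}

# literal double-sum modularity: (1/2m) sum_ij (A_ij - d_i d_j / 2m) delta
direct_q <- function(w, membership) {
  w <- w[names(membership), names(membership), drop = FALSE]
  m2 <- sum(w)
  d <- rowSums(w)
  q <- 0
  for (i in seq_along(membership)) for (j in seq_along(membership))
    if (membership[i] == membership[j])
      q <- q + w[i, j] - d[i] * d[j] / m2
  unname(q / m2)
}

# exhaustive maximum over all 2-cluster partitions (both sides non-empty)
exhaustive_max_q2 <- function(w) {
  labs <- rownames(w)
  n <- length(labs)
  best <- -Inf
  for (code in 1:(2^(n - 1) - 1)) {
    side <- c(1L, 1L + as.integer(intToBits(code)[seq_len(n - 1)] == 1))
    names(side) <- labs
    best <- max(best, direct_q(w, side))
  }
  best
}

# block network: disjoint cliques of the given sizes with uniform weight
clique_network <- function(sizes, weight = 1, stage = "thresholded") {
  n <- sum(sizes)
  w <- matrix(0, n, n)
  stop_at <- cumsum(sizes)
  start_at <- c(1, utils::head(stop_at, -1) + 1)
  for (b in seq_along(sizes))
    w[start_at[b]:stop_at[b], start_at[b]:stop_at[b]] <- weight
  diag(w) <- 0
  rownames(w) <- colnames(w) <- sprintf("n%02d", seq_len(n))
  actor_network(w, stage = stage,
                threshold = if (stage == "thresholded") 0.4 else NULL)
}

# planted two-block binary network with given within/between tie probs
planted_network <- function(n_per_block, p_in, p_out, seed,
                            stage = "thresholded") {
  set.seed(seed)
  n <- 2 * n_per_block
  w <- matrix(0, n, n)
  block <- rep(1:2, each = n_per_block)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    p <- if (block[i] == block[j]) p_in else p_out
    w[i, j] <- w[j, i] <- as.numeric(stats::runif(1) < p)
  }
  rownames(w) <- colnames(w) <- sprintf("n%02d", seq_len(n))
  list(network = actor_network(w, stage = stage),
       block = stats::setNames(block, rownames(w)))
}

# statement table from (organisation, concept, "+"/"-") triples
stance_df <- function(...) {
  rows <- list(...)
  data.frame(
    person = "",
    organisation = vapply(rows, `[[`, "", 1),
    org_type = "t",
    concept = vapply(rows, `[[`, "", 2),
    agreement = vapply(rows, function(r) identical(r[[3]], "+"), TRUE),
    date = as.Date("2016-01-01") + seq_along(rows),
    article_id = paste0("a", seq_along(rows)),
    stringsAsFactors = FALSE
  )
}

# tiny fixed six-statement fixture used by the I/O tests
six_statement_csv <- function(path) {
  writeLines(c(
    "person,organisation,org_type,concept,agreement,date,article_id",
    "Ann Smith,Health First,Health charity,c_tax_works,agree,2016-01-03,a1",
    ",Health First,Health charity,c_regressive,disagree,2016-01-05,a2",
    "Bob Jones,Fizz Ltd,Soft drinks industry,c_tax_works,disagree,2016-01-04,a3",
    ",Fizz Ltd,Soft drinks industry,c_regressive,agree,2016-01-10,a4",
    ",Uni of Mid,University/Academic,c_tax_works,agree,2016-01-04,a3",
    ",Uni of Mid,University/Academic,c_tax_works,agree,2016-02-01,a5"),
    path)
  path
}
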