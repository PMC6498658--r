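#' Construct a coalition partition
#'
#' Assignment of the non-isolate actors of a network to coalitions,
#' together with its provenance (algorithm, seed) and its modularity on the
#' source network. Isolates are carried separately: an actor that lost all
#' ties at the thresholding step is not meaningfully a coalition of one.
#'
#' @param membership named integer vector actor -> cluster id; ids are
#'   renumbered to be contiguous from 1 in order of first appearance.
#' @param network the `actor_network` the partition was computed on; used to
#'   evaluate modularity.
#' @param method algorithm label.
#' @param seed integer seed used by the algorithm, or `NULL`.
#' @param isolates character vector of actors excluded as isolates.
#' @return an object of class `coalition_partition` with components
#'   `membership`, `k`, `method`, `seed`, `modularity`, `isolates` and
#'   optional `cluster_labels`.
#' @export
coalition_partition <- function(membership, network, method = "manual",
                                seed = NULL, isolates = character()) {
  stopifnot(inherits(network, "actor_network"))
  if (is.null(names(membership)))
    stop("membership must be named by actor", call. = FALSE)
  absent <- setdiff(names(membership), actors(network))
  if (length(absent))
    stop("actor(s) in partition absent from network: ",
         paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  ids <- as.integer(factor(membership, levels = unique(membership)))
  names(ids) <- names(membership)
  p <- structure(list(
    membership = ids,
    k = length(unique(ids)),
    method = method,
    seed = seed,
    modularity = NA_real_,
    isolates = isolates,
    cluster_labels = NULL
  ), class = "coalition_partition")
  p$modularity <- modularity_q(network, p)
  p
}

#' @export
print.coalition_partition <- function(x, ...) {
  sizes <- sort(table(x$membership), decreasing = TRUE)
  cat("Coalition partition (", x$method, "): k = ", x$k,
      ", sizes ", paste(sizes, collapse = "/"),
      ", Q = ", round(x$modularity, 4), sep = "")
  if (length(x$isolates))
    cat(" (+", length(x$isolates), " isolates)", sep = "")
  cat("\n")
  if (!is.null(x$cluster_labels))
    cat("  labels:", paste(names(x$cluster_labels), "=",
                           x$cluster_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Coalition size table
#' @param p a `coalition_partition`.
#' @return named integer vector of cluster sizes, largest first.
#' @export
coalition_sizes <- function(p) {
  sort(table(p$membership), decreasing = TRUE)
}

#' Newman-Girvan modularity of a partition
#'
#' \deqn{Q = \sum_c (e_{cc} - a_c^2)} where \eqn{e_{cc}} is the fraction of
#' total edge weight falling within cluster \eqn{c} and \eqn{a_c} the
#' fraction of edge ends attached to it. Evaluated on the (weighted) tie
#' weights of the network; on a binary network this reduces to the
#' unweighted definition. `Q` lies in [-1/2, 1]. Isolates contribute no
#' weight and are ignored; a non-isolate actor missing from the partition
#' is an error.
#'
#' @param n an `actor_network`.
#' @param p a `coalition_partition`, or a named cluster-id vector.
#' @return modularity value.
#' @export
modularity_q <- function(n, p) {
  stopifnot(inherits(n, "actor_network"))
  membership <- if (inherits(p, "coalition_partition")) p$membership else p
  absent <- setdiff(names(membership), actors(n))
  if (length(absent))
    stop("actor(s) in partition absent from network: ",
         paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  uncovered <- setdiff(setdiff(actors(n), isolates(n)), names(membership))
  if (length(uncovered))
    stop("non-isolate actor(s) not covered by partition: ",
         paste(utils::head(uncovered, 5), collapse = ", "), call. = FALSE)
  w <- n$weights[names(membership), names(membership), drop = FALSE]
  total <- sum(w)                      # = 2m for a symmetric matrix
  if (total == 0) return(NA_real_)
  q <- 0
  for (c_id in unique(membership)) {
    in_c <- membership == c_id
    e_cc <- sum(w[in_c, in_c]) / total
    a_c <- sum(w[in_c, , drop = FALSE]) / total
    q <- q + e_cc - a_c^2
  }
  q
}

#' Girvan-Newman edge-betweenness coalition detection
#'
#' Iteratively removes the edge of highest betweenness from the binarised
#' network (tie present iff the thresholded weight is nonzero) and cuts the
#' resulting dendrogram. The default stopping rule cuts where modularity
#' along the removal sequence is maximal; alternatively the dendrogram can
#' be cut at a requested number of clusters `k`. Isolates are excluded
#' before clustering and reported on the partition, not returned as
#' singleton coalitions (set `singleton_isolates = TRUE` to include them as
#' such).
#'
#' @param n an `actor_network` (normally `stage = "thresholded"`).
#' @param k optional number of clusters to cut the dendrogram at; default
#'   `NULL` uses the maximum-modularity cut.
#' @param singleton_isolates logical; assign each isolate its own cluster
#'   instead of reporting isolates separately.
#' @return a `coalition_partition` (method `"girvan_newman"`), with
#'   modularity evaluated on the weights of `n`.
#' @export
girvan_newman <- function(n, k = NULL, singleton_isolates = FALSE) {
  stopifnot(inherits(n, "actor_network"))
  iso <- isolates(n)
  g <- as_igraph(n, binarise = TRUE, drop_isolates = TRUE)
  if (igraph::vcount(g) == 0) {
    warning("network has no ties; every node is an isolate", call. = FALSE)
    memb <- stats::setNames(integer(0), character(0))
    if (singleton_isolates)
      memb <- stats::setNames(seq_along(iso), iso)
    p <- structure(list(membership = memb, k = length(unique(memb)),
                        method = "girvan_newman", seed = NULL,
                        modularity = NA_real_,
                        isolates = if (singleton_isolates) character() else iso,
                        cluster_labels = NULL),
                   class = "coalition_partition")
    return(p)
  }
  ceb <- igraph::cluster_edge_betweenness(g, weights = NULL,
                                          modularity = TRUE)
  memb <- if (is.null(k)) igraph::membership(ceb)
          else igraph::cut_at(ceb, no = k)
  memb <- stats::setNames(as.integer(memb), igraph::V(g)$name)
  if (singleton_isolates && length(iso)) {
    memb <- c(memb, stats::setNames(max(memb) + seq_along(iso), iso))
    iso <- character()
  }
  coalition_partition(memb, n, method = "girvan_newman", isolates = iso)
}

# --- k = 2 ensemble members ------------------------------------------------
# Each member takes the binarised adjacency matrix A of the non-isolate
# subgraph (with dimnames) plus a seed, and returns a named 1/2 membership
# vector, or stops. Stochastic members must consume randomness only through
# the seed argument.

k2_gn <- function(A, seed) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  ceb <- igraph::cluster_edge_betweenness(g, weights = NULL)
  stats::setNames(as.integer(igraph::cut_at(ceb, no = 2)), rownames(A))
}

k2_leading_eigen <- function(A, seed) {
  d <- rowSums(A)
  m2 <- sum(d)
  if (m2 == 0) stop("empty graph")
  B <- A - outer(d, d) / m2
  v <- eigen(B, symmetric = TRUE)$vectors[, 1]
  side <- ifelse(v >= 0, 1L, 2L)
  if (length(unique(side)) < 2) stop("leading eigenvector does not bisect")
  stats::setNames(side, rownames(A))
}

k2_spectral_kmeans <- function(A, seed) {
  d <- rowSums(A)
  dh <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- diag(nrow(A)) - (dh * A) %*% diag(dh)   # normalised Laplacian
  ev <- eigen(L, symmetric = TRUE)
  emb <- ev$vectors[, ncol(L) - (0:1), drop = FALSE]  # two smallest
  set.seed(seed)
  km <- stats::kmeans(emb, centers = 2, nstart = 5)
  stats::setNames(as.integer(km$cluster), rownames(A))
}

k2_kl_refine <- function(A, seed) {
  n <- nrow(A)
  d <- rowSums(A)
  m2 <- sum(d)
  if (m2 == 0) stop("empty graph")
  set.seed(seed)
  side <- sample(c(1L, 2L), n, replace = TRUE)
  if (length(unique(side)) < 2) side[1] <- 3L - side[1]
  # greedy single-node moves maximising binary modularity; the gain of
  # moving node i from its side a to b is
  #   2 (k_ib - k_ia) / m2 - 2 d_i (D_b - D_a + d_i) / m2^2
  # with k_ic its ties into cluster c and D_c the cluster degree sum
  repeat {
    in1 <- side == 1L
    k1 <- as.vector(A %*% in1)           # ties into side 1
    k_same <- ifelse(in1, k1, d - k1)
    k_other <- d - k_same
    D1 <- sum(d[in1]); D2 <- m2 - D1
    D_other_minus_same <- ifelse(in1, D2 - D1, D1 - D2)
    gain <- 2 * (k_other - k_same) / m2 -
      2 * d * (D_other_minus_same + d) / m2^2
    gain[(in1 & sum(in1) == 1) | (!in1 & sum(!in1) == 1)] <- -Inf
    if (max(gain) <= 1e-12) break
    i <- which.max(gain)
    side[i] <- 3L - side[i]
  }
  stats::setNames(side, rownames(A))
}

k2_fast_greedy <- function(A, seed) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  fg <- igraph::cluster_fast_greedy(g)
  stats::setNames(as.integer(igraph::cut_at(fg, no = 2)), rownames(A))
}

k2_walk_medoids <- function(A, seed) {
  d <- rowSums(A)
  if (any(d == 0)) stop("walk distance undefined for isolated node")
  P <- A / d
  Pt <- P %*% P %*% P %*% P                 # 4-step transition probabilities
  dd <- stats::dist(Pt)
  pm <- cluster::pam(dd, k = 2, diss = TRUE)
  stats::setNames(as.integer(pm$clustering), rownames(A))
}

k2_multilevel <- function(A, seed) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  set.seed(seed)
  ml <- igraph::cluster_louvain(g)
  comm <- as.integer(igraph::membership(ml))
  nc <- length(unique(comm))
  if (nc < 2) stop("multilevel found a single community")
  if (nc == 2) return(stats::setNames(comm, rownames(A)))
  merge_to_2(A, comm, rownames(A))
}

# merge >2 communities into the 2-group split of maximal binary modularity:
# exhaustive over group assignments when few communities, greedy otherwise
merge_to_2 <- function(A, comm, labels) {
  d <- rowSums(A)
  m2 <- sum(d)
  uc <- unique(comm)
  nc <- length(uc)
  q_of_sides <- function(side_of_comm) {
    s <- side_of_comm[match(comm, uc)]
    q <- 0
    for (c_id in 1:2) {
      in_c <- s == c_id
      q <- q + sum(A[in_c, in_c]) / m2 - (sum(d[in_c]) / m2)^2
    }
    q
  }
  if (nc <= 14) {
    best_q <- -Inf; best <- NULL
    for (code in 1:(2^(nc - 1) - 1)) {       # comm 1 fixed to side 1
      side <- c(1L, 1L + as.integer(intToBits(code)[seq_len(nc - 1)] == 1))
      q <- q_of_sides(side)
      if (q > best_q) { best_q <- q; best <- side }
    }
    side <- best
  } else {
    side <- c(1L, 2L, sample(c(1L, 2L), nc - 2, replace = TRUE))
    repeat {
      improved <- FALSE
      q <- q_of_sides(side)
      for (i in seq_len(nc)) {
        if (sum(side == side[i]) == 1) next
        cand <- side; cand[i] <- 3L - cand[i]
        if (q_of_sides(cand) > q + 1e-12) {
          side <- cand; improved <- TRUE; q <- q_of_sides(side)
        }
      }
      if (!improved) break
    }
  }
  stats::setNames(side[match(comm, uc)], labels)
}

#' Default k = 2 clustering ensemble
#'
#' Eleven bisection techniques, each forced to two clusters: Girvan-Newman
#' cut at k = 2; leading-eigenvector (modularity-matrix) bisection; spectral
#' embedding with 2-means under three seeds; Kernighan-Lin-style greedy
#' refinement from three random starts; greedy agglomerative modularity cut
#' at 2; random-walk distance with 2-medoids; and multilevel bisection.
#'
#' @return named list of member functions `(A, seed) -> membership`.
#' @export
k2_methods <- function() {
  list(
    gn_k2 = k2_gn,
    leading_eigen = k2_leading_eigen,
    spectral_kmeans_1 = k2_spectral_kmeans,
    spectral_kmeans_2 = k2_spectral_kmeans,
    spectral_kmeans_3 = k2_spectral_kmeans,
    kl_refine_1 = k2_kl_refine,
    kl_refine_2 = k2_kl_refine,
    kl_refine_3 = k2_kl_refine,
    fast_greedy_k2 = k2_fast_greedy,
    walk_medoids = k2_walk_medoids,
    multilevel_k2 = k2_multilevel
  )
}

#' Run the k = 2 clustering ensemble
#'
#' Applies every ensemble member to the binarised non-isolate subgraph of
#' `n` and returns one two-cluster partition per member that succeeds, each
#' with its modularity on the weights of `n`. A member failing on a
#' degenerate graph (for instance a graph whose component structure cannot
#' be cut into exactly two clusters) is skipped with a warning; the
#' ensemble never aborts as a whole. Stochastic members receive
#' deterministic per-member seeds derived from `seed`.
#'
#' @param n an `actor_network` with at least two non-isolate actors.
#' @param methods named list of member functions, default [k2_methods()].
#' @param seed master seed for the stochastic members.
#' @return list of `coalition_partition` objects (possibly shorter than
#'   `methods`).
#' @export
cluster_k2_ensemble <- function(n, methods = k2_methods(), seed = 1L) {
  stopifnot(inherits(n, "actor_network"))
  iso <- isolates(n)
  keep <- setdiff(actors(n), iso)
  if (length(keep) < 2)
    stop("k = 2 ensemble requires at least two non-isolate actors",
         call. = FALSE)
  A <- (n$weights[keep, keep, drop = FALSE] != 0) * 1
  out <- list()
  for (i in seq_along(methods)) {
    nm <- names(methods)[i]
    member_seed <- (as.integer(seed) %% 100000L) * 13L + i
    res <- tryCatch(methods[[i]](A, member_seed), error = function(e) e)
    if (!inherits(res, "error") && length(unique(res)) != 2)
      res <- simpleError("did not produce exactly 2 clusters")
    if (inherits(res, "error")) {
      warning("ensemble member '", nm, "' failed: ",
              conditionMessage(res), call. = FALSE)
      next
    }
    p <- coalition_partition(res, n, method = nm, seed = member_seed,
                             isolates = iso)
    out[[nm]] <- p
  }
  out
}

#' Label coalitions as supportive or sceptical
#'
#' A coalition is labelled by the mean stance of its members over a set of
#' reference concepts that express support for the policy under debate
#' (e.g. "taxation is an effective lever"): positive mean -> supportive,
#' negative -> sceptical, exact zero or no mentions at all -> other.
#'
#' @param p a `coalition_partition`.
#' @param profile the `stance_profile` of the same debate.
#' @param pro_concepts character vector of concept identifiers whose
#'   endorsement marks support; must be non-empty and present in the
#'   profile.
#' @return `p` with `cluster_labels` set (named by cluster id, values in
#'   `supportive` / `sceptical` / `other`).
#' @export
label_coalitions <- function(p, profile, pro_concepts) {
  stopifnot(inherits(p, "coalition_partition"),
            inherits(profile, "stance_profile"))
  if (!length(pro_concepts))
    stop("pro_concepts must be non-empty", call. = FALSE)
  absent <- setdiff(pro_concepts, colnames(profile$stance))
  if (length(absent))
    stop("pro_concept(s) not in concept registry: ",
         paste(absent, collapse = ", "), call. = FALSE)
  labels <- character()
  for (c_id in sort(unique(p$membership))) {
    members <- names(p$membership)[p$membership == c_id]
    st <- profile$stance[intersect(members, rownames(profile$stance)),
                         pro_concepts, drop = FALSE]
    mean_st <- mean(st, na.rm = TRUE)
    if (is.nan(mean_st)) {
      warning("no member of cluster ", c_id,
              " mentions any reference concept; labelled 'other'",
              call. = FALSE)
      lab <- "other"
    } else if (mean_st > 0) lab <- "supportive"
    else if (mean_st < 0) lab <- "sceptical"
    else lab <- "other"
    labels[as.character(c_id)] <- lab
  }
  p$cluster_labels <- labels
  p
}

# label per actor ("supportive" / "sceptical" / cluster id / "isolate")
coalition_labels_vector <- function(p, all_actors) {
  lab <- stats::setNames(rep("isolate", length(all_actors)), all_actors)
  cl <- as.character(p$membership)
  if (!is.null(p$cluster_labels)) {
    named <- p$cluster_labels[cl]
    cl <- ifelse(is.na(named), paste0("coalition_", cl), named)
  } else cl <- paste0("coalition_", cl)
  lab[names(p$membership)] <- cl
  lab
}

#' Write a partition as a two-column CSV
#'
#' @param p a `coalition_partition`.
#' @param path output file path.
#' @param network optional `actor_network`; when given, isolates are
#'   included with label `"isolate"`.
#' @return `path`, invisibly.
#' @export
write_partition_csv <- function(p, path, network = NULL) {
  all_actors <- if (is.null(network)) c(names(p$membership), p$isolates)
                else actors(network)
  lab <- coalition_labels_vector(p, all_actors)
  utils::write.csv(data.frame(actor = names(lab), coalition = unname(lab)),
                   path, row.names = FALSE)
  invisible(path)
}
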