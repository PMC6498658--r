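#' Construct an actor network
#'
#' A symmetric weighted actor-by-actor graph at a named processing stage of
#' the congruence pipeline: `congruence` / `conflict` (raw concept counts),
#' `subtract_raw` (congruence minus conflict), `normalised` (divided by the
#' actors' average activity, bounded in [-1, 1]), `thresholded` (weights
#' below the cut-off zeroed), or `unknown` (e.g. a matrix read from an
#' external export of unrecorded provenance).
#'
#' @param weights symmetric numeric matrix with actor labels as dimnames;
#'   the diagonal is forced to zero.
#' @param org_type optional named character vector actor -> organisation
#'   type.
#' @param citation_count optional named integer vector actor -> number of
#'   coded statements (drives node size in figures).
#' @param stage processing stage label.
#' @param threshold the tie-weight cut-off used, if `stage = "thresholded"`.
#' @return an object of class `actor_network`.
#' @export
actor_network <- function(weights, org_type = NULL, citation_count = NULL,
                          stage = c("unknown", "congruence", "conflict",
                                    "subtract_raw", "normalised",
                                    "thresholded"),
                          threshold = NULL) {
  stage <- match.arg(stage)
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights))
    stop("weights must be a square matrix", call. = FALSE)
  if (is.null(rownames(weights)))
    rownames(weights) <- colnames(weights) <-
      paste0("actor_", seq_len(nrow(weights)))
  if (max(abs(weights - t(weights))) > 1e-9)
    stop("weights must be symmetric", call. = FALSE)
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  actors <- rownames(weights)
  if (is.null(org_type))
    org_type <- stats::setNames(rep(NA_character_, length(actors)), actors)
  if (is.null(citation_count))
    citation_count <- stats::setNames(rep(NA_integer_, length(actors)), actors)
  structure(list(
    weights = weights,
    org_type = org_type[actors],
    citation_count = citation_count[actors],
    stage = stage,
    threshold = threshold
  ), class = "actor_network")
}

#' @export
print.actor_network <- function(x, ...) {
  w <- x$weights
  ut <- w[upper.tri(w)]
  cat("Actor network (", x$stage, "): ", nrow(w), " nodes, ",
      sum(ut != 0), " ties\n", sep = "")
  if (!is.null(x$threshold))
    cat("  threshold: ", x$threshold, "\n", sep = "")
  if (any(ut != 0))
    cat("  nonzero weights: ", signif(min(ut[ut != 0]), 3), " .. ",
        signif(max(ut), 3), "\n", sep = "")
  invisible(x)
}

#' Actor labels of a network
#' @param n an `actor_network`.
#' @return character vector of actor labels.
#' @export
actors <- function(n) rownames(n$weights)

#' Actors with no remaining tie
#' @param n an `actor_network`.
#' @return character vector of actors whose row is all zero.
#' @export
isolates <- function(n) {
  deg <- rowSums(n$weights != 0)
  names(deg)[deg == 0]
}

#' Aggregate statements into per-actor stance profiles
#'
#' For every (actor, concept) pair the agree and disagree mentions are
#' tallied and reduced to a net stance: `+1` if agreements outnumber
#' disagreements, `-1` for the reverse, and `0` (ambivalent) on an exact
#' tie. Aggregating to a sign before any network is built means the tie
#' weights measure argumentative similarity only, not how often an actor is
#' quoted. An actor's activity is the number of distinct concepts it
#' mentions at all; by default ambivalent mentions count towards activity
#' (the actor did mention the concept), controllable via
#' `count_ambivalent`.
#'
#' @param s a `statement_set`.
#' @param count_ambivalent logical; should concepts on which an actor is
#'   exactly tied still count towards that actor's activity? Default `TRUE`.
#' @return an object of class `stance_profile` with components `stance`
#'   (actors x concepts matrix in \{+1, -1, 0, NA\}, NA = never mentioned),
#'   `n_agree` / `n_disagree` (mention count matrices), `activity` (named
#'   integer vector), `citation_count` (statements per actor) and `org_type`.
#' @export
build_stances <- function(s, count_ambivalent = TRUE) {
  stopifnot(inherits(s, "statement_set"))
  st <- s$statements
  if (!nrow(st)) stop("cannot build stances from an empty statement set",
                      call. = FALSE)
  acts <- names(s$actor_registry)
  cons <- s$concept_registry
  fa <- factor(st$organisation, levels = acts)
  fc <- factor(st$concept, levels = cons)
  n_agree <- as.matrix(table(fa[st$agreement], fc[st$agreement]))
  n_disagree <- as.matrix(table(fa[!st$agreement], fc[!st$agreement]))
  # table() drops nothing because levels are fixed, but returns class "table"
  n_agree <- matrix(n_agree, length(acts), length(cons),
                    dimnames = list(acts, cons))
  n_disagree <- matrix(n_disagree, length(acts), length(cons),
                       dimnames = list(acts, cons))
  mentioned <- (n_agree + n_disagree) > 0
  stance <- sign(n_agree - n_disagree)
  stance[!mentioned] <- NA
  counted <- if (count_ambivalent) mentioned else !is.na(stance) & stance != 0
  activity <- rowSums(counted)
  structure(list(
    stance = stance,
    n_agree = n_agree,
    n_disagree = n_disagree,
    activity = activity,
    citation_count = as.vector(table(fa)[acts]),
    org_type = s$actor_registry,
    count_ambivalent = count_ambivalent
  ), class = "stance_profile")
}

#' @export
print.stance_profile <- function(x, ...) {
  cat("Stance profile: ", nrow(x$stance), " actors x ", ncol(x$stance),
      " concepts; ", sum(!is.na(x$stance)), " (actor, concept) stances (",
      sum(x$stance == 0, na.rm = TRUE), " ambivalent)\n", sep = "")
  invisible(x)
}

#' Concept congruence and conflict counts between actors
#'
#' For each actor pair, `congruence` counts the concepts on which the two
#' actors hold the same non-ambivalent stance, and `conflict` counts those
#' on which they hold opposite stances. Ambivalent stances and concepts
#' mentioned by only one of the two actors contribute to neither count.
#'
#' @param p a `stance_profile`.
#' @return list with integer matrices `congruence` and `conflict`
#'   (diagonals zero).
#' @export
congruence_conflict <- function(p) {
  stopifnot(inherits(p, "stance_profile"))
  S <- p$stance
  pos <- (!is.na(S) & S == 1) * 1
  neg <- (!is.na(S) & S == -1) * 1
  con <- pos %*% t(pos) + neg %*% t(neg)
  dis <- pos %*% t(neg) + neg %*% t(pos)
  diag(con) <- 0; diag(dis) <- 0
  storage.mode(con) <- "integer"
  storage.mode(dis) <- "integer"
  list(congruence = con, conflict = dis)
}

#' Subtract transformation with average activity normalisation
#'
#' The tie weight between two actors is their congruence count minus their
#' conflict count — argumentative similarity in excess of differences of
#' opinion — divided by the average number of distinct concepts the two
#' actors mention over the debate. The result is bounded in [-1, 1]: +1 for
#' actors agreeing on every concept either mentions, -1 for actors opposed
#' on all of them.
#'
#' @param p a `stance_profile`.
#' @param cc optional precomputed result of [congruence_conflict()];
#'   computed from `p` when omitted.
#' @return an `actor_network` with `stage = "normalised"`.
#' @export
subtract_normalise <- function(p, cc = congruence_conflict(p)) {
  stopifnot(inherits(p, "stance_profile"))
  a <- p$activity
  if (any(a == 0))
    stop("actor(s) with zero activity in stance profile: ",
         paste(utils::head(names(a)[a == 0], 5), collapse = ", "),
         call. = FALSE)
  denom <- outer(a, a, "+") / 2
  w <- (cc$congruence - cc$conflict) / denom
  diag(w) <- 0
  actor_network(w, org_type = p$org_type,
                citation_count = stats::setNames(p$citation_count,
                                                 names(a)),
                stage = "normalised")
}

#' Apply the tie-weight threshold
#'
#' Weights at or above the cut-off are kept; everything below it — including
#' all negative (net-conflict) weights — is replaced by zero, retaining only
#' relatively robust argumentative similarity as ties. Nodes that lose all
#' their ties remain in the network as isolates. The default cut-off of 0.4
#' (inclusive) is the value used for the sugar-levy debate networks.
#'
#' @param n an `actor_network` with `stage = "normalised"` (or `"unknown"`
#'   for externally supplied matrices).
#' @param tau threshold in (0, 1]; ties with weight `>= tau` survive.
#' @return an `actor_network` with `stage = "thresholded"`.
#' @export
apply_threshold <- function(n, tau = 0.4) {
  stopifnot(inherits(n, "actor_network"))
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau > 1)
    stop("threshold tau must be a single value in (0, 1]", call. = FALSE)
  if (!n$stage %in% c("normalised", "unknown"))
    stop("threshold applies to a normalised network, not stage '",
         n$stage, "'", call. = FALSE)
  w <- n$weights
  w[w < tau] <- 0
  actor_network(w, org_type = n$org_type, citation_count = n$citation_count,
                stage = "thresholded", threshold = tau)
}

#' Full statement-to-network pipeline
#'
#' Convenience composition: stance aggregation, congruence/conflict counts,
#' subtract transformation with average activity normalisation, and
#' thresholding.
#'
#' @inheritParams build_stances
#' @inheritParams apply_threshold
#' @return an `actor_network` with `stage = "thresholded"`.
#' @export
statements_to_network <- function(s, tau = 0.4, count_ambivalent = TRUE) {
  apply_threshold(subtract_normalise(build_stances(s, count_ambivalent)),
                  tau = tau)
}

#' Convert an actor network to an igraph graph
#'
#' @param n an `actor_network`.
#' @param binarise logical; drop weights and keep only tie presence
#'   (edge present iff weight != 0). Clustering and the binary network
#'   measures operate on this form.
#' @param drop_isolates logical; remove zero-degree nodes.
#' @return an `igraph` object with vertex attributes `name`, `org_type`,
#'   `citation_count` and (unless binarised) edge attribute `weight`.
#' @export
as_igraph <- function(n, binarise = FALSE, drop_isolates = FALSE) {
  stopifnot(inherits(n, "actor_network"))
  w <- n$weights
  if (drop_isolates) {
    keep <- rowSums(w != 0) > 0
    w <- w[keep, keep, drop = FALSE]
  }
  g <- igraph::graph_from_adjacency_matrix(
    if (binarise) (w != 0) * 1 else w,
    mode = "undirected", weighted = if (binarise) NULL else TRUE,
    diag = FALSE)
  igraph::V(g)$org_type <- unname(n$org_type[igraph::V(g)$name])
  igraph::V(g)$citation_count <- unname(n$citation_count[igraph::V(g)$name])
  g
}

#' Export an actor network to GraphML
#'
#' Node attributes `org_type`, `citation_count` and, when a partition is
#' supplied, `coalition` are written so that external network visualisation
#' tools can colour and size nodes.
#'
#' @param n an `actor_network`.
#' @param path output file path.
#' @param partition optional `coalition_partition`; adds a `coalition` node
#'   attribute (cluster label, or `"isolate"`).
#' @return `path`, invisibly.
#' @export
write_graphml <- function(n, path, partition = NULL) {
  g <- as_igraph(n)
  if (!is.null(partition)) {
    lab <- coalition_labels_vector(partition, actors(n))
    igraph::V(g)$coalition <- unname(lab[igraph::V(g)$name])
  }
  at <- igraph::vertex_attr(g)
  for (a in names(at))
    if (is.character(at[[a]]) || anyNA(at[[a]]))
      g <- igraph::set_vertex_attr(g, a,
             value = ifelse(is.na(at[[a]]), "", as.character(at[[a]])))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
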