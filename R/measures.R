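# binarised degree of each actor within a node set
degree_within <- function(n, node_set) {
  w <- n$weights[node_set, node_set, drop = FALSE]
  rowSums(w != 0)
}

#' Network density
#'
#' Number of ties among the given actors as a proportion of the theoretical
#' maximum `|V| (|V|-1) / 2`, counted on the binarised graph (tie present
#' iff weight nonzero). With `weighted = TRUE` the mean absolute tie weight
#' over all pairs is returned instead.
#'
#' @param n an `actor_network`.
#' @param node_set character vector of actors (default: all); at least two.
#' @param weighted logical, default `FALSE` (binary tie counts).
#' @return density in [0, 1] (for binary) or mean weight.
#' @export
network_density <- function(n, node_set = actors(n), weighted = FALSE) {
  stopifnot(inherits(n, "actor_network"))
  check_node_set(n, node_set, min_size = 2, "density")
  w <- n$weights[node_set, node_set, drop = FALSE]
  ut <- w[upper.tri(w)]
  if (weighted) mean(abs(ut)) else mean(ut != 0)
}

#' Freeman degree centralisation
#'
#' Measures how skewed the distribution of actors' connections is: the sum
#' of differences between the maximum degree and every actor's degree,
#' normalised by its maximum `(|V|-1)(|V|-2)` (attained by a star). 0 for
#' regular graphs, 1 for a star. Computed on the binarised induced
#' subgraph; with `weighted = TRUE` degrees are replaced by strengths and
#' the same normalisation (times the maximum weight) is used.
#'
#' @param n an `actor_network`.
#' @param node_set character vector of actors (default: all); at least
#'   three.
#' @param weighted logical, default `FALSE`.
#' @return centralisation in [0, 1].
#' @export
centralisation <- function(n, node_set = actors(n), weighted = FALSE) {
  stopifnot(inherits(n, "actor_network"))
  check_node_set(n, node_set, min_size = 3, "centralisation")
  nn <- length(node_set)
  if (weighted) {
    w <- n$weights[node_set, node_set, drop = FALSE]
    s <- rowSums(abs(w))
    mx <- max(abs(w))
    if (mx == 0) return(0)
    sum(max(s) - s) / ((nn - 1) * (nn - 2) * mx)
  } else {
    d <- degree_within(n, node_set)
    sum(max(d) - d) / ((nn - 1) * (nn - 2))
  }
}

check_node_set <- function(n, node_set, min_size, what) {
  absent <- setdiff(node_set, actors(n))
  if (length(absent))
    stop(what, ": actor(s) not in network: ",
         paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  if (length(node_set) < min_size)
    stop(what, " undefined for fewer than ", min_size, " actors",
         call. = FALSE)
  invisible(TRUE)
}

#' External tie ratio
#'
#' For each actor, the number of its ties to actors outside its own
#' coalition as a proportion of all its ties; the scope value is the
#' unweighted mean of these per-actor ratios over the scoped actors. Low
#' values indicate a coalition (or a stakeholder type) closed off from the
#' opposing side; high values indicate many cross-coalition agreements.
#' Actors with zero ties have an undefined ratio and are excluded from the
#' mean; their number is reported.
#'
#' @param n an `actor_network` (ties counted on the binarised graph).
#' @param p a `coalition_partition` of `n`.
#' @param scope character vector of actors to average over; default all
#'   partitioned actors. Actors outside the partition (isolates) are
#'   dropped from scope.
#' @return list with `mean` (the scope average, `NA` if the scope is empty
#'   after exclusions, with a warning), `per_actor` (named vector) and
#'   `n_excluded` (zero-tie actors dropped).
#' @export
external_ratio <- function(n, p, scope = names(p$membership)) {
  stopifnot(inherits(n, "actor_network"),
            inherits(p, "coalition_partition"))
  scope <- intersect(scope, names(p$membership))
  adj <- n$weights != 0
  per <- rep(NA_real_, length(scope))
  names(per) <- scope
  memb_all <- p$membership
  for (a in scope) {
    nbrs <- actors(n)[adj[a, ]]
    total <- length(nbrs)
    if (total == 0) next
    ext <- sum(is.na(memb_all[nbrs]) | memb_all[nbrs] != memb_all[a])
    per[a] <- ext / total
  }
  excluded <- sum(is.na(per))
  kept <- per[!is.na(per)]
  if (!length(kept)) {
    warning("external ratio scope empty after excluding zero-tie actors",
            call. = FALSE)
    m <- NA_real_
  } else m <- mean(kept)
  list(mean = m, per_actor = per, n_excluded = excluded)
}

#' Coalition and whole-network measures table
#'
#' One row for the full network and one per coalition, reporting size,
#' degree centralisation (as a percentage), density and total external
#' ratio, in the layout used to describe the sugar-levy debate networks.
#' The full-network size counts every node including isolates; coalition
#' sizes count partitioned members. A companion table gives the average
#' external ratio by organisation type (actors of each type averaged
#' across their own coalitions).
#'
#' @param n an `actor_network`.
#' @param p a `coalition_partition` of `n`.
#' @param registry optional named character vector actor -> organisation
#'   type; defaults to the network's `org_type` attribute.
#' @return list of class `coalition_measures`: `table` (data frame of
#'   per-scope measures), `by_type` (data frame of average external ratio
#'   per organisation type), `n_isolates`, `n_zero_tie_excluded`.
#' @export
summarise_measures <- function(n, p, registry = n$org_type) {
  stopifnot(inherits(n, "actor_network"),
            inherits(p, "coalition_partition"))
  cluster_ids <- sort(unique(p$membership))
  scope_name <- function(c_id) {
    if (!is.null(p$cluster_labels) &&
        !is.na(p$cluster_labels[as.character(c_id)]))
      p$cluster_labels[as.character(c_id)]
    else paste0("coalition_", c_id)
  }
  rows <- list()
  full_n <- length(actors(n))
  rows[["full_network"]] <- data.frame(
    scope = "full_network",
    size = full_n,
    centralisation_pct = if (full_n >= 3) 100 * centralisation(n) else NA,
    density = if (full_n >= 2) network_density(n) else NA,
    external_ratio = NA_real_,
    stringsAsFactors = FALSE)
  excluded <- 0L
  for (c_id in cluster_ids) {
    members <- names(p$membership)[p$membership == c_id]
    er <- external_ratio(n, p, scope = members)
    excluded <- excluded + er$n_excluded
    rows[[length(rows) + 1]] <- data.frame(
      scope = scope_name(c_id),
      size = length(members),
      centralisation_pct = if (length(members) >= 3)
        100 * centralisation(n, members) else NA,
      density = if (length(members) >= 2)
        network_density(n, members) else NA,
      external_ratio = er$mean,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  registry <- registry[names(p$membership)]
  types <- sort(unique(registry[!is.na(registry)]))
  by_type <- data.frame(org_type = types,
                        external_ratio = rep(NA_real_, length(types)),
                        n_actors = rep(NA_integer_, length(types)),
                        stringsAsFactors = FALSE)
  for (i in seq_along(types)) {
    scoped <- names(registry)[!is.na(registry) & registry == types[i]]
    er <- suppressWarnings(external_ratio(n, p, scope = scoped))
    by_type$external_ratio[i] <- er$mean
    by_type$n_actors[i] <- sum(!is.na(er$per_actor))
  }

  structure(list(table = tab, by_type = by_type,
                 n_isolates = length(isolates(n)),
                 n_zero_tie_excluded = excluded),
            class = "coalition_measures")
}

#' @export
print.coalition_measures <- function(x, ...) {
  tab <- x$table
  tab$centralisation_pct <- round(tab$centralisation_pct, 1)
  tab$density <- round(tab$density, 2)
  tab$external_ratio <- round(tab$external_ratio, 2)
  print(tab, row.names = FALSE)
  if (x$n_isolates)
    cat("isolates (reported separately):", x$n_isolates, "\n")
  if (nrow(x$by_type)) {
    cat("\nAverage external ratio by organisation type:\n")
    bt <- x$by_type
    bt$external_ratio <- round(bt$external_ratio, 2)
    print(bt, row.names = FALSE)
  }
  invisible(x)
}

#' Write a measures report as CSV
#'
#' Writes the per-scope measures table, followed by the by-type external
#' ratios, mirroring the tabular layout of published coalition summaries.
#'
#' @param m a `coalition_measures` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_measures_csv <- function(m, path) {
  stopifnot(inherits(m, "coalition_measures"))
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.csv(m$table, con, row.names = FALSE)
  writeLines("", con)
  utils::write.csv(m$by_type, con, row.names = FALSE)
  invisible(path)
}
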