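#' Fit a discourse network model to a coded debate
#'
#' The central fitting function: from a set of coded statements it builds
#' the actor congruence network (stance aggregation, subtract
#' transformation with average activity normalisation, tie-weight
#' threshold), detects advocacy coalitions by Girvan-Newman
#' edge-betweenness clustering, optionally labels them supportive or
#' sceptical from a set of reference concepts, computes the coalition
#' measures table, and evaluates the network's bipolarisation (maximal
#' k = 2 modularity over the clustering ensemble).
#'
#' @param x a `statement_set` (see [read_statements()] /
#'   [statement_set()]), or a data frame acceptable to [statement_set()].
#' @param tau tie-weight threshold in (0, 1]; default 0.4.
#' @param count_ambivalent passed to [build_stances()].
#' @param pro_concepts optional character vector of concepts whose
#'   endorsement marks support for the policy; when given, coalitions are
#'   labelled supportive / sceptical.
#' @param methods clustering ensemble, default [k2_methods()].
#' @param seed master seed for stochastic ensemble members.
#' @return an object of class `discourse_network` with components
#'   `statements`, `stances`, `network` (normalised), `thresholded`,
#'   `partition`, `measures`, `bipolarisation`, `tau`, `seed`.
#' @examples
#' deb <- generate_debate(debate_config(n_actors_per_coalition = c(15, 15),
#'                                      n_statements = 600, seed = 7))
#' fit <- discourse_network(deb$statements,
#'                          pro_concepts = pro_concepts(deb$truth))
#' fit
#' summary(fit)
#' @export
discourse_network <- function(x, tau = 0.4, count_ambivalent = TRUE,
                              pro_concepts = NULL,
                              methods = k2_methods(), seed = 1L) {
  s <- if (inherits(x, "statement_set")) x else statement_set(x)
  stances <- build_stances(s, count_ambivalent = count_ambivalent)
  normalised <- subtract_normalise(stances)
  thresholded <- apply_threshold(normalised, tau = tau)
  partition <- girvan_newman(thresholded)
  if (!is.null(pro_concepts) && length(partition$membership))
    partition <- label_coalitions(partition, stances, pro_concepts)
  measures <- if (length(partition$membership))
    summarise_measures(thresholded, partition) else NULL
  bp <- bipolarisation(thresholded, methods = methods, seed = seed)
  structure(list(
    statements = s,
    stances = stances,
    network = normalised,
    thresholded = thresholded,
    partition = partition,
    measures = measures,
    bipolarisation = bp,
    tau = tau,
    seed = seed
  ), class = "discourse_network")
}

#' @export
print.discourse_network <- function(x, ...) {
  cat("Discourse network model\n")
  cat("  statements: ", nrow(x$statements$statements),
      " | actors: ", length(x$statements$actor_registry),
      " | concepts: ", length(x$statements$concept_registry), "\n", sep = "")
  cat("  threshold: ", x$tau, " | ties kept: ",
      sum(x$thresholded$weights[upper.tri(x$thresholded$weights)] != 0),
      " | isolates: ", length(isolates(x$thresholded)), "\n", sep = "")
  szs <- coalition_sizes(x$partition)
  cat("  coalitions (Girvan-Newman): ", length(szs), " of sizes ",
      paste(szs, collapse = "/"),
      ", Q = ", round(x$partition$modularity, 3), "\n", sep = "")
  cat("  bipolarisation (max k = 2 modularity): ",
      round(x$bipolarisation, 3), "\n", sep = "")
  invisible(x)
}

#' @export
summary.discourse_network <- function(object, ...) {
  structure(list(
    statements = summary(object$statements),
    tau = object$tau,
    partition = object$partition,
    measures = object$measures,
    bipolarisation = object$bipolarisation
  ), class = "summary.discourse_network")
}

#' @export
print.summary.discourse_network <- function(x, ...) {
  print(x$statements)
  cat("\nThreshold tau =", x$tau, "\n")
  print(x$partition)
  if (!is.null(x$measures)) {
    cat("\n")
    print(x$measures)
  }
  cat("\nBipolarisation (max k = 2 modularity):",
      round(x$bipolarisation, 4), "\n")
  invisible(x)
}

#' Plot a fitted discourse network
#'
#' Draws the thresholded network with nodes coloured by detected coalition
#' and sized by citation count (number of coded statements), the standard
#' way such debate networks are displayed.
#'
#' @param x a `discourse_network`.
#' @param ... passed to [igraph::plot.igraph()].
#' @return `x`, invisibly.
#' @export
plot.discourse_network <- function(x, ...) {
  net <- x$thresholded
  g <- as_igraph(net, drop_isolates = TRUE)
  lab <- coalition_labels_vector(x$partition, actors(net))
  cols <- c(supportive = "#2166ac", sceptical = "#b2182c",
            other = "grey60", isolate = "grey85")
  node_lab <- lab[igraph::V(g)$name]
  col <- ifelse(node_lab %in% names(cols), cols[node_lab], "grey40")
  cc <- igraph::V(g)$citation_count
  size <- if (all(is.na(cc))) 6 else 3 + 8 * sqrt(cc / max(cc, na.rm = TRUE))
  igraph::plot.igraph(g, vertex.color = col, vertex.size = size,
                      vertex.label = NA, ...)
  invisible(x)
}

#' Run the complete debate analysis and write a report bundle
#'
#' Orchestrates the full pipeline over three periods — the whole debate
#' and the sub-periods before and after a split date — and writes, per
#' period, the thresholded adjacency matrix (CSV), a GraphML export with
#' coalition attributes, the partition CSV and the measures CSV; plus the
#' sliding-window bipolarisation series (CSV and PNG) over the whole
#' debate, and a run log recording parameters and seed. All randomness
#' derives from the single master seed.
#'
#' @param statements a `statement_set`, or a path to a statement CSV/TSV.
#' @param out_dir output directory (created if absent).
#' @param tau tie-weight threshold.
#' @param split_date boundary between the two sub-periods (default
#'   2016-01-15, the mid-January split of the sugar-levy debate);
#'   `NULL` disables the period split.
#' @param window bipolarisation window size in statements; the series is
#'   skipped (with a log note) when the debate is shorter than one window.
#' @param span LOESS span for the smoothed curve.
#' @param pro_concepts optional concepts marking policy support, for
#'   coalition labelling.
#' @param seed master seed.
#' @param schema [statement_schema()] used when `statements` is a path.
#' @return invisibly, a named list of the per-period `discourse_network`
#'   fits and the `polarisation_series` (or `NULL`).
#' @export
run_full_analysis <- function(statements, out_dir, tau = 0.4,
                              split_date = as.Date("2016-01-15"),
                              window = 200L, span = 0.3,
                              pro_concepts = NULL, seed = 1L,
                              schema = statement_schema()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  s <- stage("ingest", {
    if (inherits(statements, "statement_set")) statements
    else read_statements(statements, schema = schema)
  })
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  logit <- function(...) writeLines(paste0(...), log_con)
  logit("discoursenet ", as.character(utils::packageVersion("discoursenet")),
        " | R ", R.version.string)
  logit("run at ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))
  logit("seed = ", seed, "; tau = ", tau, "; window = ", window,
        "; span = ", span,
        "; split_date = ", if (is.null(split_date)) "none"
        else format(as.Date(split_date)))
  logit("statements = ", nrow(s$statements), "; actors = ",
        length(s$actor_registry), "; concepts = ",
        length(s$concept_registry))

  periods <- list(full = s)
  if (!is.null(split_date) && nrow(s$statements)) {
    split_date <- as.Date(split_date)
    rng <- range(s$statements$date)
    if (split_date > rng[1] && split_date <= rng[2]) {
      periods$pre <- suppressWarnings(
        filter_window(s, time_window(rng[1], split_date)))
      periods$post <- suppressWarnings(
        filter_window(s, time_window(split_date, rng[2] + 1)))
    } else logit("split date outside data range; period split skipped")
  }

  fits <- list()
  for (per in names(periods)) {
    fits[[per]] <- stage(paste0("network[", per, "]"),
      discourse_network(periods[[per]], tau = tau,
                        pro_concepts = pro_concepts, seed = seed))
    fit <- fits[[per]]
    stage(paste0("export[", per, "]"), {
      write_matrix(fit$thresholded,
                   file.path(out_dir, paste0(per, "_network.csv")))
      write_graphml(fit$thresholded,
                    file.path(out_dir, paste0(per, "_network.graphml")),
                    partition = fit$partition)
      write_partition_csv(fit$partition,
                          file.path(out_dir, paste0(per, "_partition.csv")),
                          network = fit$thresholded)
      if (!is.null(fit$measures))
        write_measures_csv(fit$measures,
                           file.path(out_dir, paste0(per, "_measures.csv")))
    })
    logit("period ", per, ": ", nrow(periods[[per]]$statements),
          " statements; coalitions ",
          paste(coalition_sizes(fit$partition), collapse = "/"),
          "; bipolarisation ", round(fit$bipolarisation, 4))
  }

  series <- NULL
  if (nrow(s$statements) >= window) {
    series <- stage("polarisation", {
      ser <- polarisation_series(s, window = window, tau = tau, seed = seed)
      ok <- sum(!is.na(ser$points$bipolarisation))
      if (ok >= 5 && span * ok >= 2) ser <- loess_smooth(ser, span = span)
      ser
    })
    stage("polarisation export", {
      write_series_csv(series, file.path(out_dir, "polarisation.csv"))
      grDevices::png(file.path(out_dir, "polarisation.png"),
                     width = 900, height = 450)
      plot(series, main = "Bipolarisation over the debate")
      grDevices::dev.off()
    })
    logit("polarisation series: ", nrow(series$points), " windows")
  } else logit("debate shorter than one window (", window,
               "); polarisation series skipped")

  invisible(c(fits, list(polarisation = series)))
}
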