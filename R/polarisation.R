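#' Bipolarisation of an actor network
#'
#' The tendency of the network to fall into exactly two coalitions:
#' the maximal modularity over the two-cluster partitions proposed by the
#' clustering ensemble (see [cluster_k2_ensemble()]). Values near 0.5
#' indicate two dense, mutually segregated coalitions with few
#' intermediaries; values at or below 0 indicate no two-way split better
#' than chance.
#'
#' @param n an `actor_network`.
#' @param methods ensemble member list, default [k2_methods()].
#' @param seed master seed for the stochastic ensemble members.
#' @return maximal modularity (a single value), or `NA` for a degenerate
#'   network with fewer than two non-isolate actors.
#' @export
bipolarisation <- function(n, methods = k2_methods(), seed = 1L) {
  stopifnot(inherits(n, "actor_network"))
  if (length(setdiff(actors(n), isolates(n))) < 2) return(NA_real_)
  ens <- suppressWarnings(cluster_k2_ensemble(n, methods, seed))
  if (!length(ens)) return(NA_real_)
  max(vapply(ens, function(p) p$modularity, numeric(1)), na.rm = TRUE)
}

#' Sliding-window bipolarisation series
#'
#' Slides a window of `window` consecutive statements (in date order, one
#' statement at a time) along the debate; for each window the full network
#' pipeline is run — stance aggregation, subtract transformation with
#' average activity normalisation, thresholding — and bipolarisation is
#' computed on the resulting network. Each point is dated at the median
#' statement of its window. Windows whose network is degenerate (fewer
#' than two connected actors) yield `NA` and appear as gaps.
#'
#' @param s a `statement_set` with at least `window` statements.
#' @param window window size in statements; default 200.
#' @param tau tie-weight threshold passed to [apply_threshold()].
#' @param count_ambivalent passed to [build_stances()].
#' @param methods,seed passed to [bipolarisation()].
#' @return an object of class `polarisation_series`: data frame `points`
#'   with columns `window_index`, `centre_date`, `bipolarisation`, plus
#'   the window size; smoothing is added by [loess_smooth()].
#' @export
polarisation_series <- function(s, window = 200L, tau = 0.4,
                                count_ambivalent = TRUE,
                                methods = k2_methods(), seed = 1L) {
  stopifnot(inherits(s, "statement_set"))
  st <- s$statements
  N <- nrow(st)
  if (N < window)
    stop("only ", N, " statements but window = ", window,
         "; use a smaller window", call. = FALSE)
  n_win <- N - window + 1L
  mid_off <- as.integer(ceiling(window / 2)) - 1L
  vals <- rep(NA_real_, n_win)
  centres <- st$date[seq_len(n_win) + mid_off]
  for (i in seq_len(n_win)) {
    sub <- st[i:(i + window - 1L), , drop = FALSE]
    reg <- sub[!duplicated(sub$organisation), c("organisation", "org_type")]
    ss <- structure(list(
      statements = sub,
      actor_registry = stats::setNames(reg$org_type, reg$organisation),
      concept_registry = sort(unique(sub$concept))
    ), class = "statement_set")
    net <- statements_to_network(ss, tau = tau,
                                 count_ambivalent = count_ambivalent)
    vals[i] <- bipolarisation(net, methods = methods, seed = seed)
  }
  structure(list(
    points = data.frame(window_index = seq_len(n_win),
                        centre_date = centres,
                        bipolarisation = vals),
    window_size = as.integer(window),
    smoothed = NULL,
    loess_span = NULL
  ), class = "polarisation_series")
}

#' @export
print.polarisation_series <- function(x, ...) {
  p <- x$points
  ok <- !is.na(p$bipolarisation)
  cat("Bipolarisation series: ", nrow(p), " windows of ",
      x$window_size, " statements (", sum(!ok), " degenerate)\n", sep = "")
  if (any(ok))
    cat("  values ", round(min(p$bipolarisation[ok]), 3), " .. ",
        round(max(p$bipolarisation[ok]), 3),
        "; dates ", format(min(p$centre_date)), " .. ",
        format(max(p$centre_date)), "\n", sep = "")
  if (!is.null(x$smoothed))
    cat("  LOESS smoothed (span ", x$loess_span, ")\n", sep = "")
  invisible(x)
}

#' LOESS-smooth a bipolarisation series
#'
#' Fits a locally weighted polynomial regression of the bipolarisation
#' values on the window index (windows contain equal numbers of
#' statements, so index spacing is the natural abscissa) and attaches the
#' fitted curve. Degenerate (`NA`) windows are excluded from the fit and
#' remain gaps.
#'
#' @param series a `polarisation_series` with at least 5 non-missing
#'   points.
#' @param span LOESS span in (0, 1]; default 0.3.
#' @param degree local polynomial degree, 1 (default) or 2.
#' @return the series with `smoothed` (data frame `window_index`,
#'   `centre_date`, `fitted`) and `loess_span` filled in; the raw points
#'   are unchanged.
#' @export
loess_smooth <- function(series, span = 0.3, degree = 1) {
  stopifnot(inherits(series, "polarisation_series"))
  if (!is.numeric(span) || length(span) != 1 || span <= 0 || span > 1)
    stop("span must be a single value in (0, 1]", call. = FALSE)
  if (!degree %in% c(1, 2)) stop("degree must be 1 or 2", call. = FALSE)
  p <- series$points
  ok <- !is.na(p$bipolarisation)
  if (sum(ok) < 5)
    stop("LOESS smoothing needs at least 5 non-missing points",
         call. = FALSE)
  if (span * sum(ok) < degree + 1)
    stop("span ", span, " covers fewer than ", degree + 1,
         " points; increase the span", call. = FALSE)
  fit <- tryCatch(
    stats::loess(bipolarisation ~ window_index, data = p[ok, ],
                 span = span, degree = degree,
                 family = "gaussian",
                 control = stats::loess.control(surface = "direct")),
    error = function(e)
      stop("LOESS fit failed (span ", span, "): ", conditionMessage(e),
           call. = FALSE))
  series$smoothed <- data.frame(
    window_index = p$window_index[ok],
    centre_date = p$centre_date[ok],
    fitted = as.numeric(stats::predict(fit, p$window_index[ok])))
  series$loess_span <- span
  series
}

#' Plot a bipolarisation series
#'
#' Raw windowed bipolarisation values over time with the LOESS curve (if
#' attached) overlaid.
#'
#' @param x a `polarisation_series`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.polarisation_series <- function(x, ...) {
  p <- x$points
  graphics::plot(p$centre_date, p$bipolarisation, type = "l",
                 col = "grey55", xlab = "window centre date",
                 ylab = "bipolarisation (max k = 2 modularity)", ...)
  if (!is.null(x$smoothed))
    graphics::lines(x$smoothed$centre_date, x$smoothed$fitted,
                    col = "firebrick", lwd = 2)
  invisible(x)
}

#' Write a bipolarisation series as CSV
#'
#' @param series a `polarisation_series`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "polarisation_series"))
  out <- series$points
  out$smoothed <- NA_real_
  if (!is.null(series$smoothed))
    out$smoothed[match(series$smoothed$window_index, out$window_index)] <-
      series$smoothed$fitted
  out$centre_date <- format(out$centre_date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
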