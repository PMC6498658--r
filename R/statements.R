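#' Column mapping and polarity vocabulary for statement tables
#'
#' Describes how a delimited statement table maps onto the fields of a coded
#' statement: who said it (person and organisation), what kind of actor the
#' organisation is, which concept the statement refers to, whether the actor
#' agreed or disagreed, when, and in which article. Coding-tool exports differ
#' in their headers, so the mapping is explicit rather than guessed.
#'
#' @param person,organisation,org_type,concept,agreement,date,article_id
#'   column names in the input file for each statement field.
#' @param true_values,false_values character vectors of accepted spellings of
#'   the agree / disagree polarity (matched case-insensitively).
#' @return an object of class `statement_schema`.
#' @export
statement_schema <- function(person = "person",
                             organisation = "organisation",
                             org_type = "org_type",
                             concept = "concept",
                             agreement = "agreement",
                             date = "date",
                             article_id = "article_id",
                             true_values = c("agree", "true", "yes", "1"),
                             false_values = c("disagree", "false", "no", "0")) {
  structure(list(
    columns = c(person = person, organisation = organisation,
                org_type = org_type, concept = concept,
                agreement = agreement, date = date, article_id = article_id),
    true_values = tolower(true_values),
    false_values = tolower(false_values)
  ), class = "statement_schema")
}

#' Construct a statement set from a data frame
#'
#' A statement is one coded attribution: an actor (an organisation, or a
#' self-standing individual registered as their own actor) agreeing or
#' disagreeing with a concept in one article on one date. The set keeps
#' statements sorted by (date, article id, input order) so that every
#' downstream computation — in particular the sliding statement windows of
#' the bipolarisation series — is deterministic on tied dates.
#'
#' @param data data frame with columns `person`, `organisation`, `org_type`,
#'   `concept`, `agreement` (logical: `TRUE` = agree), `date` (`Date` or
#'   ISO-8601 string), `article_id`.
#' @param study_window optional [time_window()]; when given, statements are
#'   required to fall inside it.
#' @return an object of class `statement_set`: the sorted statement table plus
#'   an actor registry (organisation -> organisation type) and the concept
#'   registry.
#' @export
statement_set <- function(data, study_window = NULL) {
  required <- c("person", "organisation", "org_type", "concept",
                "agreement", "date", "article_id")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("statement table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  data <- as.data.frame(data)[required]
  data$person <- as.character(data$person)
  data$person[is.na(data$person)] <- ""
  data$organisation <- as.character(data$organisation)
  data$org_type <- as.character(data$org_type)
  data$concept <- as.character(data$concept)
  data$article_id <- as.character(data$article_id)
  if (!inherits(data$date, "Date")) data$date <- as.Date(data$date)

  bad <- !nzchar(data$organisation) | is.na(data$organisation)
  if (any(bad))
    stop(sum(bad), " statement(s) with empty organisation (rows ",
         paste(utils::head(which(bad), 5), collapse = ", "), " ...)",
         call. = FALSE)
  bad <- !nzchar(data$concept) | is.na(data$concept)
  if (any(bad))
    stop(sum(bad), " statement(s) with empty concept", call. = FALSE)
  if (!is.logical(data$agreement) || anyNA(data$agreement))
    stop("agreement must be strictly binary (logical, no missing values)",
         call. = FALSE)
  if (anyNA(data$date))
    stop(sum(is.na(data$date)), " statement(s) with unparseable date",
         call. = FALSE)
  if (!is.null(study_window)) {
    out <- data$date < study_window$start | data$date >= study_window$end
    if (any(out))
      stop(sum(out), " statement(s) dated outside the study window ",
           format(study_window$start), " .. ", format(study_window$end),
           call. = FALSE)
  }

  ord <- order(data$date, data$article_id, seq_len(nrow(data)))
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL

  reg <- data[!duplicated(data$organisation), c("organisation", "org_type")]
  actor_registry <- stats::setNames(reg$org_type, reg$organisation)

  structure(list(
    statements = data,
    actor_registry = actor_registry,
    concept_registry = sort(unique(data$concept))
  ), class = "statement_set")
}

#' @export
print.statement_set <- function(x, ...) {
  s <- x$statements
  cat("Statement set:", nrow(s), "statements |",
      length(x$actor_registry), "actors |",
      length(x$concept_registry), "concepts\n")
  if (nrow(s))
    cat("  dates ", format(min(s$date)), " .. ", format(max(s$date)),
        "; ", length(unique(s$person[nzchar(s$person)])),
        " named persons; ", length(unique(s$article_id)),
        " articles\n", sep = "")
  invisible(x)
}

#' @export
summary.statement_set <- function(object, ...) {
  s <- object$statements
  out <- list(
    n_statements = nrow(s),
    n_actors = length(object$actor_registry),
    n_concepts = length(object$concept_registry),
    n_persons = length(unique(s$person[nzchar(s$person)])),
    n_articles = length(unique(s$article_id)),
    date_range = if (nrow(s)) range(s$date) else as.Date(character()),
    agreement_rate = if (nrow(s)) mean(s$agreement) else NA_real_
  )
  class(out) <- "summary.statement_set"
  out
}

#' @export
print.summary.statement_set <- function(x, ...) {
  cat("Statements: ", x$n_statements,
      " (", round(100 * x$agreement_rate, 1), "% agree)\n",
      "Actors: ", x$n_actors, "  Persons: ", x$n_persons,
      "  Concepts: ", x$n_concepts, "  Articles: ", x$n_articles, "\n",
      sep = "")
  if (length(x$date_range))
    cat("Dates: ", format(x$date_range[1]), " .. ",
        format(x$date_range[2]), "\n", sep = "")
  invisible(x)
}

#' Half-open time window
#'
#' Windows follow the half-open convention `[start, end)`: a statement dated
#' exactly on `end` belongs to the next period. This makes consecutive
#' periods partition the debate without double counting — e.g. the split of
#' the sugar-levy debate at mid-January 2016 into a before and an after
#' period.
#'
#' @param start,end dates (or ISO-8601 strings); `start < end`.
#' @return an object of class `time_window`.
#' @export
time_window <- function(start, end) {
  parse <- function(x) tryCatch(as.Date(x), error = function(e) NA)
  start <- parse(start); end <- parse(end)
  if (anyNA(c(start, end))) stop("unparseable window date", call. = FALSE)
  if (!(start < end)) stop("time window requires start < end", call. = FALSE)
  structure(list(start = start, end = end), class = "time_window")
}

#' Read coded statements from a delimited file
#'
#' Reads a long-format table (one statement per row) and validates it into a
#' [statement_set()]. The separator is taken from the file extension
#' (`.tsv` = tab, otherwise comma). Malformed rows are reported with their
#' file line numbers.
#'
#' @param path path to a CSV/TSV file with a header row.
#' @param schema a [statement_schema()] mapping file columns to statement
#'   fields.
#' @param study_window optional [time_window()] to enforce during validation.
#' @return a `statement_set`.
#' @export
read_statements <- function(path, schema = statement_schema(),
                            study_window = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0)
    stop("statement file is empty: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", fill = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0)
    stop("statement file is empty (no data rows): ", path, call. = FALSE)
  cols <- schema$columns
  missing_cols <- cols[!cols %in% names(raw)]
  if (length(missing_cols))
    stop("statement file lacks mapped column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  # file line = data row + header line
  line_no <- seq_len(nrow(raw)) + 1L

  agr_raw <- tolower(trimws(raw[[cols[["agreement"]]]]))
  agreement <- rep(NA, length(agr_raw))
  agreement[agr_raw %in% schema$true_values] <- TRUE
  agreement[agr_raw %in% schema$false_values] <- FALSE
  bad_agr <- is.na(agreement)

  date <- as.Date(raw[[cols[["date"]]]], format = "%Y-%m-%d")
  bad_date <- is.na(date)

  if (any(bad_agr) || any(bad_date)) {
    msg <- character()
    if (any(bad_agr))
      msg <- c(msg, paste0(sum(bad_agr), " row(s) with unrecognised ",
                           "agreement value (lines ",
                           paste(utils::head(line_no[bad_agr], 5),
                                 collapse = ", "), ")"))
    if (any(bad_date))
      msg <- c(msg, paste0(sum(bad_date), " row(s) with unparseable date ",
                           "(lines ",
                           paste(utils::head(line_no[bad_date], 5),
                                 collapse = ", "), ")"))
    stop(paste(msg, collapse = "; "), call. = FALSE)
  }

  statement_set(data.frame(
    person = raw[[cols[["person"]]]],
    organisation = raw[[cols[["organisation"]]]],
    org_type = raw[[cols[["org_type"]]]],
    concept = raw[[cols[["concept"]]]],
    agreement = agreement,
    date = date,
    article_id = raw[[cols[["article_id"]]]],
    stringsAsFactors = FALSE
  ), study_window = study_window)
}

#' Write a statement set to CSV
#'
#' Writes the canonicalised table (sorted, ISO dates); reading it back with
#' [read_statements()] reproduces the set exactly.
#'
#' @param s a `statement_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_statements <- function(s, path) {
  stopifnot(inherits(s, "statement_set"))
  out <- s$statements
  out$date <- format(out$date, "%Y-%m-%d")
  out$agreement <- ifelse(out$agreement, "agree", "disagree")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Restrict a statement set to a time window
#'
#' Keeps statements with `start <= date < end` and restricts both registries
#' to actors and concepts that retain at least one statement. A window that
#' covers no statements yields an empty set with a warning rather than an
#' error, so that period sweeps need no special-casing.
#'
#' @param s a `statement_set`.
#' @param window a [time_window()].
#' @return a `statement_set`.
#' @export
filter_window <- function(s, window) {
  stopifnot(inherits(s, "statement_set"), inherits(window, "time_window"))
  keep <- s$statements$date >= window$start & s$statements$date < window$end
  if (!any(keep))
    warning("time window ", format(window$start), " .. ",
            format(window$end), " contains no statements", call. = FALSE)
  out <- s$statements[keep, , drop = FALSE]
  rownames(out) <- NULL
  reg <- out[!duplicated(out$organisation), c("organisation", "org_type")]
  structure(list(
    statements = out,
    actor_registry = stats::setNames(reg$org_type, reg$organisation),
    concept_registry = sort(unique(out$concept))
  ), class = "statement_set")
}

#' Read a weighted actor-by-actor adjacency matrix
#'
#' Reads a square labelled CSV matrix of the shape produced by discourse
#' network coding software when exporting one-mode actor networks (first row
#' and first column hold the actor labels). Whether such an export is raw,
#' normalised or already thresholded is generally not recorded in the file,
#' so the resulting network is marked with processing stage `"unknown"`
#' unless stated.
#'
#' @param path path to the CSV file.
#' @param stage processing stage to record on the network; default
#'   `"unknown"`.
#' @param tol tolerance for accepting numerically symmetric input; larger
#'   asymmetries are an error naming the offending pair.
#' @return an `actor_network`.
#' @export
read_matrix <- function(path, stage = "unknown", tol = 1e-9) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, header = TRUE, row.names = 1,
                         check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(raw)
  if (nrow(m) != ncol(m))
    stop("adjacency matrix is not square: ", nrow(m), " rows vs ",
         ncol(m), " columns", call. = FALSE)
  if (!is.numeric(m))
    stop("adjacency matrix has non-numeric cells", call. = FALSE)
  if (!identical(rownames(m), colnames(m))) {
    off <- which(rownames(m) != colnames(m))
    stop("row/column labels differ at position(s) ",
         paste(utils::head(off, 5), collapse = ", "), ": ",
         paste(utils::head(paste0(rownames(m)[off], " vs ",
                                  colnames(m)[off]), 3), collapse = "; "),
         call. = FALSE)
  }
  asym <- abs(m - t(m))
  if (any(asym > tol)) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop("adjacency matrix is asymmetric beyond tolerance at (",
         rownames(m)[ij[1]], ", ", colnames(m)[ij[2]], "): ",
         m[ij[1], ij[2]], " vs ", m[ij[2], ij[1]], call. = FALSE)
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  actor_network(m, stage = stage)
}

#' Write an actor network as a labelled CSV adjacency matrix
#'
#' @param n an `actor_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(n, path) {
  stopifnot(inherits(n, "actor_network"))
  utils::write.csv(as.data.frame(n$weights), path, row.names = TRUE)
  invisible(path)
}
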