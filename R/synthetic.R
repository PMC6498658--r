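#' Configuration for a synthetic two-coalition debate
#'
#' Describes the generative model used for validation: two latent advocacy
#' coalitions ("supportive" and "sceptical" of the debated policy) plus
#' optional intermediaries, a fixed concept vocabulary with per-concept
#' coalition polarity, skewed actor activity, and a stance-noise level
#' that may change over the debate.
#'
#' The generative assumptions: each emitted statement picks its actor from
#' a discretised power-law activity distribution (a few actors dominate
#' the debate, as celebrity campaigners and lead agencies do in real media
#' debates), its concept uniformly, and its date uniformly over the study
#' range; a coalition member takes its coalition's preferred stance on the
#' concept with probability `p_on_message` and the opposite stance
#' otherwise, while intermediaries take either stance with equal
#' probability.
#'
#' @param n_actors_per_coalition integer pair: supportive and sceptical
#'   coalition sizes.
#' @param n_intermediaries number of unaligned intermediary actors.
#' @param n_concepts number of concepts; each concept is assigned a
#'   preferred stance for the supportive coalition (+1 agree / -1
#'   disagree, half each by default), the sceptical coalition preferring
#'   the opposite.
#' @param p_on_message probability that a coalition member's statement
#'   follows its coalition's polarity (1 - stance noise).
#' @param activity_skew tail exponent of the power-law (Pareto) actor
#'   activity distribution: each actor's emission weight is drawn from a
#'   Pareto law with this exponent, so a few actors dominate the debate
#'   while most speak occasionally; 0 gives uniform activity.
#' @param n_statements total number of statements to emit.
#' @param date_range pair of dates bounding the debate.
#' @param polarisation_schedule optional data frame with columns `from`
#'   (date) and `p_on_message`, overriding `p_on_message` piecewise over
#'   time (each row applies from its date to the next row's date).
#' @param seed integer seed; the generated debate is fully reproducible
#'   from it.
#' @return an object of class `debate_config`.
#' @export
debate_config <- function(n_actors_per_coalition = c(40L, 40L),
                          n_intermediaries = 6L,
                          n_concepts = 20L,
                          p_on_message = 0.95,
                          activity_skew = 1.5,
                          n_statements = 3000L,
                          date_range = as.Date(c("2015-05-01",
                                                 "2016-11-30")),
                          polarisation_schedule = NULL,
                          seed = 1L) {
  date_range <- as.Date(date_range)
  stopifnot(length(n_actors_per_coalition) == 2,
            all(n_actors_per_coalition >= 1),
            n_intermediaries >= 0, n_concepts >= 1, n_statements >= 1,
            p_on_message >= 0, p_on_message <= 1,
            activity_skew >= 0,
            length(date_range) == 2, !anyNA(date_range),
            date_range[1] <= date_range[2])
  if (!is.null(polarisation_schedule)) {
    stopifnot(is.data.frame(polarisation_schedule),
              all(c("from", "p_on_message") %in%
                    names(polarisation_schedule)))
    polarisation_schedule$from <- as.Date(polarisation_schedule$from)
    stopifnot(!anyNA(polarisation_schedule$from),
              all(polarisation_schedule$p_on_message >= 0),
              all(polarisation_schedule$p_on_message <= 1),
              polarisation_schedule$from[1] <= date_range[1])
  }
  structure(list(
    n_actors_per_coalition = as.integer(n_actors_per_coalition),
    n_intermediaries = as.integer(n_intermediaries),
    n_concepts = as.integer(n_concepts),
    p_on_message = p_on_message,
    activity_skew = activity_skew,
    n_statements = as.integer(n_statements),
    date_range = date_range,
    polarisation_schedule = polarisation_schedule,
    seed = as.integer(seed)
  ), class = "debate_config")
}

org_type_pools <- list(
  supportive = c("Health charity", "Campaign group",
                 "Professional association", "Advisory body", "NHS",
                 "International body"),
  sceptical = c("Soft drinks industry", "Food and drink industry",
                "Retailer/Retail association", "Think tank/Analyst",
                "Restaurant"),
  intermediary = c("University/Academic", "Political party",
                   "Government department")
)

#' Generate a synthetic debate with known ground truth
#'
#' Draws a statement stream from the generative model described in
#' [debate_config()] and returns both the resulting [statement_set()] and
#' the ground truth (which coalition each actor was planted in), so that
#' every stage of the network pipeline can be validated against known
#' structure.
#'
#' @param cfg a `debate_config`.
#' @return list with components `statements` (a `statement_set`) and
#'   `truth` (class `debate_truth`: named vector `coalition_of` with
#'   values `supportive` / `sceptical` / `intermediary`, plus the config).
#' @export
generate_debate <- function(cfg = debate_config()) {
  stopifnot(inherits(cfg, "debate_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  n_sup <- cfg$n_actors_per_coalition[1]
  n_sce <- cfg$n_actors_per_coalition[2]
  n_int <- cfg$n_intermediaries
  acts <- c(sprintf("SUP_%03d", seq_len(n_sup)),
            sprintf("SCE_%03d", seq_len(n_sce)),
            if (n_int) sprintf("INT_%03d", seq_len(n_int)))
  coalition_of <- stats::setNames(
    rep(c("supportive", "sceptical", "intermediary"),
        c(n_sup, n_sce, n_int)), acts)
  org_type <- stats::setNames(unlist(lapply(
    c("supportive", "sceptical", "intermediary")[c(rep(1, n_sup),
                                                   rep(2, n_sce),
                                                   rep(3, n_int))],
    function(side) sample(org_type_pools[[side]], 1))), acts)

  concepts <- sprintf("concept_%02d", seq_len(cfg$n_concepts))
  # preferred stance of the supportive coalition per concept (+1 agree,
  # -1 disagree), half each; sceptical takes the opposite
  polarity <- stats::setNames(
    rep_len(c(1, -1), cfg$n_concepts)[sample(cfg$n_concepts)], concepts)

  # Pareto-distributed activity weights: heavy upper tail without handing
  # one actor the majority of all statements
  wts <- if (cfg$activity_skew > 0)
    stats::runif(length(acts))^(-1 / cfg$activity_skew)
  else rep(1, length(acts))
  wts <- wts / sum(wts)

  N <- cfg$n_statements
  who <- sample(acts, N, replace = TRUE, prob = wts)
  span_days <- as.integer(cfg$date_range[2] - cfg$date_range[1])
  when <- cfg$date_range[1] +
    sort(sample.int(span_days + 1L, N, replace = TRUE) - 1L)
  what <- sample(concepts, N, replace = TRUE)

  p_at <- rep(cfg$p_on_message, N)
  sched <- cfg$polarisation_schedule
  if (!is.null(sched)) {
    idx <- findInterval(as.numeric(when), as.numeric(sched$from))
    p_at <- sched$p_on_message[pmax(idx, 1L)]
  }

  side <- coalition_of[who]
  preferred <- ifelse(side == "supportive", polarity[what],
                      ifelse(side == "sceptical", -polarity[what], NA))
  on_message <- stats::runif(N) < p_at
  stance <- ifelse(is.na(preferred),
                   sample(c(1, -1), N, replace = TRUE),
                   ifelse(on_message, preferred, -preferred))
  agreement <- stance > 0

  # consecutive same-day statements are grouped into articles of 1-5
  n_art_max <- ceiling(N / 1)
  art_sizes <- sample(1:5, N, replace = TRUE)
  art_id <- rep(seq_along(art_sizes), art_sizes)[seq_len(N)]
  article_id <- sprintf("art_%05d", art_id)

  # a minority of statements carry a named spokesperson
  person <- ifelse(stats::runif(N) < 0.3,
                   paste(who, "spokesperson"), "")

  s <- statement_set(data.frame(
    person = person,
    organisation = who,
    org_type = unname(org_type[who]),
    concept = what,
    agreement = agreement,
    date = when,
    article_id = article_id,
    stringsAsFactors = FALSE))

  truth <- structure(list(coalition_of = coalition_of,
                          polarity = polarity,
                          config = cfg),
                     class = "debate_truth")
  list(statements = s, truth = truth)
}

#' @export
print.debate_truth <- function(x, ...) {
  tab <- table(x$coalition_of)
  cat("Planted debate:", paste(names(tab), tab, collapse = ", "), "\n")
  invisible(x)
}

#' Concepts whose endorsement marks policy support
#'
#' Convenience accessor for labelling detected coalitions on synthetic
#' debates: the concepts on which the planted supportive coalition agrees.
#'
#' @param truth a `debate_truth`.
#' @return character vector of concept identifiers.
#' @export
pro_concepts <- function(truth) {
  stopifnot(inherits(truth, "debate_truth"))
  names(truth$polarity)[truth$polarity > 0]
}

#' Coalition recovery score (adjusted Rand index)
#'
#' Compares a detected partition against the planted coalitions.
#' Intermediaries have no planted side and are excluded; actors absent
#' from the partition (isolates) are likewise excluded. ARI is 1 for
#' perfect recovery and has expectation 0 under random labelling.
#'
#' @param truth a `debate_truth`.
#' @param p a `coalition_partition`.
#' @return adjusted Rand index.
#' @export
evaluate_recovery <- function(truth, p) {
  stopifnot(inherits(truth, "debate_truth"),
            inherits(p, "coalition_partition"))
  planted <- truth$coalition_of[truth$coalition_of != "intermediary"]
  shared <- intersect(names(planted), names(p$membership))
  if (!length(shared))
    stop("partition and planted coalitions share no actors", call. = FALSE)
  mclust::adjustedRandIndex(planted[shared], p$membership[shared])
}
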