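#' Deterministic exact-match record linkage
#'
#' Links each survey row to the admission episodes that agree exactly on
#' every one of the `key_fields` (default: the ten-variable identifier key).
#' A survey row with exactly one candidate episode is a unique (1:1) match;
#' with two or more, a one-to-many (1:M) match; with none, unmatched. The
#' three classes partition the survey, and the result is independent of the
#' row order of either input.
#'
#' One refinement beyond survey-side multiplicity: if a single admission
#' episode is the unique candidate of two or more survey rows, one episode
#' cannot belong to several respondents, so all involved survey rows are
#' demoted to one-to-many. The demoted ids are reported separately in
#' `reverse_demoted` so the effect is auditable.
#'
#' Candidate lookup is by composite-key equality (a hash join on the
#' concatenated key), with no fuzzy tolerance on any field.
#'
#' @param survey Standardized survey tibble with a `survey_id` column.
#' @param admission_candidates Standardized candidate episodes with an
#'   `episode_id` and `pseudo_id` column.
#' @param key_fields Columns to match on; must exist in both tables.
#' @return A `linkage_result`: list with `unique_pairs` (tibble `survey_id`,
#'   `episode_id`, `pseudo_id`), `one_to_many_ids`, `unmatched_ids`,
#'   `reverse_demoted`, `matching_rate` and `n_survey`.
#' @export
link_deterministic <- function(survey, admission_candidates,
                               key_fields = identifier_keys()) {
  missing_s <- setdiff(key_fields, names(survey))
  missing_a <- setdiff(key_fields, names(admission_candidates))
  if (length(missing_s) || length(missing_a)) {
    stop("configuration error: key field(s) absent from input: ",
         paste(unique(c(missing_s, missing_a)), collapse = ", "),
         call. = FALSE)
  }
  if (!"survey_id" %in% names(survey)) {
    stop("survey input needs a 'survey_id' column", call. = FALSE)
  }

  composite <- function(df) {
    do.call(paste, c(lapply(df[key_fields], as.character), sep = "\r"))
  }
  skey <- composite(survey)
  akey <- composite(admission_candidates)

  counts <- table(akey)
  n_cand <- as.integer(counts[skey])
  n_cand[is.na(n_cand)] <- 0L

  unmatched_ids <- survey$survey_id[n_cand == 0L]
  multi_ids <- survey$survey_id[n_cand >= 2L]
  uni <- which(n_cand == 1L)

  # the single candidate episode of each uniquely matched survey row
  first_idx <- match(skey[uni], akey)
  pairs <- tibble::tibble(
    survey_id = survey$survey_id[uni],
    episode_id = admission_candidates$episode_id[first_idx],
    pseudo_id = admission_candidates$pseudo_id[first_idx])

  # reverse multiplicity: an episode claimed by >= 2 survey rows
  dup_ep <- unique(pairs$episode_id[duplicated(pairs$episode_id)])
  reverse_demoted <- sort(pairs$survey_id[pairs$episode_id %in% dup_ep])
  if (length(reverse_demoted)) {
    multi_ids <- c(multi_ids, reverse_demoted)
    pairs <- pairs[!(pairs$survey_id %in% reverse_demoted), , drop = FALSE]
  }

  pairs <- pairs[order(pairs$survey_id), , drop = FALSE]
  n_survey <- nrow(survey)
  structure(list(
    unique_pairs = pairs,
    one_to_many_ids = sort(multi_ids),
    unmatched_ids = sort(unmatched_ids),
    reverse_demoted = reverse_demoted,
    matching_rate = if (n_survey > 0) nrow(pairs) / n_survey else NA_real_,
    n_survey = n_survey),
    class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  cat("<linkage_result> ", x$n_survey, " survey rows: ",
      nrow(x$unique_pairs), " unique, ", length(x$one_to_many_ids),
      " one-to-many, ", length(x$unmatched_ids), " unmatched",
      if (!is.na(x$matching_rate))
        sprintf(" (matching rate %.1f%%)", 100 * x$matching_rate) else "",
      "\n", sep = "")
  invisible(x)
}

#' Linkage summary from class counts
#'
#' Computes the matching-rate arithmetic from the three class counts:
#' matching rate = unique / total; the one-to-many and unmatched classes are
#' expressed both as shares of the whole survey and as shares of the
#' non-unique remainder.
#'
#' @param n_unique,n_one_to_many,n_unmatched Non-negative class counts.
#' @return List of counts, `matching_rate_pct`, per-class percentages of
#'   total (`*_pct`) and of the non-unique subset (`*_pct_nonunique`). With
#'   zero survey rows every percentage is `NA` (defined empty report).
#' @export
matching_summary <- function(n_unique, n_one_to_many, n_unmatched) {
  stopifnot(n_unique >= 0, n_one_to_many >= 0, n_unmatched >= 0)
  n_total <- n_unique + n_one_to_many + n_unmatched
  n_nonunique <- n_one_to_many + n_unmatched
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  list(
    n_survey = n_total,
    n_unique = n_unique,
    n_one_to_many = n_one_to_many,
    n_unmatched = n_unmatched,
    n_nonunique = n_nonunique,
    matching_rate_pct = pct(n_unique, n_total),
    one_to_many_pct = pct(n_one_to_many, n_total),
    unmatched_pct = pct(n_unmatched, n_total),
    one_to_many_pct_nonunique = pct(n_one_to_many, n_nonunique),
    unmatched_pct_nonunique = pct(n_unmatched, n_nonunique))
}

#' Summary report of a linkage result
#'
#' @param result A `linkage_result` from [link_deterministic()].
#' @return The [matching_summary()] of its class counts.
#' @export
matching_report <- function(result) {
  stopifnot(inherits(result, "linkage_result"))
  matching_summary(nrow(result$unique_pairs),
                   length(result$one_to_many_ids),
                   length(result$unmatched_ids))
}
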