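# Manual-verification support: seeded sampling of working lists for human
# review, capture of review outcomes, the verification-accuracy statistic,
# and carry-forward of prior rounds so a re-run does not repeat completed
# reviews. The reviews themselves (expert knowledge, internet search,
# phone call) are out of scope; only their recording and scoring live here.

verification_methods <- c("government_list", "expert", "internet", "phone")
verification_outcomes <- c("provides_primary_care",
                           "does_not_provide_primary_care", "unknown")

# Working lists sourced from government-prepared lists are assumed
# accurate and default to a verification proportion of zero.
government_sourced_lists <- c("walk_in", "upcc", "hospital",
                              "long_term_care", "corrections")

#' A per-working-list sampling plan
#'
#' Default proportions: 0 for the government-list-sourced lists, 0.27 for
#' the family list and 0.1598 for the single-practitioner list (the two
#' partially verified lists with a stated proportion), and 1 elsewhere.
#' The non-stated defaults are placeholders a study team should revisit.
#'
#' @param proportions named numeric vector overriding defaults; values in
#'   \[0, 1\].
#' @param seed integer seed recorded in run metadata; all draws flow from
#'   it.
#' @param rounding how `proportion * n` becomes a sample size:
#'   `"nearest"` (default), `"floor"` or `"ceiling"`.
#' @return a `cla_sampling_plan`.
#' @export
sampling_plan <- function(proportions = NULL, seed = 1L,
                          rounding = c("nearest", "floor", "ceiling")) {
  rounding <- match.arg(rounding)
  props <- stats::setNames(rep(1, length(working_list_dispositions)),
                           names(working_list_dispositions))
  props[government_sourced_lists] <- 0
  props["family"] <- 0.27
  props["single_practitioner"] <- 0.1598
  if (!is.null(proportions)) {
    bad <- proportions < 0 | proportions > 1
    if (any(bad)) {
      stop("config error: sampling proportion out of [0, 1] for ",
           paste(names(proportions)[bad], collapse = ", "), call. = FALSE)
    }
    props[names(proportions)] <- proportions
  }
  structure(list(proportions = props, seed = as.integer(seed),
                 rounding = rounding), class = "cla_sampling_plan")
}

sample_size_for <- function(n, proportion, rounding) {
  x <- proportion * n
  k <- switch(rounding,
              nearest = round_half_up(x, 0),
              floor = floor(x),
              ceiling = ceiling(x))
  as.integer(min(k, n))
}

#' Draw the manual-verification sample
#'
#' Per working list, `proportion * n` addresses (rounded per the plan) are
#' drawn uniformly without replacement from a generator seeded by the
#' plan; the same plan and partition always yield the same sample, and
#' samples are disjoint across lists.
#'
#' @param partition a `cla_partition`.
#' @param plan a [sampling_plan()].
#' @return data.frame `canonical_key`, `working_list`, `disposition`,
#'   `suggested_method`.
#' @export
draw_verification_sample <- function(partition, plan = sampling_plan()) {
  a <- partition$assignments
  out <- list()
  set.seed(plan$seed)
  for (wl in sort(unique(a$working_list))) {
    p <- plan$proportions[[wl]] %||% 0
    keys <- sort(a$canonical_key[a$working_list == wl])
    k <- sample_size_for(length(keys), p, plan$rounding)
    if (k == 0) next
    drawn <- sort(sample(keys, k))
    method <- if (wl %in% government_sourced_lists) "government_list"
    else "internet"
    out[[length(out) + 1L]] <- data.frame(
      canonical_key = drawn, working_list = wl,
      disposition = unname(working_list_dispositions[wl]),
      suggested_method = method, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(canonical_key = character(), working_list = character(),
                      disposition = character(),
                      suggested_method = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Verification accuracy of a working list
#'
#' The share of sampled addresses whose human-verified status agrees with
#' the list's expected disposition: a `provides_primary_care` outcome
#' agrees with `included`, `does_not_provide_primary_care` agrees with
#' `excluded`. `unknown` outcomes count in the denominator and never the
#' numerator (conservative; set `count_unknown = FALSE` to drop them).
#'
#' @param records data.frame with an `outcome` column in the closed
#'   vocabulary; non-empty.
#' @param expected_disposition `"included"` or `"excluded"`.
#' @param count_unknown keep `unknown` outcomes in the denominator.
#' @return percent on 0–100, one decimal, half-up.
#' @export
verification_accuracy <- function(records,
                                  expected_disposition = c("included",
                                                           "excluded"),
                                  count_unknown = TRUE) {
  expected_disposition <- match.arg(expected_disposition)
  if (is.null(records) || nrow(records) == 0) {
    stop("verification_accuracy(): no records", call. = FALSE)
  }
  bad <- setdiff(unique(records$outcome), verification_outcomes)
  if (length(bad)) {
    stop("unknown verification outcome(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!count_unknown) {
    records <- records[records$outcome != "unknown", , drop = FALSE]
    if (nrow(records) == 0) {
      stop("verification_accuracy(): all outcomes unknown", call. = FALSE)
    }
  }
  agree_outcome <- if (expected_disposition == "included")
    "provides_primary_care" else "does_not_provide_primary_care"
  round_half_up(100 * sum(records$outcome == agree_outcome) / nrow(records), 1)
}

#' Read a verification-results CSV
#'
#' @param path CSV with columns `canonical_key`, `working_list`, `method`,
#'   `outcome`, `reviewer`, `date` (ISO-8601).
#' @return validated data.frame.
#' @export
import_verification_results <- function(path) {
  df <- read_csv_strict(path)
  need <- c("canonical_key", "working_list", "method", "outcome",
            "reviewer", "date")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("verification results missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(df$outcome), verification_outcomes)
  if (length(bad)) {
    stop("unknown verification outcome(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad_m <- setdiff(unique(df$method), verification_methods)
  if (length(bad_m)) {
    stop("unknown verification method(s): ", paste(bad_m, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$canonical_key)) {
    stop("one verification record per address per round; duplicated key(s): ",
         paste(unique(df$canonical_key[duplicated(df$canonical_key)]),
               collapse = ", "), call. = FALSE)
  }
  df[need]
}

#' Carry prior-round verification forward to a new partition
#'
#' Records re-attach by canonical key; records whose address no longer
#' exists in the new partition are returned as orphans for review, so that
#' manual work from earlier rounds is never silently lost.
#'
#' @param previous_round verification records data.frame.
#' @param new_partition a `cla_partition`.
#' @return list `carried` (still-applicable records) and `orphans`.
#' @export
carry_forward <- function(previous_round, new_partition) {
  if (is.null(previous_round) || nrow(previous_round) == 0) {
    empty <- previous_round %||%
      data.frame(canonical_key = character(), stringsAsFactors = FALSE)
    return(list(carried = empty[0, , drop = FALSE],
                orphans = empty[0, , drop = FALSE]))
  }
  known <- previous_round$canonical_key %in%
    new_partition$assignments$canonical_key
  list(carried = previous_round[known, , drop = FALSE],
       orphans = previous_round[!known, , drop = FALSE])
}
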