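# Three-stage assignment of every unique address to exactly one working
# list:
#   stage 1  join against the authoritative partial lists (first match in
#            configured order wins; later matches are logged as conflicts)
#   stage 2  term criteria in configured precedence (default: every
#            exclusion criterion before any inclusion criterion — an
#            address that looks like both a hospital and a family clinic
#            must not inflate the clinic list)
#   stage 3  practitioner-count fallback: >= 2 physicians -> the
#            multi-practitioner list (included), exactly 1 -> the
#            single-practitioner list (undetermined)

#' Disposition of each working list
#'
#' Named character vector mapping the fourteen working-list names to
#' `included` / `excluded` / `undetermined`.
#' @export
working_list_dispositions <- c(
  walk_in = "included", upcc = "included", family = "included",
  first_nations = "included", clinic_center = "included",
  multi_practitioner = "included",
  hospital = "excluded", long_term_care = "excluded",
  corrections = "excluded", sexual_health = "excluded",
  womens_health = "excluded", virtual = "excluded",
  administrative = "excluded",
  single_practitioner = "undetermined")

default_partial_list_order <- c("walk_in", "upcc", "hospital", "corrections",
                                "long_term_care")

#' Default term-criterion precedence: exclusions first
#' @param criteria output of [default_criteria()].
#' @return character vector of criterion names.
#' @export
default_term_order <- function(criteria = default_criteria()) {
  tb <- term_bearing_criteria(criteria)
  pol <- vapply(criteria[tb], `[[`, character(1), "polarity")
  c(tb[pol == "exclude"], tb[pol == "include"])
}

#' Partition configuration
#'
#' @param partial_list_order order in which partial lists claim addresses.
#' @param term_order criterion precedence for stage 2; must cover every
#'   term-bearing criterion exactly once.
#' @param extra_lists named character vector of additional custom working
#'   lists and their dispositions (config slot; none by default).
#' @param rules normalization rules used to key partial-list addresses.
#' @return a list used as the `config` argument of [partition_addresses()].
#' @export
partition_config <- function(partial_list_order = default_partial_list_order,
                             term_order = NULL,
                             extra_lists = character(),
                             rules = normalization_rules()) {
  list(partial_list_order = partial_list_order, term_order = term_order,
       extra_lists = extra_lists, rules = rules)
}

# Normalize a partial list's entries to canonical keys.
partial_list_keys <- function(pl, rules) {
  if (nrow(pl) == 0) return(character())
  vapply(seq_len(nrow(pl)), function(i) {
    normalize_address(pl$line1[i], pl$line2[i], pl$city[i], pl$province[i],
                      pl$postal_code[i], rules)$canonical_key
  }, character(1))
}

#' Stage 1: join partial lists to address groups
#'
#' @param groups a `cla_groups` data.frame.
#' @param partial_lists named list of partial-list data.frames (see
#'   [read_partial_list()]); names must be category names.
#' @param rules normalization rules (partial-list addresses pass through
#'   the same normalizer as registry addresses).
#' @param order category precedence; first match wins.
#' @return list: `assigned` (data.frame canonical_key / working_list /
#'   stage / detail), `conflicts` (later matches on already-claimed keys),
#'   `unjoined` (partial-list entries whose key has no registry group —
#'   candidate clinics with no registered physician, reported, not dropped).
#' @export
join_partial_lists <- function(groups, partial_lists,
                               rules = normalization_rules(),
                               order = default_partial_list_order) {
  assigned <- data.frame(canonical_key = character(),
                         working_list = character(), stage = character(),
                         detail = character(), stringsAsFactors = FALSE)
  conflicts <- assigned
  unjoined <- data.frame(category = character(), facility_name = character(),
                         canonical_key = character(), stringsAsFactors = FALSE)
  claimed <- stats::setNames(character(0), character(0))
  for (cat in order) {
    pl <- partial_lists[[cat]]
    if (is.null(pl) || nrow(pl) == 0) next
    keys <- partial_list_keys(pl, rules)
    for (i in seq_along(keys)) {
      k <- keys[i]
      if (!k %in% groups$canonical_key) {
        unjoined <- rbind(unjoined, data.frame(
          category = cat, facility_name = pl$facility_name[i],
          canonical_key = k, stringsAsFactors = FALSE))
        next
      }
      row <- data.frame(canonical_key = k, working_list = cat,
                        stage = "partial_list",
                        detail = pl$facility_name[i], stringsAsFactors = FALSE)
      if (k %in% names(claimed)) {
        if (claimed[[k]] != cat) conflicts <- rbind(conflicts, row)
        next
      }
      claimed[[k]] <- cat
      assigned <- rbind(assigned, row)
    }
  }
  list(assigned = assigned, conflicts = conflicts, unjoined = unjoined)
}

#' Stage 2: apply term criteria in precedence order
#'
#' The first criterion (in `order`) whose evaluation matches a group's
#' label/street text claims the group; every criterion that fires is
#' recorded for audit even when it does not claim.
#'
#' @param groups remaining (stage-1-unassigned) `cla_groups` rows.
#' @param criteria named list of [term_criterion()] objects.
#' @param order criterion names covering all term-bearing criteria once.
#' @return list `assigned` (as in [join_partial_lists()], stage `"term"`)
#'   and `fired` (full audit data.frame of all firings).
#' @export
apply_term_criteria <- function(groups, criteria = default_criteria(),
                                order = default_term_order(criteria)) {
  unknown <- setdiff(order, names(criteria))
  if (length(unknown)) {
    stop("config error: unknown criterion name(s) in order: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  tb <- term_bearing_criteria(criteria)
  missing <- setdiff(tb, order)
  if (length(missing)) {
    stop("config error: term order omits criterion/criteria: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(order)) {
    stop("config error: duplicated criterion in order", call. = FALSE)
  }
  assigned <- data.frame(canonical_key = character(),
                         working_list = character(), stage = character(),
                         detail = character(), stringsAsFactors = FALSE)
  fired_all <- list()
  for (i in seq_len(nrow(groups))) {
    txt <- groups$match_text[i]
    claimer <- NA_character_
    claim_atom <- ""
    for (nm in order) {
      r <- evaluate_criterion(criteria[[nm]], txt)
      if (nrow(r$fired_atoms)) {
        fired_all[[length(fired_all) + 1L]] <-
          cbind(canonical_key = groups$canonical_key[i], r$fired_atoms)
      }
      if (r$matched && is.na(claimer)) {
        claimer <- nm
        claim_atom <- paste(r$fired_atoms$atom, collapse = "; ")
      }
    }
    if (!is.na(claimer)) {
      assigned <- rbind(assigned, data.frame(
        canonical_key = groups$canonical_key[i], working_list = claimer,
        stage = "term", detail = claim_atom, stringsAsFactors = FALSE))
    }
  }
  fired <- if (length(fired_all)) do.call(rbind, fired_all) else
    data.frame(canonical_key = character(), criterion = character(),
               atom = character(), span = character(),
               stringsAsFactors = FALSE)
  list(assigned = assigned, fired = fired)
}

#' Stage 3: practitioner-count fallback
#'
#' @param groups `cla_groups` rows unassigned by stages 1–2.
#' @return assignment data.frame (stage `"count_fallback"`).
#' @export
count_fallback <- function(groups) {
  stopifnot(all(groups$fp_assignment_count >= 1))
  if (nrow(groups) == 0) {
    return(data.frame(canonical_key = character(), working_list = character(),
                      stage = character(), detail = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    canonical_key = groups$canonical_key,
    working_list = ifelse(groups$fp_assignment_count >= 2,
                          "multi_practitioner", "single_practitioner"),
    stage = "count_fallback",
    detail = paste0("fp_assignment_count=", groups$fp_assignment_count),
    stringsAsFactors = FALSE)
}

#' Partition every address group into exactly one working list
#'
#' Composes the three stages and validates the partition invariants:
#' assignments are exhaustive and mutually exclusive, and both the
#' unique-address count and the physician-address pairing count are
#' conserved across working lists.
#'
#' @param groups a `cla_groups` data.frame.
#' @param partial_lists named list of partial-list data.frames.
#' @param criteria named list of [term_criterion()] objects.
#' @param config a [partition_config()].
#' @return a `cla_partition`: list with `assignments` (one row per group:
#'   canonical_key, working_list, disposition, stage, detail,
#'   fp_assignment_count), `flow_counts` (per-stage input/assigned/
#'   remaining tallies), `conflicts`, `unjoined_partial_entries`, `fired`.
#' @export
partition_addresses <- function(groups, partial_lists = list(),
                                criteria = default_criteria(),
                                config = partition_config()) {
  order1 <- config$partial_list_order
  order2 <- config$term_order %||% default_term_order(criteria)
  dispositions <- c(working_list_dispositions, config$extra_lists)

  # stable processing order regardless of input row order
  groups <- groups[order(groups$canonical_key), , drop = FALSE]

  n_total <- nrow(groups)
  flow <- list()
  s1 <- join_partial_lists(groups, partial_lists, config$rules, order1)
  for (cat in order1) {
    flow[[length(flow) + 1L]] <- data.frame(
      stage = paste0("partial_list:", cat),
      input_n = NA_integer_,
      assigned_n = sum(s1$assigned$working_list == cat),
      remaining_n = NA_integer_, stringsAsFactors = FALSE)
  }
  rem1 <- groups[!groups$canonical_key %in% s1$assigned$canonical_key, ,
                 drop = FALSE]

  s2 <- apply_term_criteria(rem1, criteria, order2)
  for (nm in order2) {
    flow[[length(flow) + 1L]] <- data.frame(
      stage = paste0("term:", nm), input_n = NA_integer_,
      assigned_n = sum(s2$assigned$working_list == nm),
      remaining_n = NA_integer_, stringsAsFactors = FALSE)
  }
  rem2 <- rem1[!rem1$canonical_key %in% s2$assigned$canonical_key, ,
               drop = FALSE]

  s3 <- count_fallback(rem2)
  for (nm in c("multi_practitioner", "single_practitioner")) {
    flow[[length(flow) + 1L]] <- data.frame(
      stage = paste0("count_fallback:", nm), input_n = NA_integer_,
      assigned_n = sum(s3$working_list == nm), remaining_n = NA_integer_,
      stringsAsFactors = FALSE)
  }

  assignments <- rbind(s1$assigned, s2$assigned, s3)
  assignments <- merge(assignments,
                       groups[, c("canonical_key", "fp_assignment_count")],
                       by = "canonical_key", sort = TRUE)
  assignments$disposition <- unname(dispositions[assignments$working_list])
  assignments <- assignments[order(assignments$canonical_key), ,
                             drop = FALSE]
  rownames(assignments) <- NULL

  # fill running input/remaining tallies in stage order
  flow <- do.call(rbind, flow)
  running <- n_total
  for (i in seq_len(nrow(flow))) {
    flow$input_n[i] <- running
    running <- running - flow$assigned_n[i]
    flow$remaining_n[i] <- running
  }

  # partition invariants: exhaustive, exclusive, conservation
  stopifnot(nrow(assignments) == n_total,
            !anyDuplicated(assignments$canonical_key),
            setequal(assignments$canonical_key, groups$canonical_key),
            sum(assignments$fp_assignment_count) ==
              sum(groups$fp_assignment_count),
            flow$remaining_n[nrow(flow)] == 0)

  structure(list(assignments = assignments, flow_counts = flow,
                 conflicts = s1$conflicts,
                 unjoined_partial_entries = s1$unjoined,
                 fired = s2$fired,
                 term_order = order2, partial_list_order = order1),
            class = "cla_partition")
}

#' @export
print.cla_partition <- function(x, ...) {
  tab <- table(x$assignments$disposition)
  cat("Address partition:", nrow(x$assignments), "unique addresses\n")
  for (d in c("included", "excluded", "undetermined")) {
    cat(sprintf("  %-12s %d\n", d, if (d %in% names(tab)) tab[[d]] else 0L))
  }
  invisible(x)
}
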