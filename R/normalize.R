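# Address canonicalization and the physician->unique-address collapse.
#
# The canonical key is a deterministic function of the raw address:
# case-folded, punctuation-stripped, whitespace-collapsed, street-type
# abbreviations expanded, unit/suite tokens moved to a dedicated key slot,
# postal code normalized to "A1A 1A1". Matching is exact-key only; no fuzzy
# merge ever happens automatically (near-duplicates are reported for human
# review instead).

#' Address normalization rules
#'
#' @param abbreviations named character vector mapping street-type
#'   abbreviations (lower case, no dot) to their expansion.
#' @param unit_designators tokens introducing a unit/suite number.
#' @param keep_units keep the unit slot in the canonical key (default TRUE:
#'   two suites in one building are distinct candidate clinics). Setting
#'   FALSE merges across suites; the choice is reviewable through
#'   [near_duplicate_report()].
#' @param strict_hyphen passed through to term matching config elsewhere;
#'   unused here, reserved.
#' @return a `cla_norm_rules` list.
#' @export
normalization_rules <- function(abbreviations = default_abbreviations(),
                                unit_designators = c("suite", "ste", "unit",
                                                     "apt", "apartment",
                                                     "rm", "room"),
                                keep_units = TRUE,
                                strict_hyphen = FALSE) {
  structure(list(abbreviations = abbreviations,
                 unit_designators = unit_designators,
                 keep_units = keep_units,
                 strict_hyphen = strict_hyphen),
            class = "cla_norm_rules")
}

#' Default street-type abbreviation table
#' @return named character vector, abbreviation -> expansion.
#' @export
default_abbreviations <- function() {
  c(st = "street", ave = "avenue", av = "avenue", rd = "road", dr = "drive",
    blvd = "boulevard", hwy = "highway", cres = "crescent", pl = "place",
    sq = "square", ln = "lane", ct = "court", tr = "trail", pkwy = "parkway")
}

# lower-case, strip apostrophes, dashes unified, everything else to spaces
fold_text <- function(x) {
  x <- tolower(x)
  x <- gsub("['’]", "", x)
  x <- gsub("[–—]", "-", x)
  x
}

squash <- function(x) trimws(gsub("\\s+", " ", x))

normalize_postal <- function(postal) {
  p <- toupper(gsub("[^A-Za-z0-9]", "", postal))
  ifelse(grepl("^[A-Z][0-9][A-Z][0-9][A-Z][0-9]$", p),
         paste(substr(p, 1, 3), substr(p, 4, 6)), "")
}

# Pull a unit/suite designation out of a folded street string.
# Handles "suite 200 - 1234 main st", "#200 1234 main st",
# "200-1234 main st", "1234 main st, suite 200".
extract_unit <- function(s, designators) {
  unit <- ""
  des <- paste(designators, collapse = "|")
  pat_lead <- paste0("^(?:", des, ")\\.?\\s*#?\\s*([0-9]+[a-z]?)\\b[-,\\s]*")
  m <- regexpr(pat_lead, s, perl = TRUE)
  if (m > 0) {
    unit <- sub(pat_lead, "\\1", substr(s, m, m + attr(m, "match.length") - 1),
                perl = TRUE)
    s <- substr(s, m + attr(m, "match.length"), nchar(s))
  } else if (grepl("^#\\s*[0-9]+[a-z]?\\b", s, perl = TRUE)) {
    unit <- sub("^#\\s*([0-9]+[a-z]?)\\b.*$", "\\1", s, perl = TRUE)
    s <- sub("^#\\s*[0-9]+[a-z]?\\b[-,\\s]*", "", s, perl = TRUE)
  } else if (grepl("^[0-9]+[a-z]?\\s*-\\s*[0-9]", s, perl = TRUE)) {
    unit <- sub("^([0-9]+[a-z]?)\\s*-.*$", "\\1", s, perl = TRUE)
    s <- sub("^[0-9]+[a-z]?\\s*-\\s*", "", s, perl = TRUE)
  }
  pat_tail <- paste0("[-,\\s]+(?:", des, ")\\.?\\s*#?\\s*([0-9]+[a-z]?)\\s*$")
  m <- regexpr(pat_tail, s, perl = TRUE)
  if (m > 0 && !nzchar(unit)) {
    unit <- sub(pat_tail, "\\1",
                substr(s, m, m + attr(m, "match.length") - 1), perl = TRUE)
    s <- substr(s, 1, m - 1)
  }
  list(unit = unit, rest = s)
}

is_po_box <- function(street_folded) {
  grepl("\\bp\\.?\\s*o\\.?\\s*box\\b|^\\s*box\\s+[0-9]", street_folded,
        perl = TRUE)
}

expand_abbreviations <- function(tokens, abbr) {
  hit <- tokens %in% names(abbr)
  tokens[hit] <- abbr[tokens[hit]]
  tokens
}

#' Canonicalize one raw address
#'
#' @param line1,line2,city,province,postal_code address fields (character
#'   scalars; `line2` and others may be empty).
#' @param rules a [normalization_rules()] object.
#' @return list with `canonical_key`, `display_address`, `postal_code_norm`,
#'   `po_box_flag`, `unit`, `street_norm`, `city_norm`.
#' @export
normalize_address <- function(line1, line2 = "", city = "", province = "",
                              postal_code = "", rules = normalization_rules()) {
  f <- function(x) if (is.na(x) || is.null(x)) "" else x
  line1 <- f(line1); line2 <- f(line2); city <- f(city)
  province <- f(province); postal_code <- f(postal_code)
  if (!nzchar(trimws(line1)) && !nzchar(trimws(city)) &&
      !nzchar(trimws(postal_code))) {
    stop("unusable address: all of line1/city/postal_code empty", call. = FALSE)
  }
  street_raw <- squash(paste(line1, line2))
  s <- squash(fold_text(street_raw))
  po <- is_po_box(s)
  eu <- extract_unit(s, rules$unit_designators)
  unit <- eu$unit
  s <- gsub("[^a-z0-9]+", " ", eu$rest)
  toks <- strsplit(squash(s), " ", fixed = TRUE)[[1]]
  toks <- expand_abbreviations(toks, rules$abbreviations)
  street_norm <- paste(toks, collapse = " ")
  city_norm <- squash(gsub("[^a-z0-9]+", " ", fold_text(city)))
  postal_norm <- normalize_postal(postal_code)
  unit_part <- if (rules$keep_units) unit else ""
  key <- paste(unit_part, street_norm, city_norm, tolower(postal_norm),
               sep = "|")
  display <- squash(paste0(street_raw,
                           ifelse(nzchar(trimws(city)), paste0(", ", squash(city)), ""),
                           ifelse(nzchar(trimws(province)), paste0(", ", squash(province)), ""),
                           ifelse(nzchar(postal_norm), paste0(" ", postal_norm), "")))
  list(canonical_key = key, display_address = display,
       postal_code_norm = postal_norm, po_box_flag = po, unit = unit,
       street_norm = street_norm, city_norm = city_norm)
}

# Vectorized over the rows of a registry-shaped data.frame.
normalize_frame <- function(df, rules = normalization_rules()) {
  n <- nrow(df)
  out <- data.frame(canonical_key = character(n),
                    display_address = character(n),
                    postal_code_norm = character(n),
                    po_box_flag = logical(n),
                    unit = character(n),
                    street_norm = character(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    na <- normalize_address(df$line1[i], df$line2[i], df$city[i],
                            df$province[i], df$postal_code[i], rules)
    out$canonical_key[i] <- na$canonical_key
    out$display_address[i] <- na$display_address
    out$postal_code_norm[i] <- na$postal_code_norm
    out$po_box_flag[i] <- na$po_box_flag
    out$unit[i] <- na$unit
    out$street_norm[i] <- na$street_norm
  }
  out
}

#' Rewrite canonical keys with manual overrides
#'
#' Applied before grouping, mirroring the manual alteration of addresses
#' (almost exclusively post-office boxes) that cannot otherwise be
#' processed. An override targeting a key that never occurs is a warning,
#' not an error.
#'
#' @param keys character vector of canonical keys.
#' @param overrides data.frame with columns `raw_key`, `replacement_key`
#'   (or NULL / zero rows for a no-op).
#' @return list `keys` (rewritten) and `applied` (log data.frame).
#' @export
apply_overrides <- function(keys, overrides = NULL) {
  if (is.null(overrides) || nrow(overrides) == 0) {
    return(list(keys = keys, applied = data.frame(raw_key = character(),
                                                  replacement_key = character(),
                                                  n = integer())))
  }
  applied <- data.frame(raw_key = overrides$raw_key,
                        replacement_key = overrides$replacement_key,
                        n = 0L, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(overrides))) {
    hit <- keys == overrides$raw_key[i]
    if (!any(hit)) {
      warning("override targets a key not present: ", overrides$raw_key[i],
              call. = FALSE)
      next
    }
    keys[hit] <- overrides$replacement_key[i]
    applied$n[i] <- sum(hit)
  }
  list(keys = keys, applied = applied)
}

#' Collapse physician-address pairings into unique-address groups
#'
#' The physician-to-clinic transformation: one group per canonical key,
#' carrying every physician registered there. A physician listing the same
#' address twice counts once in that group, so the sum of
#' `fp_assignment_count` over groups equals the number of distinct
#' (physician, unique address) pairings.
#'
#' @param registry an addressed, filtered `cla_registry`.
#' @param rules a [normalization_rules()] object.
#' @param overrides optional manual key overrides (see [apply_overrides()]).
#' @return a `cla_groups` data.frame: `canonical_key`, `display_address`,
#'   `postal_code_norm`, `po_box_flag`, `physician_ids` (";"-joined),
#'   `fp_assignment_count`, `source_labels` (";"-joined unique labels),
#'   `match_text` (labels + street lines, the text term criteria see),
#'   `flagged` (any member row was province-flagged).
#' @export
group_unique_addresses <- function(registry, rules = normalization_rules(),
                                   overrides = NULL) {
  reg <- addressed_rows(registry)
  if (nrow(reg) == 0) {
    out <- data.frame(canonical_key = character(),
                      display_address = character(),
                      postal_code_norm = character(),
                      po_box_flag = logical(), physician_ids = character(),
                      fp_assignment_count = integer(),
                      source_labels = character(), match_text = character(),
                      flagged = logical(), stringsAsFactors = FALSE)
    class(out) <- c("cla_groups", "data.frame")
    return(out)
  }
  norm <- normalize_frame(reg, rules)
  ov <- apply_overrides(norm$canonical_key, overrides)
  keys <- ov$keys
  uk <- unique(keys)
  rows <- lapply(uk, function(k) {
    idx <- which(keys == k)
    ids <- unique(reg$registrant_id[idx])
    labels <- unique(trimws(reg$source_label[idx]))
    labels <- labels[nzchar(labels)]
    streets <- unique(trimws(c(reg$line1[idx], reg$line2[idx])))
    streets <- streets[nzchar(streets)]
    # most frequent raw variant as display
    disp <- names(sort(table(norm$display_address[idx]), decreasing = TRUE))[1]
    data.frame(canonical_key = k,
               display_address = disp,
               postal_code_norm = norm$postal_code_norm[idx[1]],
               po_box_flag = any(norm$po_box_flag[idx]),
               physician_ids = collapse_ids(ids),
               fp_assignment_count = length(ids),
               source_labels = collapse_ids(labels),
               match_text = squash(paste(c(labels, streets), collapse = " ")),
               flagged = any(reg$province_flagged[idx]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  stopifnot(all(out$fp_assignment_count >= 1))
  class(out) <- c("cla_groups", "data.frame")
  out
}

#' Near-duplicate canonical keys for human review
#'
#' Emits pairs of keys whose string similarity (1 - normalized Levenshtein
#' distance via [utils::adist()]) exceeds `threshold`. Advisory only: the
#' pipeline never auto-merges on similarity.
#'
#' @param groups a `cla_groups` data.frame.
#' @param threshold similarity in (0, 1]; default 0.9.
#' @return data.frame `key_a`, `key_b`, `similarity`, sorted descending.
#' @export
near_duplicate_report <- function(groups, threshold = 0.9) {
  k <- groups$canonical_key
  if (length(k) < 2) {
    return(data.frame(key_a = character(), key_b = character(),
                      similarity = numeric()))
  }
  d <- utils::adist(k)
  len <- nchar(k)
  out <- list()
  for (i in seq_len(length(k) - 1)) {
    for (j in seq((i + 1), length(k))) {
      sim <- 1 - d[i, j] / max(len[i], len[j])
      if (sim >= threshold) {
        out[[length(out) + 1]] <- data.frame(key_a = k[i], key_b = k[j],
                                             similarity = sim)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(key_a = character(), key_b = character(),
                      similarity = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(-res$similarity), , drop = FALSE]
}
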