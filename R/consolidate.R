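# Merge the working lists into the final clinic list and compute the
# descriptive statistics: per-rurality address and physician-assignment
# counts with percentages, and median / IQR / range of physicians per
# unique address.

#' Merge working lists into the final clinic list
#'
#' Buckets are assembled by working-list disposition. When verification
#' results are supplied, a verified "does not provide primary care"
#' outcome moves that address to the excluded bucket and a verified
#' "provides primary care" outcome moves an *undetermined* address to the
#' included bucket; every move is logged. Results referencing an unknown
#' address are collected in a warning list, not an error.
#'
#' @param annotated groups annotated by [annotate_metadata()].
#' @param verification_results optional data.frame of verification
#'   records (see [import_verification_results()]).
#' @return a `cla_final_list`: list with `addresses` (the annotated groups
#'   plus a `final_disposition` column), `moves` (log of
#'   verification-driven moves), `unknown_keys` (results that matched no
#'   address), `counts` (named totals).
#' @export
consolidate <- function(annotated, verification_results = NULL) {
  out <- annotated
  out$final_disposition <- out$disposition
  moves <- data.frame(canonical_key = character(), from = character(),
                      to = character(), outcome = character(),
                      stringsAsFactors = FALSE)
  unknown <- character()
  if (!is.null(verification_results) && nrow(verification_results) > 0) {
    for (i in seq_len(nrow(verification_results))) {
      k <- verification_results$canonical_key[i]
      oc <- verification_results$outcome[i]
      j <- which(out$canonical_key == k)
      if (!length(j)) {
        unknown <- c(unknown, k)
        next
      }
      from <- out$final_disposition[j]
      to <- from
      if (oc == "does_not_provide_primary_care" && from != "excluded") {
        to <- "excluded"
      } else if (oc == "provides_primary_care" && from == "undetermined") {
        to <- "included"
      }
      if (to != from) {
        out$final_disposition[j] <- to
        moves <- rbind(moves, data.frame(canonical_key = k, from = from,
                                         to = to, outcome = oc,
                                         stringsAsFactors = FALSE))
      }
    }
    if (length(unknown)) {
      warning("verification results reference unknown address(es): ",
              paste(unique(unknown), collapse = ", "), call. = FALSE)
    }
  }
  counts <- c(unique_addresses = nrow(out),
              included = sum(out$final_disposition == "included"),
              excluded = sum(out$final_disposition == "excluded"),
              undetermined = sum(out$final_disposition == "undetermined"),
              fp_assignments = sum(out$fp_assignment_count))
  # bucket conservation, asserted on every run
  stopifnot(counts[["included"]] + counts[["excluded"]] +
              counts[["undetermined"]] == counts[["unique_addresses"]])
  structure(list(addresses = out, moves = moves,
                 unknown_keys = unique(unknown), counts = counts),
            class = "cla_final_list")
}

#' @export
print.cla_final_list <- function(x, ...) {
  cat("Final clinic list:",
      x$counts[["included"]], "included /",
      x$counts[["excluded"]], "excluded /",
      x$counts[["undetermined"]], "undetermined",
      "of", x$counts[["unique_addresses"]], "unique addresses\n")
  invisible(x)
}

#' Unique physicians across a set of address groups
#' @param addresses rows of the final list.
#' @return integer count of distinct registrant ids.
#' @export
unique_physician_count <- function(addresses) {
  length(unique(unlist(lapply(addresses$physician_ids, split_ids))))
}

rurality_levels <- c("metropolitan", "large_urban", "medium_urban",
                     "small_urban", "rural_hub", "rural", "remote")

#' Geographic summary of one disposition bucket
#'
#' One row per rurality class present, an `unclassified` row for groups
#' whose geocode did not resolve to a health area, and a `Total` row.
#' Physician counts are reported two ways: physician-address assignments
#' (`fp_assignment_*`, the additive quantity across buckets) and unique
#' physicians (`unique_fp_n`). Percentages are on the bucket total,
#' half-up to two decimals. Quartiles: linear interpolation (type 7).
#'
#' @param final a `cla_final_list`.
#' @param bucket which disposition to summarize (default `"included"`).
#' @return data.frame, one row per class plus Total; zero rows (with a
#'   warning) when the bucket is empty.
#' @export
geo_summary <- function(final, bucket = "included") {
  adr <- final$addresses[final$addresses$final_disposition == bucket, ,
                         drop = FALSE]
  if (nrow(adr) == 0) {
    warning("geo_summary(): bucket '", bucket, "' is empty", call. = FALSE)
    return(data.frame(rurality = character(), unique_address_n = integer(),
                      unique_address_pct = numeric(),
                      fp_assignment_n = integer(),
                      fp_assignment_pct = numeric(),
                      unique_fp_n = integer(), median_fp = numeric(),
                      q1_fp = numeric(), q3_fp = numeric(),
                      min_fp = integer(), max_fp = integer()))
  }
  rur <- adr$rurality
  rur[is.na(rur) | !nzchar(rur)] <- "unclassified"
  classes <- c(rurality_levels[rurality_levels %in% rur],
               if ("unclassified" %in% rur) "unclassified")
  n_tot <- nrow(adr)
  fp_tot <- sum(adr$fp_assignment_count)
  one_row <- function(cls, rows) {
    s <- median_iqr_range(rows$fp_assignment_count)
    data.frame(rurality = cls,
               unique_address_n = nrow(rows),
               unique_address_pct = cla_percentage(nrow(rows), n_tot),
               fp_assignment_n = sum(rows$fp_assignment_count),
               fp_assignment_pct = cla_percentage(sum(rows$fp_assignment_count),
                                                  fp_tot),
               unique_fp_n = unique_physician_count(rows),
               median_fp = s[["median"]], q1_fp = s[["q1"]], q3_fp = s[["q3"]],
               min_fp = s[["min"]], max_fp = s[["max"]],
               stringsAsFactors = FALSE)
  }
  rows <- lapply(classes, function(cls)
    one_row(cls, adr[rur == cls, , drop = FALSE]))
  out <- rbind(do.call(rbind, rows), one_row("Total", adr))
  # row sums must equal bucket totals
  body <- out[out$rurality != "Total", , drop = FALSE]
  stopifnot(sum(body$unique_address_n) == n_tot,
            sum(body$fp_assignment_n) == fp_tot)
  out
}

#' Urban/rural dichotomies of an included-bucket summary
#'
#' Two candidate dichotomizations of the seven-class vocabulary are
#' reported side by side — `urban4` (metropolitan + large, medium and
#' small urban) and `urban5` (`urban4` + rural hub) — since more than one
#' reasonable cut exists; neither is authoritative.
#'
#' @param summary output of [geo_summary()].
#' @return data.frame with one row per dichotomy: class set, address n and
#'   percentage.
#' @export
urban_dichotomies <- function(summary) {
  tot <- summary$unique_address_n[summary$rurality == "Total"]
  pick <- function(classes) {
    sum(summary$unique_address_n[summary$rurality %in% classes])
  }
  u4 <- pick(c("metropolitan", "large_urban", "medium_urban", "small_urban"))
  u5 <- u4 + pick("rural_hub")
  data.frame(
    dichotomy = c("urban4", "urban5"),
    classes = c("metropolitan+large_urban+medium_urban+small_urban",
                "metropolitan+large_urban+medium_urban+small_urban+rural_hub"),
    urban_n = c(u4, u5),
    urban_pct = c(cla_percentage(u4, tot), cla_percentage(u5, tot)),
    stringsAsFactors = FALSE)
}
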