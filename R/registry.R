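# Registry I/O and the physician-level filters (specialty + province).
#
# A registry is held in long form: one row per (physician, address block).
# Physicians with no usable address get a single row with empty address
# fields so that nothing is silently lost; they are routed to the
# "unaddressed" report rather than erroring, because license registries are
# dirty by nature.

#' Default registry column mapping
#'
#' Readers take a schema mapping because column names vary by licensing
#' body. `address_blocks` gives the prefixes of repeated address blocks in
#' a wide export (e.g. `addr1_line1`, `addr2_line1`, ...); each block has
#' `_line1`, `_line2`, `_city`, `_province`, `_postal_code`, `_label`
#' suffixes, where `label` is any clinic/organization name embedded in the
#' registry address field.
#'
#' @param registrant_id,full_name,specialties column names in the CSV.
#' @param address_blocks character vector of address-block prefixes.
#' @param specialty_sep separator inside the specialties cell.
#' @return a named list usable as the `schema` argument of [read_registry()].
#' @export
registry_schema <- function(registrant_id = "registrant_id",
                            full_name = "full_name",
                            specialties = "specialties",
                            address_blocks = c("addr1", "addr2", "addr3"),
                            specialty_sep = ";") {
  list(registrant_id = registrant_id, full_name = full_name,
       specialties = specialties, address_blocks = address_blocks,
       specialty_sep = specialty_sep)
}

address_suffixes <- c("line1", "line2", "city", "province", "postal_code", "label")

empty_registry <- function() {
  data.frame(registrant_id = character(), full_name = character(),
             specialties = character(), line1 = character(),
             line2 = character(), city = character(), province = character(),
             postal_code = character(), source_label = character(),
             province_flagged = logical(), stringsAsFactors = FALSE)
}

as_cla_registry <- function(df) {
  class(df) <- c("cla_registry", "data.frame")
  df
}

#' Read a physician registry CSV
#'
#' One output row per (registrant, address block); a registrant whose
#' address blocks are all empty keeps one row with blank address fields.
#' Registrant ids must be unique across rows of the CSV.
#'
#' @param path CSV file path.
#' @param schema column mapping from [registry_schema()].
#' @return a `cla_registry` data.frame with columns `registrant_id`,
#'   `full_name`, `specialties` (separator-joined), `line1`, `line2`,
#'   `city`, `province`, `postal_code`, `source_label`, `province_flagged`.
#' @export
read_registry <- function(path, schema = registry_schema()) {
  raw <- read_csv_strict(path)
  if (nrow(raw) == 0) {
    warning("registry file is empty: ", path, call. = FALSE)
    return(as_cla_registry(empty_registry()))
  }
  needed <- c(schema$registrant_id, schema$full_name, schema$specialties)
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop("registry schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ids <- raw[[schema$registrant_id]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate registrant_id in registry: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }

  rows <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    blocks <- list()
    for (p in schema$address_blocks) {
      cols <- paste(p, address_suffixes, sep = "_")
      vals <- vapply(cols, function(cl) {
        if (cl %in% names(raw)) raw[[cl]][i] else ""
      }, character(1))
      vals[is.na(vals)] <- ""
      names(vals) <- address_suffixes
      if (any(nzchar(trimws(vals[c("line1", "city", "postal_code")])))) {
        blocks[[length(blocks) + 1L]] <- vals
      }
    }
    if (length(blocks) == 0) {
      blocks <- list(stats::setNames(rep("", 6), address_suffixes))
    }
    rows[[i]] <- data.frame(
      registrant_id = ids[i],
      full_name = raw[[schema$full_name]][i],
      specialties = raw[[schema$specialties]][i],
      line1 = vapply(blocks, `[[`, "", "line1"),
      line2 = vapply(blocks, `[[`, "", "line2"),
      city = vapply(blocks, `[[`, "", "city"),
      province = vapply(blocks, `[[`, "", "province"),
      postal_code = vapply(blocks, `[[`, "", "postal_code"),
      source_label = vapply(blocks, `[[`, "", "label"),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$specialties[is.na(out$specialties)] <- ""
  out$province_flagged <- FALSE
  message(nrow(raw), " registry rows read (", nrow(out),
          " physician-address rows) from ", path)
  as_cla_registry(out)
}

#' Write a registry back to the wide CSV layout
#'
#' Inverse of [read_registry()] under the same schema, used for round-trip
#' checks and for persisting generator output.
#'
#' @param registry a `cla_registry`.
#' @param path output CSV path.
#' @param schema column mapping from [registry_schema()].
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path, schema = registry_schema()) {
  ids <- unique(registry$registrant_id)
  nblk <- length(schema$address_blocks)
  cols <- c(schema$registrant_id, schema$full_name, schema$specialties,
            unlist(lapply(schema$address_blocks,
                          function(p) paste(p, address_suffixes, sep = "_"))))
  out <- as.data.frame(matrix("", nrow = length(ids), ncol = length(cols),
                              dimnames = list(NULL, cols)),
                       stringsAsFactors = FALSE, check.names = FALSE)
  for (k in seq_along(ids)) {
    sub <- registry[registry$registrant_id == ids[k], , drop = FALSE]
    if (nrow(sub) > nblk) {
      stop("write_registry(): registrant ", ids[k], " has ", nrow(sub),
           " addresses but schema has only ", nblk, " address blocks",
           call. = FALSE)
    }
    out[k, schema$registrant_id] <- ids[k]
    out[k, schema$full_name] <- sub$full_name[1]
    out[k, schema$specialties] <- sub$specialties[1]
    for (j in seq_len(nrow(sub))) {
      if (all(blank(unlist(sub[j, c("line1", "city", "postal_code")])))) next
      p <- schema$address_blocks[j]
      out[k, paste(p, address_suffixes, sep = "_")] <-
        unlist(sub[j, c("line1", "line2", "city", "province",
                        "postal_code", "source_label")])
    }
  }
  write_table(out, path)
}

#' Keep only family physicians
#'
#' A physician is kept when at least one specialty label matches any of the
#' `fp_terms` by case-insensitive substring. Records with an empty
#' specialties cell are dropped, never an error.
#'
#' @param registry a `cla_registry`.
#' @param fp_terms non-empty character vector of match terms.
#' @param sep separator inside the specialties cell.
#' @return `list(kept = cla_registry, dropped_count = n)` where
#'   `dropped_count` counts physicians (not rows); kept + dropped equals the
#'   input physician count.
#' @export
filter_family_physicians <- function(registry, fp_terms = c("family"),
                                     sep = ";") {
  if (length(fp_terms) == 0) {
    stop("filter_family_physicians(): fp_terms must be non-empty", call. = FALSE)
  }
  is_fp_cell <- function(cell) {
    labs <- tolower(trimws(strsplit(cell %||% "", sep, fixed = TRUE)[[1]]))
    any(vapply(tolower(fp_terms),
               function(t) any(grepl(t, labs, fixed = TRUE)), logical(1)))
  }
  per_phys <- !duplicated(registry$registrant_id)
  keep_phys <- vapply(registry$specialties[per_phys], is_fp_cell, logical(1))
  kept_ids <- registry$registrant_id[per_phys][keep_phys]
  kept <- registry[registry$registrant_id %in% kept_ids, , drop = FALSE]
  n_in <- sum(per_phys)
  dropped <- n_in - length(kept_ids)
  stopifnot(length(kept_ids) + dropped == n_in)
  list(kept = as_cla_registry(kept), dropped_count = dropped)
}

#' Drop practice addresses outside the target province
#'
#' Removes non-matching *addresses*; a physician left with no address is
#' dropped entirely. A blank province field falls back to a postal-code
#' prefix rule (default prefix "V" for British Columbia) and the row is
#' flagged for review.
#'
#' @param registry a `cla_registry`.
#' @param province_code two-letter code to keep (default `"BC"`).
#' @param postal_prefix first postal letter accepted when province is blank.
#' @return `list(kept = cla_registry, removed_address_count = n,
#'   dropped_physician_count = n)`.
#' @export
filter_in_province <- function(registry, province_code = "BC",
                               postal_prefix = "V") {
  prov <- toupper(trimws(registry$province))
  pc <- toupper(gsub("[^A-Za-z0-9]", "", registry$postal_code))
  match_prov <- prov == toupper(province_code)
  blank_prov <- blank(registry$province)
  fallback <- blank_prov & nzchar(pc) & startsWith(pc, toupper(postal_prefix))
  has_addr <- !(blank(registry$line1) & blank(registry$city) &
                  blank(registry$postal_code))
  keep_row <- has_addr & (match_prov | fallback)
  removed <- sum(has_addr & !keep_row)

  kept <- registry[keep_row | !has_addr, , drop = FALSE]
  kept$province_flagged <- kept$province_flagged |
    (fallback[keep_row | !has_addr])
  # physicians whose every *addressed* row was removed are dropped;
  # physicians that only ever had blank addresses stay (unaddressed report)
  addressed_ids <- unique(registry$registrant_id[has_addr])
  surviving_ids <- unique(kept$registrant_id[!(blank(kept$line1) &
                                                 blank(kept$city) &
                                                 blank(kept$postal_code))])
  gone <- setdiff(addressed_ids, surviving_ids)
  kept <- kept[!(kept$registrant_id %in% gone), , drop = FALSE]
  list(kept = as_cla_registry(kept),
       removed_address_count = removed,
       dropped_physician_count = length(gone))
}

#' Physicians with no usable practice address
#'
#' @param registry a `cla_registry`.
#' @return data.frame of registrant_id / full_name for the unaddressed report.
#' @export
unaddressed_report <- function(registry) {
  no_addr <- blank(registry$line1) & blank(registry$city) &
    blank(registry$postal_code)
  unique(registry[no_addr, c("registrant_id", "full_name")])
}

#' Rows of a registry that carry a usable address
#'
#' @param registry a `cla_registry`.
#' @return the addressed subset, still a `cla_registry`.
#' @export
addressed_rows <- function(registry) {
  keep <- !(blank(registry$line1) & blank(registry$city) &
              blank(registry$postal_code))
  as_cla_registry(registry[keep, , drop = FALSE])
}

partial_list_categories <- c("walk_in", "upcc", "hospital", "corrections",
                             "long_term_care")

#' Read a partial facility list
#'
#' Authoritative external facility lists (walk-in clinics, urgent and
#' primary care centres, hospitals, corrections and long-term care
#' facilities) joined to address groups before any term matching.
#'
#' @param path CSV with columns `facility_name`, `line1`, `line2`, `city`,
#'   `province`, `postal_code`.
#' @param category one of `"walk_in"`, `"upcc"`, `"hospital"`,
#'   `"corrections"`, `"long_term_care"`.
#' @return data.frame with a `category` column stamped on every entry.
#' @export
read_partial_list <- function(path, category) {
  if (!category %in% partial_list_categories) {
    stop("unknown partial-list category: ", category, call. = FALSE)
  }
  df <- read_csv_strict(path)
  if (nrow(df) == 0) {
    warning("partial list '", category, "' is empty: ", path, call. = FALSE)
    df <- data.frame(facility_name = character(), line1 = character(),
                     line2 = character(), city = character(),
                     province = character(), postal_code = character(),
                     stringsAsFactors = FALSE)
  }
  for (cl in c("facility_name", "line1", "line2", "city", "province",
               "postal_code")) {
    if (!cl %in% names(df)) df[[cl]] <- rep("", nrow(df))
  }
  df$category <- rep(category, nrow(df))
  df
}

chsa_classes <- c("metropolitan", "large_urban", "medium_urban",
                  "small_urban", "rural_hub", "rural", "remote")

#' Read the community-health-service-area lookup table
#'
#' @param path CSV with columns `chsa_id`, `chsa_name`, `urban_rural_class`;
#'   the class vocabulary is closed to the seven values `metropolitan`,
#'   `large_urban`, `medium_urban`, `small_urban`, `rural_hub`, `rural`,
#'   `remote`.
#' @return data.frame of the three columns.
#' @export
read_chsa_table <- function(path) {
  df <- read_csv_strict(path)
  need <- c("chsa_id", "chsa_name", "urban_rural_class")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("CHSA table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$urban_rural_class), chsa_classes)
  if (length(bad)) {
    stop("CHSA table has unknown urban_rural_class value(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df[need]
}
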