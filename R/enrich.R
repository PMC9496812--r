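# Geographic enrichment: coordinates, community-health-service-area id and
# rurality class per address group. Pure annotation — never changes
# partition membership or group counts. The geocoder is a pluggable
# resolver contract (one address text in, coordinates + area id or
# "unresolved" out); offline runs use only the cache and are fully
# deterministic and network-free.

#' Read a geocode cache
#'
#' @param path CSV with columns `canonical_key`, `latitude`, `longitude`,
#'   `chsa_id`.
#' @return data.frame with numeric coordinates.
#' @export
read_geocode_cache <- function(path) {
  df <- read_csv_strict(path)
  need <- c("canonical_key", "latitude", "longitude", "chsa_id")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("geocode cache missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$latitude <- as.numeric(df$latitude)
  df$longitude <- as.numeric(df$longitude)
  df[need]
}

#' Geocode address groups
#'
#' The cache is consulted first; a configured resolver function is called
#' only for cache misses, and any resolver failure (including a thrown
#' error, e.g. a network fault) marks the address `unresolved` rather than
#' aborting the run. Unresolved addresses are flagged, never dropped.
#'
#' @param groups a `cla_groups` data.frame.
#' @param cache geocode cache data.frame (see [read_geocode_cache()]), or
#'   NULL.
#' @param resolver optional function(address_text) returning
#'   `list(latitude=, longitude=, chsa_id=)` or NULL for unresolved.
#' @param chsa optional CHSA lookup (see [read_chsa_table()]) to attach the
#'   rurality class.
#' @return data.frame keyed by `canonical_key` with `latitude`,
#'   `longitude`, `chsa_id`, `rurality`, `geocode_status`.
#' @export
geocode_groups <- function(groups, cache = NULL, resolver = NULL,
                           chsa = NULL) {
  n <- nrow(groups)
  ann <- data.frame(canonical_key = groups$canonical_key,
                    latitude = NA_real_, longitude = NA_real_,
                    chsa_id = "", rurality = "",
                    geocode_status = "unresolved", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    k <- groups$canonical_key[i]
    hit <- if (!is.null(cache)) which(cache$canonical_key == k) else integer()
    if (length(hit)) {
      j <- hit[1]
      ann$latitude[i] <- cache$latitude[j]
      ann$longitude[i] <- cache$longitude[j]
      ann$chsa_id[i] <- cache$chsa_id[j]
      ann$geocode_status[i] <- "cache_hit"
    } else if (!is.null(resolver)) {
      res <- tryCatch(resolver(groups$display_address[i]),
                      error = function(e) {
                        message("geocode resolver failed for '",
                                groups$display_address[i], "': ",
                                conditionMessage(e))
                        NULL
                      })
      if (!is.null(res)) {
        ann$latitude[i] <- res$latitude
        ann$longitude[i] <- res$longitude
        ann$chsa_id[i] <- res$chsa_id %||% ""
        ann$geocode_status[i] <- "resolved"
      }
    }
  }
  resolved <- ann$geocode_status != "unresolved"
  stopifnot(all(is.na(ann$latitude[resolved]) |
                  (ann$latitude[resolved] >= -90 & ann$latitude[resolved] <= 90)),
            all(is.na(ann$longitude[resolved]) |
                  (ann$longitude[resolved] >= -180 & ann$longitude[resolved] <= 180)))
  if (!is.null(chsa)) {
    m <- match(ann$chsa_id, chsa$chsa_id)
    ann$rurality <- ifelse(is.na(m), "", chsa$urban_rural_class[m])
  }
  ann
}

#' Attach partition, firing and geographic metadata to groups
#'
#' @param groups a `cla_groups` data.frame.
#' @param partition a `cla_partition` over the same groups.
#' @param geo output of [geocode_groups()] (or NULL).
#' @return the groups with `working_list`, `disposition`, `stage`,
#'   `provenance_detail`, `fired_atoms`, `latitude`, `longitude`,
#'   `chsa_id`, `rurality`, `geocode_status` columns added; row count and
#'   membership unchanged.
#' @export
annotate_metadata <- function(groups, partition, geo = NULL) {
  a <- partition$assignments
  m <- match(groups$canonical_key, a$canonical_key)
  stopifnot(!anyNA(m))
  out <- groups
  out$working_list <- a$working_list[m]
  out$disposition <- a$disposition[m]
  out$stage <- a$stage[m]
  out$provenance_detail <- a$detail[m]
  fired <- partition$fired
  out$fired_atoms <- vapply(groups$canonical_key, function(k) {
    paste(unique(fired$atom[fired$canonical_key == k]), collapse = "; ")
  }, character(1), USE.NAMES = FALSE)
  if (!is.null(geo)) {
    g <- match(groups$canonical_key, geo$canonical_key)
    out$latitude <- geo$latitude[g]
    out$longitude <- geo$longitude[g]
    out$chsa_id <- geo$chsa_id[g]
    out$rurality <- geo$rurality[g]
    out$geocode_status <- geo$geocode_status[g]
  } else {
    out$latitude <- NA_real_
    out$longitude <- NA_real_
    out$chsa_id <- ""
    out$rurality <- ""
    out$geocode_status <- "unresolved"
  }
  stopifnot(nrow(out) == nrow(groups))
  out
}
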