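# End-to-end orchestration: one reproducible, logged run from input CSVs
# to the final clinic list, flow report and run metadata. A run is fully
# determined by its config + inputs + seed; outputs are byte-identical
# across re-runs (run metadata carries an optional timestamp, disabled by
# default so whole output directories can be compared).

#' Assemble a run configuration
#'
#' @param registry path to the registry CSV.
#' @param partial_lists named character vector of partial-list CSV paths,
#'   keyed by category.
#' @param chsa optional CHSA lookup CSV path.
#' @param geocode_cache optional geocode cache CSV path.
#' @param overrides optional manual key-override CSV (columns `raw_key`,
#'   `replacement_key`).
#' @param verification_results optional prior verification results CSV.
#' @param out_dir output directory.
#' @param seed integer seed driving sampling.
#' @param fp_terms specialty match terms.
#' @param province_code,postal_prefix province filter settings.
#' @param term_order optional criterion precedence (default:
#'   exclusions first).
#' @param sampling_proportions optional named proportions for
#'   [sampling_plan()].
#' @param name_lists clinic-specific literal names per criterion.
#' @param timestamp write a timestamp into run metadata (default FALSE so
#'   re-runs are byte-identical).
#' @return a `cla_run_config` list.
#' @export
run_config <- function(registry, partial_lists = character(), chsa = NULL,
                       geocode_cache = NULL, overrides = NULL,
                       verification_results = NULL, out_dir = "cla_output",
                       seed = 1L, fp_terms = c("family"),
                       province_code = "BC", postal_prefix = "V",
                       term_order = NULL, sampling_proportions = NULL,
                       name_lists = list(), timestamp = FALSE) {
  cfg <- list(registry = registry, partial_lists = partial_lists,
              chsa = chsa, geocode_cache = geocode_cache,
              overrides = overrides,
              verification_results = verification_results,
              out_dir = out_dir, seed = as.integer(seed),
              fp_terms = fp_terms, province_code = province_code,
              postal_prefix = postal_prefix, term_order = term_order,
              sampling_proportions = sampling_proportions,
              name_lists = name_lists, timestamp = isTRUE(timestamp))
  class(cfg) <- "cla_run_config"
  cfg
}

#' Load a run configuration from YAML
#' @param path YAML file with the fields of [run_config()].
#' @return a `cla_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$registry)) {
    stop("invalid config: missing field 'registry'", call. = FALSE)
  }
  do.call(run_config, c(
    list(registry = y$registry),
    y[setdiff(names(y), "registry")]))
}

validate_run_config <- function(config) {
  if (!file.exists(config$registry)) {
    stop("missing input: ", config$registry, call. = FALSE)
  }
  for (p in c(unlist(config$partial_lists), config$chsa,
              config$geocode_cache, config$overrides,
              config$verification_results)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("missing input: ", p, call. = FALSE)
    }
  }
  bad <- setdiff(names(config$partial_lists), partial_list_categories)
  if (length(bad)) {
    stop("invalid config: unknown partial-list category ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(config)
}

#' Run the full pipeline
#'
#' Reads and filters the registry, canonicalizes and groups addresses,
#' joins partial lists, applies term criteria, falls back on practitioner
#' counts, enriches, consolidates (folding in verification results when
#' supplied), draws the next verification sample, and writes all outputs:
#' one CSV per working list, `final_clinics.csv`, `summary.csv`,
#' `flow_report.csv`, `verification_sample.csv`, side reports
#' (`unaddressed.csv`, `unjoined_partial_entries.csv`, `conflicts.csv`,
#' `near_duplicates.csv`) and `run_metadata.yaml` (config echo, input
#' checksums, conservation tallies).
#'
#' @param config a [run_config()] (or a YAML path).
#' @return invisibly, a list of the in-memory stage objects.
#' @export
cla_run <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  rules <- normalization_rules()
  criteria <- default_criteria(config$name_lists)

  reg <- read_registry(config$registry)
  n_phys <- length(unique(reg$registrant_id))
  fp <- filter_family_physicians(reg, config$fp_terms)
  message("FP filter: kept ", length(unique(fp$kept$registrant_id)),
          " of ", n_phys, " physicians (dropped ", fp$dropped_count, ")")
  prov <- filter_in_province(fp$kept, config$province_code,
                             config$postal_prefix)
  message("Province filter: removed ", prov$removed_address_count,
          " addresses; dropped ", prov$dropped_physician_count,
          " physicians")

  overrides <- if (!is.null(config$overrides)) {
    read_table(config$overrides)
  } else NULL
  groups <- group_unique_addresses(prov$kept, rules, overrides)
  n_pairings <- sum(groups$fp_assignment_count)
  message(nrow(groups), " unique addresses from ", n_pairings,
          " physician-address pairings")

  partial_lists <- lapply(seq_along(config$partial_lists), function(i) {
    read_partial_list(config$partial_lists[[i]],
                      names(config$partial_lists)[i])
  })
  names(partial_lists) <- names(config$partial_lists)

  pcfg <- partition_config(term_order = config$term_order, rules = rules)
  part <- partition_addresses(groups, partial_lists, criteria, pcfg)
  for (i in seq_len(nrow(part$flow_counts))) {
    message(sprintf("  %-32s in=%d assigned=%d remaining=%d",
                    part$flow_counts$stage[i], part$flow_counts$input_n[i],
                    part$flow_counts$assigned_n[i],
                    part$flow_counts$remaining_n[i]))
  }

  cache <- if (!is.null(config$geocode_cache)) {
    read_geocode_cache(config$geocode_cache)
  } else NULL
  chsa <- if (!is.null(config$chsa)) read_chsa_table(config$chsa) else NULL
  geo <- geocode_groups(groups, cache, resolver = NULL, chsa = chsa)
  annotated <- annotate_metadata(groups, part, geo)

  ver <- if (!is.null(config$verification_results)) {
    vr <- import_verification_results(config$verification_results)
    carry_forward(vr, part)$carried
  } else NULL
  final <- consolidate(annotated, ver)

  plan <- sampling_plan(config$sampling_proportions, seed = config$seed)
  sample_tbl <- draw_verification_sample(part, plan)

  write_run_outputs(config, final, part, annotated, groups, sample_tbl)
  invisible(list(registry = reg, groups = groups, partition = part,
                 annotated = annotated, final = final,
                 verification_sample = sample_tbl))
}

write_run_outputs <- function(config, final, part, annotated, groups,
                              sample_tbl) {
  od <- config$out_dir
  adr <- final$addresses
  final_cols <- c("canonical_key", "display_address", "working_list",
                  "final_disposition", "fp_assignment_count",
                  "physician_ids", "latitude", "longitude", "chsa_id",
                  "rurality", "stage", "provenance_detail", "fired_atoms")
  out <- adr[order(adr$canonical_key), final_cols]
  out$unique_fp_n <- vapply(out$physician_ids,
                            function(x) length(split_ids(x)), integer(1),
                            USE.NAMES = FALSE)
  write_table(out, file.path(od, "final_clinics.csv"))
  for (wl in sort(unique(adr$working_list))) {
    write_table(adr[adr$working_list == wl,
                    c("canonical_key", "display_address",
                      "fp_assignment_count", "stage", "provenance_detail")],
                file.path(od, paste0("working_list_", wl, ".csv")))
  }
  write_table(part$flow_counts, file.path(od, "flow_report.csv"))
  if (final$counts[["included"]] > 0) {
    write_table(geo_summary(final), file.path(od, "summary.csv"))
  }
  write_table(sample_tbl, file.path(od, "verification_sample.csv"))
  write_table(part$unjoined_partial_entries,
              file.path(od, "unjoined_partial_entries.csv"))
  write_table(part$conflicts, file.path(od, "conflicts.csv"))
  write_table(near_duplicate_report(groups),
              file.path(od, "near_duplicates.csv"))

  inputs <- c(registry = config$registry, unlist(config$partial_lists),
              chsa = config$chsa %||% character(),
              geocode_cache = config$geocode_cache %||% character())
  meta <- list(
    run_id = substr(tools::md5sum(file.path(od, "final_clinics.csv"))[[1]],
                    1, 12),
    seed = config$seed,
    input_checksums = stats::setNames(
      as.list(unname(tools::md5sum(unname(inputs)))), basename(inputs)),
    counts = as.list(final$counts),
    conservation = list(
      addresses = unname(final$counts[["included"]] +
                           final$counts[["excluded"]] +
                           final$counts[["undetermined"]]),
      fp_assignments = sum(groups$fp_assignment_count)),
    term_order = part$term_order,
    partial_list_order = part$partial_list_order)
  if (config$timestamp) meta$timestamp <- format(Sys.time(), tz = "UTC")
  yaml::write_yaml(meta, file.path(od, "run_metadata.yaml"))
  invisible(od)
}

#' Generate a synthetic study area and write its input files
#'
#' @param dir output directory.
#' @param config a [generator_config()].
#' @return the [run_config()] pointing at the written inputs, invisibly.
#' @export
cla_simulate <- function(dir, config = generator_config()) {
  data <- generate_synthetic_data(config)
  paths <- write_synthetic_data(data, dir)
  cfg <- run_config(
    registry = paths[["registry"]],
    partial_lists = stats::setNames(
      paths[paste0("partial_", partial_list_categories)],
      partial_list_categories),
    chsa = paths[["chsa"]],
    geocode_cache = paths[["geocode_cache"]],
    out_dir = file.path(dir, "output"),
    seed = config$seed)
  invisible(cfg)
}
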