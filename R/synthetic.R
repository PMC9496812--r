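# Synthetic fixture generator. Emulates the structural features of a
# license registry the pipeline must cope with — multi-address physicians,
# multi-physician addresses, spelling/format variants of one address,
# facility names drawn from the criterion vocabularies, out-of-province
# and non-family-physician records — with full gold labels so every stage
# is testable offline. It makes no claim of geographic or workforce
# realism.

synthetic_cities <- function() {
  data.frame(
    city = c("Vancouver", "Surrey", "Victoria", "Kelowna", "Nanaimo",
             "Kamloops", "Terrace", "Smithers", "Fernie", "Atlin"),
    chsa_id = sprintf("CHSA-%03d", 1:10),
    chsa_name = c("Vancouver Core", "Surrey Central", "Victoria Downtown",
                  "Kelowna City", "Nanaimo Harbour", "Kamloops South",
                  "Terrace Area", "Smithers Area", "Fernie Valley",
                  "Atlin North"),
    urban_rural_class = c("metropolitan", "metropolitan", "large_urban",
                          "large_urban", "medium_urban", "small_urban",
                          "rural_hub", "rural", "rural", "remote"),
    stringsAsFactors = FALSE)
}

# Street names deliberately free of any criterion vocabulary.
synthetic_streets <- function() {
  c("Main Street", "Oak Avenue", "Birch Road", "Cedar Drive",
    "Maple Boulevard", "Hemlock Street", "Granville Street",
    "Cambie Avenue", "Douglas Road", "Fir Street")
}

surname_pool <- c("Smith", "Lee", "Patel", "Garcia", "Chen", "Singh",
                  "Martin", "Brown", "Wilson", "Tremblay", "Nguyen",
                  "Campbell", "Fraser", "Stewart", "Morin", "Roy")

# One facility name per category, built from vocabulary that triggers the
# intended criterion (and only that criterion) under the default
# exclusion-first precedence; list-backed categories rely on their partial
# list, not their name.
synthetic_facility_name <- function(category, city, surname) {
  switch(category,
    walk_in = paste(surname, "Walk-In Medical"),
    upcc = paste(city, "Urgent and Primary Care Centre"),
    hospital = paste(city, "General Hospital"),
    corrections = paste(city, "Correctional Centre"),
    long_term_care = paste(surname, "Manor"),
    family = paste(surname, "Family Practice"),
    first_nations = paste(surname, "First Nations Health Centre"),
    clinic_center = paste(surname, "Medical Clinic"),
    sexual_health = paste(city, "Sexual Health Clinic"),
    womens_health = paste(surname, "Maternity Clinic"),
    virtual = paste(surname, "Telehealth Services"),
    administrative = paste(city, "Health Administration Office"),
    multi_practitioner = "",
    single_practitioner = "",
    stop("unknown category: ", category))
}

default_category_mix <- c(
  walk_in = 0.08, upcc = 0.04, hospital = 0.06, corrections = 0.03,
  long_term_care = 0.07, family = 0.10, first_nations = 0.04,
  clinic_center = 0.22, sexual_health = 0.03, womens_health = 0.05,
  virtual = 0.04, administrative = 0.06, multi_practitioner = 0.18)

# Physicians per clinic: mass concentrated at 2 with a long right tail to
# 23 — median 2, quartiles 2 and 4 under type-7 interpolation at scale.
default_fp_count_probs <- function() {
  p <- c(0.18, 0.34, 0.16, 0.12, 0.07, 0.04, 0.03, 0.02,
         rep(0.04 / 15, 15))
  stats::setNames(p, 1:23)
}

#' Generator configuration
#'
#' @param seed integer; all randomness flows from it.
#' @param n_clinics number of clinic-candidate addresses to plant (solo
#'   addresses are extra, see `n_solo_fps`).
#' @param category_mix named proportions over the working-list categories
#'   (must sum to 1).
#' @param fp_count_probs probabilities over 1..23 physicians per clinic.
#' @param n_solo_fps physicians alone at an unlabeled address (the
#'   single-practitioner truth).
#' @param n_non_fp physicians whose specialties exclude family medicine.
#' @param n_out_of_province family physicians with an address outside the
#'   province (half carry only that address and vanish; the rest carry it
#'   alongside an in-province clinic address).
#' @param n_unjoined_facilities partial-list facilities with no registered
#'   physician (exercises the unjoined report).
#' @param multi_address_rate share of clinic physicians also registered at
#'   a second clinic.
#' @param address_noise logical toggles: `case`, `abbreviation`, `suite`,
#'   `punctuation` — each enables one family of surface variants that the
#'   normalizer owns.
#' @return a `cla_generator_config`.
#' @export
generator_config <- function(seed = 1L, n_clinics = 60,
                             category_mix = default_category_mix,
                             fp_count_probs = default_fp_count_probs(),
                             n_solo_fps = 25, n_non_fp = 30,
                             n_out_of_province = 8,
                             n_unjoined_facilities = 2,
                             multi_address_rate = 0.08,
                             address_noise = list(case = FALSE,
                                                  abbreviation = FALSE,
                                                  suite = FALSE,
                                                  punctuation = FALSE)) {
  if (abs(sum(category_mix) - 1) > 1e-8) {
    stop("generator config error: category_mix must sum to 1", call. = FALSE)
  }
  counts <- c(n_clinics, n_solo_fps, n_non_fp, n_out_of_province,
              n_unjoined_facilities)
  if (any(counts < 0)) {
    stop("generator config error: counts must be >= 0", call. = FALSE)
  }
  if (n_clinics == 0 && any(category_mix > 0)) {
    stop("generator config error: category proportions over zero clinics",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_clinics = n_clinics,
                 category_mix = category_mix,
                 fp_count_probs = fp_count_probs, n_solo_fps = n_solo_fps,
                 n_non_fp = n_non_fp, n_out_of_province = n_out_of_province,
                 n_unjoined_facilities = n_unjoined_facilities,
                 multi_address_rate = multi_address_rate,
                 address_noise = address_noise),
            class = "cla_generator_config")
}

# Largest-remainder apportionment: exact n, deterministic.
apportion <- function(n, props) {
  raw <- n * props
  k <- floor(raw)
  short <- n - sum(k)
  if (short > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(short)]] <- k[ord[seq_len(short)]] + 1
  }
  stats::setNames(as.integer(k), names(props))
}

make_postal <- function(i) {
  letters_ok <- c("A", "B", "C", "E", "G", "H", "J", "K", "L", "M", "N", "P",
                  "R", "S", "T", "V", "W", "X", "Y", "Z")
  paste0("V", (i %% 10), letters_ok[(i %% 20) + 1], " ",
         ((i + 3) %% 10), letters_ok[((i + 7) %% 20) + 1], (i %% 7 + 1))
}

abbrev_back <- c(Street = "St.", Avenue = "Ave.", Road = "Rd.",
                 Drive = "Dr.", Boulevard = "Blvd.", Highway = "Hwy.")

# Render one planted address as a registry string, applying only the
# enabled noise families. Draws from the active RNG stream.
render_address_line <- function(number, street, unit, noise) {
  s <- street
  if (isTRUE(noise$abbreviation) && stats::runif(1) < 0.5) {
    for (full in names(abbrev_back)) {
      s <- sub(paste0("\\b", full, "\\b"), abbrev_back[[full]], s)
    }
  }
  line <- paste(number, s)
  if (nzchar(unit)) {
    if (isTRUE(noise$suite)) {
      fmt <- sample(1:3, 1)
      line <- switch(fmt,
                     paste0("Suite ", unit, " - ", line),
                     paste0("#", unit, " ", line),
                     paste0(unit, "-", line))
    } else {
      line <- paste0("Suite ", unit, " - ", line)
    }
  }
  if (isTRUE(noise$punctuation) && stats::runif(1) < 0.4) {
    line <- paste0(line, ",")
  }
  if (isTRUE(noise$case)) {
    u <- stats::runif(1)
    if (u < 0.3) line <- toupper(line) else if (u < 0.5) line <- tolower(line)
  }
  line
}

#' Generate a synthetic registry with gold labels
#'
#' Deterministic under the configured seed: the same config always yields
#' byte-identical CSVs through [write_synthetic_data()]. With all noise
#' disabled, running the full pipeline on the output reproduces the gold
#' labels exactly.
#'
#' @param config a [generator_config()].
#' @return list: `registry` (long-form `cla_registry`), `partial_lists`
#'   (named list of data.frames), `chsa` (lookup table), `geocode_cache`,
#'   `gold` (per planted address: canonical_key, working_list,
#'   disposition, chsa_id, rurality, fp_n, fp_ids — never read by the
#'   pipeline).
#' @export
generate_synthetic_data <- function(config = generator_config()) {
  set.seed(config$seed)
  cities <- synthetic_cities()
  streets <- synthetic_streets()
  rules <- normalization_rules()

  cat_n <- apportion(config$n_clinics, config$category_mix)
  categories <- rep(names(cat_n), cat_n)

  nclin <- length(categories)
  clinics <- data.frame(
    clinic_id = seq_len(nclin),
    category = categories,
    number = 100 + 10 * seq_len(nclin),
    street = sample(streets, nclin, replace = TRUE),
    city_idx = sample(nrow(cities), nclin, replace = TRUE),
    unit = ifelse(stats::runif(nclin) < 0.25,
                  as.character(200 + 10 * seq_len(nclin)), ""),
    stringsAsFactors = FALSE)
  clinics$city <- cities$city[clinics$city_idx]
  clinics$postal <- make_postal(clinics$clinic_id)
  clinics$name <- vapply(seq_len(nclin), function(i) {
    synthetic_facility_name(clinics$category[i], clinics$city[i],
                            sample(surname_pool, 1))
  }, character(1))

  fp_vals <- as.integer(names(config$fp_count_probs))
  clinics$fp_n <- sample(fp_vals, nclin, replace = TRUE,
                         prob = config$fp_count_probs)
  clinics$fp_n[clinics$category == "multi_practitioner" & clinics$fp_n < 2] <- 2L

  # physicians: one per assignment slot, then a share re-used at a second
  # clinic so multi-address physicians exist
  assign_clinic <- rep(clinics$clinic_id, clinics$fp_n)
  n_fp <- length(assign_clinic)
  fp_ids <- sprintf("R%05d", seq_len(n_fp))
  assignments <- data.frame(registrant_id = fp_ids, clinic_id = assign_clinic,
                            stringsAsFactors = FALSE)
  safe_sample <- function(x, k) x[sample.int(length(x), k)]
  n_extra <- floor(config$multi_address_rate * n_fp)
  movers <- character()
  if (n_extra > 0 && nclin > 1) {
    movers <- safe_sample(fp_ids, n_extra)
    for (m in movers) {
      own <- assignments$clinic_id[assignments$registrant_id == m]
      other <- safe_sample(setdiff(clinics$clinic_id, own), 1)
      assignments <- rbind(assignments,
                           data.frame(registrant_id = m, clinic_id = other,
                                      stringsAsFactors = FALSE))
    }
  }

  # solo physicians at unlabeled residential-style addresses
  solo_ids <- sprintf("S%05d", seq_len(config$n_solo_fps))
  solo <- data.frame(
    registrant_id = solo_ids,
    number = 5000 + 10 * seq_len(config$n_solo_fps),
    street = sample(streets, config$n_solo_fps, replace = TRUE),
    city_idx = sample(nrow(cities), config$n_solo_fps, replace = TRUE),
    stringsAsFactors = FALSE)
  solo$city <- cities$city[solo$city_idx]
  solo$postal <- make_postal(9000 + seq_len(config$n_solo_fps))

  fp_specialties <- c("Family Medicine", "Family Medicine",
                      "Family Medicine;Emergency Medicine",
                      "Family Practice")
  non_fp_specialties <- c("General Surgery", "Dermatology", "Cardiology",
                          "Psychiatry", "Radiology", "")

  surname_of <- function(id) surname_pool[(as.integer(substring(id, 2)) %%
                                             length(surname_pool)) + 1]

  rows <- list()
  add_row <- function(id, specialties, line1, city, province, postal, label) {
    rows[[length(rows) + 1L]] <<- data.frame(
      registrant_id = id, full_name = paste("Dr.", surname_of(id)),
      specialties = specialties, line1 = line1, line2 = "", city = city,
      province = province, postal_code = postal, source_label = label,
      province_flagged = FALSE, stringsAsFactors = FALSE)
  }

  noise <- config$address_noise
  all_fp <- unique(assignments$registrant_id)
  fp_spec <- stats::setNames(sample(fp_specialties, length(all_fp),
                                    replace = TRUE), all_fp)
  for (i in seq_len(nrow(assignments))) {
    id <- assignments$registrant_id[i]
    cl <- clinics[clinics$clinic_id == assignments$clinic_id[i], ]
    add_row(id, fp_spec[[id]],
            render_address_line(cl$number, cl$street, cl$unit, noise),
            cl$city, "BC", cl$postal, cl$name)
  }
  for (i in seq_len(nrow(solo))) {
    add_row(solo$registrant_id[i], sample(fp_specialties, 1),
            render_address_line(solo$number[i], solo$street[i], "", noise),
            solo$city[i], "BC", solo$postal[i], "")
  }
  # non-family physicians, parked at existing clinic addresses
  if (config$n_non_fp > 0) {
    for (i in seq_len(config$n_non_fp)) {
      id <- sprintf("N%05d", i)
      cl <- clinics[sample(nclin, 1), ]
      add_row(id, sample(non_fp_specialties, 1),
              render_address_line(cl$number, cl$street, cl$unit, noise),
              cl$city, "BC", cl$postal, cl$name)
    }
  }
  # out-of-province: half vanish entirely, half lose one address
  oop_cities <- data.frame(city = c("Calgary", "Toronto"),
                           province = c("AB", "ON"),
                           postal = c("T2P 1B1", "M5V 2T6"))
  n_pure <- floor(config$n_out_of_province / 2)
  if (config$n_out_of_province > 0) {
    # extras target single-address physicians so no registrant exceeds the
    # registry's address-block capacity
    n_side <- config$n_out_of_province - n_pure
    side_pool <- setdiff(all_fp, movers)
    side_ids <- if (n_side > 0 && length(side_pool) > 0) {
      safe_sample(side_pool, min(n_side, length(side_pool)))
    } else character()
    for (i in seq_len(config$n_out_of_province)) {
      oc <- oop_cities[(i %% 2) + 1, ]
      if (i <= n_pure) {
        id <- sprintf("O%05d", i)
        add_row(id, "Family Medicine",
                paste(700 + i, "8 Avenue"), oc$city, oc$province, oc$postal, "")
      } else if ((i - n_pure) <= length(side_ids)) {
        id <- side_ids[i - n_pure]
        add_row(id, fp_spec[[id]],
                paste(700 + i, "8 Avenue"), oc$city, oc$province, oc$postal, "")
      }
    }
  }
  registry <- as_cla_registry(do.call(rbind, rows))

  # partial lists: clean authoritative addresses for list-backed categories
  clean_line <- function(cl) {
    base <- paste(cl$number, cl$street)
    if (nzchar(cl$unit)) paste0("Suite ", cl$unit, " - ", base) else base
  }
  partial_lists <- stats::setNames(
    lapply(partial_list_categories, function(cat) {
      sub <- clinics[clinics$category == cat, , drop = FALSE]
      df <- data.frame(
        facility_name = sub$name,
        line1 = vapply(seq_len(nrow(sub)),
                       function(j) clean_line(sub[j, ]), character(1)),
        line2 = rep("", nrow(sub)), city = sub$city,
        province = rep("BC", nrow(sub)),
        postal_code = sub$postal, stringsAsFactors = FALSE)
      df$category <- rep(cat, nrow(sub))
      df
    }), partial_list_categories)
  # facilities with no registered physician
  if (config$n_unjoined_facilities > 0) {
    uj <- data.frame(
      facility_name = paste("Orphan Walk-In Medical",
                            seq_len(config$n_unjoined_facilities)),
      line1 = paste(8000 + 10 * seq_len(config$n_unjoined_facilities),
                    "Hemlock Street"),
      line2 = "", city = "Vancouver", province = "BC",
      postal_code = make_postal(700 + seq_len(config$n_unjoined_facilities)),
      category = "walk_in", stringsAsFactors = FALSE)
    partial_lists$walk_in <- rbind(partial_lists$walk_in, uj)
  }

  chsa <- cities[, c("chsa_id", "chsa_name", "urban_rural_class")]

  # gold labels + geocode cache keyed on the clean rendering
  gold_rows <- list()
  cache_rows <- list()
  fp_at_clinic <- function(cid) {
    sort(unique(assignments$registrant_id[assignments$clinic_id == cid]))
  }
  for (i in seq_len(nclin)) {
    cl <- clinics[i, ]
    key <- normalize_address(clean_line(cl), "", cl$city, "BC", cl$postal,
                             rules)$canonical_key
    ids <- fp_at_clinic(cl$clinic_id)
    wl <- cl$category
    gold_rows[[i]] <- data.frame(
      canonical_key = key, working_list = wl,
      disposition = unname(working_list_dispositions[wl]),
      chsa_id = cities$chsa_id[cl$city_idx],
      rurality = cities$urban_rural_class[cl$city_idx],
      fp_n = length(ids), fp_ids = collapse_ids(ids),
      stringsAsFactors = FALSE)
    cache_rows[[i]] <- data.frame(
      canonical_key = key,
      latitude = round(48 + 12 * stats::runif(1), 5),
      longitude = round(-139 + 25 * stats::runif(1), 5),
      chsa_id = cities$chsa_id[cl$city_idx], stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(solo))) {
    key <- normalize_address(paste(solo$number[i], solo$street[i]), "",
                             solo$city[i], "BC", solo$postal[i],
                             rules)$canonical_key
    gold_rows[[length(gold_rows) + 1L]] <- data.frame(
      canonical_key = key, working_list = "single_practitioner",
      disposition = "undetermined",
      chsa_id = cities$chsa_id[solo$city_idx[i]],
      rurality = cities$urban_rural_class[solo$city_idx[i]],
      fp_n = 1L, fp_ids = solo$registrant_id[i], stringsAsFactors = FALSE)
    cache_rows[[length(cache_rows) + 1L]] <- data.frame(
      canonical_key = key,
      latitude = round(48 + 12 * stats::runif(1), 5),
      longitude = round(-139 + 25 * stats::runif(1), 5),
      chsa_id = cities$chsa_id[solo$city_idx[i]], stringsAsFactors = FALSE)
  }
  gold <- do.call(rbind, gold_rows)
  stopifnot(!anyDuplicated(gold$canonical_key))

  list(registry = registry, partial_lists = partial_lists, chsa = chsa,
       geocode_cache = do.call(rbind, cache_rows), gold = gold,
       config = config)
}

#' Write generator output as the pipeline's input CSVs
#'
#' Same schemas as real inputs; gold labels land in `gold_labels.csv`,
#' which the pipeline never reads.
#'
#' @param data output of [generate_synthetic_data()].
#' @param dir output directory (created if needed).
#' @param schema registry column mapping for [write_registry()].
#' @return named vector of written paths, invisibly.
#' @export
write_synthetic_data <- function(data, dir,
                                 schema = registry_schema()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(registry = file.path(dir, "registry.csv"))
  write_registry(data$registry, paths[["registry"]], schema)
  for (cat in names(data$partial_lists)) {
    p <- file.path(dir, paste0("partial_", cat, ".csv"))
    write_table(data$partial_lists[[cat]][
      , c("facility_name", "line1", "line2", "city", "province",
          "postal_code")], p)
    paths[[paste0("partial_", cat)]] <- p
  }
  paths[["chsa"]] <- file.path(dir, "chsa.csv")
  write_table(data$chsa, paths[["chsa"]])
  paths[["geocode_cache"]] <- file.path(dir, "geocode_cache.csv")
  write_table(data$geocode_cache, paths[["geocode_cache"]])
  paths[["gold"]] <- file.path(dir, "gold_labels.csv")
  write_table(data$gold, paths[["gold"]])
  invisible(paths)
}

#' Hand-built hard cases for the pipeline
#'
#' A fixed fixture of documented adversarial inputs with their expected
#' assignment under the default configuration: the Hospice/hospital-prefix
#' collision, the women's-family precedence sensitivity, a post-office
#' box, two suites in one building, one physician at three locations, and
#' a two-variant spelling of one address.
#'
#' @return list `registry` (a `cla_registry`), `partial_lists`, and
#'   `expected` (data.frame: case, line1, expected_working_list).
#' @export
adversarial_cases <- function() {
  row <- function(id, spec, line1, city, postal, label) {
    data.frame(registrant_id = id, full_name = paste("Dr.", id),
               specialties = spec, line1 = line1, line2 = "", city = city,
               province = "BC", postal_code = postal, source_label = label,
               province_flagged = FALSE, stringsAsFactors = FALSE)
  }
  registry <- as_cla_registry(rbind(
    # 1. Hospice fires the hospital prefix term (not on the hospital list)
    row("A00001", "Family Medicine", "100 Main Street", "Victoria",
        "V8V 1A1", "Hospice House"),
    row("A00002", "Family Medicine", "100 Main Street", "Victoria",
        "V8V 1A1", "Hospice House"),
    # 2. order-sensitive: women's-health (exclusion) beats family inclusion
    row("A00003", "Family Medicine", "200 Oak Avenue", "Victoria",
        "V8V 2B2", "Women's Family Clinic"),
    row("A00004", "Family Medicine", "200 Oak Avenue", "Victoria",
        "V8V 2B2", "Women's Family Clinic"),
    # 3. post-office box
    row("A00005", "Family Medicine", "PO Box 99", "Smithers", "V0J 2N0", ""),
    # 4. same building, different suites: distinct candidate clinics
    row("A00006", "Family Medicine", "Suite 200 - 1234 Main Street",
        "Vancouver", "V5K 1A1", ""),
    row("A00007", "Family Medicine", "Suite 300 - 1234 Main Street",
        "Vancouver", "V5K 1A1", ""),
    # 5. one physician registered at three locations
    row("A00008", "Family Medicine", "300 Birch Road", "Kelowna", "V1Y 1A1", ""),
    row("A00008", "Family Medicine", "310 Birch Road", "Kelowna", "V1Y 1A2", ""),
    row("A00008", "Family Medicine", "320 Birch Road", "Kelowna", "V1Y 1A3", ""),
    # 6. two spelling variants of one address merge into one group
    row("A00009", "Family Medicine", "Suite 400 – 4321 Cambie Ave.",
        "Vancouver", "v5z4s6", ""),
    row("A00010", "Family Medicine", "400-4321 CAMBIE AVENUE", "Vancouver",
        "V5Z 4S6", "")
  ))
  expected <- data.frame(
    case = c("hospice_term_collision", "womens_family_precedence",
             "po_box", "suite_200", "suite_300",
             "three_locations", "variant_merge"),
    line1 = c("100 Main Street", "200 Oak Avenue", "PO Box 99",
              "Suite 200 - 1234 Main Street", "Suite 300 - 1234 Main Street",
              "300 Birch Road", "Suite 400 – 4321 Cambie Ave."),
    city = c("Victoria", "Victoria", "Smithers", "Vancouver", "Vancouver",
             "Kelowna", "Vancouver"),
    postal_code = c("V8V 1A1", "V8V 2B2", "V0J 2N0", "V5K 1A1", "V5K 1A1",
                    "V1Y 1A1", "V5Z 4S6"),
    expected_working_list = c("hospital", "womens_health",
                              "single_practitioner", "single_practitioner",
                              "single_practitioner", "single_practitioner",
                              "multi_practitioner"),
    stringsAsFactors = FALSE)
  list(registry = registry, partial_lists = list(), expected = expected)
}
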