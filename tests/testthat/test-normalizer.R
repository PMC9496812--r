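test_that("spelling/format variants of one address share a canonical key", {
  a <- normalize_address("Suite 200 – 1234 Main St.", "", "Vancouver", "BC",
                         "v5k1a1")
  b <- normalize_address("200-1234 MAIN STREET", "", "Vancouver", "BC",
                         "V5K 1A1")
  c <- normalize_address("#200 1234 Main Street", "", "Vancouver", "BC",
                         "V5K 1A1")
  expect_equal(a$canonical_key, b$canonical_key)
  expect_equal(a$canonical_key, c$canonical_key)
  expect_equal(a$postal_code_norm, "V5K 1A1")
  expect_equal(a$unit, "200")
})

test_that("units are kept in the key by default and droppable by config", {
  keep <- normalization_rules()
  drop <- normalization_rules(keep_units = FALSE)
  s2 <- normalize_address("Suite 200 - 1234 Main St", "", "Vancouver", "BC",
                          "V5K 1A1", keep)
  s3 <- normalize_address("Suite 300 - 1234 Main St", "", "Vancouver", "BC",
                          "V5K 1A1", keep)
  expect_false(s2$canonical_key == s3$canonical_key)
  d2 <- normalize_address("Suite 200 - 1234 Main St", "", "Vancouver", "BC",
                          "V5K 1A1", drop)
  d3 <- normalize_address("Suite 300 - 1234 Main St", "", "Vancouver", "BC",
                          "V5K 1A1", drop)
  expect_equal(d2$canonical_key, d3$canonical_key)
})

test_that("normalization is idempotent on randomized synthetic addresses", {
  set.seed(42)
  streets <- c("Main St", "Oak Ave.", "Birch Rd", "Cedar Drive",
               "MAPLE BLVD", "Granville   Street")
  for (i in 1:60) {
    unit <- sample(c("", "Suite 210 - ", "#210 ", "210-"), 1)
    line1 <- paste0(unit, sample(100:999, 1), " ", sample(streets, 1))
    city <- sample(c("Vancouver", "VICTORIA", "smithers"), 1)
    postal <- sample(c("V5K1A1", "v5k 1a1", ""), 1)
    n1 <- normalize_address(line1, "", city, "BC", postal)
    # rebuild a raw address from the canonical pieces and re-normalize
    line_back <- if (nzchar(n1$unit)) {
      paste0(n1$unit, "-", n1$street_norm)
    } else {
      n1$street_norm
    }
    n2 <- normalize_address(line_back, "", n1$city_norm, "BC",
                            n1$postal_code_norm)
    expect_equal(n2$canonical_key, n1$canonical_key)
  }
})

test_that("post-office boxes are flagged and empty addresses rejected", {
  p <- normalize_address("PO Box 99", "", "Smithers", "BC", "")
  expect_true(p$po_box_flag)
  p2 <- normalize_address("P.O. Box 12", "", "Fernie", "BC", "V0B 1M0")
  expect_true(p2$po_box_flag)
  expect_false(normalize_address("99 Boxwood St", "", "Fernie", "BC",
                                 "")$po_box_flag)
  expect_error(normalize_address("", "", "", "", ""), "unusable")
})

test_that("grouping merges variants, de-duplicates physicians and
           conserves pairings", {
  reg <- make_registry(
    reg_row("R1", line1 = "Suite 200 - 1234 Main St."),
    reg_row("R2", line1 = "200-1234 MAIN STREET"),
    reg_row("R3", line1 = "#200 1234 Main Street"),
    reg_row("R4", line1 = "900 Oak Avenue", city = "Victoria",
            postal = "V8V 1A1"),
    reg_row("R4", line1 = "901 Oak Avenue", city = "Victoria",
            postal = "V8V 1A1"),
    # same physician lists one address twice: counted once
    reg_row("R5", line1 = "77 Fir Street", postal = "V5T 1A1"),
    reg_row("R5", line1 = "77 Fir St.", postal = "V5T 1A1"))
  g <- group_unique_addresses(reg)
  shared <- g[grepl("1234 main street", g$canonical_key), ]
  expect_equal(nrow(shared), 1)
  expect_equal(shared$fp_assignment_count, 3)
  expect_setequal(strsplit(shared$physician_ids, ";")[[1]],
                  c("R1", "R2", "R3"))
  expect_equal(sum(g$canonical_key %in%
                     g$canonical_key[grepl("oak avenue", g$canonical_key)]), 2)
  fir <- g[grepl("fir street", g$canonical_key), ]
  expect_equal(fir$fp_assignment_count, 1)
  # pairing conservation: distinct (physician, key) pairs = 3 + 2 + 1
  expect_equal(sum(g$fp_assignment_count), 6)
})

test_that("grouping equals a brute-force all-pairs merge on small inputs", {
  data <- generate_synthetic_data(generator_config(
    seed = 13, n_clinics = 40,
    address_noise = list(case = TRUE, abbreviation = TRUE, suite = TRUE,
                         punctuation = TRUE)))
  reg <- addressed_rows(filter_in_province(
    filter_family_physicians(data$registry)$kept)$kept)
  expect_lte(nrow(reg), 200)
  g <- group_unique_addresses(reg)

  # brute force: pairwise key comparison -> connected components
  keys <- vapply(seq_len(nrow(reg)), function(i) {
    normalize_address(reg$line1[i], reg$line2[i], reg$city[i],
                      reg$province[i], reg$postal_code[i])$canonical_key
  }, character(1))
  comp <- seq_along(keys)
  for (i in seq_along(keys)) {
    for (j in seq_along(keys)) {
      if (keys[i] == keys[j]) comp[comp == comp[j]] <- comp[i]
    }
  }
  brute_sizes <- sort(as.integer(table(
    vapply(split(reg$registrant_id, comp), function(x)
      length(unique(x)), integer(1)))))
  expect_equal(length(unique(comp)), nrow(g))
  pkg_sizes <- sort(as.integer(table(g$fp_assignment_count)))
  expect_equal(brute_sizes, pkg_sizes)
})

test_that("manual overrides rewrite keys before grouping", {
  reg <- make_registry(
    reg_row("R1", line1 = "PO Box 99", city = "Smithers", postal = ""),
    reg_row("R2", line1 = "12 Main Street", city = "Smithers",
            postal = "V0J 2N0"))
  base <- group_unique_addresses(reg)
  expect_equal(nrow(base), 2)
  ov <- data.frame(raw_key = "|po box 99|smithers|",
                   replacement_key = "|12 main street|smithers|v0j 2n0",
                   stringsAsFactors = FALSE)
  merged <- group_unique_addresses(reg, overrides = ov)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$fp_assignment_count, 2)
  # identity and empty overrides are no-ops; unknown target warns
  same <- group_unique_addresses(reg, overrides = ov[0, ])
  expect_equal(same$canonical_key, base$canonical_key)
  expect_warning(
    apply_overrides(c("a|b"), data.frame(raw_key = "zzz",
                                         replacement_key = "a|b")),
    "not present")
})

test_that("near-duplicate report finds lookalike keys without merging", {
  g <- group_unique_addresses(make_registry(
    reg_row("R1", line1 = "1234 Main Street"),
    reg_row("R2", line1 = "1234 Mane Street"),
    reg_row("R3", line1 = "99 Completely Different Boulevard",
            city = "Terrace", postal = "V8G 1A1")))
  expect_equal(nrow(g), 3)
  rep <- near_duplicate_report(g, threshold = 0.85)
  expect_equal(nrow(rep), 1)
  expect_true(all(grepl("ma[in]*e* street", rep$key_a)))
})
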