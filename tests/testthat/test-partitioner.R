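make_groups <- function(...) {
  g <- group_unique_addresses(make_registry(...))
  g
}

pl_entry <- function(name, line1, city = "Vancouver", postal = "V5K 1A1",
                     category = "hospital") {
  data.frame(facility_name = name, line1 = line1, line2 = "", city = city,
             province = "BC", postal_code = postal, category = category,
             stringsAsFactors = FALSE)
}

test_that("partial-list joins precede term matching and log conflicts", {
  g <- make_groups(
    reg_row("R1", line1 = "1 Hosp Way", label = "Family Medical Clinic",
            postal = "V1A 1A1"),
    reg_row("R2", line1 = "2 Walk Way", label = "", postal = "V1A 1A2"),
    reg_row("R3", line1 = "3 Plain Street", label = "", postal = "V1A 1A3"))
  pls <- list(
    hospital = pl_entry("St X Hospital", "1 Hosp Way", postal = "V1A 1A1"),
    walk_in = pl_entry("Quick Care Walk-In", "2 Walk Way",
                       postal = "V1A 1A2", category = "walk_in"),
    long_term_care = pl_entry("Dual Manor", "1 Hosp Way", postal = "V1A 1A1",
                              category = "long_term_care"))
  part <- partition_addresses(g, pls)
  a <- part$assignments
  # a hospital-listed address carrying a "Family" label is still a hospital
  expect_equal(a$working_list[grepl("hosp way", a$canonical_key)], "hospital")
  expect_equal(a$stage[grepl("hosp way", a$canonical_key)], "partial_list")
  expect_equal(a$working_list[grepl("walk way", a$canonical_key)], "walk_in")
  # the hospital/LTC dual listing is resolved by order and logged
  expect_equal(nrow(part$conflicts), 1)
  expect_equal(part$conflicts$working_list, "long_term_care")
})

test_that("unjoined partial-list entries are reported, not dropped", {
  g <- make_groups(reg_row("R1", line1 = "5 Main Street"))
  pls <- list(walk_in = pl_entry("Ghost Clinic", "99 Nowhere Street",
                                 postal = "V9Z 9Z9", category = "walk_in"))
  part <- partition_addresses(g, pls)
  expect_equal(nrow(part$unjoined_partial_entries), 1)
  expect_equal(part$unjoined_partial_entries$facility_name, "Ghost Clinic")
})

test_that("term stage claims by configured precedence; both orders work", {
  g <- make_groups(
    reg_row("R1", line1 = "10 Oak Avenue", label = "Women's Family Clinic"),
    reg_row("R2", line1 = "10 Oak Avenue", label = "Women's Family Clinic"),
    reg_row("R3", line1 = "20 Oak Avenue",
            label = "First Nations Health Centre"))
  crits <- default_criteria()
  excl_first <- partition_addresses(g, list(), crits)
  a1 <- excl_first$assignments
  expect_equal(a1$working_list[grepl("10 oak", a1$canonical_key)],
               "womens_health")
  expect_equal(a1$working_list[grepl("20 oak", a1$canonical_key)],
               "first_nations")

  tb <- term_bearing_criteria(crits)
  pol <- vapply(crits[tb], `[[`, character(1), "polarity")
  incl_first <- partition_addresses(
    g, list(), crits,
    partition_config(term_order = c(tb[pol == "include"],
                                    tb[pol == "exclude"])))
  a2 <- incl_first$assignments
  expect_equal(a2$working_list[grepl("10 oak", a2$canonical_key)], "family")

  expect_error(
    partition_addresses(g, list(), crits,
                        partition_config(term_order = c("family", "bogus"))),
    "bogus")
  expect_error(
    partition_addresses(g, list(), crits,
                        partition_config(term_order = "family")),
    "omits")
})

test_that("count fallback splits on the two-physician threshold", {
  g <- make_groups(
    reg_row("R1", line1 = "1 Plain St", postal = "V1B 1B1"),
    reg_row("R2", line1 = "2 Plain St", postal = "V1B 1B2"),
    reg_row("R3", line1 = "2 Plain St", postal = "V1B 1B2"),
    reg_row("R4", line1 = "3 Plain St", postal = "V1B 1B3"),
    reg_row("R5", line1 = "3 Plain St", postal = "V1B 1B3"),
    reg_row("R6", line1 = "3 Plain St", postal = "V1B 1B3"))
  fb <- count_fallback(g)
  got <- stats::setNames(fb$working_list, sub("\\|.*", "",
                                              sub("^\\|", "", fb$canonical_key)))
  expect_equal(unname(got[grepl("1 plain", names(got))]),
               "single_practitioner")
  expect_equal(unname(got[grepl("2 plain", names(got))]),
               "multi_practitioner")
  expect_equal(unname(got[grepl("3 plain", names(got))]),
               "multi_practitioner")
})

test_that("with no criteria and no lists everything reaches the fallback", {
  g <- make_groups(
    reg_row("R1", line1 = "1 Plain St", label = "Totally A Hospital"),
    reg_row("R2", line1 = "2 Plain St", postal = "V1B 1B2"))
  none <- list(a = term_criterion("a", "include", "zzzznever"))
  part <- partition_addresses(g, list(), none,
                              partition_config(term_order = "a"))
  expect_setequal(part$assignments$stage, "count_fallback")
})

test_that("the partition is exhaustive, exclusive and order-invariant", {
  data <- generate_synthetic_data(generator_config(seed = 21, n_clinics = 30))
  reg <- filter_in_province(filter_family_physicians(
    data$registry)$kept)$kept
  g <- group_unique_addresses(reg)
  part <- partition_addresses(g, data$partial_lists)
  a <- part$assignments
  expect_equal(nrow(a), nrow(g))
  expect_false(anyDuplicated(a$canonical_key) > 0)
  expect_setequal(a$canonical_key, g$canonical_key)
  expect_equal(sum(a$fp_assignment_count), sum(g$fp_assignment_count))
  # permuting input rows yields the identical partition
  set.seed(1)
  g2 <- g[sample(nrow(g)), , drop = FALSE]
  part2 <- partition_addresses(g2, data$partial_lists)
  expect_equal(part2$assignments, part$assignments)
  expect_equal(part2$flow_counts, part$flow_counts)
  # flow report conserves counts stage by stage
  fl <- part$flow_counts
  expect_equal(fl$input_n[1], nrow(g))
  expect_true(all(fl$input_n - fl$assigned_n == fl$remaining_n))
  expect_equal(fl$remaining_n[nrow(fl)], 0)
})

test_that("removing a partial-list entry moves its group to a later stage", {
  g <- make_groups(
    reg_row("R1", line1 = "8 Hospital Hill", label = "City General Hospital"),
    reg_row("R2", line1 = "8 Hospital Hill", label = "City General Hospital"))
  with_pl <- partition_addresses(
    g, list(hospital = pl_entry("City General Hospital", "8 Hospital Hill")))
  expect_equal(with_pl$assignments$stage, "partial_list")
  without <- partition_addresses(g, list())
  expect_equal(without$assignments$stage, "term")
  expect_equal(without$assignments$working_list, "hospital")
})
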