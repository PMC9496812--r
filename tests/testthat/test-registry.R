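test_that("read_registry parses address blocks and rejects duplicate ids", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_registry_csv(path, list(
    c(registrant_id = "R1", full_name = "Dr. A", specialties = "Family Medicine",
      addr1_line1 = "100 Main Street", addr1_city = "Vancouver",
      addr1_province = "BC", addr1_postal_code = "V5K 1A1",
      addr2_line1 = "200 Oak Avenue", addr2_city = "Victoria",
      addr2_province = "BC", addr2_postal_code = "V8V 1A1"),
    c(registrant_id = "R2", full_name = "Dr. B", specialties = "Dermatology",
      addr1_line1 = "300 Birch Road", addr1_city = "Kelowna",
      addr1_province = "BC", addr1_postal_code = "V1Y 1A1",
      addr2_line1 = "", addr2_city = "", addr2_province = "",
      addr2_postal_code = "")))
  reg <- suppressMessages(read_registry(path))
  expect_s3_class(reg, "cla_registry")
  expect_equal(sum(reg$registrant_id == "R1"), 2)  # two address blocks
  expect_equal(sum(reg$registrant_id == "R2"), 1)

  dup <- withr::local_tempfile(fileext = ".csv")
  write_registry_csv(dup, list(
    c(registrant_id = "R1", full_name = "a", specialties = "x",
      addr1_line1 = "1 A St", addr1_city = "V", addr1_province = "BC",
      addr1_postal_code = "V1A 1A1"),
    c(registrant_id = "R1", full_name = "b", specialties = "y",
      addr1_line1 = "2 B St", addr1_city = "V", addr1_province = "BC",
      addr1_postal_code = "V1A 1A2"),
    c(registrant_id = "R3", full_name = "c", specialties = "z",
      addr1_line1 = "3 C St", addr1_city = "V", addr1_province = "BC",
      addr1_postal_code = "V1A 1A3")))
  expect_error(read_registry(dup), "R1")
})

test_that("schema errors name the missing column; empty file warns", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(registrant_id = "R1", full_name = "x"),
                   path, row.names = FALSE)
  expect_error(read_registry(path), "specialties")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("registrant_id,full_name,specialties", empty)
  expect_warning(reg <- read_registry(empty), "empty")
  expect_equal(nrow(reg), 0)
})

test_that("synthetic registry round-trips through write/read unchanged", {
  data <- generate_synthetic_data(generator_config(seed = 5, n_clinics = 30))
  path <- withr::local_tempfile(fileext = ".csv")
  write_registry(data$registry, path)
  back <- suppressMessages(read_registry(path))
  expect_equal(length(unique(back$registrant_id)),
               length(unique(data$registry$registrant_id)))
  cols <- c("registrant_id", "line1", "city", "province", "postal_code",
            "source_label")
  orig <- data$registry[do.call(order, data$registry[cols]), cols]
  got <- back[do.call(order, back[cols]), cols]
  rownames(orig) <- rownames(got) <- NULL
  expect_equal(got, orig)
})

test_that("family-physician filter matches any specialty, conserves counts", {
  reg <- make_registry(
    reg_row("R1", "Family Medicine"),
    reg_row("R2", "General Surgery"),
    reg_row("R3", "Family Medicine;Emergency Medicine"),
    reg_row("R4", ""))
  res <- filter_family_physicians(reg)
  expect_setequal(unique(res$kept$registrant_id), c("R1", "R3"))
  expect_equal(res$dropped_count, 2)
  expect_equal(length(unique(res$kept$registrant_id)) + res$dropped_count, 4)
  expect_error(filter_family_physicians(reg, character()), "non-empty")
})

test_that("province filter removes addresses, drops emptied physicians,
           flags postal-prefix fallbacks", {
  reg <- make_registry(
    reg_row("R1", line1 = "1 A St", province = "BC"),
    reg_row("R1", line1 = "2 B St", city = "Calgary", province = "AB",
            postal = "T2P 1B1"),
    reg_row("R2", line1 = "3 C St", city = "Toronto", province = "ON",
            postal = "M5V 2T6"),
    reg_row("R3", line1 = "4 D St", province = "", postal = "V6B 1A1"))
  res <- filter_in_province(reg)
  expect_setequal(unique(res$kept$registrant_id), c("R1", "R3"))
  expect_equal(sum(res$kept$registrant_id == "R1"), 1)
  expect_equal(res$removed_address_count, 2)
  expect_equal(res$dropped_physician_count, 1)
  flagged <- res$kept[res$kept$registrant_id == "R3", ]
  expect_true(all(flagged$province_flagged))
})

test_that("FP and province filters commute on synthetic registries", {
  data <- generate_synthetic_data(generator_config(seed = 9, n_clinics = 25))
  reg <- data$registry
  a <- filter_in_province(filter_family_physicians(reg)$kept)$kept
  b <- filter_family_physicians(filter_in_province(reg)$kept)$kept
  key <- function(r) sort(paste(r$registrant_id, r$line1, r$postal_code))
  expect_equal(key(a), key(b))
})

test_that("partial lists are stamped with category and validate it;
           CHSA vocabulary is closed", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(data.frame(facility_name = c("A Hospital", "B Hospital"),
                         line1 = c("1 X St", "2 Y St"), line2 = "",
                         city = "Vancouver", province = "BC",
                         postal_code = c("V1A 1A1", "V1A 1A2")), path)
  pl <- read_partial_list(path, "hospital")
  expect_equal(nrow(pl), 2)
  expect_true(all(pl$category == "hospital"))
  expect_error(read_partial_list(path, "pharmacy"), "unknown")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("facility_name,line1,line2,city,province,postal_code", empty)
  expect_warning(pl0 <- read_partial_list(empty, "long_term_care"), "empty")
  expect_equal(nrow(pl0), 0)

  cpath <- withr::local_tempfile(fileext = ".csv")
  write_table(data.frame(chsa_id = "C1", chsa_name = "X",
                         urban_rural_class = "suburban"), cpath)
  expect_error(read_chsa_table(cpath), "suburban")
})

test_that("write_table then read_table is the identity on output schemas", {
  df <- data.frame(canonical_key = c("a|b", "c,d\"e"),
                   display_address = c("1 Main St, Vancouver", "2 Oak Ave"),
                   fp_assignment_count = c("3", "1"),
                   stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(df, path)
  expect_equal(read_table(path), df)
})
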