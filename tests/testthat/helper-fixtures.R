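# Small in-code fixture builders shared across test files.

reg_row <- function(id, spec = "Family Medicine", line1 = "100 Main Street",
                    city = "Vancouver", province = "BC",
                    postal = "V5K 1A1", label = "", line2 = "") {
  data.frame(registrant_id = id, full_name = paste("Dr.", id),
             specialties = spec, line1 = line1, line2 = line2, city = city,
             province = province, postal_code = postal,
             source_label = label, province_flagged = FALSE,
             stringsAsFactors = FALSE)
}

make_registry <- function(...) {
  df <- rbind(...)
  class(df) <- c("cla_registry", "data.frame")
  df
}

# A minimal annotated-addresses frame accepted by consolidate().
annotated_row <- function(key, disposition, fp_n = 1,
                          ids = paste0("R", seq_len(fp_n), "_", key),
                          rurality = "metropolitan",
                          working_list = "clinic_center") {
  data.frame(canonical_key = key, display_address = key,
             working_list = working_list, disposition = disposition,
             fp_assignment_count = fp_n,
             physician_ids = paste(ids, collapse = ";"),
             rurality = rurality, stringsAsFactors = FALSE)
}

# A bare partition object for sampling tests.
fake_partition <- function(assignments) {
  structure(list(assignments = assignments), class = "cla_partition")
}

# Write a wide registry CSV from raw field lists.
write_registry_csv <- function(path, rows) {
  df <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(as.list(r), stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}
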