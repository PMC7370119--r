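test_that("packaged census loads with the curated partition and alias lookup works", {
  cen <- rnamod_census()
  expect_s3_class(cen, "mod_census")
  expect_identical(nrow(cen$records), 158L)
  st <- table(cen$records$status)
  expect_identical(unname(st[["placed"]]), 134L)
  expect_identical(unname(st[["unplaced"]]), 3L)
  expect_identical(unname(st[["nascent"]]), 21L)

  expect_identical(census_record(cen, "m6A")$full_name, "6-methyladenosine")
  expect_identical(census_record(cen, "psi-m")$short_name, paste0(PSI, "m"))
  expect_identical(census_record(cen, paste0(PSI, "m"))$ascii_alias, "psi-m")
  expect_error(census_record(cen, "nosuchmark"), "unknown modification")
})

test_that("unplaced marks are exactly the three biosynthetically unresolved ones", {
  cen <- rnamod_census()
  unplaced <- cen$records$short_name[cen$records$status == "unplaced"]
  expect_setequal(unplaced, c("ac6A", "cm5s2U", "cnm5U"))
})

test_that("loader raises hard errors for structurally broken input", {
  cen <- rnamod_census()
  tsv <- write_census(cen, "tsv")
  lines <- strsplit(tsv, "\n")[[1]]
  hdr_at <- which(startsWith(lines, "short_name"))

  bad_header <- lines
  bad_header[hdr_at] <- paste0(lines[hdr_at], "\tmystery_column")
  expect_error(load_census(paste(bad_header, collapse = "\n"), "tsv"),
               "unknown columns: mystery_column")

  dup <- c(lines, lines[hdr_at + 1L])
  expect_error(load_census(paste(dup, collapse = "\n"), "tsv"),
               "duplicate short_name")

  two <- paste(c("short_name\tascii_alias\tfull_name\tstatus\troot_base\tparent\talt_parents\tkingdoms\trna_classes\ttrna_positions\tmrna_regions\tmotifs\twriters\treaders\terasers\treversible\tstoichiometry_note\tnotes\trefs",
                 "m7G\tm7G\t7-methylguanosine\tplaced\tG\t\t\t\t\t\t\t\t\t\t\tunknown\t\t\t",
                 "m2,7G\tm2,7G\tN2,7-dimethylguanosine\tplaced\tG\tzzz\t\t\t\t\t\t\t\t\t\tunknown\t\t\t"),
               collapse = "\n")
  expect_error(load_census(two, "tsv"), "unresolvable parent 'zzz'")

  one <- sub("\nm2,7G.*$", "", two)
  bad_enum <- sub("\tplaced\t", "\tplacedd\t", one, fixed = TRUE)
  expect_error(load_census(bad_enum, "tsv"), "column 'status'.*malformed")
})

test_that("write/load round-trips both dialects and the dialects are equivalent", {
  cen <- rnamod_census()
  rt_tsv <- load_census(write_census(cen, "tsv"), "tsv")
  rt_json <- load_census(write_census(cen, "json"), "json")
  expect_identical(unclass(rt_tsv), unclass(cen))
  expect_identical(unclass(rt_json), unclass(cen))

  # TSV written, converted to JSON, read back: identical record sets
  via_json <- load_census(write_census(rt_tsv, "json"), "json")
  expect_identical(via_json$records, cen$records)

  # byte stability
  expect_identical(write_census(cen, "tsv"), write_census(rt_tsv, "tsv"))
  expect_identical(write_census(cen, "json"), write_census(rt_json, "json"))
})

test_that("round-trip identity holds for arbitrary valid censuses", {
  for (seed in c(11L, 23L, 47L)) {
    cen <- random_census(seed)
    expect_true(validate_census(cen)$ok)
    expect_identical(unclass(load_census(write_census(cen, "tsv"), "tsv")),
                     unclass(cen))
    expect_identical(unclass(load_census(write_census(cen, "json"), "json")),
                     unclass(cen))
  }
})

test_that("writer refuses an invalid census and carries the report", {
  cen <- tiny_census(
    list(short_name = "capX", status = "nascent", parent = "m7G", root_base = ""),
    list(short_name = "m7G", root_base = "G"))
  err <- tryCatch(write_census(cen, "tsv"), condition = identity)
  expect_s3_class(err, "census_invalid")
  expect_s3_class(err$report, "census_validation")
  expect_true("nascent-has-parent" %in% err$report$violations$rule_id)
})

test_that("validator reports each lineage violation as data", {
  expect_true(validate_census(rnamod_census())$ok)

  rep1 <- validate_census(tiny_census(
    list(short_name = "capX", status = "nascent", parent = "m7G", root_base = "G"),
    list(short_name = "m7G", root_base = "G")))
  expect_false(rep1$ok)
  expect_true(all(c("nascent-has-parent", "nascent-has-root") %in%
                  rep1$violations$rule_id))

  rep2 <- validate_census(tiny_census(
    list(short_name = "m5C", root_base = "C"),
    list(short_name = "m5C", root_base = "C")))
  expect_true("duplicate-short-name" %in% rep2$violations$rule_id)

  rep3 <- validate_census(tiny_census(
    list(short_name = "m5U", root_base = "U"),
    list(short_name = "m5Um", root_base = "U", parent = "m5C"),
    list(short_name = "m5C", root_base = "C")))
  expect_true("parent-root-mismatch" %in% rep3$violations$rule_id)

  rep4 <- validate_census(tiny_census(
    list(short_name = "x", root_base = "G", parent = "y"),
    list(short_name = "y", root_base = "G", parent = "x")))
  expect_true("parent-cycle" %in% rep4$violations$rule_id)

  rep5 <- validate_census(tiny_census(
    list(short_name = "m1A", root_base = "A", trna_positions = "58")))
  expect_true("trna-position-without-trna-class" %in% rep5$violations$rule_id)
})

test_that("status partition always sums to the record count", {
  for (seed in c(3L, 5L)) {
    cen <- random_census(seed)
    st <- table(factor(cen$records$status,
                       levels = c("placed", "unplaced", "nascent")))
    expect_identical(sum(st), nrow(cen$records))
  }
})
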