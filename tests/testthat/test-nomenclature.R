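test_that("normalization maps aliases and strips whitespace, case-sensitively", {
  expect_identical(normalize_name("psi-m"), paste0(PSI, "m"))
  expect_identical(normalize_name("psi"), PSI)
  expect_identical(normalize_name("m6A"), "m6A")
  expect_identical(normalize_name(" m5C "), "m5C")
  expect_identical(normalize_name("M6A"), "M6A")  # unknown case passes through
  expect_error(normalize_name(""), "empty")
  expect_error(normalize_name("   "), "empty")
})

test_that("parser matches the full-name gloss oracle for roots and methyl counts", {
  # hand-built from the printed glosses: expected root base and the number
  # of methyl additions (base methylation + ribose 2'-O-methylation) that
  # the full chemical name spells out ("...dimethyl..." = 2, etc.)
  oracle <- list(
    #        name                root methyls
    list("m1A",                  "A", 1L),  # 1-methyladenosine
    list("Am",                   "A", 1L),  # 2'-O-methyladenosine
    list("m6Am",                 "A", 2L),  # N6,2'-O-dimethyladenosine
    list("m6,6Am",               "A", 3L),  # N6,N6,2'-O-trimethyladenosine
    list("m1Im",                 "A", 2L),  # 1,2'-O-dimethylinosine
    list("I",                    "A", 0L),  # inosine
    list("msms2i6A",             "A", 0L),  # 2-methylthiomethylenethio-N6-isopentenyl-adenosine
    list("t6A",                  "A", 0L),  # N6-threonylcarbamoyladenosine
    list("m4,4Cm",               "C", 3L),  # N4,N4,2'-O-trimethylcytidine
    list("k2C",                  "C", 0L),  # 2-lysidine
    list("hm5C",                 "C", 0L),  # 5-hydroxymethylcytidine: hydroxymethylation, not methylation
    list("m2,2G",                "G", 2L),  # N2,N2-dimethylguanosine
    list("m2,2,7G",              "G", 3L),  # N2,N2,7-trimethylguanosine
    list("m2,7Gm",               "G", 3L),  # N2,7,2'-O-trimethylguanosine
    list("Gr(p)",                "G", 0L),  # 2'-O-ribosylguanosine (phosphate)
    list("m3U",                  "U", 1L),  # 3-methyluridine
    list("m5Um",                 "U", 2L),  # 5,2'-O-dimethyluridine
    list("m5D",                  "U", 1L),  # 5-methyldihydrouridine
    list(paste0(PSI, "m"),       "U", 1L),  # 2'-O-methylpseudouridine
    list(paste0("m1acp3", PSI),  "U", 1L),  # 1-methyl-3-(3-amino-3-carboxypropyl)pseudouridine
    list("mcm5s2U",              "U", 0L),  # 5-methoxycarbonylmethyl-2-thiouridine
    list("cmnm5Um",              "U", 1L),  # 5-carboxymethylaminomethyl-2'-O-methyluridine
    list("s2U",                  "U", 0L))  # 2-thiouridine
  for (case in oracle) {
    dec <- parse_short_name(case[[1]])
    expect_identical(dec$root_base, case[[2]], info = case[[1]])
    methyls <- sum(dec$operations$count[
      dec$operations$kind %in% c("methylation", "2'-O-methylation")])
    expect_identical(methyls, case[[3]], info = case[[1]])
  }
})

test_that("decompositions expose operation multisets and op counts", {
  d <- parse_short_name("m2,2,7G")
  expect_identical(d$root_base, "G")
  expect_identical(d$op_count, 3L)
  expect_identical(sort(paste0(d$operations$site, ":", d$operations$count)),
                   c("2:2", "7:1"))

  d <- parse_short_name("mcm5s2U")
  expect_identical(d$op_count, 2L)
  expect_setequal(d$operations$kind,
                  c("carboxymethyl-side-chain", "thiolation"))

  d <- parse_short_name(paste0(PSI, "m"))
  expect_identical(d$root_base, "U")
  expect_identical(d$op_count, 2L)
  expect_setequal(d$operations$kind, c("isomerization", "2'-O-methylation"))

  d <- parse_short_name("A")
  expect_identical(d$op_count, 0L)
  expect_identical(nrow(d$operations), 0L)

  d <- parse_short_name("Q")
  expect_true(d$atomic_core)
  expect_identical(d$root_base, "G")
  expect_true(is.na(d$op_count))
})

test_that("unparseable names raise errors naming the unconsumed text", {
  expect_error(parse_short_name("xq9Z"), "unknown token at 'xq9Z'")
  expect_error(parse_short_name("m5"), "no core found")
  expect_error(parse_short_name("m5Z"), "unknown token at 'Z'")
})

test_that("parsing is a pure function", {
  a <- parse_short_name("mcm5s2U")
  b <- parse_short_name("mcm5s2U")
  expect_identical(a, b)
})

test_that("the packaged census is nomenclature-consistent", {
  cen <- rnamod_census()
  report <- check_consistency(cen)
  expect_true(report$ok)

  placed <- cen$records[cen$records$status == "placed", ]
  decs <- lapply(placed$short_name, parse_short_name)
  expect_identical(vapply(decs, `[[`, "", "root_base"), placed$root_base)
})

test_that("consistency checking flags curated/parsed root disagreement", {
  cen <- tiny_census(list(short_name = "m5U", root_base = "C"))
  report <- check_consistency(cen)
  expect_false(report$ok)
  expect_true("root-mismatch" %in% report$violations$rule_id)
})
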