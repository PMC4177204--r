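test_that("afluria template reads with nine distinct AE types", {
  recs <- load_fixture("afluria")
  expect_true(all(recs$vaccine_name == "Afluria"))
  expect_length(unique(recs$oae_id), 9L)
  # injection-site pain split over three age groups -> 11 physical rows
  expect_equal(nrow(recs), 11L)
  expect_equal(sum(recs$oae_id == "OAE_0000369"), 3L)
})

test_that("template schema and row validation", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(vaekb:::TEMPLATE_COLUMNS, collapse = ","), path)
  expect_equal(nrow(read_template(path)), 0L)

  bad <- withr::local_tempfile(fileext = ".csv")
  cols <- setdiff(vaekb:::TEMPLATE_COLUMNS, "reference")
  writeLines(paste(cols, collapse = ","), bad)
  err <- expect_error(read_template(bad), class = "vaekb_schema")
  expect_match(conditionMessage(err), "reference")

  badrow <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste(vaekb:::TEMPLATE_COLUMNS, collapse = ","),
               "X,VO_0000001,systemic,a,a AE,not-an-id,adult,18-40,10%,ref"),
             badrow)
  err <- expect_error(read_template(badrow), class = "vaekb_row")
  expect_match(conditionMessage(err), "row 1")
})

test_that("round-trip write/read preserves records", {
  recs <- load_fixture("afluria")
  path <- withr::local_tempfile(fileext = ".csv")
  write_template(recs, path)
  back <- read_template(path)
  attr(recs, "counts") <- NULL
  expect_equal(back, as.data.frame(recs))
})

test_that("age grammar: ranges, open bounds, months, single ages", {
  expect_equal(parse_age_years("18-40"), list(min = 18, max = 40))
  expect_equal(parse_age_years("65+"), list(min = 65, max = Inf))
  iv <- parse_age_years("6mo-35mo")
  expect_equal(iv$min, 0.5)
  expect_equal(iv$max, 35 / 12)
  expect_equal(parse_age_years("2"), list(min = 2, max = 3))
  expect_error(parse_age_years("40-18"), class = "vaekb_range")
  expect_error(parse_age_years("5-5"), class = "vaekb_range")
  expect_error(parse_age_years("two"), class = "vaekb_parse")
})

test_that("occurrence grammar: percent, bare fraction, bounds", {
  expect_equal(parse_occurrence("97.5%"), 0.975)
  expect_equal(parse_occurrence("0"), 0)
  expect_equal(parse_occurrence("0.31"), 0.31)
  expect_error(parse_occurrence("1.5"), class = "vaekb_range")
  expect_error(parse_occurrence("150%"), class = "vaekb_range")
  expect_error(parse_occurrence("lots"), class = "vaekb_parse")
})

test_that("age categorization matches the child/adult/senior/child-adult rules", {
  expect_equal(categorize_age(list(min = 18, max = 40)), "adult")
  expect_equal(categorize_age(list(min = 0, max = 18)), "child")
  expect_equal(categorize_age(list(min = 2, max = 49)), "child-adult")
  expect_equal(categorize_age(list(min = 65, max = Inf)), "senior")
  expect_equal(categorize_age(list(min = 18, max = Inf)), "adult")
})

test_that("records merge into associations keyed by (vaccine, AE)", {
  recs <- load_fixture("afluria")
  assocs <- records_to_associations(recs)
  expect_length(assocs, 9L)
  pain <- Filter(function(a) a$ae == "OAE_0000369", assocs)[[1]]
  expect_length(pain$groups, 3L)
  # sorted ascending by min age
  expect_equal(vapply(pain$groups, function(g) g$min, numeric(1)), c(5, 18, 65))

  one <- recs[4L, , drop = FALSE]
  a1 <- records_to_associations(one)
  expect_length(a1, 1L)
  expect_length(a1[[1]]$groups, 1L)

  # order-insensitive up to the stated sort
  shuffled <- recs[rev(seq_len(nrow(recs))), ]
  a2 <- records_to_associations(shuffled)
  key <- function(as) sort(vapply(as, function(a)
    paste(a$vaccine, a$ae), character(1)))
  expect_equal(key(a2), key(assocs))

  overlap <- recs[1:2, ]
  overlap$age_years <- c("0-10", "5-20")
  expect_error(records_to_associations(overlap), class = "vaekb_overlap")

  conflict <- recs[1:2, ]
  conflict$vae_location <- c("injection-site", "systemic")
  conflict$age_years <- c("0-10", "10-20")
  expect_error(records_to_associations(conflict), class = "vaekb_conflict")
})

test_that("declared vs computed category mismatch is a warning, not an error", {
  recs <- load_fixture("afluria")[4L, , drop = FALSE]
  recs$age_category <- "child" # but 18-64 computes to adult
  path <- withr::local_tempfile(fileext = ".csv")
  write_template(recs, path)
  expect_warning(read_template(path), class = "vaekb_category_mismatch")
})
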