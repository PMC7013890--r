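test_that("CSV round-trip is the identity on valid tables", {
  tab <- toy_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_accident_csv(tab, path)
  back <- read_accident_csv(path, toy_coding())
  expect_equal(back$records, tab$records, tolerance = 1e-12)
  expect_equal(names(back$coding), names(tab$coding))
})

test_that("a small CSV written by hand reads into a validated table", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "record_id,lon,lat,year,fatalities,injuries,x1,x2",
    "r1,114.0,22.5,2014,1,0,1,1",
    "r2,114.1,22.6,2015,0,2,2,1",
    "r3,114.2,22.7,2016,0,1,5,3",
    "r4,114.3,22.8,2014,0,0,3,2"), path)
  tab <- read_accident_csv(path, toy_coding())
  expect_s3_class(tab, "accident_table")
  expect_equal(nrow(tab$records), 4L)
})

test_that("invalid records are rejected with row-level diagnostics", {
  rec <- toy_table()$records
  rec$fatalities[2] <- -1
  expect_error(accident_table(rec, toy_coding()), "row\\(s\\): 2")

  rec <- toy_table()$records
  rec$x1[3] <- 99L
  expect_error(accident_table(rec, toy_coding()), "x1.*row\\(s\\): 3")

  rec <- toy_table()$records
  rec$lat[1] <- 123
  expect_error(accident_table(rec, toy_coding()), "WGS84")

  rec <- toy_table()$records
  rec$x2 <- NULL
  expect_error(accident_table(rec, toy_coding()), "missing required column")

  expect_error(accident_table(toy_table()$records[0, ], toy_coding()),
               "at least one record")
})

test_that("missing factor codes are admitted and excluded from stratification", {
  rec <- toy_table()$records
  rec$x1[c(1, 4)] <- NA
  tab <- accident_table(rec, toy_coding())
  s <- stratify(tab, "x1")
  expect_equal(s$n_used, 4L)
  expect_true(all(is.na(s$assignment[c(1, 4)])))
  expect_equal(sum(s$strata$n), s$n_used)
})

test_that("writing a full-size synthetic table yields one line per record", {
  tab <- generate(make_preset("shenzhen_like"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_accident_csv(tab, path)
  expect_equal(length(readLines(path)), 3250L + 1L)
})

test_that("split_groups applies the fatality / injuries-only rule", {
  tab <- toy_table(fatalities = c(1, 0, 0), injuries = c(0, 2, 0))
  sp <- split_groups(tab)
  expect_equal(nrow(sp$group1$records), 1L)
  expect_equal(nrow(sp$group2$records), 1L)
  expect_equal(sp$excluded, 1L)
  expect_equal(sp$group1$records$record_id, "a1")
  expect_equal(sp$group2$records$record_id, "a2")
})

test_that("split_groups conserves records and warns on empty groups", {
  tab <- generate(make_preset("shenzhen_like"))
  sp <- split_groups(tab)
  expect_equal(nrow(sp$group1$records) + nrow(sp$group2$records) +
                 sp$excluded, sp$n)

  all_fatal <- toy_table(fatalities = c(1, 2, 1), injuries = c(0, 0, 0))
  expect_warning(sp2 <- split_groups(all_fatal), "group 2.*empty")
  expect_null(sp2$group2)
})

test_that("stratify partitions observed categories", {
  tab <- toy_table()
  tab$records$x1 <- c(1L, 1L, 2L, 1L, 2L, 1L)
  tab <- accident_table(tab$records, tab$coding)
  s <- stratify(tab, "x1")
  expect_equal(nrow(s$strata), 2L)
  expect_equal(sort(s$strata$n), c(2L, 4L))
  expect_equal(sum(s$strata$n), nrow(tab$records))

  tab$records$x2 <- 2L
  tab <- accident_table(tab$records, tab$coding)
  expect_equal(nrow(stratify(tab, "x2")$strata), 1L)
  expect_equal(compute_q(tab$records$injuries, stratify(tab, "x2"))$q, 0)

  expect_error(stratify(tab, "nope"), "unknown factor")
})

test_that("year is stratifiable and zone strata respect the coding bound", {
  tab <- generate(make_preset("shenzhen_like"))
  sy <- stratify(tab, "year")
  expect_lte(nrow(sy$strata), 3L)
  sz <- stratify(tab, "zones")
  expect_lte(nrow(sz$strata), 5L)
})

test_that("GeoJSON export writes one point feature per record", {
  tab <- toy_table()
  path <- withr::local_tempfile(fileext = ".geojson")
  write_accident_geojson(tab, path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, nrow(tab$records))
  f1 <- gj$features[[1]]
  expect_equal(f1$geometry$type, "Point")
  expect_equal(unlist(f1$geometry$coordinates),
               c(tab$records$lon[1], tab$records$lat[1]))
  expect_equal(f1$properties$fatalities, tab$records$fatalities[1])
})

test_that("the shipped factor codings mirror the study inventory", {
  cod <- shenzhen_codings()
  expect_length(cod, 17L)
  expect_equal(length(cod$primary_cause$codes), 21L)
  expect_equal(length(cod$responsible_party$codes), 10L)
  expect_equal(cod$traffic_sign$codes, c(0L, 1L))
  expect_equal(cod$zones$labels[1], "City Center zone")
  expect_equal(cod$primary_cause$labels[1], "Drunk driving")
})
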