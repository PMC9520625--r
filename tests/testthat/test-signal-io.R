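test_that("write/read round trip reproduces records exactly", {
  dir <- withr::local_tempdir()
  set.seed(11)
  for (i in 1:10) {
    lab <- sample(c(0L, 1L, NA_integer_), 1)
    rec <- ultrasoundRecord(rnorm(50) * 10^sample(-3:3, 1), label = lab,
                            sampleId = sprintf("rt%02d", i))
    f <- file.path(dir, paste0(rec@sampleId, ".csv"))
    writeSignalCsv(rec, f)
    back <- readSignalCsv(f, labelled = !is.na(lab))
    expect_identical(back@amplitudes, rec@amplitudes)
    expect_identical(back@label, rec@label)
    expect_identical(back@sampleId, rec@sampleId)
  }
})

test_that("label convention: final CSV line is the class", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(sprintf("%.6f", rnorm(450)), "1"), f)
  rec <- readSignalCsv(f)
  expect_length(rec@amplitudes, 450)
  expect_identical(rec@label, 1L)

  ## label absent: the whole file is amplitudes
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeSignalCsv(ultrasoundRecord(c(0.5, -1, 2)), f2)
  expect_identical(length(readLines(f2)), 3L)
  rec2 <- readSignalCsv(f2, labelled = FALSE)
  expect_true(is.na(rec2@label))
  expect_length(rec2@amplitudes, 3)
})

test_that("malformed files raise informative format errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), f)
  expect_error(readSignalCsv(f), "empty")

  writeLines(c("0.1", "abc", "0.3", "1"), f)
  expect_error(readSignalCsv(f), "line 2")

  writeLines(c("0.1", "Inf", "1"), f)
  expect_error(readSignalCsv(f), "line 2")

  writeLines(c("0.1", "0.2", "7"), f)
  expect_error(readSignalCsv(f), "label")
})

test_that("dataset loading is ordered, validated, and label-aware", {
  dir <- withr::local_tempdir()
  ## write in non-alphabetical order; loading must sort by filename
  for (nm in c("c_seed", "a_seed", "b_seed")) {
    writeSignalCsv(ultrasoundRecord(rnorm(20), label = 1L, sampleId = nm),
                   file.path(dir, paste0(nm, ".csv")))
  }
  recs <- loadDataset(dir)
  expect_identical(vapply(recs, sampleId, character(1)),
                   c("a_seed", "b_seed", "c_seed"))

  ## inconsistent lengths
  writeSignalCsv(ultrasoundRecord(rnorm(19), label = 0L, sampleId = "d"),
                 file.path(dir, "d_seed.csv"))
  expect_error(loadDataset(dir), "shape")

  expect_error(loadDataset(withr::local_tempdir()), "empty")
})

test_that("a study-sized synthetic dataset survives the CSV round trip", {
  dir <- withr::local_tempdir()
  records <- generateDataset(296, 304, seed = 1)
  writeDataset(records, dir, params = echoModelParams(), seed = 1)
  back <- loadDataset(dir)
  expect_length(back, 600)
  labs <- vapply(back, recordLabel, integer(1))
  expect_identical(sum(labs == 1L), 296L)
  expect_identical(sum(labs == 0L), 304L)
  expect_true(all(vapply(back, function(r) length(r@amplitudes),
                         integer(1)) == 450L))
})
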