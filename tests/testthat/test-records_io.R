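test_that("ecg_record validates inputs", {
  expect_error(ecg_record(numeric(0), 100), "at least one sample")
  expect_error(ecg_record(c(1, NA, 2), 100), "non-finite")
  expect_error(ecg_record(c(1, 2), 0), "positive")
  r <- ecg_record(sin(1:10), 200, "I", "r1")
  expect_s3_class(r, "ecg_record")
  expect_equal(r$fs, 200)
})

test_that("annotated_record enforces sorting, uniqueness and bounds", {
  rec <- ecg_record(rnorm(100), 100)
  a <- annotated_record(rec, beat_annotations(c(50, 10), c("PVC", "N")))
  expect_equal(a$annotations$sample_index, c(10, 50))
  expect_equal(a$annotations$beat_class, c("N", "PVC"))
  expect_error(beat_annotations(c(10, 10), c("N", "N")), "duplicate")
  expect_error(beat_annotations(5, "X"), "unknown beat class")
  expect_error(annotated_record(rec, beat_annotations(100, "N")),
               "out of bounds.*100")
})

test_that("select_lead prefers lead I, falls back to first lead", {
  m <- matrix(1:9, ncol = 3)
  sel <- select_lead(m, c("II", "I", "V5"))
  expect_equal(sel$lead_name, "I")
  expect_equal(sel$samples, as.numeric(m[, 2]))
  sel2 <- select_lead(m[, 1:2], c("MLII", "V1"))
  expect_equal(sel2$lead_name, "MLII")
  expect_equal(sel2$samples, as.numeric(m[, 1]))
  sel3 <- select_lead(m[, 1, drop = FALSE], "I")
  expect_equal(sel3$samples, as.numeric(m[, 1]))
  sel4 <- select_lead(m[, 1:2], c("i", "A"))   # case-insensitive
  expect_equal(sel4$lead_name, "i")
  expect_error(select_lead(matrix(nrow = 0, ncol = 0), character(0)), "no leads")
})

test_that("CSV annotations round-trip and report parse errors", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  ann <- beat_annotations(c(1000, 1600), c("N", "PVC"))
  write_csv_annotations(ann, tmp)
  expect_identical(read_csv_annotations(tmp), ann)

  write_csv_annotations(beat_annotations(), tmp)
  expect_equal(nrow(read_csv_annotations(tmp)), 0L)

  writeLines(c("sample_index,beat_class", "500,X"), tmp)
  expect_error(read_csv_annotations(tmp), "unknown beat class token 'X' at line 2")
  writeLines(c("bogus,header"), tmp)
  expect_error(read_csv_annotations(tmp), "bad annotation header")
})

test_that("JSON record container round-trips", {
  tmp <- withr::local_tempfile(fileext = ".json")
  arec <- annotated_record(ecg_record(round(rnorm(300), 6), 200, "I", "j1"),
                           beat_annotations(c(20, 120, 250), c("N", "PAC", "PVC")))
  write_json_record(arec, tmp)
  back <- read_json_record(tmp)
  expect_equal(back$record$samples, arec$record$samples)
  expect_equal(back$record$fs, 200)
  expect_identical(back$annotations, arec$annotations)
})

test_that("WFDB round-trip: signals, lead selection, symbol mapping", {
  dir <- withr::local_tempdir()
  set.seed(11)
  x <- matrix(round(rnorm(600), 2), ncol = 2)   # lead II then lead I
  ann <- data.frame(sample = c(30, 90, 150, 200, 250),
                    symbol = c("N", "V", "A", "/", "+"))
  write_wfdb_fixture(dir, "rec1", x, fs = 250, lead_names = c("II", "I"),
                     ann = ann)
  a <- read_wfdb_record(file.path(dir, "rec1"))
  expect_equal(a$record$lead_name, "I")
  expect_equal(a$record$fs, 250)
  expect_equal(a$record$samples, x[, 2], tolerance = 1 / 200)  # adc quantization
  # "+" (rhythm change) dropped; "/" paced -> N; V -> PVC; A -> PAC
  expect_equal(nrow(a$annotations), 4L)
  got <- a$annotations
  expect_equal(got$beat_class[got$sample_index == 150], "PAC")
  expect_equal(got$beat_class[got$sample_index == 200], "N")
  expect_true("PVC" %in% got$beat_class)
})

test_that("WFDB reader: no lead I falls back to first; long intervals; errors", {
  dir <- withr::local_tempdir()
  x <- matrix(rnorm(8000), ncol = 1)
  ann <- data.frame(sample = c(100, 5000), symbol = c("N", "N"))  # needs SKIP
  write_wfdb_fixture(dir, "rec2", x, fs = 360, lead_names = "MLII", ann = ann)
  a <- read_wfdb_record(file.path(dir, "rec2"))
  expect_equal(a$record$lead_name, "MLII")
  expect_equal(a$annotations$sample_index, c(100, 5000))

  expect_error(read_wfdb_record(file.path(dir, "nope")), "header not found")
  writeLines("broken", file.path(dir, "bad.hea"))
  expect_error(read_wfdb_record(file.path(dir, "bad")), "corrupt WFDB header")

  # annotation beyond signal end
  ann2 <- data.frame(sample = 9000, symbol = "N")
  write_wfdb_fixture(dir, "rec3", x, fs = 360, lead_names = "MLII", ann = ann2)
  expect_error(read_wfdb_record(file.path(dir, "rec3")), "beyond signal end.*9000")

  # unknown beat symbol maps to N with warning
  ann3 <- data.frame(sample = 100, symbol = "Q")
  write_wfdb_fixture(dir, "rec4", x, fs = 360, lead_names = "MLII", ann = ann3)
  expect_equal(read_wfdb_record(file.path(dir, "rec4"))$annotations$beat_class, "N")
})

test_that("read_wfdb_record output is sorted and in bounds on random fixtures", {
  dir <- withr::local_tempdir()
  set.seed(21)
  for (k in 1:5) {
    n <- sample(1000:3000, 1)
    idx <- sort(sample(0:(n - 1), 20))
    idx <- idx[!duplicated(idx)]
    sym <- sample(c("N", "V", "A", "L", "R"), length(idx), replace = TRUE)
    write_wfdb_fixture(dir, paste0("rr", k), matrix(rnorm(n), ncol = 1),
                       fs = 200, lead_names = "I",
                       ann = data.frame(sample = idx, symbol = sym))
    a <- read_wfdb_record(file.path(dir, paste0("rr", k)))
    expect_false(is.unsorted(a$annotations$sample_index))
    expect_true(all(a$annotations$sample_index >= 0 &
                      a$annotations$sample_index < n))
    expect_equal(nrow(a$annotations), length(idx))
  }
})
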