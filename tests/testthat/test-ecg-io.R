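test_that("record CSV round trip is exact and fs is mandatory", {
  rec <- ecg_record(c(0.5, -1.25, 1e-7, 3.14159, 0), fs = 250, id = "rt")
  path <- withr::local_tempfile(fileext = ".csv")
  write_record(rec, path)
  back <- read_record(path, "csv")
  expect_identical(back$samples, rec$samples)
  expect_identical(back$fs, rec$fs)

  # a file without the fs comment needs an explicit rate
  no_fs <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_mv", "0.1", "0.2", "0.3"), no_fs)
  expect_error(read_record(no_fs, "csv"), "sampling rate")
  expect_equal(read_record(no_fs, "csv", fs = 100)$samples, c(0.1, 0.2, 0.3))
})

test_that("WFDB format-212 bit packing decodes by the 12-bit two's-complement rule", {
  td <- withr::local_tempdir()
  # manual bit arithmetic: triplet 0x01 0x00 0x02 -> (1, 2);
  # 0xFF 0x03 0x00 -> (1023, 0); 0x00 0xF8 0x9C -> (-2048, -100)
  adc <- c(1L, 2L, 1023L, 0L, -2048L, -100L)
  writeLines(c("w212 1 360 6", "w212.dat 212 200(0)/mV 12 0 1 0 0 MLII"),
             file.path(td, "w212.hea"))
  bytes <- pack_wfdb_212(adc)
  expect_identical(bytes[1:3], as.raw(c(0x01, 0x00, 0x02)))
  writeBin(bytes, file.path(td, "w212.dat"))
  rec <- read_record(file.path(td, "w212"), "wfdb")
  expect_equal(rec$samples, adc / 200)
  expect_equal(rec$fs, 360)
})

test_that("WFDB physical conversion applies (raw - baseline) / gain per channel", {
  td <- withr::local_tempdir()
  writeLines(c("two 2 360 3",
               "two.dat 212 200(1024)/mV 12 1024 0 0 0 MLII",
               "two.dat 212 100/mV 12 64 0 0 0 V5"),
             file.path(td, "two.hea"))
  ch1 <- c(1224L, 1024L, 824L)   # -> 1, 0, -1 mV
  ch2 <- c(164L, 64L, -36L)      # baseline from adczero=64 -> 1, 0, -1 mV
  writeBin(pack_wfdb_212(as.vector(rbind(ch1, ch2))), file.path(td, "two.dat"))
  expect_equal(read_record(file.path(td, "two"), "wfdb", channel = 1)$samples,
               c(1, 0, -1))
  expect_equal(read_record(file.path(td, "two"), "wfdb", channel = 2)$samples,
               c(1, 0, -1))
  expect_error(read_record(file.path(td, "two"), "wfdb", channel = 3), "out of range")
})

test_that("WFDB format 16 is read and other formats are rejected loudly", {
  td <- withr::local_tempdir()
  writeLines(c("f16 1 500 4", "f16.dat 16 100(0)/mV 16 0 0 0 0 lead"),
             file.path(td, "f16.hea"))
  writeBin(c(-300L, 0L, 150L, 32000L), file.path(td, "f16.dat"),
           size = 2L, endian = "little")
  rec <- read_record(file.path(td, "f16"), "wfdb")
  expect_equal(rec$samples, c(-300, 0, 150, 32000) / 100)
  expect_equal(rec$fs, 500)

  writeLines(c("f80 1 500 4", "f80.dat 80 100(0)/mV 8 0 0 0 0 lead"),
             file.path(td, "f80.hea"))
  writeBin(as.raw(1:4), file.path(td, "f80.dat"))
  expect_error(read_record(file.path(td, "f80"), "wfdb"), "unsupported WFDB")
})

test_that("annotation CSV round trips exactly, including empty and interval precision", {
  sim <- generate_ecg(quiet_config(duration_s = 10))
  ann <- locate_qs(sim$record, sim$truth$r)
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotation(ann, path)
  back <- read_annotation(path)
  expect_identical(back$r, ann$r)
  expect_identical(back$q, ann$q)
  expect_identical(back$s, ann$s)
  expect_lt(max(abs(back$qrs - ann$qrs)), 1e-6)
  expect_lt(max(abs(back$rr - ann$rr)), 1e-6)
  # indices are stored 0-based on disk
  first_row <- read.csv(path)[1, ]
  expect_equal(first_row$r_index, ann$r[1] - 1L)

  empty <- qrs_annotation(integer(0), integer(0), integer(0),
                          qrs = numeric(0), rr = numeric(0))
  epath <- withr::local_tempfile(fileext = ".csv")
  write_annotation(empty, epath)
  expect_length(read_annotation(epath)$r, 0)

  simple <- qrs_annotation(c(101L, 461L, 821L), fs = 360)
  spath <- withr::local_tempfile(fileext = ".csv")
  write_annotation(simple, spath)
  expect_identical(read_annotation(spath)$r, c(101L, 461L, 821L))
})
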