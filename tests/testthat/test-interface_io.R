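test_that("peak-list CSV reading validates structure and cells", {
  pk <- table1_peaks()
  expect_s3_class(pk, "peak_list")
  expect_equal(nrow(pk), 6)

  tmp <- tempfile(fileext = ".csv")
  writeLines("rt_min,mz,intensity", tmp)
  expect_equal(nrow(read_peaklist(tmp)), 0)

  writeLines(c("rt_min,intensity", "1.0,2.0"), tmp)
  expect_error(read_peaklist(tmp), "mz")

  writeLines(c("rt_min,mz,intensity", "1.0,abc,2.0"), tmp)
  expect_error(read_peaklist(tmp), "column 'mz', row 1")

  # ids default to the row index and must be unique
  writeLines(c("rt_min,mz,intensity", "1.0,500,2.0", "2.0,600,3.0"), tmp)
  expect_identical(read_peaklist(tmp)$id, c("1", "2"))

  # write/read round trip
  write_peaklist(pk, tmp)
  expect_equal(read_peaklist(tmp), pk, ignore_attr = TRUE)
})

test_that("MGF files round-trip and malformed blocks are skipped", {
  sp1 <- simulate_ms2(lipopeptide_spec("LLLVDLL", 12, "cyclic"), seed = 1)
  sp2 <- simulate_ms2(lipopeptide_spec("LLLVDLL", 14, "linear"), seed = 2)
  sp1$rt_s <- 1420.2; sp1$title <- "iso A"
  tmp <- tempfile(fileext = ".mgf")
  write_mgf(list(sp1, sp2), tmp)
  back <- read_mgf(tmp)
  expect_length(back, 2)
  expect_equal(back[[1]]$precursor_mz, sp1$precursor_mz, tolerance = 1e-6)
  expect_equal(back[[1]]$rt_s, 1420.2, tolerance = 1e-3)
  expect_identical(back[[1]]$title, "iso A")
  expect_equal(back[[1]]$peaks$mz, sp1$peaks$mz, tolerance = 1e-6)
  expect_equal(back[[2]]$peaks$mz, sp2$peaks$mz, tolerance = 1e-6)

  writeLines(c("BEGIN IONS", "TITLE=no pepmass", "100.0 1.0", "END IONS",
               "", "BEGIN IONS", "PEPMASS=994.67", "1012.79 5.0", "END IONS"),
             tmp)
  expect_warning(back <- read_mgf(tmp), "PEPMASS")
  expect_length(back, 1)
  expect_equal(back[[1]]$precursor_mz, 994.67)

  writeLines(character(), tmp)
  expect_length(read_mgf(tmp), 0)
  expect_error(read_mgf(tempfile()), "cannot read")
})

test_that("run configuration round-trips and rejects bad keys", {
  cfg <- run_config(ch2_tol = 0.02, anchor_mz = 1008.6832, anchor_carbons = 13)
  tmp <- tempfile(fileext = ".yaml")
  write_run_config(cfg, tmp)
  back <- read_run_config(tmp)
  expect_equal(back$ch2_tol, 0.02)
  expect_equal(back$anchor_mz, 1008.6832)
  expect_equal(unclass(back)[order(names(back))],
               unclass(cfg)[order(names(unclass(cfg)))])
  expect_error(run_config(bogus_key = 1), "unknown config key")
  expect_error(run_config(frag_tol = -0.1), "positive")
})

test_that("family reports mirror the published table and are deterministic", {
  fams <- annotate_peaks(table1_peaks(),
                         anchor = list(mz = 1008.6832, carbons = 13))
  j1 <- tempfile(fileext = ".json"); c1 <- tempfile(fileext = ".csv")
  j2 <- tempfile(fileext = ".json"); c2 <- tempfile(fileext = ".csv")
  write_report(fams[[1]], j1, c1)
  write_report(fams[[1]], j2, c2)
  expect_identical(readLines(j1), readLines(j2))
  expect_identical(readLines(c1), readLines(c2))

  csv <- utils::read.csv(c1, stringsAsFactors = FALSE)
  expect_identical(names(csv), c("designation", "rt_min", "mz", "type",
                                 "tail_carbons", "nominal_offset"))
  expect_identical(csv$designation, c("A", "B", "C", "D", "C_L", "D_L"))
  expect_identical(csv$type, c(rep("cyclic", 4), rep("linear", 2)))
  expect_equal(csv$tail_carbons, c(12, 13, 14, 15, 14, 15))
  expect_equal(csv$nominal_offset, c(0, 14, 28, 42, 46, 60))

  json <- jsonlite::read_json(j1)
  expect_length(json$members, 6)
  expect_length(json$edges, 6)

  # singleton family: one-row CSV
  single <- annotate_peaks(peak_list(rt = 5, mz = 900))
  write_report(single[[1]], csv_path = c1)
  expect_equal(nrow(utils::read.csv(c1)), 1)
})
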