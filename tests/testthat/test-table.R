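# Table assembly tests run on a reduced detector subset at modest quadrature
# so they stay quick; full-resolution runs live in the acceptance suite.
small_fields <- function() list("16" = fixture_field(16),
                                "8" = fixture_field(8),
                                "4" = fixture_field(4))

small_lib <- function() fixture_lib()[c("Diode P T60016", "Diode E T60017",
                                        "RAZOR chamber", "IBA CC04")]

test_that("run_full_table fills kvol, ratio, k and flag columns", {
  tab <- suppressWarnings(run_full_table(small_fields(), small_lib(),
                                         steps_per_axis = 20))
  expect_s3_class(tab, "correction_table")
  expect_equal(nrow(tab), 4)
  expect_true(all(c("kvol_16", "kvol_8", "kvol_4", "ratio_16", "ratio_8",
                    "ratio_4", "k_16", "k_8", "k_4", "flagged_16",
                    "flagged_4") %in% names(tab)))
  # msr identity column: ratio at 16 mm is exactly 1 for every detector
  expect_identical(tab$ratio_16, rep(1, 4))
  # identical active volumes give identical kvol in every field
  p <- tab[tab$detector == "Diode P T60016", ]
  e <- tab[tab$detector == "Diode E T60017", ]
  expect_identical(unlist(p[paste0("kvol_", c(16, 8, 4))], use.names = FALSE),
                   unlist(e[paste0("kvol_", c(16, 8, 4))], use.names = FALSE))
  # kQ present for CC04 at 16 mm, absent (NA) at 8/4 mm
  cc <- tab[tab$detector == "IBA CC04", ]
  expect_false(is.na(cc$k_16))
  expect_true(is.na(cc$k_8) && is.na(cc$k_4))
  # detectors without any published kQ propagate as NA, not failure
  expect_true(all(is.na(tab[tab$detector == "RAZOR chamber",
                            c("k_16", "k_8", "k_4")])))
})

test_that("missing kQ entries raise a warning, not an error", {
  w <- capture_warnings(run_full_table(small_fields(), small_lib(),
                                       steps_per_axis = 10))
  expect_match(w, "no published kQ", all = FALSE)
})

test_that("an empty detector library yields an empty table with a warning", {
  expect_warning(tab <- run_full_table(small_fields(),
                                       structure(list(), names = character(0))),
                 "empty detector library")
  expect_equal(nrow(tab), 0)
})

test_that("the msr field is required", {
  expect_error(run_full_table(list("8" = fixture_field(8)), small_lib()),
               "msr field")
})

test_that("correction CSV output is byte-reproducible and uses N.A.", {
  tab <- suppressWarnings(run_full_table(small_fields(), small_lib(),
                                         steps_per_axis = 20))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_correction_csv(tab, f1)
  tab2 <- suppressWarnings(run_full_table(small_fields(), small_lib(),
                                          steps_per_axis = 20))
  write_correction_csv(tab2, f2)
  expect_identical(readLines(f1), readLines(f2))
  long <- utils::read.csv(f1)
  expect_equal(nrow(long), 12)
  expect_true("N.A." %in% long$k)
})

test_that("published tables ship complete and self-describing", {
  kv <- gk_published_kvol()
  kq <- gk_published_kq()
  expect_equal(nrow(kv), 14)
  expect_equal(names(kv), c("detector", "kvol_16", "kvol_8", "kvol_4",
                            "ratio_16", "ratio_8", "ratio_4"))
  expect_equal(nrow(kq), 6)
  expect_true(all(kq$detector %in% kv$detector))
  expect_true(all(kv$ratio_16 == 1.000))
})

test_that("run_config drives the pipeline from YAML and writes artifacts", {
  out_dir <- withr::local_tempdir()
  # profile CSVs for one field, via the synthetic generator
  pdir <- withr::local_tempdir()
  paths <- list()
  for (ax in c("x", "y", "z")) {
    p <- file.path(pdir, paste0("p4", ax, ".csv"))
    write_profile(synth_profile(profile_spec(4, ax, seed = 3)), p)
    paths[[ax]] <- p
  }
  cfg <- list(profiles = list("4" = paths),
              steps_per_axis = 10, seed = 3, output_dir = out_dir)
  # 16 mm (msr) and 8 mm fall back to synthetic fields
  tab <- suppressWarnings(run_config(cfg))
  expect_s3_class(tab, "correction_table")
  expect_true(file.exists(file.path(out_dir, "correction_table.csv")))
  expect_equal(nrow(tab), 14)
})
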