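#' Published correction-table constants
#'
#' `gk_published_kvol()` returns the published volume-averaging correction
#' factors and clin/msr ratios per detector and field size;
#' `gk_published_kq()` returns the TRS-483 field output correction factors
#' kQ consumed as constants (entries not listed in TRS-483 are NA). Both are
#' shipped as plain CSV under `inst/extdata/`.
#'
#' @return a data frame, one row per detector.
#' @export
gk_published_kvol <- function() {
  utils::read.csv(system.file("extdata", "published_kvol.csv",
                              package = "gkvol"), check.names = FALSE)
}

#' @rdname gk_published_kvol
#' @export
gk_published_kq <- function() {
  utils::read.csv(system.file("extdata", "published_kq.csv",
                              package = "gkvol"), check.names = FALSE)
}

#' Full correction table over a detector library
#'
#' Computes k_vol for every detector at every supplied field, the clin/msr
#' ratios against the 16 mm machine-specific reference field, and — where a
#' published kQ is available — the volume-averaging contribution k to the
#' field output correction factor. Cells without a kQ propagate as NA with a
#' warning, never as a failure. All chaining is done in full precision;
#' rounding (half away from zero, `digits` decimals) is applied only in the
#' returned table.
#'
#' @param fields named list of [dose_field()]s; names must include `"16"`
#'   (the msr field), plus any of `"8"`, `"4"`.
#' @param detectors a detector library from [load_detector_library()] (the
#'   shipped 14-detector library by default).
#' @param kq data frame with columns `detector`, `kq_16`, `kq_8`, `kq_4`
#'   (default [gk_published_kq()]); pass `NULL` to skip the k columns.
#' @param steps_per_axis Simpson steps per direction.
#' @param digits reporting decimals.
#' @return a `correction_table` data frame with columns `detector`,
#'   `kvol_*`, `ratio_*`, `k_*` and logical `flagged_*` per field size.
#' @export
run_full_table <- function(fields, detectors = load_detector_library(),
                           kq = gk_published_kq(), steps_per_axis = 100L,
                           digits = 3) {
  if (!"16" %in% names(fields))
    stop("fields must include the 16 mm msr field under the name '16'")
  sizes <- intersect(c("16", "8", "4"), names(fields))
  if (length(detectors) == 0) {
    warning("empty detector library: returning an empty table")
    out <- data.frame(detector = character(0))
    class(out) <- c("correction_table", "data.frame")
    return(out)
  }
  kv <- sapply(sizes, function(s)
    vapply(detectors, function(d)
      kvol(fields[[s]], d, steps_per_axis)$kvol, 0))
  kv <- matrix(kv, nrow = length(detectors),
               dimnames = list(names(detectors), sizes))
  out <- data.frame(detector = names(detectors), row.names = NULL)
  for (s in sizes) out[[paste0("kvol_", s)]] <- round_report(kv[, s], digits)
  for (s in sizes)
    out[[paste0("ratio_", s)]] <-
      round_report(kv[, s] / kv[, "16"], digits)
  if (!is.null(kq)) {
    for (s in sizes) {
      col <- paste0("kq_", s)
      kq_s <- kq[[col]][match(out$detector, kq$detector)]
      missing_kq <- is.na(kq_s)
      if (any(missing_kq))
        warning(sprintf("no published kQ at %s mm for: %s", s,
                        paste(out$detector[missing_kq], collapse = ", ")))
      out[[paste0("k_", s)]] <-
        round_report(kv[, s] / kv[, "16"] / kq_s, digits)
    }
  }
  class(out) <- c("correction_table", "data.frame")
  flag_unsuitable(out)
}

#' @export
print.correction_table <- function(x, ...) {
  cat("Volume-averaging correction table",
      sprintf("(%d detector%s)\n", nrow(x), if (nrow(x) == 1) "" else "s"))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write a correction table as long-format CSV
#'
#' One row per detector and field size with columns
#' `detector, field_mm, kvol, ratio, k, flagged`; NA cells are written as
#' `N.A.` to mirror the published-table convention.
#'
#' @param table a `correction_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_correction_csv <- function(table, path) {
  stopifnot(inherits(table, "correction_table"))
  sizes <- sub("^kvol_", "", grep("^kvol_", names(table), value = TRUE))
  long <- do.call(rbind, lapply(sizes, function(s) {
    data.frame(detector = table$detector, field_mm = as.numeric(s),
               kvol = table[[paste0("kvol_", s)]],
               ratio = table[[paste0("ratio_", s)]],
               k = if (paste0("k_", s) %in% names(table))
                 table[[paste0("k_", s)]] else NA_real_,
               flagged = table[[paste0("flagged_", s)]])
  }))
  long <- long[order(long$detector, -long$field_mm), ]
  fmt <- function(v) ifelse(is.na(v), "N.A.", format(v, trim = TRUE))
  long$kvol <- fmt(long$kvol); long$ratio <- fmt(long$ratio)
  long$k <- fmt(long$k)
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the pipeline from a YAML configuration
#'
#' Configuration keys: `profiles` (per field size, per axis CSV paths — if
#' absent, synthetic fixture fields are generated), `detector_library`
#' (YAML path, default shipped), `kq_table` (CSV path, default shipped),
#' `steps_per_axis`, `digits`, `seed`, `output_dir`.
#'
#' @param config path to a YAML config file, or an equivalent list.
#' @return the `correction_table`, invisibly; CSV artifacts are written to
#'   `output_dir` when set.
#' @export
run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  steps <- as.integer(cfg$steps_per_axis %||% 100L)
  digits <- cfg$digits %||% 3
  seed <- as.integer(cfg$seed %||% 1L)
  detectors <- if (is.null(cfg$detector_library)) load_detector_library()
    else load_detector_library(cfg$detector_library)
  kq <- if (is.null(cfg$kq_table)) gk_published_kq()
    else utils::read.csv(cfg$kq_table, check.names = FALSE)
  fields <- list()
  for (s in c("16", "8", "4")) {
    pf <- cfg$profiles[[s]]
    fields[[s]] <- if (is.null(pf)) {
      synth_field(as.numeric(s), seed = seed)
    } else {
      fits <- lapply(c("x", "y", "z"), function(ax)
        fit_profile(read_profile(pf[[ax]], axis = ax, field_size_mm = as.numeric(s)),
                    seed = seed))
      dose_field(fits[[1]], fits[[2]], fits[[3]], field_size_mm = as.numeric(s))
    }
  }
  tab <- run_full_table(fields, detectors, kq, steps_per_axis = steps,
                        digits = digits)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_correction_csv(tab, file.path(cfg$output_dir, "correction_table.csv"))
  }
  invisible(tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
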