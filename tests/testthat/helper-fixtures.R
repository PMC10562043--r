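# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture_lib <- function() {
  if (is.null(.fixtures$lib)) .fixtures$lib <- load_detector_library()
  .fixtures$lib
}

# Fitted synthetic dose field for one collimator; `scale` multiplies all
# profile lengths (proportionally scaled fields for ordering checks).
fixture_field <- function(field_size_mm, scale = 1, seed = 1) {
  key <- sprintf("field_%g_%g_%d", field_size_mm, scale, seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- synth_field(field_size_mm, seed = seed, scale = scale)
  .fixtures[[key]]
}

# kvol on a fixture field, cached so acceptance blocks can share results.
fixture_kvol <- function(field_size_mm, detector_name, steps = 100L) {
  key <- sprintf("kvol_%g_%s_%d", field_size_mm, detector_name, steps)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- kvol(fixture_field(field_size_mm),
                             fixture_lib()[[detector_name]], steps)
  .fixtures[[key]]
}

# A hand-built erf-sum penumbra model used where a known ground truth is
# needed: flat top of ~8 mm FWHM with ~2 mm penumbrae.
fixture_known_model <- function(symmetric = TRUE) {
  if (symmetric)
    erf_sum(A = -50, a = -4, b = 1.2, C0 = 50, symmetric = TRUE)
  else
    erf_sum(A = c(50, -50), a = c(4.5, -4), b = c(1.0, 1.3), C0 = 0,
            symmetric = FALSE)
}
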