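# Shared fixtures for the kesct test suite.  Everything is generated in
# code; expensive objects are built once per test run and memoised here.

# geometry whose effective pixel size equals the given voxel size exactly
test_geometry <- function(n_angles, voxel_mm, span_deg = 360) {
  ct_geometry(n_angles = n_angles, span_deg = span_deg,
              detector_pixel_um = voxel_mm * 1000 * 16.4 / 15.3)
}

.fixtures <- new.env()

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

default_spectra <- function() fixture("spectra", function() {
  u <- model_spectrum(source_config())
  f <- apply_filter(u, filter_spec())
  f$label <- "filtered"
  list(unfiltered = u, filtered = f)
})

# desk-test kidney phantom: 256^2 at 140 um, seed 1
test_phantom <- function() fixture("phantom", function()
  kidney_phantom(n = 256, voxel_size_mm = 0.14, seed = 1))

# read a packaged attenuation TSV directly (independent of interp code)
raw_table <- function(name) {
  path <- system.file("extdata", "attenuation", paste0(name, ".tsv"),
                      package = "kesct")
  read.delim(path)
}
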