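# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

layout_3t <- function() cached("layout_3t", build_layout(3.0))
layout_15t <- function() cached("layout_15t", build_layout(1.5))

siemens_ti <- c(35, 75, 100, 125, 150, 250, 1000, 1500, 2000, 3000)
vfa_angles <- c(2, 5, 10, 20, 25, 30)

# noise-free IR series, centered phantom
ir_series_clean <- function() {
  cached("ir_clean", render_series(layout_3t(), acquisition_protocol("ir")))
}

# noise-free VFA series, centered phantom
vfa_series_clean <- function() {
  cached("vfa_clean", render_series(layout_3t(), acquisition_protocol("vfa")))
}

# ROIs segmented on the clean IR series
rois_clean <- function() {
  cached("rois_clean", segment_series(ir_series_clean(), layout_3t()))
}
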