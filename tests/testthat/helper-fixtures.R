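# Shared synthetic fixtures, built once per test session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A small slide with enough nuclei for detection/classification checks.
test_slide <- function() {
  fixture("slide", function() {
    cfg <- synthetic_slide_config(width_px = 900, height_px = 700,
                                  nucleus_density = 6000, seed = 101L)
    sl <- generate_synthetic_slide(cfg)
    path <- file.path(tempdir(), "histocell_test_slide.png")
    write_synthetic_slide(sl, path)
    list(slide = sl, path = path, handle = open_slide(path))
  })
}

rand_points <- function(n, lim = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cbind(runif(n, 0, lim), runif(n, 0, lim))
}
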