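# Shared synthetic fixtures, generated once per test run.

clean_spec <- function(...) {
  synthetic_spec(noise_sigma = 2, illumination_amplitude = 5,
                 blur_sigma = 1, ...)
}

.fixture_env <- new.env()

fixture <- function(name, maker) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- maker()
  .fixture_env[[name]]
}

# 256x256 low-noise mosaic with ground truth and render
fixture_clean <- function() {
  fixture("clean", function() {
    spec <- clean_spec()
    truth <- generate_mosaic(spec)
    list(spec = spec, truth = truth, img = render_specular(truth, spec))
  })
}

# small low-noise mosaic for fast segmentation tests
fixture_mini <- function() {
  fixture("mini", function() {
    spec <- clean_spec(width = 128L, height = 128L, seed = 7L)
    truth <- generate_mosaic(spec)
    list(spec = spec, truth = truth, img = render_specular(truth, spec))
  })
}

# tuned parameter sets for the frozen synthetic conditions
tuned_params <- function(method) {
  switch(method,
         vm = params_vm(o = 2, h = 10),
         am = params_am(s1 = 1, g = 2, s2 = 4, t = 8, h = 1),
         gp = params_gp(c = 1, t_s = 5, o = 1, s = 4))
}

# coarse learning grids used by the cross-validation studies
coarse_grid <- function(method) {
  switch(method,
         vm = parameter_grid("vm", o = c(1, 2), h = c(8, 15)),
         am = parameter_grid("am", s1 = c(1, 2), g = 2, s2 = c(3, 4),
                             t = c(8, 12), h = 1),
         gp = parameter_grid("gp", c = c(1, 2), t_s = c(5, 7),
                             o = c(1, 2), s = c(2, 4)))
}

# build a quality table object directly from a values matrix (for
# aggregator tests that need no segmentation runs)
fake_table <- function(values, method = "vm") {
  np <- ncol(values)
  grid <- parameter_grid(method, o = seq_len(np), h = 1)
  structure(list(images = sprintf("img-%02d", seq_len(nrow(values))),
                 params = grid$params, method = method,
                 criterion = "epsilon", rho = 2,
                 values = values),
            class = "endo_quality_table")
}
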