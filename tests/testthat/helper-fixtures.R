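# Shared fixtures, built once per test run and cached (full-grid volumes are
# the expensive part).

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# one random full-grid brain-like volume
fixture_volume <- function() fixture("volume", function() {
  cfg <- generator_config(n_patients = 3, prevalence = 1 / 3, seed = 404,
                          effect_size = 0)
  generate_cohort(cfg)$volumes[[1L]]
})

# small cohort with a strong planted signal filling axial slab 3
fixture_cohort <- function() fixture("cohort", function() {
  cfg <- generator_config(
    n_patients = 16, prevalence = 0.25, seed = 2024,
    effect_size = 100, noise_sd = 5,
    signal_regions = list(signal_region(c(10L, 20L, 42L), c(80L, 100L, 56L))))
  generate_cohort(cfg)
})

# axial features + labels of the small cohort
fixture_axial_features <- function() fixture("axial_features", function() {
  co <- fixture_cohort()
  list(features = slice_features(co$volumes, "axial"),
       labels = co$truth$labels,
       patients = label_patients(co$patients))
})
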