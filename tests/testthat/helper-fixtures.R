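# Shared fixtures: templates are deterministic, so build each level once
# and cache for the whole test run.

.fixtures <- new.env(parent = emptyenv())

fixture_mesh <- function(level) {
  key <- paste0("l", level)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- build_symmetric_template(level)
  .fixtures[[key]]
}

# A small cohort reused by feature/classifier tests.
fixture_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- generate_cohort(
      cohort_config(n_controls = 8, n_positive = 2, n_negative = 2,
                    n_lesions = 3, seed = 42),
      fixture_mesh(2))
  }
  .fixtures$cohort
}

# Sparse "guessing" score map: Poisson-many uniform-height spikes at random
# vertices; thresholding such a map reproduces the guessing mark process.
spike_map <- function(mesh, lambda = 10) {
  v <- numeric(mesh$nv)
  n <- rpois(1, lambda)
  if (n > 0) v[sample.int(mesh$nv, n)] <- runif(n)
  score_map(v, method = "IF")
}

# Smooth random score map (for monotonicity / convergence properties).
smooth_map <- function(mesh, id = NA_character_, two_tailed = FALSE) {
  score_map(smooth_field(mesh, rnorm(mesh$nv), 15), method = "GLM",
            subject_id = id, two_tailed = two_tailed)
}
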