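# Shared hip-model cache: generating a mesh pair takes a few tenths of a
# second, so models used by several test files are built once per session.
.hip_cache <- new.env(parent = emptyenv())

cached_hip <- function(key, params, resolution = 2.0) {
  if (is.null(.hip_cache[[key]]))
    .hip_cache[[key]] <- generate_hip(params, resolution = resolution)
  .hip_cache[[key]]
}

mean_hip <- function(resolution = 2.0) {
  cached_hip(paste0("mean", resolution), anatomy_params(), resolution)
}

nocam_hip <- function(resolution = 2.0) {
  cached_hip(paste0("nocam", resolution),
             anatomy_params(alpha_angle = 40, lcea = 30,
                            acetabular_version = 19, femoral_version = 15,
                            aiis_type = "I"), resolution)
}

# A small deterministic cohort for directional tests; memoized.
cached_cohort <- function(n = 20, seed = 11, resolution = 2.0) {
  key <- paste("cohort", n, seed, resolution)
  if (is.null(.hip_cache[[key]]))
    .hip_cache[[key]] <- sample_cohort(cohort_spec(n_patients = n, seed = seed),
                                       resolution = resolution, quiet = TRUE)
  .hip_cache[[key]]
}
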