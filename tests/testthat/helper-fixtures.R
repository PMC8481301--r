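# Shared fixtures, built once per test run and cached. Everything is
# generated in code; the coarse refinement-1 mesh keeps the default test
# run fast, refinement 2 is reserved for the full-pipeline checks.

.fixtures <- new.env(parent = emptyenv())

fix_cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

fix_mesh <- function(refinement = 1) {
  fix_cached(paste0("mesh", refinement),
             build_thorax_mesh("circle", refinement))
}

fix_jacobian <- function(refinement = 1, sigma0 = 0.48) {
  fix_cached(sprintf("jac%d_%g", refinement, sigma0), {
    mesh <- fix_mesh(refinement)
    compute_jacobian(mesh, rep(sigma0, nrow(mesh$elements)))
  })
}

fix_greit <- function(refinement = 1) {
  fix_cached(paste0("greit", refinement), greit(fix_jacobian(refinement)))
}

# noiseless default-protocol simulation of a right_weight = 0.6 phantom
fix_sim06 <- function(refinement = 1) {
  fix_cached(paste0("sim06_", refinement), {
    phantom <- phantom_config(fix_mesh(refinement), right_weight = 0.6)
    simulate_sequence(phantom, breathing_protocol(), noise_model(0))
  })
}

# hand-built image sequence from a flat pixel matrix (n_px x n_frames in
# full 32 x 32 layout), for index-level unit tests
make_images <- function(frames_list, timestamps = seq_along(frames_list),
                        mask = matrix(TRUE, 32, 32)) {
  arr <- array(0, dim = c(nrow(frames_list[[1]]), ncol(frames_list[[1]]),
                          length(frames_list)))
  for (i in seq_along(frames_list)) arr[, , i] <- frames_list[[i]]
  structure(list(images = arr, timestamps = timestamps, mask = mask),
            class = "eit_images")
}
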