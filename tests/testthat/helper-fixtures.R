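# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

default_prior <- function() trajectory_prior(0.75, 0.35, 0.25)

small_intr <- function(size = 48) {
  camera_intrinsics(0.75 * size, 0.75 * size, size / 2, size / 2, size, size)
}

# tiny rendered capture shared across tests (8 views, 48 x 48)
tiny_capture <- function() {
  fixture("tiny_capture", function() {
    field <- make_plant_field(seed = 2, n_leaves = 8)
    simulate_capture(field, default_prior(), n_per_ring = 4,
                     intr = small_intr(48), n_quad = 48)
  })
}

# small randomly-initialized field over the standard ROI (never trained)
random_field <- function(seed = 5) {
  cal <- calibrate_poses(tiny_capture()$true_poses, default_prior())
  box <- compute_roi_aabb(cal$calibration, default_prior())
  rf <- radiance_field(box, length(tiny_capture()$frames),
                       fine_cfg = hash_grid_config(4, 2^12, n_max = 64),
                       coarse_cfg = hash_grid_config(3, 2^10, n_max = 32),
                       hidden_density = 16, hidden_color = 16, seed = seed)
  rf$n_c <- 16
  rf$n_f <- 24
  set.seed(seed)
  rf$params$f_tab <- matrix(rnorm(length(rf$params$f_tab), 0, 0.3), nrow = 2)
  rf$params$c_tab <- matrix(rnorm(length(rf$params$c_tab), 0, 0.3), nrow = 2)
  rf
}

random_unit <- function(n) {
  m <- matrix(rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

# frame set with prescribed sharpness values and dummy pixels
fake_frame_set <- function(sharpness, view = "lower") {
  n <- length(sharpness)
  frame_set(replicate(n, array(0.5, c(2, 2, 3)), simplify = FALSE),
            rep_len(view, n), seq_len(n), sharpness)
}
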