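# Fixtures are built in code; nothing binary ships with the package.

# a motionless standing sequence built from the simulator's template body
make_static_sequence <- function(n = 10, rate_hz = 30, height_cm = 172) {
  tr <- structure(list(t30 = (seq_len(n) - 1) / rate_hz,
                       ml30 = rep(0, n), ap30 = rep(0, n),
                       t100 = 0, ml100 = 0, ap100 = 0,
                       sway_30 = 0, sway_100 = 0,
                       target_rms_mm = 0, theta = 1, duration_s = n / rate_hz),
                  class = "ground_truth")
  synthesize_skeleton(tr, seed = 1, height_cm = height_cm,
                      joint_noise_sd_mm = 0)
}

# sequence with iid random joint positions (not a plausible body; useful for
# geometric property tests)
make_random_sequence <- function(n = 12, seed = 42) {
  set.seed(seed)
  pos <- array(stats::rnorm(n * 25 * 3, sd = 0.3), dim = c(n, 25, 3))
  dimnames(pos) <- list(NULL, kinect_joints(), NULL)
  skeleton_sequence((seq_len(n) - 1) / 30, pos, height_cm = 172)
}

# single frame with all joints at given positions matrix (25 x 3)
make_frame <- function(pos, state = NULL) {
  joints <- kinect_joints()
  rownames(pos) <- joints
  if (is.null(state)) state <- stats::setNames(rep("tracked", 25), joints)
  structure(list(t = 0, pos = pos, state = state), class = "skeleton_frame")
}

frame_at <- function(p) make_frame(matrix(rep(p, each = 25), 25, 3))

quiet_preset <- function() sot_presets()[1, ]
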