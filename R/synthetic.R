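#' Sensory Organisation Test condition presets
#'
#' Default simulation presets for the six SOT conditions (a)-(f): target
#' resultant sway RMS, hip-strategy mix `lambda` (0 = pure ankle pivot,
#' 1 = pure hip strategy), sway-process bandwidth, and trial duration.
#' Targets follow the characteristic sway magnitudes of the six conditions —
#' around 3 mm for quiet stance with eyes open, rising to 15-17 mm when the
#' support surface is sway-referenced; `lambda` rises with the perturbed
#' conditions, in which balance recovery recruits the hip strategy.
#'
#' @return Data frame of class `sot_presets` with columns `condition`,
#'   `target_rms_mm`, `lambda`, `bandwidth_hz`, `duration_s`.
#' @export
sot_presets <- function() {
  out <- data.frame(
    condition = letters[1:6],
    target_rms_mm = c(2.9, 4.2, 4.0, 5.8, 17, 15),
    lambda = c(0, 0.1, 0, 0.5, 0.7, 0.7),
    bandwidth_hz = c(0.3, 0.3, 0.3, 0.6, 0.6, 0.6),
    duration_s = 20)
  class(out) <- c("sot_presets", "data.frame")
  out
}

# default between-method sway bias (plate - camera, mm) injected per
# condition by generate_study(): small for unperturbed standing, growing
# with task difficulty as the rigid pendulum assumption degrades
default_bias_mm <- function() {
  c(a = 0.12, b = 0.45, c = 0.09, d = 0.64, e = 1.64, f = 1.69)
}

base_rate_hz <- 300 # common multiple of the 30 Hz camera and 100 Hz plate

#' Simulate the true CoM sway process
#'
#' Draws a 2D stationary mean-reverting Gaussian (Ornstein-Uhlenbeck)
#' process, independent in ML and AP, with mean-reversion rate
#' `theta = 2 * pi * bandwidth_hz` and diffusion set so the stationary RMS of
#' the resultant equals `target_rms_mm` (per-axis stationary SD
#' `target / sqrt(2)`). One underlying path is simulated on a 300 Hz grid and
#' subsampled onto both measurement grids (30 Hz camera, 100 Hz plate), so
#' the two channels observe the same motion.
#'
#' @param preset One row of [sot_presets()] (or a list with
#'   `target_rms_mm`, `bandwidth_hz`, `duration_s`).
#' @param seed Integer seed; same seed, same output.
#' @param target_rms_mm,duration_s Optional overrides of the preset.
#' @return An object of class `ground_truth`: list with 30 Hz samples
#'   (`t30`, `ml30`, `ap30`), 100 Hz samples (`t100`, `ml100`, `ap100`),
#'   the empirical sway RMS on each grid (`sway_30`, `sway_100`), and the
#'   generating parameters (`target_rms_mm`, `theta`, `duration_s`).
#' @export
generate_com_process <- function(preset, seed, target_rms_mm = NULL,
                                 duration_s = NULL) {
  target <- if (!is.null(target_rms_mm)) target_rms_mm else preset$target_rms_mm
  dur <- if (!is.null(duration_s)) duration_s else preset$duration_s
  if (is.null(dur) || dur <= 0) stop("duration must be positive")
  if (target < 0) stop("target RMS must be non-negative")
  theta <- 2 * pi * preset$bandwidth_hz
  n <- round(dur * base_rate_hz)
  if (n < 2L) stop("duration too short for the base sampling grid")
  dt <- 1 / base_rate_hz
  s_axis <- target / sqrt(2)

  set.seed(as.integer(seed %% .Machine$integer.max))
  r <- exp(-theta * dt)
  sim_axis <- function() {
    z <- stats::rnorm(n)
    innov <- s_axis * sqrt(1 - r^2) * z
    innov[1] <- s_axis * z[1] # stationary initial draw
    as.numeric(stats::filter(innov, r, method = "recursive"))
  }
  ml <- sim_axis()
  ap <- sim_axis()

  i30 <- seq(1L, n, by = base_rate_hz / 30)
  i100 <- seq(1L, n, by = base_rate_hz / 100)
  t <- (seq_len(n) - 1) * dt
  popsway <- function(x, y)
    sqrt(mean((x - mean(x))^2) + mean((y - mean(y))^2))
  structure(list(
    t30 = t[i30], ml30 = ml[i30], ap30 = ap[i30],
    t100 = t[i100], ml100 = ml[i100], ap100 = ap[i100],
    sway_30 = popsway(ml[i30], ap[i30]),
    sway_100 = popsway(ml[i100], ap[i100]),
    target_rms_mm = target, theta = theta, duration_s = dur),
    class = "ground_truth")
}

# Expected value of the population-variance estimator of a stationary OU
# process with unit stationary variance, observed at n samples spaced dt:
#   E[popvar] = 1 - S / n^2,  S = sum_{i,j} exp(-theta dt |i-j|)
ou_popvar_factor <- function(theta, n, dt) {
  r <- exp(-theta * dt)
  d <- seq_len(n - 1)
  s <- n + 2 * sum((n - d) * r^d)
  1 - s / n^2
}

# Template standing skeleton: 25 joints in camera space (metres), scaled to
# subject stature. Proportions are standard anthropometric landmark heights
# (fractions of stature); the camera views the back from 2.5 m.
template_skeleton <- function(height_cm) {
  if (is.na(height_cm) || height_cm <= 0) stop("height must be positive")
  h <- height_cm / 100
  hw <- 0.096 * h / 2   # hip half-width
  sw <- 0.204 * h / 2   # shoulder half-width
  cam_z <- 2.5          # camera-to-subject distance (depth offset)
  J <- function(x, y, z = 0) c(x, y * h, z + cam_z)
  pos <- rbind(
    spine_base     = J(0,   0.530),
    spine_mid      = J(0,   0.650),
    neck           = J(0,   0.860),
    head           = J(0,   0.940),
    shoulder_left  = J(-sw, 0.818),
    elbow_left     = J(-sw, 0.630),
    wrist_left     = J(-sw, 0.485),
    hand_left      = J(-sw, 0.430),
    shoulder_right = J(sw,  0.818),
    elbow_right    = J(sw,  0.630),
    wrist_right    = J(sw,  0.485),
    hand_right     = J(sw,  0.430),
    hip_left       = J(-hw, 0.520),
    knee_left      = J(-hw, 0.285),
    ankle_left     = J(-hw, 0.039),
    foot_left      = J(-hw, 0.020, 0.10),
    hip_right      = J(hw,  0.520),
    knee_right     = J(hw,  0.285),
    ankle_right    = J(hw,  0.039),
    foot_right     = J(hw,  0.020, 0.10),
    spine_shoulder = J(0,   0.820),
    hand_tip_left  = J(-sw, 0.400),
    thumb_left     = J(-sw * 0.8, 0.440),
    hand_tip_right = J(sw,  0.400),
    thumb_right    = J(sw * 0.8, 0.440))
  pos[kinect_joints(), , drop = FALSE]
}

#' Synthesise a camera skeleton recording from a true CoM path
#'
#' Places the 25 joints on a template standing body scaled to the subject's
#' height and drives it so that the three-joint centroid follows the true
#' CoM trajectory exactly (before sensor noise). The strategy mix `lambda`
#' shapes *how*: a fraction `1 - lambda` of the displacement translates the
#' whole body (ankle strategy), while the remainder is realised as a trunk
#' lean — joints above the pelvis displace proportionally to their height,
#' scaled so the mid-spine joint carries three times the hip deficit and the
#' centroid excursion is preserved (hip strategy). Zero-mean Gaussian noise
#' (default SD 2 mm per joint and axis) models the tracker jitter, and the
#' rear-camera convention is applied: the camera's ML axis is the mirror of
#' the plate's, so [flip_ml()] is exercised non-trivially downstream.
#'
#' @param truth A [generate_com_process()] result (plate frame, mm).
#' @param seed Integer seed for the sensor noise.
#' @param height_cm,mass_kg,subject Subject metadata.
#' @param lambda Hip-strategy mix in `[0, 1]`.
#' @param joint_noise_sd_mm Per-joint, per-axis noise SD, mm (default 2).
#' @param condition,repeat_idx Trial metadata.
#' @return A [skeleton_sequence()] at 30 Hz, metres, camera space.
#' @export
synthesize_skeleton <- function(truth, seed, height_cm = 172, mass_kg = 75,
                                subject = NA_character_, lambda = 0,
                                joint_noise_sd_mm = 2,
                                condition = NA_character_,
                                repeat_idx = NA_integer_) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.na(height_cm) || height_cm <= 0) stop("height must be positive")
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  tmpl <- template_skeleton(height_cm)
  joints <- kinect_joints()
  n <- length(truth$t30)

  # per-joint share of the trunk-lean displacement: proportional to height
  # above the pelvis, normalised so spine_mid carries weight 3 (it is one of
  # three joints in the centroid, so the centroid gains exactly lambda * d)
  si <- tmpl[, 2]
  h0 <- si["spine_base"]
  hs <- pmax(si - h0, 0) / (si["spine_mid"] - h0)
  wj <- (1 - lambda) + 3 * lambda * hs # displacement multiplier per joint

  d_ml <- truth$ml30 / 1000 # plate-frame metres
  d_ap <- truth$ap30 / 1000
  pos <- array(0, dim = c(n, 25L, 3L), dimnames = list(NULL, joints, NULL))
  for (k in seq_along(joints)) {
    pos[, k, 1] <- tmpl[k, 1] - wj[k] * d_ml # mirrored ML (rear camera)
    pos[, k, 2] <- tmpl[k, 2]
    pos[, k, 3] <- tmpl[k, 3] + wj[k] * d_ap
  }
  if (joint_noise_sd_mm > 0) {
    set.seed(as.integer(seed %% .Machine$integer.max))
    pos <- pos + array(stats::rnorm(length(pos),
                                    sd = joint_noise_sd_mm / 1000),
                       dim = dim(pos))
  }
  skeleton_sequence(truth$t30, pos, rate_hz = 30, height_cm = height_cm,
                    mass_kg = mass_kg, subject = subject,
                    condition = condition, repeat_idx = repeat_idx)
}

#' Synthesise a force-plate CoF trace from a true CoM path
#'
#' Applies the forward pendulum model ([com_to_cof()]) to the 100 Hz samples
#' of the true CoM path — including the static anterior-lean offset — and
#' adds plate sensor noise (default SD 0.5 mm per axis).
#'
#' @param truth A [generate_com_process()] result.
#' @param seed Integer seed for the sensor noise.
#' @param height_cm Subject height, cm.
#' @param cof_noise_sd_mm Per-axis sensor noise SD, mm (default 0.5).
#' @param params Optional [pendulum_params()] override.
#' @param scale Multiplier applied to the true path before projection (used
#'   by [generate_study()] to inject between-method bias).
#' @return A [cof_trace()] at 100 Hz.
#' @export
synthesize_cof <- function(truth, seed, height_cm = 172,
                           cof_noise_sd_mm = 0.5, params = NULL,
                           scale = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.null(params)) params <- pendulum_params(height_cm)
  path <- com_path_new(truth$t100, scale * truth$ml100, scale * truth$ap100,
                       rate_hz = 100, method = "pendulum",
                       meta = list(height_cm = height_cm))
  trace <- com_to_cof(path, params)
  if (cof_noise_sd_mm > 0) {
    set.seed(as.integer(seed %% .Machine$integer.max))
    trace$ml_mm <- trace$ml_mm + stats::rnorm(nrow(trace), sd = cof_noise_sd_mm)
    trace$ap_mm <- trace$ap_mm + stats::rnorm(nrow(trace), sd = cof_noise_sd_mm)
  }
  trace
}

#' Simulate a full paired agreement study
#'
#' Generates the full factorial `subjects x conditions x repeats`, with both
#' measurement channels per trial — a 30 Hz camera skeleton and a 100 Hz
#' plate CoF trace driven by one shared true sway process — then runs each
#' channel through its measurement pipeline ([com_path()] with the
#' three-joint estimator; [cof_to_com()]) and returns the long-format sway
#' dataset ready for [agreement_report()] and [repeatability_report()].
#'
#' A between-method bias is injectable per condition, additively
#' (`bias_add_mm`, plate minus camera, the default following the
#' characteristic pattern of growing pendulum-model error with task
#' difficulty) and/or multiplicatively (`bias_mult`); it is realised
#' physically by scaling the plate channel's true path. Preset sway targets
#' and injected biases refer to *measured* sway: the generator corrects
#' analytically for the finite-window shrinkage of the sway estimator and
#' for sensor-noise inflation on each channel, so no empirical tuning is
#' involved (see the methods vignette).
#'
#' Randomness is fully determined by `seed` via per-trial seed streams.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param repeats Repeats per subject and condition (default 2).
#' @param presets Condition presets, as [sot_presets()].
#' @param bias_add_mm Named per-condition additive sway bias (mm),
#'   plate minus camera. Default [default_bias_mm()][sot_presets()]-style
#'   pattern; use `0` for a null study.
#' @param bias_mult Named or scalar per-condition multiplicative bias.
#' @param joint_noise_sd_mm,cof_noise_sd_mm Sensor noise SDs (mm).
#' @param seed Master integer seed.
#' @param dir Optional directory; when given, every trial's skeleton (JSON),
#'   CoF trace (CSV) and ground truth (CSV) are written there along with a
#'   `manifest.csv` of trials and per-trial seeds.
#' @return List of class `sway_study`: `data` (long-format data frame with
#'   columns `trial_id`, `subject`, `condition`, `repeat_idx`, `method`,
#'   `sway_rms_mm`), `truth` (per-trial true sway, data frame), `presets`,
#'   `seed`.
#' @export
generate_study <- function(n_subjects = 15, repeats = 2,
                           presets = sot_presets(),
                           bias_add_mm = default_bias_mm(),
                           bias_mult = 1,
                           joint_noise_sd_mm = 2, cof_noise_sd_mm = 0.5,
                           seed = 1, dir = NULL) {
  if (n_subjects < 1) stop("need at least one subject")
  conds <- presets$condition
  if (length(bias_add_mm) == 1L && is.null(names(bias_add_mm)))
    bias_add_mm <- stats::setNames(rep(bias_add_mm, length(conds)), conds)
  if (length(bias_mult) == 1L && is.null(names(bias_mult)))
    bias_mult <- stats::setNames(rep(bias_mult, length(conds)), conds)

  set.seed(as.integer(seed %% .Machine$integer.max))
  heights <- pmax(stats::rnorm(n_subjects, 172, 11), 145)
  masses <- pmax(stats::rnorm(n_subjects, 75.1, 14.2), 40)
  grid <- expand.grid(repeat_idx = seq_len(repeats),
                      condition = conds,
                      subject = seq_len(n_subjects),
                      stringsAsFactors = FALSE)
  trial_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                   3L * nrow(grid)),
                        ncol = 3L)

  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)

  rows <- vector("list", nrow(grid))
  truth_rows <- vector("list", nrow(grid))
  manifest <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    pr <- presets[presets$condition == g$condition, ]
    h <- heights[g$subject]

    # calibrate the true stationary RMS so the *measured* camera sway has
    # expectation target, and the plate-channel scale so the measured plate
    # sway has expectation (target + bias) * mult
    n30 <- round(pr$duration_s * 30); n100 <- round(pr$duration_s * 100)
    g30 <- ou_popvar_factor(2 * pi * pr$bandwidth_hz, n30, 1 / 30)
    g100 <- ou_popvar_factor(2 * pi * pr$bandwidth_hz, n100, 1 / 100)
    v_cam <- 2 * (joint_noise_sd_mm^2 / 3) * (n30 - 1) / n30
    v_bm <- 2 * cof_noise_sd_mm^2 * (n100 - 1) / n100
    t_cam <- pr$target_rms_mm
    t_bm <- (pr$target_rms_mm + bias_add_mm[[g$condition]]) *
      bias_mult[[g$condition]]
    if (t_cam^2 <= v_cam || t_bm^2 <= v_bm)
      stop("sensor noise exceeds the sway target for condition ", g$condition)
    r_true <- sqrt((t_cam^2 - v_cam) / g30)
    k_bm <- sqrt((t_bm^2 - v_bm) / g100) / r_true

    truth <- generate_com_process(pr, seed = trial_seeds[i, 1],
                                  target_rms_mm = r_true)
    skel <- synthesize_skeleton(truth, seed = trial_seeds[i, 2],
                                height_cm = h, mass_kg = masses[g$subject],
                                subject = as.character(g$subject),
                                lambda = pr$lambda,
                                joint_noise_sd_mm = joint_noise_sd_mm,
                                condition = g$condition,
                                repeat_idx = g$repeat_idx)
    trace <- synthesize_cof(truth, seed = trial_seeds[i, 3], height_cm = h,
                            cof_noise_sd_mm = cof_noise_sd_mm, scale = k_bm)

    sway_cam <- sway(com_path(skel, "three_joint",
                              reference_duration_s = NULL))$sway_rms_mm
    sway_bm <- sway(cof_to_com(trace))$sway_rms_mm

    trial_id <- sprintf("s%02d_%s_r%d", g$subject, g$condition, g$repeat_idx)
    rows[[i]] <- data.frame(
      trial_id = trial_id, subject = g$subject, condition = g$condition,
      repeat_idx = g$repeat_idx,
      method = c("pendulum", "three_joint"),
      sway_rms_mm = c(sway_bm, sway_cam))
    truth_rows[[i]] <- data.frame(
      trial_id = trial_id, condition = g$condition,
      true_sway_30 = truth$sway_30, true_sway_100 = truth$sway_100,
      true_stationary_rms = r_true, plate_scale = k_bm,
      joint_noise_sd_mm = joint_noise_sd_mm,
      cof_noise_sd_mm = cof_noise_sd_mm)
    if (!is.null(dir)) {
      write_skeleton(skel, file.path(dir, paste0(trial_id, "_skeleton.json")),
                     "json")
      write_cof(trace, file.path(dir, paste0(trial_id, "_cof.csv")))
      utils::write.csv(data.frame(t = truth$t30, ml_mm = truth$ml30,
                                  ap_mm = truth$ap30),
                       file.path(dir, paste0(trial_id, "_truth.csv")),
                       row.names = FALSE)
      manifest[[i]] <- data.frame(
        trial_id = trial_id, subject = g$subject, condition = g$condition,
        repeat_idx = g$repeat_idx, height_cm = h,
        seed_process = trial_seeds[i, 1], seed_skeleton = trial_seeds[i, 2],
        seed_cof = trial_seeds[i, 3])
    }
  }
  if (!is.null(dir))
    utils::write.csv(do.call(rbind, manifest),
                     file.path(dir, "manifest.csv"), row.names = FALSE)
  structure(list(data = do.call(rbind, rows),
                 truth = do.call(rbind, truth_rows),
                 presets = presets, seed = seed),
            class = "sway_study")
}

#' @export
print.sway_study <- function(x, ...) {
  cat(sprintf("<sway_study> %d trials x 2 methods (seed %d)\n",
              nrow(x$data) / 2L, x$seed))
  agg <- stats::aggregate(sway_rms_mm ~ condition + method, data = x$data,
                          FUN = mean)
  print.data.frame(agg, row.names = FALSE)
  invisible(x)
}
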