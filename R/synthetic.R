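# Synthetic tactile scenes: parameterized poses -> contact blobs on the mat,
# corrupted the way the sensor corrupts them (additive noise, spurious small
# blobs, a hard pressure ceiling), with timestamp-paired keypoint labels.

TACTPOSE_JOINTS <- c("head", "l_shoulder", "r_shoulder", "l_elbow", "r_elbow",
                     "l_hand", "r_hand", "pelvis", "l_knee", "r_knee",
                     "l_foot", "r_foot")

TACTPOSE_ACTIVITIES <- c("standing", "squat", "plank", "lunge", "lunge_left",
                         "sit", "situp", "bend_forward", "goddess",
                         "wide_fold", "walk", "extend_legs")

#' Body model for pose sampling
#'
#' @param n_joints number of keypoints (the default 12 matches the marker set:
#'   head, shoulders, elbows, hands, pelvis, knees, feet).
#' @param segment_lengths named vector of characteristic body dimensions (mm).
#' @param weight_kg body mass driving the total integrated pressure.
#' @return an object of class `body_model`.
#' @export
body_model <- function(n_joints = 12,
                       segment_lengths = c(stature = 1700, shoulder_width = 380,
                                           hip_width = 250, arm = 580,
                                           leg = 880, stance = 250),
                       weight_kg = 70) {
  if (n_joints < 2) stop_("n_joints must be >= 2")
  if (any(segment_lengths <= 0)) stop_("segment_lengths must be positive")
  structure(list(n_joints = as.integer(n_joints),
                 segment_lengths = segment_lengths,
                 weight_kg = weight_kg,
                 joints = if (n_joints == 12) TACTPOSE_JOINTS
                          else paste0("j", seq_len(n_joints))),
            class = "body_model")
}

#' Scene/sensor configuration
#'
#' Defaults mirror the mat the pipeline targets: a 45 x 16 tactel grid
#' resampled to 496 x 298 frames over a 1.80 m x 0.60 m surface, pressures
#' resolved up to a 15 kPa ceiling with 0.1 kPa sensitivity. Contact blobs are
#' axis-aligned Gaussians, elongated along the mat's long axis like a foot.
#'
#' @param grid_h,grid_w tactel grid size.
#' @param frame_h,frame_w rendered frame size in pixels (rows along the mat's
#'   long axis); tests and desk-scale runs pass smaller frames.
#' @param max_pressure sensor ceiling (kPa); rendered and corrupted values are
#'   clipped here.
#' @param noise_sigma additive zero-mean Gaussian sensor noise sd (kPa).
#' @param spurious_blob_rate Poisson mean of spurious small blobs per frame.
#' @param spurious_blob_size max side (pixels) of a spurious blob's support;
#'   kept below the opening kernel so mask refinement removes them.
#' @param sigma_len_mm,sigma_wid_mm contact-blob Gaussian sd along / across
#'   the mat (mm).
#' @param mat_length_mm,mat_width_mm physical mat extent.
#' @param seed integer root seed for scene randomness.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(grid_h = 45, grid_w = 16, frame_h = 496, frame_w = 298,
                         max_pressure = 15, noise_sigma = 0.5,
                         spurious_blob_rate = 3, spurious_blob_size = 3,
                         sigma_len_mm = 90, sigma_wid_mm = 45,
                         mat_length_mm = 1800, mat_width_mm = 600, seed = 1) {
  if (frame_h < grid_h || frame_w < grid_w) {
    stop_("frame dimensions must be >= tactel grid dimensions")
  }
  if (max_pressure <= 0) stop_("max_pressure must be positive")
  if (noise_sigma < 0 || spurious_blob_rate < 0) {
    stop_("noise_sigma and spurious_blob_rate must be nonnegative")
  }
  structure(list(grid_h = grid_h, grid_w = grid_w,
                 frame_h = frame_h, frame_w = frame_w,
                 max_pressure = max_pressure, noise_sigma = noise_sigma,
                 spurious_blob_rate = spurious_blob_rate,
                 spurious_blob_size = as.integer(spurious_blob_size),
                 sigma_len_mm = sigma_len_mm, sigma_wid_mm = sigma_wid_mm,
                 mat_length_mm = mat_length_mm, mat_width_mm = mat_width_mm,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# activity templates: J x 3 in mm, x along mat length, y across, z up, plus
# the set of joints in ground contact (z forced to exactly 0).
pose_template <- function(body, activity) {
  sl <- body$segment_lengths
  st <- unname(sl["stance"]) / 2
  cx <- 900; cy <- 300
  P <- matrix(0, 12, 3, dimnames = list(TACTPOSE_JOINTS, c("x", "y", "z")))
  set_j <- function(name, x, y, z) P[name, ] <<- c(x, y, z)
  contacts <- switch(activity,
    standing = , bend_forward = , walk = c("l_foot", "r_foot"),
    squat = , goddess = , wide_fold = c("l_foot", "r_foot"),
    plank = c("l_hand", "r_hand", "l_foot", "r_foot"),
    lunge = c("l_foot", "r_foot", "l_knee"),
    lunge_left = c("l_foot", "r_foot", "r_knee"),
    sit = , situp = , extend_legs = c("pelvis", "l_foot", "r_foot"),
    stop_("unknown activity '%s'; supported: %s", activity,
          paste(TACTPOSE_ACTIVITIES, collapse = ", ")))
  sw <- unname(sl["shoulder_width"]) / 2
  switch(activity,
    standing = {
      set_j("l_foot", cx, cy - st, 0); set_j("r_foot", cx, cy + st, 0)
      set_j("l_knee", cx, cy - st, 480); set_j("r_knee", cx, cy + st, 480)
      set_j("pelvis", cx, cy, 950)
      set_j("l_shoulder", cx, cy - sw, 1420); set_j("r_shoulder", cx, cy + sw, 1420)
      set_j("l_elbow", cx, cy - sw - 30, 1120); set_j("r_elbow", cx, cy + sw + 30, 1120)
      set_j("l_hand", cx, cy - sw - 40, 830); set_j("r_hand", cx, cy + sw + 40, 830)
      set_j("head", cx, cy, 1650)
    },
    walk = {
      set_j("l_foot", cx - 200, cy - st, 0); set_j("r_foot", cx + 200, cy + st, 0)
      set_j("l_knee", cx - 120, cy - st, 470); set_j("r_knee", cx + 120, cy + st, 470)
      set_j("pelvis", cx, cy, 940)
      set_j("l_shoulder", cx + 40, cy - sw, 1410); set_j("r_shoulder", cx - 40, cy + sw, 1410)
      set_j("l_elbow", cx + 120, cy - sw, 1120); set_j("r_elbow", cx - 120, cy + sw, 1120)
      set_j("l_hand", cx + 180, cy - sw, 860); set_j("r_hand", cx - 180, cy + sw, 860)
      set_j("head", cx, cy, 1640)
    },
    squat = {
      set_j("l_foot", cx, cy - st, 0); set_j("r_foot", cx, cy + st, 0)
      set_j("l_knee", cx + 180, cy - st, 380); set_j("r_knee", cx + 180, cy + st, 380)
      set_j("pelvis", cx - 80, cy, 480)
      set_j("l_shoulder", cx + 40, cy - sw, 980); set_j("r_shoulder", cx + 40, cy + sw, 980)
      set_j("l_elbow", cx + 180, cy - sw, 900); set_j("r_elbow", cx + 180, cy + sw, 900)
      set_j("l_hand", cx + 300, cy - sw, 880); set_j("r_hand", cx + 300, cy + sw, 880)
      set_j("head", cx + 60, cy, 1220)
    },
    plank = {
      set_j("l_foot", cx - 550, cy - st, 0); set_j("r_foot", cx - 550, cy + st, 0)
      set_j("l_hand", cx + 550, cy - sw, 0); set_j("r_hand", cx + 550, cy + sw, 0)
      set_j("l_knee", cx - 250, cy - st, 160); set_j("r_knee", cx - 250, cy + st, 160)
      set_j("pelvis", cx, cy, 320)
      set_j("l_elbow", cx + 480, cy - sw, 250); set_j("r_elbow", cx + 480, cy + sw, 250)
      set_j("l_shoulder", cx + 420, cy - sw, 480); set_j("r_shoulder", cx + 420, cy + sw, 480)
      set_j("head", cx + 650, cy, 520)
    },
    lunge = {
      set_j("r_foot", cx + 320, cy + st, 0); set_j("l_foot", cx - 320, cy - st, 0)
      set_j("l_knee", cx - 150, cy - st, 0); set_j("r_knee", cx + 300, cy + st, 420)
      set_j("pelvis", cx, cy, 720)
      set_j("l_shoulder", cx, cy - sw, 1250); set_j("r_shoulder", cx, cy + sw, 1250)
      set_j("l_elbow", cx, cy - sw - 30, 980); set_j("r_elbow", cx, cy + sw + 30, 980)
      set_j("l_hand", cx, cy - sw - 40, 740); set_j("r_hand", cx, cy + sw + 40, 740)
      set_j("head", cx, cy, 1480)
    },
    lunge_left = {
      set_j("l_foot", cx + 320, cy - st, 0); set_j("r_foot", cx - 320, cy + st, 0)
      set_j("r_knee", cx - 150, cy + st, 0); set_j("l_knee", cx + 300, cy - st, 420)
      set_j("pelvis", cx, cy, 720)
      set_j("l_shoulder", cx, cy - sw, 1250); set_j("r_shoulder", cx, cy + sw, 1250)
      set_j("l_elbow", cx, cy - sw - 30, 980); set_j("r_elbow", cx, cy + sw + 30, 980)
      set_j("l_hand", cx, cy - sw - 40, 740); set_j("r_hand", cx, cy + sw + 40, 740)
      set_j("head", cx, cy, 1480)
    },
    sit = {
      set_j("pelvis", cx - 150, cy, 0)
      set_j("l_foot", cx + 300, cy - st, 0); set_j("r_foot", cx + 300, cy + st, 0)
      set_j("l_knee", cx + 180, cy - st, 260); set_j("r_knee", cx + 180, cy + st, 260)
      set_j("l_shoulder", cx - 150, cy - sw, 520); set_j("r_shoulder", cx - 150, cy + sw, 520)
      set_j("l_elbow", cx - 60, cy - sw, 320); set_j("r_elbow", cx - 60, cy + sw, 320)
      set_j("l_hand", cx + 60, cy - sw, 180); set_j("r_hand", cx + 60, cy + sw, 180)
      set_j("head", cx - 140, cy, 780)
    },
    situp = {
      set_j("pelvis", cx - 100, cy, 0)
      set_j("l_foot", cx + 260, cy - st, 0); set_j("r_foot", cx + 260, cy + st, 0)
      set_j("l_knee", cx + 140, cy - st, 300); set_j("r_knee", cx + 140, cy + st, 300)
      set_j("l_shoulder", cx - 240, cy - sw, 260); set_j("r_shoulder", cx - 240, cy + sw, 260)
      set_j("l_elbow", cx - 160, cy - sw, 340); set_j("r_elbow", cx - 160, cy + sw, 340)
      set_j("l_hand", cx - 60, cy - sw, 380); set_j("r_hand", cx - 60, cy + sw, 380)
      set_j("head", cx - 330, cy, 380)
    },
    bend_forward = {
      set_j("l_foot", cx, cy - st, 0); set_j("r_foot", cx, cy + st, 0)
      set_j("l_knee", cx, cy - st, 480); set_j("r_knee", cx, cy + st, 480)
      set_j("pelvis", cx - 40, cy, 930)
      set_j("l_shoulder", cx + 280, cy - sw, 820); set_j("r_shoulder", cx + 280, cy + sw, 820)
      set_j("l_elbow", cx + 300, cy - sw, 560); set_j("r_elbow", cx + 300, cy + sw, 560)
      set_j("l_hand", cx + 300, cy - sw, 320); set_j("r_hand", cx + 300, cy + sw, 320)
      set_j("head", cx + 380, cy, 700)
    },
    goddess = {
      set_j("l_foot", cx, cy - 280, 0); set_j("r_foot", cx, cy + 280, 0)
      set_j("l_knee", cx + 60, cy - 260, 420); set_j("r_knee", cx + 60, cy + 260, 420)
      set_j("pelvis", cx, cy, 820)
      set_j("l_shoulder", cx, cy - sw, 1300); set_j("r_shoulder", cx, cy + sw, 1300)
      set_j("l_elbow", cx, cy - sw - 60, 1300); set_j("r_elbow", cx, cy + sw + 60, 1300)
      set_j("l_hand", cx, cy - sw - 60, 1560); set_j("r_hand", cx, cy + sw + 60, 1560)
      set_j("head", cx, cy, 1530)
    },
    wide_fold = {
      set_j("l_foot", cx, cy - 280, 0); set_j("r_foot", cx, cy + 280, 0)
      set_j("l_knee", cx, cy - 270, 470); set_j("r_knee", cx, cy + 270, 470)
      set_j("pelvis", cx - 40, cy, 900)
      set_j("l_shoulder", cx + 200, cy - sw, 600); set_j("r_shoulder", cx + 200, cy + sw, 600)
      set_j("l_elbow", cx + 220, cy - sw, 380); set_j("r_elbow", cx + 220, cy + sw, 380)
      set_j("l_hand", cx + 230, cy - sw + 60, 120); set_j("r_hand", cx + 230, cy + sw - 60, 120)
      set_j("head", cx + 260, cy, 420)
    },
    extend_legs = {
      set_j("pelvis", cx - 250, cy, 0)
      set_j("l_foot", cx + 550, cy - st, 0); set_j("r_foot", cx + 550, cy + st, 0)
      set_j("l_knee", cx + 180, cy - st, 120); set_j("r_knee", cx + 180, cy + st, 120)
      set_j("l_shoulder", cx - 260, cy - sw, 540); set_j("r_shoulder", cx - 260, cy + sw, 540)
      set_j("l_elbow", cx - 180, cy - sw, 320); set_j("r_elbow", cx - 180, cy + sw, 320)
      set_j("l_hand", cx - 80, cy - sw, 120); set_j("r_hand", cx - 80, cy + sw, 120)
      set_j("head", cx - 250, cy, 800)
    })
  list(coords = P, contacts = contacts)
}

#' Sample a 3D pose for an activity
#'
#' Activity-specific 12-joint templates (mm; x along the mat's long axis,
#' y across it, z up, origin at the mat corner with the mat plane at z = 0)
#' plus seeded placement and per-joint jitter. Joints in ground contact are
#' pinned to z = 0 exactly.
#'
#' @param body a [body_model()].
#' @param activity one of `tactpose_activities()`.
#' @param rng_seed integer seed; same seed gives a bitwise-identical pose.
#' @return J x 3 matrix (mm) with joint rownames and attributes `activity`
#'   and `contacts`.
#' @export
sample_pose <- function(body, activity, rng_seed = 0) {
  if (!activity %in% TACTPOSE_ACTIVITIES) {
    stop_("unknown activity '%s'; supported: %s", activity,
          paste(TACTPOSE_ACTIVITIES, collapse = ", "))
  }
  tpl <- pose_template(body, activity)
  P <- tpl$coords
  with_seed(rng_seed, {
    shift <- c(rnorm(1, 0, 40), rnorm(1, 0, 25))
    P[, 1] <- P[, 1] + shift[1] + rnorm(nrow(P), 0, 12)
    P[, 2] <- P[, 2] + shift[2] + rnorm(nrow(P), 0, 12)
    P[, 3] <- P[, 3] + rnorm(nrow(P), 0, 8)
  })
  P[tpl$contacts, 3] <- 0
  P[, 3] <- pmax(P[, 3], 0)
  if (body$n_joints != 12) {
    P <- P[rep_len(seq_len(12), body$n_joints), , drop = FALSE]
    rownames(P) <- body$joints
  }
  structure(P, activity = activity, contacts = tpl$contacts)
}

#' Supported activity labels
#' @return character vector.
#' @export
tactpose_activities <- function() TACTPOSE_ACTIVITIES

# pixel-center coordinates (mm) of a frame
frame_axes <- function(cfg) {
  list(x = (seq_len(cfg$frame_h) - 0.5) * cfg$mat_length_mm / cfg$frame_h,
       y = (seq_len(cfg$frame_w) - 0.5) * cfg$mat_width_mm / cfg$frame_w)
}

#' Render the noise-free pressure frame of a pose
#'
#' Each joint lying on the mat plane (z = 0) contributes an anisotropic
#' Gaussian pressure blob at its mat projection. The body weight is shared
#' equally between contact joints, so the integrated (unclipped) pressure is
#' proportional to the configured weight; values are clipped at the sensor
#' ceiling. Blobs centred off the mat are simply truncated at the frame edge.
#'
#' @param pose J x 3 keypoint matrix (mm) as from [sample_pose()].
#' @param cfg a [scene_config()].
#' @param weight_kg body mass (kg); defaults to 70.
#' @param clip clip at `cfg$max_pressure` (default TRUE).
#' @return `frame_h` x `frame_w` nonnegative matrix (kPa).
#' @export
render_pressure <- function(pose, cfg, weight_kg = 70, clip = TRUE) {
  stopifnot(all(is.finite(pose)))
  contacts <- which(pose[, 3] <= 1e-6)
  out <- matrix(0, cfg$frame_h, cfg$frame_w)
  if (length(contacts) == 0) return(out)
  ax <- frame_axes(cfg)
  force_n <- weight_kg * 9.81 / length(contacts)
  # amplitude in kPa: N / mm^2 = MPa, so x1000
  amp <- 1000 * force_n / (2 * pi * cfg$sigma_len_mm * cfg$sigma_wid_mm)
  for (j in contacts) {
    gx <- exp(-((ax$x - pose[j, 1])^2) / (2 * cfg$sigma_len_mm^2))
    gy <- exp(-((ax$y - pose[j, 2])^2) / (2 * cfg$sigma_wid_mm^2))
    out <- out + amp * outer(gx, gy)
  }
  if (clip) out <- clamp(out, 0, cfg$max_pressure)
  out
}

#' Corrupt a clean pressure frame
#'
#' Adds zero-mean Gaussian sensor noise and a Poisson number of spurious
#' small blobs (support strictly smaller than `spurious_blob_size + 1`
#' squared, i.e. below the mask-opening survival size), then clips to
#' `[0, max_pressure]`.
#'
#' @param clean nonnegative pressure matrix.
#' @param cfg a [scene_config()].
#' @param rng_seed seed (defaults to `cfg$seed`).
#' @param clip clip the result (default TRUE); `FALSE` exposes the raw
#'   noise-added frame, e.g. for checking the noise model's moments.
#' @return matrix of the same shape.
#' @export
corrupt <- function(clean, cfg, rng_seed = cfg$seed, clip = TRUE) {
  stopifnot(all(clean >= 0))
  h <- nrow(clean); w <- ncol(clean)
  out <- with_seed(rng_seed, {
    x <- clean
    if (cfg$noise_sigma > 0) {
      x <- x + matrix(rnorm(h * w, 0, cfg$noise_sigma), h, w)
    }
    n_blob <- if (cfg$spurious_blob_rate > 0) rpois(1, cfg$spurious_blob_rate) else 0L
    s <- cfg$spurious_blob_size
    for (b in seq_len(n_blob)) {
      i0 <- sample.int(h - s + 1, 1); j0 <- sample.int(w - s + 1, 1)
      a <- runif(1, 2, 6)
      x[i0:(i0 + s - 1), j0:(j0 + s - 1)] <-
        x[i0:(i0 + s - 1), j0:(j0 + s - 1)] + a
    }
    x
  })
  if (clip) out <- clamp(out, 0, cfg$max_pressure)
  out
}

#' Generate a paired synthetic dataset with splits
#'
#' Frames cycle through the requested activities at the mat's 60 Hz frame
#' period. Scenes of the held-out activities form an activity-disjoint
#' validation split; the remaining frames are shuffled into train/test by the
#' given fractions.
#'
#' @param n_frames total number of scenes (>= 10).
#' @param cfg a [scene_config()].
#' @param body a [body_model()].
#' @param split named fractions `c(train = , test = )` summing to 1, applied
#'   to the non-held-out activities.
#' @param activities activity labels to cycle through.
#' @param val_activities activities held out entirely for validation.
#' @return list with `scenes` (list of scene records: `clean`, `noisy`,
#'   `pose`, `activity`, `t`) and `split` (tibble: frame, t, activity, split).
#' @export
make_dataset <- function(n_frames, cfg = scene_config(), body = body_model(),
                         split = c(train = 0.8, test = 0.2),
                         activities = tactpose_activities(),
                         val_activities = c("sit", "squat")) {
  if (n_frames < 10) stop_("n_frames must be >= 10")
  if (abs(sum(split) - 1) > 1e-8) stop_("split fractions must sum to 1")
  acts <- rep_len(activities, n_frames)
  scenes <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    pose <- sample_pose(body, acts[i], derive_seed(cfg$seed, "pose", i))
    clean <- render_pressure(pose, cfg, weight_kg = body$weight_kg)
    noisy <- corrupt(clean, cfg, derive_seed(cfg$seed, "noise", i))
    scenes[[i]] <- list(clean = clean, noisy = noisy, pose = pose,
                        activity = acts[i], t = (i - 1) / 60)
  }
  lab <- rep(NA_character_, n_frames)
  lab[acts %in% val_activities] <- "val"
  rest <- which(is.na(lab))
  perm <- with_seed(derive_seed(cfg$seed, "split"), sample(rest))
  n_train <- round(split[["train"]] * length(rest))
  lab[perm[seq_len(n_train)]] <- "train"
  lab[perm[-seq_len(n_train)]] <- "test"
  list(scenes = scenes,
       split = tibble::tibble(frame = seq_len(n_frames),
                              t = (seq_len(n_frames) - 1) / 60,
                              activity = acts, split = lab))
}
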