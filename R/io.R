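# Configuration, dataset readers/writers and timestamp pairing.
#
# On-disk layout (documented stand-in for the mat's undocumented native
# format): per-frame pressure grids as headerless CSV plus a frames.csv
# manifest (file, t); keypoints as CSV (t, joint_id, x_mm, y_mm, z_mm);
# split manifest as JSON.

default_sections <- function() {
  list(
    seed = 1L,
    scene = formals(scene_config),
    schedule = list(D = 50L, alpha_start = 0.999, alpha_end = 0.95,
                    mode = "variance_preserving"),
    mask = formals(mask_params),
    cda = list(atrous_rates = c(2L, 4L, 6L, 8L), channels = 32L,
               pool_size = 4L, n_heads = 2L),
    unet = list(depth = 3L, base_channels = 32L),
    posenet = formals(posenet_config),
    train1 = list(lr = 1e-3, epochs = 5L, batch = 8L),
    train2 = list(lr = 1e-3, epochs = 10L, batch = 8L),
    ablation = c("PSFD", "RMFD", "CA", "PP")
  )
}

eval_formals <- function(f) lapply(as.list(f), eval, envir = baseenv())

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) file with any subset of the documented sections
#' (`seed`, `scene`, `schedule`, `mask`, `cda`, `unet`, `posenet`, `train1`,
#' `train2`, `ablation`), fills the remaining fields with defaults and
#' validates invariants. Unknown sections or fields are errors.
#'
#' @param path file path, or `NULL` for the full default configuration.
#' @return object of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop_("config file '%s' does not exist", path)
    if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  }
  defs <- default_sections()
  unknown <- setdiff(names(raw), names(defs))
  if (length(unknown) > 0) {
    stop_("unknown config section(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- list()
  for (sec in names(defs)) {
    d <- defs[[sec]]
    if (sec %in% c("seed", "ablation")) {
      cfg[[sec]] <- if (is.null(raw[[sec]])) d else raw[[sec]]
      next
    }
    d <- eval_formals(d)
    given <- raw[[sec]]
    bad <- setdiff(names(given), names(d))
    if (length(bad) > 0) {
      stop_("unknown field(s) in section '%s': %s", sec,
            paste(paste0(sec, ".", bad), collapse = ", "))
    }
    cfg[[sec]] <- utils::modifyList(d, as.list(given))
  }
  if (!"PSFD" %in% cfg$ablation) {
    stop_("ablation must always contain PSFD (field path: ablation)")
  }
  extra <- setdiff(cfg$ablation, c("PSFD", "RMFD", "CA", "PP"))
  if (length(extra) > 0) {
    stop_("unknown ablation flag(s): %s", paste(extra, collapse = ", "))
  }
  if ("PP" %in% cfg$ablation && !"CA" %in% cfg$ablation) {
    stop_("ablation flag PP requires CA (PP feeds CA; field path: ablation)")
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Save a run configuration as YAML
#'
#' @param cfg a [load_config()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write / read pressure frames as headerless CSV grids
#'
#' `write_frames` writes one CSV per frame plus a `frames.csv` manifest with
#' columns `file` and `t`; `read_frames` reads them back, erroring on
#' duplicate timestamps.
#'
#' @param frames list of matrices.
#' @param dir directory (created if needed).
#' @param t numeric timestamps (seconds), one per frame.
#' @return `write_frames`: the directory, invisibly. `read_frames`: list with
#'   `frames` (list of matrices) and `t`.
#' @export
write_frames <- function(frames, dir, t = (seq_along(frames) - 1) / 60) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("frame_%06d.csv", seq_along(frames))
  for (i in seq_along(frames)) {
    utils::write.table(frames[[i]], file.path(dir, files[i]), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  utils::write.csv(data.frame(file = files, t = t),
                   file.path(dir, "frames.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  man_path <- file.path(dir, "frames.csv")
  if (!file.exists(man_path)) stop_("no frames.csv manifest in '%s'", dir)
  man <- utils::read.csv(man_path)
  missing_cols <- setdiff(c("file", "t"), names(man))
  if (length(missing_cols) > 0) {
    stop_("frames.csv is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(man$t)) stop_("duplicate timestamps in frames.csv")
  frames <- lapply(man$file, function(f) {
    as.matrix(utils::read.csv(file.path(dir, f), header = FALSE))
  })
  frames <- lapply(frames, function(m) { dimnames(m) <- NULL; m })
  list(frames = frames, t = man$t)
}

#' Write / read 3D keypoints as CSV
#'
#' Long format with columns `t`, `joint_id`, `x_mm`, `y_mm`, `z_mm`.
#'
#' @param poses list of `J x 3` matrices (mm).
#' @param path CSV path.
#' @param t timestamps, one per pose.
#' @return `write_keypoints`: the path, invisibly. `read_keypoints`: list
#'   with `poses` and `t`.
#' @export
write_keypoints <- function(poses, path, t = (seq_along(poses) - 1) / 60) {
  rows <- do.call(rbind, lapply(seq_along(poses), function(i) {
    p <- poses[[i]]
    data.frame(t = t[i], joint_id = seq_len(nrow(p)),
               x_mm = p[, 1], y_mm = p[, 2], z_mm = p[, 3])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_keypoints
#' @export
read_keypoints <- function(path) {
  if (!file.exists(path)) stop_("keypoint file '%s' does not exist", path)
  d <- utils::read.csv(path)
  missing_cols <- setdiff(c("t", "joint_id", "x_mm", "y_mm", "z_mm"), names(d))
  if (length(missing_cols) > 0) {
    stop_("keypoint CSV is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  ts <- unique(d$t)
  poses <- lapply(ts, function(tt) {
    s <- d[d$t == tt, ]
    s <- s[order(s$joint_id), ]
    m <- as.matrix(s[, c("x_mm", "y_mm", "z_mm")])
    dimnames(m) <- list(NULL, c("x", "y", "z"))
    m
  })
  list(poses = poses, t = ts)
}

#' Pair frames with keypoints on timestamps
#'
#' Exact matching by default; `tolerance` (seconds) switches to
#' nearest-neighbour matching within the tolerance — the default 1/60 s is
#' the mat's frame period. Unmatched records are reported with a warning.
#'
#' @param frames as returned by [read_frames()].
#' @param keypoints as returned by [read_keypoints()].
#' @param tolerance `NULL` for exact matching, else seconds.
#' @return list of pairs (`frame`, `pose`, `t`).
#' @export
pair_by_timestamp <- function(frames, keypoints, tolerance = NULL) {
  out <- list()
  used <- logical(length(keypoints$t))
  unmatched <- 0L
  for (i in seq_along(frames$t)) {
    tt <- frames$t[i]
    j <- if (is.null(tolerance)) {
      match(TRUE, !used & keypoints$t == tt)
    } else {
      dd <- abs(keypoints$t - tt)
      dd[used] <- Inf
      cand <- which.min(dd)
      if (length(cand) == 1 && dd[cand] <= tolerance) cand else NA_integer_
    }
    if (is.na(j)) {
      unmatched <- unmatched + 1L
      next
    }
    used[j] <- TRUE
    out[[length(out) + 1]] <- list(frame = frames$frames[[i]],
                                   pose = keypoints$poses[[j]], t = tt)
  }
  if (unmatched > 0) {
    warning(sprintf("%d frame(s) had no matching keypoints", unmatched),
            call. = FALSE)
  }
  out
}

#' Write / read a full synthetic dataset directory
#'
#' Layout: `clean/`, `noisy/` frame directories, `keypoints.csv` and a
#' `manifest.json` holding the split table.
#'
#' @param ds a [make_dataset()] result.
#' @param dir output directory.
#' @return `write_dataset`: `dir` invisibly; `read_dataset`: a list shaped
#'   like [make_dataset()] output.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ts <- vapply(ds$scenes, function(s) s$t, numeric(1))
  write_frames(lapply(ds$scenes, `[[`, "clean"), file.path(dir, "clean"), ts)
  write_frames(lapply(ds$scenes, `[[`, "noisy"), file.path(dir, "noisy"), ts)
  write_keypoints(lapply(ds$scenes, `[[`, "pose"),
                  file.path(dir, "keypoints.csv"), ts)
  jsonlite::write_json(as.list(ds$split), file.path(dir, "manifest.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  clean <- read_frames(file.path(dir, "clean"))
  noisy <- read_frames(file.path(dir, "noisy"))
  kp <- read_keypoints(file.path(dir, "keypoints.csv"))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  split <- tibble::as_tibble(man)
  scenes <- lapply(seq_along(clean$frames), function(i) {
    list(clean = clean$frames[[i]], noisy = noisy$frames[[i]],
         pose = kp$poses[[i]], activity = split$activity[i], t = clean$t[i])
  })
  list(scenes = scenes, split = split)
}

#' Save / load a trained model
#'
#' Single-file checkpoint (RDS) holding configuration, weights and auxiliary
#' state; a saved-then-reloaded model reproduces outputs bitwise.
#'
#' @param model a `ddse_model` or `posenet_model`.
#' @param path file path.
#' @return `save_model`: the path invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, c("ddse_model", "posenet_model"))) {
    stop_("'%s' does not contain a tactpose model", path)
  }
  m
}

#' Export a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask 0/1 matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  if (!is_binary(mask)) stop_("write_mask_png expects a binary (0/1) mask")
  if (!requireNamespace("png", quietly = TRUE)) {
    stop_("the png package is required for PNG export")
  }
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}

# canonicalise: recursively sort list fields by name
canonical <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) x <- x[order(nm)]
    lapply(x, canonical)
  } else x
}

#' Stable hash of a run configuration
#'
#' MD5 over the canonicalised (recursively name-sorted) YAML serialisation,
#' so the hash does not depend on field order.
#'
#' @param cfg a [load_config()] object (or any named list).
#' @return hex string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp), add = TRUE)
  yaml::write_yaml(canonical(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}
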