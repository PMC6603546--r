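#' Synthetic-motion generator configuration
#'
#' Describes a ground-truth articulated motion (constant bone lengths by
#' construction, C2-smooth trajectories) plus an SDK-like corruption model:
#' Gaussian noise whose magnitude grows as a bone aligns with the optical
#' axis, transient outlier runs, tracking-state dropouts, and optional
#' left/right flip events.
#'
#' @param dialect a `skeleton_dialect` or built-in name.
#' @param bone_lengths named per-bone lengths in meters (mirror bones equal);
#'   defaults to [default_bone_lengths()].
#' @param frames number of frames.
#' @param fps frame rate, Hz (default 30, the Kinect v2 rate).
#' @param n_keyframes number of random spline keyframes driving the motion;
#'   0 gives a static pose.
#' @param angle_amplitude half-range (radians) of the random per-bone joint
#'   angle excursions around the rest pose.
#' @param root_amplitude half-range (meters) of the root-joint excursions.
#' @param noise_base isotropic Gaussian noise sigma, meters (default 5 mm).
#' @param noise_axis_gain multiplier by which the noise sigma grows for a
#'   bone parallel to the optical axis:
#'   `sigma_eff = noise_base * (1 + gain * |cos(theta)|)` (default 2).
#' @param outlier_rate probability that a given joint-frame is corrupted by
#'   an outlier run (runs have random length `1..outlier_max_run`).
#' @param outlier_magnitude displacement magnitude of an outlier, meters.
#' @param outlier_max_run maximum outlier run length in frames (default 4).
#' @param dropout_rate per-joint-frame probability of an inferred/notTracked
#'   tracking-state dropout.
#' @param flip_rate per-frame probability that a left/right flip event
#'   starts (positions of mirrored joints swapped for a short run).
#' @param seed integer RNG seed; a fixed seed gives byte-identical output.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(dialect = "kinect21", bone_lengths = NULL,
                             frames = 600L, fps = 30, n_keyframes = 5L,
                             angle_amplitude = 0.4, root_amplitude = 0.3,
                             noise_base = 0.005, noise_axis_gain = 2,
                             outlier_rate = 0, outlier_magnitude = 0.5,
                             outlier_max_run = 4L, dropout_rate = 0,
                             flip_rate = 0, seed = 1L) {
  dialect <- get_dialect(dialect)
  if (is.null(bone_lengths)) bone_lengths <- default_bone_lengths(dialect)
  stopifnot(frames >= 1L, fps > 0, all(bone_lengths > 0),
            outlier_rate >= 0, outlier_rate <= 1,
            dropout_rate >= 0, dropout_rate <= 1,
            flip_rate >= 0, flip_rate <= 1,
            outlier_max_run >= 1L, abs(seed) < 2^31)
  missing_b <- setdiff(dialect$bone_names, names(bone_lengths))
  if (length(missing_b))
    stop("bone_lengths missing for: ", paste(missing_b, collapse = ", "))
  structure(list(dialect = dialect,
                 bone_lengths = bone_lengths[dialect$bone_names],
                 frames = as.integer(frames), fps = fps,
                 n_keyframes = as.integer(n_keyframes),
                 angle_amplitude = angle_amplitude,
                 root_amplitude = root_amplitude,
                 noise_base = noise_base, noise_axis_gain = noise_axis_gain,
                 outlier_rate = outlier_rate,
                 outlier_magnitude = outlier_magnitude,
                 outlier_max_run = as.integer(outlier_max_run),
                 dropout_rate = dropout_rate, flip_rate = flip_rate,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Default bone lengths for a built-in dialect
#'
#' Adult human proportions in meters; mirrored bones are equal.
#'
#' @param dialect a `skeleton_dialect` or built-in name.
#' @return named numeric vector, one entry per bone of the dialect.
#' @export
default_bone_lengths <- function(dialect = "kinect21") {
  dialect <- get_dialect(dialect)
  # length by body part, looked up from the class label
  part <- c("SpineBase-SpineMid" = 0.20, "SpineMid-SpineShoulder" = 0.22,
            "SpineShoulder-Neck" = 0.08, "Neck-Head" = 0.15,
            "SpineShoulder-Shoulder" = 0.18, "Shoulder-Elbow" = 0.30,
            "Elbow-Wrist" = 0.26, "Wrist-Hand" = 0.08,
            "SpineBase-HipLeft" = 0.10, "SpineBase-HipRight" = 0.10,
            "Hip-Knee" = 0.42, "Knee-Ankle" = 0.40,
            "AnkleLeft-FootLeft" = 0.15, "AnkleRight-FootRight" = 0.15,
            "Waist-Torso" = 0.25, "Torso-Neck" = 0.22,
            "Neck-LeftCollar" = 0.06, "Neck-RightCollar" = 0.06,
            "Collar-Shoulder" = 0.15,
            "Waist-LeftHip" = 0.10, "Waist-RightHip" = 0.10)
  labels <- dialect$class_names[dialect$bone_class]
  out <- unname(part[labels])
  if (anyNA(out)) out[is.na(out)] <- 0.25   # custom dialects: generic bone
  names(out) <- dialect$bone_names
  out
}

# rest-pose unit direction of each bone for a person standing upright,
# facing the camera (+Z toward the subject, +Y up)
.rest_directions <- function(dialect) {
  side_sign <- function(bone)
    if (grepl("Left", bone)) 1 else if (grepl("Right", bone)) -1 else 0
  dirs <- matrix(0, dialect$n_bones, 3L)
  for (k in seq_len(dialect$n_bones)) {
    bone <- dialect$bone_names[k]
    s <- side_sign(bone)
    label <- gsub("Left|Right", "", bone)
    v <- switch(label,
      "SpineBase-SpineMid" = , "SpineMid-SpineShoulder" = ,
      "Waist-Torso" = , "Torso-Neck" = ,
      "SpineShoulder-Neck" = , "Neck-Head" = c(0, 1, 0),
      "SpineShoulder-Shoulder" = , "Neck-Collar" = c(s, -0.15, 0),
      "Collar-Shoulder" = c(s, 0, 0),
      "Shoulder-Elbow" = c(0.35 * s, -0.95, 0.1),
      "Elbow-Wrist" = c(0.1 * s, -1, 0.15),
      "Wrist-Hand" = c(0, -1, 0.2),
      "SpineBase-Hip" = , "Waist-Hip" = c(s, -0.35, 0),
      "Hip-Knee" = c(0.05 * s, -1, 0.08),
      "Knee-Ankle" = c(0, -1, -0.08),
      "Ankle-Foot" = c(0, -0.25, -1),
      NULL)
    if (is.null(v)) {   # custom dialect: deterministic spread of directions
      a <- 2.399963 * k   # golden-angle increments
      v <- c(cos(a), sin(a), 0.3)
    }
    dirs[k, ] <- v / sqrt(sum(v^2))
  }
  dirs
}

# natural cubic spline through keyframe values, evaluated at frame times;
# constant when there are no keyframes
.spline_track <- function(times, key_t, key_v) {
  if (length(key_v) == 0L) stop("empty keyframe track")
  if (length(key_v) == 1L) return(rep(key_v, length(times)))
  stats::splinefun(key_t, key_v, method = "natural")(times)
}

#' Generate a ground-truth skeleton sequence
#'
#' Builds the skeleton frame by frame from a root trajectory and per-bone
#' directions obtained from splined random joint-angle keyframes on the
#' kinematic tree (azimuth/elevation around the rest pose). Positions are
#' `parent + length * unit(direction)`, so every bone length equals the
#' configured truth exactly in every frame, and trajectories are C2 between
#' keyframes. All joints are `tracked`.
#'
#' @param config a [generator_config()].
#' @return list with `sequence` (a `skeleton_sequence`) and `true_lengths`
#'   (named per-bone vector).
#' @export
generate_ground_truth <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$frames < 1L) stop("need at least 1 frame")
  d <- config$dialect
  nf <- config$frames
  nj <- d$n_joints
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed))
            assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  times <- (seq_len(nf) - 1L) / config$fps
  nk <- config$n_keyframes
  key_t <- if (nk >= 2L)
    seq(times[1L], times[nf] + 1e-9, length.out = nk) else 0

  root_rest <- c(0, 0, 2.5)
  root <- sapply(1:3, function(ax) {
    kv <- if (nk >= 2L)
      root_rest[ax] + stats::runif(nk, -config$root_amplitude,
                                   config$root_amplitude)
    else root_rest[ax]
    .spline_track(times, key_t, kv)
  })
  if (nf == 1L) root <- matrix(root, 1L, 3L)

  rest <- .rest_directions(d)
  pos <- array(NA_real_, dim = c(nf, nj, 3L))
  pos[, 1L, ] <- root
  placed <- c(TRUE, rep(FALSE, nj - 1L))
  todo <- seq_len(d$n_bones)
  while (length(todo)) {
    progressed <- FALSE
    for (k in todo) {
      i <- d$edge_idx[k, 1L]; j <- d$edge_idx[k, 2L]
      if (!placed[i]) next
      az0 <- atan2(rest[k, 2L], rest[k, 1L])
      el0 <- asin(max(-1, min(1, rest[k, 3L])))
      amp <- config$angle_amplitude
      az <- if (nk >= 2L)
        .spline_track(times, key_t, az0 + stats::runif(nk, -amp, amp))
      else rep(az0, nf)
      el <- if (nk >= 2L)
        .spline_track(times, key_t, el0 + stats::runif(nk, -amp, amp))
      else rep(el0, nf)
      dir <- cbind(cos(el) * cos(az), cos(el) * sin(az), sin(el))
      L <- config$bone_lengths[[k]]
      pos[, j, ] <- pos[, i, ] + L * dir
      placed[j] <- TRUE
      todo <- setdiff(todo, k)
      progressed <- TRUE
    }
    if (!progressed) stop("edge list is not a connected tree")
  }
  seqn <- skeleton_sequence(times, pos, "tracked", d)
  list(sequence = seqn, true_lengths = config$bone_lengths)
}

#' Corrupt a ground-truth sequence with an SDK-like error model
#'
#' Applies, in order: angle-scaled Gaussian noise (a joint inherits the
#' angle of the bone connecting it to its parent; the noise sigma is
#' `noise_base * (1 + noise_axis_gain * |cos(theta)|)`), outlier runs of
#' random length up to `outlier_max_run` (a constant random displacement of
#' magnitude `outlier_magnitude`), tracking-state dropouts, and left/right
#' flip events. Every injected event is recorded in the corruption log so
#' detection precision/recall can be computed exactly.
#'
#' @param sequence a ground-truth `skeleton_sequence`.
#' @param config the [generator_config()] used to generate it.
#' @return list with `sequence` (corrupted copy) and `log` (data frame with
#'   columns `type`, `joint`, `frame_start`, `frame_end`, `magnitude`,
#'   `dx`, `dy`, `dz`, `detail`).
#' @export
corrupt <- function(sequence, config) {
  stopifnot(inherits(sequence, "skeleton_sequence"),
            inherits(config, "generator_config"))
  d <- sequence$dialect
  nf <- n_frames(sequence)
  nj <- d$n_joints
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed))
            assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed + 1L)

  pos <- sequence$pos
  state <- sequence$state
  log_rows <- list()

  # --- angle-scaled Gaussian noise ------------------------------------
  if (config$noise_base > 0) {
    cosm <- abs(bone_axis_cosine(sequence))        # frames x bones
    cosm[is.na(cosm)] <- 0
    parent_bone <- match(seq_len(nj), d$edge_idx[, 2L])  # NA for the root
    sig <- matrix(config$noise_base, nf, nj)
    has_parent <- !is.na(parent_bone)
    sig[, has_parent] <- config$noise_base *
      (1 + config$noise_axis_gain * cosm[, parent_bone[has_parent],
                                         drop = FALSE])
    for (ax in 1:3)
      pos[, , ax] <- pos[, , ax] + stats::rnorm(nf * nj, sd = sig)
  }

  # --- outlier runs ----------------------------------------------------
  if (config$outlier_rate > 0) {
    mean_run <- (1 + config$outlier_max_run) / 2
    p_start <- min(1, config$outlier_rate / mean_run)
    for (j in seq_len(nj)) {
      f <- 1L
      while (f <= nf) {
        if (stats::runif(1) < p_start) {
          len <- sample.int(config$outlier_max_run, 1L)
          to <- min(nf, f + len - 1L)
          dirv <- stats::rnorm(3)
          dirv <- dirv / sqrt(sum(dirv^2)) * config$outlier_magnitude
          for (ax in 1:3) pos[f:to, j, ax] <- pos[f:to, j, ax] + dirv[ax]
          log_rows[[length(log_rows) + 1L]] <- data.frame(
            type = "outlier", joint = d$joints[j], frame_start = f,
            frame_end = to, magnitude = config$outlier_magnitude,
            dx = dirv[1L], dy = dirv[2L], dz = dirv[3L], detail = "",
            stringsAsFactors = FALSE)
          f <- to + 2L   # leave a gap so runs never merge
        } else f <- f + 1L
      }
    }
  }

  # --- tracking-state dropouts ----------------------------------------
  if (config$dropout_rate > 0) {
    hits <- which(matrix(stats::runif(nf * nj), nf, nj) <
                  config$dropout_rate, arr.ind = TRUE)
    if (nrow(hits)) {
      new_state <- sample(c("inferred", "notTracked"), nrow(hits),
                          replace = TRUE)
      for (r in seq_len(nrow(hits))) {
        state[hits[r, 1L], hits[r, 2L]] <- new_state[r]
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          type = "dropout", joint = d$joints[hits[r, 2L]],
          frame_start = hits[r, 1L], frame_end = hits[r, 1L],
          magnitude = NA_real_, dx = NA_real_, dy = NA_real_,
          dz = NA_real_, detail = new_state[r], stringsAsFactors = FALSE)
      }
    }
  }

  # --- left/right flip events -----------------------------------------
  if (config$flip_rate > 0) {
    mirror <- .mirror_joints(d)
    f <- 1L
    while (f <= nf) {
      if (stats::runif(1) < config$flip_rate) {
        len <- sample.int(10L, 1L)
        to <- min(nf, f + len - 1L)
        swp <- pos[f:to, mirror, , drop = FALSE]
        pos[f:to, , ] <- swp
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          type = "flip", joint = "", frame_start = f, frame_end = to,
          magnitude = NA_real_, dx = NA_real_, dy = NA_real_,
          dz = NA_real_, detail = "left-right swap",
          stringsAsFactors = FALSE)
        f <- to + 2L
      } else f <- f + 1L
    }
  }

  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(type = character(0), joint = character(0),
               frame_start = integer(0), frame_end = integer(0),
               magnitude = numeric(0), dx = numeric(0), dy = numeric(0),
               dz = numeric(0), detail = character(0),
               stringsAsFactors = FALSE)
  list(sequence = skeleton_sequence(sequence$t, pos, state, d), log = log)
}

# joint index of the left/right mirror of each joint (identity for unpaired)
.mirror_joints <- function(dialect) {
  out <- seq_len(dialect$n_joints)
  for (j in seq_len(dialect$n_joints)) {
    nm <- dialect$joints[j]
    mirrored <- if (grepl("Left", nm)) sub("Left", "Right", nm)
                else if (grepl("Right", nm)) sub("Right", "Left", nm)
                else nm
    m <- match(mirrored, dialect$joints)
    if (!is.na(m)) out[j] <- m
  }
  out
}

#' Generate a ground-truth sequence and its corrupted counterpart
#'
#' @param config a [generator_config()].
#' @return list with `truth`, `noisy` (both `skeleton_sequence`), `log`
#'   (corruption log) and `true_lengths`.
#' @export
simulate_sequence <- function(config) {
  gt <- generate_ground_truth(config)
  cr <- corrupt(gt$sequence, config)
  list(truth = gt$sequence, noisy = cr$sequence, log = cr$log,
       true_lengths = gt$true_lengths)
}

#' Inject a deterministic outlier run into a sequence
#'
#' Displaces one joint by a constant offset over a contiguous frame range —
#' useful for controlled recovery experiments.
#'
#' @param seq a `skeleton_sequence`.
#' @param joint joint name.
#' @param frames integer vector of frame indices.
#' @param offset length-3 displacement in meters.
#' @return the modified `skeleton_sequence`.
#' @export
inject_outlier_run <- function(seq, joint, frames, offset) {
  j <- match(joint, seq$dialect$joints)
  if (is.na(j)) stop("unknown joint '", joint, "'")
  stopifnot(all(frames >= 1L), all(frames <= n_frames(seq)),
            length(offset) == 3L)
  pos <- seq$pos
  for (ax in 1:3) pos[frames, j, ax] <- pos[frames, j, ax] + offset[ax]
  skeleton_sequence(seq$t, pos, seq$state, seq$dialect)
}
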