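#' Second-order forward prediction
#'
#' Extrapolates a joint position one step ahead from the three preceding
#' samples with a second-order Taylor step, the first and second derivatives
#' taken from one-sided 3-point finite differences:
#' `f'(t[h-1]) = (3 f[h-1] - 4 f[h-2] + f[h-3]) / (2 dt)` and
#' `f''(t[h-1]) = (f[h-1] - 2 f[h-2] + f[h-3]) / dt^2`. The scheme is exact
#' for componentwise polynomial trajectories of degree <= 2 (the time step
#' cancels: the prediction is `3 f[h-1] - 3 f[h-2] + f[h-3]`).
#'
#' @param history numeric matrix with 3 rows — the samples at
#'   `t[h-3]`, `t[h-2]`, `t[h-1]` in increasing time — and one column per
#'   coordinate (or a length-3 vector for a scalar trajectory).
#' @param dt time step, seconds (kept in the signature for symmetry with the
#'   derivation; it cancels analytically).
#' @return predicted coordinates (vector), or `NULL` when any history sample
#'   is missing/non-finite.
#' @export
forward_predict <- function(history, dt = 1) {
  if (is.null(history)) return(NULL)
  if (is.null(dim(history))) history <- matrix(history, ncol = 1L)
  stopifnot(nrow(history) == 3L, dt > 0)
  if (!all(is.finite(history))) return(NULL)
  drop(3 * history[3L, ] - 3 * history[2L, ] + history[1L, ])
}

#' Second-order backward prediction
#'
#' Mirror image of [forward_predict()]: extrapolates one step back from the
#' three following samples. Equivalent to a forward prediction on the
#' time-reversed trajectory; exact for degree <= 2.
#'
#' @param future numeric matrix with 3 rows — the samples at
#'   `t[h+1]`, `t[h+2]`, `t[h+3]` in increasing time — one column per
#'   coordinate (or a length-3 vector).
#' @param dt time step, seconds.
#' @return predicted coordinates, or `NULL` when a sample is missing.
#' @export
backward_predict <- function(future, dt = 1) {
  if (is.null(future)) return(NULL)
  if (is.null(dim(future))) future <- matrix(future, ncol = 1L)
  stopifnot(nrow(future) == 3L, dt > 0)
  if (!all(is.finite(future))) return(NULL)
  drop(3 * future[1L, ] - 3 * future[2L, ] + future[3L, ])
}

#' Combine forward and backward predictions
#'
#' The combined estimate is the midpoint of the two predictions. When they
#' disagree by more than `theta_p` the prediction is inadequate — at least
#' one of the neighboring frames is suspect. A missing side degrades
#' gracefully: the available single-sided prediction is used and absence
#' alone never makes the prediction inadequate.
#'
#' @param f_fwd,f_bwd predictions from [forward_predict()] /
#'   [backward_predict()], either possibly `NULL`.
#' @param theta_p disagreement threshold, meters (default 0.08).
#' @return list with `position` (or `NULL` when both sides are missing),
#'   `adequate` (logical) and `fb_distance` (meters, `NA` unless both sides
#'   are present).
#' @export
combine_predictions <- function(f_fwd, f_bwd, theta_p = 0.08) {
  if (is.null(f_fwd) && is.null(f_bwd))
    return(list(position = NULL, adequate = TRUE, fb_distance = NA_real_))
  if (is.null(f_fwd))
    return(list(position = f_bwd, adequate = TRUE, fb_distance = NA_real_))
  if (is.null(f_bwd))
    return(list(position = f_fwd, adequate = TRUE, fb_distance = NA_real_))
  fb <- sqrt(sum((f_fwd - f_bwd)^2))
  list(position = (f_fwd + f_bwd) / 2, adequate = fb <= theta_p,
       fb_distance = fb)
}

#' Consecutive-inadequacy score
#'
#' Counts consecutive frames with inadequate combined predictions for a
#' joint: increments while inadequate, resets to 0 on any adequate frame.
#'
#' @param k_prev previous score(s), non-negative integer.
#' @param adequate logical: was the current combined prediction adequate?
#' @return updated score(s).
#' @export
update_k_score <- function(k_prev, adequate) {
  stopifnot(all(k_prev >= 0))
  n <- max(length(k_prev), length(adequate))
  out <- rep_len(as.integer(k_prev), n) + 1L
  out[rep_len(as.logical(adequate), n)] <- 0L
  out
}

#' Local-maximum outlier rule
#'
#' A joint-frame whose score strictly exceeds the score in both temporal
#' neighbor frames is surely an outlier. Missing neighbors (sequence
#' boundaries) count as infinitely large: a boundary frame is never flagged.
#'
#' @param k_prev,k_cur,k_next scores in the previous, current and next frame
#'   (vectorized; `NA` marks a missing neighbor).
#' @return logical.
#' @export
flag_outlier <- function(k_prev, k_cur, k_next) {
  kp <- ifelse(is.na(k_prev), Inf, k_prev)
  kn <- ifelse(is.na(k_next), Inf, k_next)
  k_cur > kp & k_cur > kn
}

#' Trust-detection configuration
#'
#' @param length_threshold bone-length deviation threshold `theta`, meters
#'   (default 0.10): a bone whose observed length deviates more than this
#'   from its class reference marks both endpoint joints unreliable.
#' @param prediction_threshold forward/backward disagreement threshold
#'   `theta_p`, meters (default 0.08).
#' @param max_speed per-joint speed caps, m/s, for the motion-plausibility
#'   rule: either a single number applied to every joint or a named vector
#'   (missing joints fall back to `default_speed`). The shipped default of
#'   4 m/s for all joints is a stand-in for caps derived from motion-capture
#'   corpora.
#' @param default_speed fallback cap, m/s.
#' @return a list of class `trust_config`.
#' @export
trust_config <- function(length_threshold = 0.10,
                         prediction_threshold = 0.08,
                         max_speed = NULL, default_speed = 4) {
  stopifnot(length_threshold > 0, prediction_threshold > 0,
            default_speed > 0)
  structure(list(length_threshold = length_threshold,
                 prediction_threshold = prediction_threshold,
                 max_speed = max_speed, default_speed = default_speed),
            class = "trust_config")
}

# per-joint speed caps resolved against a dialect
speed_caps <- function(config, dialect) {
  caps <- rep(config$default_speed, dialect$n_joints)
  names(caps) <- dialect$joints
  ms <- config$max_speed
  if (!is.null(ms)) {
    if (is.null(names(ms)) && length(ms) == 1L) caps[] <- ms
    else caps[intersect(names(ms), dialect$joints)] <-
        ms[intersect(names(ms), dialect$joints)]
  }
  caps
}

#' Per-joint trust assessment of one frame
#'
#' Applies the three reliability rules: (1) a joint whose tracking state is
#' not `tracked` is unreliable (`untracked`); (2) a bone whose observed
#' length deviates from its class reference by more than `length_threshold`
#' marks both endpoint joints unreliable (`length_deviation`); (3) a joint
#' farther from its predicted position than its speed cap times `dt` is
#' unreliable (`motion_implausible`; skipped for joints without a
#' prediction).
#'
#' @param pose a `frame_pose`.
#' @param refs a complete `bone_reference_table`.
#' @param predicted `n_joints x 3` matrix of combined predictions (`NA`
#'   rows for joints without one), or `NULL`.
#' @param config a [trust_config()].
#' @param dt frame time step, seconds.
#' @return data frame with one row per joint: `joint`, `reliable`,
#'   `reasons` (comma-separated subset of the three rule tags, empty when
#'   reliable).
#' @export
assess_frame <- function(pose, refs, predicted = NULL,
                         config = trust_config(), dt = 1 / 30) {
  d <- pose$dialect
  nj <- d$n_joints
  reasons <- vector("list", nj)

  bad_state <- pose$state != "tracked"
  for (j in which(bad_state)) reasons[[j]] <- "untracked"

  l_obs <- bone_length(pose)
  l_ref <- ref_by_bone(refs, d)
  dev <- which(abs(l_obs - l_ref) > config$length_threshold)
  for (k in dev) {
    for (j in d$edge_idx[k, ])
      reasons[[j]] <- union(reasons[[j]], "length_deviation")
  }

  if (!is.null(predicted)) {
    caps <- speed_caps(config, d)
    dist <- sqrt(rowSums((pose$pos - predicted)^2))
    far <- which(is.finite(dist) & dist > caps * dt)
    for (j in far)
      reasons[[j]] <- union(reasons[[j]], "motion_implausible")
  }

  reliable <- lengths(reasons) == 0L
  data.frame(joint = d$joints, reliable = reliable,
             reasons = vapply(reasons, paste, character(1), collapse = ","),
             stringsAsFactors = FALSE)
}

# Forward/backward predictions for every frame of one sequence, both sides
# computed from the sequence itself. Returns list(fwd, bwd): F x J x 3
# arrays with NA where fewer than 3 frames are available on that side.
sequence_predictions <- function(seq) {
  nf <- n_frames(seq)
  nj <- seq$dialect$n_joints
  fwd <- bwd <- array(NA_real_, dim = c(nf, nj, 3L))
  if (nf >= 4L) {
    idx <- 4:nf
    fwd[idx, , ] <- 3 * seq$pos[idx - 1L, , , drop = FALSE] -
                    3 * seq$pos[idx - 2L, , , drop = FALSE] +
                        seq$pos[idx - 3L, , , drop = FALSE]
    idx <- 1:(nf - 3L)
    bwd[idx, , ] <- 3 * seq$pos[idx + 1L, , , drop = FALSE] -
                    3 * seq$pos[idx + 2L, , , drop = FALSE] +
                        seq$pos[idx + 3L, , , drop = FALSE]
  }
  list(fwd = fwd, bwd = bwd)
}

#' Export a trust report as CSV
#'
#' @param trust the `trust` data frame of a [refine_sequence()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
trust_to_csv <- function(trust, path) {
  utils::write.csv(trust, path, row.names = FALSE)
  invisible(path)
}
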