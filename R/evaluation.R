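#' Per-bone length variance of a sequence
#'
#' Population variance (divisor `n`) of each bone's length series across
#' frames, and their sum. Constant bone lengths give zero; the drop in this
#' statistic before vs after refinement is the primary stability
#' diagnostic.
#'
#' @param seq a `skeleton_sequence`.
#' @return list with `per_bone` (named vector, m^2) and `total`.
#' @export
bone_length_variance <- function(seq) {
  if (n_frames(seq) < 2L) stop("need at least 2 frames")
  lm <- bone_length_matrix(seq)
  v <- apply(lm, 2L, function(x) mean((x - mean(x))^2))
  list(per_bone = v, total = sum(v))
}

#' Per-frame forward/backward prediction disagreement
#'
#' For each frame where both prediction windows exist (frames 4 to
#' `n - 3`), the sum over joints of the distance between the forward and
#' backward predicted positions, both computed from the sequence itself.
#' Boundary frames are `NA`. A smooth, consistent sequence gives small
#' values; outliers and jitter inflate them.
#'
#' @param seq a `skeleton_sequence`.
#' @param config a [trust_config()] (unused thresholds are ignored; kept so
#'   callers can carry one configuration object).
#' @return numeric vector, one entry per frame (meters).
#' @export
fb_distance_series <- function(seq, config = trust_config()) {
  preds <- sequence_predictions(seq)
  nf <- n_frames(seq)
  out <- rep(NA_real_, nf)
  if (nf < 7L) return(out)
  idx <- 4:(nf - 3L)
  dd <- preds$fwd[idx, , , drop = FALSE] - preds$bwd[idx, , , drop = FALSE]
  out[idx] <- rowSums(sqrt(apply(dd^2, c(1, 2), sum)))
  out
}

#' Per-frame distance between observations and combined predictions
#'
#' The companion diagnostic: the sum over joints of the distance between
#' each observed joint position and the midpoint of its forward and
#' backward predictions (both from the sequence itself).
#'
#' @inheritParams fb_distance_series
#' @return numeric vector, one entry per frame (meters).
#' @export
prediction_distance_series <- function(seq, config = trust_config()) {
  preds <- sequence_predictions(seq)
  nf <- n_frames(seq)
  out <- rep(NA_real_, nf)
  if (nf < 7L) return(out)
  idx <- 4:(nf - 3L)
  mid <- (preds$fwd[idx, , , drop = FALSE] +
          preds$bwd[idx, , , drop = FALSE]) / 2
  dd <- seq$pos[idx, , , drop = FALSE] - mid
  out[idx] <- rowSums(sqrt(apply(dd^2, c(1, 2), sum)))
  out
}

#' Left/right symmetry error
#'
#' For each symmetry pair, the mean over frames of
#' `|l_left - l_right|`. Zero for a perfectly mirror-symmetric skeleton.
#'
#' @param seq a `skeleton_sequence`.
#' @return named numeric vector, one entry per symmetry pair (meters).
#' @export
symmetry_error <- function(seq) {
  d <- seq$dialect
  if (!length(d$symmetry_pairs)) return(stats::setNames(numeric(0), character(0)))
  lm <- bone_length_matrix(seq)
  out <- vapply(d$symmetry_pairs, function(p)
    mean(abs(lm[, p[1L]] - lm[, p[2L]])), numeric(1))
  names(out) <- vapply(d$symmetry_pairs, .class_label, character(1))
  out
}

#' Recovery metrics against a known ground truth
#'
#' Compares a refined (or raw) sequence with the ground truth that generated
#' it, and, when a corruption log is supplied together with a
#' `refined_sequence` trust report, scores outlier detection and per-run
#' recovery.
#'
#' Detection scoring uses a +-3-frame tolerance window (the prediction
#' stencil width): a logged outlier run counts as detected if any outlier
#' flag for that joint falls within 3 frames of the run, and a flag is a
#' true positive if it falls within 3 frames of a logged run. A run counts
#' as recovered when the maximum refined position error of its joint over
#' the run frames is below half the injected magnitude; runs longer than
#' 4 frames are beyond the recovery limit and are reported with their
#' `unrecovered` flag from the pipeline.
#'
#' @param refined a `refined_sequence` (preferred) or `skeleton_sequence`.
#' @param truth the ground-truth `skeleton_sequence`.
#' @param corruption_log optional corruption log from [corrupt()].
#' @return list with `mean_error`, `max_error` (meters), `per_joint_error`
#'   (named mean errors) and, when scoring is possible, `detection`
#'   (precision, recall, counts) and `runs` (per-run recovery table).
#' @export
ground_truth_metrics <- function(refined, truth, corruption_log = NULL) {
  trust <- NULL
  if (inherits(refined, "refined_sequence")) {
    trust <- refined$trust
    refined <- refined$sequence
  }
  stopifnot(n_frames(refined) == n_frames(truth))
  err <- sqrt(apply((refined$pos - truth$pos)^2, c(1, 2), sum))
  out <- list(mean_error = mean(err), max_error = max(err),
              per_joint_error = colMeans(err))
  names(out$per_joint_error) <- truth$dialect$joints

  if (!is.null(corruption_log)) {
    runs <- corruption_log[corruption_log$type == "outlier", , drop = FALSE]
    if (nrow(runs)) {
      runs$length <- runs$frame_end - runs$frame_start + 1L
      jidx <- match(runs$joint, truth$dialect$joints)
      runs$max_refined_error <- vapply(seq_len(nrow(runs)), function(r)
        max(err[runs$frame_start[r]:runs$frame_end[r], jidx[r]]),
        numeric(1))
      runs$recovered <- runs$max_refined_error < runs$magnitude / 2
      if (!is.null(trust)) {
        win <- 3L
        flags <- trust[trust$outlier, c("frame", "joint")]
        runs$detected <- vapply(seq_len(nrow(runs)), function(r) {
          f <- flags$frame[flags$joint == runs$joint[r]]
          any(f >= runs$frame_start[r] - win & f <= runs$frame_end[r] + win)
        }, logical(1))
        tp <- vapply(seq_len(nrow(flags)), function(i) {
          rr <- runs[runs$joint == flags$joint[i], , drop = FALSE]
          any(flags$frame[i] >= rr$frame_start - win &
              flags$frame[i] <= rr$frame_end + win)
        }, logical(1))
        out$detection <- list(
          precision = if (nrow(flags)) mean(tp) else NA_real_,
          recall = mean(runs$detected),
          n_flagged = nrow(flags), n_runs = nrow(runs))
        runs$flagged_unrecovered <- vapply(seq_len(nrow(runs)), function(r)
          any(trust$unrecovered[trust$joint == runs$joint[r] &
                                trust$frame >= runs$frame_start[r] &
                                trust$frame <= runs$frame_end[r]]),
          logical(1))
      }
      out$runs <- runs
    }
  }
  out
}

#' Full evaluation report
#'
#' Bundles the diagnostics for a noisy input sequence and its refined
#' counterpart: per-bone length variances, both per-frame prediction
#' series, symmetry errors, and (when ground truth is available)
#' recovery metrics.
#'
#' @param noisy the input `skeleton_sequence`.
#' @param refined the refined `skeleton_sequence` or a `refined_sequence`.
#' @param truth optional ground-truth `skeleton_sequence`.
#' @param corruption_log optional corruption log.
#' @return list of class `evaluation_report`.
#' @export
evaluation_report <- function(noisy, refined, truth = NULL,
                              corruption_log = NULL) {
  refined_seq <- if (inherits(refined, "refined_sequence"))
    refined$sequence else refined
  rep_ <- list(
    variance_input = bone_length_variance(noisy),
    variance_refined = bone_length_variance(refined_seq),
    fb_distance_input = fb_distance_series(noisy),
    fb_distance_refined = fb_distance_series(refined_seq),
    prediction_distance_input = prediction_distance_series(noisy),
    prediction_distance_refined = prediction_distance_series(refined_seq),
    symmetry_input = symmetry_error(noisy),
    symmetry_refined = symmetry_error(refined_seq))
  if (!is.null(truth)) {
    rep_$vs_truth_input <- ground_truth_metrics(noisy, truth)
    rep_$vs_truth_refined <- ground_truth_metrics(refined, truth,
                                                  corruption_log)
  }
  structure(rep_, class = "evaluation_report")
}

#' Write an evaluation report as JSON
#'
#' @param report an [evaluation_report()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", force = TRUE)
  invisible(path)
}
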