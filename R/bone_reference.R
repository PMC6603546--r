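#' Initialization-window configuration
#'
#' Controls the estimation of per-class reference bone lengths from the
#' first frames of a capture.
#'
#' @param n_init_frames number of leading frames used for the estimate
#'   (default 100; the estimate is frozen afterwards).
#' @param deviation_ratio_cap relative deviation `d / l_ref` above which an
#'   observation gets zero weight in the refinement pass (default 0.5).
#' @param t_half tracking-state factor for half-tracked bones (default 0.8).
#' @return a list of class `init_config`.
#' @export
init_config <- function(n_init_frames = 100L, deviation_ratio_cap = 0.5,
                        t_half = 0.8) {
  stopifnot(n_init_frames >= 4L, deviation_ratio_cap > 0,
            t_half >= 0, t_half <= 1)
  structure(list(n_init_frames = as.integer(n_init_frames),
                 deviation_ratio_cap = deviation_ratio_cap,
                 t_half = t_half),
            class = "init_config")
}

#' Angle-dependent confidence weight of a bone-length observation
#'
#' Depth cameras localize a bone's joints best when the bone is
#' perpendicular to the optical axis and worst when it is parallel to it.
#' The weight is `1 - |cos(theta)|` where `theta` is the angle between the
#' bone direction and the optical axis: 0 for an on-axis bone, 1 for a
#' perpendicular one. Zero-length (degenerate) bones get weight 0.
#'
#' @param direction bone direction: a 3-vector or an `n x 3` matrix of rows.
#' @param axis optical axis (default `+Z`).
#' @return weights in `[0, 1]`.
#' @examples
#' angle_weight(c(0, 0, 1))  # parallel: 0
#' angle_weight(c(1, 0, 0))  # perpendicular: 1
#' @export
angle_weight <- function(direction, axis = c(0, 0, 1)) {
  if (is.null(dim(direction))) direction <- matrix(direction, nrow = 1L)
  an <- sqrt(sum(axis^2))
  if (an == 0) stop("optical axis must be nonzero")
  dn <- sqrt(rowSums(direction^2))
  cosv <- as.vector(direction %*% (axis / an)) / dn
  w <- 1 - abs(cosv)
  w[dn == 0] <- 0
  unname(w)
}

#' Deviation-dependent weight of a bone-length observation
#'
#' Down-weights observations whose length deviates from the current
#' reference: `T * max(0, 1 - (d / l_ref) / cap)` with `d = |l_obs - l_ref|`
#' and `T` the tracking-state factor (1 tracked, `t_half` half-tracked,
#' 0 untracked). Observations deviating by more than `cap * l_ref`
#' (default half the reference length) get weight 0.
#'
#' @param l_obs observed length(s), meters.
#' @param l_ref reference length(s), meters, positive.
#' @param state bone state(s): tracked / halfTracked / notTracked.
#' @param config an [init_config()].
#' @return weights in `[0, 1]`.
#' @export
deviation_weight <- function(l_obs, l_ref, state = "tracked",
                             config = init_config()) {
  stopifnot(all(l_ref > 0))
  d <- abs(l_obs - l_ref)
  w <- pmax(0, 1 - (d / l_ref) / config$deviation_ratio_cap)
  bone_state_factor(state, config$t_half) * w
}

# pooled per-class weighted mean of bone-length observations.
# lengths, weights: frames x bones matrices. Returns list(mean, n, wsum)
# per class; mean is NA when a class has zero total weight.
.class_weighted_mean <- function(lengths, weights, dialect) {
  ncl <- length(dialect$class_names)
  m <- n <- ws <- numeric(ncl)
  for (cl in seq_len(ncl)) {
    cols <- which(dialect$bone_class == cl)
    l <- as.vector(lengths[, cols])
    w <- as.vector(weights[, cols])
    ws[cl] <- sum(w)
    n[cl] <- length(l)
    m[cl] <- if (ws[cl] > 0) sum(w * l) / ws[cl] else NA_real_
  }
  list(mean = m, n = n, wsum = ws)
}

#' Initial reference bone lengths (angle-weighted pass)
#'
#' For each symmetry class, pools the length observations of its bone(s)
#' — both mirror bones of a pair — over the initialization window and takes
#' the angle-weight-weighted mean. Pooling is what enforces equal left and
#' right reference lengths.
#'
#' @param seq a `skeleton_sequence`; the first `n_init_frames` frames are
#'   used (all frames if the sequence is shorter, minimum 4).
#' @param config an [init_config()].
#' @return a `bone_reference_table` data frame, one row per symmetry class,
#'   with `l_ref_initial` filled and `l_ref_final` still `NA`.
#' @export
initial_reference_lengths <- function(seq, config = init_config()) {
  d <- seq$dialect
  nf <- min(n_frames(seq), config$n_init_frames)
  if (nf < 4L)
    stop("need at least 4 frames to initialize reference lengths, got ", nf)
  win <- window_sequence(seq, 1L, nf)
  lengths <- bone_length_matrix(win)
  cosm <- bone_axis_cosine(win)
  weights <- 1 - abs(cosm)
  weights[is.na(weights)] <- 0   # zero-length bones are degenerate
  agg <- .class_weighted_mean(lengths, weights, d)
  if (anyNA(agg$mean))
    stop("all angle weights are zero for class(es): ",
         paste(d$class_names[is.na(agg$mean)], collapse = ", "),
         " (bone never off-axis in the initialization window)")
  tab <- data.frame(class = d$class_names,
                    l_ref_initial = agg$mean,
                    l_ref_final = NA_real_,
                    n_observations = as.integer(agg$n),
                    weight_sum_initial = agg$wsum,
                    weight_sum_final = NA_real_,
                    stringsAsFactors = FALSE)
  attr(tab, "dialect") <- d$name
  class(tab) <- c("bone_reference_table", "data.frame")
  tab
}

#' Refined reference bone lengths (deviation-weighted pass)
#'
#' Recomputes each class reference as the mean of the same pooled
#' observations, now weighted by [deviation_weight()] against the initial
#' reference: gross outliers (relative deviation above the cap) and
#' untracked bones contribute nothing. Classes whose every weight is zero
#' fall back to the initial reference with a warning.
#'
#' @inheritParams initial_reference_lengths
#' @param table output of [initial_reference_lengths()].
#' @return the table with `l_ref_final` filled.
#' @export
refined_reference_lengths <- function(seq, table, config = init_config()) {
  d <- seq$dialect
  stopifnot(inherits(table, "bone_reference_table"),
            !anyNA(table$l_ref_initial))
  nf <- min(n_frames(seq), config$n_init_frames)
  win <- window_sequence(seq, 1L, nf)
  lengths <- bone_length_matrix(win)
  states <- bone_state_matrix(win)
  l_ref <- table$l_ref_initial[d$bone_class]   # per bone
  weights <- matrix(0, nrow(lengths), ncol(lengths))
  for (k in seq_len(d$n_bones))
    weights[, k] <- deviation_weight(lengths[, k], l_ref[k], states[, k],
                                     config)
  agg <- .class_weighted_mean(lengths, weights, d)
  fallback <- is.na(agg$mean)
  if (any(fallback)) {
    warning("no usable observation for class(es) ",
            paste(table$class[fallback], collapse = ", "),
            "; falling back to the initial reference")
    agg$mean[fallback] <- table$l_ref_initial[fallback]
  }
  table$l_ref_final <- agg$mean
  table$weight_sum_final <- agg$wsum
  table
}

#' Estimate reference bone lengths (both passes)
#'
#' Convenience wrapper running [initial_reference_lengths()] then
#' [refined_reference_lengths()].
#'
#' @inheritParams initial_reference_lengths
#' @return a complete `bone_reference_table`.
#' @export
reference_lengths <- function(seq, config = init_config()) {
  tab <- initial_reference_lengths(seq, config)
  refined_reference_lengths(seq, tab, config)
}

# per-bone vector of final (or initial) reference lengths
ref_by_bone <- function(table, dialect, which = "l_ref_final") {
  table[[which]][dialect$bone_class]
}

#' Export / import a reference table as JSON
#'
#' Lets a later `refine` run reuse a table computed previously.
#'
#' @param table a `bone_reference_table`.
#' @param path file path.
#' @return `path` (write) or the table (read).
#' @export
write_reference_table <- function(table, path) {
  payload <- list(dialect = attr(table, "dialect"),
                  classes = as.data.frame(table))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- as.data.frame(x$classes, stringsAsFactors = FALSE)
  attr(tab, "dialect") <- x$dialect
  class(tab) <- c("bone_reference_table", "data.frame")
  tab
}

# contiguous sub-sequence [from, to]
window_sequence <- function(seq, from, to) {
  idx <- seq.int(from, to)
  skeleton_sequence(seq$t[idx],
                    seq$pos[idx, , , drop = FALSE],
                    seq$state[idx, , drop = FALSE],
                    seq$dialect)
}
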