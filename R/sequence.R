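#' Skeleton sequences and frame poses
#'
#' A `skeleton_sequence` stores a motion clip: per-frame timestamps,
#' an `frames x joints x 3` position array (camera coordinates, meters,
#' +Z along the optical axis, right-handed), and a `frames x joints`
#' matrix of tracking states.
#'
#' @param t numeric vector of timestamps in seconds, strictly increasing.
#' @param pos numeric array `c(length(t), n_joints, 3)`; joint order must
#'   follow the dialect.
#' @param state character matrix `length(t) x n_joints` of
#'   tracked/inferred/notTracked, or a single state recycled to all.
#' @param dialect a `skeleton_dialect`.
#' @return an object of class `skeleton_sequence`.
#' @export
skeleton_sequence <- function(t, pos, state = "tracked", dialect) {
  nf <- length(t)
  nj <- dialect$n_joints
  if (nf == 0L) {
    pos <- array(numeric(0), dim = c(0L, nj, 3L))
    state <- matrix(character(0), 0L, nj)
  }
  if (length(state) == 1L)
    state <- matrix(state, nf, nj)
  stopifnot(is.array(pos), length(dim(pos)) == 3L)
  if (!identical(dim(pos), c(nf, nj, 3L)))
    stop("position array must be ", nf, " x ", nj, " x 3 for dialect '",
         dialect$name, "'")
  if (!identical(dim(state), c(nf, nj)))
    stop("state matrix must be ", nf, " x ", nj)
  .check_states(state)
  if (nf > 1L && any(diff(t) <= 0))
    stop("timestamps must be strictly increasing")
  tracked_pos <- pos[rep(state != "notTracked", 3L)]
  if (length(tracked_pos) && !all(is.finite(tracked_pos)))
    stop("non-finite position for a joint whose state is not 'notTracked'")
  dimnames(pos) <- list(NULL, dialect$joints, c("x", "y", "z"))
  colnames(state) <- dialect$joints
  structure(list(t = as.numeric(t), pos = pos, state = state,
                 dialect = dialect),
            class = "skeleton_sequence")
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  cat("<skeleton_sequence> ", n_frames(x), " frames, dialect ",
      x$dialect$name, "\n", sep = "")
  invisible(x)
}

#' Number of frames in a sequence
#' @param seq a `skeleton_sequence`.
#' @return integer frame count.
#' @export
n_frames <- function(seq) length(seq$t)

#' Extract one frame as a pose
#'
#' @param seq a `skeleton_sequence`.
#' @param i frame index.
#' @return a `frame_pose`: timestamp, `n_joints x 3` position matrix,
#'   joint states, and the dialect.
#' @export
get_frame <- function(seq, i) {
  stopifnot(i >= 1L, i <= n_frames(seq))
  frame_pose(seq$t[i], seq$pos[i, , , drop = TRUE], seq$state[i, ],
             seq$dialect)
}

#' @rdname get_frame
#' @param t timestamp (seconds).
#' @param pos `n_joints x 3` numeric matrix.
#' @param state character vector of joint states.
#' @param dialect a `skeleton_dialect`.
#' @export
frame_pose <- function(t, pos, state, dialect) {
  pos <- as.matrix(pos)
  stopifnot(nrow(pos) == dialect$n_joints, ncol(pos) == 3L)
  if (length(state) == 1L) state <- rep(state, dialect$n_joints)
  .check_states(state)
  rownames(pos) <- dialect$joints
  structure(list(t = t, pos = pos, state = state, dialect = dialect),
            class = "frame_pose")
}

#' Bone length(s) of a pose
#'
#' Euclidean distance between the two endpoint joints of a bone.
#'
#' @param pose a `frame_pose`.
#' @param bone bone name `"<parent>-<child>"`; `NULL` returns all bones.
#' @return named numeric vector of lengths in meters.
#' @examples
#' d <- dialect_kinect21()
#' p <- frame_pose(0, matrix(rnorm(63), 21, 3), "tracked", d)
#' bone_length(p, "Neck-Head")
#' @export
bone_length <- function(pose, bone = NULL) {
  d <- pose$dialect
  idx <- d$edge_idx
  if (!is.null(bone)) {
    k <- match(bone, d$bone_names)
    if (anyNA(k))
      stop("unknown bone(s) for dialect '", d$name, "': ",
           paste(bone[is.na(k)], collapse = ", "))
    idx <- idx[k, , drop = FALSE]
  }
  diffs <- pose$pos[idx[, 2L], , drop = FALSE] -
           pose$pos[idx[, 1L], , drop = FALSE]
  out <- sqrt(rowSums(diffs^2))
  names(out) <- if (is.null(bone)) d$bone_names else bone
  out
}

#' Bone lengths for every frame of a sequence
#'
#' @param seq a `skeleton_sequence`.
#' @return `frames x bones` matrix of lengths (meters), columns named by bone.
#' @export
bone_length_matrix <- function(seq) {
  d <- seq$dialect
  idx <- d$edge_idx
  nf <- n_frames(seq)
  out <- matrix(NA_real_, nf, d$n_bones, dimnames = list(NULL, d$bone_names))
  if (nf == 0L) return(out)
  for (k in seq_len(d$n_bones)) {
    dd <- seq$pos[, idx[k, 2L], ] - seq$pos[, idx[k, 1L], ]
    if (nf == 1L) dd <- matrix(dd, 1L, 3L)
    out[, k] <- sqrt(rowSums(dd^2))
  }
  out
}

# per-frame x bone matrix of bone states
bone_state_matrix <- function(seq) {
  idx <- seq$dialect$edge_idx
  si <- seq$state[, idx[, 1L], drop = FALSE]
  sj <- seq$state[, idx[, 2L], drop = FALSE]
  out <- matrix(bone_state(si, sj), nrow(si), ncol(si))
  colnames(out) <- seq$dialect$bone_names
  out
}

# per-frame x bone matrix of unit-direction cosines against the optical axis
bone_axis_cosine <- function(seq, axis = c(0, 0, 1)) {
  d <- seq$dialect
  axis <- axis / sqrt(sum(axis^2))
  nf <- n_frames(seq)
  out <- matrix(NA_real_, nf, d$n_bones, dimnames = list(NULL, d$bone_names))
  for (k in seq_len(d$n_bones)) {
    dd <- seq$pos[, d$edge_idx[k, 2L], ] - seq$pos[, d$edge_idx[k, 1L], ]
    if (nf == 1L) dd <- matrix(dd, 1L, 3L)
    nrm <- sqrt(rowSums(dd^2))
    cosv <- as.vector(dd %*% axis) / nrm
    cosv[nrm == 0] <- NA_real_   # degenerate zero-length bone
    out[, k] <- cosv
  }
  out
}

#' Read a skeleton sequence from a JSON-lines file
#'
#' One frame per line:
#' `{"t": <seconds>, "joints": [{"name": "...", "p": [x,y,z], "state": "..."}]}`.
#' Joint order within a line is free; names must match the dialect exactly.
#'
#' @param path file path.
#' @param dialect a `skeleton_dialect` or built-in dialect name.
#' @return a `skeleton_sequence`.
#' @export
read_sequence <- function(path, dialect) {
  dialect <- get_dialect(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  nf <- length(lines)
  nj <- dialect$n_joints
  tvec <- numeric(nf)
  pos <- array(NA_real_, dim = c(nf, nj, 3L))
  state <- matrix(NA_character_, nf, nj)
  for (i in seq_len(nf)) {
    rec <- tryCatch(
      jsonlite::parse_json(lines[i], simplifyVector = FALSE),
      error = function(e)
        stop("malformed JSON on line ", i, " of ", path, ": ",
             conditionMessage(e), call. = FALSE))
    if (is.null(rec$t) || is.null(rec$joints))
      stop("line ", i, ": frame record needs fields 't' and 'joints'")
    jnames <- vapply(rec$joints, function(j) j$name %||% NA_character_,
                     character(1))
    unknown <- setdiff(jnames, dialect$joints)
    if (length(unknown))
      stop("line ", i, ": unknown joint(s) for dialect '", dialect$name,
           "': ", paste(unknown, collapse = ", "))
    if (length(jnames) != nj || anyDuplicated(jnames))
      stop("line ", i, ": expected ", nj, " distinct joints for dialect '",
           dialect$name, "', got ", length(jnames))
    ord <- match(dialect$joints, jnames)
    tvec[i] <- as.numeric(rec$t)
    for (j in seq_len(nj)) {
      obs <- rec$joints[[ord[j]]]
      p <- unlist(obs$p)
      if (length(p) != 3L)
        stop("line ", i, ", joint ", dialect$joints[j],
             ": position must have 3 components")
      pos[i, j, ] <- as.numeric(p)
      state[i, j] <- obs$state %||% "tracked"
    }
  }
  if (nf > 1L && any(diff(tvec) <= 0))
    stop("timestamps are not strictly increasing (first violation after ",
         "line ", which(diff(tvec) <= 0)[1L], ")")
  skeleton_sequence(tvec, pos, state, dialect)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a skeleton sequence to a JSON-lines file
#'
#' Positions are written with enough precision that a read/write round trip
#' reproduces them to well under 1e-9 m; states round-trip exactly.
#'
#' @param seq a `skeleton_sequence`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  d <- seq$dialect
  con <- file(path, open = "wt")
  on.exit(close(con))
  num <- function(x) sprintf("%.12g", x)
  for (i in seq_len(n_frames(seq))) {
    joints <- vapply(seq_len(d$n_joints), function(j) {
      sprintf('{"name":"%s","p":[%s,%s,%s],"state":"%s"}',
              d$joints[j], num(seq$pos[i, j, 1L]), num(seq$pos[i, j, 2L]),
              num(seq$pos[i, j, 3L]), seq$state[i, j])
    }, character(1))
    writeLines(sprintf('{"t":%s,"joints":[%s]}',
                       num(seq$t[i]), paste(joints, collapse = ",")), con)
  }
  invisible(path)
}

#' Flatten a sequence to a long data frame
#'
#' One row per (frame, joint) with columns `frame`, `t`, `joint`,
#' `x`, `y`, `z`, `state` — the layout used by the CSV export.
#'
#' @param x a `skeleton_sequence`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return a `data.frame`.
#' @export
as.data.frame.skeleton_sequence <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  nf <- n_frames(x)
  nj <- x$dialect$n_joints
  data.frame(
    frame = rep(seq_len(nf), each = nj),
    t = rep(x$t, each = nj),
    joint = rep(x$dialect$joints, times = nf),
    x = as.vector(t(x$pos[, , 1L])),
    y = as.vector(t(x$pos[, , 2L])),
    z = as.vector(t(x$pos[, , 3L])),
    state = as.vector(t(x$state)),
    stringsAsFactors = FALSE)
}

#' Export a sequence as CSV
#'
#' @param seq a `skeleton_sequence`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
sequence_to_csv <- function(seq, path) {
  utils::write.csv(as.data.frame(seq), path, row.names = FALSE)
  invisible(path)
}

# median time step, with a jitter guard: the prediction stencils assume
# constant dt, so relative jitter above 10% is an error
sequence_dt <- function(seq, max_jitter = 0.10) {
  dts <- diff(seq$t)
  if (!length(dts)) stop("need at least 2 frames to derive a time step")
  dt <- stats::median(dts)
  if (any(abs(dts - dt) / dt > max_jitter))
    stop("timestamp jitter exceeds ", max_jitter * 100,
         "% of the median time step; prediction assumes constant dt")
  dt
}
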