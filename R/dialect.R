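#' Skeleton dialects
#'
#' A skeleton dialect describes the joint set of a particular SDK: the ordered
#' joint names, the bone edges (a tree over the joints), and the left/right
#' symmetry pairing of bones. Bones of a symmetry pair share a single
#' reference-length class; unpaired bones form singleton classes.
#'
#' @param name identifier for the dialect.
#' @param joints character vector of joint names (order defines storage order).
#' @param edges two-column character matrix (or list of length-2 vectors),
#'   one row per bone, `parent` then `child` joint name.
#' @param symmetry_pairs list of length-2 character vectors of bone names
#'   (a bone name is `"<parent>-<child>"`); each names a bone and its mirror.
#' @return an object of class `skeleton_dialect`.
#' @examples
#' d <- dialect_kinect21()
#' d$n_joints
#' bone_names(d)[1:4]
#' @export
skeleton_dialect <- function(name, joints, edges, symmetry_pairs = list()) {
  stopifnot(is.character(joints), length(joints) >= 2L)
  if (anyDuplicated(joints))
    stop("duplicate joint names in dialect '", name, "'")
  if (is.list(edges))
    edges <- do.call(rbind, edges)
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L)
    stop("edges must have two columns (parent, child)")
  bad <- setdiff(c(edges), joints)
  if (length(bad))
    stop("edge endpoint(s) not in joint list: ", paste(bad, collapse = ", "))
  if (nrow(edges) != length(joints) - 1L)
    stop("dialect '", name, "' is not a tree: |E| = ", nrow(edges),
         " but |V| - 1 = ", length(joints) - 1L)

  edge_idx <- cbind(match(edges[, 1L], joints), match(edges[, 2L], joints))
  .check_connected(length(joints), edge_idx, name)

  bnames <- paste(edges[, 1L], edges[, 2L], sep = "-")
  if (anyDuplicated(bnames)) stop("duplicate bones in dialect '", name, "'")

  bone_class <- seq_along(bnames)
  seen <- character(0)
  for (p in symmetry_pairs) {
    if (length(p) != 2L || p[1L] == p[2L])
      stop("symmetry pair must name two distinct bones")
    i <- match(p, bnames)
    if (anyNA(i))
      stop("symmetry pair references unknown bone(s): ",
           paste(p[is.na(i)], collapse = ", "))
    if (any(p %in% seen))
      stop("bone appears in more than one symmetry pair: ",
           paste(intersect(p, seen), collapse = ", "))
    seen <- c(seen, p)
    bone_class[i] <- min(bone_class[i])
  }
  bone_class <- match(bone_class, sort(unique(bone_class)))
  class_names <- vapply(split(bnames, bone_class), .class_label, character(1))

  structure(
    list(name = name, joints = joints, edges = edges, edge_idx = edge_idx,
         bone_names = bnames, symmetry_pairs = symmetry_pairs,
         bone_class = bone_class, class_names = unname(class_names),
         n_joints = length(joints), n_bones = nrow(edges)),
    class = "skeleton_dialect")
}

# shared label for a symmetry class: drop Left/Right tokens when the two
# mirrored bone names then agree, else keep the joined names
.class_label <- function(members) {
  if (length(members) == 1L) return(members)
  stripped <- unique(gsub("Left|Right", "", members))
  if (length(stripped) == 1L) stripped else paste(sort(members), collapse = "|")
}

.check_connected <- function(n, edge_idx, name) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edge_idx))) {
    i <- edge_idx[k, 1L]; j <- edge_idx[k, 2L]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n)
  queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  if (!all(seen))
    stop("dialect '", name, "' edge set is not connected")
  invisible(TRUE)
}

#' @export
print.skeleton_dialect <- function(x, ...) {
  cat("<skeleton_dialect> ", x$name, ": ", x$n_joints, " joints, ",
      x$n_bones, " bones, ", length(x$symmetry_pairs),
      " symmetry pairs\n", sep = "")
  invisible(x)
}

#' Bone names of a dialect
#'
#' @param dialect a `skeleton_dialect`.
#' @return character vector `"<parent>-<child>"`, one per bone.
#' @export
bone_names <- function(dialect) dialect$bone_names

#' Built-in Kinect-style 21-joint dialect
#'
#' The Kinect v2 25-joint set with the four hand tip / thumb joints dropped
#' (they are poorly estimated at usual camera distances). Symmetry pairs:
#' upper arms, lower arms, upper legs, lower legs, and the shoulder-to-neck
#' (SpineShoulder-to-Shoulder) bones.
#'
#' @return a `skeleton_dialect` with 21 joints and 20 bones.
#' @export
dialect_kinect21 <- function() {
  joints <- c("SpineBase", "SpineMid", "SpineShoulder", "Neck", "Head",
              "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
              "ShoulderRight", "ElbowRight", "WristRight", "HandRight",
              "HipLeft", "KneeLeft", "AnkleLeft", "FootLeft",
              "HipRight", "KneeRight", "AnkleRight", "FootRight")
  edges <- rbind(
    c("SpineBase", "SpineMid"), c("SpineMid", "SpineShoulder"),
    c("SpineShoulder", "Neck"), c("Neck", "Head"),
    c("SpineShoulder", "ShoulderLeft"), c("ShoulderLeft", "ElbowLeft"),
    c("ElbowLeft", "WristLeft"), c("WristLeft", "HandLeft"),
    c("SpineShoulder", "ShoulderRight"), c("ShoulderRight", "ElbowRight"),
    c("ElbowRight", "WristRight"), c("WristRight", "HandRight"),
    c("SpineBase", "HipLeft"), c("HipLeft", "KneeLeft"),
    c("KneeLeft", "AnkleLeft"), c("AnkleLeft", "FootLeft"),
    c("SpineBase", "HipRight"), c("HipRight", "KneeRight"),
    c("KneeRight", "AnkleRight"), c("AnkleRight", "FootRight"))
  pairs <- list(
    c("SpineShoulder-ShoulderLeft", "SpineShoulder-ShoulderRight"),
    c("ShoulderLeft-ElbowLeft", "ShoulderRight-ElbowRight"),
    c("ElbowLeft-WristLeft", "ElbowRight-WristRight"),
    c("HipLeft-KneeLeft", "HipRight-KneeRight"),
    c("KneeLeft-AnkleLeft", "KneeRight-AnkleRight"))
  skeleton_dialect("kinect21", joints, edges, pairs)
}

#' Built-in Nuitrack-style 20-joint dialect
#'
#' A canonical naming of the Nuitrack joint set (head, neck, torso, waist,
#' collars, and left/right shoulder, elbow, wrist, hand, hip, knee, ankle).
#' Symmetry pairs mirror the Kinect dialect, with the collar-to-shoulder
#' bones as the shoulder-to-neck class.
#'
#' @return a `skeleton_dialect` with 20 joints and 19 bones.
#' @export
dialect_nuitrack20 <- function() {
  joints <- c("Waist", "Torso", "Neck", "Head",
              "LeftCollar", "LeftShoulder", "LeftElbow", "LeftWrist",
              "LeftHand",
              "RightCollar", "RightShoulder", "RightElbow", "RightWrist",
              "RightHand",
              "LeftHip", "LeftKnee", "LeftAnkle",
              "RightHip", "RightKnee", "RightAnkle")
  edges <- rbind(
    c("Waist", "Torso"), c("Torso", "Neck"), c("Neck", "Head"),
    c("Neck", "LeftCollar"), c("LeftCollar", "LeftShoulder"),
    c("LeftShoulder", "LeftElbow"), c("LeftElbow", "LeftWrist"),
    c("LeftWrist", "LeftHand"),
    c("Neck", "RightCollar"), c("RightCollar", "RightShoulder"),
    c("RightShoulder", "RightElbow"), c("RightElbow", "RightWrist"),
    c("RightWrist", "RightHand"),
    c("Waist", "LeftHip"), c("LeftHip", "LeftKnee"),
    c("LeftKnee", "LeftAnkle"),
    c("Waist", "RightHip"), c("RightHip", "RightKnee"),
    c("RightKnee", "RightAnkle"))
  pairs <- list(
    c("LeftCollar-LeftShoulder", "RightCollar-RightShoulder"),
    c("LeftShoulder-LeftElbow", "RightShoulder-RightElbow"),
    c("LeftElbow-LeftWrist", "RightElbow-RightWrist"),
    c("LeftHip-LeftKnee", "RightHip-RightKnee"),
    c("LeftKnee-LeftAnkle", "RightKnee-RightAnkle"))
  skeleton_dialect("nuitrack20", joints, edges, pairs)
}

#' Look up a built-in dialect by name
#'
#' @param name `"kinect21"` or `"nuitrack20"`, or a path to a dialect JSON
#'   file (see [read_dialect()]).
#' @return a `skeleton_dialect`.
#' @export
get_dialect <- function(name) {
  if (inherits(name, "skeleton_dialect")) return(name)
  switch(name,
         kinect21   = dialect_kinect21(),
         nuitrack20 = dialect_nuitrack20(),
         if (file.exists(name)) read_dialect(name)
         else stop("unknown dialect '", name, "'"))
}

#' Read a custom dialect from JSON
#'
#' The file must contain `joints` (array of names), `edges` (array of
#' `[parent, child]` pairs) and optionally `symmetry_pairs` (array of
#' `[bone, mirror-bone]` pairs, bones named `"<parent>-<child>"`).
#'
#' @param path file path.
#' @param name dialect identifier; defaults to the file base name.
#' @return a `skeleton_dialect`.
#' @export
read_dialect <- function(path, name = NULL) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  if (is.null(name))
    name <- if (!is.null(x$name)) x$name else
      sub("\\.[^.]*$", "", basename(path))
  pairs <- list()
  if (!is.null(x$symmetry_pairs)) {
    sp <- x$symmetry_pairs
    pairs <- if (is.matrix(sp)) lapply(seq_len(nrow(sp)), function(i) sp[i, ])
             else sp
  }
  skeleton_dialect(name, x$joints, x$edges, pairs)
}

#' Classify a bone's tracking state from its endpoint joint states
#'
#' A bone is `tracked` when both endpoint joints are tracked, `notTracked`
#' when neither is, and `halfTracked` when exactly one is. `inferred` joints
#' count as not tracked for this rule: they are exactly the estimates the
#' refinement is meant to fix.
#'
#' @param state_i,state_j joint states, each one of
#'   `"tracked"`, `"inferred"`, `"notTracked"` (vectorized).
#' @return character vector of bone states.
#' @examples
#' bone_state("tracked", "tracked")   # "tracked"
#' bone_state("tracked", "inferred")  # "halfTracked"
#' @export
bone_state <- function(state_i, state_j) {
  .check_states(c(state_i, state_j))
  ti <- state_i == "tracked"
  tj <- state_j == "tracked"
  out <- rep("halfTracked", length(ti))
  out[ti & tj] <- "tracked"
  out[!ti & !tj] <- "notTracked"
  out
}

.joint_states <- c("tracked", "inferred", "notTracked")

.check_states <- function(s) {
  bad <- setdiff(unique(s), .joint_states)
  if (length(bad))
    stop("invalid tracking state(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Per-bone tracking-state factor
#'
#' The confidence factor applied to a bone-length observation:
#' 1 for tracked bones, `t_half` (default 0.8) for half-tracked bones,
#' 0 for untracked bones.
#'
#' @param state bone states (from [bone_state()]).
#' @param t_half factor for half-tracked bones.
#' @return numeric vector of factors in `[0, 1]`.
#' @export
bone_state_factor <- function(state, t_half = 0.8) {
  out <- numeric(length(state))
  out[state == "tracked"] <- 1
  out[state == "halfTracked"] <- t_half
  out
}
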