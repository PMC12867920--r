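# Skeleton topology and the three model input streams (joint / bone / velocity).

#' Default 25-joint skeleton topology
#'
#' A COCO-style extended tree over the 25 tracked joints (pelvis-rooted torso
#' chain, two arms with hands, two legs with feet, head with eyes and jaw).
#' Motion-capture corpora rarely ship their joint tree with the coordinates, so
#' the topology is configuration: any connected 25-node tree can be supplied in
#' its place (see [read_skeleton()]).
#'
#' @return An object of class `skeleton_topology`: a list with `parent`
#'   (integer vector of length 25, `NA` at the root) and `joint_names`.
#' @export
#' @examples
#' topo <- default_skeleton()
#' sum(!is.na(topo$parent))  # 24 bones
default_skeleton <- function() {
  joint_names <- c(
    "pelvis", "spine", "chest", "neck", "head", "nose", "l_eye", "r_eye",
    "l_shoulder", "l_elbow", "l_wrist", "l_hand",
    "r_shoulder", "r_elbow", "r_wrist", "r_hand",
    "l_hip", "l_knee", "l_ankle", "l_foot",
    "r_hip", "r_knee", "r_ankle", "r_foot", "jaw"
  )
  parent <- c(NA, 1L, 2L, 3L, 4L, 5L, 5L, 5L,
              3L, 9L, 10L, 11L,
              3L, 13L, 14L, 15L,
              1L, 17L, 18L, 19L,
              1L, 21L, 22L, 23L, 5L)
  structure(list(parent = parent, joint_names = joint_names),
            class = "skeleton_topology")
}

# Rest-pose joint offsets (metres, relative to parent) for a 1.70 m figure.
# Used by the generator and by the local-frame angle-jitter augmentation.
skeleton_rest_offsets <- function() {
  rbind(
    pelvis     = c(0, 0.95, 0),
    spine      = c(0, 0.15, 0),
    chest      = c(0, 0.18, 0),
    neck       = c(0, 0.12, 0),
    head       = c(0, 0.10, 0),
    nose       = c(0, 0.05, 0.08),
    l_eye      = c(0.03, 0.08, 0.07),
    r_eye      = c(-0.03, 0.08, 0.07),
    l_shoulder = c(0.18, 0.05, 0),
    l_elbow    = c(0.28, 0, 0),
    l_wrist    = c(0.25, 0, 0),
    l_hand     = c(0.09, 0, 0),
    r_shoulder = c(-0.18, 0.05, 0),
    r_elbow    = c(-0.28, 0, 0),
    r_wrist    = c(-0.25, 0, 0),
    r_hand     = c(-0.09, 0, 0),
    l_hip      = c(0.10, -0.05, 0),
    l_knee     = c(0, -0.42, 0),
    l_ankle    = c(0, -0.40, 0),
    l_foot     = c(0, -0.05, 0.12),
    r_hip      = c(-0.10, -0.05, 0),
    r_knee     = c(0, -0.42, 0),
    r_ankle    = c(0, -0.40, 0),
    r_foot     = c(0, -0.05, 0.12),
    jaw        = c(0, -0.02, 0.06)
  )
}

#' Validate a skeleton topology
#'
#' Checks that `parent` describes a connected tree over 25 joints with exactly
#' one root and no cycles.
#'
#' @param topo A `skeleton_topology` (or plain list with a `parent` field).
#' @return `topo`, invisibly, on success; otherwise an error.
#' @export
validate_skeleton <- function(topo) {
  parent <- topo$parent
  stop_if(length(parent) != 25L, "skeleton topology must have 25 joints")
  roots <- which(is.na(parent))
  stop_if(length(roots) != 1L, "skeleton topology must have exactly one root")
  stop_if(any(parent[!is.na(parent)] < 1 | parent[!is.na(parent)] > 25),
          "parent indices out of range")
  # walk each joint to the root; more than 25 hops means a cycle
  for (j in seq_along(parent)) {
    cur <- j
    for (hop in 1:26) {
      if (is.na(parent[cur])) break
      cur <- parent[cur]
      stop_if(hop == 26, "skeleton topology contains a cycle")
    }
  }
  invisible(topo)
}

# Joints in depth-first order from the root (parents always precede children).
skeleton_order <- function(topo) {
  parent <- topo$parent
  ord <- which(is.na(parent))
  while (length(ord) < length(parent)) {
    nxt <- which(parent %in% ord & !(seq_along(parent) %in% ord))
    ord <- c(ord, nxt)
  }
  ord
}

#' Read a skeleton topology from JSON
#'
#' The file must contain `joint_names` and 1-based `parent` indices (the root's
#' parent encoded as 0 or null).
#'
#' @param path Path to a JSON topology file.
#' @return A validated `skeleton_topology`.
#' @export
read_skeleton <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  parent <- as.integer(spec$parent)
  parent[parent == 0L] <- NA_integer_
  topo <- structure(list(parent = parent,
                         joint_names = spec$joint_names %||% paste0("j", seq_along(parent) - 1L)),
                    class = "skeleton_topology")
  validate_skeleton(topo)
  topo
}

#' Bone vectors of a pose sequence
#'
#' For every non-root joint j, `bone_j(t) = coords_j(t) - coords_parent(j)(t)`.
#' Bone vectors carry the spatial structure between body segments and are
#' invariant to whole-body translation.
#'
#' @param seq A [pose_sequence()] or a T x 25 x 3 coordinate array.
#' @param topo Skeleton topology; defaults to [default_skeleton()].
#' @return A T x 72 matrix (24 bones x 3 axes, child-joint order).
#' @export
bone_vectors <- function(seq, topo = default_skeleton()) {
  validate_skeleton(topo)
  coords <- as_coords(seq)
  children <- which(!is.na(topo$parent))
  out <- matrix(0, dim(coords)[1], length(children) * 3L)
  for (i in seq_along(children)) {
    j <- children[i]
    p <- topo$parent[j]
    out[, (3L * i - 2L):(3L * i)] <- coords[, j, ] - coords[, p, ]
  }
  out
}

#' Frame-to-frame joint velocities
#'
#' First differences of the joint coordinates scaled by the frame rate,
#' `v(t) = (x(t) - x(t-1)) * fps`, with the first frame's velocity replicated
#' from the second so all streams keep the same length.
#'
#' @inheritParams bone_vectors
#' @param fps Frames per second; taken from the sequence when available.
#' @return A T x 75 matrix (25 joints x 3 axes) in metres/second.
#' @export
velocities <- function(seq, fps = NULL) {
  coords <- as_coords(seq)
  fps <- fps %||% (if (inherits(seq, "pose_sequence")) seq$fps else 25)
  n <- dim(coords)[1]
  stop_if(n < 2L, "velocities need at least 2 frames")
  flat <- flatten_coords(coords)
  v <- rbind(flat[2, , drop = FALSE] - flat[1, , drop = FALSE],
             diff(flat)) * fps
  v
}

#' Decompose a pose sequence into the three model input streams
#'
#' Produces the joint stream (raw coordinates, T x 75), the bone stream
#' (parent-relative segment vectors, T x 72) and the velocity stream
#' (T x 75) that feed the three temporal-convolution branches.
#'
#' @inheritParams bone_vectors
#' @return A list of class `branch_features` with elements `joint`, `bone`,
#'   `velocity`.
#' @export
branch_features <- function(seq, topo = default_skeleton()) {
  coords <- as_coords(seq)
  out <- list(joint = flatten_coords(coords),
              bone = bone_vectors(seq, topo),
              velocity = velocities(seq))
  stopifnot(all(vapply(out, function(m) all(is.finite(m)), logical(1))))
  class(out) <- "branch_features"
  out
}

# ---- coordinate array plumbing -------------------------------------------

as_coords <- function(x) {
  if (inherits(x, "pose_sequence")) return(x$coords)
  stop_if(!(is.array(x) && length(dim(x)) == 3L && dim(x)[2] == 25L && dim(x)[3] == 3L),
          "expected a pose_sequence or a T x 25 x 3 array")
  x
}

# T x 25 x 3 -> T x 75 with columns j1_x, j1_y, j1_z, j2_x, ...
flatten_coords <- function(coords) {
  n <- dim(coords)[1]
  out <- matrix(0, n, 75L)
  for (j in 1:25) out[, (3L * j - 2L):(3L * j)] <- coords[, j, ]
  out
}

unflatten_coords <- function(flat) {
  n <- nrow(flat)
  coords <- array(0, c(n, 25L, 3L))
  for (j in 1:25) coords[, j, ] <- flat[, (3L * j - 2L):(3L * j)]
  coords
}
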