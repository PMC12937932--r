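#' Canonical body-segment names
#'
#' The 23 body segments tracked by a full-body inertial motion-capture suit:
#' the axial chain (pelvis through head) plus bilateral shoulder girdle, arm,
#' hand, leg, foot and toe segments. Feature names throughout the package
#' (`pos_<Segment>`, `vel_<Segment>`, `A_<Seg1>_<Seg2>`, `<metric>_<Segment>`)
#' use these names verbatim, including spaces.
#'
#' @return Character vector of 23 segment names.
#' @export
#' @examples
#' body_segments()
body_segments <- function() {
  c(
    "Pelvis", "L5", "L3", "T12", "T8", "Neck", "Head",
    "Right Shoulder", "Right Upper Arm", "Right Forearm", "Right Hand",
    "Left Shoulder", "Left Upper Arm", "Left Forearm", "Left Hand",
    "Right Upper Leg", "Right Lower Leg", "Right Foot", "Right Toe",
    "Left Upper Leg", "Left Lower Leg", "Left Foot", "Left Toe"
  )
}

# Anatomical metadata used by the synthetic generator and the body-network
# export: approximate standing height of each segment (m), lateral offset (m),
# body side and limb class, and whether the segment is distal (hands, feet,
# toes) or proximal/axial (trunk chain + head).
segment_template <- function() {
  seg <- body_segments()
  z <- c(
    1.00, 1.08, 1.16, 1.24, 1.32, 1.44, 1.58,
    1.45, 1.30, 1.10, 0.95,
    1.45, 1.30, 1.10, 0.95,
    0.75, 0.45, 0.18, 0.10,
    0.75, 0.45, 0.18, 0.10
  )
  x <- c(
    rep(0, 7),
    rep(-0.20, 4), rep(0.20, 4),
    rep(-0.10, 4), rep(0.10, 4)
  )
  side <- c(
    rep("center", 7),
    rep("right", 4), rep("left", 4),
    rep("right", 4), rep("left", 4)
  )
  limb <- c(
    rep("trunk", 6), "head",
    rep("arm", 4), rep("arm", 4),
    rep("leg", 4), rep("leg", 4)
  )
  distal <- seg %in% c(
    "Right Hand", "Left Hand", "Right Foot", "Left Foot",
    "Right Toe", "Left Toe"
  )
  proximal <- seg %in% c("Pelvis", "L5", "L3", "T12", "T8", "Neck", "Head")
  data.frame(
    segment = seg, z = z, x = x, side = side, limb = limb,
    distal = distal, proximal = proximal, stringsAsFactors = FALSE
  )
}

# 2D stickman coordinates (frontal plane) for the body-network export.
segment_layout <- function() {
  tpl <- segment_template()
  data.frame(segment = tpl$segment, x = tpl$x, y = tpl$z,
             stringsAsFactors = FALSE)
}

assert_known_segments <- function(names) {
  bad <- setdiff(unique(names), body_segments())
  if (length(bad) > 0L) {
    stop("unknown segment name(s): ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
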