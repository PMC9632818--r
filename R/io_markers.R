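#' Marker-set label conventions
#'
#' The package ships a 26-label dorsal marker set in the spirit of
#' hand-and-wrist kinematics protocols: one marker per digit joint centre
#' and fingertip (20), a wrist-centre marker, radial/ulnar wrist and
#' forearm markers, and a hand-dorsum marker.  `hawk_joint_map()` maps the
#' 21 joint-centre labels onto the 0-based hand keypoint indices used by
#' [hand_track]; the remaining five markers are tracking/reference markers
#' with no keypoint counterpart.
#'
#' @return `hawk_marker_labels()`: character vector of the 26 labels.
#' @export
hawk_marker_labels <- function() {
  c("FA_RAD", "FA_ULN", "WRST", "WRIST_RAD", "WRIST_ULN", "HAND_DOR",
    "T_CMC", "T_MCP", "T_IP", "T_TIP",
    "I_MCP", "I_PIP", "I_DIP", "I_TIP",
    "M_MCP", "M_PIP", "M_DIP", "M_TIP",
    "R_MCP", "R_PIP", "R_DIP", "R_TIP",
    "L_MCP", "L_PIP", "L_DIP", "L_TIP")
}

#' @rdname hawk_marker_labels
#' @return `hawk_joint_map()`: named integer vector, marker label ->
#'   0-based keypoint index.
#' @export
hawk_joint_map <- function() {
  c(WRST = 0L,
    T_CMC = 1L, T_MCP = 2L, T_IP = 3L, T_TIP = 4L,
    I_MCP = 5L, I_PIP = 6L, I_DIP = 7L, I_TIP = 8L,
    M_MCP = 9L, M_PIP = 10L, M_DIP = 11L, M_TIP = 12L,
    R_MCP = 13L, R_PIP = 14L, R_DIP = 15L, R_TIP = 16L,
    L_MCP = 17L, L_PIP = 18L, L_DIP = 19L, L_TIP = 20L)
}

#' Construct a labelled 3D marker trajectory set
#'
#' @param positions Numeric array `frames x 3 x markers` in mm; `NA`
#'   coordinates mark gaps (frames where a marker was not reconstructed).
#' @param labels Character vector of marker labels, one per slice of the
#'   third array dimension.
#' @param fps Capture rate in Hz.
#' @return An object of class `marker_set`.
#' @export
marker_set <- function(positions, labels, fps = 30) {
  positions <- unclass(positions)
  if (length(dim(positions)) != 3L || dim(positions)[2L] != 3L)
    stop("positions must be a frames x 3 x markers array")
  if (dim(positions)[3L] != length(labels))
    stop("number of labels must match number of markers")
  if (anyDuplicated(labels)) stop("duplicate marker labels")
  if (!is.numeric(fps) || fps <= 0) stop("fps must be positive")
  dimnames(positions) <- list(NULL, c("x", "y", "z"), labels)
  structure(list(positions = positions, labels = labels, fps = fps),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  gaps <- sum(apply(is.na(x$positions), c(1, 3), any))
  cat(sprintf("<marker_set> %d markers, %d frames @ %g Hz, %d gap(s)\n",
              length(x$labels), dim(x$positions)[1L], x$fps, gaps))
  invisible(x)
}

#' @rdname marker_set
#' @param markers A `marker_set`.
#' @return `marker_gaps()`: logical frames x markers matrix, `TRUE` where
#'   any coordinate of the marker is missing at that frame.
#' @export
marker_gaps <- function(markers) {
  stopifnot(inherits(markers, "marker_set"))
  apply(is.na(markers$positions), c(1, 3), any)
}

#' Read a marker trajectory TSV export
#'
#' Expects the plain-text dialect: line 1 `FREQUENCY<TAB><Hz>`, line 2
#' `MARKER_NAMES<TAB>name1<TAB>...`, then one row per frame with
#' tab-separated `X Y Z` columns per marker, in mm.  Empty cells become
#' gaps (`NA`).  Labels outside the configured marker-set definition are
#' retained with a warning.
#'
#' @param path File path.
#' @param known_labels Labels considered valid (default
#'   [hawk_marker_labels()]).
#' @return A [marker_set].
#' @export
read_marker_tsv <- function(path, known_labels = hawk_marker_labels()) {
  if (!file.exists(path)) stop("marker TSV not found: '", path, "'")
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1L], "FREQUENCY\t") ||
      !startsWith(lines[2L], "MARKER_NAMES\t"))
    stop("'", path, "' is not a marker TSV: FREQUENCY / MARKER_NAMES ",
         "header lines missing")
  fps <- as.numeric(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][2L])
  if (!is.finite(fps) || fps <= 0) stop("invalid FREQUENCY in '", path, "'")
  labels <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]][-1L]
  unknown <- setdiff(labels, known_labels)
  if (length(unknown))
    warning("marker label(s) not in marker-set definition: ",
            paste(unknown, collapse = ", "), " (retained)")
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  m <- length(labels)
  n <- length(body)
  pos <- array(NA_real_, c(n, 3L, m))
  for (i in seq_len(n)) {
    cells <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    length(cells) <- 3L * m  # right-pad short rows with NA
    vals <- suppressWarnings(as.numeric(cells))
    vals[!nzchar(cells) | is.na(cells)] <- NA_real_
    pos[i, , ] <- matrix(vals, nrow = 3L)
  }
  marker_set(pos, labels, fps = fps)
}

#' Write a marker trajectory set as TSV
#'
#' Inverse of [read_marker_tsv()]; gaps are written as empty cells.
#'
#' @param markers A [marker_set].
#' @param path Output file path.
#' @param digits Decimal places for coordinates (default 6).
#' @return Invisibly, `path`.
#' @export
write_marker_tsv <- function(markers, path, digits = 6) {
  stopifnot(inherits(markers, "marker_set"))
  n <- dim(markers$positions)[1L]
  m <- length(markers$labels)
  fmt <- paste0("%.", digits, "f")
  header <- c(paste0("FREQUENCY\t", format(markers$fps)),
              paste(c("MARKER_NAMES", markers$labels), collapse = "\t"))
  rows <- vapply(seq_len(n), function(i) {
    vals <- as.vector(markers$positions[i, , ])  # x,y,z per marker
    cells <- ifelse(is.na(vals), "", sprintf(fmt, vals))
    paste(cells, collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Camera projection specification
#'
#' Two modes are supported for taking 3D marker positions to the 2D image
#' plane.  `"orthographic"` drops one axis (the camera axis of a purely
#' frontal view) and scales the remaining two from mm to px; `"matrix"`
#' applies a full-rank 3 x 4 homogeneous camera matrix with perspective
#' division.
#'
#' @param mode `"orthographic"` or `"matrix"`.
#' @param drop_axis Axis dropped in orthographic mode (1 = x, 2 = y,
#'   3 = z; default 3).
#' @param scale px/mm scale in orthographic mode; must be positive.
#' @param matrix 3 x 4 camera matrix (matrix mode).
#' @return An object of class `projection`.
#' @export
projection <- function(mode = c("orthographic", "matrix"), drop_axis = 3L,
                       scale = 1, matrix = NULL) {
  mode <- match.arg(mode)
  if (mode == "orthographic") {
    if (!drop_axis %in% 1:3) stop("drop_axis must be 1, 2 or 3")
    if (!is.numeric(scale) || scale <= 0) stop("scale must be positive")
  } else {
    if (is.null(matrix) || !is.matrix(matrix) ||
        !identical(dim(matrix), c(3L, 4L)))
      stop("matrix mode requires a 3 x 4 camera matrix")
    if (qr(matrix)$rank < 3L)
      stop("camera matrix must have full rank 3")
  }
  structure(list(mode = mode, drop_axis = as.integer(drop_axis),
                 scale = scale, matrix = matrix),
            class = "projection")
}

#' Project 3D marker trajectories onto the 2D image plane
#'
#' Maps joint-centre markers to hand keypoints via `joint_map` and
#' projects them with the given [projection].  Gapped markers yield
#' missing landmarks at those frames; keypoint slots with no mapped
#' marker are missing throughout.  No extrapolation is performed.
#'
#' @param markers A [marker_set].
#' @param proj A [projection].
#' @param joint_map Named integer vector, marker label -> 0-based keypoint
#'   index (default [hawk_joint_map()]).
#' @param hand_side Hand the markers belong to.
#' @return A [hand_track] with `source = "projected_marker"`.
#' @export
project_markers <- function(markers, proj = projection(),
                            joint_map = hawk_joint_map(),
                            hand_side = c("right", "left")) {
  stopifnot(inherits(markers, "marker_set"), inherits(proj, "projection"))
  hand_side <- match.arg(hand_side)
  if (any(joint_map < 0L | joint_map > 20L))
    stop("joint_map keypoint indices must lie in 0..20")
  if (anyDuplicated(joint_map))
    stop("joint_map assigns two markers to one keypoint")
  n <- dim(markers$positions)[1L]
  x <- matrix(NA_real_, n, 21L)
  y <- matrix(NA_real_, n, 21L)
  mapped <- intersect(names(joint_map), markers$labels)
  for (lab in mapped) {
    p3 <- markers$positions[, , lab, drop = TRUE]
    if (n == 1L) p3 <- matrix(p3, 1L, 3L)
    p2 <- project_points(p3, proj)
    col <- joint_map[[lab]] + 1L
    x[, col] <- p2[, 1L]
    y[, col] <- p2[, 2L]
  }
  hand_track(x, y, fps = markers$fps, hand_side = hand_side,
             source = "projected_marker")
}

#' @rdname project_markers
#' @param points Numeric `n x 3` matrix of 3D points (mm).
#' @return `project_points()`: an `n x 2` matrix of pixel coordinates
#'   (`NA` rows for points with any missing coordinate).
#' @export
project_points <- function(points, proj = projection()) {
  stopifnot(inherits(proj, "projection"))
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be n x 3")
  bad <- rowSums(is.na(points)) > 0L
  if (proj$mode == "orthographic") {
    keep <- setdiff(1:3, proj$drop_axis)
    out <- points[, keep, drop = FALSE] * proj$scale
  } else {
    h <- proj$matrix %*% rbind(t(points), 1)
    out <- cbind(h[1L, ] / h[3L, ], h[2L, ] / h[3L, ])
  }
  out[bad, ] <- NA_real_
  dimnames(out) <- NULL
  out
}
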