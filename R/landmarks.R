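#' Landmark tables
#'
#' Landmarks are named 3D points bonded to a model: the two palatal-suture
#' points (`A`, `B`, no tooth), alignment points used to seed registration,
#' functional-occlusal-plane cusp points, and the per-tooth crown landmarks —
#' for a first molar (U6) `A` mesial-buccal cusp, `B`/`C` distal/mesial points
#' of the central groove, `D`/`E` most occlusal/gingival points of the buccal
#' groove; for a central incisor (U1) `F` incisal-edge midpoint, `G`/`H`
#' distal/mesial incisal-edge points, `I` gingival-edge midpoint.
#'
#' A landmark table is a tibble with columns `id` (character), `tooth`
#' (character or `NA` for midline/suture points) and `x`, `y`, `z` (mm).
#' The pair `(tooth, id)` is unique within a model.
#'
#' @param id Character vector of landmark ids.
#' @param tooth Character vector of tooth labels (`"RU6"`, `"LU6"`, `"RU1"`,
#'   `"LU1"`, premolar labels for cusp points) or `NA`.
#' @param xyz n x 3 matrix of coordinates (mm).
#' @return A landmark tibble.
#' @export
landmark_table <- function(id, tooth, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  lms <- tibble::tibble(id = as.character(id),
                        tooth = as.character(tooth),
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  validate_landmarks(lms)
}

#' Validate a landmark table
#' @param lms Landmark tibble.
#' @return `lms` (as tibble), errors on duplicate `(tooth, id)` pairs or
#'   non-finite coordinates.
#' @export
validate_landmarks <- function(lms) {
  lms <- tibble::as_tibble(lms)
  req <- c("id", "tooth", "x", "y", "z")
  if (!all(req %in% names(lms))) {
    stop("landmarks: need columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(as.matrix(lms[, c("x", "y", "z")])))) {
    stop("landmarks: non-finite coordinates", call. = FALSE)
  }
  key <- paste(ifelse(is.na(lms$tooth), "-", lms$tooth), lms$id)
  if (anyDuplicated(key)) {
    stop("landmarks: duplicate landmark id(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  lms
}

#' Extract landmark coordinates as a matrix
#'
#' @param lms Landmark tibble.
#' @param id Optional id filter.
#' @param tooth Optional tooth filter (`NA` selects tooth-free landmarks).
#' @return n x 3 coordinate matrix with rownames `tooth:id` (or `id`).
#' @export
landmark_xyz <- function(lms, id = NULL, tooth = NULL) {
  sel <- rep(TRUE, nrow(lms))
  if (!is.null(id)) sel <- sel & lms$id %in% id
  if (!is.null(tooth)) {
    sel <- sel & if (all(is.na(tooth))) is.na(lms$tooth) else
      (!is.na(lms$tooth) & lms$tooth %in% tooth)
  }
  out <- as.matrix(lms[sel, c("x", "y", "z")])
  rownames(out) <- ifelse(is.na(lms$tooth[sel]), lms$id[sel],
                          paste0(lms$tooth[sel], ":", lms$id[sel]))
  out
}

landmark_point <- function(lms, id, tooth = NA) {
  sel <- lms$id == id &
    (if (is.na(tooth)) is.na(lms$tooth) else !is.na(lms$tooth) & lms$tooth == tooth)
  if (sum(sel) != 1L) {
    stop("landmark not found (or ambiguous): ",
         if (is.na(tooth)) id else paste0(tooth, ":", id), call. = FALSE)
  }
  as.numeric(lms[sel, c("x", "y", "z")])
}

#' @export
apply_transform.tbl_df <- function(x, transform) {
  stopifnot(all(c("x", "y", "z") %in% names(x)))
  xyz <- transform_points(as.matrix(x[, c("x", "y", "z")]), transform)
  x$x <- xyz[, 1]; x$y <- xyz[, 2]; x$z <- xyz[, 3]
  x
}

#' Read a landmark sidecar file
#'
#' STL has no attribute channel, so landmarks travel in a plain-text,
#' diff-friendly sidecar: whitespace-delimited columns `id tooth x y z`, one
#' landmark per line, `-` for tooth-free landmarks, `#` comments allowed.
#'
#' @param path Path to the landmark file.
#' @return A landmark tibble.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) {
    stop("read_landmarks: no such file: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^id[[:space:]]", lines)]  # optional header
  if (!length(lines)) stop("read_landmarks: no landmarks in ", path,
                           call. = FALSE)
  fields <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(fields) != 5L)) {
    stop("read_landmarks: expected 5 columns (id tooth x y z) in ", path,
         call. = FALSE)
  }
  m <- do.call(rbind, fields)
  xyz <- suppressWarnings(matrix(as.numeric(m[, 3:5]), ncol = 3L))
  if (anyNA(xyz)) {
    stop("read_landmarks: non-numeric coordinate in ", path, call. = FALSE)
  }
  landmark_table(m[, 1], ifelse(m[, 2] == "-", NA_character_, m[, 2]), xyz)
}

#' Write a landmark sidecar file
#'
#' Coordinates are written with 17 significant digits so decimal inputs with
#' up to 6 fractional digits round-trip exactly.
#'
#' @param lms Landmark tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lms, path) {
  lms <- validate_landmarks(lms)
  num <- function(v) format(v, digits = 17, trim = TRUE, scientific = FALSE)
  writeLines(c("id tooth x y z",
               paste(lms$id, ifelse(is.na(lms$tooth), "-", lms$tooth),
                     num(lms$x), num(lms$y), num(lms$z))), path)
  invisible(path)
}
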