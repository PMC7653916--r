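#' Region masks
#'
#' A region mask names a set of faces of a mesh: the palatal-vault stable
#' reference region (the medial part of the third rugae and the palatal vault
#' dorsal to it) used for model-to-model superimposition, or a dental-crown
#' patch used for reference superimposition and landmark transfer. Clinical
#' workflows select these regions interactively; here masks are explicit
#' inputs (and phantom outputs), stored as 1-based face-index lists.
#'
#' @param kind One of `"palatal_vault"`, `"crown"`, `"cusp_set"`.
#' @param faces Integer face indices (1-based) into the referenced mesh.
#' @param mesh_ref Optional label of the mesh the indices refer to.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(kind = c("palatal_vault", "crown", "cusp_set"),
                        faces, mesh_ref = "") {
  kind <- match.arg(kind)
  faces <- sort(unique(as.integer(faces)))
  if (length(faces) == 0L || anyNA(faces) || min(faces) < 1L) {
    stop("region_mask: faces must be a non-empty set of positive indices",
         call. = FALSE)
  }
  structure(list(kind = kind, faces = faces, mesh_ref = as.character(mesh_ref)),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat("<region_mask>", x$kind, "-", length(x$faces), "faces",
      if (nzchar(x$mesh_ref)) paste0("on '", x$mesh_ref, "'") else "", "\n")
  invisible(x)
}

#' Validate masks against a mesh
#'
#' Checks index ranges and that the palatal-vault mask is disjoint from every
#' crown mask (a face cannot be both stable reference and moving tooth).
#'
#' @param masks Named list of [region_mask] objects.
#' @param mesh The [trimesh] the masks refer to.
#' @return `masks`, invisibly; errors on violation.
#' @export
validate_masks <- function(masks, mesh) {
  stopifnot(is.list(masks))
  nf <- nrow(mesh$faces)
  for (nm in names(masks)) {
    m <- masks[[nm]]
    stopifnot(inherits(m, "region_mask"))
    if (max(m$faces) > nf) {
      stop("mask '", nm, "': face index ", max(m$faces),
           " exceeds mesh face count ", nf, call. = FALSE)
    }
  }
  kinds <- vapply(masks, function(m) m$kind, character(1))
  pal <- unlist(lapply(masks[kinds == "palatal_vault"], `[[`, "faces"))
  for (nm in names(masks)[kinds == "crown"]) {
    ov <- intersect(pal, masks[[nm]]$faces)
    if (length(ov)) {
      stop("mask '", nm, "' overlaps the palatal_vault mask (",
           length(ov), " faces)", call. = FALSE)
    }
  }
  invisible(masks)
}

#' Read a mask sidecar file (JSON)
#'
#' The sidecar is a JSON object keyed by mask name; each entry has fields
#' `kind`, `mesh` and `faces` (1-based face indices).
#'
#' @param path Path to the JSON mask file.
#' @return Named list of [region_mask] objects.
#' @export
read_masks <- function(path) {
  if (!file.exists(path)) stop("read_masks: no such file: ", path,
                               call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(raw, function(e) {
    region_mask(e$kind, e$faces, e$mesh %||% "")
  })
  names(out) <- names(raw)
  out
}

#' Write a mask sidecar file (JSON)
#' @param masks Named list of [region_mask] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_masks <- function(masks, path) {
  payload <- lapply(masks, function(m) {
    list(kind = m$kind, mesh = m$mesh_ref, faces = m$faces)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
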