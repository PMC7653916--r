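#' Read an STL surface file
#'
#' Reads both STL dialects. Digital dental models are exchanged as STL, which
#' stores each triangle's three corners independently; on read, vertices with
#' exactly equal coordinates are merged (no tolerance welding), so landmark to
#' surface distances are unchanged by a round trip. Face orientation is kept
#' as stored.
#'
#' Note the binary dialect stores float32 coordinates: coordinates written in
#' binary are quantised to about 7 significant digits, while the ASCII writer
#' emits 17 significant digits and round-trips doubles exactly.
#'
#' @param path Path to an `.stl` file.
#' @param name Mesh label; defaults to the solid name (ASCII) or file name.
#' @return A [trimesh].
#' @export
read_stl <- function(path, name = NULL) {
  if (!file.exists(path)) stop("read_stl: no such file: ", path, call. = FALSE)
  size <- file.info(path)$size
  if (is.na(size) || size < 15) {
    stop("read_stl: file too short to be STL (", size, " bytes): ", path,
         call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  head84 <- readBin(con, "raw", n = min(84, size))
  is_binary <- FALSE
  if (size >= 84) {
    n_tri <- readBin(head84[81:84], "integer", size = 4L, endian = "little")
    if (!is.na(n_tri) && n_tri >= 0 && size == 84 + 50 * as.numeric(n_tri)) {
      is_binary <- TRUE
    }
  }
  if (is_binary) {
    tri <- read_stl_binary(con, n_tri)
    solid_name <- ""
  } else {
    txt <- rawToChar(c(head84, readBin(con, "raw", n = size)))
    parsed <- read_stl_ascii(txt, path)
    tri <- parsed$tri
    solid_name <- parsed$name
  }
  if (nrow(tri) == 0L) stop("read_stl: empty solid in ", path, call. = FALSE)
  n <- nrow(tri)
  mesh <- trimesh(tri, matrix(seq_len(n), ncol = 3L, byrow = TRUE),
                  name = name %||% (if (nzchar(solid_name)) solid_name
                                    else basename(path)))
  weld_vertices(mesh)
}

read_stl_binary <- function(con, n_tri) {
  # each facet: 12 float32 (normal + 3 vertices) + uint16 attribute
  rec <- readBin(con, "raw", n = 50 * n_tri)
  if (length(rec) != 50 * n_tri) {
    stop("read_stl: truncated binary STL at byte ",
         84 + length(rec), call. = FALSE)
  }
  idx <- rep(seq(0L, length.out = n_tri) * 50L, each = 48L) +
    rep(1:48, times = n_tri)
  vals <- readBin(rec[idx], "numeric", n = 12 * n_tri, size = 4L,
                  endian = "little")
  m <- matrix(vals, ncol = 12L, byrow = TRUE)
  rbind_interleave(m[, 4:6, drop = FALSE], m[, 7:9, drop = FALSE],
                   m[, 10:12, drop = FALSE])
}

rbind_interleave <- function(a, b, c) {
  n <- nrow(a)
  out <- matrix(0, 3 * n, 3L)
  out[seq(1, 3 * n, by = 3), ] <- a
  out[seq(2, 3 * n, by = 3), ] <- b
  out[seq(3, 3 * n, by = 3), ] <- c
  out
}

read_stl_ascii <- function(txt, path) {
  lines <- strsplit(txt, "\r?\n")[[1]]
  lt <- trimws(lines)
  if (!length(lt) || !startsWith(lt[1], "solid")) {
    stop("read_stl: malformed STL (no 'solid' header, no binary layout) in ",
         path, call. = FALSE)
  }
  solid_name <- trimws(sub("^solid", "", lt[1]))
  vlines <- grep("^vertex[[:space:]]", lt)
  if (length(vlines) %% 3 != 0) {
    stop("read_stl: malformed ASCII STL: vertex count ", length(vlines),
         " not a multiple of 3 (near line ",
         if (length(vlines)) vlines[length(vlines)] else 1, ") in ", path,
         call. = FALSE)
  }
  if (length(vlines) == 0L) return(list(tri = matrix(0, 0, 3), name = solid_name))
  fields <- strsplit(lt[vlines], "[[:space:]]+")
  bad <- which(lengths(fields) != 4L)
  if (length(bad)) {
    stop("read_stl: malformed vertex line ", vlines[bad[1]], " in ", path,
         call. = FALSE)
  }
  coords <- suppressWarnings(
    vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
  if (anyNA(coords)) {
    bad <- vlines[which(colSums(is.na(coords)) > 0)[1]]
    stop("read_stl: non-numeric coordinate at line ", bad, " in ", path,
         call. = FALSE)
  }
  list(tri = t(coords), name = solid_name)
}

#' Write an STL surface file
#'
#' @param mesh A [trimesh].
#' @param path Output path.
#' @param dialect `"ascii"` (17 significant digits, lossless for doubles) or
#'   `"binary"` (compact, float32).
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("ascii", "binary")) {
  dialect <- match.arg(dialect)
  validate_trimesh(mesh)
  a <- face_corner(mesh, 1L); b <- face_corner(mesh, 2L); c3 <- face_corner(mesh, 3L)
  u <- b - a; v <- c3 - a
  fn <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  len <- sqrt(rowSums(fn^2))
  fn[len > 1e-300, ] <- fn[len > 1e-300, ] / len[len > 1e-300]
  if (dialect == "ascii") {
    num <- function(m) {
      s <- format(m, digits = 17, scientific = TRUE, trim = TRUE)
      matrix(s, nrow = nrow(m))
    }
    sn <- num(fn); sa <- num(a); sb <- num(b); sc <- num(c3)
    row3 <- function(s, i) paste(s[i, 1], s[i, 2], s[i, 3])
    i <- seq_len(nrow(a))
    body <- paste0("facet normal ", row3(sn, i), "\n",
                   " outer loop\n",
                   "  vertex ", row3(sa, i), "\n",
                   "  vertex ", row3(sb, i), "\n",
                   "  vertex ", row3(sc, i), "\n",
                   " endloop\n",
                   "endfacet")
    nm <- if (nzchar(mesh$name)) mesh$name else "surface"
    ok <- tryCatch({
      writeLines(c(paste("solid", nm), body, paste("endsolid", nm)), path)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("write_stl: cannot write ", path, ": ",
                          conditionMessage(ok), call. = FALSE)
  } else {
    con <- tryCatch(file(path, "wb"), error = function(e) e)
    if (inherits(con, "error")) {
      stop("write_stl: cannot open ", path, ": ", conditionMessage(con),
           call. = FALSE)
    }
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", paste("palatesup", mesh$name)))[1:80]
    writeBin(header, con)
    writeBin(as.integer(nrow(a)), con, size = 4L, endian = "little")
    block <- cbind(fn, a, b, c3)  # 12 float32 per facet
    for (i in seq_len(nrow(block))) {
      writeBin(as.numeric(block[i, ]), con, size = 4L, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
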