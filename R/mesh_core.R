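#' Triangle mesh
#'
#' The basic unit every pipeline stage consumes and produces: `n` vertex
#' coordinates in millimetres plus a shared triangulation. Face indices are
#' 1-based (converted at the I/O boundary where a format differs).
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm), columns
#'   x, y, z. Convention: right-handed frame, +z anterior (out of the face).
#' @param faces integer m x 3 matrix of 1-based triangle vertex indices.
#' @param id scan identifier string.
#' @return An object of class `trimesh` with elements `vertices`, `faces`,
#'   `id`.
#' @examples
#' m <- trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
#' aed(m, m)
#' @export
trimesh <- function(vertices, faces, id = "mesh") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L)
    stop("vertices must be an n x 3 matrix, got ", ncol(vertices), " columns")
  if (nrow(vertices) < 3L)
    stop("a mesh needs at least 3 vertices, got ", nrow(vertices))
  if (!all(is.finite(vertices)))
    stop("vertices contain non-finite values")
  if (ncol(faces) != 3L)
    stop("faces must be triangles (m x 3), got ", ncol(faces), " columns")
  if (nrow(faces) < 1L)
    stop("a mesh needs at least one triangle")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range [1, ", nrow(vertices), "]")
  structure(list(vertices = vertices, faces = faces, id = as.character(id)),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh '%s': %d vertices, %d triangles\n",
              x$id, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Named sparse landmarks on one mesh
#'
#' @param mesh_id identifier of the mesh the landmarks annotate.
#' @param points k x 3 matrix of landmark coordinates (mm).
#' @param names character vector of k landmark names.
#' @return Object of class `landmark_set`.
#' @export
landmark_set <- function(mesh_id, points, names) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  if (ncol(points) != 3L) stop("landmark points must be k x 3")
  names <- as.character(names)
  if (length(names) != nrow(points))
    stop("need one name per landmark: ", length(names), " names for ",
         nrow(points), " points")
  if (anyDuplicated(names)) stop("duplicate landmark names")
  if (!all(is.finite(points))) stop("landmark coordinates must be finite")
  structure(list(mesh_id = as.character(mesh_id), points = points,
                 names = names), class = "landmark_set")
}

#' Check landmarks lie within a mesh's (expanded) bounding box
#'
#' @param lms `landmark_set`.
#' @param mesh `trimesh`.
#' @param tol bounding-box expansion tolerance in mm.
#' @return `TRUE` invisibly; error otherwise.
#' @export
check_landmarks <- function(lms, mesh, tol = 1) {
  lo <- apply(mesh$vertices, 2, min) - tol
  hi <- apply(mesh$vertices, 2, max) + tol
  ok <- lms$points >= rep(lo, each = nrow(lms$points)) &
    lms$points <= rep(hi, each = nrow(lms$points))
  if (!all(ok)) {
    bad <- which(!apply(ok, 1, all))
    stop("landmarks outside mesh bounding box (tol ", tol, " mm): ",
         paste(lms$names[bad], collapse = ", "))
  }
  invisible(TRUE)
}

#' Flatten a mesh into a shape vector
#'
#' Concatenates vertex coordinates as (x1, y1, z1, x2, y2, z2, ...) into a
#' length-3n vector, the representation all statistical stages operate on.
#'
#' @param mesh a `trimesh`, or an n x 3 coordinate matrix.
#' @return Object of class `flat_shape`: list with `x` (length 3n) and
#'   `n_vertices`.
#' @export
flatten <- function(mesh) {
  v <- if (inherits(mesh, "trimesh")) mesh$vertices else as.matrix(mesh)
  structure(list(x = as.vector(t(v)), n_vertices = nrow(v)),
            class = "flat_shape")
}

#' Rebuild a mesh from a shape vector
#'
#' @param x `flat_shape` or bare numeric vector of length 3n.
#' @param faces triangulation to attach.
#' @param id scan identifier.
#' @return `trimesh`; exact inverse of [flatten()].
#' @export
unflatten <- function(x, faces, id = "mesh") {
  v <- shape_coords(x)
  trimesh(v, faces, id = id)
}

#' @rdname flatten
#' @param x `flat_shape` or numeric length-3n vector.
#' @return `shape_coords` returns the n x 3 coordinate matrix.
#' @export
shape_coords <- function(x) {
  if (inherits(x, "flat_shape")) x <- x$x
  if (inherits(x, "trimesh")) return(x$vertices)
  if (is.matrix(x)) {
    if (ncol(x) != 3L) stop("coordinate matrix must have 3 columns")
    storage.mode(x) <- "double"
    return(x)
  }
  x <- as.numeric(x)
  if (length(x) %% 3L != 0L)
    stop("shape vector length ", length(x), " not divisible by 3")
  matrix(x, ncol = 3L, byrow = TRUE)
}

as_flat <- function(x) {
  if (inherits(x, "flat_shape")) return(x)
  flatten(shape_coords(x))
}

#' Average Euclidean distance between two corresponded meshes
#'
#' The per-vertex error measure used throughout: mean over vertices of the
#' Euclidean distance between homologous vertices,
#' \eqn{AED = (1/n) \sum_i \|a_i - b_i\|_2}, in mm. Requires dense
#' correspondence (equal vertex count, vertex i homologous).
#'
#' @param a,b corresponded meshes (`trimesh`, `flat_shape`, or coordinate
#'   matrices).
#' @param mask optional logical or integer vertex subset over which to
#'   average (e.g. a facial region crop); default all vertices.
#' @return Non-negative scalar (mm).
#' @export
aed <- function(a, b, mask = NULL) {
  va <- shape_coords(a)
  vb <- shape_coords(b)
  if (nrow(va) != nrow(vb))
    stop("meshes not in correspondence: ", nrow(va), " vs ", nrow(vb),
         " vertices")
  d <- sqrt(rowSums((va - vb)^2))
  if (!is.null(mask)) d <- d[mask]
  mean(d)
}

#' @rdname aed
#' @export
average_euclidean_distance <- aed

#' Signed per-vertex error map
#'
#' Per-vertex Euclidean distance between two corresponded meshes, signed by
#' the anterior (z) axis: positive where the reference vertex has the larger
#' z value (reference more protrusive), negative where smaller. Zero
#' z-difference takes the positive sign (the magnitude is then typically 0).
#' Used for mean-face difference colourmaps.
#'
#' @param reference,other corresponded meshes.
#' @param axis which coordinate carries the sign (default 3 = z, anterior).
#' @return Numeric length-n vector of signed distances (mm).
#' @export
signed_error_map <- function(reference, other, axis = 3L) {
  va <- shape_coords(reference)
  vb <- shape_coords(other)
  if (nrow(va) != nrow(vb))
    stop("meshes not in correspondence: ", nrow(va), " vs ", nrow(vb),
         " vertices")
  d <- sqrt(rowSums((va - vb)^2))
  s <- ifelse(va[, axis] >= vb[, axis], 1, -1)
  s * d
}

# ---------------------------------------------------------------------------
# Mesh I/O: ASCII OBJ, ASCII / binary-little-endian PLY
# ---------------------------------------------------------------------------

#' Read a triangle mesh from OBJ or PLY
#'
#' Supports ASCII Wavefront OBJ (`v`/`f` records; `f` may use the
#' `v/vt/vn` slash syntax) and PLY in ASCII or binary little-endian form.
#' Vertex order is preserved exactly as stored. Non-triangular faces are an
#' error: silent triangulation would corrupt correspondence bookkeeping.
#'
#' @param path file path.
#' @param format `"obj"`, `"ply"`, or `NULL` to infer from the extension.
#' @return `trimesh` with `id` set to the file's base name.
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  switch(format,
         obj = read_obj(path),
         ply = read_ply(path),
         stop("unsupported mesh format '", format, "' (use obj or ply)"))
}

#' Write a triangle mesh to OBJ or PLY
#'
#' @param mesh `trimesh`.
#' @param path output path.
#' @param format `"obj"`, `"ply"`, or `NULL` to infer from the extension.
#' @param binary for PLY, write binary little-endian instead of ASCII.
#' @param quality optional per-vertex scalar (e.g. a signed error map),
#'   stored in PLY as a per-vertex `quality` property.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE,
                       quality = NULL) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  switch(format,
         obj = write_obj(mesh, path),
         ply = write_ply(mesh, path, binary = binary, quality = quality),
         stop("unsupported mesh format '", format, "'"))
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vs <- list(); fs <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#")) next
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (tok[1] == "v") {
      if (length(tok) < 4)
        stop("malformed OBJ vertex at line ", i, " of ", path)
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (any(is.na(xyz)))
        stop("malformed OBJ vertex at line ", i, " of ", path)
      vs[[length(vs) + 1L]] <- xyz
    } else if (tok[1] == "f") {
      idx <- tok[-1]
      if (length(idx) != 3)
        stop("non-triangular face (", length(idx), " vertices) at line ", i,
             " of ", path, "; only triangle meshes are accepted")
      # keep only the vertex index before any '/'
      vi <- suppressWarnings(as.integer(sub("/.*$", "", idx)))
      if (any(is.na(vi)))
        stop("malformed OBJ face at line ", i, " of ", path)
      fs[[length(fs) + 1L]] <- vi
    }
    # vn/vt/usemtl etc. ignored
  }
  if (length(vs) == 0) stop("no vertices in OBJ file ", path)
  if (length(fs) == 0) stop("no faces in OBJ file ", path)
  trimesh(do.call(rbind, vs), do.call(rbind, fs),
          id = tools::file_path_sans_ext(basename(path)))
}

write_obj <- function(mesh, path) {
  con <- file(path, "wb")  # wb: LF line endings on every platform
  on.exit(close(con))
  writeLines(c(sprintf("v %.17g %.17g %.17g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]),
               sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3])), con)
  invisible(path)
}

.ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                    short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                    int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_read_scalar <- function(con, type) {
  sz <- .ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64"))
    readBin(con, "double", n = 1L, size = sz, endian = "little")
  else
    readBin(con, "integer", n = 1L, size = sz,
            signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")),
            endian = "little")
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply"))
    stop("not a PLY file (missing 'ply' magic): ", path)
  fmt <- NULL
  elements <- list()  # each: list(name, count, props = list(list(name,type,list_count_type)))
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0) stop("unexpected end of PLY header in ", path)
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
      if (!fmt %in% c("ascii", "binary_little_endian"))
        stop("unsupported PLY format '", fmt, "' in ", path)
    } else if (tok[1] == "element") {
      elements[[length(elements) + 1L]] <-
        list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      k <- length(elements)
      if (k == 0) stop("PLY property before any element in ", path)
      if (tok[2] == "list") {
        p <- list(name = tok[5], type = tok[4], list_count_type = tok[3])
      } else {
        p <- list(name = tok[3], type = tok[2], list_count_type = NULL)
      }
      elements[[k]]$props <- c(elements[[k]]$props, list(p))
    } else if (tok[1] == "end_header") break
    else stop("malformed PLY header line '", ln, "' in ", path)
  }
  if (is.null(fmt)) stop("PLY header missing format line in ", path)

  verts <- NULL; faces <- NULL
  if (fmt == "ascii") {
    body <- readLines(con)
    pos <- 1L
    for (el in elements) {
      rows <- body[pos:(pos + el$count - 1L)]
      pos <- pos + el$count
      toks <- strsplit(trimws(rows), "[[:space:]]+")
      if (el$name == "vertex") {
        pn <- vapply(el$props, `[[`, "", "name")
        ix <- match(c("x", "y", "z"), pn)
        if (any(is.na(ix))) stop("PLY vertex element lacks x/y/z in ", path)
        verts <- t(vapply(toks, function(t) as.numeric(t[ix]), numeric(3)))
      } else if (el$name == "face") {
        faces <- t(vapply(toks, function(t) {
          cnt <- as.integer(t[1])
          if (cnt != 3L)
            stop("non-triangular PLY face (", cnt, " vertices) in ", path)
          as.integer(t[2:4])
        }, integer(3)))
      }
    }
  } else {
    for (el in elements) {
      pn <- vapply(el$props, `[[`, "", "name")
      if (el$name == "vertex" && is.null(el$props[[1]]$list_count_type)) {
        types <- vapply(el$props, `[[`, "", "type")
        vals <- matrix(0, el$count, length(el$props))
        for (r in seq_len(el$count))
          for (c in seq_along(el$props))
            vals[r, c] <- .ply_read_scalar(con, types[c])
        ix <- match(c("x", "y", "z"), pn)
        if (any(is.na(ix))) stop("PLY vertex element lacks x/y/z in ", path)
        verts <- vals[, ix, drop = FALSE]
      } else {
        rows <- vector("list", el$count)
        for (r in seq_len(el$count)) {
          vals <- vector("list", length(el$props))
          for (c in seq_along(el$props)) {
            p <- el$props[[c]]
            if (is.null(p$list_count_type)) {
              vals[[c]] <- .ply_read_scalar(con, p$type)
            } else {
              cnt <- .ply_read_scalar(con, p$list_count_type)
              vals[[c]] <- vapply(seq_len(cnt), function(j)
                .ply_read_scalar(con, p$type), numeric(1))
            }
          }
          rows[[r]] <- vals
        }
        if (el$name == "face") {
          iprop <- which(!vapply(el$props, function(p)
            is.null(p$list_count_type), logical(1)))[1]
          faces <- t(vapply(rows, function(v) {
            ii <- v[[iprop]]
            if (length(ii) != 3L)
              stop("non-triangular PLY face (", length(ii),
                   " vertices) in ", path)
            as.integer(ii)
          }, integer(3)))
        }
      }
    }
  }
  if (is.null(verts)) stop("PLY file has no vertex element: ", path)
  if (is.null(faces)) stop("PLY file has no face element: ", path)
  trimesh(verts, faces + 1L,  # PLY stores 0-based indices
          id = tools::file_path_sans_ext(basename(path)))
}

write_ply <- function(mesh, path, binary = FALSE, quality = NULL) {
  n <- nrow(mesh$vertices); m <- nrow(mesh$faces)
  if (!is.null(quality) && length(quality) != n)
    stop("quality must have one value per vertex")
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", n),
           "property double x", "property double y", "property double z",
           if (!is.null(quality)) "property double quality",
           sprintf("element face %d", m),
           "property list uchar int vertex_indices",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  f0 <- mesh$faces - 1L  # PLY is 0-based
  if (binary) {
    vdat <- if (is.null(quality)) t(mesh$vertices)
            else rbind(t(mesh$vertices), quality)
    writeBin(as.vector(vdat), con, size = 8L, endian = "little")
    for (i in seq_len(m)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f0[i, ]), con, size = 4L, endian = "little")
    }
  } else {
    vlines <- if (is.null(quality))
      sprintf("%.17g %.17g %.17g", mesh$vertices[, 1], mesh$vertices[, 2],
              mesh$vertices[, 3])
    else
      sprintf("%.17g %.17g %.17g %.17g", mesh$vertices[, 1], mesh$vertices[, 2],
              mesh$vertices[, 3], quality)
    writeLines(c(vlines, sprintf("3 %d %d %d", f0[, 1], f0[, 2], f0[, 3])),
               con)
  }
  invisible(path)
}

#' Read / write a landmark file
#'
#' Plain-text landmark format: a header line `name x y z`, then one row per
#' landmark (whitespace- or comma-separated) with the landmark name and its
#' 3D coordinates in mm.
#'
#' @param path file path.
#' @param mesh_id mesh identifier to attach (default: file base name).
#' @return [read_landmarks()] returns a `landmark_set`.
#' @export
read_landmarks <- function(path, mesh_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl(",", readLines(path, n = 1L))) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("landmark file needs columns name x y z: ", path)
  if (is.null(mesh_id)) mesh_id <- tools::file_path_sans_ext(basename(path))
  landmark_set(mesh_id, as.matrix(df[, 2:4]), df[, 1])
}

#' @rdname read_landmarks
#' @param lms `landmark_set` to write.
#' @export
write_landmarks <- function(lms, path) {
  df <- data.frame(name = lms$names, x = lms$points[, 1],
                   y = lms$points[, 2], z = lms$points[, 3])
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("name x y z",
               sprintf("%s %.17g %.17g %.17g", df$name, df$x, df$y, df$z)), con)
  invisible(path)
}
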