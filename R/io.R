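#' Read a surface mesh (OBJ / PLY / STL)
#'
#' Reads triangulated meshes in Wavefront OBJ (ASCII), PLY (ASCII or
#' binary_little_endian) or STL (ASCII or binary). OBJ's 1-based and PLY/STL's
#' 0-based face indices are converted to the internal 1-based convention at the
#' boundary; faces with more than three vertices are fan-triangulated with a
#' warning; STL's duplicated per-facet vertices are merged exactly. Coordinates
#' are taken as millimetres.
#'
#' @param path file path.
#' @param format `"obj"`, `"ply"`, `"stl"`, or `NULL` to infer from the
#'   extension.
#' @param tissue tissue tag for the result.
#' @return A `surface_mesh`.
#' @export
read_mesh <- function(path, format = NULL, tissue = "other") {
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
         obj = read_obj(path, tissue),
         ply = read_ply(path, tissue),
         stl = read_stl(path, tissue),
         stop("unsupported mesh format: ", format))
}

#' Write a surface mesh (OBJ / PLY / STL, ASCII)
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @param format `"obj"`, `"ply"`, `"stl"`, or `NULL` to infer from the
#'   extension.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  format <- tolower(format %||% tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$triangles
  lines <- switch(
    format,
    obj = c(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
            sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])),
    ply = c("ply", "format ascii 1.0",
            sprintf("element vertex %d", nrow(v)),
            "property float x", "property float y", "property float z",
            sprintf("element face %d", nrow(f)),
            "property list uchar int vertex_indices", "end_header",
            sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
            sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)),
    stl = {
      a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
      c_ <- v[f[, 3], , drop = FALSE]
      n <- unit_rows(cross_rows(b - a, c_ - a), zero_error = FALSE)
      c("solid mesh",
        as.vector(rbind(
          sprintf("facet normal %.9g %.9g %.9g", n[, 1], n[, 2], n[, 3]),
          "outer loop",
          sprintf("vertex %.9g %.9g %.9g", a[, 1], a[, 2], a[, 3]),
          sprintf("vertex %.9g %.9g %.9g", b[, 1], b[, 2], b[, 3]),
          sprintf("vertex %.9g %.9g %.9g", c_[, 1], c_[, 2], c_[, 3]),
          "endloop", "endfacet")),
        "endsolid mesh")
    },
    stop("unsupported mesh format: ", format))
  writeLines(lines, path)
  invisible(path)
}

fan_triangulate <- function(idx_list) {
  # list of integer vectors (>= 3) -> T x 3 matrix, fanning polygons
  polys <- lengths(idx_list)
  if (any(polys < 3L)) stop("face with fewer than 3 vertices")
  if (any(polys > 3L))
    warning("non-triangular faces fan-triangulated")
  do.call(rbind, lapply(idx_list, function(ix) {
    if (length(ix) == 3L) rbind(ix)
    else cbind(ix[1L], ix[2:(length(ix) - 1L)], ix[3:length(ix)])
  }))
}

read_obj <- function(path, tissue) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl_idx <- grep("^f\\s", lines)
  if (!length(vl)) stop("OBJ parse error: no vertex lines in ", path)
  v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                             function(x) suppressWarnings(as.numeric(x[1:3]))))
  if (anyNA(v)) stop("OBJ parse error: malformed vertex line")
  faces <- lapply(fl_idx, function(i) {
    toks <- strsplit(trimws(sub("^f", "", lines[i])), "\\s+")[[1]]
    ix <- suppressWarnings(as.integer(sub("/.*$", "", toks)))
    if (anyNA(ix)) stop("OBJ parse error at line ", i, ": malformed face")
    if (any(ix < 0)) ix <- ifelse(ix < 0, nrow(v) + 1L + ix, ix)
    ix
  })
  tri <- if (length(faces)) fan_triangulate(faces) else matrix(integer(), 0L, 3L)
  surface_mesh(v, tri, tissue = tissue)
}

read_ply <- function(path, tissue) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stop("PLY parse error: unterminated header")
    header <- c(header, ln)
    if (ln == "end_header") break
  }
  fmt <- sub("^format\\s+(\\S+).*", "\\1", grep("^format", header, value = TRUE)[1])
  nv <- as.integer(sub(".*vertex\\s+(\\d+).*", "\\1",
                       grep("^element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub(".*face\\s+(\\d+).*", "\\1",
                       grep("^element face", header, value = TRUE)[1]))
  # vertex property layout
  vstart <- grep("^element vertex", header)
  fstart <- grep("^element face", header)
  vprops <- grep("^property", header[(vstart + 1):(fstart - 1)], value = TRUE)
  ptypes <- sub("^property\\s+(\\S+)\\s+\\S+$", "\\1", vprops)
  pnames <- sub("^property\\s+\\S+\\s+(\\S+)$", "\\1", vprops)
  if (fmt == "ascii") {
    rows <- readLines(con, n = nv)
    vm <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
    v <- vm[, match(c("x", "y", "z"), pnames), drop = FALSE]
    frows <- readLines(con, n = nf)
    faces <- lapply(strsplit(trimws(frows), "\\s+"), function(x) {
      n <- as.integer(x[1])
      as.integer(x[2:(1 + n)]) + 1L
    })
  } else if (fmt == "binary_little_endian") {
    sizes <- c(float = 4L, float32 = 4L, double = 8L, float64 = 8L,
               int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
               short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
               char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L)
    vm <- matrix(NA_real_, nv, length(vprops))
    for (i in seq_len(nv)) for (j in seq_along(vprops)) {
      sz <- sizes[[ptypes[j]]]
      vm[i, j] <- readBin(con, if (ptypes[j] %in% c("float", "float32", "double",
                                                    "float64")) "numeric" else "integer",
                          1L, size = sz, endian = "little")
    }
    v <- vm[, match(c("x", "y", "z"), pnames), drop = FALSE]
    fprop <- grep("^property list", header[(fstart + 1):length(header)], value = TRUE)[1]
    toks <- strsplit(fprop, "\\s+")[[1]] # property list <ctype> <itype> name
    csz <- sizes[[toks[3]]]; isz <- sizes[[toks[4]]]
    faces <- vector("list", nf)
    for (i in seq_len(nf)) {
      n <- readBin(con, "integer", 1L, size = csz, endian = "little", signed = csz > 1)
      faces[[i]] <- readBin(con, "integer", n, size = isz, endian = "little") + 1L
    }
  } else stop("unsupported PLY format: ", fmt)
  if (anyNA(v)) stop("PLY parse error: missing x/y/z vertex properties")
  tri <- if (nf > 0) fan_triangulate(faces) else matrix(integer(), 0L, 3L)
  surface_mesh(v, tri, tissue = tissue)
}

read_stl <- function(path, tissue) {
  # binary STLs match the exact size formula 84 + 50 * n_facets; ASCII cannot
  sz <- file.size(path)
  is_binary <- FALSE
  if (!is.na(sz) && sz >= 84) {
    hdr <- readBin(path, "raw", 84L)
    nr0 <- readBin(hdr[81:84], "integer", 1L, size = 4L, endian = "little")
    is_binary <- sz == 84 + 50 * nr0
  }
  if (!is_binary) {
    lines <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vlines) %% 3L != 0L) stop("STL parse error: vertex count not a multiple of 3")
    vm <- do.call(rbind, lapply(strsplit(trimws(sub("\\s*vertex", "", vlines)), "\\s+"),
                                function(x) as.numeric(x[1:3])))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", 80L))
    nr <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    vm <- matrix(NA_real_, 3L * nr, 3L)
    for (i in seq_len(nr)) {
      rec <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
      vm[3L * i - 2:0, ] <- matrix(rec[4:12], 3L, 3L, byrow = TRUE)
      invisible(readBin(con, "raw", 2L))
    }
  }
  key <- paste(vm[, 1], vm[, 2], vm[, 3])
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  v <- vm[uk, , drop = FALSE]
  tri <- matrix(vid, ncol = 3L, byrow = TRUE)
  surface_mesh(v, tri, tissue = tissue)
}

#' Read labelled 3D points (CSV)
#'
#' Reads a `label,x,y,z` table in mm. The reserved labels NAS, LPA and RPA are
#' extracted into a `fiducials` object; the remaining rows are returned as
#' points.
#'
#' @param path CSV path with header `label,x,y,z`.
#' @param require_fiducials error when any of NAS/LPA/RPA is missing
#'   (default TRUE).
#' @return A list: `points` (`n x 3`), `labels`, `fiducials` (`NULL` when
#'   absent and not required).
#' @export
read_points <- function(path, require_fiducials = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(df))) stop("CSV must have columns label,x,y,z")
  lab <- toupper(trimws(df$label))
  fid_rows <- match(c("NAS", "LPA", "RPA"), lab)
  fid <- NULL
  if (!anyNA(fid_rows)) {
    fid <- fiducials(as.numeric(df[fid_rows[1], c("x", "y", "z")]),
                     as.numeric(df[fid_rows[2], c("x", "y", "z")]),
                     as.numeric(df[fid_rows[3], c("x", "y", "z")]))
  } else if (require_fiducials) {
    stop("missing fiducial label(s): ",
         paste(c("NAS", "LPA", "RPA")[is.na(fid_rows)], collapse = ", "))
  }
  keep <- !(lab %in% c("NAS", "LPA", "RPA"))
  list(points = as.matrix(df[keep, c("x", "y", "z")]),
       labels = df$label[keep], fiducials = fid)
}

#' Write labelled 3D points (CSV)
#'
#' @param points `n x 3` matrix (mm).
#' @param path output CSV path.
#' @param labels optional labels (defaults `P1..Pn`).
#' @param fid optional `fiducials` prepended with reserved labels.
#' @return `path`, invisibly.
#' @export
write_points <- function(points, path, labels = NULL, fid = NULL) {
  points <- as_point_matrix(points)
  if (is.null(labels)) labels <- paste0("P", seq_len(nrow(points)))
  df <- data.frame(label = labels, x = points[, 1], y = points[, 2],
                   z = points[, 3])
  if (!is.null(fid)) {
    fm <- fiducial_matrix(fid)
    df <- rbind(data.frame(label = c("NAS", "LPA", "RPA"),
                           x = fm[, 1], y = fm[, 2], z = fm[, 3]), df)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

encode_doubles <- function(x) jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8L, endian = "little"))
decode_doubles <- function(s) readBin(jsonlite::base64_dec(s), "numeric",
                                      n = .Machine$integer.max %/% 8L,
                                      size = 8L, endian = "little")

md5_of_raw <- function(r) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(r, tf)
  unname(tools::md5sum(tf))
}

#' Save / load a shape-model bundle
#'
#' Serializes a `shape_model` to a single JSON file: versioned metadata (V,
#' tissue order, normalization, training size), base64-encoded little-endian
#' double arrays (mean, scale, components, singular values, reference head),
#' and an md5 checksum over the array bytes. `load_bundle()` refuses to load
#' when the checksum, array shapes or component orthonormality fail.
#'
#' @param model a `shape_model`.
#' @param path output path (conventionally `.json`).
#' @return `save_bundle()`: `path` invisibly; `load_bundle()`: a `shape_model`.
#' @export
save_bundle <- function(model, path) {
  stopifnot(inherits(model, "shape_model"))
  arrays <- list(mean = as.numeric(model$mean),
                 scale = as.numeric(model$scale),
                 components = as.numeric(model$components),
                 singular_values = as.numeric(model$singular_values),
                 reference = as.numeric(flatten_head(model$reference)))
  enc <- lapply(arrays, encode_doubles)
  checksum <- md5_of_raw(jsonlite::base64_dec(paste0(unlist(enc), collapse = "")))
  obj <- list(
    format = "pcawarp-shape-model", version = 1L,
    metadata = list(v_count = model$v_count, tissue_order = model$tissue_order,
                    normalization = model$normalization, n_train = model$n_train,
                    n_comp = nrow(model$components), d = length(model$mean),
                    coord_system = model$reference$coord_system,
                    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    reference_triangles = as.integer(model$reference$shells$scalp$triangles),
    arrays = enc, checksum = checksum)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "pcawarp-shape-model"))
    stop("not a shape-model bundle")
  checksum <- md5_of_raw(jsonlite::base64_dec(paste0(unlist(obj$arrays), collapse = "")))
  if (!identical(checksum, obj$checksum)) stop("bundle checksum mismatch")
  md <- obj$metadata
  D <- md$d; n_comp <- md$n_comp
  mean <- decode_doubles(obj$arrays$mean)
  scale <- decode_doubles(obj$arrays$scale)
  comp <- matrix(decode_doubles(obj$arrays$components), n_comp, D)
  sv <- decode_doubles(obj$arrays$singular_values)
  if (length(mean) != D || length(scale) != D || length(sv) != n_comp)
    stop("bundle array shape mismatch")
  gram <- tcrossprod(comp)
  if (max(abs(gram - diag(n_comp))) > 1e-8)
    stop("bundle components are not orthonormal")
  v <- md$v_count
  tri <- matrix(as.integer(obj$reference_triangles), ncol = 3L)
  ref_sv <- decode_doubles(obj$arrays$reference)
  ref_proto <- list(shells = setNames(lapply(tissue_order, function(nm)
    surface_mesh(matrix(0, v, 3L) + 1, tri, tissue = nm)), tissue_order),
    coord_system = md$coord_system)
  class(ref_proto) <- "head_model"
  reference <- unflatten_head(ref_sv, ref_proto)
  structure(list(mean = mean, scale = scale, components = comp,
                 singular_values = sv, v_count = v,
                 tissue_order = md$tissue_order, n_train = md$n_train,
                 normalization = md$normalization, reference = reference),
            class = "shape_model")
}
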