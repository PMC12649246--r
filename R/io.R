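#' Read and write image volumes
#'
#' Supported formats, chosen by extension: MetaImage (`.mha`, local-machine
#' byte order, uncompressed `MET_DOUBLE`/`MET_FLOAT`/`MET_SHORT` element
#' types) and NIfTI (`.nii`, `.nii.gz`, via the RNifti package). Round trips
#' preserve grid values, spacing and origin.
#'
#' @param path file path with a recognized extension.
#' @param volume an [image_volume()].
#' @return `read_volume` returns an [image_volume()]; `write_volume` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  ext <- volume_format(path)
  if (ext == "mha") return(read_mha(path))
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  spacing <- hdr$pixdim[2:4]
  origin <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  image_volume(array(as.numeric(img), dim = dim(img)[1:3]), spacing, origin)
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  ext <- volume_format(path)
  if (ext == "mha") {
    write_mha(volume, path)
  } else {
    d <- dim(volume$data)
    hdr <- RNifti::niftiHeader(list(
      dim = c(3L, d, 1L, 1L, 1L, 1L),
      pixdim = c(-1, volume$spacing, 0, 0, 0, 0),
      qoffset_x = volume$origin[1], qoffset_y = volume$origin[2],
      qoffset_z = volume$origin[3], qform_code = 1L,
      datatype = 64L, bitpix = 64L))
    img <- RNifti::asNifti(volume$data, reference = hdr)
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

volume_format <- function(path) {
  if (grepl("\\.mha$", path, ignore.case = TRUE)) return("mha")
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nii")
  stop(sprintf("unknown volume format: '%s' (use .mha, .nii or .nii.gz)",
               basename(path)), call. = FALSE)
}

write_mha <- function(volume, path) {
  d <- dim(volume$data)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    sprintf("BinaryDataByteOrderMSB = %s",
            if (.Platform$endian == "big") "True" else "False"),
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %.17g %.17g %.17g", volume$origin[1], volume$origin[2],
            volume$origin[3]),
    "CenterOfRotation = 0 0 0",
    "AnatomicalOrientation = RAI",
    sprintf("ElementSpacing = %.17g %.17g %.17g", volume$spacing[1],
            volume$spacing[2], volume$spacing[3]),
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    "ElementType = MET_DOUBLE",
    "ElementDataFile = LOCAL")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.numeric(volume$data), con, size = 8,
           endian = .Platform$endian)
  invisible(path)
}

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("corrupt MetaImage header: no data section",
                                call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("corrupt MetaImage header line: ", line,
                              call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    fields[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(fields[["ElementDataFile"]], "LOCAL"))
    stop("only LOCAL MetaImage data is supported", call. = FALSE)
  if (isTRUE(fields[["CompressedData"]] == "True"))
    stop("compressed MetaImage data is not supported", call. = FALSE)
  d <- as.integer(strsplit(fields[["DimSize"]], "\\s+")[[1]])
  spacing <- as.numeric(strsplit(fields[["ElementSpacing"]], "\\s+")[[1]])
  origin <- if (!is.null(fields[["Offset"]]))
    as.numeric(strsplit(fields[["Offset"]], "\\s+")[[1]]) else c(0, 0, 0)
  msb <- identical(fields[["BinaryDataByteOrderMSB"]], "True")
  endian <- if (msb) "big" else "little"
  n <- prod(d)
  type <- fields[["ElementType"]]
  vals <- switch(type,
    MET_DOUBLE = readBin(con, "double", n = n, size = 8, endian = endian),
    MET_FLOAT = readBin(con, "double", n = n, size = 4, endian = endian),
    MET_SHORT = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                        endian = endian),
    stop("unsupported MetaImage element type: ", type, call. = FALSE))
  image_volume(array(as.numeric(vals), dim = d), spacing, origin)
}

#' Read and write triangle meshes
#'
#' Supported formats, chosen by extension: STL (binary by default, ASCII
#' readable and writable with `ascii = TRUE`) and PLY (ASCII, with an
#' optional per-vertex scalar attribute named `quality`, used to carry
#' distance-map values). STL stores no connectivity, so reading an STL
#' rebuilds shared vertices by exact coordinate matching.
#'
#' @param path file path with extension `.stl` or `.ply`.
#' @param mesh a [triangle_mesh()].
#' @param ascii write ASCII STL instead of binary.
#' @param scalar optional numeric per-vertex attribute (PLY only).
#' @return `read_mesh` returns a [triangle_mesh()] (a PLY scalar, if
#'   present, is attached as attribute `scalar`); `write_mesh` returns
#'   `path` invisibly.
#' @export
read_mesh <- function(path) {
  ext <- mesh_format(path)
  if (ext == "stl") read_stl(path) else read_ply(path)
}

#' @rdname read_mesh
#' @export
write_mesh <- function(mesh, path, ascii = FALSE, scalar = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  ext <- mesh_format(path)
  if (ext == "stl") {
    if (ascii) write_stl_ascii(mesh, path) else write_stl_binary(mesh, path)
  } else {
    write_ply(mesh, path, scalar = scalar)
  }
  invisible(path)
}

mesh_format <- function(path) {
  if (grepl("\\.stl$", path, ignore.case = TRUE)) return("stl")
  if (grepl("\\.ply$", path, ignore.case = TRUE)) return("ply")
  stop(sprintf("unknown mesh format: '%s' (use .stl or .ply)",
               basename(path)), call. = FALSE)
}

stl_triangle_soup <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  ln <- sqrt(rowSums(n^2))
  n <- n / ifelse(ln > 0, ln, 1)
  list(a = a, b = b, c = c_, n = n)
}

write_stl_binary <- function(mesh, path) {
  s <- stl_triangle_soup(mesh)
  nf <- nrow(mesh$faces)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC("binary STL written by carposeg", width = -80))
  writeBin(header[1:80], con)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  # interleave: normal, a, b, c, attribute byte count
  dat <- rbind(t(s$n), t(s$a), t(s$b), t(s$c))   # 12 x nf
  for (i in seq_len(nf)) {
    writeBin(as.numeric(dat[, i]), con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  invisible(path)
}

write_stl_ascii <- function(mesh, path) {
  s <- stl_triangle_soup(mesh)
  nf <- nrow(mesh$faces)
  lines <- character(7 * nf + 2)
  lines[1] <- "solid carposeg"
  k <- 2
  fmt <- function(p) sprintf("%.9g %.9g %.9g", p[1], p[2], p[3])
  for (i in seq_len(nf)) {
    lines[k] <- paste("facet normal", fmt(s$n[i, ])); k <- k + 1
    lines[k] <- "  outer loop"; k <- k + 1
    lines[k] <- paste("    vertex", fmt(s$a[i, ])); k <- k + 1
    lines[k] <- paste("    vertex", fmt(s$b[i, ])); k <- k + 1
    lines[k] <- paste("    vertex", fmt(s$c[i, ])); k <- k + 1
    lines[k] <- "  endloop"; k <- k + 1
    lines[k] <- "endfacet"; k <- k + 1
  }
  lines[k] <- "endsolid carposeg"
  writeLines(lines, path)
  invisible(path)
}

soup_to_mesh <- function(tri) {
  # tri: (3*nf) x 3 matrix of triangle corners in face order
  key <- paste(tri[, 1], tri[, 2], tri[, 3], sep = "_")
  uid <- match(key, unique(key))
  verts <- tri[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  triangle_mesh(verts, faces)
}

read_stl <- function(path) {
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", n = 80)
  nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  # decide binary vs ascii: expected binary size
  sz <- file.info(path)$size
  close(con)
  if (length(nf) == 1 && !is.na(nf) && sz == 84 + 50 * as.numeric(nf)) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 84)
    tri <- matrix(0, 3 * nf, 3)
    for (i in seq_len(nf)) {
      vals <- readBin(con, "double", n = 12, size = 4, endian = "little")
      readBin(con, "raw", n = 2)
      tri[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
    }
    return(soup_to_mesh(tri))
  }
  # ascii
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("corrupt STL file: vertex count not a multiple of 3", call. = FALSE)
  parts <- strsplit(trimws(vl), "\\s+")
  tri <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  soup_to_mesh(tri)
}

write_ply <- function(mesh, path, scalar = NULL) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  if (!is.null(scalar) && length(scalar) != nv)
    stop("scalar must have one value per vertex", call. = FALSE)
  hdr <- c("ply", "format ascii 1.0", "comment written by carposeg",
           sprintf("element vertex %d", nv),
           "property double x", "property double y", "property double z")
  if (!is.null(scalar)) hdr <- c(hdr, "property double quality")
  hdr <- c(hdr, sprintf("element face %d", nf),
           "property list uchar int vertex_indices", "end_header")
  v <- mesh$vertices
  vlines <- if (is.null(scalar))
    sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3])
  else
    sprintf("%.17g %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3], scalar)
  f <- mesh$faces - 1L
  flines <- sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3])
  writeLines(c(hdr, vlines, flines), path)
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || lines[1] != "ply")
    stop("corrupt PLY file: missing magic line", call. = FALSE)
  if (!grepl("ascii", lines[2]))
    stop("only ASCII PLY is supported", call. = FALSE)
  endh <- match("end_header", lines)
  if (is.na(endh)) stop("corrupt PLY file: no end_header", call. = FALSE)
  hdr <- lines[seq_len(endh)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", hdr,
                                                   value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", hdr,
                                                 value = TRUE)))
  vprops <- c()
  in_vertex <- FALSE
  for (l in hdr) {
    if (grepl("^element vertex", l)) { in_vertex <- TRUE; next }
    if (grepl("^element ", l)) in_vertex <- FALSE
    if (in_vertex && grepl("^property ", l))
      vprops <- c(vprops, utils::tail(strsplit(l, " ")[[1]], 1))
  }
  vl <- lines[(endh + 1):(endh + nv)]
  vmat <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(p) as.numeric(p[seq_along(vprops)]),
                   numeric(length(vprops))))
  fl <- lines[(endh + nv + 1):(endh + nv + nf)]
  fmat <- t(vapply(strsplit(trimws(fl), "\\s+"),
                   function(p) as.integer(p[2:4]), integer(3))) + 1L
  mesh <- triangle_mesh(vmat[, match(c("x", "y", "z"), vprops), drop = FALSE],
                        fmat)
  if ("quality" %in% vprops)
    attr(mesh, "scalar") <- vmat[, match("quality", vprops)]
  mesh
}
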