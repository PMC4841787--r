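#' Read a NIfTI volume
#'
#' @param path path to a .nii or .nii.gz file.
#' @return a [volume_image()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), class = NULL)
  volume_image(array(as.numeric(img), dim(img)[1:3]), unclass(aff))
}

#' Read a NIfTI binary mask
#'
#' Values are binarised at 0.5 (segmentation masks are expected to be 0/1
#' already).
#'
#' @param path path to a .nii or .nii.gz file.
#' @return a [binary_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  binary_mask(array(v$data > 0.5, dim(v$data)), v$affine)
}

#' Write a volume or mask as NIfTI
#'
#' @param vol a [volume_image()] or [binary_mask()].
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  dat <- vol$data
  if (is.logical(dat)) dat <- array(as.integer(dat), dim(dat))
  img <- RNifti::asNifti(dat)
  img <- RNifti::`pixdim<-`(img, vol$voxel_size)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a whitespace-delimited 4x4 affine matrix
#'
#' Accepts a plain row-major 4x4 text matrix; the FLIRT .mat layout is the
#' same dialect (world-space rigid transforms are expected; FLIRT matrices
#' defined over scaled image coordinates must be converted by the caller).
#'
#' @param path text file with 4 rows of 4 numbers.
#' @return a [rigid_transform()].
#' @export
read_transform <- function(path) {
  m <- as.matrix(read.table(path))
  stopifnot(nrow(m) == 4, ncol(m) == 4)
  affine_to_rigid(m)
}

#' Write a rigid transform as a 4x4 text matrix
#' @param xfm a [rigid_transform()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(xfm, path) {
  m <- rbind(cbind(xfm$rotation, xfm$translation), c(0, 0, 0, 1))
  write.table(format(m, digits = 17), path, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# validate that a 4x4 matrix is rigid and convert
affine_to_rigid <- function(m) {
  R <- m[1:3, 1:3]
  s <- det(R)
  if (abs(abs(s) - 1) > 1e-4)
    stop("matrix is not rigid (|det| = ", signif(abs(s), 6), ")")
  if (max(abs(crossprod(R) - diag(3))) > 1e-4)
    stop("matrix is not rigid (rotation block not orthonormal)")
  if (s < 0) stop("matrix includes a reflection; expected a proper rotation")
  # re-orthonormalise against rounding in text round trips
  sv <- svd(R)
  rigid_transform(sv$u %*% t(sv$v), m[1:3, 4])
}

#' Write a triangle mesh as ASCII PLY
#'
#' Optional per-vertex scalar properties (e.g. deformity, regression maps)
#' are written as extra float properties.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param scalars optional named list/data.frame of per-vertex numeric
#'   vectors.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, scalars = NULL) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  props <- c("x", "y", "z")
  dat <- mesh$vertices
  if (!is.null(scalars)) {
    scalars <- as.data.frame(scalars)
    stopifnot(nrow(scalars) == nv)
    props <- c(props, names(scalars))
    dat <- cbind(dat, as.matrix(scalars))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nv),
               sprintf("property float %s", props),
               sprintf("element face %d", nf),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(format(dat, digits = 9, trim = TRUE, scientific = FALSE),
                   1, paste, collapse = " "), con)
  writeLines(paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY triangle mesh
#'
#' @param path input path.
#' @return a [triangle_mesh()]; extra vertex properties are attached as the
#'   `scalars` attribute (data.frame).
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply" || !grepl("ascii", lines[2]))
    stop("only ASCII PLY is supported")
  hdr_end <- match("end_header", lines)
  hdr <- lines[seq_len(hdr_end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr,
                                                   value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr,
                                                 value = TRUE)))
  vstart <- match("element vertex", substr(hdr, 1, 14))
  fstart <- match("element face", substr(hdr, 1, 12))
  vprops <- sub(".* ", "", hdr[(vstart + 1):(fstart - 1)])
  body <- lines[(hdr_end + 1):length(lines)]
  vdat <- matrix(scan(text = body[seq_len(nv)], quiet = TRUE),
                 nrow = nv, byrow = TRUE)
  colnames(vdat) <- vprops
  fdat <- matrix(scan(text = body[nv + seq_len(nf)], quiet = TRUE),
                 nrow = nf, byrow = TRUE)
  mesh <- triangle_mesh(vdat[, c("x", "y", "z"), drop = FALSE],
                        fdat[, 2:4, drop = FALSE] + 1L)
  extra <- setdiff(vprops, c("x", "y", "z"))
  if (length(extra))
    attr(mesh, "scalars") <- as.data.frame(vdat[, extra, drop = FALSE])
  mesh
}

#' Write a triangle mesh as Wavefront OBJ
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("v", mesh$vertices[, 1], mesh$vertices[, 2],
                   mesh$vertices[, 3]), con)
  writeLines(paste("f", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]),
             con)
  invisible(path)
}

#' Read a Wavefront OBJ triangle mesh
#' @param path input path.
#' @return a [triangle_mesh()].
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  V <- matrix(scan(text = sub("^v ", "", vl), quiet = TRUE), ncol = 3,
              byrow = TRUE)
  fidx <- lapply(strsplit(sub("^f ", "", fl), "\\s+"), function(tok)
    as.integer(sub("/.*", "", tok)))
  Fm <- do.call(rbind, fidx)
  if (ncol(Fm) != 3) stop("only triangle faces are supported")
  triangle_mesh(V, Fm)
}
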