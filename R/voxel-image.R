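#' Create a voxel image
#'
#' A `voxel_image` is the basic carrier for 3-D scalar data throughout the
#' pipeline: grayscale CT-like volumes, binary segmentations and label
#' fields.  Voxels are isotropic cubes; the physical centre of voxel
#' `(i, j, k)` (1-based) is `origin + (c(i, j, k) - 0.5) * voxel_size`.
#'
#' @param values 3-D numeric (or logical/integer) array.
#' @param voxel_size isotropic voxel edge length in mm (> 0).
#' @param origin physical coordinates (mm) of the corner of voxel (1,1,1);
#'   length-3 numeric.
#' @return object of class `voxel_image`.
#' @export
voxel_image <- function(values, voxel_size, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("`values` must be a 3-D array")
  if (any(dim(values) < 1L)) stop("image grid is empty")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (mm)")
  if (length(origin) != 3L) stop("`origin` must be length 3")
  structure(
    list(values = values, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin)),
    class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_image> %d x %d x %d voxels, %.4g mm/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  value range: [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.voxel_image <- function(x) dim(x$values)

is_voxel_image <- function(x) inherits(x, "voxel_image")

#' Physical centre coordinates of voxels
#'
#' @param img a `voxel_image`.
#' @param idx integer vector of linear voxel indices (column-major); default
#'   all voxels.
#' @return n x 3 matrix of coordinates in mm.
#' @export
voxel_centres <- function(img, idx = NULL) {
  d <- dim(img$values)
  if (is.null(idx)) idx <- seq_len(prod(d))
  ijk <- arrayInd(idx, d)
  sweep(ijk - 0.5, 2, c(1, 1, 1), "*") * img$voxel_size +
    matrix(img$origin, nrow(ijk), 3, byrow = TRUE)
}

#' Mirror a specimen across the frontal plane
#'
#' Left specimens are mirrored into a right-femur convention before
#' analysis by reversing the anterior-posterior (second) image axis.
#'
#' @param img a `voxel_image`.
#' @return mirrored `voxel_image`.
#' @export
mirror_frontal <- function(img) {
  stopifnot(is_voxel_image(img))
  img$values <- img$values[, rev(seq_len(dim(img$values)[2])), , drop = FALSE]
  img
}

#' Write / read a volume as NIfTI
#'
#' Thin wrappers around RNifti preserving the isotropic voxel size.
#'
#' @param img a `voxel_image`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_nifti_image` returns a `voxel_image`.
#' @export
write_nifti_image <- function(img, path) {
  stopifnot(is_voxel_image(img))
  nif <- RNifti::asNifti(img$values * 1)
  RNifti::pixdim(nif) <- rep(img$voxel_size, 3)
  RNifti::writeNifti(nif, path)
  invisible(path)
}

#' @rdname write_nifti_image
#' @export
read_nifti_image <- function(path) {
  nif <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(nif)[1]
  voxel_image(array(as.numeric(nif), dim = dim(nif)), voxel_size = vs)
}

#' Write / read a volume in MetaImage format
#'
#' Minimal MetaImage (.mhd + .raw) support: plain-text header plus a raw
#' little-endian block, the de-facto exchange format of image-based FE
#' tool chains.
#'
#' @param img a `voxel_image`.
#' @param path path to the `.mhd` header; the `.raw` sits alongside.
#' @param type element type, `"float64"` or `"uint8"`.
#' @return `read_metaimage` returns a `voxel_image`.
#' @export
write_metaimage <- function(img, path, type = c("float64", "uint8")) {
  stopifnot(is_voxel_image(img))
  type <- match.arg(type)
  raw_path <- sub("\\.mhd$", ".raw", path)
  if (identical(raw_path, path)) raw_path <- paste0(path, ".raw")
  met <- c("float64" = "MET_DOUBLE", "uint8" = "MET_UCHAR")[[type]]
  d <- dim(img$values)
  hdr <- c(
    "ObjectType = Image", "NDims = 3", "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste("DimSize =", paste(d, collapse = " ")),
    paste("ElementSpacing =", paste(rep(img$voxel_size, 3), collapse = " ")),
    paste("Offset =", paste(img$origin, collapse = " ")),
    paste("ElementType =", met),
    paste("ElementDataFile =", basename(raw_path)))
  writeLines(hdr, path)
  con <- file(raw_path, "wb")
  on.exit(close(con))
  if (type == "uint8") {
    writeBin(as.raw(as.integer(img$values)), con)
  } else {
    writeBin(as.numeric(img$values), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' @rdname write_metaimage
#' @export
read_metaimage <- function(path) {
  hdr <- readLines(path)
  get <- function(key) {
    line <- grep(paste0("^", key, " *="), hdr, value = TRUE)
    if (!length(line)) stop("MetaImage header misses field: ", key)
    trimws(sub("^[^=]*=", "", line[1]))
  }
  d <- as.integer(strsplit(get("DimSize"), " +")[[1]])
  sp <- as.numeric(strsplit(get("ElementSpacing"), " +")[[1]])
  org <- tryCatch(as.numeric(strsplit(get("Offset"), " +")[[1]]),
                  error = function(e) c(0, 0, 0))
  typ <- get("ElementType")
  raw_path <- file.path(dirname(path), get("ElementDataFile"))
  n <- prod(d)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- switch(typ,
    MET_DOUBLE = readBin(con, "numeric", n, size = 8, endian = "little"),
    MET_UCHAR = as.numeric(readBin(con, "raw", n)),
    stop("unsupported MetaImage element type: ", typ))
  voxel_image(array(vals, dim = d), voxel_size = sp[1], origin = org)
}

#' Largest connected foreground component
#'
#' @param mask logical 3-D array.
#' @param connectivity 6 (face) or 26 (face/edge/vertex) neighbourhood;
#'   26 matches the node coupling of voxel finite elements.
#' @return logical array keeping only the largest component.
#' @export
largest_component <- function(mask, connectivity = 6) {
  stopifnot(length(dim(mask)) == 3L)
  lab <- cpp_label_components(as.logical(mask), as.integer(dim(mask)),
                              as.integer(connectivity))
  if (max(lab) == 0L) return(array(FALSE, dim(mask)))
  counts <- tabulate(lab[lab > 0L])
  keep <- which.max(counts)
  array(lab == keep, dim(mask))
}
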