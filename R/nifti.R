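## Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
##
## No NIfTI-capable R package is assumed; this reader/writer covers what
## the pipeline needs: 3-D (or 4-D) volumes, common scalar datatypes,
## little-endian, sform RAS+ affine built from the voxel size.  It is not
## a general NIfTI library (no qform quaternions, no extensions).

NIFTI_DT <- list(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L,
                 float64 = 64L)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a volume as NIfTI-1
#'
#' @param vol 3-D or 4-D numeric array.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param voxel_size Voxel dimensions in mm (length 3).
#' @param datatype `"float32"` (default), `"float64"`, `"int32"`,
#'   `"int16"` or `"uint8"`.  Integer types are written rounded.
#' @param description Up to 80 bytes stored in the header `descrip` field.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, voxel_size = c(1, 1, 1),
                        datatype = "float32", description = "aslbs") {
  if (!is.array(vol) || !(length(dim(vol)) %in% c(3L, 4L))) {
    abort_data("`vol` must be a 3-D or 4-D array")
  }
  dt <- NIFTI_DT[[datatype]]
  if (is.null(dt)) abort_param(sprintf("unsupported datatype '%s'", datatype))
  bitpix <- c(`2` = 8L, `4` = 16L, `8` = 32L, `16` = 32L, `64` = 64L)[[as.character(dt)]]
  nd <- length(dim(vol))
  dims <- as.integer(c(nd, dim(vol), rep(1L, 7 - nd)))
  pd <- c(0, voxel_size, rep(1, 4))[1:8]

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wi <- function(x, size = 4L) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wc <- function(s, len) {
    raw <- charToRaw(s)
    writeBin(c(raw[seq_len(min(length(raw), len))],
               rep(as.raw(0), max(0, len - length(raw)))), con)
  }
  wi(348)                       # sizeof_hdr
  writeBin(rep(as.raw(0), 36), con)  # data_type, db_name, extents, session_error, regular, dim_info
  wi(dims, size = 2L)           # dim[8]
  wf(c(0, 0, 0))                # intent_p1..3
  wi(0, size = 2L)              # intent_code
  wi(dt, size = 2L)             # datatype
  wi(bitpix, size = 2L)         # bitpix
  wi(0, size = 2L)              # slice_start
  wf(pd)                        # pixdim[8]
  wf(352)                       # vox_offset
  wf(1); wf(0)                  # scl_slope, scl_inter
  wi(0, size = 2L)              # slice_end
  writeBin(as.raw(c(0, 0)), con)  # slice_code, xyzt_units
  wf(c(0, 0, 0))                # cal_max, cal_min, slice_duration
  wf(0)                         # toffset
  wi(c(0, 0))                   # glmax, glmin
  wc(description, 80)           # descrip
  wc("", 24)                    # aux_file
  wi(0, size = 2L)              # qform_code
  wi(1, size = 2L)              # sform_code
  wf(c(0, 0, 0, 0, 0, 0))      # quatern b,c,d + qoffset x,y,z
  wf(c(voxel_size[1], 0, 0, 0)) # srow_x
  wf(c(0, voxel_size[2], 0, 0)) # srow_y
  wf(c(0, 0, voxel_size[3], 0)) # srow_z
  wc("", 16)                    # intent_name
  wc("n+1", 4)                  # magic
  writeBin(rep(as.raw(0), 4), con)  # extension flag

  data <- as.vector(vol)
  if (datatype %in% c("uint8", "int16", "int32")) {
    writeBin(as.integer(round(data)), con, size = bitpix / 8, endian = "little")
  } else {
    writeBin(as.double(data), con, size = bitpix / 8, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_nifti()] (or compatible)
#'
#' Supports single-file little-endian NIfTI-1 with datatypes uint8,
#' int16, int32, float32, float64; applies `scl_slope`/`scl_inter` when
#' set.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return List with `data` (array), `voxel_size`, `datatype`,
#'   `description`.
#' @export
read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  ri <- function(n, size = 4L) readBin(con, "integer", n = n, size = size, endian = "little")
  rf <- function(n, size = 4L) readBin(con, "double", n = n, size = size, endian = "little")
  hdr_size <- ri(1)
  if (!identical(hdr_size, 348L)) abort_data("not a little-endian NIfTI-1 file")
  readBin(con, "raw", n = 36)
  dims <- ri(8, size = 2L)
  rf(3)                          # intent_p1..3
  ri(1, size = 2L)               # intent_code
  datatype <- ri(1, size = 2L)
  bitpix <- ri(1, size = 2L)
  ri(1, size = 2L)               # slice_start
  pixdim <- rf(8)
  vox_offset <- rf(1)
  scl_slope <- rf(1); scl_inter <- rf(1)
  ri(1, size = 2L); readBin(con, "raw", n = 2)   # slice_end, slice_code, xyzt_units
  rf(4)                          # cal_max, cal_min, slice_duration, toffset
  ri(2)                          # glmax, glmin
  descrip <- readBin(con, "raw", n = 80)
  readBin(con, "raw", n = 24)    # aux_file
  ri(2, size = 2L)               # qform_code, sform_code
  rf(6); rf(12)                  # quaternion/offsets, srows
  readBin(con, "raw", n = 16)    # intent_name
  magic <- rawToChar(readBin(con, "raw", n = 4)[1:3])
  if (!magic %in% c("n+1", "ni1")) abort_data("missing NIfTI magic")
  readBin(con, "raw", n = max(0, vox_offset - 348))

  nd <- dims[1]
  shape <- dims[2:(1 + nd)]
  n <- prod(shape)
  data <- switch(as.character(datatype),
    `2` = readBin(con, "integer", n = n, size = 1L, signed = FALSE),
    `4` = readBin(con, "integer", n = n, size = 2L, endian = "little"),
    `8` = readBin(con, "integer", n = n, size = 4L, endian = "little"),
    `16` = readBin(con, "double", n = n, size = 4L, endian = "little"),
    `64` = readBin(con, "double", n = n, size = 8L, endian = "little"),
    abort_data(sprintf("unsupported NIfTI datatype code %d", datatype)))
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    data <- data * scl_slope + scl_inter
  }
  dn <- descrip[descrip != as.raw(0)]
  list(data = array(data, dim = shape),
       voxel_size = pixdim[2:4],
       datatype = names(NIFTI_DT)[match(datatype, unlist(NIFTI_DT))],
       description = rawToChar(dn))
}
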