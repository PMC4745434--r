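#' Minimal C3D motion-capture file support
#'
#' Reads and writes the C3D subset relevant to marker kinematics: the POINT
#' section (labels, rate, units, frame range) with floating-point Intel
#' (PC) storage.  Analog channels, integer-scaled data and non-Intel
#' processor formats are out of scope and rejected with explicit errors.
#' Coordinates are converted to millimetres on import according to the
#' POINT:UNITS parameter; samples with negative residuals are marked
#' invalid in the gap mask.
#'
#' @name io_c3d
NULL

.c3d_fail <- function(path, where, msg) {
  stop("malformed C3D file '", path, "' (", where, "): ", msg, call. = FALSE)
}

.rd_u8 <- function(raw, off) as.integer(raw[off])
.rd_i8 <- function(raw, off) {
  v <- as.integer(raw[off]); if (v > 127L) v - 256L else v
}
.rd_i16 <- function(raw, off)
  readBin(raw[off:(off + 1L)], "integer", size = 2L, endian = "little",
          signed = TRUE)
.rd_u16 <- function(raw, off)
  readBin(raw[off:(off + 1L)], "integer", size = 2L, endian = "little",
          signed = FALSE)
.rd_f32 <- function(raw, off, n = 1L)
  readBin(raw[off:(off + 4L * n - 1L)], "numeric", n = n, size = 4L,
          endian = "little")

#' Read a C3D file
#'
#' @param path file path.
#' @return A [marker_trajectory_set()] in millimetres; samples whose stored
#'   residual is negative are flagged invalid.
#' @export
read_c3d <- function(path) {
  if (!file.exists(path)) stop("C3D file does not exist: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 512L)
    .c3d_fail(path, "header", paste0("file is ", length(raw),
                                     " bytes, header needs 512"))
  if (.rd_u8(raw, 2L) != 0x50L)
    .c3d_fail(path, "header byte 2", "magic 0x50 missing; not a C3D file")
  param_block <- .rd_u8(raw, 1L)
  n_points <- .rd_u16(raw, 3L)
  if (n_points == 0L)
    .c3d_fail(path, "header word 2", "file declares zero 3D points")
  first_frame <- .rd_u16(raw, 7L)
  last_frame <- .rd_u16(raw, 9L)
  n_frames <- last_frame - first_frame + 1L
  scale_hdr <- .rd_f32(raw, 13L)
  rate_hdr <- .rd_f32(raw, 21L)

  poff <- (param_block - 1L) * 512L
  if (length(raw) < poff + 4L)
    .c3d_fail(path, "parameter section", paste0("truncated at byte ", poff))
  proc <- .rd_u8(raw, poff + 4L)
  if (proc != 84L)
    .c3d_fail(path, "parameter header",
              paste0("processor type ", proc, "; only Intel (84) supported"))

  groups <- list()   # id -> name
  params <- list()   # "GROUP:PARAM" -> value
  pos <- poff + 5L
  repeat {
    if (pos > length(raw))
      .c3d_fail(path, "parameter records", paste0("truncated at byte ", pos))
    n_name <- .rd_i8(raw, pos)
    if (n_name == 0L) break
    id <- .rd_i8(raw, pos + 1L)
    nm <- rawToChar(raw[(pos + 2L):(pos + 1L + abs(n_name))])
    off_field <- pos + 2L + abs(n_name)
    nxt <- .rd_i16(raw, off_field)
    if (id < 0L) {                         # group record
      groups[[as.character(-id)]] <- toupper(nm)
    } else {                               # parameter record
      p <- off_field + 2L
      dtype <- .rd_i8(raw, p); p <- p + 1L
      ndim <- .rd_u8(raw, p); p <- p + 1L
      dims <- if (ndim > 0L) vapply(seq_len(ndim),
                                    function(d) .rd_u8(raw, p + d - 1L),
                                    integer(1)) else integer(0)
      p <- p + ndim
      count <- prod(c(1L, dims))
      size <- c(`-1` = 1L, `1` = 1L, `2` = 2L, `4` = 4L)[as.character(dtype)]
      if (is.na(size))
        .c3d_fail(path, "parameter records",
                  paste0("unknown data type ", dtype, " at byte ", p))
      nbytes <- count * size
      if (p + nbytes - 1L > length(raw))
        .c3d_fail(path, "parameter records",
                  paste0("data truncated at byte ", p))
      val <- switch(as.character(dtype),
        `-1` = {
          ch <- rawToChar(raw[p:(p + nbytes - 1L)])
          if (length(dims) >= 2L) {
            width <- dims[1]
            substring(ch, seq(1, nbytes, width), seq(width, nbytes, width))
          } else ch
        },
        `1` = vapply(seq_len(count), function(q) .rd_i8(raw, p + q - 1L),
                     integer(1)),
        `2` = vapply(seq_len(count),
                     function(q) .rd_i16(raw, p + 2L * (q - 1L)), integer(1)),
        `4` = .rd_f32(raw, p, count))
      params[[paste0(groups[[as.character(id)]] %||% id, ":", toupper(nm))]] <- val
    }
    if (nxt == 0L) break
    pos <- off_field + nxt
  }

  getp <- function(key, default = NULL) params[[key]] %||% default
  used <- getp("POINT:USED", n_points)[1]
  frames <- getp("POINT:FRAMES", n_frames)[1]
  rate <- getp("POINT:RATE", rate_hdr)[1]
  scale <- getp("POINT:SCALE", scale_hdr)[1]
  data_start <- getp("POINT:DATA_START", .rd_u16(raw, 17L))[1]
  units <- trimws(getp("POINT:UNITS", "mm")[1])
  labels <- trimws(getp("POINT:LABELS", character(0)))
  if (used == 0L)
    .c3d_fail(path, "POINT:USED", "file declares zero markers")
  if (scale >= 0)
    .c3d_fail(path, "POINT:SCALE",
              "integer-scaled point data not supported (scale >= 0)")
  if (length(labels) < used)
    labels <- c(labels, sprintf("M%03d", seq_len(used)))[seq_len(used)]
  labels <- make.unique(labels[seq_len(used)])

  unit_to_mm <- switch(tolower(units), mm = 1, cm = 10, m = 1000,
                       .c3d_fail(path, "POINT:UNITS",
                                 paste0("unknown unit '", units, "'")))
  doff <- (data_start - 1L) * 512L
  need <- doff + 4L * 4L * used * frames
  if (length(raw) < need)
    .c3d_fail(path, "data section",
              paste0("expected ", need, " bytes, file has ", length(raw)))
  vals <- .rd_f32(raw, doff + 1L, 4L * used * frames)
  arr <- array(vals, dim = c(4L, used, frames))
  posl <- vector("list", used); validl <- vector("list", used)
  for (q in seq_len(used)) {
    xyz <- t(arr[1:3, q, , drop = TRUE])
    if (frames == 1L) xyz <- matrix(arr[1:3, q, 1], 1L, 3L)
    resid <- arr[4L, q, ]
    bad <- resid < 0
    xyz[bad, ] <- NA_real_
    posl[[q]] <- xyz * unit_to_mm
    validl[[q]] <- !bad
  }
  names(posl) <- labels; names(validl) <- labels
  marker_trajectory_set(posl, rate, validl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## --- writer ---------------------------------------------------------------

.w_i8 <- function(con, x) writeBin(as.integer(x), con, size = 1L)
.w_i16 <- function(con, x) writeBin(as.integer(x), con, size = 2L,
                                    endian = "little")
.w_f32 <- function(con, x) writeBin(as.numeric(x), con, size = 4L,
                                    endian = "little")
.w_chr <- function(con, x) writeBin(charToRaw(x), con)

.c3d_param_chr <- function(con, gid, name, strings) {
  width <- max(nchar(strings), 4L)
  padded <- formatC(strings, width = width, flag = "-")
  .w_i8(con, nchar(name)); .w_i8(con, gid); .w_chr(con, name)
  body <- 2L + 1L + 1L + 2L + width * length(strings) + 1L
  .w_i16(con, body); .w_i8(con, -1L); .w_i8(con, 2L)
  .w_i8(con, width); .w_i8(con, length(strings))
  .w_chr(con, paste(padded, collapse = "")); .w_i8(con, 0L)
}

.c3d_param_num <- function(con, gid, name, value, type = c("int16", "float")) {
  type <- match.arg(type)
  .w_i8(con, nchar(name)); .w_i8(con, gid); .w_chr(con, name)
  size <- if (type == "int16") 2L else 4L
  body <- 2L + 1L + 1L + size + 1L
  .w_i16(con, body)
  .w_i8(con, if (type == "int16") 2L else 4L)
  .w_i8(con, 0L)
  if (type == "int16") .w_i16(con, value) else .w_f32(con, value)
  .w_i8(con, 0L)
}

#' Write a C3D file
#'
#' Floating-point Intel storage, POINT section only.  Invalid samples are
#' written with residual -1 (the C3D convention for missing data) and zero
#' coordinates.
#'
#' @param trajectories a [marker_trajectory_set()] (millimetres).
#' @param path output file path.
#' @param units coordinate units to declare and write (`"mm"`, `"cm"` or
#'   `"m"`); coordinates are divided accordingly on output.
#' @export
write_c3d <- function(trajectories, path, units = "mm") {
  x <- trajectories
  mm_per_unit <- switch(units, mm = 1, cm = 10, m = 1000,
                        stop("unsupported units: ", units))
  used <- length(x$labels); frames <- x$n_frames
  if (frames > 65535L) stop("C3D writer supports at most 65535 frames")

  # parameter section assembled in memory to size the block count
  pcon <- rawConnection(raw(0), "wb")
  .w_i8(pcon, 5L); .w_i8(pcon, -1L); .w_chr(pcon, "POINT")
  .w_i16(pcon, 3L); .w_i8(pcon, 0L)        # group record, empty description
  .c3d_param_num(pcon, 1L, "USED", used, "int16")
  .c3d_param_num(pcon, 1L, "FRAMES", frames, "int16")
  .c3d_param_num(pcon, 1L, "RATE", x$rate, "float")
  .c3d_param_num(pcon, 1L, "SCALE", -1, "float")
  .c3d_param_chr(pcon, 1L, "UNITS", units)
  .c3d_param_chr(pcon, 1L, "LABELS", x$labels)
  .c3d_param_num(pcon, 1L, "DATA_START", 0L, "int16")  # patched below
  .w_i8(pcon, 0L)                            # record terminator
  pbytes <- rawConnectionValue(pcon); close(pcon)
  n_pblocks <- as.integer(ceiling((length(pbytes) + 4L) / 512L))
  data_start <- 2L + n_pblocks

  # patch DATA_START value (last record before terminator: ... data int16 ...)
  # located 4 bytes before the end: [int16 value][desc_len 0][terminator 0]
  ds_raw <- writeBin(data_start, raw(), size = 2L, endian = "little")
  pbytes[(length(pbytes) - 3L):(length(pbytes) - 2L)] <- ds_raw

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  # header block
  .w_i8(con, 2L); .w_i8(con, 0x50L)
  .w_i16(con, used); .w_i16(con, 0L)
  .w_i16(con, 1L); .w_i16(con, frames)
  .w_i16(con, 10L)
  .w_f32(con, -1)
  .w_i16(con, data_start); .w_i16(con, 0L)
  .w_f32(con, x$rate)
  writeBin(raw(512L - 24L), con)
  # parameter section
  .w_i8(con, 1L); .w_i8(con, 0x50L); .w_i8(con, n_pblocks); .w_i8(con, 84L)
  writeBin(pbytes, con)
  writeBin(raw(n_pblocks * 512L - 4L - length(pbytes)), con)
  # data section
  arr <- array(0, dim = c(4L, used, frames))
  for (q in seq_len(used)) {
    xyz <- x$pos[[x$labels[q]]] / mm_per_unit
    v <- x$valid[[x$labels[q]]]
    xyz[!v, ] <- 0
    arr[1:3, q, ] <- t(xyz)
    arr[4L, q, ] <- ifelse(v, 0, -1)
  }
  .w_f32(con, as.numeric(arr))
  invisible(path)
}
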