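# Minimal DICOM 3.0 codec for single-frame MR magnitude images.
#
# Scope: explicit-VR little-endian files (the transfer syntax this package
# writes), plus implicit-VR little-endian on read. One 2D frame per file,
# 16-bit stored pixels, RescaleSlope/Intercept applied on read. This is a
# purpose-built codec for the relaxometry pipeline, not a general DICOM
# library: it reads the timing/geometry/pixel tags the fitters need and
# skips everything else (including nested sequences) structurally.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_MR_STORAGE  <- "1.2.840.10008.5.1.4.1.1.4"
UID_DICOMDIR    <- "1.2.840.10008.1.3.10"
UID_ROOT        <- "2.25"

LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

.uid_state <- new.env(parent = emptyenv())

new_uid <- function() {
  # numeric UID under a fixed root; uniqueness by timestamp + pid + counter
  n <- get0("n", .uid_state, ifnotfound = 0L) + 1L
  assign("n", n, .uid_state)
  paste(UID_ROOT,
        gsub("[^0-9]", "", format(Sys.time(), "%Y%m%d%H%M%S")),
        Sys.getpid() %% 10000L, n, sep = ".")
}

# ---- encoding -------------------------------------------------------------

u16le <- function(x) {
  x <- as.integer(x)
  writeBin(as.integer(ifelse(x > 32767L, x - 65536L, x)), raw(),
           size = 2, endian = "little")
}

u32le <- function(x) {
  lo <- x %% 65536
  hi <- x %/% 65536
  c(u16le(lo), u16le(hi))
}

pad_even <- function(v, pad = as.raw(0x20)) {
  if (length(v) %% 2 == 1) c(v, pad) else v
}

enc_value <- function(vr, value) {
  switch(vr,
    US = u16le(value),
    UL = u32le(value),
    UI = pad_even(charToRaw(paste(value, collapse = "\\")), as.raw(0)),
    OW = value,  # already raw
    SQ = value,  # already raw (encoded items)
    pad_even(charToRaw(paste(value, collapse = "\\")))  # DS IS CS LO PN SH ...
  )
}

enc_elem <- function(group, elem, vr, value) {
  v <- enc_value(vr, value)
  hdr <- c(u16le(group), u16le(elem), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(hdr, as.raw(c(0, 0)), u32le(length(v)), v)
  } else {
    if (length(v) > 65535) stop("value too long for short VR")
    c(hdr, u16le(length(v)), v)
  }
}

dcm_number <- function(x) {
  # DS encoding with enough digits to round-trip doubles we care about
  if (x == round(x) && abs(x) < 1e15) sprintf("%d", as.integer(x)) else
    sub("0+$", "", sprintf("%.10f", x))
}

encode_meta <- function(sop_class, sop_instance) {
  body <- c(
    enc_elem(0x0002, 0x0002, "UI", sop_class),
    enc_elem(0x0002, 0x0003, "UI", sop_instance),
    enc_elem(0x0002, 0x0010, "UI", UID_EXPLICIT_LE),
    enc_elem(0x0002, 0x0012, "UI", paste0(UID_ROOT, ".1.1"))
  )
  c(raw(128), charToRaw("DICM"),
    enc_elem(0x0002, 0x0000, "UL", length(body)), body)
}

# ---- writer ---------------------------------------------------------------

encode_frame_file <- function(pixels, tr_ms, te_ms, pixel_spacing_mm,
                              slice_thickness_mm, series_uid, study_uid,
                              instance_number) {
  stored <- pixels
  slope <- 1
  intercept <- 0
  is_int <- all(stored == round(stored))
  if (!is_int || max(stored) > 65535) {
    mx <- max(stored)
    slope <- if (mx > 0) mx / 65535 else 1
    stored <- round(stored / slope)
  }
  stored <- as.integer(stored)
  sop_uid <- new_uid()
  px_raw <- u16le(as.vector(t(matrix(stored, nrow(pixels), ncol(pixels)))))
  ds <- c(
    enc_elem(0x0008, 0x0016, "UI", UID_MR_STORAGE),
    enc_elem(0x0008, 0x0018, "UI", sop_uid),
    enc_elem(0x0008, 0x0060, "CS", "MR"),
    enc_elem(0x0010, 0x0010, "PN", "PHANTOM^SYNTHETIC"),
    enc_elem(0x0010, 0x0020, "LO", "RELAXMAP"),
    enc_elem(0x0018, 0x0050, "DS", dcm_number(slice_thickness_mm)),
    enc_elem(0x0018, 0x0080, "DS", dcm_number(tr_ms)),
    enc_elem(0x0018, 0x0081, "DS", dcm_number(te_ms)),
    enc_elem(0x0020, 0x000D, "UI", study_uid),
    enc_elem(0x0020, 0x000E, "UI", series_uid),
    enc_elem(0x0020, 0x0011, "IS", "1"),
    enc_elem(0x0020, 0x0013, "IS", sprintf("%d", instance_number)),
    enc_elem(0x0028, 0x0002, "US", 1L),
    enc_elem(0x0028, 0x0004, "CS", "MONOCHROME2"),
    enc_elem(0x0028, 0x0010, "US", nrow(pixels)),
    enc_elem(0x0028, 0x0011, "US", ncol(pixels)),
    enc_elem(0x0028, 0x0030, "DS",
             paste(dcm_number(pixel_spacing_mm[1]),
                   dcm_number(pixel_spacing_mm[2]), sep = "\\")),
    enc_elem(0x0028, 0x0100, "US", 16L),
    enc_elem(0x0028, 0x0101, "US", 16L),
    enc_elem(0x0028, 0x0102, "US", 15L),
    enc_elem(0x0028, 0x0103, "US", 0L),
    enc_elem(0x0028, 0x1052, "DS", dcm_number(intercept)),
    enc_elem(0x0028, 0x1053, "DS", dcm_number(slope)),
    enc_elem(0x7FE0, 0x0010, "OW", px_raw)
  )
  c(encode_meta(UID_MR_STORAGE, sop_uid), ds)
}

#' Write an image series as a DICOM file set
#'
#' One standard-conformant single-frame DICOM file (explicit-VR little
#' endian, 16-bit unsigned stored pixels) is written per frame, carrying
#' pixel data, RepetitionTime (0018,0080), EchoTime (0018,0081),
#' PixelSpacing and SliceThickness. Integer-valued frames within
#' `[0, 65535]` are stored bit-exactly with RescaleSlope 1; other frames
#' are scaled to the 16-bit range with the scale recorded in
#' RescaleSlope, so the reader recovers values to 16-bit quantization.
#'
#' @param series a valid [image_series()].
#' @param out_dir output directory (created if missing).
#' @param dicomdir also write a minimal DICOMDIR index (default FALSE).
#' @param prefix file-name prefix.
#' @return invisibly, the written file paths.
#' @export
write_series <- function(series, out_dir, dicomdir = FALSE, prefix = "IM") {
  if (!inherits(series, "image_series")) stop("expected an image_series")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir)
  }
  series_uid <- new_uid()
  study_uid <- new_uid()
  paths <- character(length(series$frames))
  for (k in seq_along(series$frames)) {
    fr <- series$frames[[k]]
    bytes <- encode_frame_file(fr$pixels, fr$tr_ms, fr$te_ms,
                               series$pixel_spacing_mm,
                               series$slice_thickness_mm,
                               series_uid, study_uid, k)
    paths[k] <- file.path(out_dir, sprintf("%s%04d.dcm", prefix, k))
    writeBin(bytes, paths[k])
  }
  if (dicomdir) write_dicomdir(out_dir, basename(paths))
  invisible(paths)
}

#' Write a minimal DICOMDIR index for a file set
#'
#' Emits a media-storage directory object whose directory record sequence
#' lists each file as an IMAGE record via ReferencedFileID (0004,1500).
#' Only the fields the package's own catalog reader consumes are written.
#'
#' @param dir directory holding the files (DICOMDIR is written here).
#' @param file_ids file names relative to `dir`.
#' @return invisibly, the DICOMDIR path.
#' @export
write_dicomdir <- function(dir, file_ids) {
  items <- raw(0)
  for (fid in file_ids) {
    body <- c(
      enc_elem(0x0004, 0x1400, "UL", 0),
      enc_elem(0x0004, 0x1410, "US", 65535L),
      enc_elem(0x0004, 0x1420, "UL", 0),
      enc_elem(0x0004, 0x1430, "CS", "IMAGE"),
      enc_elem(0x0004, 0x1500, "CS", gsub("/", "\\\\", fid))
    )
    items <- c(items, u16le(0xFFFE), u16le(0xE000), u32le(length(body)), body)
  }
  sop_uid <- new_uid()
  ds <- c(
    enc_elem(0x0004, 0x1130, "CS", "RELAXMAP"),
    enc_elem(0x0004, 0x1220, "SQ", items)
  )
  path <- file.path(dir, "DICOMDIR")
  writeBin(c(encode_meta(UID_DICOMDIR, sop_uid), ds), path)
  invisible(path)
}

# ---- decoding -------------------------------------------------------------

rd_u16 <- function(raw, off) {
  as.integer(raw[off]) + 256L * as.integer(raw[off + 1L])
}

rd_u32 <- function(raw, off) {
  rd_u16(raw, off) + 65536 * rd_u16(raw, off + 2L)
}

rd_str <- function(v) {
  s <- rawToChar(v[v != as.raw(0)])
  trimws(s)
}

rd_ds <- function(v) {
  s <- strsplit(rd_str(v), "\\\\")[[1]]
  as.numeric(s)
}

# Parse a run of data elements in [off, end]; returns a flat named list
# keyed "gggg,eeee" (sequence contents are recursed into and flattened,
# which is all the DICOMDIR use case needs). `explicit` selects the VR
# encoding.
parse_elements <- function(raw, off, end, explicit, out = list()) {
  while (off + 7L <= end) {
    group <- rd_u16(raw, off)
    elem  <- rd_u16(raw, off + 2L)
    if (group == 0xFFFE) {  # item / delimiter within a sequence
      len <- rd_u32(raw, off + 4L)
      off <- off + 8L
      if (elem == 0xE000 && len != 0xFFFFFFFF) {
        out <- parse_elements(raw, off, off + len - 1L, explicit, out)
        off <- off + len
      }
      next
    }
    if (explicit) {
      vr <- rawToChar(raw[(off + 4L):(off + 5L)])
      if (vr %in% LONG_VRS) {
        len <- rd_u32(raw, off + 8L)
        voff <- off + 12L
      } else {
        len <- rd_u16(raw, off + 6L)
        voff <- off + 8L
      }
    } else {
      vr <- "UN"
      len <- rd_u32(raw, off + 4L)
      voff <- off + 8L
    }
    key <- sprintf("%04X,%04X", group, elem)
    if (len == 0xFFFFFFFF || vr == "SQ") {
      seq_end <- if (len == 0xFFFFFFFF) end else voff + len - 1L
      out <- parse_elements(raw, voff, seq_end, explicit, out)
      if (len == 0xFFFFFFFF) {
        # scan forward for the sequence delimitation item (FFFE,E0DD)
        p <- voff
        while (p + 7L <= end &&
               !(rd_u16(raw, p) == 0xFFFE && rd_u16(raw, p + 2L) == 0xE0DD)) {
          p <- p + 2L
        }
        off <- p + 8L
      } else {
        off <- voff + len
      }
      next
    }
    if (voff + len - 1L > end) stop("truncated DICOM element")
    val <- if (len > 0) raw[voff:(voff + len - 1L)] else raw(0)
    if (key == "0004,1500") {
      out[[key]] <- c(out[[key]], rd_str(val))  # collect all file IDs
    } else {
      out[[key]] <- val
    }
    off <- voff + len
  }
  out
}

read_dicom_raw <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 140) return(NULL)
  raw <- readBin(path, "raw", n = sz)
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM") return(NULL)
  # file meta group is always explicit VR
  meta_len_hdr <- 133L
  if (rd_u16(raw, meta_len_hdr) != 0x0002) return(NULL)
  meta_len <- rd_u32(raw, meta_len_hdr + 8L)
  meta_end <- 133L + 12L + meta_len - 1L
  meta <- parse_elements(raw, 133L, meta_end, explicit = TRUE)
  ts <- rd_str(meta[["0002,0010"]] %||% raw(0))
  explicit <- !identical(ts, UID_IMPLICIT_LE)
  if (nzchar(ts) && !ts %in% c(UID_EXPLICIT_LE, UID_IMPLICIT_LE)) {
    stop("unsupported transfer syntax: ", ts)
  }
  ds <- parse_elements(raw, meta_end + 1L, length(raw), explicit = explicit)
  list(meta = meta, ds = ds)
}

decode_pixels <- function(ds) {
  px <- ds[["7FE0,0010"]]
  if (is.null(px)) return(NULL)
  rows <- rd_u16(ds[["0028,0010"]], 1L)
  cols <- rd_u16(ds[["0028,0011"]], 1L)
  bits <- if (!is.null(ds[["0028,0100"]])) rd_u16(ds[["0028,0100"]], 1L) else 16L
  signed <- !is.null(ds[["0028,0103"]]) && rd_u16(ds[["0028,0103"]], 1L) == 1L
  if (bits == 16L) {
    v <- readBin(px, "integer", n = rows * cols, size = 2,
                 signed = FALSE, endian = "little")
    if (signed) v <- ifelse(v > 32767L, v - 65536L, v)
  } else if (bits == 8L) {
    v <- as.integer(px[seq_len(rows * cols)])
  } else {
    stop("unsupported bit depth: ", bits)
  }
  slope <- if (!is.null(ds[["0028,1053"]])) rd_ds(ds[["0028,1053"]])[1] else 1
  icept <- if (!is.null(ds[["0028,1052"]])) rd_ds(ds[["0028,1052"]])[1] else 0
  m <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
  m * slope + icept
}

# Read one single-frame DICOM file into a frame record (or NULL when the
# file is not DICOM).
read_dicom_frame <- function(path) {
  parsed <- read_dicom_raw(path)
  if (is.null(parsed)) return(NULL)
  ds <- parsed$ds
  getds <- function(key) if (is.null(ds[[key]])) NA_real_ else rd_ds(ds[[key]])[1]
  pixels <- decode_pixels(ds)
  spacing <- if (is.null(ds[["0028,0030"]])) c(NA_real_, NA_real_)
             else rd_ds(ds[["0028,0030"]])
  list(
    path = path,
    sop_class = rd_str(ds[["0008,0016"]] %||% raw(0)),
    series_uid = rd_str(ds[["0020,000E"]] %||% raw(0)),
    instance = if (is.null(ds[["0020,0013"]])) NA_integer_
               else as.integer(rd_str(ds[["0020,0013"]])),
    tr_ms = getds("0018,0080"),
    te_ms = getds("0018,0081"),
    slice_thickness_mm = getds("0018,0050"),
    pixel_spacing_mm = spacing,
    rows = if (is.null(pixels)) NA_integer_ else nrow(pixels),
    cols = if (is.null(pixels)) NA_integer_ else ncol(pixels),
    pixels = pixels,
    referenced_files = ds[["0004,1500"]]
  )
}

# ---- catalog / load -------------------------------------------------------

#' Catalog the DICOM content of a directory
#'
#' Discovers readable single-frame DICOM files under `root_path` and
#' groups them into candidate series. When a DICOMDIR index is present
#' its ReferencedFileID entries drive discovery; otherwise (or when the
#' index is unusable) a recursive directory scan is the fallback. Files
#' without pixel data (including the DICOMDIR itself) and unreadable or
#' non-DICOM files are skipped with a notice, never fatally.
#'
#' Grouping is by SeriesInstanceUID; files lacking one are grouped by
#' matching geometry. Each group's protocol is inferred from which timing
#' tag varies: TR varying at fixed TE is a T1-protocol group, TE varying
#' at fixed TR a T2 one.
#'
#' @param root_path directory containing DICOM files and/or a DICOMDIR.
#' @return a `series_catalog`: `entries` (data frame of path, TR, TE,
#'   rows, cols), `groups` (named list of row indices), `skipped` paths.
#' @export
catalog_series <- function(root_path) {
  if (!dir.exists(root_path)) stop("no DICOM input found: ", root_path, " does not exist")
  files <- NULL
  dd <- list.files(root_path, full.names = TRUE)
  dd <- dd[toupper(basename(dd)) == "DICOMDIR"]
  if (length(dd) >= 1) {
    idx <- tryCatch(read_dicom_frame(dd[[1]]), error = function(e) NULL)
    if (!is.null(idx) && length(idx$referenced_files) > 0) {
      files <- file.path(root_path, gsub("\\\\", "/", idx$referenced_files))
      files <- files[file.exists(files)]
    }
  }
  if (is.null(files) || length(files) == 0) {
    files <- list.files(root_path, full.names = TRUE, recursive = TRUE)
    files <- files[toupper(basename(files)) != "DICOMDIR"]
  }
  if (length(files) == 0) stop("no DICOM input found in ", root_path)

  entries <- list()
  skipped <- character(0)
  for (f in files) {
    fr <- tryCatch(read_dicom_frame(f), error = function(e) NULL)
    if (is.null(fr) || is.null(fr$pixels)) {
      skipped <- c(skipped, f)
      next
    }
    entries[[length(entries) + 1L]] <- data.frame(
      path = f, series_uid = fr$series_uid, instance = fr$instance,
      tr_ms = fr$tr_ms, te_ms = fr$te_ms,
      rows = fr$rows, cols = fr$cols,
      spacing_row = fr$pixel_spacing_mm[1], spacing_col = fr$pixel_spacing_mm[2],
      stringsAsFactors = FALSE
    )
  }
  if (length(skipped) > 0) {
    message(length(skipped), " non-DICOM or unreadable file(s) skipped")
  }
  if (length(entries) == 0) stop("no DICOM input found in ", root_path)
  entries <- do.call(rbind, entries)

  key <- entries$series_uid
  nouid <- is.na(key) | key == ""
  if (any(nouid)) {
    key[nouid] <- paste0("geom:", entries$rows[nouid], "x", entries$cols[nouid],
                         "@", entries$spacing_row[nouid])
  }
  groups <- split(seq_len(nrow(entries)), key)
  structure(list(entries = entries, groups = groups, skipped = skipped,
                 root = root_path),
            class = "series_catalog")
}

#' @export
print.series_catalog <- function(x, ...) {
  cat(sprintf("<series_catalog> %d file(s) in %d group(s), %d skipped\n",
              nrow(x$entries), length(x$groups), length(x$skipped)))
  for (g in names(x$groups)) {
    rows <- x$entries[x$groups[[g]], ]
    cat(sprintf("  %s: %d frame(s), TR %s ms, TE %s ms\n",
                substr(g, 1, 24), nrow(rows),
                paste(sort(unique(rows$tr_ms)), collapse = "/"),
                paste(sort(unique(rows$te_ms)), collapse = "/")))
  }
  invisible(x)
}

#' Export a catalog as CSV
#'
#' @param catalog a `series_catalog`.
#' @param path output CSV path (columns: path, tr_ms, te_ms, rows, cols).
#' @return invisibly, `path`.
#' @export
export_catalog <- function(catalog, path) {
  utils::write.csv(
    catalog$entries[c("path", "tr_ms", "te_ms", "rows", "cols")],
    path, row.names = FALSE)
  invisible(path)
}

#' Load one cataloged series as an image series
#'
#' Reads every frame of the selected group, applies rescale
#' slope/intercept, averages duplicate timing points (with a notice),
#' infers the protocol from which timing tag varies, and returns frames
#' sorted ascending on the varied parameter regardless of file order.
#'
#' @param catalog a [catalog_series()] result.
#' @param selector group name (default: the only / first group).
#' @return an [image_series()].
#' @export
load_series <- function(catalog, selector = NULL) {
  if (!inherits(catalog, "series_catalog")) stop("expected a series_catalog")
  if (is.null(selector)) selector <- names(catalog$groups)[1]
  if (!selector %in% names(catalog$groups)) {
    stop("series '", selector, "' not found in catalog")
  }
  rows <- catalog$entries[catalog$groups[[selector]], ]
  frames <- lapply(rows$path, read_dicom_frame)

  shapes <- vapply(frames, function(f) paste(f$rows, f$cols), character(1))
  if (length(unique(shapes)) != 1) stop("inconsistent series geometry")
  tr <- vapply(frames, `[[`, numeric(1), "tr_ms")
  te <- vapply(frames, `[[`, numeric(1), "te_ms")
  if (any(is.na(tr)) || any(is.na(te))) stop("missing timing metadata")
  tr_varies <- length(unique(tr)) > 1
  te_varies <- length(unique(te)) > 1
  if (tr_varies && te_varies) stop("ambiguous protocol: both TR and TE vary")
  varied <- if (tr_varies) tr else te
  if (anyDuplicated(varied)) {
    message("duplicate timing points averaged")
    agg <- split(seq_along(varied), varied)
    frames <- lapply(agg, function(ix) {
      f <- frames[[ix[1]]]
      if (length(ix) > 1) {
        f$pixels <- Reduce(`+`, lapply(frames[ix], `[[`, "pixels")) / length(ix)
      }
      f
    })
    tr <- vapply(frames, `[[`, numeric(1), "tr_ms")
    te <- vapply(frames, `[[`, numeric(1), "te_ms")
  }
  spacing <- frames[[1]]$pixel_spacing_mm
  if (any(is.na(spacing))) spacing <- c(1, 1)
  thick <- frames[[1]]$slice_thickness_mm
  image_series(lapply(frames, `[[`, "pixels"), tr, te,
               pixel_spacing_mm = spacing,
               slice_thickness_mm = if (is.na(thick)) 1 else thick,
               frame_id = vapply(frames, `[[`, character(1), "path"))
}
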