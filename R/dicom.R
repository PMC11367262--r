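# Minimal DICOM codec: Explicit VR Little Endian only, covering the RT Plan
# subset this package needs (nested sequences, string/numeric VRs). A dataset
# is a list of elements; an element is list(group, element, vr, value); an SQ
# value is a list of item datasets.

.DCM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.DCM_SOP_RTPLAN <- "1.2.840.10008.5.1.4.1.1.481.5"
.DCM_IMPL_UID <- "2.25.3141592653589793238462643383279"
.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.dcmTagKey <- function(group, element) sprintf("%04X%04X", group, element)

.dcmEl <- function(group, element, vr, value) {
  list(group = group, element = element, vr = vr, value = value)
}

.u16raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32raw <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

.dcmPad <- function(bytes, padByte) {
  if (length(bytes) %% 2 == 1) c(bytes, padByte) else bytes
}

.dcmEncodeValue <- function(vr, value) {
  switch(vr,
    DS = .dcmPad(charToRaw(paste(vapply(value, function(v)
           sprintf("%.10g", v), character(1)), collapse = "\\")), as.raw(0x20)),
    IS = .dcmPad(charToRaw(paste(as.integer(value), collapse = "\\")), as.raw(0x20)),
    UI = .dcmPad(charToRaw(paste(value, collapse = "\\")), as.raw(0x00)),
    UL = .u32raw(value),
    US = .u16raw(value),
    SQ = {
      out <- raw(0)
      for (item in value) {
        body <- .dcmEncodeDataset(item)
        out <- c(out, .u16raw(0xFFFE), .u16raw(0xE000), .u32raw(length(body)), body)
      }
      out
    },
    # SH, LO, CS, DA, TM, ST, PN and other text VRs: space-padded ASCII
    .dcmPad(charToRaw(paste(value, collapse = "\\")), as.raw(0x20))
  )
}

.dcmEncodeElement <- function(el) {
  body <- .dcmEncodeValue(el$vr, el$value)
  head <- c(.u16raw(el$group), .u16raw(el$element), charToRaw(el$vr))
  if (el$vr %in% .LONG_VRS) c(head, raw(2), .u32raw(length(body)), body)
  else c(head, .u16raw(length(body)), body)
}

.dcmEncodeDataset <- function(ds) {
  # elements must be in ascending tag order within a dataset
  keys <- vapply(ds, function(e) e$group * 2^16 + e$element, numeric(1))
  do.call(c, lapply(ds[order(keys)], .dcmEncodeElement))
}

.dcmWriteFile <- function(ds, path, sopClass = .DCM_SOP_RTPLAN,
                          sopInstance = NULL) {
  if (is.null(sopInstance))
    sopInstance <- paste0("2.25.", paste(sample(0:9, 30, replace = TRUE),
                                         collapse = ""))
  meta <- list(
    .dcmEl(0x0002, 0x0002, "UI", sopClass),
    .dcmEl(0x0002, 0x0003, "UI", sopInstance),
    .dcmEl(0x0002, 0x0010, "UI", .DCM_TS_EXPLICIT_LE),
    .dcmEl(0x0002, 0x0012, "UI", .DCM_IMPL_UID)
  )
  metaBytes <- .dcmEncodeDataset(meta)
  groupLen <- .dcmEncodeElement(.dcmEl(0x0002, 0x0000, "UL", length(metaBytes)))
  body <- .dcmEncodeDataset(ds)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(groupLen, metaBytes, body), con)
  invisible(path)
}

# ---- reading ----------------------------------------------------------------

.readU16 <- function(bytes, pos)
  readBin(bytes[pos:(pos + 1)], "integer", size = 2, endian = "little",
          signed = FALSE)

.readU32 <- function(bytes, pos)
  readBin(bytes[pos:(pos + 3)], "integer", size = 4, endian = "little")

.dcmDecodeValue <- function(vr, bytes) {
  if (!length(bytes)) return(switch(vr, DS = , IS = numeric(0), character(0)))
  txt <- function() {
    s <- rawToChar(bytes[bytes != as.raw(0)])
    trimws(strsplit(s, "\\", fixed = TRUE)[[1]])
  }
  switch(vr,
    DS = as.numeric(txt()),
    IS = as.integer(txt()),
    UL = .readU32(bytes, 1),
    US = .readU16(bytes, 1),
    txt()
  )
}

# parse a dataset from bytes[pos..end]; stopTag: stop before this (group,elem)
.dcmParseDataset <- function(bytes, pos, end) {
  out <- list()
  while (pos <= end) {
    group <- .readU16(bytes, pos); element <- .readU16(bytes, pos + 2)
    pos <- pos + 4
    if (group == 0xFFFE) {                   # item/sequence delimiters
      len <- .readU32(bytes, pos); pos <- pos + 4
      if (element == 0xE00D || element == 0xE0DD)
        return(list(ds = out, pos = pos, delim = element))
      stop("unexpected item tag inside dataset")
    }
    vr <- rawToChar(bytes[pos:(pos + 1)]); pos <- pos + 2
    if (vr %in% .LONG_VRS) {
      pos <- pos + 2
      len <- .readU32(bytes, pos); pos <- pos + 4
    } else {
      len <- .readU16(bytes, pos); pos <- pos + 2
    }
    if (vr == "SQ") {
      if (len == -1L) {                      # undefined length
        items <- .dcmParseItems(bytes, pos, end, undefined = TRUE)
      } else {
        items <- .dcmParseItems(bytes, pos, pos + len - 1, undefined = FALSE)
      }
      out[[.dcmTagKey(group, element)]] <- .dcmEl(group, element, "SQ", items$items)
      pos <- items$pos
    } else {
      value <- .dcmDecodeValue(vr, if (len > 0) bytes[pos:(pos + len - 1)] else raw(0))
      out[[.dcmTagKey(group, element)]] <- .dcmEl(group, element, vr, value)
      pos <- pos + len
    }
  }
  list(ds = out, pos = pos, delim = NA)
}

.dcmParseItems <- function(bytes, pos, end, undefined) {
  items <- list()
  repeat {
    if (!undefined && pos > end) break
    group <- .readU16(bytes, pos); element <- .readU16(bytes, pos + 2)
    len <- .readU32(bytes, pos + 4)
    pos <- pos + 8
    if (group == 0xFFFE && element == 0xE0DD) break      # sequence delimiter
    if (!(group == 0xFFFE && element == 0xE000))
      stop("malformed sequence: expected an item tag")
    if (len == -1L) {                        # undefined-length item
      res <- .dcmParseDataset(bytes, pos, length(bytes))
      if (!identical(res$delim, 0xE00DL) && !identical(res$delim, 57357L))
        stop("unterminated undefined-length item")
      items[[length(items) + 1]] <- res$ds
      pos <- res$pos
    } else {
      res <- .dcmParseDataset(bytes, pos, pos + len - 1)
      items[[length(items) + 1]] <- res$ds
      pos <- pos + len
    }
  }
  list(items = items, pos = pos)
}

.dcmReadFile <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path)
  pos <- 133
  # file meta group (always explicit little endian)
  group <- .readU16(bytes, pos)
  if (group != 2) stop("missing DICOM file meta group")
  lenEl <- .dcmParseDataset(bytes, pos, pos + 11)  # (0002,0000) UL, 12 bytes
  metaLen <- lenEl$ds[[.dcmTagKey(2, 0)]]$value
  metaEnd <- lenEl$pos + metaLen - 1
  meta <- .dcmParseDataset(bytes, lenEl$pos, metaEnd)$ds
  ts <- meta[[.dcmTagKey(0x0002, 0x0010)]]$value
  if (!identical(ts, .DCM_TS_EXPLICIT_LE))
    stop("unsupported transfer syntax: ", ts,
         " (only Explicit VR Little Endian is supported)")
  .dcmParseDataset(bytes, metaEnd + 1, length(bytes))$ds
}

.dcmGet <- function(ds, group, element, default = NULL) {
  el <- ds[[.dcmTagKey(group, element)]]
  if (is.null(el)) default else el$value
}
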