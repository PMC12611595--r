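# Minimal DICOM codec: explicit VR little endian, uncompressed, with nested
# sequence support. Covers exactly what the RT pipeline needs (CT image,
# RTDOSE, RTSTRUCT); it is not a general-purpose DICOM implementation.
#
# A dataset is a named list keyed "GGGG,EEEE" (uppercase hex); each element is
# list(vr = <2-char VR>, value = <parsed value>). SQ values are lists of
# datasets. OB/OW values are raw vectors.

DCM_TRANSFER_SYNTAX_LE_EXPLICIT <- "1.2.840.10008.1.2.1"
DCM_UID_ROOT <- "2.25"  # UUID-derived numeric form; digits generated per write

dcm_vr_long <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_tag_key <- function(group, element) {
  sprintf("%04X,%04X", group, element)
}

dcm_key_tag <- function(key) {
  c(strtoi(substr(key, 1, 4), 16L), strtoi(substr(key, 6, 9), 16L))
}

raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
raw_u32 <- function(x) {
  x <- as.numeric(x)
  lo <- x %% 65536
  hi <- (x - lo) / 65536
  c(raw_u16(lo), raw_u16(hi))
}

dcm_pad_even <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2 == 1) c(bytes, pad) else bytes
}

dcm_encode_value <- function(vr, value) {
  if (vr %in% c("UI")) {
    dcm_pad_even(charToRaw(paste(value, collapse = "\\")), as.raw(0x00))
  } else if (vr %in% c("CS", "LO", "SH", "PN", "DA", "TM", "ST", "LT", "AE", "DT")) {
    dcm_pad_even(charToRaw(paste(value, collapse = "\\")))
  } else if (vr == "DS") {
    dcm_pad_even(charToRaw(paste(sprintf("%.10g", value), collapse = "\\")))
  } else if (vr == "IS") {
    dcm_pad_even(charToRaw(paste(sprintf("%d", as.integer(value)), collapse = "\\")))
  } else if (vr == "US") {
    raw_u16(value)
  } else if (vr == "UL") {
    raw_u32(value)
  } else if (vr == "FD") {
    writeBin(as.numeric(value), raw(), size = 8, endian = "little")
  } else if (vr %in% c("OB", "OW")) {
    stopifnot(is.raw(value))
    dcm_pad_even(value, as.raw(0x00))
  } else {
    stop(sprintf("dcm_encode_value: unsupported VR '%s'", vr))
  }
}

dcm_encode_element <- function(key, vr, value) {
  tag <- dcm_key_tag(key)
  head <- c(raw_u16(tag[1]), raw_u16(tag[2]), charToRaw(vr))
  if (vr == "SQ") {
    body <- raw(0)
    for (item in value) {
      item_bytes <- dcm_encode_dataset(item)
      body <- c(body,
                raw_u16(0xFFFE), raw_u16(0xE000), raw_u32(length(item_bytes)),
                item_bytes)
    }
    # undefined sequence length + sequence delimitation item
    c(head, as.raw(c(0, 0)), as.raw(c(0xFF, 0xFF, 0xFF, 0xFF)), body,
      raw_u16(0xFFFE), raw_u16(0xE0DD), raw_u32(0))
  } else {
    body <- dcm_encode_value(vr, value)
    if (vr %in% dcm_vr_long) {
      c(head, as.raw(c(0, 0)), raw_u32(length(body)), body)
    } else {
      if (length(body) > 65535) stop("dcm_encode_element: value too long for short VR")
      c(head, raw_u16(length(body)), body)
    }
  }
}

dcm_encode_dataset <- function(ds) {
  keys <- names(ds)
  ord <- order(vapply(keys, function(k) {
    t <- dcm_key_tag(k); t[1] * 2^16 + t[2]
  }, numeric(1)))
  out <- lapply(keys[ord], function(k) dcm_encode_element(k, ds[[k]]$vr, ds[[k]]$value))
  do.call(c, out)
}

dcm_element <- function(vr, value) list(vr = vr, value = value)

#' @keywords internal
dcm_write_file <- function(path, dataset, sop_class_uid, sop_instance_uid) {
  meta <- list(
    "0002,0001" = dcm_element("OB", as.raw(c(0, 1))),
    "0002,0002" = dcm_element("UI", sop_class_uid),
    "0002,0003" = dcm_element("UI", sop_instance_uid),
    "0002,0010" = dcm_element("UI", DCM_TRANSFER_SYNTAX_LE_EXPLICIT),
    "0002,0012" = dcm_element("UI", paste0(DCM_UID_ROOT, ".999.1"))
  )
  meta_bytes <- dcm_encode_dataset(meta)
  group_len <- dcm_encode_element("0002,0000", "UL", length(meta_bytes))
  body <- dcm_encode_dataset(dataset)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(group_len, meta_bytes, body), con)
  invisible(path)
}

# --- reading ---------------------------------------------------------------

dcm_reader <- function(bytes) {
  env <- new.env(parent = emptyenv())
  env$bytes <- bytes
  env$pos <- 1L
  env
}

rd_raw <- function(r, n) {
  if (r$pos + n - 1L > length(r$bytes)) stop("DICOM parse error: unexpected end of file")
  out <- r$bytes[r$pos:(r$pos + n - 1L)]
  r$pos <- r$pos + n
  out
}

rd_u16 <- function(r) readBin(rd_raw(r, 2L), "integer", size = 2, endian = "little", signed = FALSE)
rd_u32 <- function(r) {
  b <- rd_raw(r, 4L)
  sum(as.numeric(b) * c(1, 256, 65536, 16777216))
}

dcm_parse_value <- function(vr, bytes) {
  txt <- function() {
    s <- rawToChar(bytes[bytes != as.raw(0)])
    strsplit(sub("[ ]+$", "", s), "\\", fixed = TRUE)[[1]]
  }
  switch(vr,
    UI = , CS = , LO = , SH = , PN = , DA = , TM = , ST = , LT = , AE = , DT = txt(),
    DS = as.numeric(txt()),
    IS = as.integer(txt()),
    US = readBin(bytes, "integer", n = length(bytes) / 2, size = 2,
                 endian = "little", signed = FALSE),
    UL = readBin(bytes, "integer", n = length(bytes) / 4, size = 4,
                 endian = "little"),
    FD = readBin(bytes, "double", n = length(bytes) / 8, size = 8,
                 endian = "little"),
    bytes  # OB/OW/UN and anything else: keep raw
  )
}

dcm_read_dataset <- function(r, end_pos = NA) {
  ds <- list()
  repeat {
    if (!is.na(end_pos) && r$pos >= end_pos) break
    if (r$pos > length(r$bytes)) break
    group <- rd_u16(r)
    element <- rd_u16(r)
    if (group == 0xFFFE && element == 0xE00D) {  # item delimiter
      rd_u32(r)
      break
    }
    if (group == 0xFFFE && element == 0xE0DD) {  # stray sequence delimiter
      rd_u32(r)
      break
    }
    vr <- rawToChar(rd_raw(r, 2L))
    if (vr %in% dcm_vr_long) {
      rd_raw(r, 2L)  # reserved
      len <- rd_u32(r)
    } else {
      len <- rd_u16(r)
    }
    key <- dcm_tag_key(group, element)
    if (vr == "SQ") {
      ds[[key]] <- dcm_element("SQ", dcm_read_sequence(r, len))
    } else if (len == 4294967295) {
      stop(sprintf("DICOM parse error: undefined length on non-SQ element %s", key))
    } else {
      ds[[key]] <- dcm_element(vr, dcm_parse_value(vr, rd_raw(r, len)))
    }
  }
  ds
}

dcm_read_sequence <- function(r, len) {
  items <- list()
  undefined <- (len == 4294967295)
  end_pos <- if (undefined) NA else r$pos + len
  repeat {
    if (!undefined && r$pos >= end_pos) break
    group <- rd_u16(r)
    element <- rd_u16(r)
    ilen <- rd_u32(r)
    if (group == 0xFFFE && element == 0xE0DD) break  # sequence delimiter
    if (!(group == 0xFFFE && element == 0xE000)) {
      stop("DICOM parse error: expected sequence item tag")
    }
    item_end <- if (ilen == 4294967295) NA else r$pos + ilen
    items[[length(items) + 1L]] <- dcm_read_dataset(r, item_end)
  }
  items
}

#' @keywords internal
dcm_read_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 132 || rawToChar(bytes[129:132]) != "DICM") {
    stop(sprintf("'%s' is not a DICOM file (missing DICM marker)", path))
  }
  r <- dcm_reader(bytes)
  r$pos <- 133L
  meta <- dcm_read_meta(r)
  ts <- meta[["0002,0010"]]$value
  if (!is.null(ts) && !identical(ts, DCM_TRANSFER_SYNTAX_LE_EXPLICIT)) {
    stop(sprintf("unsupported transfer syntax '%s' (only explicit VR little endian)", ts))
  }
  ds <- dcm_read_dataset(r)
  attr(ds, "file_meta") <- meta
  ds
}

dcm_read_meta <- function(r) {
  # group 0002 is always explicit VR LE; its extent comes from the group length
  group <- rd_u16(r); element <- rd_u16(r)
  stopifnot(group == 2L, element == 0L)
  vr <- rawToChar(rd_raw(r, 2L))
  len <- rd_u16(r)
  glen <- dcm_parse_value("UL", rd_raw(r, len))
  dcm_read_dataset(r, r$pos + glen)
}

dcm_get <- function(ds, key, required = TRUE) {
  el <- ds[[key]]
  if (is.null(el)) {
    if (required) stop(sprintf("DICOM element %s is missing", key))
    return(NULL)
  }
  el$value
}

# Deterministic-when-seeded UID generator. DICOM UIDs must be unique in real
# interchange; for reproducible fixtures a seed pins the whole series.
dcm_uid_factory <- function(seed = NULL) {
  rng <- if (is.null(seed)) {
    function(n) sample.int(10, n, replace = TRUE) - 1L
  } else {
    local_seed <- seed
    function(n) {
      state <- globalenv()$.Random.seed
      set.seed(local_seed)
      local_seed <<- local_seed + 1L
      out <- sample.int(10, n, replace = TRUE) - 1L
      if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
      out
    }
  }
  counter <- 0L
  function() {
    counter <<- counter + 1L
    digits <- paste(rng(30), collapse = "")
    sprintf("%s.%s.%d", DCM_UID_ROOT, digits, counter)
  }
}
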