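# Minimal GIFTI (.gii) surface-data reader/writer built on xml2.
# Supports the two array intents this package needs: per-vertex scalar maps
# (shape) and integer parcellation labels. Encodings: ASCII, Base64Binary,
# GZipBase64Binary; data types FLOAT32, FLOAT64, INT32. External binary
# files and multi-dimensional arrays are out of scope.

.gifti_sizeof <- c(NIFTI_TYPE_FLOAT32 = 4L, NIFTI_TYPE_FLOAT64 = 8L,
                   NIFTI_TYPE_INT32 = 4L)

#' @noRd
.read_gifti_array <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("not a parseable GIFTI/XML file: ",
                                           path, " (", conditionMessage(e), ")",
                                           call. = FALSE))
  das <- xml2::xml_find_all(doc, ".//d1:DataArray | .//DataArray",
                            ns = c(d1 = "http://www.nitrc.org/frs/download.php/115/gifti.xsd"))
  if (length(das) == 0) das <- xml2::xml_find_all(doc, "//DataArray")
  .assert(length(das) >= 1, paste0("no DataArray found in GIFTI file: ", path))
  da <- das[[1]]
  enc <- xml2::xml_attr(da, "Encoding")
  dtype <- xml2::xml_attr(da, "DataType")
  endian <- xml2::xml_attr(da, "Endian")
  intent <- xml2::xml_attr(da, "Intent")
  dim0 <- as.integer(xml2::xml_attr(da, "Dim0"))
  dat_node <- xml2::xml_find_first(da, ".//*[local-name()='Data']")
  txt <- xml2::xml_text(dat_node)
  values <- switch(enc,
    ASCII = {
      v <- scan(text = txt, quiet = TRUE)
      v
    },
    Base64Binary = ,
    GZipBase64Binary = {
      raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", txt))
      if (enc == "GZipBase64Binary") raw <- memDecompress(raw, type = "gzip")
      .assert(dtype %in% names(.gifti_sizeof),
              paste0("unsupported GIFTI DataType: ", dtype))
      sz <- .gifti_sizeof[[dtype]]
      what <- if (dtype == "NIFTI_TYPE_INT32") "integer" else "double"
      readBin(raw, what = what, n = length(raw) %/% sz, size = sz,
              endian = if (identical(endian, "BigEndian")) "big" else "little")
    },
    stop("unsupported GIFTI Encoding: ", enc, call. = FALSE)
  )
  if (!is.na(dim0) && length(values) != dim0)
    stop("GIFTI Dim0 (", dim0, ") does not match decoded length (",
         length(values), ") in ", path, call. = FALSE)
  # label table, if present (parcellation names)
  labtab <- xml2::xml_find_all(doc, "//*[local-name()='Label']")
  labels <- NULL
  if (length(labtab) > 0) {
    labels <- data.frame(
      key = as.integer(xml2::xml_attr(labtab, "Key")),
      name = xml2::xml_text(labtab),
      stringsAsFactors = FALSE
    )
  }
  list(values = values, intent = intent, dtype = dtype, label_table = labels)
}

#' @noRd
.write_gifti_array <- function(values, path, intent, dtype, label_table = NULL) {
  # ASCII encoding with full double precision: round-trips exactly and keeps
  # files text-only.
  fmt_val <- if (dtype == "NIFTI_TYPE_INT32") {
    paste(format(as.integer(values), scientific = FALSE), collapse = " ")
  } else {
    paste(sprintf("%.17g", as.double(values)), collapse = " ")
  }
  lab_xml <- ""
  if (!is.null(label_table)) {
    rows <- sprintf('      <Label Key="%d"><![CDATA[%s]]></Label>',
                    label_table$key, label_table$name)
    lab_xml <- paste0("   <LabelTable>\n", paste(rows, collapse = "\n"),
                      "\n   </LabelTable>\n")
  }
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="1">\n',
    lab_xml,
    '   <DataArray Intent="', intent, '" DataType="', dtype,
    '" ArrayIndexingOrder="RowMajorOrder" Dimensionality="1" Dim0="',
    length(values), '" Encoding="ASCII" Endian="LittleEndian" ',
    'ExternalFileName="" ExternalFileOffset="">\n',
    "      <Data>", fmt_val, "</Data>\n",
    "   </DataArray>\n</GIFTI>\n"
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(xml, con, sep = "")
  invisible(path)
}
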