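#' Minimal GIFTI writers and readers
#'
#' Text-mode (ASCII-encoded) GIFTI support for the three file kinds the
#' pipeline emits: surface geometry (`.surf.gii`: POINTSET + TRIANGLE
#' arrays), per-vertex scalar maps (`.func.gii`), and label maps
#' (`.label.gii` with a label table).  Triangle vertex indices are written
#' 0-based per the GIFTI standard and converted back to 1-based on read.
#' These writers cover the synthetic pipeline's needs only; they are not a
#' general GIFTI implementation.
#'
#' @name gifti_io
NULL

gifti_data_array <- function(doc_root, values, intent, datatype, dims) {
  da <- xml2::xml_add_child(doc_root, "DataArray",
    Intent = intent, DataType = datatype,
    ArrayIndexingOrder = "RowMajorOrder",
    Dimensionality = as.character(length(dims)),
    Encoding = "ASCII", Endian = "LittleEndian",
    ExternalFileName = "", ExternalFileOffset = "")
  for (i in seq_along(dims))
    xml2::xml_set_attr(da, paste0("Dim", i - 1), as.character(dims[i]))
  txt <- paste(format(t(values), trim = TRUE, scientific = FALSE),
               collapse = " ")
  xml2::xml_add_child(da, "Data", txt)
  da
}

#' @rdname gifti_io
#' @param mesh a `surface_mesh`.
#' @param path output path (conventionally `.surf.gii`).
#' @return the path, invisibly.
#' @export
write_gifti_surface <- function(mesh, path) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "2")
  gifti_data_array(doc, mesh$vertices, "NIFTI_INTENT_POINTSET",
                   "NIFTI_TYPE_FLOAT32",
                   c(nrow(mesh$vertices), 3L))
  gifti_data_array(doc, mesh$triangles - 1L, "NIFTI_INTENT_TRIANGLE",
                   "NIFTI_TYPE_INT32",
                   c(nrow(mesh$triangles), 3L))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname gifti_io
#' @param values numeric per-vertex vector.
#' @export
write_gifti_func <- function(values, path) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "1")
  gifti_data_array(doc, matrix(values, ncol = 1), "NIFTI_INTENT_NONE",
                   "NIFTI_TYPE_FLOAT32", length(values))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname gifti_io
#' @param labels integer per-vertex label vector (0 = unassigned).
#' @param label_table named integer vector mapping label names to keys,
#'   e.g. `c(unassigned = 0, forehead = 1, nose = 2, lips = 3, tongue = 4)`.
#' @export
write_gifti_label <- function(labels, path,
                              label_table = c(unassigned = 0L, forehead = 1L,
                                              nose = 2L, lips = 3L,
                                              tongue = 4L)) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = "1")
  lt <- xml2::xml_add_child(doc, "LabelTable")
  for (i in seq_along(label_table))
    xml2::xml_add_child(lt, "Label", names(label_table)[i],
                        Key = as.character(label_table[i]))
  gifti_data_array(doc, matrix(as.integer(labels), ncol = 1),
                   "NIFTI_INTENT_LABEL", "NIFTI_TYPE_INT32", length(labels))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname gifti_io
#' @export
read_gifti <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  out <- lapply(arrays, function(da) {
    dims <- as.integer(vapply(
      paste0("Dim", seq_len(as.integer(xml2::xml_attr(da, "Dimensionality"))) - 1),
      function(a) xml2::xml_attr(da, a), character(1)))
    vals <- scan(text = xml2::xml_text(xml2::xml_find_first(da, ".//Data")),
                 quiet = TRUE)
    m <- if (length(dims) == 2)
      matrix(vals, dims[1], dims[2], byrow = TRUE) else vals
    intent <- xml2::xml_attr(da, "Intent")
    if (intent == "NIFTI_INTENT_TRIANGLE") m <- m + 1L
    list(intent = intent, data = m)
  })
  labs <- xml2::xml_find_all(doc, ".//LabelTable/Label")
  lt <- NULL
  if (length(labs))
    lt <- stats::setNames(as.integer(xml2::xml_attr(labs, "Key")),
                          xml2::xml_text(labs))
  list(arrays = out, label_table = lt)
}
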