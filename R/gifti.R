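# Minimal GIFTI surface I/O (ASCII encoding) built on xml2. Covers the
# subset of the format the pipeline needs: POINTSET + TRIANGLE geometry
# files and a LABEL file for the medial wall. Data arrays are written with
# Encoding="ASCII" so the files stay plain text.

gifti_data_array <- function(values, intent, datatype) {
  dims <- dim(values)
  if (is.null(dims)) dims <- length(values)
  fmt <- if (datatype == "NIFTI_TYPE_INT32") "%d" else "%.9g"
  txt <- paste(apply(matrix(values, nrow = dims[1]), 1,
                     function(r) paste(sprintf(fmt, r), collapse = " ")),
               collapse = "\n")
  attrs <- c(Intent = intent, DataType = datatype,
             ArrayIndexingOrder = "RowMajorOrder",
             Dimensionality = as.character(length(dims)))
  for (i in seq_along(dims))
    attrs[paste0("Dim", i - 1)] <- as.character(dims[i])
  attrs["Encoding"] <- "ASCII"
  attrs["Endian"] <- "LittleEndian"
  list(attrs = attrs, text = txt)
}

write_gifti <- function(arrays, path) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = as.character(length(arrays)))
  for (arr in arrays) {
    node <- xml2::xml_add_child(doc, "DataArray")
    for (nm in names(arr$attrs)) xml2::xml_set_attr(node, nm, arr$attrs[[nm]])
    xml2::xml_add_child(node, "Data", arr$text)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_gifti_arrays <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- xml2::read_xml(path)
  lapply(xml2::xml_find_all(doc, ".//DataArray"), function(node) {
    enc <- xml2::xml_attr(node, "Encoding")
    if (!identical(enc, "ASCII"))
      stop(path, ": only ASCII-encoded GIFTI data arrays are supported, ",
           "found ", enc)
    ndim <- as.integer(xml2::xml_attr(node, "Dimensionality"))
    dims <- vapply(seq_len(ndim) - 1, function(i)
      as.integer(xml2::xml_attr(node, paste0("Dim", i))), integer(1))
    raw <- xml2::xml_text(xml2::xml_find_first(node, ".//Data"))
    vals <- scan(text = raw, quiet = TRUE)
    if (length(vals) != prod(dims))
      stop(path, ": data length ", length(vals), " does not match dims ",
           paste(dims, collapse = "x"))
    mat <- if (ndim == 2) matrix(vals, nrow = dims[1], byrow = TRUE)
           else vals
    list(intent = xml2::xml_attr(node, "Intent"),
         datatype = xml2::xml_attr(node, "DataType"),
         data = mat)
  })
}

#' Write a surface mesh as GIFTI files
#'
#' Writes the white-surface geometry, the spherical registration geometry
#' and the medial-wall label map as three GIFTI files (ASCII encoding).
#' Triangle indices are stored 0-based, per the format.
#'
#' @param mesh a `surface_mesh`.
#' @param geometry_path,sphere_path,label_path output paths (conventionally
#'   `*.surf.gii`, `*.surf.gii`, `*.label.gii`).
#' @return Invisibly, the three paths.
#' @export
write_mesh <- function(mesh, geometry_path, sphere_path, label_path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  geom <- function(coords, path) {
    write_gifti(list(
      gifti_data_array(coords, "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32"),
      gifti_data_array(mesh$faces - 1L, "NIFTI_INTENT_TRIANGLE",
                       "NIFTI_TYPE_INT32")), path)
  }
  geom(mesh$vertices, geometry_path)
  geom(mesh$sphere, sphere_path)
  write_gifti(list(
    gifti_data_array(as.integer(mesh$medial_wall), "NIFTI_INTENT_LABEL",
                     "NIFTI_TYPE_INT32")), label_path)
  invisible(c(geometry_path, sphere_path, label_path))
}

#' Read a surface mesh from GIFTI files
#'
#' Counterpart to [write_mesh()]. The two geometry files must have
#' identical vertex counts; sphere coordinates off unit norm by more than
#' 1e-3 are renormalized with a warning; a missing label file yields an
#' all-false medial wall with a warning.
#'
#' @param geometry_path,sphere_path GIFTI surface geometry files.
#' @param label_path GIFTI label file flagging medial-wall vertices, or a
#'   path that does not exist.
#' @return A `surface_mesh`.
#' @export
read_mesh <- function(geometry_path, sphere_path, label_path = NULL) {
  parse_geom <- function(path) {
    arrays <- read_gifti_arrays(path)
    pts <- NULL
    tri <- NULL
    for (a in arrays) {
      if (a$intent == "NIFTI_INTENT_POINTSET") pts <- a$data
      if (a$intent == "NIFTI_INTENT_TRIANGLE") tri <- a$data + 1L
    }
    if (is.null(pts) || is.null(tri))
      stop(path, ": not a GIFTI surface (needs POINTSET and TRIANGLE arrays)")
    list(pts = pts, tri = tri)
  }
  white <- parse_geom(geometry_path)
  sphere <- parse_geom(sphere_path)
  if (nrow(white$pts) != nrow(sphere$pts))
    stop("vertex-count mismatch: ", nrow(white$pts), " (white) vs ",
         nrow(sphere$pts), " (sphere)")
  norms <- sqrt(rowSums(sphere$pts^2))
  if (any(abs(norms - 1) > 1e-3)) {
    warning("sphere coordinates off unit norm by up to ",
            signif(max(abs(norms - 1)), 3), "; renormalizing")
  }
  sph <- sphere$pts / norms
  if (!is.null(label_path) && file.exists(label_path)) {
    lab <- read_gifti_arrays(label_path)[[1]]$data
    if (length(lab) != nrow(white$pts))
      stop("label file vertex count (", length(lab),
           ") does not match geometry (", nrow(white$pts), ")")
    medial <- lab != 0
  } else {
    warning("no medial-wall label file; assuming no medial wall")
    medial <- rep(FALSE, nrow(white$pts))
  }
  structure(list(vertices = white$pts, sphere = sph,
                 faces = matrix(as.integer(white$tri), ncol = 3),
                 medial_wall = medial),
            class = "surface_mesh")
}
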