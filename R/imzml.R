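# Minimal imzML reader/writer.
#
# imzML stores spectra metadata in an mzML-style XML file plus a side-car
# ".ibd" binary file holding the m/z and intensity arrays (referenced by
# byte offset). Two dialects exist: "continuous" (one shared m/z axis) and
# "processed" (per-pixel m/z axes). The writer emits uncompressed little-
# endian IEEE floats; the reader additionally understands 32-bit arrays as
# produced by other writers.

.IMS_CV <- c(
  uuid       = "IMS:1000080",
  continuous = "IMS:1000030",
  processed  = "IMS:1000031",
  pos_x      = "IMS:1000050",
  pos_y      = "IMS:1000051",
  offset     = "IMS:1000102",
  length     = "IMS:1000103",
  enc_length = "IMS:1000104",
  mz_array   = "MS:1000514",
  int_array  = "MS:1000515",
  f64        = "MS:1000523",
  f32        = "MS:1000521",
  no_comp    = "MS:1000576",
  zlib       = "MS:1000574"
)

.random_uuid <- function() {
  bytes <- as.raw(sample(0:255, 16, replace = TRUE))
  bytes[7] <- as.raw(bitwOr(bitwAnd(as.integer(bytes[7]), 0x0F), 0x40))
  bytes[9] <- as.raw(bitwOr(bitwAnd(as.integer(bytes[9]), 0x3F), 0x80))
  bytes
}

.uuid_string <- function(bytes) {
  hex <- paste(format(bytes), collapse = "")
  paste0("{", substr(hex, 1, 8), "-", substr(hex, 9, 12), "-",
         substr(hex, 13, 16), "-", substr(hex, 17, 20), "-",
         substr(hex, 21, 32), "}")
}

#' Write an MSI dataset as imzML
#'
#' Emits `<path>.imzML` plus the binary `<path>.ibd`. In `"processed"` mode
#' every pixel keeps its own m/z axis; `"continuous"` mode requires all
#' pixels to share an identical axis, which is then stored once. Arrays are
#' written as uncompressed little-endian 64-bit floats.
#'
#' @param dataset An `msi_dataset` tibble (columns `x`, `y`, `mz`,
#'   `intensity`).
#' @param path Output path; the `.imzML`/`.ibd` extensions are added.
#' @param mode `"processed"` (default) or `"continuous"`.
#' @return Invisibly, the `.imzML` path.
#' @export
write_imzml <- function(dataset, path, mode = c("processed", "continuous")) {
  mode <- match.arg(mode)
  if (!nrow(dataset)) stop("dataset is empty", call. = FALSE)
  path <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  ibd_path <- paste0(path, ".ibd")
  xml_path <- paste0(path, ".imzML")

  if (mode == "continuous") {
    axis <- dataset$mz[[1]]
    same <- vapply(dataset$mz, function(m) {
      length(m) == length(axis) && isTRUE(all.equal(m, axis, tolerance = 0))
    }, logical(1))
    if (!all(same)) {
      stop("continuous mode requires an identical m/z axis in every pixel",
           call. = FALSE)
    }
  }

  uuid <- .random_uuid()
  con <- file(ibd_path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(uuid, con)
  offset <- 16

  n <- nrow(dataset)
  mz_off <- integer(n); mz_len <- integer(n)
  int_off <- integer(n); int_len <- integer(n)
  if (mode == "continuous") {
    axis <- dataset$mz[[1]]
    writeBin(as.double(axis), con, size = 8, endian = "little")
    mz_off[] <- offset; mz_len[] <- length(axis)
    offset <- offset + 8 * length(axis)
  }
  for (i in seq_len(n)) {
    if (mode == "processed") {
      m <- dataset$mz[[i]]
      writeBin(as.double(m), con, size = 8, endian = "little")
      mz_off[i] <- offset; mz_len[i] <- length(m)
      offset <- offset + 8 * length(m)
    }
    y <- dataset$intensity[[i]]
    writeBin(as.double(y), con, size = 8, endian = "little")
    int_off[i] <- offset; int_len[i] <- length(y)
    offset <- offset + 8 * length(y)
  }

  cv <- function(acc, name, value = "") {
    ref <- if (startsWith(acc, "IMS")) "IMS" else "MS"
    sprintf('<cvParam cvRef="%s" accession="%s" name="%s" value="%s"/>',
            ref, acc, name, value)
  }
  spectra <- vapply(seq_len(n), function(i) {
    paste0(
      sprintf('<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
              i - 1L, i, int_len[i]),
      '<scanList count="1"><scan>',
      cv(.IMS_CV[["pos_x"]], "position x", dataset$x[i] + 1L),
      cv(.IMS_CV[["pos_y"]], "position y", dataset$y[i] + 1L),
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      cv(.IMS_CV[["offset"]], "external offset", mz_off[i]),
      cv(.IMS_CV[["length"]], "external array length", mz_len[i]),
      cv(.IMS_CV[["enc_length"]], "external encoded length", 8L * mz_len[i]),
      '<binary/></binaryDataArray>',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      cv(.IMS_CV[["offset"]], "external offset", int_off[i]),
      cv(.IMS_CV[["length"]], "external array length", int_len[i]),
      cv(.IMS_CV[["enc_length"]], "external encoded length", 8L * int_len[i]),
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'
    )
  }, character(1))

  mode_acc <- if (mode == "continuous") .IMS_CV[["continuous"]] else .IMS_CV[["processed"]]
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    cv(mode_acc, mode),
    cv(.IMS_CV[["uuid"]], "universally unique identifier", .uuid_string(uuid)),
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    cv(.IMS_CV[["mz_array"]], "m/z array"),
    cv(.IMS_CV[["f64"]], "64-bit float"),
    cv(.IMS_CV[["no_comp"]], "no compression"),
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    cv(.IMS_CV[["int_array"]], "intensity array"),
    cv(.IMS_CV[["f64"]], "64-bit float"),
    cv(.IMS_CV[["no_comp"]], "no compression"),
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    sprintf('<run id="run1"><spectrumList count="%d">', n),
    paste(spectra, collapse = ""),
    '</spectrumList></run></mzML>'
  )
  writeLines(xml, xml_path)
  invisible(xml_path)
}

# collect accession -> value map for a node's cvParams (+ referenced groups)
.cv_map <- function(node, groups) {
  params <- xml2::xml_find_all(node, "./*[local-name()='cvParam']")
  acc <- xml2::xml_attr(params, "accession")
  val <- xml2::xml_attr(params, "value")
  refs <- xml2::xml_find_all(node, "./*[local-name()='referenceableParamGroupRef']")
  for (r in xml2::xml_attr(refs, "ref")) {
    g <- groups[[r]]
    if (!is.null(g)) { acc <- c(acc, g$acc); val <- c(val, g$val) }
  }
  stats::setNames(val, acc)
}

#' Read an imzML file into an MSI dataset
#'
#' Understands both the continuous and processed dialects, 32- and 64-bit
#' uncompressed float arrays, and the referenceable-param-group indirection
#' used by common writers.
#'
#' @param path Path to the `.imzML` file (the `.ibd` must sit next to it).
#' @return An `msi_dataset` tibble with columns `x`, `y` (0-based), `mz`,
#'   `intensity`.
#' @export
read_imzml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ibd_path <- paste0(sub("\\.imzML$", "", path, ignore.case = TRUE), ".ibd")
  if (!file.exists(ibd_path)) stop("missing binary file: ", ibd_path, call. = FALSE)
  doc <- xml2::read_xml(path)

  group_nodes <- xml2::xml_find_all(doc, "//*[local-name()='referenceableParamGroup']")
  groups <- lapply(group_nodes, function(g) {
    params <- xml2::xml_find_all(g, "./*[local-name()='cvParam']")
    list(acc = xml2::xml_attr(params, "accession"),
         val = xml2::xml_attr(params, "value"))
  })
  names(groups) <- xml2::xml_attr(group_nodes, "id")

  file_cv <- xml2::xml_attr(
    xml2::xml_find_all(doc, "//*[local-name()='fileContent']/*[local-name()='cvParam']"),
    "accession")
  mode <- if (.IMS_CV[["continuous"]] %in% file_cv) "continuous" else "processed"

  spectra <- xml2::xml_find_all(doc, "//*[local-name()='spectrum']")
  if (!length(spectra)) stop("no spectra found in ", path, call. = FALSE)
  con <- file(ibd_path, "rb")
  on.exit(close(con), add = TRUE)

  read_array <- function(cvm, what_pixel) {
    need <- c("offset", "length")
    accs <- .IMS_CV[need]
    if (!all(accs %in% names(cvm))) {
      stop("malformed imzML: missing external offset/length for pixel ",
           what_pixel, call. = FALSE)
    }
    if (.IMS_CV[["zlib"]] %in% names(cvm)) {
      stop("compressed binary arrays are not supported (pixel ", what_pixel, ")",
           call. = FALSE)
    }
    size <- if (.IMS_CV[["f32"]] %in% names(cvm)) 4L else 8L
    off <- as.numeric(cvm[[.IMS_CV[["offset"]]]])
    len <- as.integer(cvm[[.IMS_CV[["length"]]]])
    seek(con, where = off, origin = "start")
    readBin(con, what = "double", n = len, size = size, endian = "little")
  }

  n <- length(spectra)
  xs <- integer(n); ys <- integer(n)
  mzs <- vector("list", n); ints <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spectra[[i]]
    scan <- xml2::xml_find_first(sp, ".//*[local-name()='scan']")
    scvm <- .cv_map(scan, groups)
    if (!all(.IMS_CV[c("pos_x", "pos_y")] %in% names(scvm))) {
      stop("malformed imzML: missing pixel position for spectrum ", i, call. = FALSE)
    }
    xs[i] <- as.integer(scvm[[.IMS_CV[["pos_x"]]]]) - 1L
    ys[i] <- as.integer(scvm[[.IMS_CV[["pos_y"]]]]) - 1L
    arrays <- xml2::xml_find_all(sp, ".//*[local-name()='binaryDataArray']")
    got_mz <- FALSE; got_int <- FALSE
    for (arr in arrays) {
      cvm <- .cv_map(arr, groups)
      if (.IMS_CV[["mz_array"]] %in% names(cvm)) {
        mzs[[i]] <- read_array(cvm, i); got_mz <- TRUE
      } else if (.IMS_CV[["int_array"]] %in% names(cvm)) {
        ints[[i]] <- read_array(cvm, i); got_int <- TRUE
      }
    }
    if (!got_mz || !got_int) {
      stop("malformed imzML: spectrum ", i, " lacks m/z or intensity array",
           call. = FALSE)
    }
  }

  dataset <- tibble::tibble(x = xs, y = ys, mz = mzs, intensity = ints)
  attr(dataset, "mode") <- mode
  attr(dataset, "dims") <- c(height = max(ys) + 1L, width = max(xs) + 1L)
  class(dataset) <- c("msi_dataset", class(dataset))
  dataset
}
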