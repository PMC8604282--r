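#' Pascal VOC XML annotations
#'
#' Annotations are tibbles with columns `class` (one of `"grass"`,
#' `"broadleaf"`), `x1, y1, x2, y2` (0-based half-open pixel boxes). On disk
#' they use Pascal VOC's 1-based inclusive convention (the format emitted by
#' LabelImg); the conversion happens only here: internal `(x1, y1, x2, y2)`
#' maps to VOC `(x1 + 1, y1 + 1, x2, y2)` and back.
#'
#' @name voc
NULL

weed_classes <- c("grass", "broadleaf")

#' Write annotations for one image as Pascal VOC XML
#'
#' @param annotations tibble with columns `class, x1, y1, x2, y2`.
#' @param path output `.xml` path.
#' @param image_size `c(width, height)` in pixels.
#' @param filename image file name recorded in the XML.
#' @export
write_voc_annotations <- function(annotations, path, image_size,
                                  filename = "image.png") {
  stopifnot(length(image_size) == 2L)
  bad <- setdiff(unique(annotations$class), weed_classes)
  if (length(bad)) stop("write_voc_annotations(): unknown class: ", paste(bad, collapse = ", "))
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", filename)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(image_size[1]))
  xml2::xml_add_child(size, "height", as.character(image_size[2]))
  xml2::xml_add_child(size, "depth", "3")
  if (nrow(annotations)) {
    for (i in seq_len(nrow(annotations))) {
      ob <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(ob, "name", annotations$class[i])
      xml2::xml_add_child(ob, "difficult", "0")
      bb <- xml2::xml_add_child(ob, "bndbox")
      xml2::xml_add_child(bb, "xmin", as.character(annotations$x1[i] + 1))
      xml2::xml_add_child(bb, "ymin", as.character(annotations$y1[i] + 1))
      xml2::xml_add_child(bb, "xmax", as.character(annotations$x2[i]))
      xml2::xml_add_child(bb, "ymax", as.character(annotations$y2[i]))
    }
  }
  tryCatch(xml2::write_xml(doc, path),
           error = function(e) stop("write_voc_annotations(): cannot write ", path,
                                    ": ", conditionMessage(e)))
  invisible(path)
}

#' Read one Pascal VOC XML annotation file
#'
#' @param path `.xml` path.
#' @return a list with `annotations` (tibble `class, x1, y1, x2, y2`, 0-based
#'   half-open) and `image_size` (`c(width, height)`).
#' @export
read_voc_annotations <- function(path) {
  if (!file.exists(path)) stop("read_voc_annotations(): no such file: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("read_voc_annotations(): malformed XML in ",
                                           path, ": ", conditionMessage(e)))
  w <- as.integer(xml2::xml_text(xml2::xml_find_first(doc, "./size/width")))
  h <- as.integer(xml2::xml_text(xml2::xml_find_first(doc, "./size/height")))
  if (is.na(w) || is.na(h)) stop("read_voc_annotations(): missing <size> in ", path)
  objs <- xml2::xml_find_all(doc, "./object")
  rows <- purrr::map(objs, function(ob) {
    name_node <- xml2::xml_find_first(ob, "./name")
    cls <- xml2::xml_text(name_node)
    if (is.na(cls) || !nzchar(cls)) {
      stop("read_voc_annotations(): <object> without <name> class in ", path)
    }
    num <- function(field) {
      v <- as.numeric(xml2::xml_text(xml2::xml_find_first(ob, paste0("./bndbox/", field))))
      if (is.na(v)) stop("read_voc_annotations(): missing <bndbox>/<", field, "> in ", path)
      v
    }
    tibble::tibble(class = cls,
                   x1 = num("xmin") - 1, y1 = num("ymin") - 1,
                   x2 = num("xmax"), y2 = num("ymax"))
  })
  ann <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(class = character(0), x1 = numeric(0), y1 = numeric(0),
                   x2 = numeric(0), y2 = numeric(0))
  bad <- setdiff(unique(ann$class), weed_classes)
  if (length(bad)) stop("read_voc_annotations(): unknown class '", bad[1], "' in ", path)
  list(annotations = ann, image_size = c(w, h))
}

#' Read / write detections as JSON lines
#'
#' One JSON object per line with fields `image_id, class, x1, y1, x2, y2,
#' score, branch` — the interchange format between the detection, ensemble
#' and evaluation stages.
#'
#' @param detections detections tibble.
#' @param path `.jsonl` path.
#' @export
write_detections_jsonl <- function(detections, path) {
  con <- file(path, "w"); on.exit(close(con))
  if (nrow(detections)) {
    lines <- vapply(seq_len(nrow(detections)), function(i) {
      jsonlite::toJSON(as.list(detections[i, ]), auto_unbox = TRUE, digits = NA)
    }, character(1))
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_detections_jsonl
#' @export
read_detections_jsonl <- function(path) {
  if (!file.exists(path)) stop("read_detections_jsonl(): no such file: ", path)
  lines <- readLines(path)
  if (!length(lines)) {
    return(tibble::tibble(image_id = character(0), class = character(0),
                          x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                          y2 = numeric(0), score = numeric(0), branch = character(0)))
  }
  dplyr::bind_rows(purrr::map(lines, function(l) {
    tibble::as_tibble(jsonlite::fromJSON(l))
  }))
}
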