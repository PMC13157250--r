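# File I/O: multi-page TIFF movies, ROI label images, configs, result
# bundles. Integer movies (values 0..65535) are stored as uint16 pages and
# round-trip bit-exactly; other data are stored as normalized float32 pages
# with the affine scale recorded in a JSON sidecar (<path>.scale.json).

scale_sidecar <- function(path) paste0(path, ".scale.json")

# Write a list of H x W numeric matrices as a multi-page TIFF.
write_stack <- function(pages, path) {
  vals <- unlist(pages, use.names = FALSE)
  is_u16 <- all(vals == round(vals)) && min(vals) >= 0 && max(vals) <= 65535
  if (is_u16) {
    tiff::writeTIFF(lapply(pages, function(p) p / 65535), path,
                    bits.per.sample = 16L, compression = "none")
    if (file.exists(scale_sidecar(path))) file.remove(scale_sidecar(path))
  } else {
    mn <- min(vals); mx <- max(vals)
    span <- if (mx > mn) mx - mn else 1
    suppressWarnings(
      tiff::writeTIFF(lapply(pages, function(p) (p - mn) / span), path,
                      bits.per.sample = 32L, compression = "none"))
    jsonlite::write_json(list(min = mn, max = mx),
                         scale_sidecar(path), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# Read a multi-page TIFF back as a list of numeric matrices, undoing the
# sidecar scaling when present. Integer (<= 16 bit) pages come back as the
# stored integers; 32-bit pages are taken as float samples.
read_stack <- function(path) {
  check_that(file.exists(path), "file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  check_that(length(unique(lapply(pages, dim))) == 1,
             "TIFF pages of '%s' differ in size", path)
  pages <- lapply(pages, function(p) {
    bits <- attr(p, "bits.per.sample")
    if (length(dim(p)) == 3) p <- p[, , 1]  # tolerate single-channel RGB
    # readTIFF maps integer samples onto [0, 1]; undo to raw counts
    if (!is.null(bits) && bits <= 16) p <- round(p * (2^bits - 1))
    matrix(as.numeric(p), nrow(p), ncol(p))
  })
  sc <- scale_sidecar(path)
  if (file.exists(sc)) {
    s <- jsonlite::read_json(sc, simplifyVector = TRUE)
    span <- if (s$max > s$min) s$max - s$min else 1
    pages <- lapply(pages, function(p) p * span + s$min)
  }
  pages
}

#' Read a movie from a multi-page TIFF
#'
#' Pages are taken in file order: page k becomes frame k (0-based); pixel
#' values are preserved bit-exactly for integer (uint8/uint16) input.
#'
#' @param path path to a multi-page TIFF with at least two equally sized pages.
#' @param meta an [acquisition_meta()] describing the recording.
#' @return a [gevi_movie()].
#' @export
read_movie <- function(path, meta) {
  pages <- read_stack(path)
  check_that(length(pages) >= 2,
             "'%s' has %d page(s); a movie needs at least 2", path, length(pages))
  d <- dim(pages[[1]])
  frames <- array(unlist(pages, use.names = FALSE), dim = c(d[1], d[2], length(pages)))
  gevi_movie(frames, meta)
}

#' Write a movie to a multi-page TIFF
#'
#' Integer-valued movies within 0..65535 are written as uint16 and round-trip
#' bit-exactly; other movies are written as scaled float32 with a JSON
#' sidecar recording the intensity range.
#'
#' @param movie a [gevi_movie()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_movie <- function(movie, path) {
  check_that(inherits(movie, "gevi_movie"), "movie must be a gevi_movie")
  pages <- lapply(seq_len(n_frames(movie)), function(t) movie$frames[, , t])
  write_stack(pages, path)
  invisible(path)
}

#' Read an ROI set from a label image or JSON pixel lists
#'
#' A label-image TIFF uses 0 for background and integer k for ROI k; masks
#' are returned with stringified labels in ascending numeric order. A `.json`
#' file must hold a list of objects `{label, pixels}` where `pixels` is a
#' list of 0-based `[row, col]` pairs.
#'
#' @param path path to a label TIFF or JSON file.
#' @param kind passed to [roi_set()].
#' @return an [roi_set()].
#' @export
read_roiset <- function(path, kind = "neuron") {
  check_that(file.exists(path), "file not found: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    entries <- jsonlite::read_json(path, simplifyVector = FALSE)
    labs <- vapply(entries, function(e) as.character(e$label), character(1))
    check_that(!anyDuplicated(labs), "duplicate ROI labels in '%s'", path)
    all_px <- lapply(entries, function(e) {
      do.call(rbind, lapply(e$pixels, function(p) as.integer(unlist(p))))
    })
    hw <- c(max(vapply(all_px, function(p) max(p[, 1]), integer(1))) + 1L,
            max(vapply(all_px, function(p) max(p[, 2]), integer(1))) + 1L)
    masks <- lapply(all_px, function(p) {
      m <- matrix(FALSE, hw[1], hw[2])
      m[p + 1L] <- TRUE  # 0-based (row, col) pairs
      m
    })
    names(masks) <- labs
    return(roi_set(masks, kind = kind))
  }
  lab_img <- read_stack(path)[[1]]
  lab_img <- round(lab_img)
  labs <- sort(unique(lab_img[lab_img > 0]))
  check_that(length(labs) > 0, "label image '%s' has no nonzero pixels", path)
  masks <- lapply(labs, function(k) lab_img == k)
  names(masks) <- as.character(labs)
  roi_set(masks, kind = kind)
}

#' Write an ROI set as a label-image TIFF
#'
#' ROI k (in the set's order) is painted with label k; overlapping masks are
#' rejected since a label image cannot represent them.
#'
#' @param roiset an [roi_set()].
#' @param path output TIFF path.
#' @return the path, invisibly.
#' @export
write_roiset <- function(roiset, path) {
  check_that(inherits(roiset, "roi_set"), "roiset must be an roi_set")
  d <- dim(roiset$masks[[1]])
  overlap <- Reduce(`+`, lapply(roiset$masks, function(m) m * 1L))
  check_that(max(overlap) <= 1L, "overlapping ROIs cannot be written as a label image")
  img <- matrix(0L, d[1], d[2])
  for (k in seq_along(roiset$masks)) img[roiset$masks[[k]]] <- k
  write_stack(list(img), path)
  invisible(path)
}

#' Read or write a pipeline configuration (YAML or JSON by extension)
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  check_that(file.exists(path), "file not found: %s", path)
  lst <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(lst$exclude_frames)) {
    lst$exclude_frames <- as.integer(unlist(lst$exclude_frames))
  }
  do.call(pipeline_config, lst)
}

#' @rdname read_config
#' @param cfg a [pipeline_config()].
#' @export
write_config <- function(cfg, path) {
  check_that(inherits(cfg, "pipeline_config"), "cfg must be a pipeline_config")
  lst <- unclass(cfg)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
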