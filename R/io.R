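# File formats: multi-page TIFF image stacks, hull tables, and the
# ground-truth / kinematics CSVs.

#' Read a per-camera image stack
#'
#' Accepts a multi-page TIFF file or a directory of per-frame PNG/TIFF
#' images (sorted by file name).
#'
#' @param path file or directory.
#' @return numeric array `height x width x frames` in [0, 1].
#' @export
read_image_stack <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no PNG/TIFF frames in ", path)
    pages <- lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE)) {
        png::readPNG(f)
      } else {
        tiff::readTIFF(f)
      }
    })
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]   # first channel
    p
  })
  array(unlist(pages), c(dim(pages[[1]]), length(pages)))
}

#' Write a binary or grayscale stack as multi-page TIFF
#'
#' @param stack array `height x width x frames` (logical or numeric 0-1).
#' @param path output file.
#' @export
write_image_stack <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack)[3]), function(f) {
    m <- stack[, , f]
    storage.mode(m) <- "double"
    m
  })
  tiff::writeTIFF(pages, path)
  invisible(path)
}

#' Serialize hulls to a tabular voxel-index file
#'
#' One gzip-compressed CSV of voxel indices (columns: label, i, j, k) with
#' a one-line JSON header carrying the grid origin, pitch and dims.
#'
#' @param hulls named list of `hull` objects sharing one grid.
#' @param path output file (conventionally `.csv.gz`).
#' @export
write_hulls <- function(hulls, path) {
  g <- hulls[[1]]$grid
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", jsonlite::toJSON(
    list(origin = g$origin, pitch = g$pitch, dims = g$dims),
    digits = NA)), con)
  tab <- do.call(rbind, lapply(names(hulls), function(nm) {
    idx <- hull_indices(hulls[[nm]])
    if (!nrow(idx)) return(NULL)
    data.frame(label = nm, i = idx[, 1], j = idx[, 2], k = idx[, 3])
  }))
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' Read hulls written by [write_hulls()]
#'
#' @param path input file.
#' @return named list of `hull` objects.
#' @export
read_hulls <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  hdr <- readLines(con, n = 1)
  meta <- jsonlite::fromJSON(sub("^#", "", hdr))
  g <- voxel_grid(meta$origin, meta$pitch, meta$dims)
  tab <- utils::read.csv(con)
  out <- lapply(split(tab, tab$label), function(d) {
    hull(g, as.matrix(d[, c("i", "j", "k")]))
  })
  out
}

#' Write the ground-truth table of a pose sequence
#'
#' One row per frame: time, body CM, body angles and per-wing Euler angles.
#'
#' @param seq a `pose_sequence`.
#' @param path output CSV.
#' @export
write_truth_csv <- function(seq, path) {
  utils::write.csv(sequence_truth(seq), path, row.names = FALSE)
  invisible(path)
}

#' Write a kinematics table and its wingbeat summary
#'
#' @param result a `flyhull_result` from [run_pipeline()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_result_csvs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$kinematics, file.path(dir, "kinematics.csv"),
                   row.names = FALSE)
  if (nrow(result$wingbeats)) {
    utils::write.csv(result$wingbeats, file.path(dir, "wingbeats.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
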