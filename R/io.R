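## Plain-text readers/writers for the pipeline's external formats.

#' Read and write Transwell series CSV files
#'
#' The on-disk format is a CSV with columns `time_min` and `lower_conc_uM`;
#' the assay geometry travels separately as a YAML file with the
#' [assayGeometry()] field names (`membraneArea`, `lowerVolume`,
#' `upperVolume`, `upperConc`, `sampleVolume`, `sampleInterval`,
#' `duration`).
#'
#' @param path CSV file path.
#' @param geometry an [AssayGeometry-class], or a path to a geometry YAML.
#' @param series a [TranswellSeries-class] to write.
#' @return `readTranswellSeries` returns a [TranswellSeries-class];
#'   `writeTranswellSeries` returns `path` invisibly.
#' @export
readTranswellSeries <- function(path, geometry) {
  if (is.character(geometry)) geometry <- readAssayGeometry(geometry)
  df <- utils::read.csv(path)
  stopifnot(all(c("time_min", "lower_conc_uM") %in% names(df)))
  transwellSeries(df$time_min, df$lower_conc_uM, geometry)
}

#' @rdname readTranswellSeries
#' @export
writeTranswellSeries <- function(series, path) {
  utils::write.csv(data.frame(time_min = series@times,
                              lower_conc_uM = series@lowerConc),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname readTranswellSeries
#' @export
readAssayGeometry <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(assayGeometry, y)
}

#' Read a TEER readings CSV
#'
#' Expected columns: `sample_id`, `total_ohm`, `blank_ohm`.
#'
#' @param path CSV file path.
#' @return A data.frame of raw paired readings.
#' @export
readTeerReadings <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("sample_id", "total_ohm", "blank_ohm") %in% names(df)))
  df
}

#' Read a gene x sample count matrix from TSV
#'
#' First column `gene_id`, remaining columns one per sample.
#'
#' @param path TSV file path.
#' @param groups optional group labels (one per sample column) to attach.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts` (and `colData$group` when `groups` is given).
#' @export
readCountsTsv <- function(path, groups = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  stopifnot(names(df)[1L] == "gene_id")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene_id
  cd <- if (is.null(groups)) S4Vectors::DataFrame(row.names = colnames(m))
        else S4Vectors::DataFrame(group = factor(groups, c("WT", "DEL")),
                                  row.names = colnames(m))
  SummarizedExperiment::SummarizedExperiment(assays = list(counts = m),
                                             colData = cd)
}

#' Read an edge-list network with node annotations
#'
#' @param edgePath two-column TSV (header `from`, `to`) of undirected
#'   interactions.
#' @param annotPath optional TSV with columns `node_id`, `log2fc`,
#'   `in_deletion` (0/1 or TRUE/FALSE).
#' @return An [igraph::graph] with any annotations attached as vertex
#'   attributes.
#' @export
readEdgeList <- function(edgePath, annotPath = NULL) {
  el <- utils::read.delim(edgePath, colClasses = "character")
  stopifnot(all(c("from", "to") %in% names(el)))
  g <- igraph::graph_from_data_frame(el[, c("from", "to")], directed = FALSE)
  g <- igraph::simplify(g)
  if (!is.null(annotPath)) {
    an <- utils::read.delim(annotPath)
    stopifnot(all(c("node_id", "log2fc", "in_deletion") %in% names(an)))
    idx <- match(igraph::V(g)$name, an$node_id)
    igraph::V(g)$log2fc <- an$log2fc[idx]
    igraph::V(g)$in_deletion <- as.logical(an$in_deletion[idx])
  }
  g
}

#' Write a network as an edge-list TSV (plus node annotations)
#'
#' @param net an [igraph::graph].
#' @param edgePath output TSV path for the edges.
#' @param annotPath optional output TSV path for `node_id`, `log2fc`,
#'   `in_deletion`.
#' @return `edgePath`, invisibly.
#' @export
writeEdgeList <- function(net, edgePath, annotPath = NULL) {
  el <- igraph::as_edgelist(net)
  utils::write.table(data.frame(from = el[, 1L], to = el[, 2L]), edgePath,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotPath)) {
    utils::write.table(
      data.frame(node_id = igraph::V(net)$name,
                 log2fc = igraph::V(net)$log2fc %||% NA,
                 in_deletion = igraph::V(net)$in_deletion %||% NA),
      annotPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(edgePath)
}

#' Read and write image stacks as multi-page TIFF
#'
#' Requires the `tiff` package. Intensities are stored as 32-bit floats
#' scaled by `scale` (TIFF stores \[0, 1\]).
#'
#' @param stack an [ImageStack-class].
#' @param path TIFF file path.
#' @param pixelSize,zStep,channel metadata to attach on read.
#' @param scale intensity scale: voxel values are divided by `scale` on
#'   write and multiplied back on read.
#' @return `readImageStack` returns an [ImageStack-class].
#' @export
writeImageStack <- function(stack, path, scale = 2^16) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required for TIFF I/O")
  vox <- voxels(stack)
  pages <- lapply(seq_len(dim(vox)[1L]), function(z) vox[z, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname writeImageStack
#' @export
readImageStack <- function(path, pixelSize, zStep = 0.2,
                           channel = "unlabeled", scale = 2^16) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required for TIFF I/O")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  vox <- array(0, dim = c(length(pages), ny, nx))
  for (z in seq_along(pages)) vox[z, , ] <- pages[[z]] * scale
  imageStack(vox, pixelSize = pixelSize, zStep = zStep, channel = channel)
}

#' Read junction segments from CSV
#'
#' On disk, segment endpoints are 0-based pixel-center coordinates
#' (`x0,y0,x1,y1`); in R they are used 1-based, so 1 is added on read.
#'
#' @param path CSV path.
#' @return A data.frame with 1-based columns `x0, y0, x1, y1`.
#' @export
readSegmentsCsv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x0", "y0", "x1", "y1") %in% names(df)))
  df$x0 <- df$x0 + 1; df$x1 <- df$x1 + 1
  df$y0 <- df$y0 + 1; df$y1 <- df$y1 + 1
  df
}
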