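#' Lateral tongue-deviation percentages
#'
#' During shelf elevation the tongue can deviate laterally, with one shelf
#' already horizontal while the contralateral one is still vertical. Given
#' per-direction embryo counts (left deviation = left shelf vertical with
#' right shelf horizontal, and vice versa), returns the percentage of
#' deviated embryos in each direction.
#'
#' @param nLeft embryos with left deviation (left shelf vertical, right
#'   horizontal).
#' @param nRight embryos with right deviation (right shelf vertical, left
#'   horizontal).
#' @return data.frame with columns \code{direction}, \code{n},
#'   \code{percent} (of all deviated embryos).
#' @examples
#' lateralDeviationStats(7, 8)
#' @export
lateralDeviationStats <- function(nLeft, nRight) {
  stopifnot(nLeft >= 0, nRight >= 0, nLeft + nRight > 0)
  total <- nLeft + nRight
  data.frame(direction = c("left", "right"),
             n = c(nLeft, nRight),
             percent = 100 * c(nLeft, nRight) / total)
}

#' Read and validate a pipeline configuration
#'
#' Configurations are YAML with the per-stage keys listed below; every
#' parameter defaults to the reconstruction pipeline's standard value
#' (15 x 15 filter window, threshold 0.5, 8-connectivity, 7 um sections).
#' Either an \code{input} block (directory of section images + required
#' \code{pixel_size_um}) or a \code{phantom} block (preset stage, seed,
#' size factor) must be present.
#'
#' @param path YAML file.
#' @return A validated config list (class "palate3DConfig").
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validatePipelineConfig(yaml::read_yaml(path))
}

#' @rdname readPipelineConfig
#' @param config a config list (as from \code{yaml::read_yaml}).
#' @export
validatePipelineConfig <- function(config) {
  defaults <- list(
    section_thickness_um = 7, filter_window = 15, threshold = 0.5,
    invert = FALSE, connectivity = 8, min_area_px = 64,
    reference = "middle", max_rot_deg = 10, smooth_iterations = 10,
    spike_iqr_factor = 3, export_format = "both", keep_top_k = 1)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  hasInput <- !is.null(config$input)
  hasPhantom <- !is.null(config$phantom)
  if (!hasInput && !hasPhantom)
    stop("config error: need an 'input' or a 'phantom' block")
  if (hasInput) {
    if (is.null(config$input$dir) || !dir.exists(config$input$dir))
      stop("config error: input dir missing or not found: ",
           config$input$dir)
    if (is.null(config$input$pixel_size_um))
      stop("config error: input.pixel_size_um is required (um per pixel)")
    if (!is.null(config$input$manifest) &&
        !file.exists(config$input$manifest))
      stop("config error: manifest not found: ", config$input$manifest)
  }
  if (hasPhantom) {
    if (is.null(config$phantom$stage)) config$phantom$stage <- "elevating"
    if (is.null(config$phantom$seed)) config$phantom$seed <- 1L
    if (is.null(config$phantom$size_factor))
      config$phantom$size_factor <- 0.25
  }
  structure(config, class = "palate3DConfig")
}

.logStage <- function(logCon, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  if (!is.null(logCon)) writeLines(line, logCon)
}

#' Run the full reconstruction pipeline
#'
#' Executes, in order: stack loading (or phantom rendering), optional ROI
#' extraction, per-slice segmentation, rigid stack alignment, voxel volume
#' assembly with volume measurement, and surface meshing with spike
#' removal, smoothing and STL/PLY export. All artifacts are written under
#' \code{outDir}: the per-slice QC table (\code{mask_qc.csv}), the
#' transform table (\code{transforms.csv}), the volume report
#' (\code{volume_report.csv}), mesh files, and a machine-readable run
#' manifest (\code{manifest.json}: config echo plus MD5 checksums of every
#' artifact). Stage progress goes to stderr and \code{run.log}; artifacts
#' never go to stdout. Rerunning with an identical config reproduces
#' identical artifact checksums.
#'
#' @param config a config list or "palate3DConfig" (see
#'   \code{\link{readPipelineConfig}}).
#' @param outDir output directory (created if absent).
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config, outDir) {
  if (!inherits(config, "palate3DConfig"))
    config <- validatePipelineConfig(config)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  logCon <- file(file.path(outDir, "run.log"), "w")
  on.exit(close(logCon))
  artifacts <- character(0)

  truth <- NULL
  if (!is.null(config$phantom)) {
    .logStage(logCon, "load", sprintf("rendering phantom '%s', seed %d",
                                      config$phantom$stage,
                                      config$phantom$seed))
    spec <- embryoPreset(config$phantom$stage,
                         sizeFactor = config$phantom$size_factor,
                         seed = config$phantom$seed)
    truth <- buildTruth(spec)
    stack <- renderStack(truth, spec)
  } else {
    ord <- if (!is.null(config$input$manifest)) "manifest" else "name"
    paths <- orderStackFiles(config$input$dir, order = ord,
                             manifest = config$input$manifest)
    .logStage(logCon, "load", sprintf("%d section images", length(paths)))
    stack <- loadStack(paths, pixelSize = config$input$pixel_size_um,
                       thickness = config$section_thickness_um)
  }

  if (!is.null(config$roi)) {
    roi <- roiSpec(config$roi$row, config$roi$col, config$roi$height,
                   config$roi$width)
    .logStage(logCon, "roi", sprintf("cropping to %d x %d", roi@height,
                                     roi@width))
    stack <- extractRoi(stack, roi)
  }

  .logStage(logCon, "segment", sprintf("%d slices", nSlices(stack)))
  masks <- segmentStack(stack, window = config$filter_window,
                        threshold = config$threshold,
                        invert = config$invert,
                        connectivity = config$connectivity,
                        minAreaPx = config$min_area_px)
  qc <- maskQC(masks)
  p <- file.path(outDir, "mask_qc.csv")
  utils::write.csv(qc, p, row.names = FALSE)
  artifacts <- c(artifacts, p)
  if (all(qc$degenerate))
    stop("stage 'segment' failed: every slice is degenerate")

  .logStage(logCon, "register", "aligning stack")
  aligned <- alignStack(masks, reference = config$reference,
                        thickness = sectionThickness(stack),
                        maxRotDeg = config$max_rot_deg)
  p <- file.path(outDir, "transforms.csv")
  utils::write.csv(transformTable(aligned), p, row.names = FALSE)
  artifacts <- c(artifacts, p)

  .logStage(logCon, "reconstruct", "assembling labeled volume")
  vol <- assembleVolume(aligned)
  rep <- volumeReport(vol)
  p <- file.path(outDir, "volume_report.csv")
  utils::write.csv(rep, p, row.names = FALSE)
  artifacts <- c(artifacts, p)

  .logStage(logCon, "mesh", "extracting, cleaning and smoothing surface")
  mesh <- extractSurface(vol, label = 1L, color = "gray")
  mesh <- removeSpikes(mesh, iqrFactor = config$spike_iqr_factor)
  mesh <- smoothMesh(mesh, iterations = config$smooth_iterations)
  fmt <- config$export_format
  if (fmt %in% c("stl", "both")) {
    p <- file.path(outDir, "cavity.stl")
    exportMesh(mesh, p, "stl")
    artifacts <- c(artifacts, p)
  }
  if (fmt %in% c("ply", "both")) {
    p <- file.path(outDir, "cavity.ply")
    exportMesh(mesh, p, "ply")
    artifacts <- c(artifacts, p)
  }

  manifest <- list(
    config = unclass(config),
    n_slices = nSlices(stack),
    cavity_volume_um3 = measureVolume(vol, 1L),
    mesh_volume_um3 = meshVolume(mesh),
    artifacts = lapply(stats::setNames(artifacts, basename(artifacts)),
                       function(f) unname(tools::md5sum(f))))
  if (!is.null(truth))
    manifest$truth_cavity_volume_um3 <-
      measureVolume(truth@volume, seq_along(spec@shapes))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .logStage(logCon, "done", sprintf("%d artifacts in %s",
                                    length(artifacts) + 1L, outDir))
  invisible(manifest)
}
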