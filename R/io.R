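## File formats: PDB/DCD trajectories (via bio3d), self-describing JSON
## paths, CSV sample series and profiles, YAML anchor specs and campaign
## configs. All artifact files use 0-based atom indexing (PDB serials are
## mapped on read); coordinates are Angstrom everywhere.

#' Read a topology + trajectory into snapshots
#'
#' @param topology Path to a PDB file defining the atom count.
#' @param trajectory Path to a DCD file or a (multi-model) PDB file; when
#'   NULL the topology's own models are used.
#' @return List of n x 3 coordinate matrices (Angstrom), one per frame,
#'   with attribute `nAtoms`.
#' @export
readSystem <- function(topology, trajectory = NULL) {
  if (!file.exists(topology))
    stop(sprintf("cannot read topology '%s'", topology), call. = FALSE)
  top <- bio3d::read.pdb(topology, verbose = FALSE)
  nAtoms <- nrow(top$atom)
  if (is.null(trajectory)) trajectory <- topology
  if (!file.exists(trajectory))
    stop(sprintf("cannot read trajectory '%s'", trajectory), call. = FALSE)
  ext <- tolower(tools::file_ext(trajectory))
  xyz <- if (ext == "dcd") {
    bio3d::read.dcd(trajectory, verbose = FALSE)
  } else {
    checkMultiModelPDB(trajectory, nAtoms)
    m <- bio3d::read.pdb(trajectory, multi = TRUE, verbose = FALSE)
    m$xyz
  }
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 * nAtoms)
    stop(sprintf("atom-count mismatch: topology has %d atoms but trajectory frames have %d",
                 nAtoms, ncol(xyz) / 3), call. = FALSE)
  frames <- lapply(seq_len(nrow(xyz)), function(i) unflattenCoords(xyz[i, ]))
  attr(frames, "nAtoms") <- nAtoms
  frames
}

## Verify that every MODEL block of a multi-model PDB is complete; name
## the last good frame otherwise.
checkMultiModelPDB <- function(file, nAtoms) {
  lines <- readLines(file, warn = FALSE)
  rec <- substr(lines, 1, 6)
  nModels <- sum(rec == "MODEL ")
  if (nModels == 0) return(invisible(TRUE))
  nEnd <- sum(rec == "ENDMDL")
  atomsPerModel <- integer(0)
  count <- 0L; inModel <- FALSE
  for (r in rec) {
    if (r == "MODEL ") { inModel <- TRUE; count <- 0L }
    else if (r == "ENDMDL") { atomsPerModel <- c(atomsPerModel, count); inModel <- FALSE }
    else if (inModel && (r == "ATOM  " || r == "HETATM")) count <- count + 1L
  }
  if (nEnd < nModels || (inModel && count > 0))
    stop(sprintf("trajectory truncated: last good frame is %d ('%s')",
                 length(atomsPerModel), basename(file)), call. = FALSE)
  bad <- which(atomsPerModel != nAtoms)
  if (length(bad))
    stop(sprintf("trajectory truncated or corrupt at frame %d (%d atoms, expected %d); last good frame is %d",
                 bad[1], atomsPerModel[bad[1]], nAtoms, bad[1] - 1L), call. = FALSE)
  invisible(TRUE)
}

#' Write snapshots as a multi-model PDB
#'
#' @param frames List of n x 3 coordinate matrices.
#' @param file Output path.
#' @param elety Atom names (recycled).
#' @param resid Residue names (recycled).
#' @return Invisibly, `file`.
#' @export
writeTrajectoryPDB <- function(frames, file, elety = "C", resid = "UNK") {
  n <- nrow(frames[[1]])
  xyz <- do.call(rbind, lapply(frames, flattenCoords))
  bio3d::write.pdb(file = file, xyz = xyz,
                   resno = seq_len(n), resid = rep_len(resid, n),
                   elety = rep_len(elety, n))
  invisible(file)
}

#' Write / read a Path as self-describing JSON
#'
#' The JSON carries nodes, per-node metrics, the softmin scale, arc
#' lengths, the periodicity mask and provenance, so a path file is fully
#' reconstructible.
#'
#' @param path A [Path-class].
#' @param file Output / input path.
#' @return `writePathJSON`: invisibly `file`; `readPathJSON`: a
#'   [Path-class].
#' @export
writePathJSON <- function(path, file) {
  obj <- list(format = "pathFE-path", version = 1L,
              nodes = unname(path@nodes),
              nodeMetrics = lapply(path@nodeMetrics, unname),
              lambda = path@lambda,
              arcLengths = path@arcLengths,
              periodic = path@periodic,
              provenance = path@provenance)
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}

#' @rdname writePathJSON
#' @export
readPathJSON <- function(file) {
  obj <- tryCatch(jsonlite::read_json(file, simplifyVector = TRUE),
                  error = function(e)
                    stop(sprintf("'%s' is not a path file", file), call. = FALSE))
  if (!identical(obj$format, "pathFE-path"))
    stop(sprintf("'%s' is not a path file", file), call. = FALSE)
  nodes <- as.matrix(obj$nodes)
  metrics <- if (is.array(obj$nodeMetrics) && length(dim(obj$nodeMetrics)) == 3) {
    lapply(seq_len(dim(obj$nodeMetrics)[1]), function(i)
      as.matrix(obj$nodeMetrics[i, , ]))
  } else {
    lapply(obj$nodeMetrics, function(m) as.matrix(m))
  }
  newPathFromNodes(nodes, metrics, obj$lambda, as.logical(obj$periodic),
                   provenance = as.list(obj$provenance))
}

#' Export path nodes as CSV for plotting
#'
#' @param path A [Path-class].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
writePathCSV <- function(path, file) {
  d <- as.data.frame(path@nodes)
  if (is.null(colnames(path@nodes)))
    names(d) <- paste0("cv", seq_len(ncol(path@nodes)))
  d$arcLength <- path@arcLengths
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}

#' Write / read umbrella sample series as CSV
#'
#' The CSV carries the window parameters and seed as `# key: value`
#' header comments, so a series file round-trips through
#' `readSamplesCSV` without side information.
#'
#' @param series A [SampleSeries-class].
#' @param file Output / input path.
#' @return `writeSamplesCSV`: invisibly `file`; `readSamplesCSV`: a
#'   [SampleSeries-class].
#' @export
writeSamplesCSV <- function(series, file) {
  w <- series@window
  hdr <- c(sprintf("# pathFE-samples v1"),
           sprintf("# index: %d", w@index),
           sprintf("# sCenter: %.17g", w@sCenter),
           sprintf("# kS: %.17g", w@kS),
           sprintf("# kZ: %.17g", w@kZ),
           sprintf("# initFrame: %d", if (is.na(w@initFrame)) -1L else w@initFrame),
           sprintf("# rampSteps: %d", w@rampSteps),
           sprintf("# productionSteps: %d", w@productionSteps),
           sprintf("# seed: %d", w@seed),
           sprintf("# stride: %d", series@stride))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(series@data, con, row.names = FALSE)
  invisible(file)
}

#' @rdname writeSamplesCSV
#' @export
readSamplesCSV <- function(file) {
  lines <- readLines(file, warn = FALSE)
  hdr <- grep("^# ", lines, value = TRUE)
  kv <- list()
  for (h in grep(":", hdr, value = TRUE)) {
    parts <- strsplit(sub("^# ", "", h), ": ")[[1]]
    kv[[parts[1]]] <- parts[2]
  }
  d <- utils::read.csv(text = lines[!startsWith(lines, "# ")])
  init <- as.integer(kv$initFrame)
  w <- new("UmbrellaWindow", index = as.integer(kv$index),
           sCenter = as.numeric(kv$sCenter), kS = as.numeric(kv$kS),
           kZ = as.numeric(kv$kZ),
           initFrame = if (is.na(init) || init < 0) NA_integer_ else init,
           rampSteps = as.integer(kv$rampSteps),
           productionSteps = as.integer(kv$productionSteps),
           seed = as.integer(kv$seed))
  new("SampleSeries", data = d, window = w,
      stride = as.integer(kv$stride %||% 1L), meta = kv)
}

#' Write / read a free-energy profile (CSV + JSON metadata)
#'
#' @param profile A [FreeEnergyProfile-class].
#' @param file CSV output / input path; metadata goes to `<file>.json`.
#' @return `writeProfileCSV`: invisibly `file`; `readProfileCSV`: a
#'   [FreeEnergyProfile-class].
#' @export
writeProfileCSV <- function(profile, file) {
  d <- data.frame(s = profile@s, F = profile@F,
                  sigma = if (is.null(profile@sigma)) NA_real_ else profile@sigma,
                  n = profile@counts)
  utils::write.csv(d, file, row.names = FALSE)
  jsonlite::write_json(profile@meta, paste0(file, ".json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}

#' @rdname writeProfileCSV
#' @export
readProfileCSV <- function(file) {
  d <- utils::read.csv(file)
  meta <- if (file.exists(paste0(file, ".json")))
    jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE) else list()
  sigma <- if (all(is.na(d$sigma))) NULL else d$sigma
  new("FreeEnergyProfile", s = d$s, F = d$F, sigma = sigma,
      counts = d$n, meta = as.list(meta))
}

#' Read an anchor specification from YAML
#'
#' Expected layout: top-level keys `protein` and `ligand`, each with
#' three named groups carrying `indices` (0-based atom indices) and an
#' optional `label`.
#'
#' @param file YAML file path.
#' @param reference Optional coordinate matrix for triangle validation.
#' @param epsDeg Collinearity tolerance in degrees.
#' @return An [AnchorFrame-class].
#' @export
readAnchorsYAML <- function(file, reference = NULL, epsDeg = 10) {
  spec <- yaml::read_yaml(file)
  mk <- function(side) {
    groups <- spec[[side]]
    stopifnot2(length(groups) == 3,
               sprintf("anchor spec '%s' must contain exactly 3 %s groups", file, side))
    lapply(seq_along(groups), function(i) {
      g <- groups[[i]]
      anchorGroup(g$indices, g$label %||% names(groups)[i])
    })
  }
  anchorFrame(mk("protein"), mk("ligand"), reference = reference, epsDeg = epsDeg)
}

#' Write an anchor specification to YAML
#'
#' @param frame An [AnchorFrame-class].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
writeAnchorsYAML <- function(frame, file) {
  enc <- function(gs, names) {
    out <- lapply(seq_along(gs), function(i)
      list(indices = as.integer(gs[[i]]@indices),
           label = if (nzchar(gs[[i]]@label)) gs[[i]]@label else names[i]))
    names(out) <- names
    out
  }
  yaml::write_yaml(list(protein = enc(frame@protein, c("P1", "P2", "P3")),
                        ligand = enc(frame@ligand, c("L1", "L2", "L3"))), file)
  invisible(file)
}

#' Read and validate a campaign configuration (YAML)
#'
#' @param file YAML file with keys: `topology`, `trajectory`, `anchors`
#'   (file paths), `nNodes`, `nWindows`, `kS`, `kZ`, `masterSeed`,
#'   `outputDir`, and the `quick`/`full` sampling presets
#'   (`rampSteps`, `productionSteps` each).
#' @param checkFiles Validate that the referenced files exist.
#' @return Validated configuration list (class `pathFECampaign`).
#' @export
readCampaignConfig <- function(file, checkFiles = TRUE) {
  cfg <- yaml::read_yaml(file)
  defaults <- list(nNodes = 12L, nWindows = 16L, kS = NULL, kZ = 20,
                   masterSeed = 1L, outputDir = "pathfe-output",
                   quick = list(rampSteps = 400L, productionSteps = 60L),
                   full = list(rampSteps = 400L, productionSteps = 6000L))
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (checkFiles) {
    for (k in c("topology", "trajectory", "anchors")) {
      if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
        stop(sprintf("config '%s': %s file '%s' does not exist", file, k, cfg[[k]]),
             call. = FALSE)
    }
  }
  stopifnot2(cfg$nNodes >= 2, "nNodes must be >= 2")
  stopifnot2(cfg$nWindows >= 2, "nWindows must be >= 2")
  stopifnot2(cfg$kZ >= 0, "kZ must be >= 0")
  class(cfg) <- "pathFECampaign"
  cfg
}
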