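#' Read a 4D diffusion series with FSL-style gradient files
#'
#' Reads a NIfTI volume and its whitespace-delimited .bval (one row of
#' b-values) and .bvec (three rows of direction components) files,
#' validates the counts against the 4th dimension, normalizes non-zero
#' direction vectors and returns the volume with its acquisition scheme.
#'
#' @param image path to the 4D NIfTI file.
#' @param bval,bvec paths to the gradient files; default: the image path
#'   with its extension replaced.
#' @return list with `volume` (4D array), `scheme`
#'   ([AcquisitionScheme-class]) and `image` (the RNifti image, usable as
#'   a header template for writing).
#' @export
readIVIMSeries <- function(image, bval = NULL, bvec = NULL) {
  stub <- sub("\\.nii(\\.gz)?$", "", image)
  if (is.null(bval)) bval <- paste0(stub, ".bval")
  if (is.null(bvec)) bvec <- paste0(stub, ".bvec")
  img <- RNifti::readNifti(image)
  vol <- array(as.vector(img), dim(img))
  if (length(dim(vol)) != 4) stop("expected a 4D image: ", image)

  b <- scan(bval, quiet = TRUE)
  gl <- utils::read.table(bvec)
  if (nrow(gl) != 3)
    stop("bvec must have exactly 3 rows (FSL dialect): ", bvec)
  g <- unname(as.matrix(gl))
  if (length(b) != dim(vol)[4] || ncol(g) != dim(vol)[4])
    stop("bval/bvec entries (", length(b), "/", ncol(g),
         ") do not match the ", dim(vol)[4], " volumes")
  nrm <- sqrt(colSums(g^2))
  if (any(b > 0 & nrm < 1e-8))
    stop("zero direction vector at b > 0")
  pos <- nrm > 1e-8
  g[, pos] <- sweep(g[, pos, drop = FALSE], 2, nrm[pos], "/")
  scheme <- new("AcquisitionScheme", bValues = b, directions = g)
  list(volume = vol, scheme = scheme, image = img)
}

# tiny polynomial rolling hash for config fingerprints in sidecars
.configHash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s)) %% 256
  h <- 5381
  for (byte in bytes) h <- (h * 33 + byte) %% 2^32
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write parameter maps as NIfTI files with a JSON sidecar
#'
#' Writes one NIfTI per map — fp (percent), dstar and md (mm^2/s), kapp
#' (dimensionless), model (integer codes) and flags — plus a
#' `maps.json` sidecar recording units, the model coding, the flag-bit
#' meanings, a config hash and the seed.
#'
#' @param maps a [ParameterMaps-class] object.
#' @param dir output directory (created if needed).
#' @param reference optional RNifti image whose header (affine etc.) the
#'   maps inherit.
#' @param config optional configuration list recorded (hashed) in the
#'   sidecar.
#' @param seed optional seed recorded in the sidecar.
#' @param prefix filename prefix.
#' @return invisibly, the named vector of written file paths.
#' @export
writeParameterMaps <- function(maps, dir, reference = NULL, config = NULL,
                               seed = NULL, prefix = "ivim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(arr, name, datatype = "double") {
    path <- file.path(dir, paste0(prefix, "_", name, ".nii.gz"))
    if (!is.null(reference))
      RNifti::writeNifti(RNifti::asNifti(arr, reference = reference),
                         path, datatype = datatype)
    else
      RNifti::writeNifti(RNifti::asNifti(arr), path, datatype = datatype)
    path
  }
  files <- c(
    fp = wr(maps@fp, "fp"), dstar = wr(maps@dstar, "dstar"),
    md = wr(maps@md, "md"), kapp = wr(maps@kapp, "kapp"),
    model = wr(maps@model, "model", "uint8"),
    flags = wr(maps@flags, "flags", "uint8"))
  sidecar <- list(
    units = list(fp = "percent", dstar = "mm^2/s", md = "mm^2/s",
                 kapp = "dimensionless"),
    model_codes = list("1" = "gaussian", "2" = "kurtosis", "3" = "gamma"),
    flag_bits = as.list(ivimFlags()),
    mode = maps@mode,
    config_hash = .configHash(if (is.null(config)) list() else config),
    seed = seed)
  jsonlite::write_json(sidecar, file.path(dir, paste0(prefix, "_maps.json")),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(files)
}

#' Read parameter maps written by [writeParameterMaps()]
#'
#' @param dir directory containing the map files.
#' @param prefix filename prefix used when writing.
#' @return a [ParameterMaps-class] object.
#' @export
readParameterMaps <- function(dir, prefix = "ivim") {
  rd <- function(name) {
    x <- RNifti::readNifti(file.path(dir, paste0(prefix, "_", name,
                                                 ".nii.gz")))
    .pad3d(array(as.vector(x), dim(x)))
  }
  sidecar <- jsonlite::read_json(file.path(dir,
                                           paste0(prefix, "_maps.json")))
  model <- rd("model"); storage.mode(model) <- "integer"
  flags <- rd("flags"); storage.mode(flags) <- "integer"
  new("ParameterMaps", fp = rd("fp"), dstar = rd("dstar"), md = rd("md"),
      kapp = rd("kapp"), model = model, flags = flags,
      mode = sidecar$mode)
}

#' Write a generated phantom as a NIfTI dataset
#'
#' Writes the simulated series (the average of all repeats as `dwi.nii.gz`,
#' plus each repeat when there are several), FSL-style `.bval`/`.bvec`
#' files, the ground-truth parameter maps, the label map and a JSON truth
#' sidecar, so the file-based fitting path can be exercised end-to-end on
#' synthetic data.
#'
#' @param phantom result of [generatePhantom()].
#' @param dir output directory.
#' @param spec the [PhantomSpec-class] used (recorded in the sidecar).
#' @return invisibly, the output directory.
#' @export
writePhantom <- function(phantom, dir, spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scheme <- phantom$scheme
  avg <- averageRepeats(phantom$repeats)
  RNifti::writeNifti(RNifti::asNifti(avg), file.path(dir, "dwi.nii.gz"))
  if (length(phantom$repeats) > 1) {
    for (r in seq_along(phantom$repeats))
      RNifti::writeNifti(RNifti::asNifti(phantom$repeats[[r]]),
                         file.path(dir, sprintf("dwi_rep%d.nii.gz", r)))
  }
  writeLines(paste(scheme@bValues, collapse = " "),
             file.path(dir, "dwi.bval"))
  writeLines(apply(scheme@directions, 1, paste, collapse = " "),
             file.path(dir, "dwi.bvec"))
  for (nm in c("fp", "dstar", "md", "kapp"))
    RNifti::writeNifti(RNifti::asNifti(phantom$truth[[nm]]),
                       file.path(dir, sprintf("truth_%s.nii.gz", nm)))
  RNifti::writeNifti(RNifti::asNifti(phantom$truth$model),
                     file.path(dir, "truth_model.nii.gz"),
                     datatype = "uint8")
  RNifti::writeNifti(RNifti::asNifti(phantom$labels),
                     file.path(dir, "labels.nii.gz"), datatype = "uint8")
  sidecar <- list(
    units = list(fp = "percent", dstar = "mm^2/s", md = "mm^2/s"),
    model_codes = list("1" = "gaussian", "2" = "kurtosis", "3" = "gamma"),
    n_repeats = length(phantom$repeats))
  if (!is.null(spec)) {
    sidecar$sigma <- spec@sigma
    sidecar$seed <- spec@seed
    sidecar$regions <- spec@regions
  }
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(dir)
}
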