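volume_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) "nifti"
  else if (grepl("\\.mhd$", lp)) "mhd"
  else if (grepl("\\.mha$", lp)) "mha"
  else if (grepl("\\.json$", lp)) "raw"
  else stop("unsupported image format: ", path,
            " (expected .nii/.nii.gz, .mhd, .mha, or a .json sidecar)")
}

check_isotropic <- function(sp) {
  sp <- sp[sp > 0]
  if (length(sp) == 0) stop("image header carries no voxel spacing")
  if (diff(range(sp)) > 1e-6 * max(sp))
    stop("anisotropic voxel spacing is not supported (the element kernel assumes cubic voxels)")
  sp[1]
}

meta_types <- data.frame(
  met = c("MET_UCHAR", "MET_CHAR", "MET_SHORT", "MET_USHORT", "MET_INT",
          "MET_UINT", "MET_FLOAT", "MET_DOUBLE"),
  what = c("integer", "integer", "integer", "integer", "integer", "integer",
           "double", "double"),
  size = c(1L, 1L, 2L, 2L, 4L, 4L, 4L, 8L),
  signed = c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE)

raw_dtypes <- data.frame(
  dtype = c("uint8", "int8", "int16", "uint16", "int32", "float32", "float64"),
  what = c("integer", "integer", "integer", "integer", "integer", "double", "double"),
  size = c(1L, 1L, 2L, 2L, 4L, 4L, 8L),
  signed = c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE)

read_binary_values <- function(con_path, n, what, size, signed, endian) {
  v <- readBin(con_path, what = what, n = n, size = size, signed = signed,
               endian = endian)
  if (length(v) < n) stop("image data is shorter than the declared dimensions")
  v
}

parse_meta_header <- function(lines) {
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9]+)\\s*=\\s*(.*?)\\s*$", lines))
  out <- list()
  for (m in kv) if (length(m) == 3L) out[[m[2]]] <- m[3]
  out
}

read_meta_volume <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  txt_end <- length(bytes)
  marker <- charToRaw("ElementDataFile")
  hit <- NULL
  limit <- min(length(bytes), 8192L)
  for (s in seq_len(limit - length(marker) + 1L)) {
    if (all(bytes[s:(s + length(marker) - 1L)] == marker)) { hit <- s; break }
  }
  if (is.null(hit)) stop("MetaImage header lacks ElementDataFile")
  nl <- which(bytes == as.raw(10L))
  hdr_end <- nl[nl > hit][1]
  if (is.na(hdr_end)) hdr_end <- length(bytes)
  hdr <- parse_meta_header(strsplit(rawToChar(bytes[1:hdr_end]), "\n")[[1]])
  for (req in c("NDims", "DimSize", "ElementType", "ElementSpacing"))
    if (is.null(hdr[[req]])) stop("MetaImage header missing field: ", req)
  if (as.integer(hdr$NDims) != 3L) stop("only 3D MetaImage volumes are supported")
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  ti <- match(hdr$ElementType, meta_types$met)
  if (is.na(ti)) stop("unsupported MetaImage element type: ", hdr$ElementType)
  endian <- if (identical(hdr$BinaryDataByteOrderMSB, "True")) "big" else "little"
  n <- prod(dims)
  datafile <- hdr$ElementDataFile
  if (identical(datafile, "LOCAL")) {
    data <- bytes[(hdr_end + 1L):length(bytes)]
    v <- readBin(data, what = meta_types$what[ti], n = n,
                 size = meta_types$size[ti], signed = meta_types$signed[ti],
                 endian = endian)
    if (length(v) < n) stop("image data is shorter than the declared dimensions")
  } else {
    dpath <- file.path(dirname(path), datafile)
    if (!file.exists(dpath)) stop("MetaImage data file not found: ", dpath)
    v <- read_binary_values(dpath, n, meta_types$what[ti], meta_types$size[ti],
                            meta_types$signed[ti], endian)
  }
  list(data = array(as.numeric(v), dims), voxel_size = check_isotropic(spacing))
}

write_meta_volume <- function(arr, voxel_size, path) {
  local <- grepl("\\.mha$", tolower(path))
  datafile <- if (local) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path),
                                                 ignore.case = TRUE), ".raw")
  hdr <- paste0(
    "ObjectType = Image\n", "NDims = 3\n", "BinaryData = True\n",
    "BinaryDataByteOrderMSB = False\n",
    "DimSize = ", paste(dim(arr), collapse = " "), "\n",
    "ElementSpacing = ", paste(rep(format(voxel_size, digits = 17), 3),
                               collapse = " "), "\n",
    "ElementType = MET_DOUBLE\n",
    "ElementDataFile = ", datafile, "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  if (local) {
    writeBin(as.numeric(arr), con, size = 8, endian = "little")
  } else {
    rcon <- file(file.path(dirname(path), datafile), "wb")
    writeBin(as.numeric(arr), rcon, size = 8, endian = "little")
    close(rcon)
  }
  invisible(path)
}

read_raw_sidecar <- function(path) {
  sc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (req in c("dims", "voxel_size", "dtype", "data_file"))
    if (is.null(sc[[req]])) stop("raw sidecar missing field: ", req)
  dims <- as.integer(sc$dims)
  ti <- match(sc$dtype, raw_dtypes$dtype)
  if (is.na(ti)) stop("unsupported raw dtype: ", sc$dtype)
  endian <- if (identical(sc$byte_order, "big")) "big" else "little"
  dpath <- file.path(dirname(path), sc$data_file)
  if (!file.exists(dpath)) stop("raw data file not found: ", dpath)
  v <- read_binary_values(dpath, prod(dims), raw_dtypes$what[ti],
                          raw_dtypes$size[ti], raw_dtypes$signed[ti], endian)
  slope <- if (is.null(sc$slope)) 1 else as.numeric(sc$slope)
  intercept <- if (is.null(sc$intercept)) 0 else as.numeric(sc$intercept)
  list(data = array(slope * as.numeric(v) + intercept, dims),
       voxel_size = check_isotropic(as.numeric(sc$voxel_size)))
}

#' Read a scalar volume
#'
#' Low-level reader returning the raw values and voxel size without any BVF
#' mapping. Formats: NIfTI (`.nii`, `.nii.gz`), MetaImage (`.mhd` + `.raw`,
#' `.mha`), or raw binary described by a `.json` sidecar with fields `dims`,
#' `voxel_size`, `dtype`, `data_file` and optional `slope`/`intercept`
#' (applied for raw volumes only).
#'
#' @param path file path (sidecar path for raw volumes).
#' @return list with `data` (3D numeric array) and `voxel_size` (mm).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  switch(volume_format(path),
    nifti = {
      img <- RNifti::readNifti(path)
      if (length(dim(img)) != 3L) stop("only 3D volumes are supported")
      sp <- RNifti::pixdim(img)
      list(data = array(as.numeric(img), dim(img)),
           voxel_size = check_isotropic(sp))
    },
    mhd = read_meta_volume(path),
    mha = read_meta_volume(path),
    raw = read_raw_sidecar(path))
}

#' Write a scalar volume
#'
#' Counterpart of [read_volume()]; data are written in double precision
#' (NIfTI `DT_FLOAT64` / `MET_DOUBLE` / raw `float64`), making round trips
#' lossless.
#'
#' @param arr 3D numeric array.
#' @param voxel_size voxel edge length (mm).
#' @param path output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_volume <- function(arr, voxel_size, path) {
  stopifnot(length(dim(arr)) == 3L)
  switch(volume_format(path),
    nifti = {
      img <- RNifti::asNifti(array(as.numeric(arr), dim(arr)))
      RNifti::pixdim(img) <- rep(voxel_size, 3)
      RNifti::writeNifti(img, path, datatype = "double")
    },
    mhd = write_meta_volume(arr, voxel_size, path),
    mha = write_meta_volume(arr, voxel_size, path),
    raw = {
      datafile <- paste0(sub("\\.json$", "", basename(path)), ".raw")
      writeBin(as.numeric(arr), file.path(dirname(path), datafile),
               size = 8, endian = "little")
      jsonlite::write_json(
        list(dims = dim(arr), voxel_size = voxel_size, dtype = "float64",
             data_file = datafile, slope = 1, intercept = 0,
             byte_order = "little"),
        path, auto_unbox = TRUE, digits = NA)
    })
  invisible(path)
}

#' Read a bone-volume-fraction image
#'
#' Reads a volume and interprets it as BVF: an optional linear intensity map
#' `bvf = slope * value + intercept` is applied (raw sidecars may declare
#' their own), then values are clipped to `[0, 1]` with a warning if they
#' exceed the range by more than `1e-6`.
#'
#' @inheritParams read_volume
#' @param slope,intercept linear intensity-to-BVF calibration applied on top
#'   of the stored values (default identity).
#' @return a [voxel_model()].
#' @export
read_bvf_image <- function(path, slope = 1, intercept = 0) {
  vol <- read_volume(path)
  x <- slope * vol$data + intercept
  lo <- min(x); hi <- max(x)
  if (lo < -1e-6 || hi > 1 + 1e-6)
    warning(sprintf("BVF values outside [0, 1] (range %.4g..%.4g); clipping", lo, hi))
  x[x < 0] <- 0; x[x > 1] <- 1
  voxel_model(x, vol$voxel_size)
}

#' Write a bone-volume-fraction image
#'
#' @param model a [voxel_model()].
#' @param path output path (format by extension, as in [write_volume()]).
#' @export
write_bvf_image <- function(model, path) {
  write_volume(model$bvf, model$voxel_size, path)
}

#' Write a strain-energy map
#'
#' Writes the per-voxel energies on the model's grid (same dimensions and
#' voxel size as the input image).
#'
#' @param map 3D array from [strain_energy_map()] (or the `energy_map` field
#'   of a result).
#' @param model the [voxel_model()] that defines the geometry.
#' @param path output path (NIfTI or MetaImage).
#' @export
write_energy_map <- function(map, model, path) {
  if (!all(dim(map) == model$dims)) stop("energy map does not match the model grid")
  write_volume(map, model$voxel_size, path)
}

format_report_value <- function(v) {
  if (is.numeric(v)) paste(format(v, digits = 17), collapse = " ")
  else paste(as.character(v), collapse = " ")
}

#' Write a run report
#'
#' Plain `key: value` text report of a compression solve: stiffness, stress,
#' strain, per-level iteration counts, convergence flags, timing, seed, tool
#' version, and an echo of the configuration. Parse it back with
#' [read_report()].
#'
#' @param result a `mufe_result`.
#' @param path output path.
#' @param config optional named list echoed as `config_*` keys.
#' @param seed optional RNG seed to record.
#' @param wall_time optional elapsed seconds.
#' @export
write_report <- function(result, path, config = NULL, seed = NULL,
                         wall_time = NULL) {
  stopifnot(inherits(result, "mufe_result"))
  kv <- c(
    tool = "microfe",
    tool_version = as.character(utils::packageVersion("microfe")),
    stiffness_mpa = format_report_value(result$stiffness),
    total_stress_mpa = format_report_value(result$stress),
    applied_strain = format_report_value(result$strain),
    load_axis = c("x", "y", "z")[result$axis],
    end_condition = result$end_condition,
    converged = tolower(as.character(result$converged)),
    estimated_relative_error = format_report_value(result$estimated_error),
    n_elements = format_report_value(result$n_elements),
    n_free_variables = format_report_value(result$n_free),
    dims = format_report_value(result$dims),
    voxel_size_mm = format_report_value(result$voxel_size))
  for (nm in names(result$iterations))
    kv[[paste0("iterations_grid_", nm)]] <-
      format_report_value(result$iterations[[nm]])
  if (!is.null(wall_time)) kv[["wall_time_s"]] <- format_report_value(wall_time)
  if (!is.null(seed)) kv[["seed"]] <- format_report_value(seed)
  for (nm in names(config))
    kv[[paste0("config_", nm)]] <- format_report_value(config[[nm]])
  writeLines(paste0(names(kv), ": ", unlist(kv)), path)
  invisible(path)
}

#' Read a run report
#'
#' @param path a report written by [write_report()].
#' @return named list; values are numeric where they parse as numbers.
#' @export
read_report <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  out <- list()
  for (x in m) {
    if (length(x) != 3L) next
    val <- x[3]
    parts <- strsplit(val, "\\s+")[[1]]
    num <- suppressWarnings(as.numeric(parts))
    out[[x[2]]] <- if (length(num) > 0 && !anyNA(num)) num else val
  }
  out
}

#' Read a run configuration file
#'
#' YAML file whose keys mirror the command-line flags of the `run` subcommand
#' (`input`, `strain`, `axis`, `tissue_modulus`, `poisson_ratio`, `mode`,
#' `binary_threshold`, `tolerance`, `schedule`, `coarse_iterations`,
#' `workers`, `end_condition`, `report`, `energy_map`, ...).
#'
#' @param path YAML file path.
#' @return named list of settings.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration must be a YAML mapping")
  cfg
}
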