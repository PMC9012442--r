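#' CT volume container
#'
#' A 3D grid of Hounsfield units with physical spacing and origin, axis order
#' (x, y, z) of the anatomical frame. Voxel centers sit at
#' \code{origin + index * spacing} with 0-based indices.
#'
#' @param hu 3D numeric array of HU values.
#' @param spacing mm triple, all > 0.
#' @param origin mm triple (position of voxel (0,0,0) center).
#' @param labels optional integer array of the same shape: reference
#'   ground-truth vertebra index per voxel (0 = no bone).
#' @return object of class \code{ct_volume}.
#' @export
ct_volume <- function(hu, spacing = c(0.5, 0.5, 0.5), origin = c(0, 0, 0),
                      labels = NULL) {
  stopifnot(length(dim(hu)) == 3, length(spacing) == 3, length(origin) == 3)
  if (any(spacing <= 0)) stop("spacing must be > 0")
  if (any(!is.finite(hu))) stop("HU values must be finite")
  structure(list(hu = hu, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), labels = labels),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$hu)
  cat(sprintf("ct_volume: %d x %d x %d voxels, spacing (%g, %g, %g) mm, HU [%d, %d]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              round(min(x$hu)), round(max(x$hu))))
  invisible(x)
}

#' Hounsfield-unit model for phantom voxelization
#'
#' Tissue intensities for the simulated bone-window scan. Voxel HU is the
#' partial-volume mixture of the tissue means; the stochastic part is a
#' zero-mean Gaussian whose variance mixes the tissue variances by occupancy
#' fraction plus a global scanner noise term. \code{noise = FALSE} zeroes all
#' standard deviations, giving a fully deterministic volume.
#'
#' @param bone_mean,bone_sd trabecular/cortical bone HU (must lie within the
#'   +700..+3000 segmentation window).
#' @param soft_tissue_mean,soft_tissue_sd muscle/soft-tissue HU (below +700).
#' @param background HU of air around the specimen.
#' @param noise_sd additive scanner noise, HU.
#' @param partial_volume_supersampling lateral subsamples per voxel axis used
#'   for partial-volume fractions (1 = binary center sampling).
#' @param noise set \code{FALSE} to zero every standard deviation.
#' @return object of class \code{hu_model}.
#' @export
hu_model <- function(bone_mean = 1500, bone_sd = 150,
                     soft_tissue_mean = 40, soft_tissue_sd = 30,
                     background = -1000, noise_sd = 20,
                     partial_volume_supersampling = 3,
                     noise = TRUE) {
  if (bone_mean < 700 || bone_mean > 3000)
    stop("bone_mean must lie within the +700..+3000 bone window")
  if (soft_tissue_mean >= 700)
    stop("soft_tissue_mean must be below +700")
  if (!noise) bone_sd <- soft_tissue_sd <- noise_sd <- 0
  structure(list(bone_mean = bone_mean, bone_sd = bone_sd,
                 soft_tissue_mean = soft_tissue_mean,
                 soft_tissue_sd = soft_tissue_sd,
                 background = background, noise_sd = noise_sd,
                 partial_volume_supersampling = as.integer(partial_volume_supersampling)),
            class = "hu_model")
}

#' Voxelize a spine pose into a CT-like volume
#'
#' Rasterizes each vertebra solid into per-voxel occupancy fractions (exact
#' along z, supersampled laterally), surrounds the bone with a soft-tissue
#' envelope (Euclidean dilation by \code{soft_margin}), mixes tissue HU by
#' occupancy and adds Gaussian noise. The reference label grid stores, for
#' every voxel, the index of the vertebra holding the majority (> 0.5) of the
#' voxel volume.
#'
#' @param pose a \code{spine_pose} (may be empty only if \code{bbox} is given).
#' @param model an \code{hu_model}.
#' @param spacing mm triple (default 0.5 isotropic).
#' @param seed RNG seed for the noise draws.
#' @param soft_margin soft-tissue envelope margin around the bone, mm.
#' @param bbox optional 2x3 matrix (min row, max row) fixing the grid extent.
#' @param pad extra padding around the pose bounding box, mm.
#' @return \code{ct_volume} with the reference \code{labels} grid attached.
#' @export
voxelize <- function(pose, model = hu_model(), spacing = c(0.5, 0.5, 0.5),
                     seed = 1L, soft_margin = 30, bbox = NULL, pad = 6) {
  spacing <- rep_len(as.numeric(spacing), 3)
  n <- length(pose)
  if (is.null(bbox)) {
    if (n == 0) stop("empty pose needs an explicit bbox")
    allv <- do.call(rbind, lapply(pose, function(m) m$vertices))
    bbox <- rbind(apply(allv, 2, min) - soft_margin - pad,
                  apply(allv, 2, max) + soft_margin + pad)
  }
  origin <- bbox[1, ]
  dims <- pmax(2L, as.integer(ceiling((bbox[2, ] - bbox[1, ]) / spacing)) + 1L)
  s <- model$partial_volume_supersampling

  nvox <- prod(dims)
  f_bone <- array(0, dims)
  labels <- array(0L, dims)
  best <- array(0, dims)
  for (k in seq_len(n)) {
    mesh <- pose[[k]]
    fk <- cpp_voxelize_mesh(mesh$vertices, mesh$faces, origin, spacing, dims, s)
    if (!any(fk >= 0.5))
      stop(sprintf("spacing too coarse: vertebra %d (%s) yields no interior voxel",
                   k, if (is.null(mesh$label)) "?" else mesh$label))
    f_bone <- f_bone + fk
    sel <- fk > best & fk > 0.5
    labels[sel] <- k
    best[sel] <- fk[sel]
  }
  f_bone[f_bone > 1] <- 1

  if (n > 0) {
    d <- cpp_edt(labels > 0L, dims, spacing)
    soft <- d <= soft_margin & f_bone < 1
  } else {
    soft <- array(FALSE, dims)
  }
  f_soft <- ifelse(soft, 1 - f_bone, 0)
  f_bg <- 1 - f_bone - f_soft

  hu <- f_bone * model$bone_mean + f_soft * model$soft_tissue_mean +
    f_bg * model$background
  vr <- f_bone * model$bone_sd^2 + f_soft * model$soft_tissue_sd^2 +
    model$noise_sd^2
  if (any(vr > 0)) {
    noise <- with_local_seed(seed, stats::rnorm(nvox, 0, sqrt(vr)))
    hu <- hu + array(noise, dims)
  }
  ct_volume(hu, spacing, origin, labels = labels)
}

#' Read and write CT volumes
#'
#' NIfTI (\code{.nii}, \code{.nii.gz}; via RNifti, double precision) and
#' MetaImage (\code{.mha} single file or \code{.mhd} + \code{.raw}; MET_DOUBLE,
#' little endian). A write-read round trip preserves the HU grid exactly and
#' spacing/origin to better than 1e-6 mm. When the volume carries a reference
#' label grid it is written alongside with a \code{_labels} suffix.
#'
#' @param volume a \code{ct_volume}.
#' @param path file path; the extension selects the format.
#' @param write_labels write the \code{_labels} companion when present.
#' @return \code{write_volume}: the path, invisibly; \code{read_volume}: a
#'   \code{ct_volume} (labels are re-attached when the companion file exists).
#' @export
write_volume <- function(volume, path, write_labels = TRUE) {
  stopifnot(inherits(volume, "ct_volume"))
  fmt <- volume_format(path)
  if (fmt == "nifti") {
    write_nifti_vol(volume$hu, volume$spacing, volume$origin, path)
  } else {
    write_meta_vol(volume$hu, volume$spacing, volume$origin, path)
  }
  if (write_labels && !is.null(volume$labels)) {
    lp <- labels_path(path)
    if (fmt == "nifti") {
      write_nifti_vol(volume$labels + 0, volume$spacing, volume$origin, lp)
    } else {
      write_meta_vol(volume$labels + 0, volume$spacing, volume$origin, lp)
    }
  }
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  fmt <- volume_format(path)
  if (!file.exists(path)) stop("volume file does not exist: ", path)
  vol <- if (fmt == "nifti") read_nifti_vol(path) else read_meta_vol(path)
  lp <- labels_path(path)
  labels <- NULL
  if (file.exists(lp)) {
    lv <- if (fmt == "nifti") read_nifti_vol(lp) else read_meta_vol(lp)
    labels <- array(as.integer(round(lv$data)), dim(lv$data))
  }
  ct_volume(vol$data, vol$spacing, vol$origin, labels = labels)
}

volume_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.(mha|mhd)$", low)) return("meta")
  stop("unknown volume format (expected .nii, .nii.gz, .mha or .mhd): ", path)
}

labels_path <- function(path) {
  sub("(\\.nii\\.gz|\\.nii|\\.mha|\\.mhd)$", "_labels\\1", path)
}

write_nifti_vol <- function(arr, spacing, origin, path) {
  hdr <- list(pixdim = c(1, spacing, 0, 0, 0, 0),
              sform_code = 2L, qform_code = 0L,
              srow_x = c(spacing[1], 0, 0, origin[1]),
              srow_y = c(0, spacing[2], 0, origin[2]),
              srow_z = c(0, 0, spacing[3], origin[3]))
  img <- RNifti::asNifti(arr, hdr, datatype = "double")
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

read_nifti_vol <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("corrupt or unreadable NIfTI file: ",
                                           path, " (", conditionMessage(e), ")"))
  m <- RNifti::xform(img)
  list(data = array(as.numeric(img), dim(img)),
       spacing = as.numeric(c(m[1, 1], m[2, 2], m[3, 3])),
       origin = as.numeric(m[1:3, 4]))
}

write_meta_vol <- function(arr, spacing, origin, path) {
  d <- dim(arr)
  is_mha <- grepl("\\.mha$", tolower(path))
  datafile <- if (is_mha) "LOCAL" else paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
           sprintf("ElementSpacing = %.17g %.17g %.17g", spacing[1], spacing[2], spacing[3]),
           sprintf("Offset = %.17g %.17g %.17g", origin[1], origin[2], origin[3]),
           "ElementType = MET_DOUBLE",
           paste0("ElementDataFile = ", datafile))
  if (is_mha) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(as.numeric(arr), con, size = 8, endian = "little")
  } else {
    writeLines(hdr, path)
    rawpath <- file.path(dirname(path), datafile)
    con <- file(rawpath, "wb")
    on.exit(close(con))
    writeBin(as.numeric(arr), con, size = 8, endian = "little")
  }
  invisible(path)
}

read_meta_vol <- function(path) {
  is_mha <- grepl("\\.mha$", tolower(path))
  parse_header <- function(lines) {
    kv <- strsplit(lines, "=", fixed = TRUE)
    keys <- trimws(vapply(kv, `[`, "", 1))
    vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
    stats::setNames(vals, keys)
  }
  if (is_mha) {
    con <- file(path, "rb")
    on.exit(close(con))
    lines <- character()
    repeat {
      ln <- readLines(con, n = 1, warn = FALSE)
      if (length(ln) == 0) stop("corrupt MetaImage header (no ElementDataFile): ", path)
      lines <- c(lines, ln)
      if (grepl("^ElementDataFile", ln)) break
    }
    hd <- parse_header(lines)
    check_meta_header(hd, path)
    d <- as.integer(strsplit(hd[["DimSize"]], "\\s+")[[1]])
    data <- readBin(con, numeric(), n = prod(d), size = 8, endian = "little")
  } else {
    lines <- readLines(path, warn = FALSE)
    hd <- parse_header(lines)
    check_meta_header(hd, path)
    d <- as.integer(strsplit(hd[["DimSize"]], "\\s+")[[1]])
    rawpath <- file.path(dirname(path), hd[["ElementDataFile"]])
    if (!file.exists(rawpath)) stop("missing raw data file for MetaImage header: ", rawpath)
    con <- file(rawpath, "rb")
    on.exit(close(con))
    data <- readBin(con, numeric(), n = prod(d), size = 8, endian = "little")
  }
  if (length(data) != prod(d)) stop("truncated MetaImage data: ", path)
  list(data = array(data, d),
       spacing = as.numeric(strsplit(hd[["ElementSpacing"]], "\\s+")[[1]]),
       origin = as.numeric(strsplit(hd[["Offset"]], "\\s+")[[1]]))
}

check_meta_header <- function(hd, path) {
  need <- c("DimSize", "ElementSpacing", "Offset", "ElementType", "ElementDataFile")
  miss <- setdiff(need, names(hd))
  if (length(miss))
    stop("corrupt MetaImage header (missing ", paste(miss, collapse = ", "), "): ", path)
  if (hd[["ElementType"]] != "MET_DOUBLE")
    stop("unsupported MetaImage element type ", hd[["ElementType"]], ": ", path)
}
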