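# NIfTI ingestion, non-constant-voxel masking, and a synthetic 4D BOLD
# generator that makes every downstream stage testable without external data.

#' Load a 4D BOLD image
#'
#' Reads a NIfTI file and checks it is 4D. Voxel sizes and the repetition
#' time are surfaced from the header.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return a list with `data` (x, y, z, t array), `voxel_dims` (mm, length 3)
#'   and `tr` (seconds).
#' @export
load_bold_4d <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop("expected 4D image, got ", length(d), "D")
  pd <- RNifti::pixdim(img)
  list(data = array(as.numeric(img), dim = d),
       voxel_dims = pd[1:3],
       tr = if (length(pd) >= 4L) pd[4L] else NA_real_)
}

#' Extract the non-constant voxel timeseries matrix
#'
#' Flattens the spatial dimensions of a 4D array and drops every voxel whose
#' timeseries variance is at or below `var_tol` (default 0: exact constancy,
#' which removes background and masked-out voxels). The surviving rows are
#' returned unchanged.
#'
#' @param img 4D numeric array (x, y, z, t) or the list from [load_bold_4d()].
#' @param var_tol variance threshold for "constant".
#' @return N x t matrix with attribute `n_dropped`.
#' @export
extract_voxel_matrix <- function(img, var_tol = 0) {
  if (is.list(img)) img <- img$data
  d <- dim(img)
  if (length(d) != 4L) stop("expected 4D image, got ", length(d), "D")
  m <- matrix(as.numeric(img), nrow = prod(d[1:3]), ncol = d[4L])
  v <- row_sds(m)^2
  keep <- v > var_tol
  if (!any(keep)) stop("no usable voxels: all timeseries constant")
  structure(m[keep, , drop = FALSE], n_dropped = sum(!keep))
}

# One synthetic scan: voxel v gets sum_k w_vk * s_k(t) * strength + noise.
# Latent signals are smoothed white noise, shared by all voxels of the scan.
synth_scan_array <- function(shape, tt, n_latent, strength, noise_sd) {
  nv <- prod(shape)
  s <- sapply(seq_len(n_latent), function(k)
    smooth_values(stats::rnorm(tt), "uniform", min(5L, tt)))
  s <- scale(s)                       # unit-variance latents
  w <- matrix(stats::rnorm(nv * n_latent), nv, n_latent)
  x <- strength * (w %*% t(s)) + matrix(stats::rnorm(nv * tt, sd = noise_sd), nv, tt)
  array(x, dim = c(shape, tt))
}

# Preprocessing-level variants: level 1 is the raw scan; higher levels apply
# increasing mild temporal smoothing plus a low-frequency drift so that the
# preprocessing axis of the grid is exercised by distinct but label-preserving
# versions of each image.
level_variant <- function(arr, level) {
  if (level == 1L) return(arr)
  d <- dim(arr)
  m <- matrix(arr, prod(d[1:3]), d[4L])
  m <- t(apply(m, 1L, smooth_values, kind = "uniform", window = level))
  drift <- 0.2 * (level - 1L) * seq(-1, 1, length.out = d[4L])
  amp <- stats::rnorm(nrow(m), sd = 0.5)
  array(m + outer(amp, drift), dim = d)
}

#' Synthesize a labeled two-group fMRI dataset
#'
#' Generates `n_per_group` scans per group. Each scan's voxel timeseries is a
#' sum of `n_latent` shared latent signals with Gaussian voxel loadings plus
#' iid Gaussian noise; group B's latent-signal strength is scaled by
#' `1 + effect`, so `effect = 0` defines the null (exchangeable groups) and
#' larger values plant an increasing group difference in the voxelwise
#' correlation structure. Four preprocessing-level variants are emitted per
#' scan (increasing temporal smoothing plus drift). The grid dimensions keep
#' t much smaller than the number of voxels, as in whole-brain BOLD data.
#'
#' @param n_per_group scans per group.
#' @param shape 3D spatial dimensions (default `c(6, 6, 6)`).
#' @param t number of volumes (default 40).
#' @param n_latent number of shared latent signals per scan.
#' @param effect group-difference strength (>= 0).
#' @param noise_sd noise standard deviation.
#' @param levels preprocessing levels to emit (subset of 1:4).
#' @param seed RNG seed; identical seeds reproduce the dataset exactly.
#' @param dir optional directory: when given, each scan/level is written as a
#'   NIfTI file and a manifest data frame (path, subject, label, level) is
#'   returned alongside the in-memory data.
#' @return a list with `scans` (list indexed by level, each a list of N x t
#'   voxel matrices), `labels` (factor, `"A"`/`"B"`), and `manifest` (a data
#'   frame when `dir` is given, else NULL).
#' @export
synthesize_group_dataset <- function(n_per_group = 20L, shape = c(6L, 6L, 6L),
                                     t = 40L, n_latent = 5L, effect = 1,
                                     noise_sd = 1, levels = 1:4, seed = 1L,
                                     dir = NULL) {
  stopifnot(length(shape) == 3L, all(shape >= 2L), t >= 3L, effect >= 0,
            noise_sd > 0, all(levels %in% 1:4))
  n_scans <- 2L * n_per_group
  labels <- factor(rep(c("A", "B"), each = n_per_group))
  scans <- lapply(levels, function(l) vector("list", n_scans))
  names(scans) <- as.character(levels)
  manifest <- NULL
  with_seed(seed, {
    for (i in seq_len(n_scans)) {
      strength <- if (labels[i] == "B") 1 + effect else 1
      base <- synth_scan_array(shape, t, n_latent, strength, noise_sd)
      for (li in seq_along(levels)) {
        arr <- level_variant(base, levels[li])
        scans[[li]][[i]] <- extract_voxel_matrix(arr)
        if (!is.null(dir)) {
          if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
          fn <- file.path(dir, sprintf("sub%03d_level%d.nii.gz", i, levels[li]))
          RNifti::writeNifti(RNifti::asNifti(arr), fn)
          manifest <- rbind(manifest, data.frame(
            path = fn, subject = sprintf("sub%03d", i),
            label = as.character(labels[i]), level = levels[li],
            stringsAsFactors = FALSE))
        }
      }
    }
  })
  list(scans = scans, labels = labels, manifest = manifest)
}

#' Write a dataset manifest
#'
#' Tab-separated manifest with header columns (path, subject, label, level).
#'
#' @param manifest data frame as returned by [synthesize_group_dataset()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a dataset manifest
#'
#' @param path tab-separated manifest file with columns path, subject, label,
#'   level.
#' @return data frame.
#' @export
read_manifest <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
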