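# File I/O: NIfTI maps and complex stacks (magnitude + phase pairs),
# cohort CSVs, ground-truth JSON sidecars.

nifti_with_voxels <- function(arr, voxel_mm) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_mm[seq_len(min(3L, length(dim(arr))))]
  img
}

#' Write quantitative maps as NIfTI
#'
#' One `.nii.gz` per map; the unit is recorded in the header description
#' field. `NaN` is preserved.
#'
#' @param maps Named list of numeric arrays.
#' @param dir Output directory (created if needed).
#' @param voxel_mm Voxel size (mm, length 3).
#' @param units Optional named character vector of units per map.
#' @return Named vector of file paths, invisibly.
#' @export
write_quant_maps <- function(maps, dir, voxel_mm, units = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(maps), function(nm) {
    img <- nifti_with_voxels(maps[[nm]], voxel_mm)
    if (!is.null(units) && nm %in% names(units)) {
      img <- RNifti::asNifti(img)
      attr(img, "description") <- units[[nm]]
    }
    path <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(img, path)
    path
  }, character(1))
  invisible(paths)
}

#' Read a quantitative map written by [write_quant_maps()]
#' @param path NIfTI path.
#' @return Numeric array.
#' @export
read_quant_map <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  attributes(arr) <- list(dim = dim(arr))
  arr
}

#' Write / read a complex multi-echo stack as NIfTI magnitude + phase pairs
#'
#' The stack's 5-D complex array (x, y, z, TE, preparation) is stored as two
#' 4-D files per preparation (`<prefix>_<series>_mag.nii.gz`,
#' `<prefix>_<series>_phase.nii.gz`) plus a `<prefix>_meta.json` sidecar
#' carrying the echo times, weights and protocol.
#'
#' @param stack An `srcse_stack`.
#' @param prefix Path prefix.
#' @return `write_stack_nifti`: named vector of paths, invisibly.
#' @export
write_stack_nifti <- function(stack, prefix) {
  stopifnot(inherits(stack, "srcse_stack"))
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in 1:2) {
    series <- c("unprep", "prep")[s]
    arr <- stack$data[, , , , s, drop = FALSE]
    dim(arr) <- dim(stack$data)[1:4]
    for (part in c("mag", "phase")) {
      x <- if (part == "mag") Mod(arr) else Arg(arr)
      path <- paste0(prefix, "_", series, "_", part, ".nii.gz")
      RNifti::writeNifti(nifti_with_voxels(x, stack$voxel_mm), path)
      paths[paste(series, part, sep = "_")] <- path
    }
  }
  meta <- paste0(prefix, "_meta.json")
  jsonlite::write_json(list(te = stack$te, te_weights = stack$te_weights,
                            voxel_mm = stack$voxel_mm,
                            protocol = unclass(stack$protocol)),
                       meta, auto_unbox = TRUE, digits = NA, null = "null")
  paths["meta"] <- meta
  invisible(paths)
}

#' @rdname write_stack_nifti
#' @export
read_stack_nifti <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  pr <- meta$protocol
  pr <- do.call(srcse_protocol,
                pr[!vapply(pr, is.null, logical(1))])
  read_part <- function(series, part)
    as.array(RNifti::readNifti(paste0(prefix, "_", series, "_", part,
                                      ".nii.gz")))
  build <- function(series) {
    m <- read_part(series, "mag"); ph <- read_part(series, "phase")
    complex(modulus = m, argument = ph)
  }
  u <- build("unprep"); p4 <- build("prep")
  d4 <- dim(as.array(read_part("unprep", "mag")))
  data <- array(complex(real = 0), c(d4, 2L))
  data[, , , , 1L] <- u
  data[, , , , 2L] <- p4
  dimnames(data) <- c(rep(list(NULL), 3L),
                      list(format(meta$te), c("unprep", "prep")))
  structure(list(data = data, te = meta$te, te_weights = meta$te_weights,
                 protocol = pr, voxel_mm = meta$voxel_mm),
            class = "srcse_stack")
}

#' Write / read a cohort table as CSV
#'
#' Column names follow the package convention (`age`, `sex`, `male`, `bmi`,
#' `t1w_ms`, `mff_intra_pct`, `mff_inter_pct`, `scf_ml`, `muscle_ml`, ...).
#'
#' @param cohort Data.frame from [make_cohort()].
#' @param path CSV path.
#' @return `read_cohort` returns the data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
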