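KNOWN_GROUPS <- c("HC", "BD", "ADHD", "BPD")

fmt17 <- function(x) {
  if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
}

#' Read and write cohort tables
#'
#' Tab-separated UTF-8 with a header row; numeric columns are serialized at 17
#' significant digits so a write/read round trip is lossless. Group labels are
#' validated against the known set (HC, BD, ADHD, BPD) unless
#' `validate_groups = FALSE`.
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @param validate_groups Reject unknown group labels on read.
#' @return `read_cohort` returns the data frame; `write_cohort` returns `path`
#'   invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  for (cn in names(out)) {
    if (is.numeric(out[[cn]])) out[[cn]] <- fmt17(out[[cn]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, validate_groups = TRUE) {
  x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (validate_groups && "group" %in% names(x)) {
    bad <- setdiff(unique(x$group), KNOWN_GROUPS)
    if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  }
  x
}

#' Read and write numeric matrices as TSV
#'
#' Plain tab-separated values at 17 significant digits, no header; row order
#' is participant order, column order is voxel order (x-fastest when the
#' matrix came from a volume).
#'
#' @param m Numeric matrix.
#' @param path File path.
#' @return `read_matrix_tsv` returns a numeric matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  m <- as.matrix(m)
  txt <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' Write a variability map (or any voxel vector) as 3D NIfTI
#'
#' The vector is reshaped onto `dim` in x-fastest order (R's native array
#' order). Out-of-mask `NA`s are preserved as NaN in the volume.
#'
#' @param values Length-V numeric vector, `V == prod(dim)`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param dim Integer grid, default `c(12, 12, 12)`.
#' @param TR Optional repetition time stored in the header's pixdim slot 4.
#' @return `read_map_nifti` returns the flattened numeric vector with the grid
#'   in attribute `"dim"`.
#' @export
write_map_nifti <- function(values, path, dim = c(12L, 12L, 12L), TR = NULL) {
  if (length(values) != prod(dim)) {
    stop("map length ", length(values), " does not match grid ",
         paste(dim, collapse = "x"))
  }
  arr <- array(as.numeric(values), dim = dim)
  img <- RNifti::asNifti(arr)
  if (!is.null(TR)) {
    RNifti::pixdim(img) <- c(RNifti::pixdim(img)[1:3], TR)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_map_nifti
#' @export
read_map_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  v <- as.numeric(img)
  attr(v, "dim") <- dim(img)
  v
}

#' Read SPM-style realignment parameters
#'
#' Six whitespace-delimited columns: translations in mm, rotations in radians.
#'
#' @param path File path.
#' @return T x 6 numeric matrix.
#' @export
read_motion_params <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6) stop("motion file must have 6 columns, found ", ncol(m))
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  m
}

#' Serialize a fitted PLS model to JSON (+ TSV for the brain side)
#'
#' Scalars and behavior-side vectors go into the JSON; the voxel-length brain
#' saliences, loadings and bootstrap z-maps are written next to it as TSV
#' (`<stem>_brain_<what>.tsv`) to keep the JSON small.
#'
#' @param model Fitted `pls_model`.
#' @param path Path of the JSON file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stem <- sub("\\.json$", "", path)
  payload <- list(
    n = model$n,
    singular_values = model$d,
    explained_covariance = model$explained,
    perm_p = model$perm_p,
    behavior_names = model$behavior_names,
    behavior_saliences = model$u,
    behavior_loadings = model$behavior_loadings,
    behavior_z = model$behavior_z,
    brain_side_files = character()
  )
  brain <- list(salience = model$v, loadings = model$brain_loadings,
                z = model$brain_z)
  for (what in names(brain)) {
    if (!is.null(brain[[what]])) {
      f <- paste0(stem, "_brain_", what, ".tsv")
      write_matrix_tsv(brain[[what]], f)
      payload$brain_side_files <- c(payload$brain_side_files, basename(f))
    }
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Write the run report (flow, components, post-hoc table) as JSON
#'
#' @param report A `run_report` from [run_all()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  cfg <- report$config
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  payload <- list(
    participant_flow = list(stages = report$flow$stages,
                            final = as.list(report$flow$final),
                            final_total = report$flow$final_total),
    components = report$components,
    posthoc = report$posthoc,
    config = cfg,
    r_version = as.character(getRversion())
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
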