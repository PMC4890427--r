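#' BOLD runs, brain masks and subject tables
#'
#' `bold_run()` wraps one subject's 4D BOLD array together with its repetition
#' time and voxel-to-world affine; `brain_mask()` wraps a 3D logical array.
#' These are the units all preprocessing and decomposition functions operate
#' on. Voxel indexing is 0-based in reports; the raster order used to flatten
#' masked voxels is x-fastest (R's native column-major array order), so
#' cluster tables are reproducible across runs.
#'
#' @param data 4D numeric array indexed (x, y, z, t) for `bold_run()`;
#'   3D array coercible to logical for `brain_mask()`.
#' @param tr_seconds Positive repetition time in seconds.
#' @param affine 4x4 voxel-to-world matrix.
#' @param subject_id Subject identifier string.
#' @return An object of class `bold_run` or `brain_mask`.
#' @export
bold_run <- function(data, tr_seconds, affine = diag(c(3, 3, 3, 1)),
                     subject_id = "subject") {
  dims <- dim(data)
  if (is.null(dims) || length(dims) != 4L) {
    stop("bold_run data must be a 4D (x,y,z,t) array, got ",
         length(dims), " dimensions")
  }
  if (dims[4] < 2L) stop("bold_run needs t >= 2 time points")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0) {
    stop("tr_seconds must be a single positive number")
  }
  n_bad <- sum(!is.finite(data))
  if (n_bad > 0L) {
    stop("bold_run data contains ", n_bad, " non-finite voxel values")
  }
  structure(list(data = data, tr_seconds = as.numeric(tr_seconds),
                 affine = affine, subject_id = subject_id),
            class = "bold_run")
}

#' @rdname bold_run
#' @export
brain_mask <- function(data) {
  if (is.null(dim(data)) || length(dim(data)) != 3L) {
    stop("brain_mask data must be a 3D array")
  }
  m <- array(as.logical(data) & !is.na(data), dim = dim(data))
  structure(list(data = m, n_voxels = sum(m)), class = "brain_mask")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run '%s'> %dx%dx%d grid, %d volumes, TR = %g s\n",
              x$subject_id, d[1], d[2], d[3], d[4], x$tr_seconds))
  invisible(x)
}

#' @export
print.brain_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<brain_mask> %dx%dx%d grid, %d voxels in mask\n",
              d[1], d[2], d[3], x$n_voxels))
  invisible(x)
}

#' Load a 4D BOLD volume from a NIfTI-1 file
#'
#' The repetition time is taken from the file header (`pixdim[4]`); a `tr`
#' argument, when given, overrides the header value with a warning, since
#' synthetic fixtures may carry default headers.
#'
#' @param path Path to a `.nii` or `.nii.gz` file holding a 4D volume.
#' @param mask Optional [brain_mask()]; when supplied its spatial shape is
#'   checked against the volume.
#' @param tr Optional repetition time in seconds overriding the header.
#' @param subject_id Identifier stored in the returned run.
#' @return A [bold_run()].
#' @export
load_bold <- function(path, mask = NULL, tr = NULL, subject_id = NULL) {
  nii <- read_nifti(path)
  dims <- dim(nii$data)
  if (length(dims) != 4L) {
    stop("expected a 4D volume, got ", length(dims), "D: ", path)
  }
  n_bad <- sum(!is.finite(nii$data))
  if (n_bad > 0L) {
    stop("volume contains ", n_bad, " non-finite (NaN/Inf) voxel values: ", path)
  }
  header_tr <- nii$tr
  if (!is.null(tr)) {
    if (!is.na(header_tr) && abs(header_tr - tr) > 1e-9) {
      warning(sprintf("config TR = %g s overrides header TR = %g s", tr, header_tr))
    }
    use_tr <- tr
  } else if (!is.na(header_tr)) {
    use_tr <- header_tr
  } else {
    stop("no TR in header of ", path, "; pass tr = explicitly")
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  run <- bold_run(nii$data, tr_seconds = use_tr, affine = nii$affine,
                  subject_id = subject_id)
  if (!is.null(mask)) {
    if (!identical(dim(mask$data), dims[1:3])) {
      stop("mask shape ", paste(dim(mask$data), collapse = "x"),
           " does not match volume grid ", paste(dims[1:3], collapse = "x"))
    }
  }
  run
}

#' @rdname load_bold
#' @param run A [bold_run()] to write.
#' @param datatype On-disk datatype, see [write_nifti()].
#' @export
write_bold <- function(run, path, datatype = "float32") {
  stopifnot(inherits(run, "bold_run"))
  write_nifti(run$data, path, affine = run$affine, tr = run$tr_seconds,
              datatype = datatype)
}

#' Flatten a run to a voxels-by-time matrix and back
#'
#' Rows follow the x-fastest raster order of the `TRUE` mask voxels, i.e. the
#' order `which(mask$data)` yields for R's column-major arrays. `from_matrix()`
#' is the inverse on the mask support; off-mask voxels are filled with 0.
#'
#' @param run A [bold_run()] (or plain 4D array).
#' @param mask A [brain_mask()] with the same spatial shape.
#' @return `to_matrix()`: an `n_voxels x t` matrix. `from_matrix()`: a 4D
#'   array (or 3D when `mat` has one column and `drop = TRUE`).
#' @export
to_matrix <- function(run, mask) {
  data <- if (inherits(run, "bold_run")) run$data else run
  dims <- dim(data)
  if (length(dims) != 4L) stop("to_matrix expects 4D data")
  if (!identical(dim(mask$data), dims[1:3])) {
    stop("mask shape does not match run grid")
  }
  idx <- which(mask$data)
  mat <- matrix(0, nrow = length(idx), ncol = dims[4])
  flat <- matrix(data, nrow = prod(dims[1:3]), ncol = dims[4])
  mat[] <- flat[idx, , drop = FALSE]
  mat
}

#' @rdname to_matrix
#' @param mat Matrix of `mask$n_voxels` rows.
#' @export
from_matrix <- function(mat, mask) {
  if (is.vector(mat)) mat <- matrix(mat, ncol = 1L)
  if (nrow(mat) != mask$n_voxels) {
    stop("matrix has ", nrow(mat), " rows but mask has ", mask$n_voxels,
         " voxels")
  }
  dims <- dim(mask$data)
  idx <- which(mask$data)
  out <- matrix(0, nrow = prod(dims), ncol = ncol(mat))
  out[idx, ] <- mat
  array(out, dim = c(dims, ncol(mat)))
}

subject_table_required_cols <- c(
  "subject_id", "group", "age", "sex", "education_years", "gm_score",
  "nct_a_seconds", "nct_b_seconds", "serial_dotting_seconds",
  "digit_symbol_raw", "line_tracing_raw"
)

#' Read or write the subject table
#'
#' CSV/TSV with one row per subject. Required columns: `subject_id`, `group`
#' (one of HC/NHE/MHE), `age`, `sex` (0/1, 1 = male), `education_years`,
#' `gm_score`, and the five PHES subtest columns (`nct_a_seconds`,
#' `nct_b_seconds`, `serial_dotting_seconds`, `digit_symbol_raw`,
#' `line_tracing_raw`). A `phes_composite` column is carried through when
#' present.
#'
#' @param path CSV (`.csv`) or TSV (`.tsv`/`.txt`) file.
#' @return A `data.frame` with validated columns.
#' @export
read_subject_table <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  validate_subject_table(df)
}

#' @rdname read_subject_table
#' @param df Subject data frame.
#' @export
write_subject_table <- function(df, path) {
  validate_subject_table(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

validate_subject_table <- function(df) {
  missing <- setdiff(subject_table_required_cols, names(df))
  if (length(missing) > 0L) {
    stop("subject table missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$subject_id)) stop("duplicate subject_id values")
  bad <- setdiff(unique(df$group), c("HC", "NHE", "MHE"))
  if (length(bad) > 0L) {
    stop("invalid group labels: ", paste(bad, collapse = ", "),
         " (expected HC, NHE, MHE)")
  }
  df
}
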