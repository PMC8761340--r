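# On-disk layout of a case directory: t1.nii.gz, stir.nii.gz, optional
# t1gad.nii.gz, reference.nii.gz, meta.json; preprocessed (standard-space)
# case directories use the same names plus transforms.json.

#' Write a case to a directory
#'
#' @param case an [multiseq_case()].
#' @param dir destination directory (created if needed).
#' @param transforms optional [case_transforms()] written as
#'   `transforms.json` (4x4 matrices, row-major, world mm).
#' @param extra optional named list merged into `meta.json`.
#' @return `dir`, invisibly.
#' @export
write_case_dir <- function(case, dir, transforms = NULL, extra = NULL) {
  stopifnot(inherits(case, "mvseg_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(case$t1, file.path(dir, "t1.nii.gz"))
  write_volume(case$stir, file.path(dir, "stir.nii.gz"))
  if (!is.null(case$t1gad))
    write_volume(case$t1gad, file.path(dir, "t1gad.nii.gz"))
  write_volume(case$reference, file.path(dir, "reference.nii.gz"))
  meta <- c(list(case_id = case$case_id, location = case$location,
                 t_stage = case$t_stage, n_stage = case$n_stage,
                 t1gad = !is.null(case$t1gad)), extra)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(transforms))
    write_transforms(transforms, file.path(dir, "transforms.json"))
  invisible(dir)
}

#' Read a case from a directory
#'
#' @param dir a directory written by [write_case_dir()].
#' @return An [multiseq_case()].
#' @export
read_case_dir <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  gad_path <- file.path(dir, "t1gad.nii.gz")
  multiseq_case(
    case_id = meta$case_id,
    t1 = read_volume(file.path(dir, "t1.nii.gz"), "T1"),
    stir = read_volume(file.path(dir, "stir.nii.gz"), "STIR"),
    t1gad = if (file.exists(gad_path)) read_volume(gad_path, "T1GAD") else NULL,
    reference = read_volume(file.path(dir, "reference.nii.gz"), mask = TRUE),
    location = meta$location, t_stage = meta$t_stage, n_stage = meta$n_stage)
}

#' Serialize transforms as JSON
#'
#' @param ct a [case_transforms()].
#' @param path JSON destination (matrices stored row-major, world mm).
#' @return `path` (write) or a [case_transforms()] (read).
#' @export
write_transforms <- function(ct, path) {
  stopifnot(inherits(ct, "mvseg_case_transforms"))
  as_rows <- function(a) if (is.null(a)) NULL else
    lapply(seq_len(4), function(r) a$matrix[r, ])
  jsonlite::write_json(
    list(t1_to_std = as_rows(ct$t1_to_std),
         stir_to_t1 = as_rows(ct$stir_to_t1),
         t1gad_to_t1 = as_rows(ct$t1gad_to_t1)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_transforms
#' @export
read_transforms <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  mat <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.matrix(x)) affine_transform(x)
    else affine_transform(matrix(unlist(x), 4, 4, byrow = TRUE))
  }
  case_transforms(mat(js$t1_to_std), mat(js$stir_to_t1), mat(js$t1gad_to_t1))
}
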