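# On-disk cohort layout: one NIfTI per subject per frame plus a `_seg` mask
# companion, a covariate CSV, and a JSON manifest. Pixel indexing in the
# manifest is 0-based row/col.

#' Write one phantom subject to a directory
#'
#' Files: `<id>_ED.nii.gz`, `<id>_ED_seg.nii.gz`, `<id>_ES.nii.gz`,
#' `<id>_ES_seg.nii.gz`, plus `<id>_aux.nii.gz` holding the stacked
#' fat/body/ghost ground-truth masks.
#'
#' @param subject A `phantom_subject`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the subject id.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ph in names(subject$frames)) {
    RNifti::writeNifti(subject$frames[[ph]],
                       file.path(dir, sprintf("%s_%s.nii.gz", subject$id, ph)))
    RNifti::writeNifti(subject$masks[[ph]] + 0,
                       file.path(dir, sprintf("%s_%s_seg.nii.gz", subject$id, ph)))
  }
  aux <- array(0, c(dim(subject$aux$fat), 3))
  aux[, , 1] <- subject$aux$fat
  aux[, , 2] <- subject$aux$body
  aux[, , 3] <- subject$aux$ghost
  RNifti::writeNifti(aux, file.path(dir, sprintf("%s_aux.nii.gz", subject$id)))
  invisible(subject$id)
}

#' Read one phantom subject from a directory
#'
#' Validates that every frame has a mask on the identical grid and that mask
#' labels are in \{0,1,2,3\}; errors name the offending file.
#'
#' @param dir Directory written by [write_subject()] / [write_cohort()].
#' @param id Subject identifier.
#' @param covariates Optional covariate data frame to attach the subject's
#'   record from.
#' @return A `phantom_subject` (without the generator-private `ghosted` flag
#'   if the aux file is absent).
#' @export
read_subject <- function(dir, id, covariates = NULL) {
  frames <- list(); masks <- list()
  for (ph in c("ED", "ES")) {
    f_img <- file.path(dir, sprintf("%s_%s.nii.gz", id, ph))
    f_seg <- file.path(dir, sprintf("%s_%s_seg.nii.gz", id, ph))
    if (!file.exists(f_img)) stop("missing image file: ", f_img)
    if (!file.exists(f_seg)) stop("missing segmentation file: ", f_seg)
    img <- matrix(as.numeric(RNifti::readNifti(f_img)),
                  nrow = dim(RNifti::readNifti(f_img))[1])
    seg <- RNifti::readNifti(f_seg)
    segm <- matrix(as.integer(round(seg)), nrow = dim(seg)[1])
    if (!all(dim(img) == dim(segm)))
      stop("grid mismatch between image and mask: ", f_seg)
    if (!all(segm %in% 0:3))
      stop("unknown label code in mask file: ", f_seg)
    frames[[ph]] <- img
    masks[[ph]] <- segm
  }
  aux <- NULL
  f_aux <- file.path(dir, sprintf("%s_aux.nii.gz", id))
  if (file.exists(f_aux)) {
    a <- RNifti::readNifti(f_aux)
    aux <- list(fat = a[, , 1] > 0.5, body = a[, , 2] > 0.5,
                ghost = a[, , 3] > 0.5)
  }
  cov <- NULL; grp <- substr(id, 1, 1)
  if (!is.null(covariates)) {
    cov <- covariates[covariates$subject_id == id, , drop = FALSE]
    if (nrow(cov) == 1) grp <- cov$group
  }
  structure(list(id = id, group = grp, covariates = cov, frames = frames,
                 masks = masks, aux = aux, ghosted = NA,
                 img_size = nrow(frames$ED)),
            class = "phantom_subject")
}

#' Write a full cohort (images, masks, covariates, manifest)
#'
#' @param cohort A `cmr_cohort`.
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$subjects) write_subject(s, dir)
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  # named atomic vectors must become lists to keep their names in JSON
  shift_ser <- lapply(unclass(cohort$shift), function(x)
    if (!is.null(names(x))) as.list(x) else x)
  manifest <- list(subject_ids = names(cohort$subjects),
                   img_size = cohort$img_size,
                   pixel_indexing = "0-based row/col",
                   shift = shift_ser)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#' @param dir Cohort directory.
#' @return A `cmr_cohort` (the shift config is restored from the manifest).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  covs <- utils::read.csv(file.path(dir, "covariates.csv"),
                          stringsAsFactors = FALSE)
  subjects <- lapply(manifest$subject_ids, function(id)
    read_subject(dir, id, covs))
  names(subjects) <- manifest$subject_ids
  sh <- manifest$shift
  shift <- shift_config(
    fat_thickness_delta = sh$fat_thickness_delta,
    fat_intensity_delta = sh$fat_intensity_delta,
    ghost_prevalence = unlist(sh$ghost_prevalence),
    ghost_amplitude = unlist(sh$ghost_amplitude),
    ghost_spacing = sh$ghost_spacing,
    ghost_n_echoes = sh$ghost_n_echoes,
    ghost_axis = unlist(sh$ghost_axis),
    heart_shape_delta = sh$heart_shape_delta,
    covariate_image_coupling = unlist(sh$covariate_image_coupling),
    ghost_year_coupling = sh$ghost_year_coupling,
    noise_sigma = sh$noise_sigma)
  structure(list(subjects = subjects, covariates = covs, shift = shift,
                 img_size = manifest$img_size),
            class = "cmr_cohort")
}
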