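#' Group-shift configuration for the phantom generator
#'
#' A `shift_config` is the ground-truth specification of where and how the two
#' groups of a synthetic cohort differ. Every between-group distributional
#' shift the generator can produce is declared here, so downstream audits can
#' be validated against a known mechanism. With all deltas at zero (and equal
#' ghost prevalences) the two groups are exchangeable in distribution.
#'
#' Pixel-valued fields (`fat_thickness_delta`, `ghost_spacing`) are expressed
#' on the reference 96x96 grid and rescaled proportionally when rendering at
#' other sizes.
#'
#' @param fat_thickness_delta Added mean subcutaneous fat-ring thickness for
#'   group B, in pixels (reference grid).
#' @param fat_intensity_delta Added fat-ring intensity for group B, in
#'   normalized intensity units.
#' @param ghost_prevalence Named numeric `c(A=, B=)`: per-group probability
#'   that a subject's acquisition carries a ghosting artefact.
#' @param ghost_amplitude First-echo amplitude as a fraction of the ring
#'   intensity; echo k is scaled by `ghost_amplitude^k`. A scalar applies to
#'   both groups; a named vector `c(A=, B=)` sets per-group severities
#'   (different acquisition protocols produce artefacts of different
#'   strength).
#' @param ghost_spacing Pixel offset between successive echoes along the
#'   phase-encode axis.
#' @param ghost_n_echoes Number of echoes injected.
#' @param ghost_axis Named character `c(A=, B=)`, each `"row"` or `"col"`:
#'   per-group phase-encode axis of the echoes, emulating an
#'   acquisition-protocol difference between groups.
#' @param heart_shape_delta Multiplicative scale factor added to group-B heart
#'   radii (0 means identical heart geometry across groups).
#' @param covariate_image_coupling Named numeric `c(bmi_fat=, lvedm_myo=)`:
#'   linear coefficients linking within-group BMI deviation to fat-ring
#'   thickness (px per kg/m^2) and LVEDM deviation to myocardial thickness
#'   (px per g). Deviations are taken from the subject's own group mean, so
#'   coupling alone induces no between-group image shift.
#' @param ghost_year_coupling Added ghost probability per year of MRI scan
#'   after the earliest year in the cohort (clamped to \[0,1\]); lets a
#'   covariate act as a genuine image-quality confounder.
#' @param noise_sigma Rician noise scale (magnitude of complex Gaussian).
#'
#' @return An object of class `shift_config`.
#' @seealso [shift_config_shifted()], [shift_config_null()]
#' @export
shift_config <- function(fat_thickness_delta = 0,
                         fat_intensity_delta = 0,
                         ghost_prevalence = c(A = 0, B = 0),
                         ghost_amplitude = 0.25,
                         ghost_spacing = 3,
                         ghost_n_echoes = 2,
                         ghost_axis = c(A = "row", B = "row"),
                         heart_shape_delta = 0,
                         covariate_image_coupling = c(bmi_fat = 0.3, lvedm_myo = 0.03),
                         ghost_year_coupling = 0,
                         noise_sigma = 0.02) {
  stopifnot(all(c("A", "B") %in% names(ghost_prevalence)))
  if (any(ghost_prevalence < 0 | ghost_prevalence > 1))
    stop("ghost_prevalence must lie in [0, 1]")
  if (ghost_spacing < 1) stop("ghost_spacing must be >= 1 pixel")
  stopifnot(all(c("A", "B") %in% names(ghost_axis)),
            all(ghost_axis %in% c("row", "col")))
  if (any(ghost_amplitude < 0)) stop("ghost_amplitude must be >= 0")
  if (length(ghost_amplitude) == 1 && is.null(names(ghost_amplitude)))
    ghost_amplitude <- c(A = ghost_amplitude, B = ghost_amplitude)
  stopifnot(all(c("A", "B") %in% names(ghost_amplitude)))
  ghost_amplitude <- ghost_amplitude[c("A", "B")]
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(
    fat_thickness_delta = fat_thickness_delta,
    fat_intensity_delta = fat_intensity_delta,
    ghost_prevalence = ghost_prevalence[c("A", "B")],
    ghost_amplitude = ghost_amplitude,
    ghost_spacing = ghost_spacing,
    ghost_n_echoes = ghost_n_echoes,
    ghost_axis = ghost_axis[c("A", "B")],
    heart_shape_delta = heart_shape_delta,
    covariate_image_coupling = covariate_image_coupling,
    ghost_year_coupling = ghost_year_coupling,
    noise_sigma = noise_sigma
  ), class = "shift_config")
}

#' Default image-borne shift used throughout the audits
#'
#' Group B gets a thicker (+1.5 px) and brighter (+0.05) subcutaneous fat
#' ring, and the two groups' ghosting artefacts differ in both phase-encode
#' axis (group A echoes along columns, group B along rows) and severity
#' (first-echo amplitude 0.65 vs 0.45), emulating an acquisition-protocol
#' difference between the groups. Heart geometry is identical across groups,
#' so every group-level signal is located outside the heart. Fat stays below
#' the LV blood-pool intensity, so the per-image min-max normalization
#' reference is the same structure in both groups and the image shift
#' survives heart-blurring; the mutually out-of-distribution artefact
#' patterns give each group clutter the other lacks, which is what makes the
#' segmentation bias symmetric across the imbalance extremes.
#'
#' @param ghost_amplitude Named per-group first-echo amplitudes.
#' @return A `shift_config`.
#' @export
shift_config_shifted <- function(ghost_amplitude = c(A = 0.65, B = 0.45)) {
  shift_config(fat_thickness_delta = 1.5,
               fat_intensity_delta = 0.05,
               ghost_prevalence = c(A = 0.9, B = 0.9),
               ghost_amplitude = ghost_amplitude,
               ghost_spacing = 3,
               ghost_axis = c(A = "col", B = "row"))
}

#' Null configuration: groups exchangeable in image distribution
#' @return A `shift_config` with all between-group deltas at zero.
#' @export
shift_config_null <- function() shift_config()

#' Per-group covariate distribution parameters
#'
#' Continuous covariates are `c(mean, sd)`, binary covariates a probability,
#' and `mri_year` a categorical distribution over calendar years. Age, height,
#' weight and BMI defaults follow published cohort characteristics of
#' race-matched (White/Black) population cine CMR imaging cohorts; the
#' remaining
#' values are physiologically plausible defaults (group B is given a slightly
#' higher LV mass, and group A is on average scanned in earlier years, so the
#' spurious MRI-year confounding scenario can be recreated).
#'
#' @return A named list with elements `A` and `B`, each a list of parameters.
#' @export
covariate_defaults <- function() {
  years <- 2014:2020
  list(
    A = list(age = c(58.9, 7.0), height = c(171.3, 9.1), bmi = c(26.9, 4.6),
             heart_rate = c(68, 10), lvsv = c(75, 14), lvef = c(0.58, 0.06),
             lvedm = c(85, 18),
             diabetes = 0.0, hypertension = 0.25,
             hypercholesterolaemia = 0.20, smoking = 0.30,
             mri_year = stats::setNames(c(.30, .25, .20, .10, .08, .05, .02), years)),
    B = list(age = c(58.8, 6.9), height = c(169.4, 9.2), bmi = c(28.6, 5.1),
             heart_rate = c(70, 11), lvsv = c(74, 14), lvef = c(0.58, 0.06),
             lvedm = c(92, 19),
             diabetes = 0.08, hypertension = 0.35,
             hypercholesterolaemia = 0.20, smoking = 0.30,
             mri_year = stats::setNames(c(.02, .05, .08, .10, .20, .25, .30), years))
  )
}

#' Covariate parameters with identical distributions in both groups
#'
#' Pools the group-specific defaults into one shared table, for null cohorts
#' where exchangeability must hold in covariates as well as images.
#' @return A named list with identical `A` and `B` elements.
#' @export
covariate_defaults_null <- function() {
  d <- covariate_defaults()
  pool <- d$A
  for (nm in names(pool)) {
    a <- d$A[[nm]]; b <- d$B[[nm]]
    pool[[nm]] <- (a + b) / 2
  }
  list(A = pool, B = pool)
}

#' Sample one subject's covariate record
#'
#' Continuous covariates are drawn from group-specific normal distributions;
#' weight is derived from BMI and height (`weight = bmi * (height/100)^2`) so
#' the record is internally consistent; binary comorbidity flags are
#' Bernoulli draws; `mri_year` is categorical. LVEF is clamped to (0.01, 0.99)
#' and age/height/heart rate to positive values.
#'
#' @param group `"A"` or `"B"`.
#' @param sex `"M"` or `"F"`.
#' @param params Per-group parameter list, see [covariate_defaults()].
#' @param id Subject identifier.
#' @return A one-row `data.frame` (the covariate record).
#' @export
sample_covariates <- function(group, sex = "M", params = covariate_defaults(),
                              id = paste0(group, "0001")) {
  if (!group %in% names(params)) stop("unknown group label: ", group)
  p <- params[[group]]
  for (nm in c("age", "height", "bmi", "heart_rate", "lvsv", "lvef", "lvedm"))
    if (length(p[[nm]]) == 2 && p[[nm]][2] < 0) stop("negative SD for ", nm)
  draw <- function(nm) stats::rnorm(1, p[[nm]][1], p[[nm]][2])
  age <- max(draw("age"), 18)
  height <- max(draw("height"), 100)
  bmi <- max(draw("bmi"), 12)
  weight <- bmi * (height / 100)^2
  lvef <- min(max(draw("lvef"), 0.01), 0.99)
  yr <- as.integer(names(p$mri_year)[
    1 + findInterval(stats::runif(1), cumsum(p$mri_year) / sum(p$mri_year))])
  data.frame(
    subject_id = id, group = group, sex = sex,
    age = age, height = height, weight = weight, bmi = bmi,
    heart_rate = max(draw("heart_rate"), 30),
    lvsv = max(draw("lvsv"), 20), lvef = lvef,
    lvedm = max(draw("lvedm"), 30),
    diabetes = stats::rbinom(1, 1, p$diabetes),
    hypertension = stats::rbinom(1, 1, p$hypertension),
    hypercholesterolaemia = stats::rbinom(1, 1, p$hypercholesterolaemia),
    smoking = stats::rbinom(1, 1, p$smoking),
    mri_year = yr,
    stringsAsFactors = FALSE
  )
}

# relative geometry of the reference phantom (fractions of image size)
.phantom_geom <- list(
  body_a = 0.36, body_b = 0.44,
  lung_row = 0.42, lung_dcol = 0.23, lung_a = 0.17, lung_b = 0.105,
  heart_row = 0.55, heart_col = 0.48,
  lv_bp_r = 0.075, myo_t = 0.042,
  rv_dcol = 0.125, rv_r = 0.085, rv_gap = 0.021,
  fat_t = 0.052
)

# fat is bright but below the LV blood pool, so the per-image intensity
# maximum (the min-max normalization reference) is the same structure in
# every subject of both groups
.phantom_intensity <- c(background = 0, body = 0.35, lung = 0.12,
                        fat = 0.72, lvm = 0.3, lvbp = 0.85, rvbp = 0.8)

.ellipse_mask <- function(size, cr, cc, ra, rb) {
  r <- matrix(seq_len(size), size, size)
  cc_ <- matrix(seq_len(size), size, size, byrow = TRUE)
  ((r - cr) / ra)^2 + ((cc_ - cc) / rb)^2 <= 1
}

# Noiseless, artefact-free render of one cardiac phase.
.render_frame <- function(size, phase, fat_t_px, fat_int, heart_scale,
                          myo_t_px, contraction, rv_contraction = 0.85) {
  g <- .phantom_geom
  s <- size
  body <- .ellipse_mask(s, 0.5 * s, 0.5 * s, g$body_a * s, g$body_b * s)
  if (fat_t_px >= min(g$body_a, g$body_b) * s)
    stop("fat ring thickness exceeds body geometry")
  inner <- .ellipse_mask(s, 0.5 * s, 0.5 * s,
                         g$body_a * s - fat_t_px, g$body_b * s - fat_t_px)
  fat <- body & !inner
  lungs <- (.ellipse_mask(s, g$lung_row * s, (0.5 - g$lung_dcol) * s,
                          g$lung_a * s, g$lung_b * s) |
            .ellipse_mask(s, g$lung_row * s, (0.5 + g$lung_dcol) * s,
                          g$lung_a * s, g$lung_b * s)) & inner

  hr <- g$heart_row * s; hc <- g$heart_col * s
  r_bp <- g$lv_bp_r * s * heart_scale
  r_epi <- r_bp + myo_t_px * heart_scale
  r_bp_phase <- if (phase == "ES") r_bp * contraction else r_bp
  lv_epi <- .ellipse_mask(s, hr, hc, r_epi, r_epi)
  lvbp <- .ellipse_mask(s, hr, hc, r_bp_phase, r_bp_phase)
  lvm <- lv_epi & !lvbp
  rv_r <- g$rv_r * s * heart_scale * if (phase == "ES") rv_contraction else 1
  rv_disc <- .ellipse_mask(s, hr, hc - g$rv_dcol * s, rv_r, rv_r)
  rv_excl <- .ellipse_mask(s, hr, hc, r_epi + g$rv_gap * s, r_epi + g$rv_gap * s)
  rvbp <- rv_disc & !rv_excl
  heart <- lv_epi | rvbp
  if (any(heart & !inner)) stop("heart geometry exceeds body interior")

  ii <- .phantom_intensity
  img <- matrix(ii["background"], s, s)
  img[body] <- ii["body"]
  img[fat] <- ii["fat"] + fat_int
  img[lungs & !heart] <- ii["lung"]
  img[lvm] <- ii["lvm"]
  img[lvbp] <- ii["lvbp"]
  img[rvbp] <- ii["rvbp"]

  mask <- matrix(0L, s, s)
  mask[lvbp] <- 1L
  mask[lvm] <- 2L
  mask[rvbp] <- 3L
  list(image = img, mask = mask, fat = fat, body = body)
}

#' Inject ghosting-artefact echoes into an image
#'
#' Adds `n_echoes` attenuated copies of the ring-masked intensities, each
#' translated by `k * spacing` pixels along the phase-encode (row) axis and
#' scaled by `amplitude^k`, emulating the regular echoes of bright skin/fat
#' layers produced by periodic acquisition errors. Echoes that fall outside
#' the grid are clipped, and echo contributions that land back on the bright
#' ring itself are suppressed (they would be invisible against it, and
#' leaving them out keeps the image's intensity maximum - the min-max
#' normalization reference - stable). The echo support (shifted ring
#' positions off the ring) is returned as the ground-truth artefact mask.
#'
#' @param image Numeric matrix.
#' @param ring_mask Logical matrix marking the bright ring to be echoed.
#' @param amplitude First-echo amplitude fraction (>= 0).
#' @param spacing Pixels between successive echoes (>= 1).
#' @param n_echoes Number of echoes.
#' @param axis `"row"` or `"col"`: the phase-encode axis along which echoes
#'   are displaced.
#' @return A list with `image` (with echoes added) and `ghost` (logical
#'   support mask of the echoes).
#' @export
inject_ghosting <- function(image, ring_mask, amplitude, spacing, n_echoes,
                            axis = "row") {
  if (spacing < 1) stop("spacing must be >= 1 pixel")
  if (amplitude < 0) stop("amplitude must be >= 0")
  stopifnot(axis %in% c("row", "col"))
  flip <- axis == "col"
  if (flip) { image <- t(image); ring_mask <- t(ring_mask) }
  h <- nrow(image)
  out <- image
  support <- matrix(FALSE, h, ncol(image))
  ring_vals <- image * ring_mask
  if (amplitude > 0 && n_echoes >= 1) {
    for (k in seq_len(n_echoes)) {
      off <- round(k * spacing)
      if (off >= h) break
      rows_to <- (off + 1):h
      rows_from <- 1:(h - off)
      add <- amplitude^k * ring_vals[rows_from, ]
      add[ring_mask[rows_to, ]] <- 0
      out[rows_to, ] <- out[rows_to, ] + add
      support[rows_to, ] <- support[rows_to, ] |
        (ring_mask[rows_from, ] & !ring_mask[rows_to, ])
    }
  }
  if (flip) { out <- t(out); support <- t(support) }
  list(image = out, ghost = support)
}

.rician_noise <- function(img, sigma) {
  if (sigma <= 0) return(img)
  n <- length(img)
  sqrt((img + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

#' Render one synthetic subject
#'
#' Renders the ED and ES frames of a short-axis slice for one subject: body
#' ellipse, subcutaneous fat ring (thickness = base + coupling * (bmi - group
#' mean) + group delta), lung fields, LV blood pool disc, myocardial annulus,
#' and RV blood-pool crescent; the ES frame applies a radial contraction to
#' the blood pools with the epicardial border fixed (wall thickening).
#' Ghosting is injected with the group's prevalence and Rician noise added
#' last. Masks and auxiliary ground-truth masks (fat ring, body, ghost-echo
#' support) are consistent with the rendered geometry.
#'
#' @param cov One-row covariate record from [sample_covariates()].
#' @param shift A [shift_config()].
#' @param img_size Grid size in pixels (square).
#' @param contraction ES/ED LV blood-pool radial contraction factor.
#' @param group_center Named list per group of centering values
#'   `c(bmi=, lvedm=)` used by the covariate-image coupling; defaults to the
#'   means of [covariate_defaults()].
#' @param year_range Calendar-year range used by `ghost_year_coupling`.
#' @return An object of class `phantom_subject`: list with `id`, `group`,
#'   `covariates`, `frames` (ED/ES images), `masks` (ED/ES label matrices,
#'   0=background 1=LVBP 2=LVM 3=RVBP), `aux` (fat/body/ghost masks) and
#'   `ghosted` flag.
#' @export
render_subject <- function(cov, shift = shift_config(), img_size = 96,
                           contraction = 0.75, group_center = NULL,
                           year_range = c(2014L, 2020L)) {
  if (!inherits(shift, "shift_config")) stop("shift must be a shift_config")
  scale_px <- img_size / 96
  if (is.null(group_center)) {
    d <- covariate_defaults()
    group_center <- lapply(d, function(p) c(bmi = p$bmi[1], lvedm = p$lvedm[1]))
  }
  ctr <- group_center[[cov$group]]
  coup <- shift$covariate_image_coupling
  is_b <- cov$group == "B"

  fat_t <- .phantom_geom$fat_t * img_size +
    (coup[["bmi_fat"]] * (cov$bmi - ctr[["bmi"]]) +
       if (is_b) shift$fat_thickness_delta else 0) * scale_px
  # clamp so extreme covariate draws stay renderable (ring must not reach
  # the heart); documented saturation of the coupling
  fat_t <- min(max(fat_t, 1), 0.095 * img_size)
  fat_int <- if (is_b) shift$fat_intensity_delta else 0
  myo_t <- .phantom_geom$myo_t * 96 +  # coupling defined on the reference grid
    coup[["lvedm_myo"]] * (cov$lvedm - ctr[["lvedm"]])
  myo_t <- max(myo_t, 1) * scale_px
  heart_scale <- 1 + if (is_b) shift$heart_shape_delta else 0

  frames <- list(); masks <- list()
  aux <- NULL
  for (ph in c("ED", "ES")) {
    fr <- .render_frame(img_size, ph, fat_t, fat_int, heart_scale, myo_t,
                        contraction)
    frames[[ph]] <- fr$image
    masks[[ph]] <- fr$mask
    if (is.null(aux)) aux <- list(fat = fr$fat, body = fr$body)
  }

  prev <- min(1, shift$ghost_prevalence[[cov$group]] +
                shift$ghost_year_coupling * (cov$mri_year - year_range[1]))
  ghosted <- stats::runif(1) < prev
  ghost_mask <- matrix(FALSE, img_size, img_size)
  if (ghosted) {
    sp <- max(1, round(shift$ghost_spacing * scale_px))
    for (ph in c("ED", "ES")) {
      gh <- inject_ghosting(frames[[ph]], aux$fat,
                            shift$ghost_amplitude[[cov$group]],
                            sp, shift$ghost_n_echoes,
                            axis = shift$ghost_axis[[cov$group]])
      frames[[ph]] <- gh$image
      ghost_mask <- ghost_mask | gh$ghost
    }
  }
  aux$ghost <- ghost_mask
  for (ph in c("ED", "ES"))
    frames[[ph]] <- matrix(.rician_noise(frames[[ph]], shift$noise_sigma),
                           img_size, img_size)

  structure(list(id = cov$subject_id, group = cov$group, covariates = cov,
                 frames = frames, masks = masks, aux = aux,
                 ghosted = ghosted, img_size = img_size),
            class = "phantom_subject")
}

#' Generate a two-group synthetic cohort
#'
#' Draws `n_per_group` subjects per group, each sex-balanced as closely as
#' parity allows (an odd group size assigns the extra subject male), samples
#' covariates from the per-group tables, and renders every subject.
#'
#' @param n_per_group Subjects per group (>= 1).
#' @param shift A [shift_config()].
#' @param seed Optional integer seed; fixing it makes the cohort
#'   reproducible bit-for-bit.
#' @param covariate_params See [covariate_defaults()].
#' @param img_size Grid size in pixels.
#' @param contraction ES contraction factor.
#' @return An object of class `cmr_cohort`: list with `subjects` (named list
#'   of `phantom_subject`), `covariates` (data frame), `shift`, `img_size`.
#' @export
generate_cohort <- function(n_per_group, shift = shift_config(), seed = NULL,
                            covariate_params = covariate_defaults(),
                            img_size = 96, contraction = 0.75) {
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  group_center <- lapply(covariate_params,
                         function(p) c(bmi = p$bmi[1], lvedm = p$lvedm[1]))
  yrs <- as.integer(names(covariate_params$A$mri_year))
  subjects <- list()
  cov_rows <- list()
  for (grp in c("A", "B")) {
    n_male <- ceiling(n_per_group / 2)
    sexes <- c(rep("M", n_male), rep("F", n_per_group - n_male))
    for (i in seq_len(n_per_group)) {
      id <- sprintf("%s%04d", grp, i)
      cov <- sample_covariates(grp, sexes[i], covariate_params, id)
      subj <- render_subject(cov, shift, img_size, contraction,
                             group_center = group_center,
                             year_range = range(yrs))
      subjects[[id]] <- subj
      cov_rows[[id]] <- cov
    }
  }
  structure(list(subjects = subjects,
                 covariates = do.call(rbind, cov_rows),
                 shift = shift, img_size = img_size),
            class = "cmr_cohort")
}

#' @export
print.cmr_cohort <- function(x, ...) {
  tab <- table(x$covariates$group)
  cat(sprintf("cmr_cohort: %d subjects (%s), %dx%d grid\n",
              nrow(x$covariates),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              x$img_size, x$img_size))
  invisible(x)
}

#' Heart foreground mask (union of LVBP, LVM, RVBP) for one frame
#' @param mask Integer label matrix.
#' @return Logical matrix.
#' @export
heart_foreground <- function(mask) mask > 0L
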