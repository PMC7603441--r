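# Synthetic cephalometric cohorts with known ground truth: an ideal
# arc-convergent template (all four planes concurrent at O, arc membership
# exact), skeletal-class and digitization perturbations, repeat
# digitizations, and palate/mandible shape labels drawn from a reference
# joint distribution.

.uvec <- function(deg) c(cos(deg * pi / 180), sin(deg * pi / 180))

#' Configuration of the ideal template
#'
#' The template is built directly in frame coordinates (sella at the
#' origin, true horizontal +x, superior +y, mm). Point O and the four plane
#' directions are fixed; every landmark is then derived so that all four
#' planes pass through O exactly, ANS / N / U1 / Pog lie on the anterior
#' arc, Go / Sp on the posterior arc, and Pog on the mandibular plane
#' (optionally lifted above it, emulating its true anatomical position
#' superior to menton).
#'
#' Defaults place O posterior to the occipital region with basal plane
#' +7 degrees (so the frame transform is the identity), palatal -3,
#' occlusal -7.5 and mandibular -11 degrees, and an anterior radius giving
#' |SN| of about 71 mm.
#'
#' @param O point O in frame mm.
#' @param angles named numeric vector of plane directions (degrees,
#'   signed): `mandibular`, `occlusal`, `palatal`, `basal`.
#' @param r_anterior,r_posterior arc radii, mm.
#' @param t_PNS,t_U6,t_Me along-plane distances from O of PNS, the molar
#'   midpoint and Me, mm.
#' @param si_x frame x at which Si sits on the basal plane.
#' @param pog_above_mdp vertical lift of the traced Pog above the
#'   mandibular plane, mm (0 = strict ideal template).
#' @param pv_deviation signed palatal-vault deviation from the ANS-PNS
#'   chord as a fraction of chord length (inferior positive); the `PV`
#'   landmark is emitted accordingly.
#' @return Object of class `"template_config"`.
#' @export
template_config <- function(O = c(-248, -33.4506),
                            angles = c(mandibular = -11, occlusal = -7.5,
                                       palatal = -3, basal = 7),
                            r_anterior = 321.2, r_posterior = 242.5,
                            t_PNS = 265.4, t_U6 = 275.4, t_Me = 310,
                            si_x = 0, pog_above_mdp = 0, pv_deviation = 0) {
  need <- c("mandibular", "occlusal", "palatal", "basal")
  if (!all(need %in% names(angles))) stop("angles must name all four planes")
  if (r_anterior <= 0 || r_posterior <= 0) stop("radii must be positive")
  if (any(abs(angles) >= 90))
    stop("plane directions must point anteriorly (|angle| < 90 degrees)")
  structure(list(O = .as_pt(O), angles = angles[need],
                 r_anterior = r_anterior, r_posterior = r_posterior,
                 t_PNS = t_PNS, t_U6 = t_U6, t_Me = t_Me, si_x = si_x,
                 pog_above_mdp = pog_above_mdp, pv_deviation = pv_deviation),
            class = "template_config")
}

#' Build the ideal arc-convergent landmark template
#'
#' @param cfg a [template_config()].
#' @param subject_id identifier for the emitted set.
#' @return A [landmark_set()] in mm frame coordinates. The generating
#'   geometry (O, plane angles, radii) is attached as the
#'   `"ground_truth"` attribute.
#' @export
make_ideal_template <- function(cfg = template_config(),
                                subject_id = "template") {
  stopifnot(inherits(cfg, "template_config"))
  O <- cfg$O
  a <- cfg$angles
  u_mand <- .uvec(a[["mandibular"]]); u_occ <- .uvec(a[["occlusal"]])
  u_pal <- .uvec(a[["palatal"]]); u_bas <- .uvec(a[["basal"]])
  if (cfg$si_x <= O[1])
    stop("inconsistent config: Si must lie anterior to O on the basal plane")
  Si <- O + (cfg$si_x - O[1]) / u_bas[1] * u_bas
  # N: anterior intersection of the ray from S=(0,0) along the basal
  # direction with the anterior arc
  qb <- -2 * sum(u_bas * O)
  qc <- sum(O^2) - cfg$r_anterior^2
  disc <- qb^2 - 4 * qc
  if (disc <= 0)
    stop("inconsistent config: the S-N ray does not reach the anterior arc")
  tN <- (-qb + sqrt(disc)) / 2
  if (tN <= 0)
    stop("inconsistent config: anterior arc lies entirely posterior to S")
  N <- tN * u_bas
  ANS <- O + cfg$r_anterior * u_pal
  PNS <- O + cfg$t_PNS * u_pal
  U1 <- O + cfg$r_anterior * u_occ
  U6 <- O + cfg$t_U6 * u_occ
  Go <- O + cfg$r_posterior * u_mand
  Me <- O + cfg$t_Me * u_mand
  Pog <- O + cfg$r_anterior * u_mand + c(0, cfg$pog_above_mdp)
  Sp <- O + cfg$r_posterior * u_bas
  chord <- ANS - PNS
  len <- sqrt(sum(chord^2))
  inferior_n <- c(chord[2], -chord[1]) / len
  PV <- (ANS + PNS) / 2 + cfg$pv_deviation * len * inferior_n
  ls <- landmark_set(subject_id,
                     list(S = c(0, 0), N = N, ANS = ANS, PNS = PNS,
                          Go = Go, Me = Me, Pog = Pog, Sp = Sp, Si = Si,
                          U1 = U1, L1 = U1, U6 = U6, L6 = U6, PV = PV),
                     units = "mm")
  attr(ls, "ground_truth") <- list(O = O, angles = norm_dir(a),
                                   r_anterior = cfg$r_anterior,
                                   r_posterior = cfg$r_posterior,
                                   sn_length = tN, config = cfg)
  ls
}

#' Cohort generation parameters
#'
#' Defaults mirror the reference study conditions: 100 subjects with a
#' 28/26/46 skeletal class I/II/III mix, class II/III as a -/+6 mm sagittal
#' displacement of the mandibular landmarks, 0.5 mm isotropic digitization
#' noise, traced Pog 4 mm superior to the mandibular plane, a 5% sd
#' per-subject isotropic scale (so SN and Go-Me co-vary across subjects),
#' and shape labels drawn from the reference joint distribution.
#'
#' @param n cohort size.
#' @param class_mix proportions of skeletal classes I, II, III (sum 1).
#' @param class_shift sagittal displacement magnitude for class II
#'   (posterior) and III (anterior), mm.
#' @param digitization_sd per-axis Gaussian landmark noise, mm.
#' @param scale_sd sd of the per-subject isotropic scale factor.
#' @param pog_lift vertical lift of traced Pog above the mandibular plane,
#'   mm.
#' @param label_joint 3x3 joint probabilities (mandible rows x palate
#'   columns); defaults to [shape_reference_counts()] / 100.
#' @param seed integer seed; all cohort randomness flows from it.
#' @return Object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n = 100, class_mix = c(I = 0.28, II = 0.26, III = 0.46),
                        class_shift = 6, digitization_sd = 0.5,
                        scale_sd = 0.05, pog_lift = 4,
                        label_joint = NULL, seed = 1) {
  if (abs(sum(class_mix) - 1) > 1e-9) stop("class_mix must sum to 1")
  if (digitization_sd < 0 || scale_sd < 0) stop("sd parameters must be >= 0")
  if (is.null(label_joint))
    label_joint <- unclass(shape_reference_counts()) / 100
  if (abs(sum(label_joint) - 1) > 1e-9)
    stop("label_joint probabilities must sum to 1")
  structure(list(n = as.integer(n), class_mix = class_mix,
                 class_shift = class_shift,
                 digitization_sd = digitization_sd, scale_sd = scale_sd,
                 pog_lift = pog_lift, label_joint = label_joint,
                 seed = as.integer(seed)), class = "cohort_spec")
}

#' Generate a synthetic cephalometric cohort
#'
#' Each subject is the ideal template with (1) a per-subject isotropic
#' scale about sella, (2) a class-dependent sagittal displacement of Go,
#' Me and Pog (class II posterior, class III anterior), (3) the traced Pog
#' lifted above the mandibular plane, and (4) independent Gaussian
#' digitization jitter on every landmark. True (pre-jitter) landmarks,
#' skeletal class and shape labels are recorded per subject.
#'
#' @param spec a [cohort_spec()].
#' @param template_cfg a [template_config()]; its `pog_above_mdp` is
#'   overridden by `spec$pog_lift`.
#' @return Object of class `"ceph_cohort"`: `subjects` (list of
#'   [landmark_set()]s), `truth` (list of pre-jitter sets), `meta`
#'   (data frame with subject_id, class, scale, palate, mandible), `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            template_cfg = template_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  classes <- sample(c("I", "II", "III"), spec$n, replace = TRUE,
                    prob = spec$class_mix)
  labels <- sample_shape_labels(spec$n, spec$label_joint)
  subjects <- vector("list", spec$n)
  truth <- vector("list", spec$n)
  scales <- numeric(spec$n)
  for (i in seq_len(spec$n)) {
    cfg <- template_cfg
    cfg$pog_above_mdp <- spec$pog_lift
    id <- sprintf("subj_%03d", i)
    tpl <- make_ideal_template(cfg, subject_id = id)
    s <- max(0.5, 1 + stats::rnorm(1, 0, spec$scale_sd))
    scales[i] <- s
    pts <- lapply(tpl$points, function(p) p * s)
    shift <- switch(classes[i], I = 0, II = -spec$class_shift,
                    III = spec$class_shift)
    for (nm in c("Go", "Me", "Pog"))
      pts[[nm]] <- pts[[nm]] + c(shift, 0)
    true_ls <- landmark_set(id, pts, units = "mm")
    jit <- lapply(pts, function(p) p + stats::rnorm(2, 0, spec$digitization_sd))
    subjects[[i]] <- landmark_set(id, jit, units = "mm")
    truth[[i]] <- true_ls
  }
  structure(list(subjects = subjects, truth = truth,
                 meta = data.frame(subject_id = vapply(subjects, function(s)
                                     s$subject_id, character(1)),
                                   class = classes, scale = scales,
                                   palate = labels$palate,
                                   mandible = labels$mandible,
                                   stringsAsFactors = FALSE),
                 spec = spec), class = "ceph_cohort")
}

#' @export
print.ceph_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cephalometric cohort: n = %d (seed %d)\n",
              length(x$subjects), x$spec$seed))
  print(table(x$meta$class))
  invisible(x)
}

#' Re-digitize a landmark set with Gaussian noise
#'
#' Emulates a repeat digitization session: each point is perturbed by
#' independent Gaussian noise of the given sd per axis.
#'
#' @param ls a [landmark_set()].
#' @param sd per-axis noise, mm (>= 0).
#' @param seed optional integer seed.
#' @return The perturbed set.
#' @export
digitize_repeat <- function(ls, sd, seed = NULL) {
  stopifnot(inherits(ls, "landmark_set"), sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  ls$points <- lapply(ls$points, function(p) p + stats::rnorm(2, 0, sd))
  ls
}

#' Sample palate/mandible shape labels from a joint distribution
#'
#' @param n number of subjects.
#' @param joint 3x3 probabilities, mandible shapes (curved, horizontal,
#'   oblique) by palate shapes (concave, convex, horizontal); defaults to
#'   [shape_reference_counts()] / 100.
#' @param seed optional integer seed.
#' @return Data frame with character columns `palate` and `mandible`.
#' @export
sample_shape_labels <- function(n, joint = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(joint)) joint <- unclass(shape_reference_counts()) / 100
  joint <- as.matrix(joint)
  if (abs(sum(joint) - 1) > 1e-9) stop("joint probabilities must sum to 1")
  if (is.null(rownames(joint)))
    rownames(joint) <- c("curved", "horizontal", "oblique")
  if (is.null(colnames(joint)))
    colnames(joint) <- c("concave", "convex", "horizontal")
  cells <- sample(length(joint), n, replace = TRUE, prob = as.vector(joint))
  idx <- arrayInd(cells, dim(joint))
  data.frame(palate = colnames(joint)[idx[, 2]],
             mandible = rownames(joint)[idx[, 1]],
             stringsAsFactors = FALSE)
}

#' Simulate paired anterior-cranial-base / mandibular-body lengths
#'
#' Draws SN lengths from a normal population and generates Go-Me through
#' the linear model `Go-Me = intercept + slope * SN + e`,
#' `e ~ N(0, noise_sd)`. Used for regression parameter-recovery checks.
#'
#' @param n sample size.
#' @param intercept,slope generating coefficients (study defaults 22.65 and
#'   0.5426).
#' @param noise_sd residual sd, mm.
#' @param sn_mean,sn_sd SN population mean and sd, mm.
#' @param seed optional integer seed.
#' @return Data frame with columns `sn` and `gome`.
#' @export
simulate_sn_gome <- function(n = 100, intercept = 22.65, slope = 0.5426,
                             noise_sd = 4.5, sn_mean = 71, sn_sd = 3.5,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sn <- stats::rnorm(n, sn_mean, sn_sd)
  gome <- intercept + slope * sn + stats::rnorm(n, 0, noise_sd)
  data.frame(sn = sn, gome = gome)
}

#' Write a cohort as a directory of landmark CSVs plus metadata
#'
#' One CSV per subject in the canonical dialect and a `metadata.json`
#' recording class, shape labels, scale factors and the generating spec
#' (including the seed).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ceph_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects)
    write_landmarks(s, file.path(dir, paste0(s$subject_id, ".csv")))
  meta <- list(meta = cohort$meta,
               spec = cohort$spec[c("n", "class_mix", "class_shift",
                                    "digitization_sd", "scale_sd",
                                    "pog_lift", "seed")])
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return A list with `subjects` (landmark sets) and `meta` (data frame,
#'   or `NULL` when no metadata file is present).
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) stop("no landmark CSV files in ", dir)
  subjects <- lapply(files, read_landmarks)
  meta_path <- file.path(dir, "metadata.json")
  meta <- if (file.exists(meta_path))
    as.data.frame(jsonlite::read_json(meta_path, simplifyVector = TRUE)$meta)
  else NULL
  list(subjects = subjects, meta = meta, files = files)
}
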