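#' Specification of one synthetic lesion
#'
#' Lesions are ellipsoids with a generalized-Gaussian radial uptake falloff.
#' The falloff is scaled so that uptake crosses half of the lesion's
#' peak-above-background exactly on the ellipsoid surface, which makes the
#' half-maximum isocontour — the ground-truth definition used throughout —
#' coincide with the specified ellipsoid.
#'
#' @param class_label 1 (primary tumor) or 2 (lymph-node metastasis).
#' @param center lesion centre in world mm, length 3.
#' @param semi_axes ellipsoid semi-axes in mm, length 3, all > 0.
#' @param peak_suv peak SUV at the lesion centre; must exceed the background.
#' @param necrotic_core_fraction fraction of the lesion volume occupied by a
#'   central core with suppressed uptake, in `[0, 1)`. Core voxels are
#'   excluded from the ground-truth label, as a reader delineating the
#'   metabolically active volume would exclude them.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(class_label, center, semi_axes, peak_suv,
                        necrotic_core_fraction = 0) {
  stopifnot(class_label %in% c(1L, 2L), length(center) == 3L,
            length(semi_axes) == 3L)
  if (any(semi_axes <= 0)) stop("semi_axes must be positive")
  if (necrotic_core_fraction < 0 || necrotic_core_fraction >= 1) {
    stop("necrotic_core_fraction must lie in [0, 1)")
  }
  structure(list(class_label = as.integer(class_label),
                 center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 peak_suv = as.numeric(peak_suv),
                 necrotic_core_fraction = as.numeric(necrotic_core_fraction)),
            class = "lesion_spec")
}

#' Specification of one synthetic PET/CT phantom
#'
#' @param geometry output [grid_geometry()].
#' @param background_suv homogeneous soft-tissue background SUV (default 1.5,
#'   within the 1–2 range typical of head-and-neck soft tissue).
#' @param lesions list of [lesion_spec()] objects.
#' @param confounders list of physiological hot spots, each a list with
#'   `center`, `semi_axes`, `peak_suv`. They add uptake like lesions but are
#'   labeled background, emulating tonsils, salivary glands, brown fat and
#'   similar FDG-avid structures that a specific delineator must reject.
#' @param noise_sd standard deviation of additive Gaussian PET noise (SUV).
#' @param seed integer seed controlling all randomness in rendering.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry, background_suv = 1.5, lesions = list(),
                         confounders = list(), noise_sd = 0.1, seed = 1L) {
  stopifnot(inherits(geometry, "grid_geometry"), noise_sd >= 0)
  for (l in lesions) {
    if (!inherits(l, "lesion_spec")) stop("lesions must be lesion_spec objects")
    if (l$peak_suv <= background_suv) {
      stop("lesion peak_suv must exceed the background SUV")
    }
  }
  structure(list(geometry = geometry, background_suv = background_suv,
                 lesions = lesions, confounders = confounders,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# World-space coordinates of voxel centres along each axis.
axis_coords <- function(geometry) {
  lapply(1:3, function(ax) {
    geometry$origin[ax] + (seq_len(geometry$shape[ax]) - 1) * geometry$spacing[ax]
  })
}

# Squared normalized ellipsoid radius at every voxel: r^2 = sum ((x-c)/a)^2.
ellipsoid_r2 <- function(geometry, center, semi_axes) {
  co <- axis_coords(geometry)
  dx2 <- ((co[[1]] - center[1]) / semi_axes[1])^2
  dy2 <- ((co[[2]] - center[2]) / semi_axes[2])^2
  dz2 <- ((co[[3]] - center[3]) / semi_axes[3])^2
  sh <- geometry$shape
  outer(outer(dx2, dy2, `+`), dz2, `+`)
}

# Generalized-Gaussian profile: 2^(-r^p). Equals 1 at the centre and exactly
# 1/2 on the ellipsoid surface (r = 1), so the half-maximum contour is crisp.
uptake_profile <- function(r2, shape_power = 6) {
  2^(-(r2^(shape_power / 2)))
}

#' Render a synthetic PET/CT phantom with ground truth
#'
#' Builds the PET volume as background plus ellipsoidal lesion and confounder
#' uptake profiles plus Gaussian noise, a matching CT volume (air outside a
#' body ellipsoid, soft tissue inside, a bone-density spine column, slightly
#' elevated density inside lesions), and the ground-truth label map. A voxel
#' is labeled iff its noise-free lesion uptake exceeds half the lesion's
#' peak-above-background — i.e. it lies inside the lesion ellipsoid — and is
#' not part of a suppressed necrotic core. Confounders are labeled background.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `pet` ([scalar_volume()]), `ct`
#'   ([scalar_volume()]), `labels` ([label_map()]).
#' @examples
#' geom <- grid_geometry(c(32, 32, 16), c(2.5, 2.5, 2.5))
#' les <- lesion_spec(1, center = c(40, 40, 20), semi_axes = c(8, 8, 8),
#'                    peak_suv = 12)
#' ph <- generate_phantom(phantom_spec(geom, lesions = list(les), seed = 7))
#' sum(ph$labels$labels == 1)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- spec$geometry
  sh <- geom$shape
  pet <- array(spec$background_suv, dim = sh)
  labels <- array(0L, dim = sh)
  lesion_extra <- array(0, dim = sh)  # CT density elevation inside lesions

  for (l in spec$lesions) {
    r2 <- ellipsoid_r2(geom, l$center, l$semi_axes)
    amp <- l$peak_suv - spec$background_suv
    prof <- amp * uptake_profile(r2)
    inside <- r2 < 1
    if (l$necrotic_core_fraction > 0) {
      core_r <- l$necrotic_core_fraction^(1 / 3)
      core <- r2 < core_r^2
      prof[core] <- prof[core] * 0.2  # suppressed, falls below half-maximum
      lab_vox <- inside & !core
    } else {
      lab_vox <- inside
    }
    clash <- lab_vox & labels != 0L & labels != l$class_label
    if (any(clash)) {
      stop("lesions of different classes overlap; ground truth would be ambiguous")
    }
    labels[lab_vox] <- l$class_label
    pet <- pet + prof
    lesion_extra[inside] <- lesion_extra[inside] + 15
  }
  for (cf in spec$confounders) {
    r2 <- ellipsoid_r2(geom, cf$center, cf$semi_axes)
    pet <- pet + (cf$peak_suv - spec$background_suv) * uptake_profile(r2)
  }

  # CT: body ellipsoid of soft tissue in air, with a posterior bone column.
  extent <- (sh - 1) * geom$spacing
  body_center <- geom$origin + extent / 2
  body_axes <- pmax(extent / 2 * c(0.9, 0.9, 1.2), geom$spacing)
  body_r2 <- ellipsoid_r2(geom, body_center, body_axes)
  ct <- array(-1000, dim = sh)
  ct[body_r2 < 1] <- 40
  spine_center <- body_center + c(0, extent[2] * 0.25, 0)
  spine_axes <- c(max(extent[1] * 0.08, geom$spacing[1]),
                  max(extent[2] * 0.08, geom$spacing[2]), extent[3] * 2)
  spine_r2 <- ellipsoid_r2(geom, spine_center, spine_axes)
  ct[spine_r2 < 1 & body_r2 < 1] <- 700
  ct <- ct + lesion_extra

  withr::with_seed(spec$seed, {
    if (spec$noise_sd > 0) {
      pet <- pet + array(stats::rnorm(prod(sh), 0, spec$noise_sd), dim = sh)
      ct <- ct + array(stats::rnorm(prod(sh), 0, 10 * spec$noise_sd), dim = sh)
    }
  })
  pet[pet < 0] <- 0

  list(pet = scalar_volume(pet, geom, "PET_SUV"),
       ct = scalar_volume(ct, geom, "CT_HU"),
       labels = label_map(labels, geom))
}

# Log-normal (meanlog, sdlog) matching a target mean and median:
# median = exp(mu), mean = exp(mu + s^2/2)  =>  s^2 = 2 log(mean/median).
lognormal_from_mean_median <- function(mean, median) {
  if (mean <= median) stop("log-normal requires mean > median")
  list(meanlog = log(median), sdlog = sqrt(2 * log(mean / median)))
}

volume_to_radius_mm <- function(volume_ml) {
  (3 * 1000 * volume_ml / (4 * pi))^(1 / 3)
}

#' Sample a cohort of phantom specifications
#'
#' Draws `n` patients, each with exactly one primary tumor and 0–4 lymph-node
#' metastases. Lesion volumes follow log-normal distributions calibrated to
#' the clinical regime (primary tumors: mean 13.21 ml, median 8.16 ml;
#' LN metastases: mean 5.45 ml, median 2.74 ml). Primaries are placed in the
#' upper-central anatomical zone, LN lesions laterally and caudally, and every
#' phantom carries 1–3 physiological confounder hot spots so that specificity
#' is genuinely exercised.
#'
#' @param n number of patients, >= 1.
#' @param seed integer seed; all sampling flows from it.
#' @param geometry [grid_geometry()] shared by all phantoms.
#' @param primary_volume,ln_volume lists with `mean` and `median` (ml) from
#'   which log-normal parameters are derived.
#' @param suv_range length-2 range from which lesion peak SUVs are drawn
#'   uniformly (clinical lesions span roughly SUV 3–22 over a background of
#'   1–2).
#' @param background_suv background SUV passed to each phantom.
#' @param noise_sd PET noise standard deviation passed to each phantom.
#' @param max_ln maximum number of LN metastases per patient.
#' @param necrosis_prob probability that a primary carries a necrotic core.
#' @return list of `n` [phantom_spec()] objects.
#' @export
sample_cohort <- function(n, seed,
                          geometry = grid_geometry(c(64, 64, 48), rep(2.5, 3)),
                          primary_volume = list(mean = 13.21, median = 8.16),
                          ln_volume = list(mean = 5.45, median = 2.74),
                          suv_range = c(4, 22),
                          background_suv = 1.5,
                          noise_sd = 0.1,
                          max_ln = 4L,
                          necrosis_prob = 0.15) {
  if (n < 1) stop("n must be >= 1")
  p_par <- lognormal_from_mean_median(primary_volume$mean, primary_volume$median)
  l_par <- lognormal_from_mean_median(ln_volume$mean, ln_volume$median)
  extent <- (geometry$shape - 1) * geometry$spacing
  org <- geometry$origin

  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      lesions <- list()
      # Primary tumor: upper-central zone.
      v <- stats::rlnorm(1, p_par$meanlog, p_par$sdlog)
      v <- min(v, 60)  # cap so lesions stay inside the field of view
      r <- volume_to_radius_mm(v)
      aniso <- exp(stats::rnorm(3, 0, 0.12)); aniso <- aniso / prod(aniso)^(1 / 3)
      center <- org + extent * c(stats::runif(1, 0.40, 0.60),
                                 stats::runif(1, 0.35, 0.55),
                                 stats::runif(1, 0.55, 0.80))
      ncf <- if (stats::runif(1) < necrosis_prob && v > 8) stats::runif(1, 0.05, 0.25) else 0
      lesions[[1]] <- lesion_spec(1, center, r * aniso,
                                  peak_suv = stats::runif(1, suv_range[1], suv_range[2]),
                                  necrotic_core_fraction = ncf)
      # LN metastases: lateral/caudal zones, alternating sides. Placement is
      # rejected while the ellipsoid could touch a lesion of the other class
      # (ambiguous ground truth); same-class contact is left possible, as in
      # clinical data where neighboring nodes may fuse.
      n_ln <- sample.int(max_ln + 1L, 1L) - 1L
      for (k in seq_len(n_ln)) {
        v <- min(stats::rlnorm(1, l_par$meanlog, l_par$sdlog), 30)
        r <- volume_to_radius_mm(v)
        side <- if (k %% 2 == 0) c(0.12, 0.32) else c(0.68, 0.88)
        a2 <- exp(stats::rnorm(3, 0, 0.12)); a2 <- a2 / prod(a2)^(1 / 3)
        for (try in 1:50) {
          center <- org + extent * c(stats::runif(1, side[1], side[2]),
                                     stats::runif(1, 0.30, 0.60),
                                     stats::runif(1, 0.12, 0.50))
          prim <- lesions[[1]]
          gap <- sqrt(sum((center - prim$center)^2)) -
            1.1 * (max(r * a2) + max(prim$semi_axes))
          if (gap > 0) break
        }
        if (gap <= 0) next  # no admissible spot for a node this large; drop it
        lesions[[length(lesions) + 1L]] <- lesion_spec(2, center, r * a2,
                                         peak_suv = stats::runif(1, suv_range[1],
                                                                 min(suv_range[2], 12)))
      }
      # Physiological confounders: small, modest uptake, labeled background.
      n_cf <- sample.int(3L, 1L)
      confounders <- lapply(seq_len(n_cf), function(j) {
        list(center = org + extent * stats::runif(3, 0.15, 0.85),
             semi_axes = rep(stats::runif(1, 3, 6), 3),
             peak_suv = stats::runif(1, background_suv + 1, background_suv + 3.5))
      })
      phantom_spec(geometry, background_suv = background_suv, lesions = lesions,
                   confounders = confounders, noise_sd = noise_sd,
                   seed = sample.int(.Machine$integer.max, 1L))
    })
  })
}

#' Simulate survival records from total tumor burden values
#'
#' Event times are exponential with a baseline hazard multiplied by
#' `hr_per_split` for subjects whose TTB exceeds the sample median — the same
#' binary high/low-burden covariate used in the downstream Cox analysis.
#' Censoring is independent: each subject is censored with probability
#' `censor_rate`, at a time drawn uniformly before their event.
#'
#' @param ttb_values numeric vector of total tumor burden values (ml).
#' @param hr_per_split hazard ratio of the high-TTB group vs the low group; > 0.
#' @param censor_rate probability of censoring, in `[0, 1)`.
#' @param seed integer seed.
#' @param baseline_hazard events per month in the low-TTB group.
#' @return data.frame with columns `id`, `time` (months), `event` (logical),
#'   `ttb` (ml).
#' @export
simulate_survival <- function(ttb_values, hr_per_split, censor_rate, seed,
                              baseline_hazard = 0.02) {
  if (length(ttb_values) == 0) stop("ttb_values must be non-empty")
  if (hr_per_split <= 0) stop("hr_per_split must be > 0")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must lie in [0, 1)")
  n <- length(ttb_values)
  high <- ttb_values > stats::median(ttb_values)
  withr::with_seed(seed, {
    hazard <- baseline_hazard * ifelse(high, hr_per_split, 1)
    t_event <- stats::rexp(n, hazard)
    censored <- stats::runif(n) < censor_rate
    time <- ifelse(censored, stats::runif(n) * t_event, t_event)
  })
  data.frame(id = seq_len(n), time = pmax(time, .Machine$double.eps),
             event = !censored, ttb = ttb_values)
}
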