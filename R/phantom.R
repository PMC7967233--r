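# Synthetic phantom-nodule generator. Emulates an altered-phantom study
# design: spherical nodules of 5/10/20 mm rendered as 2D crops, optionally
# warped to irregular outlines, with sub-solid and cavitary variants,
# isolated / juxtapleural / juxtavascular surroundings, and quantum noise
# indexed by tube current. Every case carries its ground-truth mask, so the
# whole pipeline can be evaluated without any external data.

PHANTOM_CATEGORIES <- c("solid-round", "solid-irregular", "sub-solid", "cavitary")
PHANTOM_SUBCATEGORIES <- c("isolated", "juxtapleural", "juxtavascular")

# Normalized intensity levels after the -1000..+400 HU window: aerated lung
# ~ -850 HU -> 0.11 (rounded to 0.15 with partial-volume blur), soft-tissue
# nodule ~ -90 HU -> 0.65, chest wall ~ +260 HU -> 0.9.
PHANTOM_LEVELS <- list(lung = 0.15, nodule = 0.65, wall = 0.9)

#' Phantom case configuration
#'
#' @param category one of `"solid-round"`, `"solid-irregular"`,
#'   `"sub-solid"`, `"cavitary"`.
#' @param subcategory one of `"isolated"`, `"juxtapleural"`,
#'   `"juxtavascular"`.
#' @param diameter_mm nodule diameter in mm (study sizes: 5, 10, 20).
#' @param tube_current_mA tube current; noise sigma scales as
#'   `0.05 * sqrt(197 / mA)` (quantum-noise scaling anchored at the
#'   cleanest study current). `Inf` disables noise.
#' @param spacing pixel spacing in mm/px (default 0.5).
#' @param seed integer RNG seed; the same config always renders the same
#'   case.
#' @param ring_thickness_mm cavitary only: thickness of the nodule ring
#'   (default 35% of the diameter). Must be positive and smaller than the
#'   nodule radius.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(category = "solid-round", subcategory = "isolated",
                         diameter_mm = 10, tube_current_mA = 197,
                         spacing = 0.5, seed = 1L,
                         ring_thickness_mm = 0.35 * diameter_mm) {
  category <- match.arg(category, PHANTOM_CATEGORIES)
  subcategory <- match.arg(subcategory, PHANTOM_SUBCATEGORIES)
  if (diameter_mm <= 0) stop("`diameter_mm` must be > 0", call. = FALSE)
  structure(list(category = category, subcategory = subcategory,
                 diameter_mm = diameter_mm, tube_current_mA = tube_current_mA,
                 spacing = spacing, seed = as.integer(seed),
                 ring_thickness_mm = ring_thickness_mm),
            class = "synth_config")
}

noise_sigma <- function(tube_current_mA) 0.05 * sqrt(197 / tube_current_mA)

# Render a case from its recipe. All geometry is analytic: the nodule
# boundary is r(theta) = r0 * (1 + sum_k a_k sin(k theta + phi_k)); image
# and ground truth are derived from the same boundary, the image gets a
# Gaussian rim blur, category features, then additive noise.
render_phantom <- function(cfg, recipe) {
  lv <- PHANTOM_LEVELS
  side <- as.integer(round_half_up(2 * cfg$diameter_mm / cfg$spacing))
  r0 <- cfg$diameter_mm / 2 / cfg$spacing
  ctr <- (side + 1) / 2
  rr <- matrix(seq_len(side), side, side)
  cc <- matrix(seq_len(side), side, side, byrow = TRUE)
  rho <- sqrt((rr - ctr)^2 + (cc - ctr)^2)
  theta <- atan2(rr - ctr, cc - ctr)
  radius_at <- function(th, scale = 1) {
    r <- rep(r0 * scale, length(th))
    ks <- recipe$harmonics
    for (i in seq_along(ks))
      r <- r + r0 * scale * recipe$amplitude[i] * sin(ks[i] * th + recipe$phase[i])
    r
  }
  gt <- rho <= matrix(radius_at(theta), side, side)

  nodule_level <- if (cfg$category == "sub-solid") lv$lung + 0.15 else lv$nodule
  img <- matrix(lv$lung, side, side)
  img[gt] <- nodule_level

  if (cfg$category == "sub-solid") {
    # multiplicative ground-glass texture, mean-one, smooth
    tex <- gaussian_blur(matrix(recipe$texture, side, side), 1.5)
    tex <- 1 + 0.2 * tex / stats::sd(tex)
    img[gt] <- pmin(pmax(img[gt] * tex[gt], 0), 1)
  }
  cavity <- NULL
  if (cfg$category == "cavitary") {
    ring_px <- cfg$ring_thickness_mm / cfg$spacing
    if (cfg$ring_thickness_mm <= 0 || ring_px >= r0)
      stop("invalid cavitary config: ring thickness must be in (0, radius)",
           call. = FALSE)
    cav_scale <- (r0 - ring_px) / r0
    cavity <- rho <= matrix(radius_at(theta, cav_scale), side, side)
    img[cavity] <- lv$lung
    gt <- gt & !cavity
  }

  img <- gaussian_blur(img, recipe$rim_sigma)   # smudged, partial-volume rim

  lung_mask <- matrix(TRUE, side, side)
  tangent_col <- floor(ctr + r0) + 1L
  if (cfg$subcategory == "juxtapleural") {
    wall <- cc >= tangent_col
    img[wall] <- lv$wall
    lung_mask[wall] <- FALSE
    gt <- gt & lung_mask       # a warped outline may not cross into the wall
  } else if (cfg$subcategory == "juxtavascular") {
    w <- recipe$vessel_width
    vessel <- cc >= tangent_col & cc < tangent_col + w
    img[vessel] <- lv$nodule
    gt <- gt & !vessel
  }

  clean <- pmin(pmax(img, 0), 1)
  sigma <- noise_sigma(cfg$tube_current_mA)
  noisy <- if (sigma > 0) clean + matrix(recipe$noise, side, side) * sigma else clean
  noisy <- pmin(pmax(noisy, 0), 1)

  structure(list(
    image = nodule_image(noisy, cfg$spacing, lung_mask = lung_mask,
                         provenance = sprintf("synthetic phantom %s/%s %gmm %gmA seed %d",
                                              cfg$category, cfg$subcategory,
                                              cfg$diameter_mm, cfg$tube_current_mA,
                                              cfg$seed)),
    clean = clean, ground_truth = gt, cavity = cavity,
    config = cfg, recipe = recipe), class = "synth_case")
}

blank_recipe <- function(cfg, side) {
  list(harmonics = integer(0), amplitude = numeric(0), phase = numeric(0),
       rim_sigma = 0.8, vessel_width = 2L,
       texture = rep(0, side^2), noise = rep(0, side^2))
}

#' Render the base circular nodule
#'
#' A centered disk of the configured diameter at soft-tissue intensity over
#' aerated-lung background, with a Gaussian-blurred rim and additive
#' Gaussian noise whose sigma decreases with tube current.
#'
#' @param cfg a [synth_config].
#' @return An object of class `synth_case`: `image` (a [nodule_image]),
#'   `clean` (noiseless intensity matrix), `ground_truth` (logical),
#'   `config` and the realized `recipe`.
#' @export
make_base_disk <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  side <- as.integer(round_half_up(2 * cfg$diameter_mm / cfg$spacing))
  recipe <- blank_recipe(cfg, side)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  recipe$texture <- stats::rnorm(side^2)
  recipe$noise <- stats::rnorm(side^2)
  recipe$vessel_width <- sample(2:4, 1)
  render_phantom(cfg, recipe)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Warp a case to an irregular outline
#'
#' Perturbs the boundary radially, r(theta) = r0 (1 + sum a_k sin(k theta +
#' phi_k)) with harmonics k = 3..8 and small amplitudes, then re-renders the
#' case so image and ground truth are warped identically (the rim blur
#' smudges the new border). With all amplitudes zero the case is unchanged.
#'
#' @param case a `synth_case` from [make_base_disk()].
#' @param max_amplitude per-harmonic amplitude bound (default 0.15; keeps
#'   the warped area within a few percent of the disk).
#' @return A re-rendered `synth_case`.
#' @export
warp_irregular <- function(case, max_amplitude = 0.15) {
  stopifnot(inherits(case, "synth_case"))
  cfg <- case$config
  recipe <- case$recipe
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 1L)
  for (try in 1:20) {
    ks <- 3:8
    amp <- stats::runif(length(ks), -max_amplitude, max_amplitude)
    phi <- stats::runif(length(ks), 0, 2 * pi)
    # reject outlines pinched toward self-intersection
    th <- seq(0, 2 * pi, length.out = 721)
    r <- 1 + colSums(amp * sin(outer(ks, th) + phi))
    if (min(r) > 0.4) break
  }
  recipe$harmonics <- ks
  recipe$amplitude <- amp
  recipe$phase <- phi
  render_phantom(cfg, recipe)
}

#' Apply category-specific features
#'
#' Re-renders the case with its category's extra structure: sub-solid cases
#' get reduced contrast (~0.15) with multiplicative ground-glass texture;
#' cavitary cases get a concentric background-intensity cavity (ground
#' truth = the ring only); juxtapleural cases get a bright chest-wall slab
#' tangent to the nodule, excluded from the lung mask; juxtavascular cases
#' get a bright vessel (2-4 px wide) tangent to the nodule, excluded from
#' the ground truth.
#'
#' @param case a `synth_case` (base disk or warped).
#' @return A re-rendered `synth_case`.
#' @export
apply_category <- function(case) {
  stopifnot(inherits(case, "synth_case"))
  render_phantom(case$config, case$recipe)
}

#' Generate one phantom case from its configuration
#'
#' Chains [make_base_disk()], [warp_irregular()] (for every category except
#' solid-round, whose outline stays circular) and [apply_category()].
#' Deterministic in `cfg$seed`.
#'
#' @param cfg a [synth_config].
#' @return A `synth_case`.
#' @export
make_phantom_case <- function(cfg) {
  case <- make_base_disk(cfg)
  if (cfg$category != "solid-round") case <- warp_irregular(case)
  apply_category(case)
}

#' Reference per-cell case counts
#'
#' The category-by-subcategory layout of the altered-phantom study design:
#' 36 solid-round, 36 solid-irregular, 18 sub-solid and 18 cavitary cases
#' (108 total), each split 4:1:1 across isolated / juxtapleural /
#' juxtavascular surroundings.
#'
#' @return Data frame with columns `category`, `subcategory`, `n`.
#' @export
phantom_reference_counts <- function() {
  counts <- c(24, 6, 6, 24, 6, 6, 12, 3, 3, 12, 3, 3)
  data.frame(category = rep(PHANTOM_CATEGORIES, each = 3),
             subcategory = rep(PHANTOM_SUBCATEGORIES, 4),
             n = counts)
}

#' Generate a phantom dataset
#'
#' Deterministic sweep over the requested category/subcategory cells.
#' Within each cell, diameters and tube currents are cycled so that sizes
#' (5/10/20 mm) and noise levels (30/60/99/197 mA) are balanced. Per-case
#' seeds are derived from the master seed, so the same call always yields
#' the same dataset.
#'
#' @param n_per_cell either a single integer (cases per category x
#'   subcategory cell) or a data frame like [phantom_reference_counts()].
#' @param categories,subcategories cells to include (defaults: all).
#' @param diameters_mm,tube_currents_mA values cycled within each cell.
#' @param spacing pixel spacing in mm/px.
#' @param seed master RNG seed.
#' @return A list with `cases` (list of `synth_case`) and `manifest` (data
#'   frame with one row per case: id, category, subcategory, diameter,
#'   current, seed).
#' @export
make_dataset <- function(n_per_cell = 1, categories = PHANTOM_CATEGORIES,
                         subcategories = PHANTOM_SUBCATEGORIES,
                         diameters_mm = c(5, 10, 20),
                         tube_currents_mA = c(30, 60, 99, 197),
                         spacing = 0.5, seed = 1L) {
  if (is.data.frame(n_per_cell)) {
    cells <- n_per_cell
  } else {
    stopifnot(n_per_cell >= 1)
    cells <- expand.grid(category = categories, subcategory = subcategories,
                         stringsAsFactors = FALSE)
    cells$n <- as.integer(n_per_cell)
    cells <- cells[order(match(cells$category, PHANTOM_CATEGORIES),
                         match(cells$subcategory, PHANTOM_SUBCATEGORIES)), ]
  }
  rows <- list()
  i <- 0L
  for (ci in seq_len(nrow(cells))) {
    for (rep_i in seq_len(cells$n[ci])) {
      i <- i + 1L
      rows[[i]] <- data.frame(
        case_id = i,
        category = cells$category[ci],
        subcategory = cells$subcategory[ci],
        diameter_mm = diameters_mm[(rep_i - 1L) %% length(diameters_mm) + 1L],
        tube_current_mA = tube_currents_mA[(rep_i - 1L) %% length(tube_currents_mA) + 1L],
        seed = (as.integer(seed) %% 100000L) * 10000L + i)
    }
  }
  manifest <- do.call(rbind, rows)
  cases <- lapply(seq_len(nrow(manifest)), function(j) {
    m <- manifest[j, ]
    make_phantom_case(synth_config(m$category, m$subcategory, m$diameter_mm,
                                   m$tube_current_mA, spacing = spacing,
                                   seed = m$seed))
  })
  list(cases = cases, manifest = manifest)
}
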