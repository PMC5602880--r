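# Synthetic two-channel worm-nucleus scenes with exact ground truth.
#
# The photometric model: the green channel renders each nucleus as an
# elliptical annulus (bright lamina rim, dimmer interior) blurred by a small
# PSF; the red channel renders a filled ellipse modulated by band-limited
# texture at ~7 px scale (the GLCM offset used downstream). Nuclear boundaries
# are perturbed by a low-order Fourier series whose amplitude grows with age,
# emulating the loss of round nuclear shape in old worms. The green channel is
# cleaner than the red (red noise sd = 2x green). Out-of-focus distractor
# blobs are added to the green channel below the Otsu threshold by
# construction.

TISSUE_CLASSES <- c("hypodermal", "intestinal", "muscle", "neuronal")
AGE_DAYS <- c(1L, 4L, 6L, 10L, 12L, 14L, 16L)

# class-conditional shape/texture parameters for a 1000 x 1000 canvas
.class_params <- list(
  hypodermal = list(a = c(25, 40), b_over_a = c(0.60, 0.85), red_dim = 1,
                    amp0 = 0.030, amp1 = 0.150, ctex0 = 0.25, ctex1 = 0.30),
  intestinal = list(a = c(35, 55), b_over_a = c(0.70, 0.95), red_dim = 0.85,
                    amp0 = 0.030, amp1 = 0.080, ctex0 = 0.45, ctex1 = 0.05),
  muscle     = list(a = c(10, 18), b_over_a = c(0.40, 0.60), red_dim = 1,
                    amp0 = 0.020, amp1 = 0.040, ctex0 = 0.35, ctex1 = 0.05),
  neuronal   = list(a = c(8, 14),  b_over_a = c(0.85, 1.00), red_dim = 1,
                    amp0 = 0.015, amp1 = 0.030, ctex0 = 0.45, ctex1 = 0.05)
)

# photometric constants (gray levels; P is the dataset ceiling)
.photo <- list(
  P = 4095,
  peak_g = c(1200, 1700),   # per-nucleus green rim peak range
  peak_r = c(2000, 2800),   # per-nucleus red peak range
  interior_frac = 0.55,     # green interior level relative to rim peak
  rim_px = 1.8,             # lamina rim thickness
  psf_sigma = 1.0,          # global blur
  texture_scale = 7,        # red texture correlation length (px)
  distractor_amp = c(100, 180),
  distractor_sigma = c(8, 15)
)

.age_amp <- function(class, day) {
  p <- .class_params[[class]]
  p$amp0 + p$amp1 * (day - 1) / 15
}
.age_ctex <- function(class, day) {
  p <- .class_params[[class]]
  min(0.95, p$ctex0 + p$ctex1 * (day - 1) / 15)
}
.age_noise_mult <- function(day) 1 + 0.08 * (day - 1)

#' Generate a synthetic two-channel nucleus scene
#'
#' Places `n_nuclei` nuclei of the four tissue classes on an empty canvas and
#' renders green (lamina rim) and red (textured chromatin) channels with
#' additive Gaussian noise, returning the image together with exact ground
#' truth (per-pixel label map and per-nucleus class). `clump_fraction` of the
#' nuclei are placed touching a previously placed neighbour; neuronal nuclei
#' are laid out in loose clusters.
#'
#' @param n_nuclei number of nuclei (>= 1).
#' @param class_mix proportions for hypodermal/intestinal/muscle/neuronal;
#'   default 8:2:2:3 (the approximate tissue mix of the original data set).
#' @param age_day adult day in `c(1, 4, 6, 10, 12, 14, 16)`; boundary
#'   irregularity, red-texture contrast and background noise grow with age.
#' @param clump_fraction fraction of nuclei placed touching a neighbour.
#' @param noise_level green-channel noise sd in gray levels at day 1 (red is
#'   2x); default 60.
#' @param seed integer RNG seed; identical seeds reproduce the scene exactly.
#' @param dim canvas size `c(rows, cols)`, default 1000 x 1000.
#' @return list of class `wormnuc_scene` with elements `image`
#'   (a [two_channel_image()]) and `truth` (label_map, classes, specs,
#'   rng_seed, params).
#' @export
generate_scene <- function(n_nuclei, class_mix = c(8, 2, 2, 3) / 15,
                           age_day = 1L, clump_fraction = 0,
                           noise_level = 60, seed = 1L,
                           dim = c(1000L, 1000L)) {
  stopifnot(n_nuclei >= 1, length(class_mix) == 4, all(class_mix >= 0),
            abs(sum(class_mix) - 1) < 1e-8,
            clump_fraction >= 0, clump_fraction <= 1, noise_level >= 0)
  if (!age_day %in% AGE_DAYS) stop("age_day must be one of ",
                                   paste(AGE_DAYS, collapse = ", "))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  specs <- sample_specs(n_nuclei, class_mix, clump_fraction, dim)
  params <- list(dim = as.integer(dim), P = .photo$P,
                 noise_level = noise_level,
                 noise_seed = sample.int(.Machine$integer.max - 1L, 1L),
                 distract_seed = sample.int(.Machine$integer.max - 1L, 1L),
                 n_distractors = max(1L, n_nuclei %/% 5L))
  scene <- render_scene(specs, params, age_day)
  scene$truth$rng_seed <- as.integer(seed)
  scene
}

# draw per-nucleus specifications (geometry + per-nucleus render seeds)
sample_specs <- function(n, mix, clump_fraction, dim) {
  scale <- min(dim) / 1000
  counts <- largest_remainder(mix, n)
  classes <- sample(rep(TISSUE_CLASSES, counts))
  a <- b <- rot <- numeric(n)
  for (i in seq_len(n)) {
    p <- .class_params[[classes[i]]]
    a[i] <- max(4, stats::runif(1, p$a[1], p$a[2]) * scale)
    b[i] <- max(3, a[i] * stats::runif(1, p$b_over_a[1], p$b_over_a[2]))
    rot[i] <- stats::runif(1, 0, pi)
  }
  reff <- (a + b) / 2
  pos <- place_centers(classes, reff, clump_fraction, dim)
  data.frame(
    nucleus_id = seq_len(n), tissue_class = classes,
    row = pos[, 1], col = pos[, 2], a = a, b = b, rotation = rot,
    peak_green = stats::runif(n, .photo$peak_g[1], .photo$peak_g[2]),
    peak_red = stats::runif(n, .photo$peak_r[1], .photo$peak_r[2]) *
      vapply(classes, function(cl) .class_params[[cl]]$red_dim, 0),
    pert_seed = sample.int(.Machine$integer.max - 1L, n),
    tex_seed = sample.int(.Machine$integer.max - 1L, n),
    stringsAsFactors = FALSE
  )
}

largest_remainder <- function(p, n) {
  raw <- p * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# rejection-sampling placement; errors when the canvas cannot host the scene
place_centers <- function(classes, reff, clump_fraction, dim) {
  n <- length(classes)
  pos <- matrix(NA_real_, n, 2)
  margin <- reff * 1.4 + 8
  sep <- 1.15
  neuro_anchor <- NULL
  ok_at <- function(i, ctr, allow = 0L) {
    if (ctr[1] < margin[i] || ctr[1] > dim[1] - margin[i] ||
        ctr[2] < margin[i] || ctr[2] > dim[2] - margin[i]) return(FALSE)
    for (j in seq_len(i - 1L)) {
      d <- sqrt(sum((ctr - pos[j, ])^2))
      lim <- if (j == allow) (reff[i] + reff[j]) * 0.97
             else (reff[i] + reff[j]) * sep
      if (d < lim) return(FALSE)
    }
    TRUE
  }
  for (i in seq_len(n)) {
    placed <- FALSE
    clump <- i > 1L && stats::runif(1) < clump_fraction
    if (clump) {
      j <- sample.int(i - 1L, 1L)
      for (t in 1:40) {
        ang <- stats::runif(1, 0, 2 * pi)
        ctr <- pos[j, ] + (reff[i] + reff[j]) * 1.0 *
          c(cos(ang), sin(ang))
        if (ok_at(i, ctr, allow = j)) { pos[i, ] <- ctr; placed <- TRUE; break }
      }
    }
    if (!placed && classes[i] == "neuronal" && !is.null(neuro_anchor)) {
      j <- neuro_anchor
      for (t in 1:60) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, 1.2, 2.2) * (reff[i] + reff[j])
        ctr <- pos[j, ] + rad * c(cos(ang), sin(ang))
        if (ok_at(i, ctr)) { pos[i, ] <- ctr; placed <- TRUE; break }
      }
    }
    if (!placed) {
      for (t in 1:300) {
        ctr <- c(stats::runif(1, margin[i], dim[1] - margin[i]),
                 stats::runif(1, margin[i], dim[2] - margin[i]))
        if (ok_at(i, ctr)) { pos[i, ] <- ctr; placed <- TRUE; break }
      }
    }
    if (!placed) stop("canvas too small to place ", n,
                      " nuclei without total overlap")
    if (classes[i] == "neuronal" && is.null(neuro_anchor)) neuro_anchor <- i
    if (classes[i] == "neuronal" && stats::runif(1) < 0.25) neuro_anchor <- i
  }
  round(pos)
}

# render a scene at a given age from fixed specs (deterministic)
render_scene <- function(specs, params, age_day) {
  nr <- params$dim[1]; nc <- params$dim[2]
  green <- matrix(0, nr, nc)
  red <- matrix(0, nr, nc)
  label <- matrix(0L, nr, nc)
  best_t <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    amp <- .age_amp(s$tissue_class, age_day)
    ctex <- .age_ctex(s$tissue_class, age_day)
    nuc <- render_nucleus(s, amp, ctex, c(nr, nc))
    ri <- nuc$rows; ci <- nuc$cols
    green[ri, ci] <- green[ri, ci] + nuc$green
    red[ri, ci] <- red[ri, ci] + nuc$red
    upd <- nuc$t <= 1 & nuc$t < best_t[ri, ci]
    lm <- label[ri, ci]; bt <- best_t[ri, ci]
    lm[upd] <- s$nucleus_id; bt[upd] <- nuc$t[upd]
    label[ri, ci] <- lm; best_t[ri, ci] <- bt
  }
  # out-of-focus distractors, green only, dim by construction
  set.seed(params$distract_seed)
  for (k in seq_len(params$n_distractors)) {
    amp <- stats::runif(1, .photo$distractor_amp[1], .photo$distractor_amp[2])
    sg <- stats::runif(1, .photo$distractor_sigma[1],
                       .photo$distractor_sigma[2])
    ctr <- c(stats::runif(1, 3 * sg, nr - 3 * sg),
             stats::runif(1, 3 * sg, nc - 3 * sg))
    rr <- max(1L, floor(ctr[1] - 3 * sg)):min(nr, ceiling(ctr[1] + 3 * sg))
    cc <- max(1L, floor(ctr[2] - 3 * sg)):min(nc, ceiling(ctr[2] + 3 * sg))
    d2 <- outer((rr - ctr[1])^2, (cc - ctr[2])^2, `+`)
    green[rr, cc] <- green[rr, cc] + amp * exp(-d2 / (2 * sg^2))
  }
  green <- gaussian_blur(green, .photo$psf_sigma)
  red <- gaussian_blur(red, .photo$psf_sigma)
  if (params$noise_level > 0) {
    sdg <- params$noise_level * .age_noise_mult(age_day)
    set.seed(params$noise_seed)
    green <- green + matrix(stats::rnorm(nr * nc), nr, nc) * sdg
    red <- red + matrix(stats::rnorm(nr * nc), nr, nc) * (2 * sdg)
  }
  P <- params$P
  green <- round(pmin(pmax(green, 0), P))
  red <- round(pmin(pmax(red, 0), P))
  specs$age_day <- age_day
  truth <- list(label_map = label,
                classes = stats::setNames(specs$tissue_class,
                                          specs$nucleus_id),
                specs = specs, params = params, age_day = age_day,
                rng_seed = NA_integer_)
  structure(list(image = two_channel_image(green, red, P = P),
                 truth = truth),
            class = "wormnuc_scene")
}

# one nucleus on a local patch: returns row/col index ranges, green and red
# intensity patches, and the normalized elliptical radius t (<= 1 inside)
render_nucleus <- function(s, amp, ctex, dim) {
  set.seed(s$pert_seed)
  K <- 5L
  modes <- sample(3:8, K)
  u <- stats::runif(K); u <- u / sum(u)
  phase <- stats::runif(K, 0, 2 * pi)
  wmod <- stats::runif(1, 0.75, 1.25)
  half <- ceiling(s$a * (1 + 1.5 * amp) + 8)
  rows <- max(1L, s$row - half):min(dim[1], s$row + half)
  cols <- max(1L, s$col - half):min(dim[2], s$col + half)
  dy <- rows - s$row
  dx <- cols - s$col
  DY <- matrix(dy, length(rows), length(cols))
  DX <- matrix(dx, length(rows), length(cols), byrow = TRUE)
  xr <- cos(s$rotation) * DX + sin(s$rotation) * DY
  yr <- -sin(s$rotation) * DX + cos(s$rotation) * DY
  ue <- sqrt((xr / s$a)^2 + (yr / s$b)^2)
  th <- atan2(yr / s$b, xr / s$a)
  rho <- 1
  for (k in seq_len(K)) rho <- rho + amp * wmod * u[k] * cos(modes[k] * th +
                                                             phase[k])
  t <- ue / rho
  # green: rim-bright annulus with dim interior; the lamina rim peaks ~2 px
  # inside the truth boundary (t = 1) and falls off steeply outside, so the
  # photometric edge coincides with the geometric one
  rbar <- (s$a + s$b) / 2
  spx <- (t - 1) * rbar               # signed radial distance in px
  rim <- exp(-(spx + 2)^2 / (2 * (.photo$rim_px / 1.5)^2))
  g <- ifelse(spx <= 0, pmax(.photo$interior_frac, rim),
              ifelse(spx <= 4, rim, 0)) * s$peak_green
  # red: filled ellipse with band-limited texture
  set.seed(s$tex_seed)
  tex <- gaussian_blur(matrix(stats::rnorm(length(t)), nrow(t), ncol(t)),
                       .photo$texture_scale / 2)
  rng <- range(tex)
  tex <- if (rng[2] > rng[1]) (tex - rng[1]) / (rng[2] - rng[1]) else tex * 0
  r <- ifelse(t <= 1, (1 - ctex) + ctex * tex, 0) * s$peak_red
  list(rows = rows, cols = cols, green = g, red = r, t = t)
}

#' Age a synthetic scene
#'
#' Re-renders a scene (same nuclei, same random draws) at a later adult day:
#' boundary perturbation amplitude, red texture contrast and background noise
#' are non-decreasing in the target day, so truth-mask solidity of aging
#' tissues (hypodermal above all) decreases.
#'
#' @param scene a `wormnuc_scene` from [generate_scene()].
#' @param from_day the scene's current day (checked).
#' @param to_day target day, `>= from_day`, in the supported day set.
#' @return a new `wormnuc_scene` at `to_day`.
#' @export
degrade_with_age <- function(scene, from_day, to_day) {
  stopifnot(inherits(scene, "wormnuc_scene"))
  if (scene$truth$age_day != from_day) {
    stop("scene is at day ", scene$truth$age_day, ", not ", from_day)
  }
  if (!to_day %in% AGE_DAYS) stop("unsupported day: ", to_day)
  if (to_day < from_day) stop("to_day must be >= from_day")
  if (to_day == from_day) return(scene)
  out <- render_scene(scene$truth$specs, scene$truth$params, to_day)
  out$truth$rng_seed <- scene$truth$rng_seed
  out
}

#' @export
print.wormnuc_scene <- function(x, ...) {
  cat(sprintf("<wormnuc_scene> %d x %d px, %d nuclei, day %d\n",
              nrow(x$image$green), ncol(x$image$green),
              nrow(x$truth$specs), x$truth$age_day))
  print(table(x$truth$specs$tissue_class))
  invisible(x)
}

#' Write a scene to disk
#'
#' Writes the paired channels and the truth label map as 16-bit grayscale
#' TIFFs (`<stem>_g.tif`, `<stem>_r.tif`, `<stem>_truth.tif`), the class table
#' as CSV (`nucleus_id,tissue_class`) and the nucleus specification as JSON.
#'
#' @param scene a `wormnuc_scene`.
#' @param stem output path stem.
#' @return the file paths, invisibly.
#' @export
write_scene <- function(scene, stem) {
  paths <- c(g = paste0(stem, "_g.tif"), r = paste0(stem, "_r.tif"),
             truth = paste0(stem, "_truth.tif"),
             classes = paste0(stem, "_classes.csv"),
             specs = paste0(stem, "_specs.json"))
  write_tiff_gray(scene$image$green, paths["g"])
  write_tiff_gray(scene$image$red, paths["r"])
  write_tiff_gray(scene$truth$label_map, paths["truth"])
  utils::write.csv(data.frame(nucleus_id = scene$truth$specs$nucleus_id,
                              tissue_class = scene$truth$specs$tissue_class),
                   paths["classes"], row.names = FALSE)
  jsonlite::write_json(scene$truth$specs, paths["specs"], digits = NA)
  invisible(paths)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
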