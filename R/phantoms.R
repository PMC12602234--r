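# Seeded phantom generator: elliptical lesion masks plus saliency maps of
# controlled alignment quality. The five tiers emulate the qualitative
# behaviours of explanation methods on clinical images — tight lesion-
# conforming maps, boundary overreach, diffuse blobs, scattered off-target
# fragments, and fully off-target activations — so the metrics and the
# harness are testable without clinical data.

#' Rasterise an elliptical lesion mask
#'
#' Pixel centres lie at integer coordinates; a pixel is foreground when its
#' centre falls inside the (optionally rotated) ellipse.
#'
#' @param shape `c(H, W)` frame size (default 96 x 96).
#' @param center `c(row, col)` ellipse centre; defaults to the frame centre.
#' @param semi_axes `c(a, b)` semi-axes in pixels, each `>= 1`.
#' @param rotation Rotation angle in radians (default 0).
#' @return Binary mask matrix; errors if the rasterised lesion is empty.
#' @export
make_lesion_mask <- function(shape = c(96, 96), center = NULL,
                             semi_axes = c(16, 12), rotation = 0) {
  h <- shape[1]; w <- shape[2]
  if (is.null(center)) center <- c((h + 1) / 2, (w + 1) / 2)
  a <- semi_axes[1]; b <- semi_axes[2]
  if (a < 1 || b < 1) abort("Semi-axes must be at least 1 pixel.")
  rr <- matrix(seq_len(h), h, w) - center[1]
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - center[2]
  u <- cos(rotation) * cc + sin(rotation) * rr
  v <- -sin(rotation) * cc + cos(rotation) * rr
  mask <- ((u / a)^2 + (v / b)^2 <= 1) * 1
  if (sum(mask) == 0) abort("Degenerate lesion: zero area after rasterisation.")
  mask
}

lesion_centroid <- function(mask) {
  fg <- which(mask == 1, arr.ind = TRUE)
  c(mean(fg[, 1]), mean(fg[, 2]))
}

equivalent_diameter <- function(mask) 2 * sqrt(sum(mask) / pi)

gaussian_blob <- function(shape, center, sigma, peak = 1) {
  ry <- exp(-((seq_len(shape[1]) - center[1])^2) / (2 * sigma^2))
  rx <- exp(-((seq_len(shape[2]) - center[2])^2) / (2 * sigma^2))
  peak * outer(ry, rx)
}

# Additive noise truncated at zero so saliency maps stay nonnegative.
truncated_noise <- function(shape, level) {
  if (level <= 0) return(matrix(0, shape[1], shape[2]))
  pmax(matrix(rnorm(prod(shape), 0, level), shape[1], shape[2]), 0)
}

#' Generate a saliency phantom of a given quality tier
#'
#' Deterministic given `(mask, tier, noise, seed)`. Tiers:
#' \describe{
#'   \item{aligned}{mass on the lesion with a sharp exponential falloff just
#'     outside its boundary; at zero noise at least 95% of the mass lies
#'     inside the mask.}
#'   \item{overreach}{uniform mass on the mask dilated by roughly 10% of the
#'     equivalent lesion diameter (at least 2 px) — boundary spillover.}
#'   \item{diffuse}{a broad Gaussian centred on the lesion centroid with
#'     scale 1.5x the equivalent lesion radius.}
#'   \item{scattered}{most mass in compact off-lesion blobs plus a minor
#'     on-lesion component.}
#'   \item{off_target}{all mass in a region disjoint from the lesion (the map
#'     is exactly zero on the mask and a 3 px guard band around it).}
#' }
#'
#' @param mask Binary lesion mask (non-empty).
#' @param tier One of `"aligned"`, `"overreach"`, `"diffuse"`, `"scattered"`,
#'   `"off_target"`.
#' @param noise Standard deviation of additive zero-truncated Gaussian noise
#'   (default 0.05, relative to a unit-peak signal).
#' @param seed Integer seed; same inputs give bit-identical maps.
#' @return Nonnegative saliency matrix.
#' @export
make_saliency_phantom <- function(mask, tier = c("aligned", "overreach",
                                                 "diffuse", "scattered",
                                                 "off_target"),
                                  noise = 0.05, seed = 42L) {
  tier <- match.arg(tier)
  assert_binary_grid(mask)
  if (sum(mask) == 0) abort("`mask` must be non-empty.")
  if (noise < 0) abort("`noise` must be nonnegative.")
  shape <- dim(mask)
  withr::with_seed(as.integer(seed), {
    base <- switch(tier,
      aligned = {
        # unit mass inside G, exponentially decaying 3-pixel skirt outside
        m <- mask
        prev <- mask
        for (k in 1:3) {
          cur <- dilate_disc(mask, k)
          m <- m + exp(-2 * k) * (cur - prev)
          prev <- cur
        }
        m
      },
      overreach = {
        r <- max(2L, as.integer(round(0.1 * equivalent_diameter(mask))))
        dilate_disc(mask, r)
      },
      diffuse = {
        ctr <- lesion_centroid(mask)
        gaussian_blob(shape, ctr, sigma = 1.5 * equivalent_diameter(mask) / 2)
      },
      scattered = {
        m <- 0.2 * mask  # minor on-lesion component, below the 0.5 threshold
        ctr <- lesion_centroid(mask)
        r_excl <- equivalent_diameter(mask) / 2 + 12
        for (b in 1:3) {
          cand <- sample_off_lesion_center(shape, ctr, r_excl)
          m <- m + gaussian_blob(shape, cand, sigma = 6)
        }
        m
      },
      off_target = {
        ctr <- lesion_centroid(mask)
        corners <- rbind(c(10, 10), c(10, shape[2] - 9),
                         c(shape[1] - 9, 10), c(shape[1] - 9, shape[2] - 9))
        d <- sqrt((corners[, 1] - ctr[1])^2 + (corners[, 2] - ctr[2])^2)
        gaussian_blob(shape, corners[which.max(d), ], sigma = 6)
      }
    )
    sal <- base + truncated_noise(shape, noise)
    if (tier == "off_target") {
      sal[dilate_disc(mask, 3) == 1] <- 0  # support strictly disjoint from G
    }
    sal
  })
}

# Uniformly sample a blob centre at least `r_excl` pixels from the lesion
# centroid and 8 pixels from the frame edge. The exclusion radius is capped
# by what the frame can actually satisfy so small frames stay feasible.
sample_off_lesion_center <- function(shape, centroid, r_excl) {
  corners <- rbind(c(9, 9), c(9, shape[2] - 8),
                   c(shape[1] - 8, 9), c(shape[1] - 8, shape[2] - 8))
  d_max <- max(sqrt((corners[, 1] - centroid[1])^2 +
                    (corners[, 2] - centroid[2])^2))
  r_excl <- min(r_excl, 0.7 * d_max)
  repeat {
    p <- c(runif(1, 9, shape[1] - 8), runif(1, 9, shape[2] - 8))
    if (sqrt(sum((p - centroid)^2)) >= r_excl) return(p)
  }
}

#' Generate a planted-channel activation stack
#'
#' Informative channels carry a lesion-concentrated signal with a high mean
#' activation (well separated, by construction, from the low-mean background
#' noise channels), so top-k selection recovers them exactly at the matching
#' k. Deterministic per seed.
#'
#' @param mask Binary lesion mask.
#' @param n_channels Number of channels `C >= 1`.
#' @param informative_fraction Fraction of channels carrying signal, in
#'   `(0, 1]`; the planted count is `max(1, round(fraction * C))` (half-up).
#' @param seed Integer seed.
#' @param template Optional nonnegative signal template (defaults to the mask
#'   indicator); it is rescaled to peak 1.
#' @param noise_sd Standard deviation of the zero-truncated background noise.
#' @return An [activation_stack()] with attribute `informative`, the sorted
#'   indices of the planted channels.
#' @export
make_activation_stack <- function(mask, n_channels = 32,
                                  informative_fraction = 0.2, seed = 42L,
                                  template = NULL, noise_sd = 0.02) {
  assert_binary_grid(mask)
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 1L) abort("`n_channels` must be >= 1.")
  if (informative_fraction <= 0 || informative_fraction > 1) {
    abort("`informative_fraction` must lie in (0, 1].")
  }
  if (is.null(template)) template <- mask
  assert_grid(template, "template")
  if (max(template) > 0) template <- template / max(template)
  shape <- dim(mask)
  n_inf <- max(1L, as.integer(round_half_up(informative_fraction * n_channels)))
  withr::with_seed(as.integer(seed), {
    inf_idx <- sort(sample(n_channels, n_inf))
    channels <- lapply(seq_len(n_channels), function(c) {
      if (c %in% inf_idx) {
        runif(1, 0.8, 1.2) * template + truncated_noise(shape, noise_sd)
      } else {
        truncated_noise(shape, noise_sd)
      }
    })
    structure(activation_stack(channels), informative = inf_idx)
  })
}

#' Generate a seeded phantom dataset
#'
#' Draws `n_per_tier` random elliptical lesions and, for each, one saliency
#' phantom per requested tier (so tiers are paired on identical masks and
#' item ids). A single root seed drives a counter-based per-item stream,
#' making the dataset reproducible and extensible.
#'
#' @param n_per_tier Number of mask/saliency pairs per tier (default 30).
#' @param tiers Character vector of tier names (default: the four rankable
#'   tiers, `aligned`, `overreach`, `diffuse`, `scattered`).
#' @param shape Frame size `c(H, W)` (default 96 x 96).
#' @param noise Noise level passed to [make_saliency_phantom()].
#' @param seed Root seed (default 42).
#' @return A tibble with columns `id`, `tier`, `mask` (list of matrices),
#'   `sal` (list of matrices) and `seed` (the per-item stream seed).
#' @export
phantom_dataset <- function(n_per_tier = 30,
                            tiers = c("aligned", "overreach", "diffuse",
                                      "scattered"),
                            shape = c(96, 96), noise = 0.05, seed = 42L) {
  tiers <- match.arg(tiers, c("aligned", "overreach", "diffuse", "scattered",
                              "off_target"), several.ok = TRUE)
  seed <- as.integer(seed)
  items <- purrr::map(seq_len(n_per_tier), function(i) {
    item_seed <- (seed + 7919L * i) %% .Machine$integer.max
    mask <- withr::with_seed(item_seed, {
      # lesion extent scales with the frame: 12.5%-21% of the short side,
      # centre jittered by up to 1/12 of the frame
      s <- min(shape)
      a <- runif(1, 0.125, 0.21) * s
      b <- runif(1, 0.125, 0.21) * s
      rot <- runif(1, 0, pi)
      jit <- s / 12
      ctr <- c(shape[1] / 2 + runif(1, -jit, jit),
               shape[2] / 2 + runif(1, -jit, jit))
      make_lesion_mask(shape, ctr, c(a, b), rot)
    })
    purrr::map(seq_along(tiers), function(j) {
      sal <- make_saliency_phantom(mask, tiers[j], noise, item_seed + j)
      tibble::tibble(
        id = sprintf("phantom_%03d", i),
        tier = tiers[j],
        mask = list(mask),
        sal = list(sal),
        seed = item_seed
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  items
}
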