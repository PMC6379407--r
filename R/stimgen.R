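#' Display geometry of the simulated monitor
#'
#' Physical description of the display used to convert visual angle to pixels.
#' Defaults describe a 40 x 30 cm CRT at 1024 x 768 px viewed from 58 cm.
#'
#' @param screen_width_cm physical width of the display (cm)
#' @param screen_px_w,screen_px_h resolution (px)
#' @param viewing_distance_cm eye-to-screen distance (cm)
#' @return object of class `display_geometry`
#' @export
display_geometry <- function(screen_width_cm = 40, screen_px_w = 1024,
                             screen_px_h = 768, viewing_distance_cm = 58) {
  g <- list(screen_width_cm = screen_width_cm, screen_px_w = screen_px_w,
            screen_px_h = screen_px_h, viewing_distance_cm = viewing_distance_cm)
  if (!all(vapply(g, function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0,
                  logical(1))))
    stop("invalid display geometry: all fields must be positive finite scalars")
  structure(g, class = "display_geometry")
}

#' Pixels per degree of visual angle
#'
#' One degree at distance d spans 2 d tan(0.5 deg) cm on the screen; the pixel
#' pitch converts that to pixels.
#'
#' @param geom a [display_geometry()]
#' @return pixels per degree (scalar)
#' @examples
#' px_per_degree(display_geometry())  # ~25.92
#' @export
px_per_degree <- function(geom = display_geometry()) {
  stopifnot(inherits(geom, "display_geometry"))
  (geom$screen_px_w / geom$screen_width_cm) *
    2 * geom$viewing_distance_cm * tan(0.5 * pi / 180)
}

#' Vertices of the inducer hexagram
#'
#' Six points on a circle at polar angles 90 + 60k degrees (counterclockwise
#' from rightward; vertex k = 0 at the top). Alternating vertices form an
#' upright (k even) and an inverted (k odd) equilateral triangle whose edge
#' length is `circumradius_deg * sqrt(3)`.
#'
#' @param circumradius_deg radius of the circumscribing circle (deg)
#' @return a 6 x 2 matrix of (x, y) positions in degrees, y upward
#' @export
hexagram_vertices <- function(circumradius_deg) {
  if (!is.numeric(circumradius_deg) || length(circumradius_deg) != 1 ||
      !is.finite(circumradius_deg) || circumradius_deg <= 0)
    stop("circumradius_deg must be a positive scalar")
  ang <- (90 + 60 * (0:5)) * pi / 180
  cbind(x = circumradius_deg * cos(ang), y = circumradius_deg * sin(ang))
}

#' Single pacman inducer
#'
#' A disc with a 60 degree wedge ("jaw") removed; the jaw bisector points along
#' `jaw_heading_deg` (counterclockwise from rightward).
#'
#' @param center_deg length-2 position (deg) relative to figure center
#' @param polarity `"black"` (0 cd/m^2) or `"white"` (40 cd/m^2)
#' @param diameter_deg disc diameter (deg)
#' @param jaw_angle_deg angular width of the removed wedge (deg)
#' @param jaw_heading_deg direction the open jaw faces (deg)
#' @return object of class `inducer_spec`
#' @export
inducer_spec <- function(center_deg, polarity, diameter_deg = 3,
                         jaw_angle_deg = 60, jaw_heading_deg) {
  polarity <- match.arg(polarity, c("black", "white"))
  if (diameter_deg <= 0) stop("diameter_deg must be positive")
  if (jaw_angle_deg <= 0 || jaw_angle_deg >= 360)
    stop("jaw_angle_deg must lie in (0, 360)")
  structure(list(center_deg = as.numeric(center_deg), polarity = polarity,
                 luminance = if (polarity == "black") 0 else 40,
                 diameter_deg = diameter_deg, jaw_angle_deg = jaw_angle_deg,
                 jaw_heading_deg = jaw_heading_deg %% 360),
            class = "inducer_spec")
}

#' Parametric Kanizsa hexagram display
#'
#' Six pacman inducers at the hexagram vertices on a uniform gray background.
#' In the mixed arrangement black inducers occupy the inverted-triangle
#' vertices and white inducers the upright-triangle vertices; homogeneous
#' arrangements use one polarity throughout. Every jaw faces the figure center
#' so the notch edges imply the corners of an illusory triangle.
#'
#' @param inducer_condition `"homog_black"`, `"homog_white"` or `"mixed"`
#' @param blur_sigma_deg Gaussian filter sd, one of [blur_sigmas()]
#' @param circumradius_deg hexagram vertex radius (deg); the default makes the
#'   implied triangle edge 6 deg, matching the comparison triangle
#' @param background_lum background luminance (cd/m^2)
#' @return object of class `kanizsa_spec`
#' @export
kanizsa_spec <- function(inducer_condition, blur_sigma_deg,
                         circumradius_deg = 6 / sqrt(3), background_lum = 20) {
  inducer_condition <- match.arg(inducer_condition,
                                 c("homog_black", "homog_white", "mixed"))
  if (!blur_sigma_deg %in% blur_sigmas())
    stop("blur_sigma_deg must be one of ", paste(blur_sigmas(), collapse = ", "))
  v <- hexagram_vertices(circumradius_deg)
  pol <- switch(inducer_condition,
                homog_black = rep("black", 6),
                homog_white = rep("white", 6),
                # k = 0, 2, 4 (upright triangle) white; k = 1, 3, 5 (inverted) black
                mixed = rep(c("white", "black"), 3))
  heading <- (90 + 60 * (0:5) + 180) %% 360  # jaw faces figure center
  inducers <- lapply(1:6, function(k)
    inducer_spec(v[k, ], pol[k], jaw_heading_deg = heading[k]))
  structure(list(inducers = inducers, circumradius_deg = circumradius_deg,
                 background_lum = background_lum, blur_sigma_deg = blur_sigma_deg,
                 inducer_condition = inducer_condition),
            class = "kanizsa_spec")
}

#' Parametric matching display
#'
#' An equilateral triangle of uniform luminance on a field of white noise
#' (mean 20 cd/m^2) filtered with the same Gaussian as the paired Kanizsa
#' display. The triangle's orientation cues the same-oriented illusory
#' triangle.
#'
#' @param orientation `"up"` or `"down"` (apex direction)
#' @param triangle_lum triangle luminance Lm (cd/m^2), in \[0, 40\]
#' @param blur_sigma_deg Gaussian filter sd (deg)
#' @param edge_len_deg triangle edge length (deg)
#' @param noise_mean_lum mean of the noise field (cd/m^2)
#' @param noise_dist `"uniform"` (on \[0, 40\]) or `"gaussian"` (truncated)
#' @param noise_seed RNG seed for the noise field
#' @param blur_triangle if `TRUE`, blur after compositing the triangle;
#'   default blurs only the noise field
#' @return object of class `match_spec`
#' @export
match_spec <- function(orientation, triangle_lum, blur_sigma_deg,
                       edge_len_deg = 6, noise_mean_lum = 20,
                       noise_dist = c("uniform", "gaussian"),
                       noise_seed = 1L, blur_triangle = FALSE) {
  orientation <- match.arg(orientation, c("up", "down"))
  noise_dist <- match.arg(noise_dist)
  if (!is.finite(triangle_lum) || triangle_lum < 0 || triangle_lum > 40)
    stop("triangle_lum must lie in [0, 40] cd/m^2")
  structure(list(orientation = orientation, edge_len_deg = edge_len_deg,
                 triangle_lum = triangle_lum, noise_mean_lum = noise_mean_lum,
                 blur_sigma_deg = blur_sigma_deg, noise_dist = noise_dist,
                 noise_seed = as.integer(noise_seed),
                 blur_triangle = isTRUE(blur_triangle)),
            class = "match_spec")
}

#' Build the paired stimulus specification for one condition
#'
#' @param inducer_condition `"homog_black"`, `"homog_white"` or `"mixed"`
#' @param blur_sigma_deg one of [blur_sigmas()]
#' @param cue_orientation `"up"` (cues the white/upright triangle) or `"down"`
#'   (cues the black/inverted triangle)
#' @param triangle_lum luminance of the matching triangle (cd/m^2)
#' @param ... further arguments passed to [match_spec()]
#' @return list with elements `kanizsa` ([kanizsa_spec()]) and `match`
#'   ([match_spec()])
#' @export
make_stimulus_spec <- function(inducer_condition, blur_sigma_deg,
                               cue_orientation = c("up", "down"),
                               triangle_lum = 20, ...) {
  cue_orientation <- match.arg(cue_orientation)
  list(kanizsa = kanizsa_spec(inducer_condition, blur_sigma_deg),
       match = match_spec(cue_orientation, triangle_lum, blur_sigma_deg, ...))
}

#' Calibrated luminance image
#'
#' @param values numeric matrix of luminances (cd/m^2), all within \[0, 40\]
#' @param px_per_deg raster scale (px/deg)
#' @return object of class `luminance_image`
#' @export
luminance_image <- function(values, px_per_deg) {
  if (!is.matrix(values) || !all(is.finite(values)))
    stop("values must be a finite numeric matrix")
  # tolerate float dust from convolution, never real excursions
  if (min(values) < -1e-8 || max(values) > 40 + 1e-8)
    stop("luminance values outside [0, 40] cd/m^2")
  values[values < 0] <- 0
  values[values > 40] <- 40
  structure(list(values = values, px_per_deg = px_per_deg),
            class = "luminance_image")
}

#' @export
print.luminance_image <- function(x, ...) {
  cat(sprintf("luminance_image: %d x %d px, %.2f px/deg, range [%.2f, %.2f] cd/m^2\n",
              nrow(x$values), ncol(x$values), x$px_per_deg,
              min(x$values), max(x$values)))
  invisible(x)
}

# pixel-center coordinates in degrees (x rightward, y upward, origin at center)
.pixel_axes <- function(n_px, px_per_deg) {
  (seq_len(n_px) - (n_px + 1) / 2) / px_per_deg
}

# block-average an (nr*ss) x (nc*ss) matrix down to nr x nc
.block_mean <- function(m, ss) {
  if (ss == 1L) return(m)
  nr <- nrow(m) / ss
  m <- rowsum(m, rep(seq_len(nr), each = ss))
  t(rowsum(t(m), rep(seq_len(ncol(m) / ss), each = ss))) / ss^2
}

# fractional pacman coverage on the supersampled grid spanned by xs (cols,
# deg) and ys (rows, deg, decreasing = downward rows)
.pacman_coverage <- function(ind, xs, ys) {
  dx <- outer(rep(1, length(ys)), xs - ind$center_deg[1])
  dy <- outer(ys - ind$center_deg[2], rep(1, length(xs)))
  r2 <- dx^2 + dy^2
  inside <- r2 <= (ind$diameter_deg / 2)^2
  ang <- atan2(dy, dx) * 180 / pi
  d <- abs((ang - ind$jaw_heading_deg + 180) %% 360 - 180)
  inside & d > ind$jaw_angle_deg / 2
}

#' Render a Kanizsa hexagram display
#'
#' Rasterises the pacmen onto a uniform 20 cd/m^2 background with sub-pixel
#' anti-aliasing (supersampled coverage), then applies the specified Gaussian
#' blur. The illusory central triangle carries no luminance signal: before
#' blurring, every pixel outside an inducer equals the background exactly.
#'
#' @param spec a [kanizsa_spec()]
#' @param geom a [display_geometry()]
#' @param extent_deg rendered panel width/height (deg); panels are square
#' @param supersample linear supersampling factor for edge anti-aliasing
#' @param blur apply the spec's Gaussian filter (set `FALSE` for the raw image)
#' @return a [luminance_image()]
#' @export
render_kanizsa <- function(spec, geom = display_geometry(), extent_deg = 13,
                           supersample = 4L, blur = TRUE) {
  stopifnot(inherits(spec, "kanizsa_spec"))
  ppd <- px_per_degree(geom)
  n <- max(16L, round(extent_deg * ppd))
  ss <- as.integer(supersample)

  centers <- t(vapply(spec$inducers, `[[`, numeric(2), "center_deg"))
  radii <- vapply(spec$inducers, function(i) i$diameter_deg / 2, numeric(1))
  dmat <- as.matrix(stats::dist(centers))
  lim <- outer(radii, radii, `+`)
  if (any(dmat[upper.tri(dmat)] < lim[upper.tri(lim)]))
    stop("inducers overlap; reduce diameter or increase circumradius")

  img <- matrix(spec$background_lum, n, n)
  xs_px <- .pixel_axes(n, ppd)
  sub <- (seq_len(ss) - (ss + 1) / 2) / (ss * ppd)
  for (ind in spec$inducers) {
    r <- ind$diameter_deg / 2
    cols <- which(xs_px >= ind$center_deg[1] - r - 2 / ppd &
                  xs_px <= ind$center_deg[1] + r + 2 / ppd)
    rows <- which(-xs_px >= ind$center_deg[2] - r - 2 / ppd &
                  -xs_px <= ind$center_deg[2] + r + 2 / ppd)
    if (!length(cols) || !length(rows)) next
    xs <- rep(xs_px[cols], each = ss) + sub
    ys <- rep(-xs_px[rows], each = ss) + sub
    cov <- .block_mean(.pacman_coverage(ind, xs, ys) + 0, ss)
    img[rows, cols] <- img[rows, cols] * (1 - cov) + ind$luminance * cov
  }
  out <- luminance_image(img, ppd)
  if (blur && spec$blur_sigma_deg > 0)
    out <- apply_blur(out, spec$blur_sigma_deg, pad_value = spec$background_lum)
  out
}

# fractional coverage of an equilateral triangle (centroid at origin)
.triangle_coverage <- function(edge_len_deg, orientation, xs, ys) {
  rad <- edge_len_deg / sqrt(3)
  ang <- if (orientation == "up") c(90, 210, 330) else c(270, 30, 150)
  v <- cbind(rad * cos(ang * pi / 180), rad * sin(ang * pi / 180))
  px <- outer(rep(1, length(ys)), xs)
  py <- outer(ys, rep(1, length(xs)))
  inside <- TRUE
  for (k in 1:3) {
    a <- v[k, ]; b <- v[k %% 3 + 1, ]
    inside <- inside & ((b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1]) >= 0)
  }
  inside
}

#' Render a matching display
#'
#' A seeded white-noise field (mean 20 cd/m^2) is generated, filtered with the
#' condition's Gaussian, and the uniform matching triangle is composited at the
#' field center. By default the triangle itself is left sharp; set
#' `blur_triangle = TRUE` in the spec to filter after compositing.
#'
#' @inheritParams render_kanizsa
#' @param spec a [match_spec()]
#' @return a [luminance_image()]
#' @export
render_matching <- function(spec, geom = display_geometry(), extent_deg = 13,
                            supersample = 4L) {
  stopifnot(inherits(spec, "match_spec"))
  ppd <- px_per_degree(geom)
  n <- max(16L, round(extent_deg * ppd))
  noise <- with_preserved_seed(spec$noise_seed, {
    if (spec$noise_dist == "uniform") {
      matrix(stats::runif(n * n, 0, 2 * spec$noise_mean_lum), n, n)
    } else {
      # inverse-CDF truncation of N(mean, 10) to [0, 40]
      u <- stats::runif(n * n)
      lo <- stats::pnorm(0, spec$noise_mean_lum, 10)
      hi <- stats::pnorm(40, spec$noise_mean_lum, 10)
      matrix(stats::qnorm(lo + u * (hi - lo), spec$noise_mean_lum, 10), n, n)
    }
  })
  field <- luminance_image(noise, ppd)
  if (!spec$blur_triangle && spec$blur_sigma_deg > 0)
    field <- apply_blur(field, spec$blur_sigma_deg, pad_value = spec$noise_mean_lum)

  ss <- as.integer(supersample)
  xs_px <- .pixel_axes(n, ppd)
  sub <- (seq_len(ss) - (ss + 1) / 2) / (ss * ppd)
  xs <- rep(xs_px, each = ss) + sub
  ys <- rep(-xs_px, each = ss) + sub
  cov <- .block_mean(.triangle_coverage(spec$edge_len_deg, spec$orientation,
                                        xs, ys) + 0, ss)
  img <- field$values * (1 - cov) + spec$triangle_lum * cov
  out <- luminance_image(img, ppd)
  if (spec$blur_triangle && spec$blur_sigma_deg > 0)
    out <- apply_blur(out, spec$blur_sigma_deg, pad_value = spec$noise_mean_lum)
  out
}

#' Gaussian spatial filter in degrees of visual angle
#'
#' Isotropic 2-D Gaussian convolution with sd `sigma_deg * px_per_deg` pixels,
#' implemented separably with constant-extension boundaries at `pad_value`
#' (the background luminance). The kernel is normalised to unit mass, so the
#' global mean of figures fully inside the frame is preserved.
#'
#' @param img a [luminance_image()]
#' @param sigma_deg filter sd (deg); 0 returns the input unchanged
#' @param pad_value boundary-extension luminance (cd/m^2)
#' @return a blurred [luminance_image()]
#' @export
apply_blur <- function(img, sigma_deg, pad_value = 20) {
  stopifnot(inherits(img, "luminance_image"))
  if (!is.finite(sigma_deg) || sigma_deg < 0) stop("sigma_deg must be >= 0")
  if (sigma_deg == 0) return(img)
  s <- sigma_deg * img$px_per_deg
  rad <- max(1L, ceiling(4 * s))
  k <- stats::dnorm(seq(-rad, rad), sd = s)
  k <- k / sum(k)
  conv_mat <- function(n) {
    a <- matrix(0, n, n + 2 * rad)
    for (i in seq_len(n)) a[i, i:(i + 2 * rad)] <- k
    a
  }
  v <- img$values
  nr <- nrow(v); nc <- ncol(v)
  a_r <- conv_mat(nr)
  a_c <- if (nc == nr) a_r else conv_mat(nc)
  pad_r <- rbind(matrix(pad_value, rad, nc), v, matrix(pad_value, rad, nc))
  v <- a_r %*% pad_r
  pad_c <- cbind(matrix(pad_value, nr, rad), v, matrix(pad_value, nr, rad))
  luminance_image(pad_c %*% t(a_c), img$px_per_deg)
}

#' Render a vertical luminance step edge (QA helper)
#'
#' @param geom a [display_geometry()]
#' @param extent_deg panel width/height (deg)
#' @param edge_x_deg x-position of the step (deg from center)
#' @param low,high luminances left/right of the edge (cd/m^2)
#' @param supersample linear supersampling factor
#' @return a [luminance_image()]
#' @export
make_step_edge <- function(geom = display_geometry(), extent_deg = 13,
                           edge_x_deg = 0, low = 0, high = 40,
                           supersample = 4L) {
  ppd <- px_per_degree(geom)
  n <- max(16L, round(extent_deg * ppd))
  ss <- as.integer(supersample)
  xs_px <- .pixel_axes(n, ppd)
  sub <- (seq_len(ss) - (ss + 1) / 2) / (ss * ppd)
  xs <- rep(xs_px, each = ss) + sub
  cov <- colMeans(matrix(xs >= edge_x_deg, ss))  # right-of-edge fraction/pixel
  luminance_image(matrix(low * (1 - cov) + high * cov, n, n, byrow = TRUE), ppd)
}

#' Estimate blur from a step edge
#'
#' Averages the image across rows to a horizontal luminance profile and fits a
#' Gaussian-CDF edge model `a + b * pnorm((x - x0) / sigma)` by least squares.
#' Used as a QA cross-check that rendered blur matches its nominal sigma.
#'
#' @param img a [luminance_image()] containing one vertical step edge
#' @param edge_location approximate x-position of the edge (deg from center)
#' @param fit_halfwidth_deg restrict the fit to x within `edge_location` plus
#'   or minus this width (deg); use it to exclude profile ends contaminated by
#'   boundary padding. `Inf` fits the whole profile.
#' @return estimated sigma in degrees
#' @export
estimate_edge_sigma <- function(img, edge_location = 0,
                                fit_halfwidth_deg = Inf) {
  stopifnot(inherits(img, "luminance_image"))
  x <- .pixel_axes(ncol(img$values), img$px_per_deg)
  p <- colMeans(img$values)
  keep <- abs(x - edge_location) <= fit_halfwidth_deg
  if (sum(keep) < 8) stop("fit window too narrow: fewer than 8 profile samples")
  x <- x[keep]; p <- p[keep]
  if (max(p) - min(p) < 1e-3 || max(abs(diff(p))) < 1e-6)
    stop("no detectable luminance gradient: cannot estimate edge blur")
  a0 <- p[1]; b0 <- p[length(p)] - p[1]
  obj <- function(th) {
    pred <- th[1] + th[2] * stats::pnorm((x - th[3]) / exp(th[4]))
    sum((p - pred)^2)
  }
  fit <- stats::optim(c(a0, b0, edge_location, log(0.5 / img$px_per_deg)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  fit <- stats::optim(fit$par, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  exp(fit$par[4])
}

#' Export a luminance image as 8-bit grayscale PNG
#'
#' Uses the linear mapping 0-40 cd/m^2 to 0-255 (gamma-linearised display
#' convention); the mapping is recorded in the PNG text metadata.
#'
#' @param img a [luminance_image()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_stimulus_png <- function(img, path) {
  stopifnot(inherits(img, "luminance_image"))
  png::writePNG(img$values / 40, target = path,
                text = c(Description = "linear luminance map: 0-40 cd/m^2 -> 0-255",
                         Software = "kanizsaPSE"))
  invisible(path)
}

#' Export a luminance image as 32-bit float TIFF
#'
#' Stores `values / 40` as floating point so calibrated luminance can be
#' recovered exactly. Requires the optional `tiff` package.
#'
#' @inheritParams write_stimulus_png
#' @export
write_stimulus_tiff <- function(img, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for float TIFF export")
  tiff::writeTIFF(img$values / 40, path, bits.per.sample = 32)
  invisible(path)
}

#' Serialize a stimulus specification to YAML
#'
#' Units are explicit in the written fields (degrees of visual angle, cd/m^2).
#'
#' @param spec_pair a list with `kanizsa` and `match` entries, as returned by
#'   [make_stimulus_spec()]
#' @param path output YAML file
#' @export
write_stimulus_yaml <- function(spec_pair, path) {
  strip <- function(x) { x <- unclass(x); x$inducers <- lapply(x$inducers, unclass); x }
  out <- list(units = list(length = "degrees visual angle", luminance = "cd/m^2"),
              kanizsa = strip(spec_pair$kanizsa),
              match = unclass(spec_pair$match))
  yaml::write_yaml(out, path)
  invisible(path)
}
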