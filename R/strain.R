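#' Material points and per-frame displacements for strain analysis
#'
#' Container for DENSE-style strain input: reference positions of myocardial
#' material points, their in-plane displacement at each cardiac frame, the
#' LV center used to define circumferential directions, frame times, and a
#' transmural depth coordinate (0 = endocardium, 1 = epicardium) used for
#' layer-resolved strain.
#'
#' @param positions n x 2 matrix of reference positions, mm.
#' @param displacements n x 2 x n_frames array of displacements, mm.
#' @param center length-2 LV center, mm.
#' @param times frame times, seconds.
#' @param depth length-n transmural depth in \[0, 1\].
#' @return A `strain_frame_set` object.
#' @export
strain_frame_set <- function(positions, displacements, center, times, depth) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L)
    stop("strain_frame_set: positions must be n x 2", call. = FALSE)
  n <- nrow(positions)
  d <- dim(displacements)
  if (length(d) != 3L || d[1] != n || d[2] != 2L)
    stop("strain_frame_set: displacements must be n x 2 x n_frames",
         call. = FALSE)
  if (length(times) != d[3])
    stop("strain_frame_set: times and frame count differ", call. = FALSE)
  if (length(depth) != n || any(depth < -1e-9) || any(depth > 1 + 1e-9))
    stop("strain_frame_set: depth must be length n in [0, 1]", call. = FALSE)
  structure(list(positions = positions, displacements = displacements,
                 center = rep_len(as.numeric(center), 2L),
                 times = as.numeric(times), depth = pmin(pmax(depth, 0), 1)),
            class = "strain_frame_set")
}

#' Per-point deformation gradient by local weighted least squares
#'
#' For each material point, relative displacements of the neighbors within a
#' given radius are fit against their relative reference positions by
#' Gaussian distance-weighted least squares, and the deformation gradient
#' `F = I + du/dX` is read off the linear term. By default the local model
#' is a quartic polynomial (its higher-order terms absorb the curvature of
#' smooth nonlinear deformations, removing the gradient bias a purely
#' linear fit would have at this stencil size); `order = 1` reduces to the
#' plain linear fit of deformed versus reference relative positions. The
#' order is lowered automatically when a neighborhood is too small to
#' support it, and a tiny ridge penalty on the nonlinear terms only keeps
#' near-degenerate boundary neighborhoods stable without affecting affine
#' fields, which are always reproduced exactly (rigid motions give `F`
#' equal to the rotation to machine precision). Points with fewer than
#' `min_neighbors` neighbors, or whose neighborhood is collinear, are
#' flagged and excluded from downstream profiles rather than reported.
#'
#' @param points n x 2 reference positions, mm.
#' @param disp n x 2 displacements for one frame, mm.
#' @param radius neighborhood radius, mm (default 4x the median
#'   nearest-neighbor spacing). Boundary points simply use their one-sided
#'   neighborhoods.
#' @param min_neighbors minimum neighbors (excluding the point itself).
#' @param order maximum polynomial order of the local displacement model
#'   (1-4).
#' @param lambda relative ridge penalty applied to the nonlinear
#'   coefficients.
#' @return List with `F` (n x 2 x 2 array) and `flagged` (logical n).
#' @export
deformation_gradient <- function(points, disp, radius = NULL,
                                 min_neighbors = 3L, order = 4L,
                                 lambda = 1e-6) {
  points <- as.matrix(points); disp <- as.matrix(disp)
  n <- nrow(points)
  order <- max(1L, min(4L, as.integer(order)))
  d2 <- outer(points[, 1], points[, 1], `-`)^2 +
        outer(points[, 2], points[, 2], `-`)^2
  if (is.null(radius)) {
    nn <- sqrt(apply(d2 + diag(Inf, n), 1, min))
    radius <- 4 * median(nn)
  }
  sigma2 <- (0.4 * radius)^2
  n_terms <- c(2L, 5L, 9L, 14L)
  Fout <- array(NA_real_, dim = c(n, 2L, 2L))
  flagged <- logical(n)
  r2 <- radius^2
  for (i in seq_len(n)) {
    idx <- which(d2[i, ] <= r2)
    idx <- idx[idx != i]
    if (length(idx) < min_neighbors) { flagged[i] <- TRUE; next }
    dX <- points[idx, , drop = FALSE] -
      matrix(points[i, ], length(idx), 2, byrow = TRUE)
    du <- disp[idx, , drop = FALSE] -
      matrix(disp[i, ], length(idx), 2, byrow = TRUE)
    # largest order this neighborhood supports
    ord <- max(which(n_terms[seq_len(order)] + 2L <= length(idx) |
                       seq_len(order) == 1L))
    x <- dX[, 1] / radius; y <- dX[, 2] / radius
    terms <- cbind(x, y)
    if (ord >= 2) terms <- cbind(terms, x^2, x * y, y^2)
    if (ord >= 3) terms <- cbind(terms, x^3, x^2 * y, x * y^2, y^3)
    if (ord >= 4) terms <- cbind(terms, x^4, x^3 * y, x^2 * y^2, x * y^3, y^4)
    w <- sqrt(exp(-d2[i, idx] / sigma2))
    A <- terms * w
    M <- crossprod(A)
    nt <- ncol(terms)
    if (nt > 2)
      M <- M + lambda * mean(diag(M)) * diag(c(0, 0, rep(1, nt - 2L)))
    if (rcond(M[1:2, 1:2]) < 1e-12) { flagged[i] <- TRUE; next }  # collinear
    co <- tryCatch(solve(M, crossprod(A, du * w)), error = function(e) NULL)
    if (is.null(co)) { flagged[i] <- TRUE; next }
    Fout[i, , ] <- diag(2) + t(co[1:2, , drop = FALSE]) / radius
  }
  list(F = Fout, flagged = flagged)
}

#' Circumferential Lagrangian strain at a point
#'
#' Given the deformation gradient `F` at a reference point, the Green-
#' Lagrange strain is `E = (F'F - I)/2` and the circumferential component is
#' `Ecc = c' E c`, with `c` the unit circumferential direction (tangent to
#' the circle about the LV center through the point).
#'
#' @param F 2x2 deformation gradient.
#' @param point length-2 reference position, mm.
#' @param center length-2 LV center, mm; must differ from `point`.
#' @return Ecc, dimensionless (negative for circumferential shortening).
#' @export
circumferential_strain <- function(F, point, center) {
  rvec <- point - center
  rn <- sqrt(sum(rvec^2))
  if (rn == 0)
    stop("circumferential_strain: point coincides with the center",
         call. = FALSE)
  e_r <- rvec / rn
  c_hat <- c(-e_r[2], e_r[1])
  E <- 0.5 * (crossprod(F) - diag(2))
  drop(t(c_hat) %*% E %*% c_hat)
}

#' Segmental, global and layer-resolved Ecc over all frames
#'
#' Runs [deformation_gradient()] and [circumferential_strain()] for every
#' frame of a [strain_frame_set()], bins points into angular sectors about
#' the LV center, and returns per-frame segmental Ecc (sector means), the
#' global Ecc (mean over all valid points, i.e. the count-weighted mean of
#' the segmental values) and subendocardial (depth < 0.5) and subepicardial
#' (depth >= 0.5) layer means.
#'
#' @param fs a [strain_frame_set()].
#' @param n_sectors number of angular sectors.
#' @param radius neighborhood radius passed to [deformation_gradient()].
#' @return An `ecc_profile`: list with `segmental` (frames x sectors),
#'   `global`, `subendo`, `subepi` (per-frame vectors), `times`, `n_points`,
#'   `pointwise` (points x frames Ecc matrix) and `flagged`.
#' @export
ecc_profile <- function(fs, n_sectors = 24, radius = NULL) {
  stopifnot(inherits(fs, "strain_frame_set"))
  n <- nrow(fs$positions)
  nf <- dim(fs$displacements)[3]
  rel <- sweep(fs$positions, 2, fs$center)
  ang <- atan2(rel[, 2], rel[, 1])
  sector <- pmin(floor((ang + pi) / (2 * pi / n_sectors)) + 1L, n_sectors)
  ecc <- matrix(NA_real_, n, nf)
  flagged <- logical(n)
  for (k in seq_len(nf)) {
    dg <- deformation_gradient(fs$positions, fs$displacements[, , k],
                               radius = radius)
    flagged <- flagged | dg$flagged
    for (i in seq_len(n)) {
      if (dg$flagged[i]) next
      ecc[i, k] <- circumferential_strain(dg$F[i, , ], fs$positions[i, ],
                                          fs$center)
    }
  }
  valid <- !flagged
  seg <- matrix(NA_real_, nf, n_sectors)
  for (s in seq_len(n_sectors)) {
    sel <- valid & sector == s
    if (any(sel))
      seg[, s] <- colMeans(ecc[sel, , drop = FALSE])
  }
  structure(list(
    segmental = seg,
    global = colMeans(ecc[valid, , drop = FALSE]),
    subendo = colMeans(ecc[valid & fs$depth < 0.5, , drop = FALSE]),
    subepi = colMeans(ecc[valid & fs$depth >= 0.5, , drop = FALSE]),
    times = fs$times, n_points = sum(valid),
    pointwise = ecc, flagged = flagged),
    class = "ecc_profile")
}

#' Peak global (and layer) circumferential strain
#'
#' Returns the extremum of global Ecc over frames with the largest
#' magnitude (the most negative value during contraction), along with the
#' corresponding layer peaks (each layer's own largest-magnitude value).
#'
#' @param profile an [ecc_profile()].
#' @return List with `global`, `subendo`, `subepi` peak values and `frame`,
#'   the frame index of the global peak.
#' @export
peak_global_ecc <- function(profile) {
  stopifnot(inherits(profile, "ecc_profile"))
  g <- profile$global
  if (all(!is.finite(g)))
    stop("peak_global_ecc: no valid frames", call. = FALSE)
  if (length(g) < 2L)
    stop("peak_global_ecc: need at least two frames", call. = FALSE)
  pk <- function(x) x[which.max(abs(x))]
  list(global = pk(g), subendo = pk(profile$subendo),
       subepi = pk(profile$subepi), frame = which.max(abs(g)))
}

#' CURE: circumferential uniformity ratio estimate
#'
#' Synchrony index from the spatial Fourier spectrum of segmental Ecc: per
#' frame, `s0` and `s1` are the squared magnitudes of the zeroth and first
#' circumferential harmonics of the segmental strain, and
#' `CURE = mean(s0 / (s0 + s1))` over the included frames (1 = perfectly
#' uniform contraction, 0 = pure first-harmonic dyssynchrony). Frames with
#' `s0 + s1 = 0` are excluded. By default frames from the first through the
#' peak-strain frame (systole) are included. A square-root convention
#' (`sqrt(s0) / (sqrt(s0) + sqrt(s1))`, also found in the literature) is
#' available via `sqrt_power = TRUE`.
#'
#' @param x an [ecc_profile()] or a frames x sectors matrix of segmental
#'   Ecc (>= 4 sectors).
#' @param frames integer indices of frames to include; default frames 1
#'   through the peak global-strain frame.
#' @param sqrt_power use the square-root convention.
#' @return A `cure_result`: list with `cure`, per-frame `s0`, `s1` and the
#'   included `frames`.
#' @export
compute_cure <- function(x, frames = NULL, sqrt_power = FALSE) {
  seg <- if (inherits(x, "ecc_profile")) x$segmental else as.matrix(x)
  if (ncol(seg) < 4L)
    stop("compute_cure: need at least 4 sectors", call. = FALSE)
  if (is.null(frames)) {
    g <- rowMeans(seg)
    frames <- if (all(is.finite(g)) && length(g) > 1L)
      seq_len(which.max(abs(g))) else seq_len(nrow(seg))
  }
  s0 <- s1 <- rep(NA_real_, nrow(seg))
  for (k in frames) {
    v <- seg[k, ]
    if (any(!is.finite(v)))
      stop("compute_cure: non-finite segmental values in frame ", k,
           call. = FALSE)
    z <- fft(v)
    s0[k] <- Mod(z[1L])^2
    s1[k] <- Mod(z[2L])^2
  }
  keep <- frames[(s0[frames] + s1[frames]) > 0]
  if (!length(keep))
    stop("compute_cure: all frames have zero spectral power", call. = FALSE)
  ratio <- if (sqrt_power)
    sqrt(s0[keep]) / (sqrt(s0[keep]) + sqrt(s1[keep]))
  else s0[keep] / (s0[keep] + s1[keep])
  structure(list(cure = mean(ratio), s0 = s0, s1 = s1, frames = keep),
            class = "cure_result")
}

#' @export
print.cure_result <- function(x, ...) {
  cat(sprintf("CURE = %.3f over %d frame(s)\n", x$cure, length(x$frames)))
  invisible(x)
}
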