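# Shared internal helpers.
#
# Image convention throughout the package: a 2-D image is a plain numeric
# matrix indexed img[x, y] with x running rightward (first index) and y
# downward (second index) from the top-left pixel, which is (1, 1).  This is
# the EBImage storage convention, so EBImage filters apply directly.

# Evaluate `code` with a locally-set RNG seed, restoring the caller's RNG
# state afterwards so generators do not perturb a user's session.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

# Clip intensities to the dynamic range of an integer bit depth.
clip_intensity <- function(x, bit_depth = 8) {
  pmin(pmax(x, 0), 2^bit_depth - 1)
}

check_image <- function(img, arg = "image") {
  if (!is.matrix(img) || !is.numeric(img)) {
    abort(sprintf("`%s` must be a numeric matrix (img[x, y])", arg))
  }
  invisible(img)
}

# Pixel-centre coordinate grids for an nx-by-ny image.
coord_grid <- function(nx, ny) {
  list(
    x = matrix(rep(seq_len(nx), ny), nx, ny),
    y = matrix(rep(seq_len(ny), each = nx), nx, ny)
  )
}

# Translate an image by integer (dx, dy): output[x, y] = input[x - dx, y - dy].
shift_image <- function(img, dx, dy, fill = 0) {
  nx <- nrow(img); ny <- ncol(img)
  out <- matrix(fill, nx, ny)
  xs <- seq_len(nx) - dx
  ys <- seq_len(ny) - dy
  okx <- xs >= 1 & xs <= nx
  oky <- ys >= 1 & ys <= ny
  out[okx, oky] <- img[xs[okx], ys[oky]]
  out
}

# Integer translation (dx, dy) such that shift_image(moving, dx, dy) best
# matches `fixed`, by the peak of the FFT cross-correlation of mean-centred
# images (normalised cross-correlation up to a constant for a pure shift).
best_shift <- function(fixed, moving) {
  stopifnot(all(dim(fixed) == dim(moving)))
  a <- fixed - mean(fixed)
  b <- moving - mean(moving)
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE))
  idx <- arrayInd(which.max(cc), dim(cc))
  dx <- idx[1] - 1L
  dy <- idx[2] - 1L
  if (dx > nrow(cc) / 2) dx <- dx - nrow(cc)
  if (dy > ncol(cc) / 2) dy <- dy - ncol(cc)
  c(dx = dx, dy = dy)
}

# Zero-filled shift of a logical/numeric matrix; neighbour value in direction
# (dx, dy) at each pixel is neighbour_mat(m, dx, dy).
neighbour_mat <- function(m, dx, dy) {
  shift_image(m, -dx, -dy, fill = 0)
}

# Shoelace area of a polygon given vertex coordinates.
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# 8-connected component labelling (union-find). EBImage::bwlabel is
# 4-connected, which severs diagonal runs — fatal for skeleton branches.
# Intended for sparse masks (skeletons, puncta); solid large regions can use
# bwlabel.
label_components8 <- function(mask) {
  idx <- which(mask)
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0) return(out)
  nx <- nrow(mask); ny <- ncol(mask)
  id <- integer(length(mask))
  id[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  xs <- ((idx - 1L) %% nx) + 1L
  ys <- ((idx - 1L) %/% nx) + 1L
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    ok <- xs + d[1] >= 1L & xs + d[1] <= nx & ys + d[2] <= ny
    nidx <- idx[ok] + d[1] + d[2] * nx
    nb <- id[nidx]
    sel <- which(nb > 0L)
    a <- id[idx[ok]][sel]
    b <- nb[sel]
    for (k in seq_along(a)) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  out[idx] <- match(roots, unique(roots))
  out
}

fold_orientation <- function(theta_deg) {
  th <- (theta_deg + 90) %% 180 - 90
  th[th >= 90] <- th[th >= 90] - 180
  th
}
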