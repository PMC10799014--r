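#' Morphological skeleton of a binary mask
#'
#' Zhang–Suen two-subiteration thinning, iterated to convergence. The result
#' is a one-pixel-wide, 8-connected skeleton preserving the topology of the
#' input mask.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  m <- (mask > 0) * 1
  if (!any(m > 0)) return(mask > 0 & FALSE)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbours clockwise from north; y increases downward
      p2 <- neighbour_mat(m, 0, -1)
      p3 <- neighbour_mat(m, 1, -1)
      p4 <- neighbour_mat(m, 1, 0)
      p5 <- neighbour_mat(m, 1, 1)
      p6 <- neighbour_mat(m, 0, 1)
      p7 <- neighbour_mat(m, -1, 1)
      p8 <- neighbour_mat(m, -1, 0)
      p9 <- neighbour_mat(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) +
           (p4 == 0 & p5 == 1) + (p5 == 0 & p6 == 1) +
           (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      cond <- m == 1 & b >= 2 & b <= 6 & a == 1
      if (sub == 1) {
        cond <- cond & (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- cond & (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        m[cond] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m > 0
}

# 8-neighbour count of each foreground pixel within a logical matrix.
neighbour_count <- function(m) {
  mm <- (m > 0) * 1
  s <- neighbour_mat(mm, 0, -1) + neighbour_mat(mm, 1, -1) +
       neighbour_mat(mm, 1, 0) + neighbour_mat(mm, 1, 1) +
       neighbour_mat(mm, 0, 1) + neighbour_mat(mm, -1, 1) +
       neighbour_mat(mm, -1, 0) + neighbour_mat(mm, -1, -1)
  s * mm
}

# Number of distinct 8-connected arms leaving each pixel: 0->1 transitions
# around the ordered 8-neighbour ring. Robust to diagonal staircases, where
# a raw neighbour count of 3 does not mean a branching point.
crossing_number <- function(m) {
  mm <- (m > 0) * 1
  p2 <- neighbour_mat(mm, 0, -1); p3 <- neighbour_mat(mm, 1, -1)
  p4 <- neighbour_mat(mm, 1, 0);  p5 <- neighbour_mat(mm, 1, 1)
  p6 <- neighbour_mat(mm, 0, 1);  p7 <- neighbour_mat(mm, -1, 1)
  p8 <- neighbour_mat(mm, -1, 0); p9 <- neighbour_mat(mm, -1, -1)
  a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) +
       (p4 == 0 & p5 == 1) + (p5 == 0 & p6 == 1) +
       (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
       (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
  a * mm
}

# Split a skeleton into junction clusters and branch segments.
# Junction pixels have >= 3 distinct arms (crossing number); adjacent
# junction pixels collapse into one junction. Branches are the 8-connected
# components left after removing junction pixels.
split_skeleton <- function(skel) {
  junction_px <- skel & crossing_number(skel) >= 3
  n_junctions <- if (any(junction_px)) {
    max(label_components8(junction_px))
  } else 0L
  branch_mask <- skel & !junction_px
  branch_lab <- label_components8(branch_mask)
  list(
    junction_px = junction_px,
    n_junctions = as.integer(n_junctions),
    branch_lab = branch_lab,
    n_branches = as.integer(max(as.integer(branch_lab)))
  )
}

#' Branch and junction counts of a skeletonised mask
#'
#' Skeletonises the mask, then counts junctions (skeleton pixels with at
#' least three 8-connected skeleton neighbours, adjacent junction pixels
#' merged) and branches (the skeleton segments remaining between endpoints
#' and junctions). A single straight line yields one branch and no junction;
#' an "X" of two crossing lines yields four branches and one junction.
#'
#' @param mask Logical or 0/1 matrix (raw mask; it is skeletonised first),
#'   or an already-thin skeleton.
#' @return Tibble with `n_branches` and `n_junctions`.
#' @export
skeleton_stats <- function(mask) {
  check_image(mask * 1)
  skel <- skeletonize(mask)
  sp <- split_skeleton(skel)
  tibble::tibble(n_branches = sp$n_branches, n_junctions = sp$n_junctions)
}

# Order the pixels of one branch (a simple 8-connected path) from one
# endpoint to the other. Falls back to the nearest-unvisited walk, which
# also handles small cycles.
trace_branch <- function(coords) {
  n <- nrow(coords)
  if (n <= 2) return(coords)
  key <- coords[, 1] + 1i * coords[, 2]
  # endpoint: pixel with exactly one neighbour within the branch
  nnb <- vapply(seq_len(n), function(i) {
    d <- pmax(abs(coords[, 1] - coords[i, 1]), abs(coords[, 2] - coords[i, 2]))
    sum(d == 1)
  }, integer(1))
  start <- which(nnb == 1)[1]
  if (is.na(start)) start <- 1L
  visited <- logical(n)
  order <- integer(n)
  cur <- start
  for (k in seq_len(n)) {
    order[k] <- cur
    visited[cur] <- TRUE
    if (k == n) break
    d <- pmax(abs(coords[, 1] - coords[cur, 1]),
              abs(coords[, 2] - coords[cur, 2]))
    cand <- which(!visited & d == 1)
    if (length(cand) == 0) {
      cand <- which(!visited)[which.min(
        (coords[!visited, 1] - coords[cur, 1])^2 +
          (coords[!visited, 2] - coords[cur, 2])^2)]
    }
    # prefer axial steps so the chain length bookkeeping stays local
    cur <- cand[1]
  }
  coords[order, , drop = FALSE]
}

# Geodesic length of an ordered pixel chain. The polyline is smoothed with a
# short moving average first: the raw 8-connected staircase overestimates the
# continuous length of oblique lines by up to ~8%, and noise-induced zigzag
# inflates it further.
chain_length <- function(coords, window = 5) {
  n <- nrow(coords)
  if (n < 2) return(0)
  sm <- smooth_trace(coords, window)
  dx <- diff(sm[, 1]); dy <- diff(sm[, 2])
  sum(sqrt(dx^2 + dy^2))
}

# Moving-average smoothing of an ordered trace, endpoints preserved.
smooth_trace <- function(coords, window = 5) {
  n <- nrow(coords)
  if (n <= window) return(coords)
  half <- window %/% 2
  out <- coords
  cx <- stats::filter(coords[, 1], rep(1 / window, window), sides = 2)
  cy <- stats::filter(coords[, 2], rep(1 / window, window), sides = 2)
  mid <- (half + 1):(n - half)
  out[mid, 1] <- cx[mid]
  out[mid, 2] <- cy[mid]
  out
}

# Remove terminal spurs (endpoint branches shorter than min_spur pixels that
# hang off a junction) until the skeleton is stable. Short staircase spurs
# are thinning artefacts of ragged masks, not filaments.
prune_skeleton <- function(skel, min_spur = 5, max_iter = 20) {
  for (it in seq_len(max_iter)) {
    nb <- neighbour_count(skel)
    if (!any(skel & crossing_number(skel) >= 3)) break  # no junctions
    sp <- split_skeleton(skel)
    lab <- sp$branch_lab
    endpoints <- skel & nb == 1
    labs_all <- as.integer(lab)
    sizes <- tabulate(labs_all)
    end_labs <- unique(labs_all[which(endpoints)])
    end_labs <- end_labs[end_labs > 0]
    # only spurs that hang off a junction; free-standing short branches are
    # legitimate (short) filaments and are left for the min_length filter
    jn <- (sp$junction_px) * 1
    jdil <- (neighbour_mat(jn, 0, -1) + neighbour_mat(jn, 1, -1) +
             neighbour_mat(jn, 1, 0) + neighbour_mat(jn, 1, 1) +
             neighbour_mat(jn, 0, 1) + neighbour_mat(jn, -1, 1) +
             neighbour_mat(jn, -1, 0) + neighbour_mat(jn, -1, -1) + jn) > 0
    junction_labs <- unique(labs_all[which(jdil & lab > 0)])
    drop <- intersect(end_labs[sizes[end_labs] < min_spur], junction_labs)
    if (length(drop) == 0) break
    skel[labs_all %in% drop] <- FALSE
    # re-thin so former junction pixels rejoin the remaining branches
    skel <- skeletonize(skel)
  }
  skel
}
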