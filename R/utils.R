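`%||%` <- function(a, b) if (is.null(a)) b else a

stop_voxflap <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "voxflap_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

assert_that <- function(ok, msg, class = "voxflap_invalid_argument") {
  if (!isTRUE(ok)) stop_voxflap(msg, class)
  invisible(TRUE)
}

is_point3 <- function(x) is.numeric(x) && length(x) == 3 && all(is.finite(x))

#' Dice similarity coefficient between two binary masks
#'
#' 2|A intersect B| / (|A| + |B|). Both inputs may be [label_mask] objects or
#' plain arrays; they must share dimensions. Two empty masks have Dice 1.
#'
#' @param a,b Binary masks ([label_mask] or 3D arrays of 0/1).
#' @return A number in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  da <- if (inherits(a, "voxflap_mask")) a$data else a
  db <- if (inherits(b, "voxflap_mask")) b$data else b
  assert_that(identical(dim(da), dim(db)), "masks must share dimensions")
  na <- sum(da != 0)
  nb <- sum(db != 0)
  if (na + nb == 0) return(1)
  2 * sum(da != 0 & db != 0) / (na + nb)
}

# Separable Gaussian smoothing of a 3D array. `sigma` is in the same unit as
# `spacing` (mm for volumes, voxels when spacing = c(1,1,1)). Edges are
# replicate-padded so mass is preserved at the boundary.
gauss_smooth_3d <- function(arr, sigma, spacing = c(1, 1, 1)) {
  d <- dim(arr)
  for (ax in 1:3) {
    sd_vox <- sigma / spacing[ax]
    if (sd_vox <= 0) next
    r <- max(1L, as.integer(ceiling(3 * sd_vox)))
    kern <- exp(-0.5 * ((-r:r) / sd_vox)^2)
    kern <- kern / sum(kern)
    perm <- switch(ax, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    a <- aperm(arr, perm)
    dd <- dim(a)
    m <- matrix(a, nrow = dd[1])
    idx <- c(rep(1L, r), seq_len(dd[1]), rep(dd[1], r))
    sm <- stats::filter(m[idx, , drop = FALSE], kern, sides = 2)
    m <- sm[(r + 1):(r + dd[1]), , drop = FALSE]
    arr <- aperm(array(m, dd), order(perm))
  }
  arr
}

# Rasterize a union of capsules (cylinders with hemispherical caps) onto a
# voxel lattice: occupied where the voxel center is within `radius` of any
# segment. `segments` is a list of list(p0 =, p1 =) world points (mm); a
# degenerate segment (p0 == p1) gives a sphere.
rasterize_capsules <- function(dims, spacing, origin, segments, radius) {
  out <- array(FALSE, dims)
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * spacing[a])
  for (seg in segments) {
    p0 <- as.numeric(seg$p0)
    p1 <- as.numeric(seg$p1)
    lo <- pmin(p0, p1) - radius
    hi <- pmax(p0, p1) + radius
    rng <- lapply(1:3, function(a) which(ax[[a]] >= lo[a] & ax[[a]] <= hi[a]))
    if (any(lengths(rng) == 0)) next
    nn <- lengths(rng)
    X <- array(ax[[1]][rng[[1]]], nn)
    Y <- array(rep(ax[[2]][rng[[2]]], each = nn[1]), nn)
    Z <- array(rep(ax[[3]][rng[[3]]], each = nn[1] * nn[2]), nn)
    d <- p1 - p0
    len2 <- sum(d^2)
    if (len2 == 0) {
      d2 <- (X - p0[1])^2 + (Y - p0[2])^2 + (Z - p0[3])^2
    } else {
      t <- ((X - p0[1]) * d[1] + (Y - p0[2]) * d[2] + (Z - p0[3]) * d[3]) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (X - p0[1] - t * d[1])^2 +
            (Y - p0[2] - t * d[2])^2 +
            (Z - p0[3] - t * d[3])^2
    }
    hit <- d2 <= radius^2
    out[rng[[1]], rng[[2]], rng[[3]]] <-
      out[rng[[1]], rng[[2]], rng[[3]]] | hit
  }
  out
}

# Stage-tagged logging used by the pipeline and CLI. Collects structured
# records so runs are auditable; `quiet` suppresses console echo only.
vox_log <- function(log, stage, ..., quiet = FALSE) {
  rec <- list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              ...)
  if (!quiet) {
    extra <- list(...)
    msg <- paste(names(extra), vapply(extra, function(x)
      paste(format(x), collapse = " "), character(1)),
      sep = "=", collapse = " ")
    message(sprintf("[voxflap:%s] %s", stage, msg))
  }
  c(log, list(rec))
}
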