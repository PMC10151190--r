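#' 3D volume images
#'
#' A minimal container for volumetric data in a common space: a 3D array plus
#' an isotropic voxel edge length in millimetres. Used for lesion masks,
#' continuous abnormality images, parcellations and statistic maps.
#'
#' @param data A 3D numeric, integer or logical array.
#' @param voxel_mm Positive scalar, voxel edge length in mm (isotropic).
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, voxel_mm = 2) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array", call. = FALSE)
  if (!is.numeric(voxel_mm) || length(voxel_mm) != 1L || voxel_mm <= 0) {
    stop("`voxel_mm` must be a positive scalar", call. = FALSE)
  }
  structure(list(data = data, voxel_mm = as.numeric(voxel_mm)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels @ %g mm (range %g..%g)\n",
              d[1], d[2], d[3], x$voxel_mm,
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

vol_data <- function(x) if (inherits(x, "volume3d")) x$data else x

vol_voxel_mm <- function(x, default = 2) {
  if (inherits(x, "volume3d")) x$voxel_mm else default
}

voxel_volume_mm3 <- function(x) vol_voxel_mm(x)^3

#' Write / read a volume as NIfTI
#'
#' Thin wrappers around \pkg{RNifti} carrying the voxel size into `pixdim`.
#'
#' @param vol A [volume3d()].
#' @param path Output file (`.nii` or `.nii.gz`).
#' @return `write_nifti_volume` returns `path` invisibly; `read_nifti_volume`
#'   returns a [volume3d()].
#' @export
write_nifti_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol_data(vol))
  RNifti::pixdim(img) <- rep(vol_voxel_mm(vol), 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_volume
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  volume3d(array(as.numeric(img), dim(img)[1:3]), RNifti::pixdim(img)[1])
}

gauss_kernel <- function(fwhm_vox) {
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

# Cache of frequency-domain kernels keyed by (dims, fwhm); the Monte-Carlo
# cluster simulation smooths thousands of same-shaped fields.
.smooth_cache <- new.env(parent = emptyenv())

smooth_kernel_fft <- function(dims, fwhm_vox) {
  key <- paste(c(dims, fwhm_vox), collapse = "x")
  hit <- .smooth_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- gauss_kernel(fwhm_vox)
  h <- (length(k) - 1L) / 2L
  pd <- vapply(dims + h, stats::nextn, integer(1), factors = c(2L, 3L, 5L))
  axis_fft <- lapply(pd, function(n) {
    v <- numeric(n)
    v[1:(h + 1)] <- k[(h + 1):(2 * h + 1)]
    v[(n - h + 1):n] <- k[1:h]
    stats::fft(v)
  })
  Kf <- outer(outer(axis_fft[[1]], axis_fft[[2]]), axis_fft[[3]])
  out <- list(Kf = Kf, pd = pd, h = h)
  .smooth_cache[[key]] <- out
  out
}

#' 3D Gaussian smoothing
#'
#' Convolves a 3D array with an isotropic Gaussian kernel (zero padding at
#' the edges), implemented as an FFT convolution on a zero-padded grid.
#'
#' @param arr A 3D array.
#' @param fwhm_vox Kernel full width at half maximum, in voxels. `0` returns
#'   the input unchanged.
#' @return A smoothed array of the same dimensions.
#' @export
gaussian_smooth3d <- function(arr, fwhm_vox) {
  if (fwhm_vox <= 0) return(arr)
  d <- dim(arr)
  kf <- smooth_kernel_fft(d, fwhm_vox)
  A <- array(0, kf$pd)
  A[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- arr
  sm <- Re(stats::fft(stats::fft(A) * kf$Kf, inverse = TRUE)) / prod(kf$pd)
  sm[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
}

# Disjoint-set components for small voxel sets (igraph construction overhead
# dominates there); path-halving union-find over the edge list.
union_find_components <- function(nv, from, to) {
  parent <- seq_len(nv)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_along(from)) {
    ra <- find(from[e])
    rb <- find(to[e])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(nv), find, integer(1))
  match(roots, unique(roots))
}

neighbour_offsets <- function(connectivity = c("face", "edge", "corner")) {
  connectivity <- match.arg(connectivity)
  max_l1 <- switch(connectivity, face = 1L, edge = 2L, corner = 3L)
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  l1 <- rowSums(abs(g))
  keep <- l1 >= 1L & l1 <= max_l1
  g <- g[keep, , drop = FALSE]
  # keep one representative per +/- pair so each undirected edge is built once
  lexpos <- g[, 1] > 0 | (g[, 1] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 3] > 0)))
  g[lexpos, , drop = FALSE]
}

#' Label connected components of a 3D mask
#'
#' Components are found on the voxel adjacency graph (built per the chosen
#' neighbourhood) using \pkg{igraph}, and relabelled `1..n` in order of
#' decreasing size (ties broken by first linear index).
#'
#' @param mask A 3D logical array (or [volume3d()] of 0/1 values).
#' @param connectivity `"face"` (6 neighbours, default), `"edge"` (18) or
#'   `"corner"` (26).
#' @return An integer array of component labels; background voxels are `0`.
#' @export
label_components <- function(mask, connectivity = c("face", "edge", "corner")) {
  connectivity <- match.arg(connectivity)
  m <- vol_data(mask)
  dims <- dim(m)
  m <- m != 0
  out <- array(0L, dims)
  idx <- which(m)
  nv <- length(idx)
  if (nv == 0L) return(out)
  compact <- integer(prod(dims))
  compact[idx] <- seq_len(nv)
  coords <- arrayInd(idx, dims)
  offs <- neighbour_offsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nb <- coords + matrix(offs[k, ], nv, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
          nb[, 2] >= 1L & nb[, 2] <= dims[2] &
          nb[, 3] >= 1L & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nli <- (nb[ok, 3] - 1L) * dims[1] * dims[2] +
           (nb[ok, 2] - 1L) * dims[1] + nb[ok, 1]
    tgt <- compact[nli]
    sel <- tgt > 0L
    if (any(sel)) {
      from <- c(from, compact[idx[ok]][sel])
      to <- c(to, tgt[sel])
    }
  }
  memb <- if (nv <= 2000L) {
    union_find_components(nv, from, to)
  } else {
    g <- igraph::make_empty_graph(n = nv, directed = FALSE)
    if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
    igraph::components(g)$membership
  }
  sizes <- tabulate(memb)
  first_idx <- rep(NA_integer_, length(sizes))
  for (i in seq_len(nv)) {
    if (is.na(first_idx[memb[i]])) first_idx[memb[i]] <- i
  }
  relabel <- integer(length(sizes))
  relabel[order(-sizes, first_idx)] <- seq_along(sizes)
  out[idx] <- relabel[memb]
  out
}
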