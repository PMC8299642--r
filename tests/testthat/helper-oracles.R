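# Independent oracles used across the suite. These deliberately take
# different algorithmic routes from the package implementation.

# Shoelace polygon area over explicitly listed vertex coordinates.
shoelaceArea <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Convex hull area of a pixel mask by brute force: enumerate all four
# corners of every foreground pixel, take the hull with chull() on the
# corner cloud and apply the shoelace formula.
hullAreaOracle <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  pts <- rbind(cbind(idx[, 1] - 1, idx[, 2] - 1),
               cbind(idx[, 1],     idx[, 2] - 1),
               cbind(idx[, 1] - 1, idx[, 2]),
               cbind(idx[, 1],     idx[, 2]))
  h <- grDevices::chull(pts)
  shoelaceArea(pts[h, 1], pts[h, 2])
}

# Connected components of a 3-D binary array via an adjacency graph:
# voxel pairs are enumerated by array shifts and the components come from
# igraph's union-find, a different route from the package's BFS frontier
# fill.
componentsOracle <- function(a, connectivity = 26) {
  d <- dim(a)
  fg <- which(a > 0)
  if (!length(fg)) return(list(count = 0L, sizes = integer(0)))
  id <- array(0L, d)
  id[fg] <- seq_along(fg)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  edges <- list()
  for (i in seq_len(nrow(offs))) {
    dz <- offs$dz[i]; dy <- offs$dy[i]; dx <- offs$dx[i]
    zr <- max(1, 1 + dz):min(d[1], d[1] + dz)
    yr <- max(1, 1 + dy):min(d[2], d[2] + dy)
    xr <- max(1, 1 + dx):min(d[3], d[3] + dx)
    aSub <- id[zr, yr, xr, drop = FALSE]
    bSub <- id[zr - dz, yr - dy, xr - dx, drop = FALSE]
    both <- aSub > 0 & bSub > 0
    if (any(both)) edges[[length(edges) + 1]] <- cbind(aSub[both], bSub[both])
  }
  g <- igraph::graph_from_edgelist(
    if (length(edges)) do.call(rbind, edges) else matrix(0L, 0, 2),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)
  list(count = comp$no, sizes = sort(as.integer(comp$csize)))
}

diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
iouCoef <- function(a, b) sum(a & b) / sum(a | b)

# Direct evaluation of the multi-exponential decay model.
decayOracle <- function(components, times) {
  as.vector(exp(-outer(times, 1 / components[, 1])) %*% components[, 2])
}

# Digitised sphere label map (single label 1) at given radius/voxel size.
sphereLabelMap <- function(r = 10, voxelSize = c(1.1, 1, 1), pad = 4) {
  nz <- ceiling(2 * (r + pad) / voxelSize[1])
  ny <- ceiling(2 * (r + pad) / voxelSize[2])
  nx <- ceiling(2 * (r + pad) / voxelSize[3])
  cz <- (nz - 1) / 2 * voxelSize[1]
  cy <- (ny - 1) / 2 * voxelSize[2]
  cx <- (nx - 1) / 2 * voxelSize[3]
  q <- outer(outer(((0:(nz - 1)) * voxelSize[1] - cz)^2,
                   ((0:(ny - 1)) * voxelSize[2] - cy)^2, "+"),
             ((0:(nx - 1)) * voxelSize[3] - cx)^2, "+") <= r^2
  TuberLabelMap(array(as.integer(q), dim(q)), voxelSize = voxelSize)
}
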