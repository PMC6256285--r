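# Independent oracles and fixture builders used across the suite. The
# oracles deliberately avoid the package's compiled code paths.

# Brute-force 26-connected component labeling by breadth-first search over
# an explicit neighbour graph (igraph components). Returns an integer array
# whose label partition can be compared against the package's labeling.
bfs_label_oracle <- function(mask) {
  d <- dim(mask)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  idx <- which(mask)
  if (length(idx) == 0) return(array(0L, d))
  coord <- cbind(z = (idx - 1L) %% nz,
                 y = ((idx - 1L) %/% nz) %% ny,
                 x = (idx - 1L) %/% (nz * ny))
  offsets <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  # keep one direction of each offset pair (positive linear shift) to avoid
  # duplicate edges
  offsets <- offsets[offsets[, 3] * nz * ny + offsets[, 2] * nz +
                       offsets[, 1] > 0, , drop = FALSE]
  in_set <- array(0L, d)
  in_set[idx] <- seq_along(idx)
  edges <- NULL
  for (k in seq_len(nrow(offsets))) {
    zz <- coord[, 1] + offsets[k, 1]
    yy <- coord[, 2] + offsets[k, 2]
    xx <- coord[, 3] + offsets[k, 3]
    ok <- zz >= 0 & zz < nz & yy >= 0 & yy < ny & xx >= 0 & xx < nx
    if (!any(ok)) next
    nb_lin <- zz[ok] + nz * (yy[ok] + ny * xx[ok]) + 1L
    nb_id <- in_set[nb_lin]
    hit <- nb_id > 0L
    if (any(hit))
      edges <- rbind(edges, cbind(which(ok)[hit], nb_id[hit]))
  }
  g <- igraph::make_graph(t(edges), n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  out <- array(0L, d)
  out[idx] <- as.integer(comp)
  out
}

# TRUE when two labelings induce the same partition of the foreground.
same_partition <- function(lab1, lab2) {
  pos1 <- lab1 > 0L; pos2 <- lab2 > 0L
  if (!identical(pos1, pos2)) return(FALSE)
  key <- paste(lab1[pos1], lab2[pos2])
  length(unique(key)) == length(unique(lab1[pos1])) &&
    length(unique(key)) == length(unique(lab2[pos2]))
}

# Exhaustive voxel-intersection colocalization oracle: explicit double loop
# over label pairs.
overlap_oracle <- function(lab_a, lab_b, min_shared = 1L) {
  ids_a <- setdiff(sort(unique(as.vector(lab_a))), 0L)
  ids_b <- setdiff(sort(unique(as.vector(lab_b))), 0L)
  overlapping <- integer(0)
  for (i in ids_a) {
    vox_i <- lab_a == i
    for (j in ids_b) {
      if (sum(vox_i & lab_b == j) >= min_shared) {
        overlapping <- c(overlapping, i)
        break
      }
    }
  }
  list(ids = as.integer(overlapping),
       fraction = if (length(ids_a) > 0)
         length(overlapping) / length(ids_a) else NA_real_)
}

# Random paired label maps: two independent binary volumes, each labeled by
# the BFS oracle (so the fixtures do not depend on the code under test).
random_label_pair <- function(dims = c(16, 16, 16), p = 0.2) {
  mk <- function() {
    m <- array(runif(prod(dims)) < p, dims)
    lab <- bfs_label_oracle(m)
    label_map(lab, max(lab))
  }
  list(A = mk(), B = mk())
}

# Greedy one-to-one matching of segmented centroids to ground-truth puncta;
# a punctum matches when the centroid lies within its ground-truth radius.
match_puncta <- function(truth, props, voxel_size) {
  tc <- cbind(truth$z * voxel_size[1], truth$y * voxel_size[2],
              truth$x * voxel_size[3])
  cc <- cbind(props$puncta$centroid_z_um, props$puncta$centroid_y_um,
              props$puncta$centroid_x_um)
  if (nrow(cc) == 0)
    return(list(recall = 0, precision = NA_real_))
  dmat <- outer(seq_len(nrow(tc)), seq_len(nrow(cc)),
                Vectorize(function(i, j) sqrt(sum((tc[i, ] - cc[j, ])^2))))
  recall <- mean(apply(dmat, 1, min) <= truth$radius_um)
  precision <- mean(apply(dmat, 2, function(dj)
    any(dj <= truth$radius_um)))
  list(recall = recall, precision = precision)
}

# Gaussian blob fixture on an empty volume (z, y, x dims), centre in 0-based
# voxel coordinates.
gaussian_blob <- function(dims, center, sigma, amplitude = 100) {
  z <- (seq_len(dims[1]) - 1)
  y <- (seq_len(dims[2]) - 1)
  x <- (seq_len(dims[3]) - 1)
  gz <- exp(-(z - center[1])^2 / (2 * sigma[1]^2))
  gy <- exp(-(y - center[2])^2 / (2 * sigma[2]^2))
  gx <- exp(-(x - center[3])^2 / (2 * sigma[3]^2))
  amplitude * outer(outer(gz, gy), gx)
}
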