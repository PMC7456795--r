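# Minimal volume/mesh bridge: threshold + 26-connected components + centroid
# extraction of electrode contacts, isosurface extraction for scalp meshes
# (marching tetrahedra) and NIfTI volume I/O. All world coordinates follow the
# volume affine as stored; volumes are never re-oriented — all inputs are
# assumed co-registered into one space upstream.

#' CT-like image volume
#'
#' @param data 3D numeric array of intensities.
#' @param affine 4 x 4 matrix mapping 0-based voxel indices (homogeneous) to
#'   world mm: `world = affine %*% c(i-1, j-1, k-1, 1)` for R's 1-based
#'   `data[i, j, k]`.
#' @return Object of class `ctvolume`.
#' @export
ctvolume <- function(data, affine = diag(4)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array")
  if (length(data) == 0L) stop("volume array is empty")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4 x 4 matrix")
  structure(list(data = data, affine = affine), class = "ctvolume")
}

#' @export
print.ctvolume <- function(x, ...) {
  d <- dim(x$data)
  vs <- sqrt(colSums(x$affine[1:3, 1:3]^2))
  cat(sprintf("<ctvolume> %d x %d x %d voxels, voxel size %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3]))
  invisible(x)
}

# world coordinates of voxel centers for an index matrix (1-based ijk rows)
.voxel_world <- function(vol, ijk) {
  ijk <- as.matrix(ijk)
  h <- cbind(ijk - 1, 1)
  w <- h %*% t(vol$affine)
  w[, 1:3, drop = FALSE]
}

#' Supra-threshold connected components with world-space centroids
#'
#' Thresholds the volume at `threshold` (inclusive), labels 26-connected
#' components, and returns one blob per component with its voxel count,
#' intensity-weighted centroid mapped through the affine into world mm, and
#' mean intensity. Components smaller than `min_voxels` are suppressed
#' (single-voxel noise). Blobs are sorted by voxel count descending.
#'
#' @param vol a [ctvolume()].
#' @param threshold intensity threshold (voxels `>= threshold` are foreground).
#' @param min_voxels minimum component size (default 2).
#' @return Data frame with columns `n_voxels`, `cx_mm`, `cy_mm`, `cz_mm`,
#'   `mean_intensity`; zero rows when the mask is empty.
#' @export
threshold_components <- function(vol, threshold, min_voxels = 2L) {
  stopifnot(inherits(vol, "ctvolume"))
  mask <- vol$data >= threshold
  nv <- sum(mask)
  empty <- data.frame(n_voxels = integer(0), cx_mm = numeric(0),
                      cy_mm = numeric(0), cz_mm = numeric(0),
                      mean_intensity = numeric(0))
  if (nv == 0L) return(empty)
  d <- dim(vol$data)
  lin <- which(mask)
  id <- array(0L, d)
  id[lin] <- seq_along(lin)
  ijk <- arrayInd(lin, d)
  # 26-connectivity: 13 positive offsets suffice for undirected edges
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(ijk, 2L, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nbl <- nb[ok, 1] + (nb[ok, 2] - 1) * d[1] + (nb[ok, 3] - 1) * d[1] * d[2]
    nbid <- id[nbl]
    hit <- nbid > 0L
    if (any(hit))
      edges[[length(edges) + 1L]] <- cbind(which(ok)[hit], nbid[hit])
  }
  g <- igraph::make_empty_graph(n = nv, directed = FALSE)
  if (length(edges) > 0L)
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership
  w <- .voxel_world(vol, ijk)
  inten <- vol$data[lin]
  rows <- lapply(seq_len(max(comp)), function(cid) {
    sel <- comp == cid
    if (sum(sel) < min_voxels) return(NULL)
    wi <- inten[sel]
    ctr <- colSums(w[sel, , drop = FALSE] * wi) / sum(wi)
    data.frame(n_voxels = sum(sel), cx_mm = ctr[1], cy_mm = ctr[2],
               cz_mm = ctr[3], mean_intensity = mean(wi))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_voxels), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# 6-tetrahedra decomposition of the unit cube around the 1-7 main diagonal.
# Corner numbering: 1..8 with offsets below (x fastest).
.mt_corners <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                     c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
.mt_tets <- rbind(c(1, 6, 2, 7), c(1, 2, 3, 7), c(1, 3, 4, 7),
                  c(1, 4, 8, 7), c(1, 8, 5, 7), c(1, 5, 6, 7))

#' Extract an isosurface mesh from a volume
#'
#' Marching-tetrahedra level-set extraction: each voxel cube crossing `level`
#' is split into 6 tetrahedra, crossing edges are linearly interpolated, and
#' the resulting triangles are welded into a shared-vertex mesh in world mm.
#' Only the largest connected surface component is retained (satellite noise
#' components are dropped).
#'
#' @param vol a [ctvolume()].
#' @param level iso-level, strictly inside the volume's intensity range.
#' @return A [trimesh()] in world mm.
#' @export
extract_isosurface <- function(vol, level) {
  stopifnot(inherits(vol, "ctvolume"))
  v <- vol$data
  rng <- range(v)
  if (!(level > rng[1] && level < rng[2]))
    stop("iso-level must lie strictly inside the intensity range [",
         rng[1], ", ", rng[2], "]")
  d <- dim(v)
  if (any(d < 2L)) stop("volume too small for isosurface extraction")
  i1 <- seq_len(d[1] - 1L); j1 <- seq_len(d[2] - 1L); k1 <- seq_len(d[3] - 1L)
  corner_val <- function(o) v[i1 + o[1], j1 + o[2], k1 + o[3], drop = FALSE]
  cmin <- corner_val(.mt_corners[1, ]); cmax <- cmin
  for (c in 2:8) {
    cv <- corner_val(.mt_corners[c, ])
    cmin <- pmin(cmin, cv); cmax <- pmax(cmax, cv)
  }
  active <- which(cmin < level & cmax > level)
  if (length(active) == 0L) stop("empty level set at level ", level)
  base <- arrayInd(active, d - 1L) # 1-based lower corner of active cubes
  nact <- nrow(base)
  # corner values and 0-based index coordinates for active cubes: nact x 8
  vals <- matrix(0, nact, 8L)
  for (c in 1:8) {
    o <- .mt_corners[c, ]
    vals[, c] <- v[cbind(base[, 1] + o[1], base[, 2] + o[2], base[, 3] + o[3])]
  }
  tris <- list()
  interp <- function(ca, cb, rows) {
    # linear interpolation along cube edge ca->cb for the given cube rows,
    # in 0-based voxel index space
    va <- vals[rows, ca]; vb <- vals[rows, cb]
    t <- (level - va) / (vb - va)
    pa <- sweep(base[rows, , drop = FALSE] - 1, 2L, .mt_corners[ca, ], "+")
    pb <- sweep(base[rows, , drop = FALSE] - 1, 2L, .mt_corners[cb, ], "+")
    pa + (pb - pa) * t
  }
  for (tt in seq_len(nrow(.mt_tets))) {
    tet <- .mt_tets[tt, ]
    inside <- vals[, tet, drop = FALSE] > level
    code <- inside %*% c(1L, 2L, 4L, 8L)
    for (cs in 1:14) {
      rows <- which(code == cs)
      if (length(rows) == 0L) next
      bits <- as.logical(bitwAnd(cs, c(1L, 2L, 4L, 8L)))
      ins <- tet[bits]; outs <- tet[!bits]
      if (length(ins) == 1L || length(ins) == 3L) {
        apex <- if (length(ins) == 1L) ins else outs
        others <- if (length(ins) == 1L) outs else ins
        p1 <- interp(apex, others[1], rows)
        p2 <- interp(apex, others[2], rows)
        p3 <- interp(apex, others[3], rows)
        tris[[length(tris) + 1L]] <- cbind(p1, p2, p3)
      } else { # 2 inside, 2 outside: quad split into two triangles
        ac <- interp(ins[1], outs[1], rows)
        ad <- interp(ins[1], outs[2], rows)
        bc <- interp(ins[2], outs[1], rows)
        bd <- interp(ins[2], outs[2], rows)
        tris[[length(tris) + 1L]] <- cbind(ac, bc, bd)
        tris[[length(tris) + 1L]] <- cbind(ac, bd, ad)
      }
    }
  }
  tri <- do.call(rbind, tris) # n x 9: the 3 corners in index space
  corner_mat <- matrix(t(tri), ncol = 3L, byrow = TRUE) # interleaved corners
  key <- paste(round(corner_mat[, 1] * 1e6), round(corner_mat[, 2] * 1e6),
               round(corner_mat[, 3] * 1e6))
  vi <- match(key, unique(key))
  verts_idx <- corner_mat[!duplicated(key), , drop = FALSE]
  faces <- matrix(vi, ncol = 3L, byrow = TRUE)
  faces <- faces[faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
                   faces[, 1] != faces[, 3], , drop = FALSE]
  # keep the largest connected surface component
  g <- igraph::graph_from_edgelist(
    rbind(faces[, 1:2, drop = FALSE], faces[, 2:3, drop = FALSE],
          faces[, c(1, 3), drop = FALSE]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(verts_idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  keep_face <- comp$membership[faces[, 1]] == main
  faces <- faces[keep_face, , drop = FALSE]
  # map vertices from 0-based index space to world mm via the affine
  verts_world <- .voxel_world(list(affine = vol$affine), verts_idx + 1)
  m <- trimesh(verts_world, faces)
  # drop unreferenced vertices
  used <- sort(unique(as.vector(m$faces)))
  remap <- integer(nrow(m$vertices)); remap[used] <- seq_along(used)
  trimesh(m$vertices[used, , drop = FALSE],
          matrix(remap[m$faces], ncol = 3L))
}

#' Read a NIfTI volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return A [ctvolume()] with the stored sform/qform affine.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  ctvolume(array(as.numeric(img), dim(img)), matrix(as.numeric(aff), 4L, 4L))
}

#' Write a NIfTI volume
#'
#' @param vol a [ctvolume()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ctvolume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  aff <- structure(vol$affine, code = 2L)
  RNifti::qform(img) <- aff
  RNifti::sform(img) <- aff
  RNifti::writeNifti(img, path)
  invisible(path)
}
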