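#' 3D reconstruction of predicted label maps
#'
#' Ordered per-frame label maps from a sweep are stacked into a voxel
#' volume at uniform slice spacing (no inter-frame registration), each
#' class's binary mask is lightly Gaussian-smoothed, and a triangle surface
#' is extracted at the 0.5 iso-level with a marching-tetrahedra pass
#' (6-tetrahedra cube decomposition, edge-keyed shared vertices, outward
#' normals). Volumes export to NIfTI, meshes to ASCII PLY/STL with a JSON
#' scene file carrying the per-class colour palette.
#'
#' @name recon3d
NULL

#' Stack label frames into a labelled volume
#'
#' @param label_frames Ordered list of `H x W` integer label matrices.
#' @param spacing Voxel spacing `c(dz, dy, dx)` (or a scalar `dz` with
#'   `dy = dx = 1`), arbitrary consistent units.
#' @param closing_radius Radius (voxels) of an optional per-class 3-D
#'   morphological closing that bridges small inter-frame gaps; 0 disables
#'   it. Default 1.
#' @return `sono_volume`: list with `values` (`(nz, ny, nx)` integer
#'   array, `values[z, , ]` = frame z) and `spacing`.
#' @export
stack_predictions <- function(label_frames, spacing = 1, closing_radius = 1L) {
  if (length(label_frames) < 2L) stop("need at least 2 frames")
  d1 <- dim(label_frames[[1L]])
  if (!all(vapply(label_frames, function(f) all(dim(f) == d1), TRUE))) {
    stop("frames differ in shape")
  }
  if (length(spacing) == 1L) spacing <- c(spacing, 1, 1)
  if (any(spacing <= 0)) stop("spacing must be positive")
  nz <- length(label_frames)
  vol <- array(0L, c(nz, d1[1], d1[2]))
  for (z in seq_len(nz)) vol[z, , ] <- as.integer(label_frames[[z]])
  if (closing_radius > 0L) {
    for (cl in sort(setdiff(unique(as.vector(vol)), 0L))) {
      closed <- binary_close3(vol == cl, closing_radius)
      vol[closed & vol == 0L] <- cl
    }
  }
  structure(list(values = vol, spacing = as.numeric(spacing)),
            class = "sono_volume")
}

# shift-based 6-connected dilation/erosion repeated r times
shift3 <- function(a, dz, dy, dx, fill) {
  d <- dim(a)
  out <- array(fill, d)
  zs <- max(1, 1 + dz):min(d[1], d[1] + dz)
  ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
  xs <- max(1, 1 + dx):min(d[3], d[3] + dx)
  out[zs, ys, xs] <- a[zs - dz, ys - dy, xs - dx]
  out
}

morph3 <- function(mask, r, dilate) {
  fill <- !dilate
  for (k in seq_len(r)) {
    acc <- mask
    for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      sh <- shift3(mask, s[1], s[2], s[3], fill)
      acc <- if (dilate) acc | sh else acc & sh
    }
    mask <- acc
  }
  mask
}

binary_close3 <- function(mask, r) morph3(morph3(mask, r, TRUE), r, FALSE)

# separable 3-D Gaussian blur along each axis
gauss_blur3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  Ks <- lapply(d, gauss_blur_mat, sigma = sigma)
  m <- matrix(a, d[1])            # blur along z
  a <- array(Ks[[1]] %*% m, d)
  a <- aperm(a, c(2, 1, 3))       # blur along y
  a <- array(Ks[[2]] %*% matrix(a, d[2]), c(d[2], d[1], d[3]))
  a <- aperm(a, c(2, 1, 3))
  a <- aperm(a, c(3, 2, 1))       # blur along x
  a <- array(Ks[[3]] %*% matrix(a, d[3]), c(d[3], d[2], d[1]))
  aperm(a, c(3, 2, 1))
}

#' Extract the surface mesh of one class
#'
#' The class's binary mask is padded with a background shell (so surfaces
#' close at volume borders), Gaussian-smoothed (`smooth_sigma` voxels), and
#' contoured at iso-level 0.5 by marching tetrahedra. Vertices are in world
#' units (voxel index times spacing).
#'
#' @param vol A `sono_volume`.
#' @param class_index 0-based class to mesh.
#' @param smooth_sigma Gaussian sigma in voxels (default 1).
#' @return `sono_mesh`: list with `vertices` (V x 3 matrix, columns x, y,
#'   z in world units), `faces` (F x 3, 1-based), `class_index`,
#'   `class_name`. An absent class yields an empty mesh with a warning.
#' @export
extract_mesh <- function(vol, class_index, smooth_sigma = 1) {
  stopifnot(inherits(vol, "sono_volume"))
  mask <- vol$values == class_index
  nm <- if (class_index < length(sono_classes())) {
    sono_classes()[class_index + 1L]
  } else as.character(class_index)
  if (!any(mask)) {
    warning("class ", class_index, " absent from volume; empty mesh")
    return(structure(list(vertices = matrix(0, 0, 3), faces = matrix(0L, 0, 3),
                          class_index = class_index, class_name = nm),
                     class = "sono_mesh"))
  }
  d <- dim(mask)
  padded <- array(0, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  sm <- gauss_blur3(padded, smooth_sigma)
  mt <- .march_tets(sm, 0.5)
  # C++ grid coords are 0-based (dim1, dim2, dim3) = (z, y, x); shift for
  # the pad and scale into world units, reordering columns to (x, y, z)
  v <- mt$vertices - 1
  world <- cbind(v[, 3] * vol$spacing[3], v[, 2] * vol$spacing[2],
                 v[, 1] * vol$spacing[1])
  colnames(world) <- c("x", "y", "z")
  # the axis reordering is an odd permutation; swap a face column pair to
  # keep normals outward (positive enclosed volume)
  structure(list(vertices = world, faces = mt$faces[, c(1L, 3L, 2L), drop = FALSE],
                 class_index = class_index, class_name = nm),
            class = "sono_mesh")
}

#' Signed volume enclosed by a watertight mesh
#' @param mesh A `sono_mesh`.
#' @export
mesh_volume <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(0)
  v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  cr <- cbind(v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2],
              v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3],
              v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  sum(rowSums(v1 * cr)) / 6
}

#' Euler characteristic V - E + F of a mesh
#' @param mesh A `sono_mesh`.
#' @export
mesh_euler <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(NA_integer_)
  e <- rbind(cbind(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2])),
             cbind(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3])),
             cbind(pmin(f[, 1], f[, 3]), pmax(f[, 1], f[, 3])))
  nrow(mesh$vertices) - nrow(unique(e)) + nrow(f)
}

#' Per-class display palette for the scene file
#'
#' Matches the annotation convention: red carotid, blue trachea, green
#' thyroid, yellow NoV, purple esophagus.
#' @return Named vector of hex colours for the five foreground classes.
#' @export
class_palette <- function() {
  c(thyroid = "#00A000", trachea = "#0050FF", NoV = "#FFD700",
    esophagus = "#8000A0", carotid = "#E00000")
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  if (nrow(mesh$vertices)) {
    writeLines(apply(mesh$vertices, 1, function(r)
      paste(format(r, trim = TRUE, scientific = FALSE), collapse = " ")), con)
  }
  if (nrow(mesh$faces)) {
    writeLines(paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
  }
  invisible(path)
}

#' Read an ASCII PLY written by this package
#' @param path PLY file path.
#' @return List with `vertices` and `faces`.
#' @export
read_ply <- function(path) {
  ln <- readLines(path)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", ln, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", ln, value = TRUE)))
  start <- which(ln == "end_header")
  verts <- if (nv) {
    do.call(rbind, lapply(ln[start + seq_len(nv)], function(s)
      as.numeric(strsplit(s, " ")[[1]])))
  } else matrix(0, 0, 3)
  faces <- if (nf) {
    do.call(rbind, lapply(ln[start + nv + seq_len(nf)], function(s)
      as.integer(strsplit(s, " ")[[1]])[2:4] + 1L))
  } else matrix(0L, 0, 3)
  list(vertices = verts, faces = faces)
}

write_stl <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", mesh$class_name), con)
  if (nrow(mesh$faces)) {
    for (i in seq_len(nrow(mesh$faces))) {
      tri <- mesh$vertices[mesh$faces[i, ], , drop = FALSE]
      u <- tri[2, ] - tri[1, ]; v <- tri[3, ] - tri[1, ]
      nrm <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
               u[1] * v[2] - u[2] * v[1])
      nl <- sqrt(sum(nrm^2)); if (nl > 0) nrm <- nrm / nl
      writeLines(c(paste(" facet normal", paste(nrm, collapse = " ")),
                   "  outer loop",
                   paste("   vertex", apply(tri, 1, paste, collapse = " ")),
                   "  endloop", " endfacet"), con)
    }
  }
  writeLines(paste("endsolid", mesh$class_name), con)
  invisible(path)
}

#' Export a reconstruction
#'
#' Writes the labelled volume as NIfTI (spacing in the header), one PLY and
#' one STL per present foreground class, and `scene.json` listing the
#' meshes with their display colours.
#'
#' @param vol A `sono_volume`.
#' @param meshes List of `sono_mesh` objects.
#' @param out_dir Output directory.
#' @return Invisibly, the written paths.
#' @export
export_recon <- function(vol, meshes, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  nii_path <- file.path(out_dir, "labels.nii")
  img <- RNifti::asNifti(vol$values, reference = NULL)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, nii_path)
  pal <- class_palette()
  paths <- nii_path
  scene <- list()
  for (m in meshes) {
    if (nrow(m$faces) == 0L) next
    ply <- file.path(out_dir, paste0(m$class_name, ".ply"))
    stl <- file.path(out_dir, paste0(m$class_name, ".stl"))
    write_ply(m, ply); write_stl(m, stl)
    scene[[length(scene) + 1L]] <- list(
      class_index = m$class_index, class_name = m$class_name,
      color = unname(pal[m$class_name]), ply = basename(ply),
      stl = basename(stl))
    paths <- c(paths, ply, stl)
  }
  sj <- file.path(out_dir, "scene.json")
  jsonlite::write_json(scene, sj, auto_unbox = TRUE)
  invisible(c(paths, sj))
}

#' Read back a NIfTI label volume
#' @param path NIfTI file.
#' @return A `sono_volume`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  structure(list(values = array(as.integer(img), dim(img)),
                 spacing = RNifti::pixdim(img)[1:3]),
            class = "sono_volume")
}
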