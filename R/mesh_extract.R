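# Metric surface-mesh extraction: the trained density field is sampled on a
# regular grid over the ROI box, masked to the box's inscribed cylinder, and
# iso-contoured at a density threshold.

#' Mesh-extraction configuration
#'
#' @param grid_resolution voxels per axis (>= 8); 256 is a production
#'   default, 64-128 suits tests.
#' @param sigma_threshold density iso-value demarcating the object boundary,
#'   1/m (> 0).
#' @param cylinder_mask if `TRUE` (default), zero the density outside the
#'   inscribed cylinder of the ROI box before contouring.
#' @return An object of class `mesh_config`.
#' @export
mesh_config <- function(grid_resolution = 256, sigma_threshold = 25,
                        cylinder_mask = TRUE) {
  stopifnot(grid_resolution >= 8, sigma_threshold > 0)
  structure(list(grid_resolution = as.integer(grid_resolution),
                 sigma_threshold = sigma_threshold,
                 cylinder_mask = cylinder_mask),
            class = "mesh_config")
}

# uniform density query across the supported field representations
density_query_fn <- function(field) {
  if (inherits(field, "radiance_field")) {
    function(pts) query_density(field, pts)
  } else if (inherits(field, "plant_field")) {
    function(pts) field$density_fn(pts)
  } else if (is.function(field)) {
    function(pts) field(pts)
  } else {
    stop("`field` must be a radiance_field, plant_field or function",
         call. = FALSE)
  }
}

#' Sample a density field on a regular grid over the ROI box
#'
#' Grid corner coordinates span the box corners exactly (`res` points per
#' axis).  With the cylinder mask on, densities at points outside the box's
#' inscribed cylinder `x^2 + y^2 > r^2` (r = half the box x-extent, centred
#' in xy) are set to 0, restricting the mesh to the region the orbital
#' cameras actually observe.
#'
#' @param field a trained [radiance_field()], a [make_plant_field()] field,
#'   or a function mapping an n x 3 matrix to densities.
#' @param box an [aabb()].
#' @param res grid points per axis.
#' @param cylinder_mask logical.
#' @return list with `density` (res x res x res array), `mask` (logical
#'   array), `xs`, `ys`, `zs` (grid coordinates).
#' @export
sample_density_grid <- function(field, box, res = 128, cylinder_mask = TRUE) {
  stopifnot(inherits(box, "aabb"), res >= 8)
  qf <- density_query_fn(field)
  xs <- seq(box$min[1], box$max[1], length.out = res)
  ys <- seq(box$min[2], box$max[2], length.out = res)
  zs <- seq(box$min[3], box$max[3], length.out = res)
  pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dens <- array(qf(pts), c(res, res, res))
  r <- (box$max[1] - box$min[1]) / 2
  cx <- (box$max[1] + box$min[1]) / 2
  cy <- (box$max[2] + box$min[2]) / 2
  inside <- outer((xs - cx)^2, (ys - cy)^2, "+") <= r^2
  mask <- array(inside, c(res, res, res))  # z-invariant
  if (cylinder_mask) dens[!mask] <- 0
  list(density = dens, mask = mask, xs = xs, ys = ys, zs = zs)
}

#' Extract a metric surface mesh from a density field
#'
#' Iso-contours the gridded density at `cfg$sigma_threshold` (marching
#' tetrahedra over the voxel grid, with linear interpolation along cell
#' edges) and maps vertices to metric world coordinates.  Optionally queries
#' the color network at the vertices for vertex colors.
#'
#' @inheritParams sample_density_grid
#' @param cfg a [mesh_config()].
#' @param vertex_colors if `TRUE` and `field` is a [radiance_field()], attach
#'   per-vertex colors queried with a fixed downward view direction.
#' @return An object of class `triangle_mesh` with `vertices` (n x 3,
#'   meters), `faces` (m x 3, 1-based) and optional `colors` (n x 3).  An
#'   empty isosurface gives an empty mesh with a warning.
#' @export
extract_mesh <- function(field, box, cfg = mesh_config(), vertex_colors = FALSE) {
  stopifnot(inherits(cfg, "mesh_config"))
  g <- sample_density_grid(field, box, cfg$grid_resolution,
                           cfg$cylinder_mask)
  res <- cfg$grid_resolution
  spacing <- c(g$xs[2] - g$xs[1], g$ys[2] - g$ys[1], g$zs[2] - g$zs[1])
  mc <- cpp_marching_tetrahedra(g$density,
                                c(g$xs[1], g$ys[1], g$zs[1]), spacing,
                                cfg$sigma_threshold)
  if (nrow(mc$vertices) == 0) {
    warning("empty isosurface at sigma_threshold = ", cfg$sigma_threshold)
    return(structure(list(vertices = matrix(0, 0, 3),
                          faces = matrix(0L, 0, 3), colors = NULL),
                     class = "triangle_mesh"))
  }
  colors <- NULL
  if (vertex_colors && inherits(field, "radiance_field")) {
    colors <- query_color(field, mc$vertices)
  }
  structure(list(vertices = mc$vertices, faces = mc$faces, colors = colors),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$colors)) "" else ", vertex colors"))
  invisible(x)
}

#' Plant height from a mesh
#'
#' The z-extent `max(z) - min(z)` over the mesh vertices, the standard
#' mesh-derived plant-height estimate.
#'
#' @param mesh a `triangle_mesh`.
#' @return height in meters.
#' @export
mesh_height <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$vertices) == 0) stop("empty mesh", call. = FALSE)
  diff(range(mesh$vertices[, 3]))
}

#' Write a mesh to Wavefront OBJ
#' @param mesh a `triangle_mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices
  vl <- if (is.null(mesh$colors)) {
    sprintf("v %.8g %.8g %.8g", v[, 1], v[, 2], v[, 3])
  } else {
    sprintf("v %.8g %.8g %.8g %.6g %.6g %.6g", v[, 1], v[, 2], v[, 3],
            mesh$colors[, 1], mesh$colors[, 2], mesh$colors[, 3])
  }
  fl <- sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                mesh$faces[, 3])
  writeLines(c("# orbitnerf mesh", vl, fl), path)
  invisible(path)
}

#' Write a mesh to PLY (binary little-endian or ASCII)
#' @param mesh a `triangle_mesh`.
#' @param path output file path.
#' @param binary write binary little-endian (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(mesh, path, binary = TRUE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  has_col <- !is.null(mesh$colors)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           if (has_col) c("property uchar red", "property uchar green",
                          "property uchar blue"),
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  f0 <- mesh$faces - 1L
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    cols <- if (has_col) {
      matrix(as.integer(round(pmin(1, pmax(0, mesh$colors)) * 255)), nv, 3)
    }
    for (i in seq_len(nv)) {
      writeBin(as.numeric(mesh$vertices[i, ]), con, size = 4,
               endian = "little")
      if (has_col) {
        writeBin(as.raw(cols[i, ]), con)
      }
    }
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f0[i, ]), con, size = 4, endian = "little")
    }
  } else {
    vl <- if (has_col) {
      cols <- matrix(as.integer(round(pmin(1, pmax(0, mesh$colors)) * 255)),
                     nv, 3)
      sprintf("%.8g %.8g %.8g %d %d %d", mesh$vertices[, 1],
              mesh$vertices[, 2], mesh$vertices[, 3], cols[, 1], cols[, 2],
              cols[, 3])
    } else {
      sprintf("%.8g %.8g %.8g", mesh$vertices[, 1], mesh$vertices[, 2],
              mesh$vertices[, 3])
    }
    writeLines(c(hdr, vl, sprintf("3 %d %d %d", f0[, 1], f0[, 2], f0[, 3])),
               path)
  }
  invisible(path)
}
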