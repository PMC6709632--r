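#' Build a Voronoi meshwork of membrane compartments
#'
#' Generator points are drawn from a uniform Poisson process with density
#' `1 / mesh_size^2`, so the expected number of compartments is
#' `area / mesh_size^2` and the square root of the mean compartment area
#' matches `mesh_size` up to Monte Carlo sampling error. Cell membership is
#' the nearest-seed rule (Euclidean; minimum-image distances on the periodic
#' square domain).
#'
#' @param domain_size domain extent in um.
#' @param mesh_size characteristic compartment size in nm (square root of the
#'   mean compartment area).
#' @param domain_shape `"square"` (periodic) or `"circle"`.
#' @return An object of class `"voronoi_mesh"`: list with `seeds` (k x 2
#'   matrix, um), `mesh_size` (nm), `mean_cell_area` (um^2, domain area / k),
#'   `domain_size`, `periodic`.
#' @examples
#' set.seed(1)
#' mesh <- voronoi_mesh(3, 110)
#' sqrt(mesh$mean_cell_area) * 1000  # ~ 110 nm
#' @export
voronoi_mesh <- function(domain_size, mesh_size,
                         domain_shape = c("square", "circle")) {
  domain_shape <- match.arg(domain_shape)
  if (mesh_size <= 0) stop("mesh_size must be > 0", call. = FALSE)
  if (mesh_size / 1000 >= domain_size)
    stop("mesh_size must be smaller than the domain", call. = FALSE)
  mesh_um <- mesh_size / 1000
  area <- if (domain_shape == "square") domain_size^2 else
    pi * (domain_size / 2)^2
  k <- rpois(1, area / mesh_um^2)
  if (k < 4)
    stop("mesh density implies fewer than 4 compartments; increase the ",
         "domain or decrease mesh_size", call. = FALSE)
  if (domain_shape == "square") {
    seeds <- cbind(runif(k, -domain_size / 2, domain_size / 2),
                   runif(k, -domain_size / 2, domain_size / 2))
  } else {
    # uniform on the disc by rejection
    seeds <- matrix(NA_real_, 0, 2)
    while (nrow(seeds) < k) {
      cand <- cbind(runif(k, -domain_size / 2, domain_size / 2),
                    runif(k, -domain_size / 2, domain_size / 2))
      keep <- rowSums(cand^2) <= (domain_size / 2)^2
      seeds <- rbind(seeds, cand[keep, , drop = FALSE])
    }
    seeds <- seeds[seq_len(k), , drop = FALSE]
  }
  structure(list(seeds = seeds, mesh_size = mesh_size,
                 mean_cell_area = area / k, domain_size = domain_size,
                 periodic = domain_shape == "square"),
            class = "voronoi_mesh")
}

#' Map positions to Voronoi compartments
#'
#' @param mesh a [voronoi_mesh()] object.
#' @param points an n x 2 matrix (or length-2 vector) of positions in um.
#' @return Integer vector of 1-based compartment indices.
#' @export
mesh_cell <- function(mesh, points) {
  stopifnot(inherits(mesh, "voronoi_mesh"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  voronoi_cell_cpp(points, mesh$seeds, mesh$domain_size, mesh$periodic)
}

#' @export
print.voronoi_mesh <- function(x, ...) {
  cat(sprintf(
    "Voronoi meshwork: %d compartments on a %g um %s domain\n",
    nrow(x$seeds), x$domain_size, if (x$periodic) "periodic square" else "circular"))
  cat(sprintf("  sqrt(mean cell area) = %.1f nm (target %g nm)\n",
              1000 * sqrt(x$mean_cell_area), x$mesh_size))
  invisible(x)
}
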