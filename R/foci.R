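# Leukocyte infiltration foci.
#
# A focus is a spatial cluster of MORE THAN 20 infiltrating leukocytes
# (implemented strictly: >= 21 members). Clusters are the connected components
# of the graph linking cells closer than a linking radius (single linkage);
# densities are expressed per 20 mm^2 of scored section area.

#' Construct a leukocyte point set
#'
#' @param x_um,y_um Numeric coordinate vectors (micrometres), equal length,
#'   finite.
#' @param section_area_mm2 Scored section area in mm^2 (> 0).
#' @param section_id,subject_id Identifiers.
#' @return A `leukocyte_points` object.
#' @export
leukocyte_points <- function(x_um, y_um, section_area_mm2,
                             section_id = "S1", subject_id = "M1") {
  x_um <- as.numeric(x_um); y_um <- as.numeric(y_um)
  if (length(x_um) != length(y_um)) stop("coordinate vectors differ in length")
  if (length(x_um) && !all(is.finite(x_um) & is.finite(y_um)))
    stop("coordinates must be finite")
  if (!is.numeric(section_area_mm2) || section_area_mm2 <= 0)
    stop("section_area_mm2 must be positive")
  structure(list(x_um = x_um, y_um = y_um,
                 section_area_mm2 = section_area_mm2,
                 section_id = section_id, subject_id = subject_id),
            class = "leukocyte_points")
}

#' Detect leukocyte infiltration foci
#'
#' Single-linkage clustering: points within `linking_radius_um` of each other
#' are linked, connected components are clusters, and components with at least
#' `min_cells` members are counted as foci. Neighbour search uses spatial grid
#' hashing with union-find, so only near pairs are examined.
#'
#' @param points A [leukocyte_points()] object.
#' @param linking_radius_um Linking distance, um (default 25, about two
#'   leukocyte diameters).
#' @param min_cells Minimum cluster size to count as a focus; the default 21
#'   implements the strict "more than 20 cells" rule.
#' @return A `foci_result`: `n_foci`, `foci_members` (list of point-index
#'   vectors), `foci_per_20mm2`, `n_points`, `section_area_mm2`.
#' @export
detect_foci <- function(points, linking_radius_um = 25, min_cells = 21L) {
  stopifnot(inherits(points, "leukocyte_points"))
  if (linking_radius_um <= 0) stop("linking_radius_um must be positive")
  if (min_cells < 1L) stop("min_cells must be at least 1")
  n <- length(points$x_um)
  if (n == 0L) {
    return(structure(list(n_foci = 0L, foci_members = list(),
                          foci_per_20mm2 = 0,
                          n_points = 0L,
                          section_area_mm2 = points$section_area_mm2),
                     class = "foci_result"))
  }
  comp <- .link_components(points$x_um, points$y_um, linking_radius_um)
  members <- split(seq_len(n), comp)
  foci <- members[lengths(members) >= min_cells]
  names(foci) <- NULL
  structure(list(n_foci = length(foci), foci_members = foci,
                 foci_per_20mm2 = foci_density(length(foci),
                                               points$section_area_mm2),
                 n_points = n,
                 section_area_mm2 = points$section_area_mm2),
            class = "foci_result")
}

#' @export
print.foci_result <- function(x, ...) {
  cat(sprintf("%d foci among %d cells over %.2f mm^2: %.3f foci / 20 mm^2\n",
              x$n_foci, x$n_points, x$section_area_mm2, x$foci_per_20mm2))
  invisible(x)
}

# connected components under distance <= r, via grid buckets + union-find;
# each pair is examined once (own bucket + half of the 8-neighbourhood)
.link_components <- function(x, y, r) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  link <- function(i, j) {
    ok <- (x[i] - x[j])^2 + (y[i] - y[j])^2 <= r2
    for (k in which(ok)) {
      ri <- find(i[k]); rj <- find(j[k])
      if (ri != rj) parent[ri] <<- rj
    }
  }
  gx <- as.integer(floor(x / r)); gy <- as.integer(floor(y / r))
  buckets <- split(seq_len(n), paste(gx, gy, sep = ","))
  r2 <- r * r
  for (b in buckets) {
    if (length(b) > 1L) {
      prs <- utils::combn(b, 2L)
      link(prs[1L, ], prs[2L, ])
    }
    a <- gx[b[1L]]; c0 <- gy[b[1L]]
    neigh <- c(buckets[[paste(a + 1L, c0 - 1L, sep = ",")]],
               buckets[[paste(a + 1L, c0, sep = ",")]],
               buckets[[paste(a + 1L, c0 + 1L, sep = ",")]],
               buckets[[paste(a, c0 + 1L, sep = ",")]])
    if (length(neigh))
      link(rep(b, each = length(neigh)), rep(neigh, times = length(b)))
  }
  comp <- vapply(seq_len(n), find, integer(1L))
  match(comp, unique(comp))
}

#' Focus density per 20 mm^2
#'
#' @param n_foci Focus count (>= 0).
#' @param section_area_mm2 Scored area in mm^2 (> 0).
#' @return `n_foci * 20 / section_area_mm2`.
#' @examples
#' foci_density(12, 60)  # 4
#' @export
foci_density <- function(n_foci, section_area_mm2) {
  if (!is.numeric(section_area_mm2) || any(section_area_mm2 <= 0))
    stop("invalid input: section_area_mm2 must be positive")
  if (any(n_foci < 0)) stop("invalid input: negative focus count")
  n_foci * 20 / section_area_mm2
}
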