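#' Build a structured 2D explant domain
#'
#' Creates a node-centered rectangular grid over the cross-section of a
#' cartilage explant (default 3 mm wide, 1 mm thick), with an optional
#' lesion cut out of the top surface.  Nodes are ordered with the depth
#' coordinate fastest: node index \code{k = (ix - 1) * nz + iz}, so a field
#' vector reshapes to an \code{nz x nx} matrix with \code{matrix(v, nz, nx)}.
#'
#' The normalized depth coordinate runs from 0 at the articular (top)
#' surface to 1 at the bottom of the explant.  Nodes strictly inside the
#' lesion polygon are masked out and carry no species unknowns; grid faces
#' between a live node and a masked node are labelled \code{"lesion"} and
#' are treated as an additional boundary exchanging with the culture bath.
#'
#' @param width lateral extent in metres (default 3 mm).
#' @param thickness axial extent in metres (default 1 mm).
#' @param nx,nz node counts along the lateral and depth axes (>= 3 each).
#' @param lesion optional lesion polygon: a matrix or data frame with two
#'   columns (x, z) in metres, at least 3 vertices, lying inside the domain
#'   rectangle and touching the top surface (z = 0).
#' @return An object of class \code{cart_domain}: a list with the grid
#'   geometry, per-node coordinates and normalized depth, the lesion mask,
#'   per-node quadrature weights (zero on masked nodes) and the boundary
#'   face table (\code{node}, \code{side}, \code{label}).
#' @examples
#' dom <- build_domain()
#' dom$n_nodes          # 61 * 21 = 1281
#' range(dom$depth)     # 0 .. 1
#' @export
build_domain <- function(width = 3e-3, thickness = 1e-3, nx = 61, nz = 21,
                         lesion = NULL) {
  if (!is.finite(width) || !is.finite(thickness) || width <= 0 || thickness <= 0)
    stop("geometry error: width and thickness must be positive", call. = FALSE)
  if (nx < 3 || nz < 3)
    stop("geometry error: nx and nz must each be at least 3", call. = FALSE)
  nx <- as.integer(nx); nz <- as.integer(nz)

  x <- seq(0, width, length.out = nx)
  z <- seq(0, thickness, length.out = nz)
  dx <- x[2] - x[1]
  dz <- z[2] - z[1]

  # node-major ordering: z (depth) fastest
  node_x <- rep(x, each = nz)
  node_z <- rep(z, times = nx)
  depth <- node_z / thickness
  n_nodes <- nx * nz

  lesion_mask <- rep(FALSE, n_nodes)
  lesion_poly <- NULL
  if (!is.null(lesion)) {
    lesion_poly <- validate_lesion_polygon(lesion, width, thickness)
    lesion_mask <- pracma::inpolygon(node_x, node_z,
                                     lesion_poly[, 1], lesion_poly[, 2],
                                     boundary = FALSE)
  }

  dom <- structure(list(
    width = width, thickness = thickness,
    nx = nx, nz = nz, dx = dx, dz = dz,
    x = x, z = z,
    node_x = node_x, node_z = node_z,
    depth = depth,
    lesion_mask = lesion_mask,
    lesion_polygon = lesion_poly,
    n_nodes = n_nodes
  ), class = "cart_domain")

  dom$weights <- quadrature_weights(dom)
  dom$faces <- boundary_faces(dom)
  dom
}

validate_lesion_polygon <- function(lesion, width, thickness) {
  poly <- as.matrix(lesion)
  if (!is.numeric(poly) || ncol(poly) < 2)
    stop("input error: lesion polygon needs two numeric columns (x, z)",
         call. = FALSE)
  poly <- poly[, 1:2, drop = FALSE]
  if (nrow(poly) < 3)
    stop("input error: degenerate lesion polygon (< 3 vertices)", call. = FALSE)
  tol <- 1e-12
  if (any(poly[, 1] < -tol) || any(poly[, 1] > width + tol) ||
      any(poly[, 2] < -tol) || any(poly[, 2] > thickness + tol))
    stop("geometry error: lesion polygon extends outside the domain",
         call. = FALSE)
  if (min(poly[, 2]) > 1e-9)
    stop("geometry error: lesion polygon must touch the top surface (z = 0)",
         call. = FALSE)
  poly
}

#' @keywords internal
quadrature_weights <- function(dom) {
  wx <- rep(dom$dx, dom$nx); wx[c(1, dom$nx)] <- dom$dx / 2
  wz <- rep(dom$dz, dom$nz); wz[c(1, dom$nz)] <- dom$dz / 2
  w <- rep(wx, each = dom$nz) * rep(wz, times = dom$nx)
  w[dom$lesion_mask] <- 0
  w
}

# Enumerate boundary faces: outer rectangle faces plus faces separating a
# live node from a masked lesion node.  side is the outward direction seen
# from the live node.
boundary_faces <- function(dom) {
  nx <- dom$nx; nz <- dom$nz
  idx <- function(ix, iz) (ix - 1L) * nz + iz
  node <- integer(0); side <- character(0); label <- character(0)
  add <- function(n, s, l) {
    node <<- c(node, n); side <<- c(side, s); label <<- c(label, l)
  }
  masked <- dom$lesion_mask
  for (ix in seq_len(nx)) {
    for (iz in seq_len(nz)) {
      k <- idx(ix, iz)
      if (masked[k]) next
      # four neighbours; outside grid -> outer boundary, masked -> lesion face
      if (iz == 1L) add(k, "up", "top")
      else if (masked[idx(ix, iz - 1L)]) add(k, "up", "lesion")
      if (iz == nz) add(k, "down", "bottom")
      else if (masked[idx(ix, iz + 1L)]) add(k, "down", "lesion")
      if (ix == 1L) add(k, "left", "lateral")
      else if (masked[idx(ix - 1L, iz)]) add(k, "left", "lesion")
      if (ix == nx) add(k, "right", "lateral")
      else if (masked[idx(ix + 1L, iz)]) add(k, "right", "lesion")
    }
  }
  data.frame(node = node, side = side, label = label,
             stringsAsFactors = FALSE)
}

#' @export
print.cart_domain <- function(x, ...) {
  cat(sprintf("cart_domain: %.2f x %.2f mm, %d x %d nodes (%d total)\n",
              x$width * 1e3, x$thickness * 1e3, x$nx, x$nz, x$n_nodes))
  if (any(x$lesion_mask))
    cat(sprintf("  lesion: %d masked nodes\n", sum(x$lesion_mask)))
  invisible(x)
}

#' Specify a full- or partial-depth region of interest
#'
#' A rectangular depth-wise region of interest (ROI) mirroring the
#' 200-um-wide full-depth strips used when depth profiles are extracted
#' from collagen maps.
#'
#' @param x_center lateral centre of the ROI (m).
#' @param width lateral width of the ROI (m, default 200 um).
#' @param depth_range normalized depth interval covered, within [0, 1].
#' @return An object of class \code{roi_spec}.
#' @export
roi_spec <- function(x_center, width = 200e-6, depth_range = c(0, 1)) {
  if (!is.finite(x_center) || !is.finite(width) || width < 0)
    stop("input error: invalid ROI geometry", call. = FALSE)
  if (length(depth_range) != 2 || depth_range[1] > depth_range[2] ||
      depth_range[1] < 0 || depth_range[2] > 1)
    stop("input error: depth_range must be an ordered interval in [0, 1]",
         call. = FALSE)
  structure(list(x_center = x_center, width = width,
                 depth_range = depth_range), class = "roi_spec")
}

#' Node mask for a region of interest
#'
#' Marks nodes with \code{|x - x_center| <= width / 2} and normalized depth
#' inside \code{depth_range}.  Lesion nodes are excluded; if the ROI
#' overlaps the lesion a warning is issued rather than an error.
#'
#' @param domain a \code{cart_domain}.
#' @param roi a \code{roi_spec}.
#' @return Logical vector over the domain nodes.
#' @export
roi_depth_mask <- function(domain, roi) {
  stopifnot(inherits(domain, "cart_domain"), inherits(roi, "roi_spec"))
  if (roi$x_center < 0 || roi$x_center > domain$width)
    stop("input error: ROI centre outside the domain", call. = FALSE)
  tol <- 1e-9
  geom <- abs(domain$node_x - roi$x_center) <= roi$width / 2 + tol &
    domain$depth >= roi$depth_range[1] - tol &
    domain$depth <= roi$depth_range[2] + tol
  overlap <- geom & domain$lesion_mask
  if (any(overlap))
    warning(sprintf("ROI overlaps the lesion: %d nodes excluded",
                    sum(overlap)))
  geom & !domain$lesion_mask
}

#' Read a lesion polygon from a two-column CSV of (x, z) vertices in metres
#'
#' @param path CSV file with columns x and z (header optional).
#' @return A two-column numeric matrix of vertices.
#' @export
read_lesion_polygon <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("[A-Za-z]", first)
  poly <- utils::read.csv(path, header = has_header)
  as.matrix(poly[, 1:2])
}

#' Export per-node fields as a delimited table
#'
#' Writes node coordinates, normalized depth, the lesion mask and any
#' number of per-node field vectors to CSV, one row per node.
#'
#' @param domain a \code{cart_domain}.
#' @param fields named list of per-node numeric vectors.
#' @param path output CSV path.
#' @return The written data frame, invisibly.
#' @export
write_fields_csv <- function(domain, fields, path) {
  stopifnot(inherits(domain, "cart_domain"))
  if (length(fields) && (is.null(names(fields)) || any(names(fields) == "")))
    stop("input error: fields must be a named list", call. = FALSE)
  bad <- vapply(fields, function(f) length(f) != domain$n_nodes, logical(1))
  if (any(bad))
    stop("format error: field length does not match node count", call. = FALSE)
  df <- data.frame(x = domain$node_x, z = domain$node_z,
                   depth = domain$depth, lesion = domain$lesion_mask)
  for (nm in names(fields)) df[[nm]] <- fields[[nm]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
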