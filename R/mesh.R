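#' Structured multi-block meshes with named boundary patches
#'
#' The solver operates on a single conforming 2-D tensor-product grid of
#' rectangular cells (unit depth), assembled from one or more rectangular
#' blocks.  Boundary faces are partitioned into named patches; the patch named
#' `"injuryWalls"` marks the reactive, adhesive portion of the vessel wall on
#' which subendothelium-bound species live.
#'
#' @name mesh_geometry
NULL

BOUNDARY_SIDES <- c("west", "east", "south", "north")

#' Build a conforming mesh from rectangular blocks
#'
#' Blocks must tile a rectangle without overlap, with matching face
#' coordinates along shared edges, and uniform cell spacing per axis (no
#' grading).  Every boundary edge of the tiling must be assigned to a named
#' patch.
#'
#' @param blocks list of block specs, each a list with `x0`, `x1`, `y0`, `y1`
#'   (um) and cell counts `nx`, `ny`.
#' @param patch_assignments named character vector mapping `"<block>.<side>"`
#'   (side one of `west`, `east`, `south`, `north`; block is the index in
#'   `blocks`) to a patch name.  Interior (shared) edges must not be assigned.
#' @param patch_types optional named character vector mapping patch names to a
#'   type tag (`"wall"`, `"inflow"`, `"outflow"`).  Unlisted patches default to
#'   `"wall"` except names `"inlet"` (`"inflow"`) and `"outlet"`
#'   (`"outflow"`).
#' @param tol coordinate matching tolerance (um).
#' @return an object of class `clot_mesh`: cell counts `nx`, `ny`; strictly
#'   increasing face coordinates `x_faces`, `y_faces`; spacings `dx`, `dy`;
#'   cell centres `xc`, `yc`; `cell_volumes` (nx x ny, unit depth); and
#'   `patches`, a named list of data frames with columns `side`, `i`, `j`
#'   (the boundary-adjacent cell) and a `type_tag` attribute.
#' @export
build_multiblock_mesh <- function(blocks, patch_assignments,
                                  patch_types = NULL, tol = 1e-9) {
  stopifnot(length(blocks) >= 1)
  for (b in seq_along(blocks)) {
    bl <- blocks[[b]]
    need <- c("x0", "x1", "y0", "y1", "nx", "ny")
    if (!all(need %in% names(bl)))
      stop("block ", b, " is missing fields: ",
           paste(setdiff(need, names(bl)), collapse = ", "))
    if (bl$x1 <= bl$x0 || bl$y1 <= bl$y0)
      stop("block ", b, " has non-positive extent")
    if (bl$nx < 1 || bl$ny < 1) stop("block ", b, " has no cells")
  }

  xf_all <- sort(unique(unlist(lapply(blocks, function(b)
    seq(b$x0, b$x1, length.out = b$nx + 1)))))
  yf_all <- sort(unique(unlist(lapply(blocks, function(b)
    seq(b$y0, b$y1, length.out = b$ny + 1)))))
  xf <- dedupe_coords(xf_all, tol)
  yf <- dedupe_coords(yf_all, tol)

  x0 <- min(xf); x1 <- max(xf); y0 <- min(yf); y1 <- max(yf)

  ## tiling: total block area equals bounding-rectangle area, no overlaps
  area <- sum(vapply(blocks, function(b) (b$x1 - b$x0) * (b$y1 - b$y0), 0))
  if (abs(area - (x1 - x0) * (y1 - y0)) > tol * max(1, area))
    stop("blocks do not tile the bounding rectangle (area mismatch)")
  if (length(blocks) > 1) {
    for (a in seq_len(length(blocks) - 1)) for (b in (a + 1):length(blocks)) {
      ba <- blocks[[a]]; bb <- blocks[[b]]
      ox <- min(ba$x1, bb$x1) - max(ba$x0, bb$x0)
      oy <- min(ba$y1, bb$y1) - max(ba$y0, bb$y0)
      if (ox > tol && oy > tol)
        stop("blocks ", a, " and ", b, " overlap")
    }
  }

  ## conformity: every global face line inside a block must be one of that
  ## block's own faces (this catches mismatched shared-edge discretisation)
  for (b in seq_along(blocks)) {
    bl <- blocks[[b]]
    bxf <- seq(bl$x0, bl$x1, length.out = bl$nx + 1)
    byf <- seq(bl$y0, bl$y1, length.out = bl$ny + 1)
    inx <- xf[xf > bl$x0 - tol & xf < bl$x1 + tol]
    iny <- yf[yf > bl$y0 - tol & yf < bl$y1 + tol]
    bad_x <- inx[vapply(inx, function(v) min(abs(bxf - v)) > tol, TRUE)]
    bad_y <- iny[vapply(iny, function(v) min(abs(byf - v)) > tol, TRUE)]
    if (length(bad_x) > 0)
      stop("non-conforming block interface: block ", b,
           " has no x-face at coordinate ", format(bad_x[1]))
    if (length(bad_y) > 0)
      stop("non-conforming block interface: block ", b,
           " has no y-face at coordinate ", format(bad_y[1]))
  }

  nx <- length(xf) - 1L; ny <- length(yf) - 1L
  dxs <- diff(xf); dys <- diff(yf)
  if (any(dxs <= 0) || any(dys <= 0)) stop("face coordinates not strictly increasing")
  if (diff(range(dxs)) > tol || diff(range(dys)) > tol)
    stop("mesh is graded (non-uniform spacing); only uniform spacing per axis is supported")
  dx <- mean(dxs); dy <- mean(dys)
  xc <- (xf[-1] + xf[-(nx + 1)]) / 2
  yc <- (yf[-1] + yf[-(ny + 1)]) / 2

  ## assign every global boundary face to a patch via its owning block edge
  locate_block_edge <- function(side, coord_along) {
    for (b in seq_along(blocks)) {
      bl <- blocks[[b]]
      hit <- switch(side,
        west  = abs(bl$x0 - x0) < tol && coord_along > bl$y0 - tol && coord_along < bl$y1 + tol,
        east  = abs(bl$x1 - x1) < tol && coord_along > bl$y0 - tol && coord_along < bl$y1 + tol,
        south = abs(bl$y0 - y0) < tol && coord_along > bl$x0 - tol && coord_along < bl$x1 + tol,
        north = abs(bl$y1 - y1) < tol && coord_along > bl$x0 - tol && coord_along < bl$x1 + tol)
      if (hit) return(b)
    }
    stop("internal error: boundary face not inside any block")
  }

  face_rows <- list()
  add_face <- function(side, i, j, along_mid) {
    b <- locate_block_edge(side, along_mid)
    key <- paste0(b, ".", side)
    pname <- if (key %in% names(patch_assignments)) patch_assignments[[key]] else NULL
    if (is.null(pname) || is.na(pname))
      stop("unnamed boundary edge: block ", b, " side '", side,
           "' has no patch assignment")
    face_rows[[length(face_rows) + 1L]] <<-
      data.frame(patch = pname, side = side, i = i, j = j,
                 stringsAsFactors = FALSE)
  }
  for (j in seq_len(ny)) add_face("west",  1L,  j, yc[j])
  for (j in seq_len(ny)) add_face("east",  nx,  j, yc[j])
  for (i in seq_len(nx)) add_face("south", i, 1L,  xc[i])
  for (i in seq_len(nx)) add_face("north", i, ny,  xc[i])
  all_faces <- do.call(rbind, face_rows)

  default_type <- function(nm) {
    if (!is.null(patch_types) && nm %in% names(patch_types)) return(patch_types[[nm]])
    if (nm == "inlet") return("inflow")
    if (nm == "outlet") return("outflow")
    "wall"
  }
  patches <- lapply(split(all_faces[c("side", "i", "j")], all_faces$patch),
                    function(df) { rownames(df) <- NULL; df })
  for (nm in names(patches)) {
    tt <- default_type(nm)
    if (!tt %in% c("wall", "inflow", "outflow"))
      stop("unknown patch type tag '", tt, "' for patch '", nm, "'")
    attr(patches[[nm]], "type_tag") <- tt
  }
  if ("injuryWalls" %in% names(patches) &&
      attr(patches[["injuryWalls"]], "type_tag") != "wall")
    stop("injuryWalls must be a wall-type patch")

  mesh <- list(nx = nx, ny = ny, x_faces = xf, y_faces = yf,
               dx = dx, dy = dy, xc = xc, yc = yc,
               cell_volumes = matrix(dx * dy, nx, ny),
               patches = patches)
  class(mesh) <- "clot_mesh"
  mesh
}

## collapse coordinates closer than tol (matching shared faces across blocks)
dedupe_coords <- function(v, tol) {
  v <- sort(v)
  keep <- c(TRUE, diff(v) > tol)
  v[keep]
}

#' @exportS3Method base::print
print.clot_mesh <- function(x, ...) {
  cat("clot_mesh:", x$nx, "x", x$ny, "cells, ",
      format(diff(range(x$x_faces))), "x", format(diff(range(x$y_faces))),
      "um\n  patches:",
      paste(sprintf("%s[%d,%s]", names(x$patches),
                    vapply(x$patches, nrow, 0L),
                    vapply(x$patches, attr, "", "type_tag")),
            collapse = ", "), "\n")
  invisible(x)
}

#' Total number of boundary faces of a mesh
#' @param mesh a `clot_mesh`
#' @return integer count
#' @export
n_boundary_faces <- function(mesh) 2L * (mesh$nx + mesh$ny)

#' Geometry of the faces of a boundary patch
#'
#' @param mesh a `clot_mesh`
#' @param patch patch name
#' @return data frame of face segments: `side`, `i`, `j`, endpoints
#'   `xa`, `ya`, `xb`, `yb` and face `length` (um)
#' @export
patch_face_segments <- function(mesh, patch) {
  df <- mesh$patches[[patch]]
  if (is.null(df)) stop("mesh has no patch named '", patch, "'")
  xf <- mesh$x_faces; yf <- mesh$y_faces
  seg <- function(side, i, j) {
    switch(side,
      west  = c(xf[1],      yf[j], xf[1],      yf[j + 1]),
      east  = c(xf[mesh$nx + 1], yf[j], xf[mesh$nx + 1], yf[j + 1]),
      south = c(xf[i], yf[1],      xf[i + 1], yf[1]),
      north = c(xf[i], yf[mesh$ny + 1], xf[i + 1], yf[mesh$ny + 1]))
  }
  m <- t(mapply(seg, df$side, df$i, df$j))
  out <- cbind(df, data.frame(xa = m[, 1], ya = m[, 2], xb = m[, 3], yb = m[, 4]))
  out$length <- sqrt((out$xb - out$xa)^2 + (out$yb - out$ya)^2)
  rownames(out) <- NULL
  out
}

## distance from points (x, y) to the nearest face segment of a patch
min_distance_to_patch <- function(mesh, patch) {
  segs <- patch_face_segments(mesh, patch)
  X <- matrix(mesh$xc, mesh$nx, mesh$ny)
  Y <- matrix(mesh$yc, mesh$nx, mesh$ny, byrow = TRUE)
  d <- matrix(Inf, mesh$nx, mesh$ny)
  for (k in seq_len(nrow(segs))) {
    if (segs$side[k] %in% c("south", "north")) {
      cx <- pmin(pmax(X, segs$xa[k]), segs$xb[k])
      dk <- sqrt((X - cx)^2 + (Y - segs$ya[k])^2)
    } else {
      cy <- pmin(pmax(Y, segs$ya[k]), segs$yb[k])
      dk <- sqrt((X - segs$xa[k])^2 + (Y - cy)^2)
    }
    d <- pmin(d, dk)
  }
  d
}

#' Check injury-site mesh resolution against the platelet diameter
#'
#' The adhesion region is only well defined when every cell near the injury
#' patch is no larger than a platelet diameter in each direction.
#'
#' @param mesh a `clot_mesh` with an `injuryWalls` patch
#' @param Pdiam platelet diameter (um, default 3)
#' @return a list with `pass` (logical), `violations` (data frame of offending
#'   cells with their sizes) and the `Pdiam` used
#' @export
validate_injury_resolution <- function(mesh, Pdiam = 3) {
  if (!"injuryWalls" %in% names(mesh$patches))
    stop("mesh has no injuryWalls patch")
  d <- min_distance_to_patch(mesh, "injuryWalls")
  inj <- mesh$patches[["injuryWalls"]]
  adjacent <- matrix(FALSE, mesh$nx, mesh$ny)
  adjacent[cbind(inj$i, inj$j)] <- TRUE
  near <- adjacent | (d <= Pdiam)
  ok <- (mesh$dx <= Pdiam) & (mesh$dy <= Pdiam)
  bad <- which(near & !ok, arr.ind = TRUE)
  violations <- data.frame(i = bad[, 1], j = bad[, 2],
                           dx = rep(mesh$dx, nrow(bad)),
                           dy = rep(mesh$dy, nrow(bad)))
  list(pass = nrow(violations) == 0L, violations = violations, Pdiam = Pdiam)
}

#' Compute the wall-adhesion indicator region
#'
#' Marks the cells in which mobile platelets may adhere directly to the
#' subendothelium: those whose centre lies within one platelet diameter
#' (Euclidean centre-to-face distance) of an `injuryWalls` face.  The
#' indicator is binary; a different functional form can be substituted by
#' post-processing the returned distances.
#'
#' @param mesh a `clot_mesh`
#' @param Pdiam platelet diameter (um, default 3)
#' @param enabled if `FALSE` (adhesion disabled for the case) an all-zero
#'   indicator is returned and no `injuryWalls` patch is required.
#' @return class `clot_adhesion_region`: `indicator` (nx x ny, values 0/1),
#'   `distance` (um, `Inf` where disabled) and `Pdiam`
#' @export
compute_adhesion_region <- function(mesh, Pdiam = 3, enabled = TRUE) {
  if (!enabled) {
    out <- list(indicator = matrix(0, mesh$nx, mesh$ny),
                distance = matrix(Inf, mesh$nx, mesh$ny), Pdiam = Pdiam)
    class(out) <- "clot_adhesion_region"
    return(out)
  }
  if (!"injuryWalls" %in% names(mesh$patches))
    stop("configuration error: adhesion enabled but mesh has no injuryWalls patch")
  d <- min_distance_to_patch(mesh, "injuryWalls")
  out <- list(indicator = (d <= Pdiam) * 1, distance = d, Pdiam = Pdiam)
  class(out) <- "clot_adhesion_region"
  out
}
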