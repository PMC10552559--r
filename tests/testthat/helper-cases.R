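# Shared fixtures built in code: small meshes and cases for fast tests.

## single rectangular block with all four edges named
rect_mesh <- function(nx, ny, Lx = nx, Ly = ny,
                      south = "walls",
                      names = c(west = "inlet", east = "outlet",
                                north = "walls")) {
  build_multiblock_mesh(
    list(list(x0 = 0, x1 = Lx, y0 = 0, y1 = Ly, nx = nx, ny = ny)),
    c("1.west" = unname(names["west"]), "1.east" = unname(names["east"]),
      "1.south" = south, "1.north" = unname(names["north"])))
}

## closed box: every edge is a wall (optionally the south edge is the injury)
box_mesh <- function(nx, ny, Lx = nx, Ly = ny, injury_south = FALSE) {
  rect_mesh(nx, ny, Lx, Ly,
            south = if (injury_south) "injuryWalls" else "walls",
            names = c(west = "walls", east = "walls", north = "walls"))
}

zero_flux <- function(mesh) {
  list(x = matrix(0, mesh$nx + 1, mesh$ny), y = matrix(0, mesh$nx, mesh$ny + 1))
}

uniform_flux <- function(mesh, u = 0, v = 0) {
  list(x = matrix(u * mesh$dy, mesh$nx + 1, mesh$ny),
       y = matrix(v * mesh$dx, mesh$nx, mesh$ny + 1))
}

bc_all <- function(mesh, kind = "zero_gradient", value = 0) {
  out <- lapply(names(mesh$patches), function(p) list(kind = kind, value = value))
  names(out) <- names(mesh$patches)
  out
}

## miniature thrombosis channel (60 x 30 um, 15 um injury) for fast
## integration tests; same physics as the shipped case
tiny_channel_case <- function(end_time = 2, injury = TRUE) {
  blocks <- list(
    list(x0 = 0, x1 = 22.5, y0 = 0, y1 = 30, nx = 9L, ny = 12L),
    list(x0 = 22.5, x1 = 37.5, y0 = 0, y1 = 30, nx = 6L, ny = 12L),
    list(x0 = 37.5, x1 = 60, y0 = 0, y1 = 30, nx = 9L, ny = 12L))
  pa <- c("1.west" = "inlet", "3.east" = "outlet",
          "1.south" = "walls", "3.south" = "walls",
          "2.south" = if (injury) "injuryWalls" else "walls",
          "1.north" = "walls", "2.north" = "walls", "3.north" = "walls")
  mesh <- build_multiblock_mesh(blocks, pa)
  config <- list(mesh_spec = list(blocks = blocks, patch_assignments = pa),
                 end_time = end_time, injury = injury,
                 with_inhibitor = FALSE, params = default_parameters())
  list(mesh = mesh, config = config)
}

## default well-mixed initial concentrations (nM) with an E1 seed
wellmixed_init <- function(p, E1 = 1) {
  list(S1 = 170, E1 = E1, S2 = 1400, E2 = 0, I1 = p$I1_inlet, I2 = p$I2_inlet,
       E1I1 = 0, E2I2 = 0, E1b = 0, S2b = 0, E2b = 0)
}
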