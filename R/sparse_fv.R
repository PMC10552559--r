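#' Cached pentadiagonal SPD solver for structured-grid operators
#'
#' All implicit operators in the package (backward-Euler diffusion, the
#' momentum equations, the pressure-correction equation) are symmetric
#' positive-definite 5-point stencils on an nx x ny grid.  This helper builds
#' the sparsity pattern and CHOLMOD symbolic factorisation once and then only
#' refreshes numeric values, which keeps per-time-step cost low.
#'
#' Cells are numbered column-major: id = i + (j-1)*nx.
#'
#' @param nx,ny grid extents of the unknown field
#' @return an environment with functions `set_coefficients(diagv, aE, aN)`
#'   (off-diagonals are `-aE[cell]` towards i+1 and `-aN[cell]` towards j+nx)
#'   and `solve(rhs)`.
#' @keywords internal
make_penta_solver <- function(nx, ny) {
  n <- nx * ny
  I <- rep(seq_len(nx), ny)
  J <- rep(seq_len(ny), each = nx)
  id <- seq_len(n)

  e_src <- id[I < nx]              # cells owning an east link
  n_src <- id[J < ny]              # cells owning a north link
  ii <- c(id, e_src, n_src)
  jj <- c(id, e_src + 1L, n_src + nx)
  xx <- c(rep(1, n), rep(0, length(e_src)), rep(0, length(n_src)))
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            symmetric = TRUE)

  ## map stored (upper-triangle) entries back to stencil slots
  Ai <- A@i + 1L
  Ap <- A@p
  cols <- rep(seq_len(n), diff(Ap))
  kind_diag <- which(Ai == cols)
  kind_e <- which(cols == Ai + 1L & ((Ai - 1L) %% nx) != (nx - 1L))
  kind_n <- which(cols == Ai + nx)
  stopifnot(length(kind_diag) == n,
            length(kind_e) == length(e_src),
            length(kind_n) == length(n_src))
  e_of <- Ai[kind_e]               # source cell for each east entry
  n_of <- Ai[kind_n]

  env <- new.env(parent = emptyenv())
  env$A <- A
  env$chol <- NULL
  env$set_coefficients <- function(diagv, aE, aN) {
    x <- env$A@x
    x[kind_diag] <- diagv
    x[kind_e] <- -aE[e_of]
    x[kind_n] <- -aN[n_of]
    env$A@x <- x
    if (is.null(env$chol)) {
      env$chol <- Matrix::Cholesky(env$A, LDL = FALSE, perm = TRUE)
    } else {
      env$chol <- update(env$chol, env$A)
    }
    invisible(NULL)
  }
  env$solve <- function(rhs) {
    if (is.null(env$chol)) stop("solver coefficients not set")
    res <- solve(env$chol, rhs, system = "A")
    if (is.null(dim(rhs))) as.numeric(res) else as.matrix(res)
  }
  env
}
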