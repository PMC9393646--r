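# Landmark-based registration of serial-section panels into one frame.
#
# Serial sections stained with different panels are misaligned by a small
# rotation/translation (and slight scale from sectioning). The default model
# is a similarity transform, which preserves distances up to a single scale
# factor and so protects distance-based statistics; a full affine fit is
# available behind `type = "affine"` for sections with shear.

#' Estimate a planar transform from landmark pairs
#'
#' Least-squares fit mapping moving-frame landmarks onto fixed-frame
#' landmarks. `type = "similarity"` (default) fits rotation + isotropic
#' scale + translation in closed form (orthogonal Procrustes);
#' `type = "affine"` fits all six coefficients by linear least squares.
#'
#' @param moving,fixed n x 2 matrices (or data.frames) of corresponding
#'   landmark coordinates in micrometres; n >= 3, not collinear
#' @param type `"similarity"` or `"affine"`
#' @return a `planar_transform`: 2 x 3 matrix `A` (so `y = A %*% c(x, 1)`),
#'   `rmse_um`, `n_landmarks`, `type`
#' @export
estimate_transform <- function(moving, fixed, type = c("similarity", "affine")) {
  type <- match.arg(type)
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  assert_that(nrow(moving) == nrow(fixed) && ncol(moving) == 2 && ncol(fixed) == 2,
              "landmark sets must be n x 2 with equal n")
  n <- nrow(moving)
  assert_that(n >= 3, "need >= 3 landmark pairs")
  sv <- svd(sweep(moving, 2, colMeans(moving)))$d
  assert_that(sv[2] > 1e-9 * max(sv[1], 1), "landmarks are collinear")

  if (type == "similarity") {
    mu_m <- colMeans(moving); mu_f <- colMeans(fixed)
    X <- sweep(moving, 2, mu_m); Y <- sweep(fixed, 2, mu_f)
    S <- crossprod(Y, X) / n              # 2x2 covariance
    dec <- svd(S)
    D <- diag(c(1, sign(det(dec$u %*% t(dec$v)))))
    R <- dec$u %*% D %*% t(dec$v)
    s <- sum(diag(D) * dec$d) / mean(rowSums(X^2))
    A_lin <- s * R
    t_vec <- mu_f - as.vector(A_lin %*% mu_m)
  } else {
    M <- cbind(moving, 1)
    coef <- qr.solve(M, fixed)            # 3 x 2
    A_lin <- t(coef[1:2, ])
    t_vec <- coef[3, ]
  }
  A <- unname(cbind(A_lin, t_vec))
  dimnames(A) <- NULL
  pred <- t(A_lin %*% t(moving)) + rep(t_vec, each = n)
  rmse <- sqrt(mean(rowSums((pred - fixed)^2)))
  structure(list(A = A, rmse_um = rmse, n_landmarks = n, type = type),
            class = "planar_transform")
}

#' @export
print.planar_transform <- function(x, ...) {
  cat(sprintf("planar_transform (%s), %d landmarks, rmse %.3f um\n",
              x$type, x$n_landmarks, x$rmse_um))
  print(round(x$A, 6))
  invisible(x)
}

#' Invert a planar transform
#'
#' @param t a `planar_transform`
#' @return the inverse transform
#' @export
invert_transform <- function(t) {
  L <- t$A[, 1:2]
  assert_that(abs(det(L)) > 1e-12, "transform is singular")
  Li <- solve(L)
  structure(list(A = cbind(Li, -Li %*% t$A[, 3]), rmse_um = t$rmse_um,
                 n_landmarks = t$n_landmarks, type = t$type),
            class = "planar_transform")
}

#' Apply a planar transform to cell coordinates
#'
#' Maps `x_um`, `y_um` of every cell; all other columns are untouched.
#'
#' @param cells a cell table (or any data.frame with `x_um`, `y_um`)
#' @param t a `planar_transform`
#' @return the table with transformed coordinates
#' @export
apply_transform <- function(cells, t) {
  L <- t$A[, 1:2]
  assert_that(abs(det(L)) > 1e-12, "transform is singular")
  xy <- cbind(cells$x_um, cells$y_um) %*% t(L)
  cells$x_um <- xy[, 1] + t$A[1, 3]
  cells$y_um <- xy[, 2] + t$A[2, 3]
  cells
}

#' Write / read a transform as JSON
#'
#' @param t a `planar_transform`
#' @param path JSON path
#' @return `path` (write) or a `planar_transform` (read)
#' @export
write_transform <- function(t, path) {
  jsonlite::write_json(list(matrix = t$A, rmse_um = t$rmse_um,
                            n_landmarks = t$n_landmarks, type = t$type),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  v <- jsonlite::fromJSON(path)
  structure(list(A = matrix(unlist(v$matrix), 2, 3), rmse_um = v$rmse_um,
                 n_landmarks = v$n_landmarks, type = v$type),
            class = "planar_transform")
}
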