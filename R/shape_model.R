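# Statistical shape model: generalised Procrustes mean, eigenposes, and
# per-frame decomposition into shape coefficients plus a rigid transform.

# Rigid (Kabsch) alignment of source onto target (both K x 3, rows =
# landmarks): finds proper rotation R (right-multiplied, row-vector
# convention) and translation T minimising ||source %*% R + T - target||.
# kabsch_yaw restricts the rotation to the vertical (z) axis.
kabsch_yaw <- function(source, target) {
  cs <- colMeans(source); ct <- colMeans(target)
  sx <- source[, 1] - cs[1]; sy <- source[, 2] - cs[2]
  tx <- target[, 1] - ct[1]; ty <- target[, 2] - ct[2]
  theta <- atan2(sum(sy * tx - sx * ty), sum(sx * tx + sy * ty))
  R <- yaw_matrix(theta)
  list(R = R, T = ct - drop(cs %*% R))
}

kabsch <- function(source, target) {
  cs <- colMeans(source); ct <- colMeans(target)
  H <- t(source - rep(cs, each = nrow(source))) %*%
    (target - rep(ct, each = nrow(target)))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(R = R, T = ct - drop(cs %*% R))
}

#' Fit a statistical shape model to landmark sequences
#'
#' Rigidly aligns every frame to a common reference by generalised Procrustes
#' analysis (rotation + translation, no scaling), takes the aligned mean as
#' the mean pose and the principal axes of the aligned residuals as ordered
#' eigenposes. The pose of frame `t` is then modelled as
#' `X(t) = (Xbar + sum_i P_i b_i(t)) R(t) + T(t)`.
#'
#' By default the alignment rotations are restricted to yaw (rotation about
#' the vertical axis): landmark data from an arena have a physical vertical,
#' and keeping it fixed makes the XZ (sagittal) and XY (horizontal) feature
#' planes meaningful. After alignment the model is put in a canonical
#' orientation with the mean body axis (first landmark to last) along +x.
#' `align = "full"` allows unrestricted 3-D alignment rotations.
#'
#' Two designated deformation modes are also computed for the behavioural
#' features: the leading principal mode of the residuals restricted to the
#' XZ plane (elongation) and to the XY plane (bend), each sign-fixed so that
#' an increase in the distance between the first and last landmark along the
#' body axis is positive.
#'
#' @param frames T x K x 3 array of landmark coordinates (mm), or a list of
#'   such arrays (sessions are stacked).
#' @param n_eigenposes number of eigenposes to keep, or `NULL` to keep modes
#'   up to `variance_target`.
#' @param variance_target cumulative variance fraction retained when
#'   `n_eigenposes` is `NULL`.
#' @param landmarks optional character vector of landmark names (should
#'   include `"neck"` and `"tail_base"` for the rear feature).
#' @param align `"yaw"` (default) or `"full"` alignment rotations.
#' @param max_iter,tol GPA iteration controls.
#' @return object of class `shape_model`: `mean_pose` (K x 3, centred at the
#'   origin), `eigenposes` (list of K x 3 matrices, orthonormal under the
#'   flattened inner product), `variance` per eigenpose, `elongation_mode`
#'   and `bend_mode` (K x 3), `landmarks`.
#' @export
fit_shape_model <- function(frames, n_eigenposes = NULL,
                            variance_target = 0.95, landmarks = NULL,
                            align = c("yaw", "full"),
                            max_iter = 50, tol = 1e-10) {
  align <- match.arg(align)
  if (is.list(frames)) {
    frames <- do.call(abind3, frames)
  }
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] == 3)
  Tn <- dim(frames)[1]; K <- dim(frames)[2]
  if (Tn < 10 * K) {
    warning("fewer than 10 frames per landmark; model may be unstable")
  }
  fit_rigid <- if (align == "yaw") kabsch_yaw else kabsch
  ref <- frames[1, , ]
  ref <- ref - rep(colMeans(ref), each = K)
  aligned <- array(0, dim = dim(frames))
  for (iter in seq_len(max_iter)) {
    for (t in seq_len(Tn)) {
      tr <- fit_rigid(frames[t, , ], ref)
      aligned[t, , ] <- frames[t, , ] %*% tr$R +
        rep(tr$T, each = K)
    }
    new_ref <- apply(aligned, c(2, 3), mean)
    new_ref <- new_ref - rep(colMeans(new_ref), each = K)
    if (sum((new_ref - ref)^2) < tol) { ref <- new_ref; break }
    ref <- new_ref
  }
  # canonical orientation: mean body axis (first to last landmark) along +x
  ax <- ref[1, 1:2] - ref[K, 1:2]
  if (sqrt(sum(ax^2)) > 1e-9) {
    Rc <- yaw_matrix(atan2(ax[2], ax[1]))
    ref <- ref %*% Rc
    for (t in seq_len(Tn)) aligned[t, , ] <- aligned[t, , ] %*% Rc
  }
  resid <- matrix(aligned, nrow = Tn) -
    matrix(rep(as.vector(ref), each = Tn), nrow = Tn)
  total_var <- sum(apply(resid, 2, stats::var))
  if (total_var < 1e-12) {
    model <- list(mean_pose = ref, eigenposes = list(), variance = numeric(0),
                  elongation_mode = NULL, bend_mode = NULL,
                  landmarks = landmarks, degenerate = TRUE)
    class(model) <- "shape_model"
    return(model)
  }
  pca <- stats::prcomp(resid, center = TRUE, scale. = FALSE)
  vars <- pca$sdev^2
  keep <- if (!is.null(n_eigenposes)) {
    seq_len(min(n_eigenposes, sum(vars > 1e-12)))
  } else {
    seq_len(max(1L, which(cumsum(vars) / sum(vars) >= variance_target)[1]))
  }
  eig <- lapply(keep, function(i) matrix(pca$rotation[, i], nrow = K))
  plane_mode <- function(cols) {
    sub <- resid[, as.vector(outer(seq_len(K), (cols - 1) * K, `+`))]
    p <- stats::prcomp(sub, center = TRUE, scale. = FALSE)$rotation[, 1]
    m <- matrix(0, K, 3)
    m[, cols] <- matrix(p, nrow = K)
    # sign convention: first-to-last landmark axial distance increases
    axis_gain <- sum((m[K, ] - m[1, ]) * (ref[K, ] - ref[1, ]))
    if (axis_gain < 0) m <- -m
    m
  }
  model <- list(mean_pose = ref, eigenposes = eig,
                variance = vars[keep],
                elongation_mode = plane_mode(c(1, 3)),
                bend_mode = plane_mode(c(1, 2)),
                landmarks = landmarks, degenerate = FALSE)
  class(model) <- "shape_model"
  model
}

abind3 <- function(...) {
  mats <- list(...)
  K <- dim(mats[[1]])[2]
  out <- array(0, dim = c(sum(vapply(mats, function(m) dim(m)[1], 0L)), K, 3))
  at <- 0L
  for (m in mats) {
    out[at + seq_len(dim(m)[1]), , ] <- m
    at <- at + dim(m)[1]
  }
  out
}

#' Decompose landmark frames against a shape model
#'
#' Per frame, jointly estimates shape coefficients `b`, a proper rotation
#' `R` and translation `T` minimising landmark RMSE under
#' `X(t) = (Xbar + sum_i P_i b_i(t)) R(t) + T(t)`, by alternating a rigid
#' Procrustes step (given the current shape) and a shape-projection step
#' (given the current rigid transform) until the objective changes by less
#' than `tol`.
#'
#' @param frames T x K x 3 array.
#' @param model a [fit_shape_model()] result.
#' @param max_iter per-frame iteration cap.
#' @param tol convergence tolerance on the summed squared error.
#' @return object of class `pose_decomposition`: `b` (T x n_modes), `R`
#'   (list of 3 x 3 rotations), `T` (T x 3), `rmse` per frame (mm),
#'   `converged` per frame.
#' @export
decompose_pose <- function(frames, model, max_iter = 500, tol = 1e-15) {
  stopifnot(inherits(model, "shape_model"),
            dim(frames)[2] == nrow(model$mean_pose))
  Tn <- dim(frames)[1]; K <- dim(frames)[2]
  nm <- length(model$eigenposes)
  P <- if (nm) vapply(model$eigenposes, as.vector, numeric(3 * K)) else
    matrix(0, 3 * K, 0)
  b <- matrix(0, Tn, max(1L, nm))[, seq_len(nm), drop = FALSE]
  Rs <- vector("list", Tn)
  Ts <- matrix(0, Tn, 3)
  rmse <- numeric(Tn)
  conv <- logical(Tn)
  bt_prev <- rep(0, nm)
  for (t in seq_len(Tn)) {
    X <- frames[t, , ]
    bt <- bt_prev                       # warm start: frames change smoothly
    err_prev <- Inf
    for (it in seq_len(max_iter)) {
      S <- model$mean_pose + matrix(P %*% bt, nrow = K)
      tr <- kabsch(S, X)
      # back-transform the frame into shape space and project on the basis
      Xs <- (X - rep(tr$T, each = K)) %*% t(tr$R)
      if (nm) bt <- drop(t(P) %*% as.vector(Xs - model$mean_pose))
      Sh <- model$mean_pose + matrix(P %*% bt, nrow = K)
      err <- sum((Sh %*% tr$R + rep(tr$T, each = K) - X)^2)
      if (abs(err_prev - err) <= tol + 1e-10 * err) { conv[t] <- TRUE; break }
      err_prev <- err
    }
    if (nm) { b[t, ] <- bt; bt_prev <- bt }
    Rs[[t]] <- tr$R
    Ts[t, ] <- tr$T
    rmse[t] <- sqrt(err / (K * 3))
  }
  if (!all(conv)) {
    warning(sum(!conv), " frame(s) did not converge; best iterate returned")
  }
  structure(list(b = b, R = Rs, T = Ts, rmse = rmse, converged = conv),
            class = "pose_decomposition")
}

#' Reconstruct landmark frames from a pose decomposition
#' @param decomp a [decompose_pose()] result.
#' @param model the [fit_shape_model()] used.
#' @return T x K x 3 array.
#' @export
reconstruct_pose <- function(decomp, model) {
  K <- nrow(model$mean_pose)
  Tn <- nrow(decomp$T)
  nm <- length(model$eigenposes)
  P <- if (nm) vapply(model$eigenposes, as.vector, numeric(3 * K)) else
    matrix(0, 3 * K, 0)
  out <- array(0, dim = c(Tn, K, 3))
  for (t in seq_len(Tn)) {
    S <- model$mean_pose +
      matrix(P %*% decomp$b[t, , drop = TRUE], nrow = K)
    out[t, , ] <- S %*% decomp$R[[t]] + rep(decomp$T[t, ], each = K)
  }
  out
}
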