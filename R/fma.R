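#' Conformational ensemble with a scalar observable
#'
#' Pairs an ordered set of conformations over a fixed atom selection with
#' one observable value per conformation (e.g. per-frame overlap volume).
#'
#' @param coords Numeric matrix, one row per conformation and one column
#'   per Cartesian coordinate of the selection, or a list of
#'   [atom_set()]s sharing the same atoms (flattened row-wise as x,y,z per
#'   atom).
#' @param observable Numeric vector, one value per conformation.
#' @return List of class `ensemble` with `coords` and `observable`.
#' @export
ensemble <- function(coords, observable) {
  if (is.list(coords) && !is.matrix(coords)) {
    n_atoms <- vapply(coords, nrow, integer(1))
    if (length(unique(n_atoms)) != 1L)
      stop("all conformations must share the atom selection")
    coords <- do.call(rbind, lapply(coords, function(a) as.vector(t(.xyz(a)))))
  }
  coords <- as.matrix(coords)
  if (nrow(coords) != length(observable))
    stop("observable length must equal the number of conformations")
  structure(list(coords = coords, observable = as.numeric(observable)),
            class = "ensemble")
}

#' Functional mode analysis: the collective coordinate predicting an observable
#'
#' Identifies the single partial-least-squares latent mode: the unit-norm
#' linear combination of mean-centered coordinates that maximizes
#' covariance with the observable, fitted on the training conformations
#' only (`w` proportional to `t(X_c) %*% y_c`). The per-frame projection
#' onto the mode and its Pearson correlation with the observable on the
#' training and validation sets are reported; for an MD ensemble, half of
#' the replicas train the model and the other half validate it.
#'
#' @param ens An [ensemble()], or a coordinate matrix (then `observable`
#'   must be given).
#' @param train Indices (integer or logical) of the training
#'   conformations; all remaining conformations form the validation set.
#' @param observable Observable vector when `ens` is a bare matrix.
#' @return Object of class `functional_mode`: `mode` (unit-norm weights),
#'   `projection` (all frames, centered on the training mean),
#'   `train_cor`, `validation_cor` (NA when no validation frames), and
#'   `center`.
#' @export
functional_mode <- function(ens, train, observable = NULL) {
  if (!inherits(ens, "ensemble")) ens <- ensemble(ens, observable)
  X <- ens$coords
  y <- ens$observable
  n <- nrow(X)
  if (is.logical(train)) train <- which(train)
  train <- sort(unique(as.integer(train)))
  if (any(train < 1L | train > n)) stop("training indices out of range")
  if (length(train) < 2L) stop("need at least 2 training conformations")
  val <- setdiff(seq_len(n), train)
  if (sd(y[train]) == 0) stop("observable is constant on the training set")
  center <- colMeans(X[train, , drop = FALSE])
  Xc <- sweep(X, 2L, center)
  yc <- y[train] - mean(y[train])
  w <- as.vector(crossprod(Xc[train, , drop = FALSE], yc))
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("coordinates are constant on the training set")
  w <- w / nw
  proj <- as.vector(Xc %*% w)
  structure(list(
    mode = w,
    projection = proj,
    center = center,
    train = train,
    train_cor = cor(proj[train], y[train]),
    validation_cor = if (length(val) >= 3L) cor(proj[val], y[val]) else NA_real_
  ), class = "functional_mode")
}

#' Simulate a conformational ensemble moving along a planted mode
#'
#' Frames displace along a single unit-norm collective coordinate
#' (`mode`), with amplitude drawn from a standard normal scaled by
#' `amplitude`; independent Gaussian noise of standard deviation
#' `amplitude / snr` is added to every coordinate (`snr = Inf` for a
#' noiseless rank-1 ensemble). The observable is the displacement
#' amplitude itself, so the planted mode is the collective coordinate that
#' predicts it.
#'
#' @param n_frames Number of conformations.
#' @param n_coords Number of Cartesian coordinates.
#' @param mode Optional unit-norm planted mode (drawn at random when
#'   `NULL`).
#' @param amplitude Standard deviation of the displacement along the mode.
#' @param snr Ratio of displacement amplitude to per-coordinate noise.
#' @param seed Integer seed.
#' @return An [ensemble()] with attribute `"true_mode"`.
#' @export
simulate_mode_ensemble <- function(n_frames, n_coords, mode = NULL,
                                   amplitude = 3, snr = Inf, seed = 1L) {
  withr::with_seed(seed, {
    if (is.null(mode)) {
      mode <- rnorm(n_coords)
      mode <- mode / sqrt(sum(mode^2))
    }
    stopifnot(length(mode) == n_coords,
              abs(sum(mode^2) - 1) < 1e-8)
    t_amp <- rnorm(n_frames, 0, amplitude)
    X <- tcrossprod(t_amp, mode)
    if (is.finite(snr))
      X <- X + matrix(rnorm(n_frames * n_coords, 0, amplitude / snr),
                      n_frames)
    e <- ensemble(X, t_amp)
    attr(e, "true_mode") <- mode
    e
  })
}

#' @export
print.functional_mode <- function(x, ...) {
  cat("<functional_mode>", length(x$mode), "coordinates; train r =",
      round(x$train_cor, 3), "; validation r =",
      round(x$validation_cor, 3), "\n")
  invisible(x)
}
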