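#' Train a single-hidden-layer shape autoencoder
#'
#' Compresses rasterized cross-section shapes (binary images, flattened
#' row-major) to an m-dimensional code. Encoder and decoder are single
#' dense layers with logistic-sigmoid activations; the loss is mean squared
#' reconstruction error, minimized with Adam. Deterministic given the seed.
#'
#' @param images training shapes: list of `shape_image` matrices, a 3D
#'   array, or an n x p matrix of flattened images (p a perfect square).
#' @param m code (hidden) size; 4 by default.
#' @param seed integer seed.
#' @param epochs full-batch Adam steps.
#' @param lr learning rate.
#' @param min_images minimum corpus size (guards against meaningless fits).
#' @return object of class `shape_autoencoder`: weights `W1`, `b1`, `W2`,
#'   `b2`, the code size `m`, `grid_size`, `loss_history`, `seed`.
#' @export
train_autoencoder <- function(images, m = 4L, seed = 1L, epochs = 1200L,
                              lr = 1e-2, min_images = 100L) {
  X <- stack_images(images)
  if (nrow(X) < min_images) {
    abort(sprintf("need at least %d images to train the autoencoder", min_images))
  }
  p <- ncol(X)
  grid_size <- as.integer(round(sqrt(p)))
  if (grid_size^2 != p) abort("images must be square")

  with_seed(seed, {
    params <- list(
      W1 = init_mat(p, m, fan_in = p),
      b1 = matrix(0, 1, m),
      W2 = init_mat(m, p, fan_in = m),
      b2 = matrix(0, 1, p)
    )
  })
  state <- adam_init(params)
  n <- nrow(X)
  loss_hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    Z <- sigmoid(sweep(X %*% params$W1, 2, params$b1, "+"))
    Xhat <- sigmoid(sweep(Z %*% params$W2, 2, params$b2, "+"))
    E <- Xhat - X
    loss_hist[ep] <- mean(E^2)
    dXhat <- (2 / (n * p)) * E * Xhat * (1 - Xhat)
    gW2 <- crossprod(Z, dXhat)
    gb2 <- matrix(colSums(dXhat), 1)
    dZ <- (dXhat %*% t(params$W2)) * Z * (1 - Z)
    gW1 <- crossprod(X, dZ)
    gb1 <- matrix(colSums(dZ), 1)
    upd <- adam_step(params, list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2),
                     state, lr = lr)
    params <- upd$params
    state <- upd$state
  }
  structure(
    c(params, list(m = as.integer(m), grid_size = grid_size,
                   loss_history = loss_hist, seed = as.integer(seed),
                   epochs = as.integer(epochs))),
    class = "shape_autoencoder"
  )
}

stack_images <- function(images) {
  if (is.list(images)) {
    sizes <- vapply(images, length, integer(1))
    if (length(unique(sizes)) != 1) abort("inconsistent image sizes")
    X <- t(vapply(images, function(img) as.numeric(img), numeric(sizes[1])))
    return(X)
  }
  if (length(dim(images)) == 3) {
    return(t(apply(images, 3, as.numeric)))
  }
  as.matrix(images)
}

#' Encode shapes to m-dimensional codes
#'
#' @param object a trained `shape_autoencoder`.
#' @param image a single `shape_image` matrix or an n x p matrix of
#'   flattened images.
#' @return length-m numeric vector (single image) or n x m matrix.
#' @export
encode <- function(object, image) UseMethod("encode")

#' @export
encode.shape_autoencoder <- function(object, image) {
  single <- is.matrix(image) && nrow(image) == object$grid_size &&
    ncol(image) == object$grid_size
  X <- if (single) matrix(as.numeric(image), 1) else as.matrix(image)
  if (ncol(X) != object$grid_size^2) {
    abort(sprintf("image size mismatch: model expects %d x %d",
                  object$grid_size, object$grid_size))
  }
  Z <- sigmoid(sweep(X %*% object$W1, 2, object$b1, "+"))
  if (single) as.numeric(Z) else Z
}

#' Decode m-dimensional codes back to images
#'
#' @param object a trained `shape_autoencoder`.
#' @param code length-m vector or n x m matrix of codes.
#' @return reconstructed image matrix (values in \[0, 1\]); a
#'   `grid_size` x `grid_size` matrix for a single code.
#' @export
decode <- function(object, code) UseMethod("decode")

#' @export
decode.shape_autoencoder <- function(object, code) {
  single <- is.null(dim(code))
  Z <- if (single) matrix(code, 1) else as.matrix(code)
  if (ncol(Z) != object$m) abort(sprintf("code length must be %d", object$m))
  Xhat <- sigmoid(sweep(Z %*% object$W2, 2, object$b2, "+"))
  if (single) matrix(as.numeric(Xhat), object$grid_size, object$grid_size)
  else Xhat
}

#' @export
print.shape_autoencoder <- function(x, ...) {
  cat("<shape_autoencoder> input", x$grid_size, "x", x$grid_size,
      " code size", x$m, "\n")
  cat("  final reconstruction MSE:",
      format(tail(x$loss_history, 1), digits = 4),
      "after", x$epochs, "epochs\n")
  invisible(x)
}

#' @method tidy shape_autoencoder
#' @export
tidy.shape_autoencoder <- function(x, ...) {
  tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' @method glance shape_autoencoder
#' @export
glance.shape_autoencoder <- function(x, ...) {
  tibble(m = x$m, grid_size = x$grid_size, epochs = x$epochs,
         final_loss = tail(x$loss_history, 1),
         n_parameters = length(x$W1) + length(x$b1) + length(x$W2) + length(x$b2))
}
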