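#' Surrogate model configuration
#'
#' Hyperparameters of the bi-directional LSTM sequence regressor. The
#' published optimum used LSTM hidden size 900 and a fully connected layer
#' of 200 units; the desk-scale defaults (64 / 32) train in minutes on one
#' CPU and are the sizes used throughout the test benchmarks. All sizes are
#' configurable up to the published optimum.
#'
#' @param lstm_hidden LSTM hidden units per direction.
#' @param fc_size fully connected layer units.
#' @param m shape-code size expected in the features.
#' @param learning_rate initial Adam learning rate.
#' @param lr_decay multiplicative per-epoch learning-rate decay (1 = none).
#' @param epochs training epochs.
#' @param batch_size sequences per minibatch.
#' @param clip global gradient-norm clip.
#' @param seed integer seed.
#' @return list of class `surrogate_config`.
#' @export
surrogate_config <- function(lstm_hidden = 64L, fc_size = 32L, m = 4L,
                             learning_rate = 2e-3, lr_decay = 1,
                             epochs = 60L, batch_size = 64L, clip = 1.0,
                             seed = 1L) {
  sizes <- c(lstm_hidden = lstm_hidden, fc_size = fc_size, m = m,
             epochs = epochs, batch_size = batch_size)
  if (any(sizes < 1) || any(sizes != round(sizes))) {
    abort("all sizes must be positive integers")
  }
  if (lr_decay <= 0 || lr_decay > 1) abort("lr_decay must be in (0, 1]")
  structure(list(lstm_hidden = as.integer(lstm_hidden),
                 fc_size = as.integer(fc_size), m = as.integer(m),
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), clip = clip,
                 seed = as.integer(seed)),
            class = "surrogate_config")
}

surrogate_n_params <- function(config, n_features = 5L + config$m) {
  H <- config$lstm_hidden; f <- config$fc_size
  2 * (n_features * 4 * H + H * 4 * H + 4 * H) + 2 * H * f + f + f * 2 + 2
}

init_surrogate_params <- function(d, H, f) {
  b <- matrix(0, 1, 4 * H)
  b[1, (H + 1):(2 * H)] <- 1  # forget-gate bias
  list(
    fw_Wx = init_mat(d, 4 * H, fan_in = d), fw_Wh = init_mat(H, 4 * H, fan_in = H), fw_b = b,
    bw_Wx = init_mat(d, 4 * H, fan_in = d), bw_Wh = init_mat(H, 4 * H, fan_in = H), bw_b = b,
    W1 = init_mat(2 * H, f, fan_in = 2 * H), b1 = matrix(0, 1, f),
    W2 = init_mat(f, 2, fan_in = f), b2 = matrix(0, 1, 2)
  )
}

# Gather a (B, N, K) array along time with a per-sequence index matrix
# IDX (B x N). Used to reverse each sequence within its own length, so the
# backward-direction LSTM sees right-padded input too.
gather_time <- function(arr, gidx_flat) {
  d <- dim(arr)
  K <- d[3]
  off <- rep((seq_len(K) - 1L) * d[1] * d[2], each = length(gidx_flat))
  array(arr[rep(gidx_flat, K) + off], d)
}

reverse_index <- function(lengths, N) {
  B <- length(lengths)
  IDX <- matrix(rep(seq_len(N), each = B), B, N)
  for (j in seq_len(B)) {
    L <- lengths[j]
    IDX[j, seq_len(L)] <- rev(seq_len(L))
  }
  # flat index into the (B, N) leading block
  as.vector(matrix(seq_len(B), B, N) + (IDX - 1L) * B)
}

lstm_forward_dir <- function(Xarr, Wx, Wh, b, H) {
  d <- dim(Xarr)
  B <- d[1]; N <- d[2]
  Harr <- array(0, c(B, N, H))
  cache <- vector("list", N)
  h <- matrix(0, B, H)
  cs <- matrix(0, B, H)
  i1 <- 1:H; i2 <- (H + 1):(2 * H); i3 <- (2 * H + 1):(3 * H); i4 <- (3 * H + 1):(4 * H)
  bmat <- matrix(b, B, 4 * H, byrow = TRUE)
  for (t in seq_len(N)) {
    Xt <- matrix(Xarr[, t, ], B)
    Z <- Xt %*% Wx + h %*% Wh + bmat
    ig <- sigmoid(Z[, i1, drop = FALSE])
    fg <- sigmoid(Z[, i2, drop = FALSE])
    og <- sigmoid(Z[, i3, drop = FALSE])
    gg <- tanh(Z[, i4, drop = FALSE])
    c_prev <- cs
    cs <- fg * c_prev + ig * gg
    tc <- tanh(cs)
    h_prev <- h
    h <- og * tc
    Harr[, t, ] <- h
    cache[[t]] <- list(i = ig, f = fg, o = og, g = gg, tc = tc,
                       c_prev = c_prev, h_prev = h_prev, Xt = Xt)
  }
  list(H = Harr, cache = cache)
}

lstm_backward_dir <- function(cache, dHarr, Wx, Wh, H) {
  N <- length(cache)
  B <- nrow(cache[[1]]$i)
  gWx <- matrix(0, nrow(Wx), ncol(Wx))
  gWh <- matrix(0, H, 4 * H)
  gb <- matrix(0, 1, 4 * H)
  dh_carry <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  for (t in rev(seq_len(N))) {
    cc <- cache[[t]]
    dh <- matrix(dHarr[, t, ], B) + dh_carry
    do_ <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dc_next <- dc * cc$f
    dZ <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                do_ * cc$o * (1 - cc$o),
                dg * (1 - cc$g^2))
    gWx <- gWx + crossprod(cc$Xt, dZ)
    gWh <- gWh + crossprod(cc$h_prev, dZ)
    gb <- gb + colSums(dZ)
    dh_carry <- dZ %*% t(Wh)
  }
  list(Wx = gWx, Wh = gWh, b = gb)
}

# Forward pass + loss + gradients for one padded batch.
surrogate_batch_pass <- function(params, Xarr, Tarr, mask, lengths, H,
                                 want_grads = TRUE) {
  d <- dim(Xarr)
  B <- d[1]; N <- d[2]
  gidx <- reverse_index(lengths, N)
  Xrev <- gather_time(Xarr, gidx)

  fw <- lstm_forward_dir(Xarr, params$fw_Wx, params$fw_Wh, params$fw_b, H)
  bw <- lstm_forward_dir(Xrev, params$bw_Wx, params$bw_Wh, params$bw_b, H)
  Hb_aligned <- gather_time(bw$H, gidx)

  U <- cbind(matrix(fw$H, B * N), matrix(Hb_aligned, B * N))
  A1 <- tanh(sweep(U %*% params$W1, 2, params$b1, "+"))
  Y <- sweep(A1 %*% params$W2, 2, params$b2, "+")
  Tmat <- matrix(Tarr, B * N, 2)
  mvec <- as.numeric(mask)
  resid <- (Y - Tmat) * mvec
  n_valid <- 2 * sum(mvec)
  loss <- sum(resid^2) / n_valid
  if (!want_grads) return(list(loss = loss, Y = Y, B = B, N = N))

  dY <- 2 * resid / n_valid
  gW2 <- crossprod(A1, dY)
  gb2 <- matrix(colSums(dY), 1)
  dA1 <- (dY %*% t(params$W2)) * (1 - A1^2)
  gW1 <- crossprod(U, dA1)
  gb1 <- matrix(colSums(dA1), 1)
  dU <- dA1 %*% t(params$W1)
  dHf <- array(dU[, seq_len(H)], c(B, N, H))
  dHb_aligned <- array(dU[, H + seq_len(H)], c(B, N, H))
  dHb_rev <- gather_time(dHb_aligned, gidx)

  gf <- lstm_backward_dir(fw$cache, dHf, params$fw_Wx, params$fw_Wh, H)
  gb_ <- lstm_backward_dir(bw$cache, dHb_rev, params$bw_Wx, params$bw_Wh, H)
  grads <- list(fw_Wx = gf$Wx, fw_Wh = gf$Wh, fw_b = gf$b,
                bw_Wx = gb_$Wx, bw_Wh = gb_$Wh, bw_b = gb_$b,
                W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
  list(loss = loss, grads = grads)
}

pack_batch <- function(xs, ts = NULL) {
  lengths <- vapply(xs, nrow, integer(1))
  B <- length(xs); N <- max(lengths); dft <- ncol(xs[[1]])
  Xarr <- array(0, c(B, N, dft))
  Tarr <- array(0, c(B, N, 2))
  mask <- matrix(0, B, N)
  for (j in seq_len(B)) {
    L <- lengths[j]
    Xarr[j, seq_len(L), ] <- xs[[j]]
    if (!is.null(ts)) Tarr[j, seq_len(L), ] <- ts[[j]]
    mask[j, seq_len(L)] <- 1
  }
  list(X = Xarr, T = Tarr, mask = mask, lengths = lengths)
}

#' Train the bi-directional LSTM surrogate
#'
#' Fits the sequence model mapping per-point input features (coordinates,
#' area, area-normalized flow, shape code) to per-point pressure and WSS.
#' Inputs and both output channels are z-scored with statistics fitted on
#' the supplied (training) records; the loss is plain mean squared error
#' over both standardized channels and all valid points. Variable sequence
#' lengths are handled by right-padding with masked loss; the
#' backward-direction LSTM runs on per-sequence-reversed input so padding
#' never contaminates valid states. Optimized with Adam under global
#' gradient-norm clipping. Deterministic given the config seed.
#'
#' @param feature_set records with `features` and `targets` list columns
#'   (see [build_feature_set()]); training records only.
#' @param config a [surrogate_config()].
#' @return object of class `aorta_surrogate`: weights, `config`, `stats`
#'   (feature and target standardization), `loss_history`.
#' @export
train_surrogate <- function(feature_set, config = surrogate_config()) {
  if (nrow(feature_set) < 2) abort("need at least two training records")
  xs <- feature_set$features
  ts <- feature_set$targets
  d <- ncol(xs[[1]])
  if (d != 5L + config$m) {
    abort(sprintf("feature width %d does not match config (expected %d)", d, 5L + config$m))
  }
  fstats <- feature_stats(xs)
  tstats <- feature_stats(ts)
  xs <- scale_seqs(xs, fstats)
  ts <- scale_seqs(ts, tstats)
  H <- config$lstm_hidden

  with_seed(config$seed, {
    params <- init_surrogate_params(d, H, config$fc_size)
    state <- adam_init(params)
    n <- length(xs)
    loss_hist <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      lr_ep <- config$learning_rate * (config$lr_decay %||% 1)^(ep - 1)
      perm <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      ep_loss <- 0
      for (b0 in starts) {
        idx <- perm[b0:min(b0 + config$batch_size - 1L, n)]
        batch <- pack_batch(xs[idx], ts[idx])
        pass <- surrogate_batch_pass(params, batch$X, batch$T, batch$mask,
                                     batch$lengths, H)
        if (!is.finite(pass$loss)) {
          abort(paste0("training diverged (NaN loss) with config: hidden=",
                       config$lstm_hidden, " fc=", config$fc_size,
                       " lr=", config$learning_rate))
        }
        grads <- clip_grads(pass$grads, config$clip)
        upd <- adam_step(params, grads, state, lr = lr_ep)
        params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + pass$loss * length(idx)
      }
      loss_hist[ep] <- ep_loss / n
    }
  })
  structure(list(params = params, config = config,
                 stats = list(features = fstats, targets = tstats),
                 loss_history = loss_hist, n_train = length(xs)),
            class = "aorta_surrogate")
}

#' Predict pressure and WSS sequences from features
#'
#' @param object a trained `aorta_surrogate`.
#' @param features one raw feature matrix (n x (5+m)) or a list of them.
#' @param ... unused.
#' @return for a single matrix, a tibble (`index`, `pressure_mmHg`,
#'   `wss_Pa`) with attribute `source = "surrogate"`; for a list, a list of
#'   such tibbles. Output length always equals input length.
#' @export
predict.aorta_surrogate <- function(object, features, ...) {
  single <- !is.list(features)
  xs <- if (single) list(features) else features
  d_expect <- length(object$stats$features$mean)
  bad <- vapply(xs, function(x) ncol(x) != d_expect, logical(1))
  if (any(bad)) abort(sprintf("feature width mismatch: model expects %d columns", d_expect))
  xs <- scale_seqs(xs, object$stats$features)
  H <- object$config$lstm_hidden
  out <- vector("list", length(xs))
  # batch equal-length groups to keep prediction fast
  lens <- vapply(xs, nrow, integer(1))
  for (L in unique(lens)) {
    sel <- which(lens == L)
    batch <- pack_batch(xs[sel])
    pass <- surrogate_batch_pass(object$params, batch$X, batch$T, batch$mask,
                                 batch$lengths, H, want_grads = FALSE)
    Yarr <- array(pass$Y, c(length(sel), L, 2))
    for (k in seq_along(sel)) {
      Yk <- matrix(Yarr[k, , ], L)
      Yk <- sweep(sweep(Yk, 2, object$stats$targets$sd, "*"), 2,
                  object$stats$targets$mean, "+")
      prof <- tibble(index = seq_len(L), pressure_mmHg = Yk[, 1], wss_Pa = Yk[, 2])
      attr(prof, "source") <- "surrogate"
      out[[sel[k]]] <- prof
    }
  }
  if (single) out[[1]] else out
}

#' Cross-validate a surrogate configuration
#'
#' Rotates over the non-test subsets of a [split_datasets()] split: trains
#' on k-1 subsets and validates on the held-out one. Geometry grouping
#' guarantees no geometry appears in both train and validation of a fold.
#'
#' @param feature_set records with features/targets (all subsets).
#' @param split a `dataset_split`.
#' @param config a [surrogate_config()].
#' @return tibble with one row per fold: `fold`, `n_train`, `n_val`,
#'   `rmse_p` (mmHg), `rmse_wss` (Pa), `rmse_combined` (standardized);
#'   attribute `mean_rmse` (mean of `rmse_combined`).
#' @export
cross_validate <- function(feature_set, split, config = surrogate_config()) {
  fs <- dplyr::left_join(feature_set, as_tibble(split), by = "geometry_id")
  test_idx <- attr(split, "test_index")
  folds <- setdiff(sort(unique(fs$subset)), test_idx)
  if (length(folds) < 3) abort("need at least three non-test subsets")
  rows <- purrr::map(seq_along(folds), function(k) {
    val_subset <- folds[k]
    train <- fs[!(fs$subset %in% c(val_subset, test_idx)), ]
    val <- fs[fs$subset == val_subset, ]
    if (length(intersect(train$geometry_id, val$geometry_id)) > 0) {
      abort("internal error: geometry overlap between train and validation")
    }
    cfg <- config
    cfg$seed <- derive_seed(config$seed, "cv-fold", k)
    model <- train_surrogate(train, cfg)
    preds <- predict(model, val$features)
    err_p <- unlist(purrr::map2(preds, val$targets,
                                function(p, t) p$pressure_mmHg - t[, "pressure"]))
    err_w <- unlist(purrr::map2(preds, val$targets,
                                function(p, t) p$wss_Pa - t[, "wss"]))
    tsd <- model$stats$targets$sd
    tibble(fold = k, subset = val_subset, n_train = nrow(train), n_val = nrow(val),
           rmse_p = rms(err_p), rmse_wss = rms(err_w),
           rmse_combined = sqrt((mean((err_p / tsd[1])^2) +
                                   mean((err_w / tsd[2])^2)) / 2))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "mean_rmse") <- mean(out$rmse_combined)
  out
}

#' Grid-search surrogate hyperparameters
#'
#' Evaluates every configuration by cross-validation and returns the one
#' with the lowest mean validation RMSE; ties break toward the smaller
#' model (fewer parameters), then config order. The searched dimensions can
#' include AE input size, AE hidden size, LSTM hidden size and the fully
#' connected layer size.
#'
#' @param feature_set records with features/targets.
#' @param split a `dataset_split`.
#' @param grid list of [surrogate_config()] objects.
#' @return list with `best_config`, `best_index`, and `results` (one row
#'   per config: sizes, n_parameters, mean cross-validation RMSE).
#' @export
grid_search <- function(feature_set, split, grid) {
  if (length(grid) == 0) abort("empty hyperparameter grid")
  rows <- purrr::imap(grid, function(cfg, i) {
    cv <- cross_validate(feature_set, split, cfg)
    tibble(config = i, lstm_hidden = cfg$lstm_hidden, fc_size = cfg$fc_size,
           m = cfg$m, n_parameters = surrogate_n_params(cfg),
           mean_rmse = attr(cv, "mean_rmse"))
  })
  results <- dplyr::bind_rows(rows)
  ord <- order(results$mean_rmse, results$n_parameters, results$config)
  best <- results$config[ord[1]]
  list(best_config = grid[[best]], best_index = best, results = results)
}

#' @export
print.aorta_surrogate <- function(x, ...) {
  cat("<aorta_surrogate> bi-LSTM hidden", x$config$lstm_hidden,
      "/ FC", x$config$fc_size, "\n")
  cat("  trained on", x$n_train, "sequences,", x$config$epochs,
      "epochs; final loss", format(tail(x$loss_history, 1), digits = 4), "\n")
  invisible(x)
}

#' @method tidy aorta_surrogate
#' @export
tidy.aorta_surrogate <- function(x, ...) {
  tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' @method glance aorta_surrogate
#' @export
glance.aorta_surrogate <- function(x, ...) {
  tibble(lstm_hidden = x$config$lstm_hidden, fc_size = x$config$fc_size,
         m = x$config$m, epochs = x$config$epochs, n_train = x$n_train,
         n_parameters = surrogate_n_params(x$config),
         final_loss = tail(x$loss_history, 1))
}
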