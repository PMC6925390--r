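# Gated recurrent unit (GRU) sequence classifier, implemented as batched
# matrix operations with full backpropagation through time and Adam updates.
# The network: one GRU layer over the token axis (zero rows masked as
# padding, the hidden state carried through them unchanged), dropout on the
# final hidden state, and a single sigmoid output trained on binary
# cross-entropy.

sigmoid_ <- function(x) 1 / (1 + exp(pmin(pmax(-x, -30), 30)))

gru_init <- function(xi, H, seed) {
  with_seed(seed, {
    gl <- function(nin, nout) {
      lim <- sqrt(6 / (nin + nout))
      matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
    }
    list(Wz = gl(xi, H), Wr = gl(xi, H), Wh = gl(xi, H),
         Uz = gl(H, H), Ur = gl(H, H), Uh = gl(H, H),
         bz = numeric(H), br = numeric(H), bh = numeric(H),
         wo = gl(H, 1L)[, 1L], bo = 0)
  })
}

# Feature adapter: optional min-max scaling of the trailing post features
# (polarity -> [0,1], hour/23) and optional channel masking, applied only at
# real (non-padding) token positions so the padding contract is preserved.
gru_adapt <- function(values, dim_, scale_features = TRUE,
                      features = c("embedding", "sentiment", "hour")) {
  mask <- apply(values != 0, c(1L, 2L), any) * 1  # n x kappa
  if (scale_features) {
    pol <- values[, , dim_ + 1L, drop = FALSE]
    values[, , dim_ + 1L] <- ((pol + 1) / 2) * array(mask, dim(pol))
    hr <- values[, , dim_ + 3L, drop = FALSE]
    values[, , dim_ + 3L] <- (hr / 23) * array(mask, dim(hr))
  }
  if (!("embedding" %in% features)) values[, , seq_len(dim_)] <- 0
  if (!("sentiment" %in% features)) values[, , dim_ + c(1L, 2L)] <- 0
  if (!("hour" %in% features)) values[, , dim_ + 3L] <- 0
  list(values = values, mask = mask)
}

gru_forward <- function(par, X, mask, keep = NULL) {
  B <- dim(X)[1L]; Tn <- dim(X)[2L]; H <- length(par$bz)
  Hs <- vector("list", Tn); Zs <- vector("list", Tn)
  Rs <- vector("list", Tn); Cs <- vector("list", Tn)
  h <- matrix(0, B, H)
  for (t in seq_len(Tn)) {
    Xt <- matrix(X[, t, ], B)
    m <- mask[, t]
    Z <- sigmoid_(Xt %*% par$Wz + h %*% par$Uz +
                    matrix(par$bz, B, H, byrow = TRUE))
    R <- sigmoid_(Xt %*% par$Wr + h %*% par$Ur +
                    matrix(par$br, B, H, byrow = TRUE))
    C <- tanh(Xt %*% par$Wh + (R * h) %*% par$Uh +
                matrix(par$bh, B, H, byrow = TRUE))
    hnew <- (1 - Z) * h + Z * C
    hh <- m * hnew + (1 - m) * h
    Zs[[t]] <- Z; Rs[[t]] <- R; Cs[[t]] <- C; Hs[[t]] <- hh
    h <- hh
  }
  hfin <- h
  if (!is.null(keep)) hfin <- hfin * keep
  s <- drop(hfin %*% par$wo) + par$bo
  list(p = sigmoid_(s), hfin = hfin, Hs = Hs, Zs = Zs, Rs = Rs, Cs = Cs)
}

gru_backward <- function(par, X, mask, y, fw, keep = NULL) {
  B <- dim(X)[1L]; Tn <- dim(X)[2L]; H <- length(par$bz)
  g <- lapply(par, function(p) if (is.matrix(p)) p * 0 else p * 0)
  ds <- (fw$p - y) / B
  g$wo <- drop(crossprod(fw$hfin, ds))
  g$bo <- sum(ds)
  dh <- outer(ds, par$wo)
  if (!is.null(keep)) dh <- dh * keep
  for (t in rev(seq_len(Tn))) {
    hprev <- if (t == 1L) matrix(0, B, H) else fw$Hs[[t - 1L]]
    m <- mask[, t]
    Z <- fw$Zs[[t]]; R <- fw$Rs[[t]]; C <- fw$Cs[[t]]
    dnew <- dh * m
    dhp <- dh * (1 - m)
    dZ <- dnew * (C - hprev)
    dC <- dnew * Z
    dhp <- dhp + dnew * (1 - Z)
    dah <- dC * (1 - C^2)
    Xt <- matrix(X[, t, ], B)
    g$Wh <- g$Wh + crossprod(Xt, dah)
    g$Uh <- g$Uh + crossprod(R * hprev, dah)
    g$bh <- g$bh + colSums(dah)
    dRH <- dah %*% t(par$Uh)
    dR <- dRH * hprev
    dhp <- dhp + dRH * R
    dar <- dR * R * (1 - R)
    g$Wr <- g$Wr + crossprod(Xt, dar)
    g$Ur <- g$Ur + crossprod(hprev, dar)
    g$br <- g$br + colSums(dar)
    dhp <- dhp + dar %*% t(par$Ur)
    daz <- dZ * Z * (1 - Z)
    g$Wz <- g$Wz + crossprod(Xt, daz)
    g$Uz <- g$Uz + crossprod(hprev, daz)
    g$bz <- g$bz + colSums(daz)
    dhp <- dhp + daz %*% t(par$Uz)
    dh <- dhp
  }
  g
}

adam_step <- function(par, g, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(par)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^t)
    vhat <- st$v[[nm]] / (1 - beta2^t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, st = st)
}

#' Training configuration for the GRU classifier
#'
#' @param hidden_units GRU hidden-state size.
#' @param dropout dropout rate on the dense layer's input (the final hidden
#'   state); 0.5 for generalization on small data.
#' @param test_fraction held-out test share of the whole dataset (0.10).
#' @param val_fraction_of_trainval validation share of the remaining 90%
#'   (0.10), giving an overall 81/9/10 split.
#' @param epochs,batch_size,learning_rate gradient-descent budget (Adam).
#' @param seed RNG seed for splitting, initialisation, shuffling and dropout.
#' @param scale_features min-max scale the trailing post features inside the
#'   model's input adapter (polarity to `[0,1]`, hour/23) so the raw 0-23
#'   hour does not dominate the embedding channels; the stored tensor is
#'   unchanged.
#' @param features which input channels the model consumes:
#'   `"embedding"`, `"sentiment"`, `"hour"` (default all).  Excluded
#'   channels are zeroed in the adapter; useful for ablations such as
#'   text-only evaluation.
#' @return a `train_config` list.
#' @export
train_config <- function(hidden_units = 64L, dropout = 0.5,
                         test_fraction = 0.10, val_fraction_of_trainval = 0.10,
                         epochs = 20L, batch_size = 64L, learning_rate = 1e-3,
                         seed = 1L, scale_features = TRUE,
                         features = c("embedding", "sentiment", "hour")) {
  stopifnot(dropout > 0, dropout < 1, test_fraction > 0, test_fraction < 1,
            val_fraction_of_trainval > 0, val_fraction_of_trainval < 1,
            hidden_units >= 1, epochs >= 1, batch_size >= 1,
            learning_rate > 0, all(features %in% c("embedding", "sentiment", "hour")))
  structure(list(hidden_units = as.integer(hidden_units), dropout = dropout,
                 test_fraction = test_fraction,
                 val_fraction_of_trainval = val_fraction_of_trainval,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 scale_features = scale_features, features = features),
            class = "train_config")
}

#' Train the GRU classifier
#'
#' Single GRU layer over the token sequence (all-zero padding rows masked:
#' the hidden state passes through them unchanged), dropout on the final
#' hidden state, one sigmoid output, binary cross-entropy loss minimised by
#' Adam.  After each epoch the validation AUC is computed and the weights
#' from the best-validation epoch are kept.  Training diverging to NaN loss
#' is an error naming the epoch.
#'
#' @param train,val `feature_tensor`s, e.g. from [split_dataset()].
#' @param config a [train_config()].
#' @param quiet suppress the per-epoch training curve messages.
#' @return a `gru_model` (weights + adapter settings + training history).
#' @export
train_model <- function(train, val, config = train_config(), quiet = FALSE) {
  ad_tr <- gru_adapt(train$values, train$dim, config$scale_features,
                     config$features)
  ad_va <- gru_adapt(val$values, val$dim, config$scale_features,
                     config$features)
  xi <- dim(train$values)[3L]
  H <- config$hidden_units
  par <- gru_init(xi, H, config$seed)
  st <- list(m = lapply(par, function(p) p * 0),
             v = lapply(par, function(p) p * 0))
  n <- length(train$labels)
  y <- train$labels
  best <- list(auc = -Inf, par = par, epoch = 0L)
  history <- data.frame(epoch = integer(), loss = numeric(), val_auc = numeric())
  step <- 0L
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      tot_loss <- 0
      for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        Xb <- ad_tr$values[b, , , drop = FALSE]
        Mb <- ad_tr$mask[b, , drop = FALSE]
        keep <- matrix(stats::rbinom(length(b) * H, 1L, 1 - config$dropout),
                       length(b), H) / (1 - config$dropout)
        fw <- gru_forward(par, Xb, Mb, keep)
        eps <- 1e-12
        loss <- -mean(y[b] * log(fw$p + eps) + (1 - y[b]) * log(1 - fw$p + eps))
        if (!is.finite(loss))
          stop("training diverged (non-finite loss) at epoch ", ep)
        tot_loss <- tot_loss + loss * length(b)
        g <- gru_backward(par, Xb, Mb, y[b], fw, keep)
        step <- step + 1L
        upd <- adam_step(par, g, st, config$learning_rate, step)
        par <- upd$par; st <- upd$st
      }
      val_scores <- gru_forward(par, ad_va$values, ad_va$mask)$p
      val_auc <- auc_score(val_scores, val$labels)
      history <- rbind(history, data.frame(epoch = ep, loss = tot_loss / n,
                                           val_auc = val_auc))
      if (!quiet)
        message(sprintf("epoch %2d  loss %.4f  val AUC %.3f", ep,
                        tot_loss / n, val_auc))
      if (val_auc > best$auc) best <- list(auc = val_auc, par = par, epoch = ep)
    }
  })
  structure(list(par = best$par, config = config, history = history,
                 best_epoch = best$epoch, best_val_auc = best$auc,
                 dim = train$dim, kappa = train$kappa),
            class = "gru_model")
}

#' @export
print.gru_model <- function(x, ...) {
  cat(sprintf("GRU classifier: %d hidden units, best epoch %d (val AUC %.3f)\n",
              x$config$hidden_units, x$best_epoch, x$best_val_auc))
  invisible(x)
}

#' Predict sleep-deprivation scores
#' @param object a `gru_model`.
#' @param newdata a `feature_tensor`.
#' @param ... unused.
#' @return numeric scores in `(0, 1)` (probability of `sleep_deprived`).
#' @export
predict.gru_model <- function(object, newdata, ...) {
  ad <- gru_adapt(newdata$values, newdata$dim, object$config$scale_features,
                  object$config$features)
  as.numeric(gru_forward(object$par, ad$values, ad$mask)$p)
}
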