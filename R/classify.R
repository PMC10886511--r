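# TFI classification (compact neural network, trained from scratch) and the
# ITI / accuracy ANOVAs.

#' Classifier configuration
#'
#' A compact two-layer network trained from scratch on mean-pooled TFI
#' pixels: stratified 70/30 train/validation split, augmentation of the
#' training images only (random mirror about the vertical axis and random
#' translations up to 30 px both ways), minibatch Adam for 10 epochs, and
#' the reported accuracy is the mean of the validation accuracy at the final
#' 10 minibatch iterations.
#'
#' @param input_size TFI side length (pixels), 227.
#' @param pool_to side length after mean pooling (features are
#'   `pool_to^2`), default 16.
#' @param hidden hidden layer width.
#' @param epochs training epochs, default 10.
#' @param split training fraction, default 0.7.
#' @param lr Adam learning rate.
#' @param batch minibatch size.
#' @param weight_decay L2 penalty.
#' @param translate_px maximum augmentation translation (pixels at input
#'   scale), default 30.
#' @param n_augment augmented copies added per training image.
#' @param final_iters number of final iterations averaged for the report.
#' @param seed training seed (split, augmentation, initialization).
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(input_size = 227, pool_to = 16, hidden = 8,
                              epochs = 10, split = 0.7, lr = 5e-3,
                              batch = 16, weight_decay = 1e-2,
                              translate_px = 30, n_augment = 1,
                              final_iters = 10, seed = 1) {
  stopifnot(epochs >= 1, split > 0, split < 1, hidden >= 2)
  structure(as.list(environment()), class = "classifier_config")
}

# Mean-pool a square image matrix down to pool_to x pool_to.
.pool_features <- function(m, pool_to) {
  n <- nrow(m)
  f <- n %/% pool_to
  keep <- f * pool_to
  off <- (n - keep) %/% 2
  m <- m[(off + 1):(off + keep), (off + 1):(off + keep)]
  # block mean via row/col aggregation
  rowg <- rep(seq_len(pool_to), each = f)
  m2 <- rowsum(m, rowg) / f
  t(rowsum(t(m2), rowg) / f)
}

# Random flip/translate augmentation in the input pixel space.
.augment_image <- function(m, translate_px) {
  if (runif(1) < 0.5) m <- m[, rev(seq_len(ncol(m)))]  # mirror about vertical axis
  dx <- sample.int(2L * translate_px + 1L, 1L) - translate_px - 1L
  dy <- sample.int(2L * translate_px + 1L, 1L) - translate_px - 1L
  out <- matrix(0, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m)) - dy
  src_c <- seq_len(ncol(m)) - dx
  ok_r <- src_r >= 1 & src_r <= nrow(m)
  ok_c <- src_c >= 1 & src_c <= ncol(m)
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# Two-layer network with tanh hidden units, trained with minibatch Adam on
# the logistic loss. Returns the validation-accuracy trace per iteration.
.mlp_train <- function(X, y, Xv, yv, cfg) {
  n_in <- ncol(X)
  h <- cfg$hidden
  W1 <- matrix(rnorm(n_in * h, 0, sqrt(1 / n_in)), n_in, h)
  b1 <- numeric(h)
  W2 <- rnorm(h, 0, sqrt(1 / h))
  b2 <- 0
  ms <- list(W1 = 0 * W1, b1 = 0 * b1, W2 = 0 * W2, b2 = 0)
  vs <- ms
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  it <- 0
  val_acc <- function() {
    H <- tanh(sweep(Xv %*% W1, 2, b1, `+`))
    p <- 1 / (1 + exp(-(as.numeric(H %*% W2) + b2)))
    mean((p > 0.5) == (yv == 1)) * 100
  }
  acc_trace <- numeric(0)
  n <- nrow(X)
  for (ep in seq_len(cfg$epochs)) {
    idx <- sample.int(n)
    starts <- seq(1, n, by = cfg$batch)
    for (s in starts) {
      b <- idx[s:min(s + cfg$batch - 1, n)]
      Xb <- X[b, , drop = FALSE]
      yb <- y[b]
      A <- sweep(Xb %*% W1, 2, b1, `+`)
      H <- tanh(A)
      z <- as.numeric(H %*% W2) + b2
      p <- 1 / (1 + exp(-z))
      dz <- (p - yb) / length(b)
      gW2 <- as.numeric(t(H) %*% dz) + cfg$weight_decay * W2
      gb2 <- sum(dz)
      dH <- outer(dz, W2) * (1 - H^2)
      gW1 <- t(Xb) %*% dH + cfg$weight_decay * W1
      gb1 <- colSums(dH)
      it <- it + 1
      upd <- function(par, g, mname) {
        ms[[mname]] <<- beta1 * ms[[mname]] + (1 - beta1) * g
        vs[[mname]] <<- beta2 * vs[[mname]] + (1 - beta2) * g^2
        mhat <- ms[[mname]] / (1 - beta1^it)
        vhat <- vs[[mname]] / (1 - beta2^it)
        par - cfg$lr * mhat / (sqrt(vhat) + eps)
      }
      W1 <- upd(W1, gW1, "W1"); b1 <- upd(b1, gb1, "b1")
      W2 <- upd(W2, gW2, "W2"); b2 <- upd(b2, gb2, "b2")
      acc_trace <- c(acc_trace, val_acc())
    }
  }
  acc_trace
}

#' Train and validate the TFI classifier
#'
#' Classifies SA vs RA neurotactile-event TFIs: stratified 70/30 split,
#' flip/translate augmentation of the training set only, 10 training epochs,
#' and the reported accuracy is the mean (and SD) of the validation accuracy
#' over the final 10 iterations.
#'
#' @param tfis list of `tfi_image` objects with `encoding` labels (exactly
#'   two classes required).
#' @param config a [classifier_config()].
#' @return object of class `classification_result`: `accuracy_mean`,
#'   `accuracy_sd` (percent), `n_train`, `n_val`, `classes`, `history`
#'   (per-iteration validation accuracy), `seed`.
#' @export
train_and_validate <- function(tfis, config = classifier_config()) {
  labels <- vapply(tfis, function(t) as.character(t$encoding), character(1))
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stop("need two classes of TFIs; got only ", classes, call. = FALSE)
  if (length(classes) > 2)
    stop("binary classification only", call. = FALSE)
  set.seed(config$seed)
  y <- as.numeric(labels == classes[2])

  # stratified split
  tr_idx <- unlist(lapply(classes, function(cl) {
    i <- which(labels == cl)
    sample(i, round(config$split * length(i)))
  }))
  va_idx <- setdiff(seq_along(tfis), tr_idx)
  if (length(va_idx) < 1 || length(tr_idx) < 2)
    stop("too few images to split", call. = FALSE)

  feat <- function(m) as.numeric(.pool_features(m, config$pool_to))
  Xtr <- do.call(rbind, lapply(tr_idx, function(i) feat(tfis[[i]]$values)))
  ytr <- y[tr_idx]
  if (config$n_augment > 0) {
    for (rep_k in seq_len(config$n_augment)) {
      Xa <- do.call(rbind, lapply(tr_idx, function(i)
        feat(.augment_image(tfis[[i]]$values, config$translate_px))))
      Xtr <- rbind(Xtr, Xa)
      ytr <- c(ytr, y[tr_idx])
    }
  }
  Xva <- do.call(rbind, lapply(va_idx, function(i) feat(tfis[[i]]$values)))
  yva <- y[va_idx]

  mu <- colMeans(Xtr)
  sdv <- pmax(apply(Xtr, 2, sd), 1e-6)
  Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, `/`)
  Xva <- sweep(sweep(Xva, 2, mu), 2, sdv, `/`)

  hist <- .mlp_train(Xtr, ytr, Xva, yva, config)
  k <- min(config$final_iters, length(hist))
  final <- tail(hist, k)
  structure(list(accuracy_mean = mean(final), accuracy_sd = sd(final),
                 n_train = length(ytr), n_val = length(yva),
                 classes = classes, history = hist, seed = config$seed),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(
    "<classification_result> %s vs %s: %.2f%% +- %.2f%% (n_train %d, n_val %d)\n",
    x$classes[1], x$classes[2], x$accuracy_mean, x$accuracy_sd,
    x$n_train, x$n_val))
  invisible(x)
}

#' Unbalanced one-way ANOVA of RA vs SA inter-tap intervals
#'
#' Fixed-effects one-way ANOVA tolerating unequal group sizes, as used to
#' test whether the encoding method changed the tapping behavior.
#'
#' @param ra_itis ITIs (s) from the RA sessions.
#' @param sa_itis ITIs (s) from the SA sessions.
#' @param alpha significance level (default 0.05).
#' @return object of class `iti_stats`: group summaries, `F`, `p_value`,
#'   `significant`.
#' @export
compare_iti_anova <- function(ra_itis, sa_itis, alpha = 0.05) {
  stopifnot(length(ra_itis) >= 2, length(sa_itis) >= 2)
  df <- data.frame(iti = c(ra_itis, sa_itis),
                   group = factor(rep(c("RA", "SA"),
                                      c(length(ra_itis), length(sa_itis)))))
  if (stats::var(df$iti) == 0)
    stop("degenerate ITI data: zero total variance, F undefined",
         call. = FALSE)
  tab <- anova(lm(iti ~ group, data = df))
  structure(list(
    n_ra = length(ra_itis), n_sa = length(sa_itis),
    mean_ra = mean(ra_itis), mean_sa = mean(sa_itis),
    F = tab$`F value`[1], p_value = tab$`Pr(>F)`[1],
    significant = tab$`Pr(>F)`[1] < alpha, alpha = alpha),
    class = "iti_stats")
}

#' @export
print.iti_stats <- function(x, ...) {
  cat(sprintf(
    "<iti_stats> RA %.2f s (n=%d) vs SA %.2f s (n=%d): F = %.2f, p = %.3g%s\n",
    x$mean_ra, x$n_ra, x$mean_sa, x$n_sa, x$F, x$p_value,
    if (x$significant) " *" else ""))
  invisible(x)
}

#' One-way ANOVA of classification accuracies across embodiments
#'
#' Tests whether the classification accuracies differ between embodiment
#' configurations (e.g. CL vs ES vs AD replicate accuracies on one DIV).
#'
#' @param accuracies named list: one numeric vector of replicate accuracies
#'   per embodiment mode (each of length >= 2).
#' @return list with `F`, `p_value` and the per-mode means.
#' @export
compare_accuracy_anova <- function(accuracies) {
  stopifnot(length(accuracies) >= 2,
            all(vapply(accuracies, length, integer(1)) >= 2))
  df <- data.frame(
    acc = unlist(accuracies, use.names = FALSE),
    mode = factor(rep(names(accuracies),
                      vapply(accuracies, length, integer(1)))))
  if (stats::var(df$acc) == 0)
    stop("degenerate accuracies: zero total variance, F undefined",
         call. = FALSE)
  tab <- anova(lm(acc ~ mode, data = df))
  list(F = tab$`F value`[1], p_value = tab$`Pr(>F)`[1],
       means = vapply(accuracies, mean, numeric(1)))
}
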