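#' Graph specification of the sensor-array GCN
#'
#' Adjacency over 16 sensor nodes plus one reward node: every connection
#' between distinct sensor nodes is 1, and each sensor node carries a
#' self-loop of weight `self_weight` (default `n_sensors / 2`). On a
#' complete sensor graph a plain all-ones convolution returns the same
#' neighbor sum for every node, erasing node identity and degenerating the
#' node-level contrast analysis; weighting the self-loop against the
#' neighbor sum preserves each sensor's own signal through the layers. The
#' reward node's edges carry the supervision signal (+1 for rewarded
#' samples, -1 for habituated ones, 0 at test time).
#'
#' @param n_sensors number of sensor nodes.
#' @param self_weight self-loop weight on the sensor nodes.
#' @return `(n_sensors + 1)` square adjacency matrix with zeroed reward
#'   edges.
#' @export
gcn_graph <- function(n_sensors = 16L, self_weight = n_sensors / 2) {
  n <- n_sensors + 1L
  A <- matrix(0, n, n)
  A[seq_len(n_sensors), seq_len(n_sensors)] <- 1
  diag(A)[seq_len(n_sensors)] <- self_weight
  A
}

#' Set the reward-node edges of the graph
#'
#' During training the reward node is wired to every sensor node with +1
#' (rewarded sample) or -1 (habituated sample); at test time the edges are
#' 0 (no supervision signal).
#'
#' @param A adjacency matrix from [gcn_graph()].
#' @param label `"rewarded"`, `"habituated"` or `"test"`.
#' @return The adjacency with updated (symmetric) reward edges.
#' @export
set_reward_edges <- function(A, label = c("rewarded", "habituated", "test")) {
  label <- match.arg(label)
  n <- nrow(A)
  v <- switch(label, rewarded = 1, habituated = -1, test = 0)
  A[n, seq_len(n - 1)] <- v
  A[seq_len(n - 1), n] <- v
  A
}

#' One graph-convolution layer
#'
#' `H_out = h(A %*% H %*% W)`, the propagation rule of the model (raw
#' adjacency, no degree normalization; a normalized variant can be obtained
#' by passing a normalized `A`).
#'
#' @param H node-by-feature input matrix.
#' @param A adjacency matrix.
#' @param W feature weight matrix.
#' @param h nonlinearity (default ReLU); use `identity` for a linear layer.
#' @return Node-by-feature output matrix.
#' @export
gcn_layer <- function(H, A, W, h = function(x) pmax(x, 0)) {
  if (ncol(A) != nrow(H) || ncol(H) != nrow(W)) stop("shape mismatch")
  h(A %*% H %*% W)
}

# features of one dataset row -> sensor x feature matrix (+ zero reward row)
row_to_X <- function(row, n_sensors, feat_names) {
  X <- matrix(0, n_sensors + 1L, length(feat_names))
  for (j in seq_along(feat_names))
    X[seq_len(n_sensors), j] <-
      as.numeric(row[paste0("s", seq_len(n_sensors), "_", feat_names[j])])
  X
}

gcn_forward <- function(W, X, A) {
  relu <- function(x) pmax(x, 0)
  pre1 <- A %*% X %*% W$W0
  H1 <- relu(pre1)
  pre2 <- A %*% H1 %*% W$W1
  H2 <- relu(pre2)
  # the classifier head reads the sensor-node rows; the reward node is a
  # conditioning input, not data
  n_sens <- nrow(H2) - 1L
  z <- as.vector(H2[seq_len(n_sens), , drop = FALSE])
  pre3 <- drop(z %*% W$W2) + W$b2
  hfc <- relu(pre3)
  logits <- drop(hfc %*% W$W3) + W$b3
  pm <- exp(logits - max(logits))
  list(pre1 = pre1, H1 = H1, pre2 = pre2, H2 = H2, z = z, pre3 = pre3,
       hfc = hfc, logits = logits, prob = pm / sum(pm))
}

gcn_backward <- function(W, X, A, fwd, y_idx) {
  dlogits <- fwd$prob
  dlogits[y_idx] <- dlogits[y_idx] - 1
  gW3 <- outer(fwd$hfc, dlogits)
  gb3 <- dlogits
  dh <- drop(W$W3 %*% dlogits) * (fwd$pre3 > 0)
  gW2 <- outer(fwd$z, dh)
  gb2 <- dh
  dz <- drop(W$W2 %*% dh)
  n_sens <- nrow(fwd$H2) - 1L
  dH2 <- matrix(0, nrow(fwd$H2), ncol(fwd$H2))
  dH2[seq_len(n_sens), ] <- matrix(dz, n_sens, ncol(fwd$H2))
  dpre2 <- dH2 * (fwd$pre2 > 0)
  gW1 <- t(A %*% fwd$H1) %*% dpre2
  dH1 <- t(A) %*% dpre2 %*% t(W$W1)
  dpre1 <- dH1 * (fwd$pre1 > 0)
  gW0 <- t(A %*% X) %*% dpre1
  list(W0 = gW0, W1 = gW1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

#' Train the GCN analog of the antennal lobe
#'
#' Two graph-convolution layers (8 input features per sensor node to `d1`,
#' then to 4 abstract features) followed by two fully connected layers
#' classifying a sample as rewarded vs habituated. During training the
#' reward node's edges encode the sample's label (+1/-1); at test time they
#' are 0. Features are z-scored per column using training-set statistics.
#' Cross-entropy loss is minimized with a hand-rolled Adam optimizer
#' (per-sample updates); gradients are exact backpropagation through the
#' propagation rule of [gcn_layer()].
#'
#' @param data dataset from [synthetic_sensor_dataset()].
#' @param d1 width of the first convolution layer output.
#' @param fc_width hidden width of the classifier head.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param seed seed (initialization, split, sample order).
#' @param test_frac held-out fraction (stratified by odor).
#' @param shuffle_labels permute training labels (chance-level control)?
#' @return Object of class `gcn_model`: weights, train/test indices,
#'   held-out `accuracy`, final `loss`, normalization constants.
#' @export
train_gcn <- function(data, d1 = 8L, fc_width = 64L, lr = 0.01,
                      epochs = 20L, seed = 1L, test_frac = 0.2,
                      shuffle_labels = FALSE) {
  set.seed(seed)
  feat_names <- unique(sub("^s[0-9]+_", "",
                           setdiff(names(data), c("odor", "label"))))
  n_sensors <- length(grep("_dR$", names(data)))
  n_feat <- length(feat_names)
  test_idx <- unlist(lapply(split(seq_len(nrow(data)), data$odor),
                            function(ii) sample(ii, max(1, round(test_frac * length(ii))))))
  train_idx <- setdiff(seq_len(nrow(data)), test_idx)
  norm <- normalize_sensor_features(data, ref = data[train_idx, ])
  labels <- data$label
  if (shuffle_labels) labels[train_idx] <- sample(labels[train_idx])
  y <- ifelse(labels == "rewarded", 1L, 2L)

  init <- function(r, c) matrix(rnorm(r * c, 0, sqrt(2 / r)), r, c)
  W <- list(W0 = init(n_feat, d1), W1 = init(d1, 4L),
            W2 = init(n_sensors * 4L, fc_width), b2 = numeric(fc_width),
            W3 = init(fc_width, 2L), b3 = numeric(2))
  m <- lapply(W, function(w) w * 0); v <- m
  b1a <- 0.9; b2a <- 0.999; epsa <- 1e-8; tstep <- 0
  Xs <- lapply(seq_len(nrow(data)), function(i)
    row_to_X(norm[i, ], n_sensors, feat_names))
  loss <- NA_real_
  for (ep in seq_len(epochs)) {
    ord <- sample(train_idx)
    ep_loss <- 0
    for (i in ord) {
      A <- set_reward_edges(gcn_graph(n_sensors),
                            if (y[i] == 1L) "rewarded" else "habituated")
      fwd <- gcn_forward(W, Xs[[i]], A)
      ep_loss <- ep_loss - log(max(fwd$prob[y[i]], 1e-12))
      g <- gcn_backward(W, Xs[[i]], A, fwd, y[i])
      tstep <- tstep + 1
      for (nm in names(W)) {
        m[[nm]] <- b1a * m[[nm]] + (1 - b1a) * g[[nm]]
        v[[nm]] <- b2a * v[[nm]] + (1 - b2a) * g[[nm]]^2
        mhat <- m[[nm]] / (1 - b1a^tstep)
        vhat <- v[[nm]] / (1 - b2a^tstep)
        W[[nm]] <- W[[nm]] - lr * mhat / (sqrt(vhat) + epsa)
      }
    }
    loss <- ep_loss / length(ord)
    if (!is.finite(loss)) stop("training failure: non-finite loss")
  }
  model <- structure(list(
    W = W, n_sensors = n_sensors, feat_names = feat_names,
    center = attr(norm, "center"), scale = attr(norm, "scale"),
    train_idx = train_idx, test_idx = test_idx, loss = loss,
    shuffle_labels = shuffle_labels), class = "gcn_model")
  A_test <- set_reward_edges(gcn_graph(n_sensors), "test")
  pred <- vapply(test_idx, function(i)
    which.max(gcn_forward(W, Xs[[i]], A_test)$prob), 0L)
  model$accuracy <- mean(pred == y[test_idx])
  model
}

#' @export
print.gcn_model <- function(x, ...) {
  cat(sprintf("GCN analog: %d sensor nodes + reward node; held-out accuracy %.3f (final loss %.4f)\n",
              x$n_sensors, x$accuracy, x$loss))
  invisible(x)
}

#' Class probabilities for new sensor samples
#'
#' Forward pass with neutral (test-time) reward edges, using the training
#' normalization.
#'
#' @param object a `gcn_model`.
#' @param newdata data.frame of feature rows (dataset schema).
#' @param ... unused.
#' @return Matrix of class probabilities (`rewarded`, `habituated`).
#' @export
predict.gcn_model <- function(object, newdata, ...) {
  fc <- names(object$center)
  nd <- newdata
  nd[fc] <- Map(function(col, m, s) (col - m) / s, nd[fc],
                object$center, object$scale)
  A <- set_reward_edges(gcn_graph(object$n_sensors), "test")
  out <- t(vapply(seq_len(nrow(nd)), function(i)
    gcn_forward(object$W,
                row_to_X(nd[i, ], object$n_sensors, object$feat_names),
                A)$prob, numeric(2)))
  colnames(out) <- c("rewarded", "habituated")
  out
}

#' Layer-wise contrast-enhancement analysis of the GCN
#'
#' Computes the per-sensor-node uniqueness index from layer-1 average
#' activations (mean over features; rewarded vs habituated samples, neutral
#' reward edges) and the change in activity as the layer-2 minus layer-1
#' mean activation for rewarded samples, then regresses change on UI via
#' [contrast_regression()]. Nodes with zero layer-1 habituated activation
#' are excluded and reported via the `n_units` field.
#'
#' @param model a trained `gcn_model`.
#' @param data dataset (uses all rows; pass a test subset if preferred).
#' @return An `al_contrast` object.
#' @export
gcn_contrast_analysis <- function(model, data) {
  fc <- names(model$center)
  nd <- data
  nd[fc] <- Map(function(col, m, s) (col - m) / s, nd[fc],
                model$center, model$scale)
  A <- set_reward_edges(gcn_graph(model$n_sensors), "test")
  acts <- lapply(seq_len(nrow(nd)), function(i) {
    fwd <- gcn_forward(model$W,
                       row_to_X(nd[i, ], model$n_sensors, model$feat_names), A)
    list(L1 = rowMeans(fwd$H1)[seq_len(model$n_sensors)],
         L2 = rowMeans(fwd$H2)[seq_len(model$n_sensors)])
  })
  rew <- data$label == "rewarded"
  l1_rew <- rowMeans(vapply(acts[rew], `[[`, numeric(model$n_sensors), "L1"))
  l1_hab <- rowMeans(vapply(acts[!rew], `[[`, numeric(model$n_sensors), "L1"))
  l2_rew <- rowMeans(vapply(acts[rew], `[[`, numeric(model$n_sensors), "L2"))
  ui <- uniqueness_index(l1_rew, l1_hab)
  change <- l2_rew - l1_rew
  contrast_regression(ui, change)
}
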