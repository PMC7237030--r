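## small feed-forward network (ReLU hidden layers, Adam, inverted dropout)
## used by both classifier harnesses; deterministic given a seed

mlp_init <- function(n_in, hidden, n_out) {
  sizes <- c(n_in, hidden, n_out)
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- sizes[l]
    layers[[l]] <- list(
      W = matrix(rnorm(fan_in * sizes[l + 1L], sd = sqrt(2 / fan_in)),
                 fan_in, sizes[l + 1L]),
      b = rep(0, sizes[l + 1L]))
  }
  layers
}

mlp_forward <- function(layers, x, dropout = 0, train = FALSE) {
  n_layers <- length(layers)
  acts <- vector("list", n_layers + 1L)
  masks <- vector("list", n_layers)
  acts[[1L]] <- x
  for (l in seq_len(n_layers)) {
    z <- sweep(acts[[l]] %*% layers[[l]]$W, 2L, layers[[l]]$b, "+")
    if (l < n_layers) {
      a <- pmax(z, 0)
      if (train && dropout > 0) {
        m <- matrix(runif(length(a)) >= dropout, nrow(a), ncol(a)) / (1 - dropout)
        a <- a * m
        masks[[l]] <- m
      }
      acts[[l + 1L]] <- a
    } else {
      acts[[l + 1L]] <- z # logits
    }
  }
  list(acts = acts, masks = masks)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_output <- function(logits, task) {
  if (task == "binary") 1 / (1 + exp(-logits[, 1L])) else softmax_rows(logits)
}

## gradient of mean loss w.r.t. logits: (p - y) / n for both sigmoid
## cross-entropy and softmax cross-entropy
mlp_backward <- function(layers, fw, dlogits, dropout) {
  n_layers <- length(layers)
  grads <- vector("list", n_layers)
  delta <- dlogits
  for (l in rev(seq_len(n_layers))) {
    a_prev <- fw$acts[[l]]
    grads[[l]] <- list(W = crossprod(a_prev, delta), b = colSums(delta))
    if (l > 1L) {
      delta <- delta %*% t(layers[[l]]$W)
      relu_grad <- fw$acts[[l]] > 0
      delta <- delta * relu_grad
      if (!is.null(fw$masks[[l - 1L]])) delta <- delta * fw$masks[[l - 1L]]
    }
  }
  grads
}

adam_update <- function(layers, grads, state, lr, t, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(layers)) {
    for (p in c("W", "b")) {
      g <- grads[[l]][[p]]
      state[[l]][[p]]$m <- beta1 * state[[l]][[p]]$m + (1 - beta1) * g
      state[[l]][[p]]$v <- beta2 * state[[l]][[p]]$v + (1 - beta2) * g^2
      mhat <- state[[l]][[p]]$m / (1 - beta1^t)
      vhat <- state[[l]][[p]]$v / (1 - beta2^t)
      layers[[l]][[p]] <- layers[[l]][[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(layers = layers, state = state)
}

## task: "binary" (y in {0,1}) or "multiclass" (y integer in 1..n_out)
mlp_fit <- function(x, y, hidden, n_out, task = c("binary", "multiclass"),
                    dropout = 0, lr = 1e-3, epochs = 30L, batch_size = 32L,
                    seed = 1L, x_val = NULL, y_val = NULL, val_metric = NULL,
                    patience = 8L) {
  task <- match.arg(task)
  x <- as.matrix(x)
  n <- nrow(x)
  with_seed(seed, {
    layers <- mlp_init(ncol(x), hidden, n_out)
    state <- lapply(layers, function(l)
      list(W = list(m = l$W * 0, v = l$W * 0),
           b = list(m = l$b * 0, v = l$b * 0)))
    t_step <- 0L
    best <- list(metric = -Inf, layers = layers, epoch = 0L)
    stale <- 0L
    history <- numeric(0)
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        bi <- idx[start:min(start + batch_size - 1L, n)]
        xb <- x[bi, , drop = FALSE]
        fw <- mlp_forward(layers, xb, dropout, train = TRUE)
        logits <- fw$acts[[length(fw$acts)]]
        p <- mlp_output(logits, task)
        if (task == "binary") {
          dlogits <- matrix((p - y[bi]) / length(bi), ncol = 1L)
        } else {
          tgt <- matrix(0, length(bi), n_out)
          tgt[cbind(seq_along(bi), y[bi])] <- 1
          dlogits <- (p - tgt) / length(bi)
        }
        if (any(!is.finite(dlogits)))
          stop_cv("non-finite loss gradient during network training (lr = %g)", lr)
        grads <- mlp_backward(layers, fw, dlogits, dropout)
        t_step <- t_step + 1L
        upd <- adam_update(layers, grads, state, lr, t_step)
        layers <- upd$layers
        state <- upd$state
      }
      if (!is.null(x_val) && !is.null(val_metric)) {
        pv <- mlp_output(mlp_forward(layers, x_val)$acts[[length(layers) + 1L]], task)
        m <- val_metric(pv, y_val)
        history <- c(history, m)
        if (m > best$metric) {
          best <- list(metric = m, layers = layers, epoch = ep)
          stale <- 0L
        } else {
          stale <- stale + 1L
          if (stale >= patience) break
        }
      } else {
        best <- list(metric = NA_real_, layers = layers, epoch = ep)
      }
    }
  })
  structure(list(layers = best$layers, task = task, n_out = n_out,
                 best_epoch = best$epoch, best_metric = best$metric,
                 val_history = history),
            class = "conceptvec_mlp")
}

mlp_predict <- function(model, x) {
  x <- as.matrix(x)
  fw <- mlp_forward(model$layers, x)
  mlp_output(fw$acts[[length(model$layers) + 1L]], model$task)
}
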