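# Compact neural-network trainer used by the immunogenicity submodels.
#
# Two architectures are supported:
#   * fcnn: dense(input -> hidden) -> ReLU -> dropout -> dense(hidden -> 2)
#   * cnn:  three parallel 1-D convolution branches over the token axis
#           (widths 3/4/5, shared filter count), each ReLU + global max
#           pooling; branch outputs concatenated -> dropout -> dense(-> 2)
# Training is mini-batch Adam on the two-class cross-entropy (softmax on
# raw logits in the head). Everything is plain matrix algebra so training
# stays fast on one CPU: the convolution is an im2col matrix product over
# a fixed zero-padded token layout.

new_fcnn_arch <- function(input_dim, hidden_size, dropout) {
  stopifnot(input_dim >= 1, hidden_size >= 1, dropout >= 0, dropout < 1)
  structure(list(
    type = "fcnn",
    input_dim = as.integer(input_dim),
    hidden_size = as.integer(hidden_size),
    dropout = dropout,
    n_classes = 2L,
    layers = list(
      list(kind = "dense", from = as.integer(input_dim), to = as.integer(hidden_size)),
      list(kind = "relu"),
      list(kind = "dropout", p = dropout),
      list(kind = "dense", from = as.integer(hidden_size), to = 2L)
    )
  ), class = "neorank_arch")
}

new_cnn_arch <- function(embed_dim, t_max, kernel_widths = c(3, 4, 5),
                         filters = 120, dropout = 0.1) {
  stopifnot(embed_dim >= 1, t_max >= max(kernel_widths))
  concat <- length(kernel_widths) * filters
  branches <- lapply(kernel_widths, function(w) {
    list(kind = "conv1d", width = as.integer(w), filters = as.integer(filters),
         in_dim = as.integer(embed_dim), activation = "relu",
         pooling = "global_max")
  })
  structure(list(
    type = "cnn",
    embed_dim = as.integer(embed_dim),
    t_max = as.integer(t_max),
    kernel_widths = as.integer(kernel_widths),
    filters = as.integer(filters),
    dropout = dropout,
    n_classes = 2L,
    layers = c(branches, list(
      list(kind = "concat", to = as.integer(concat)),
      list(kind = "dropout", p = dropout),
      list(kind = "dense", from = as.integer(concat), to = 2L)
    ))
  ), class = "neorank_arch")
}

#' Closed-form parameter count of a network architecture
#'
#' @param arch A model architecture (or trained submodel).
#' @return Integer number of trainable parameters.
#' @export
n_params <- function(arch) {
  if (inherits(arch, "neorank_submodel")) arch <- arch$arch
  if (arch$type == "fcnn") {
    d <- arch$input_dim; h <- arch$hidden_size
    return(as.integer(d * h + h + h * 2 + 2))
  }
  f <- arch$filters; d <- arch$embed_dim
  conv <- sum(vapply(arch$kernel_widths, function(w) w * d * f + f, numeric(1)))
  as.integer(conv + length(arch$kernel_widths) * f * 2 + 2)
}

init_params <- function(arch) {
  he <- function(fan_in, nr, nc) {
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  }
  if (arch$type == "fcnn") {
    d <- arch$input_dim; h <- arch$hidden_size
    list(W1 = he(d, d, h), b1 = numeric(h),
         W2 = he(h, h, 2), b2 = numeric(2))
  } else {
    d <- arch$embed_dim; f <- arch$filters
    conv <- lapply(arch$kernel_widths, function(w) {
      list(W = he(w * d, w * d, f), b = numeric(f))
    })
    names(conv) <- paste0("w", arch$kernel_widths)
    concat <- length(arch$kernel_widths) * f
    list(conv = conv, W2 = he(concat, concat, 2), b2 = numeric(2))
  }
}

# im2col over the flat (n x t_max*d) row-major token layout.
im2col <- function(x, w, d, t_max) {
  nw <- t_max - w + 1
  n <- nrow(x)
  out <- matrix(0, nrow = n * nw, ncol = w * d)
  for (j in seq_len(nw)) {
    cols <- ((j - 1) * d + 1):((j + w - 1) * d)
    out[(seq_len(n) - 1) * nw + j, ] <- x[, cols, drop = FALSE]
  }
  out
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

fcnn_forward <- function(params, x, dropout_p = 0, train = FALSE) {
  z1 <- sweep(x %*% params$W1, 2, params$b1, "+")
  a1 <- pmax(z1, 0)
  mask <- NULL
  if (train && dropout_p > 0) {
    mask <- matrix(stats::runif(length(a1)) >= dropout_p, nrow(a1), ncol(a1)) /
      (1 - dropout_p)
    a1d <- a1 * mask
  } else {
    a1d <- a1
  }
  logits <- sweep(a1d %*% params$W2, 2, params$b2, "+")
  list(z1 = z1, a1d = a1d, mask = mask, logits = logits)
}

fcnn_backward <- function(params, x, fwd, dlogits) {
  dW2 <- crossprod(fwd$a1d, dlogits)
  db2 <- colSums(dlogits)
  da1 <- dlogits %*% t(params$W2)
  if (!is.null(fwd$mask)) da1 <- da1 * fwd$mask
  dz1 <- da1 * (fwd$z1 > 0)
  list(W1 = crossprod(x, dz1), b1 = colSums(dz1), W2 = dW2, b2 = db2)
}

cnn_forward <- function(params, arch, x, dropout_p = 0, train = FALSE,
                        cols_cache = NULL) {
  n <- nrow(x)
  d <- arch$embed_dim; t_max <- arch$t_max; f <- arch$filters
  branches <- list()
  pooled_list <- list()
  for (bi in seq_along(arch$kernel_widths)) {
    w <- arch$kernel_widths[bi]
    nw <- t_max - w + 1
    M <- if (is.null(cols_cache)) im2col(x, w, d, t_max) else cols_cache[[bi]]
    p <- params$conv[[bi]]
    Z <- sweep(M %*% p$W, 2, p$b, "+")
    A <- pmax(Z, 0)
    dim(A) <- c(nw, n, f)
    P <- A[1, , , drop = TRUE]
    if (n == 1) P <- matrix(P, 1, f)
    J <- matrix(1L, n, f)
    if (nw > 1) {
      for (j in 2:nw) {
        cur <- A[j, , , drop = TRUE]
        if (n == 1) cur <- matrix(cur, 1, f)
        upd <- cur > P
        P[upd] <- cur[upd]
        J[upd] <- j
      }
    }
    branches[[bi]] <- list(M = M, Z = Z, J = J, nw = nw)
    pooled_list[[bi]] <- P
  }
  H <- do.call(cbind, pooled_list)
  mask <- NULL
  if (train && dropout_p > 0) {
    mask <- matrix(stats::runif(length(H)) >= dropout_p, nrow(H), ncol(H)) /
      (1 - dropout_p)
    Hd <- H * mask
  } else {
    Hd <- H
  }
  logits <- sweep(Hd %*% params$W2, 2, params$b2, "+")
  list(branches = branches, Hd = Hd, mask = mask, logits = logits)
}

cnn_backward <- function(params, arch, fwd, dlogits) {
  n <- nrow(dlogits)
  f <- arch$filters
  dW2 <- crossprod(fwd$Hd, dlogits)
  db2 <- colSums(dlogits)
  dH <- dlogits %*% t(params$W2)
  if (!is.null(fwd$mask)) dH <- dH * fwd$mask
  grads_conv <- vector("list", length(arch$kernel_widths))
  for (bi in seq_along(arch$kernel_widths)) {
    br <- fwd$branches[[bi]]
    dP <- dH[, ((bi - 1) * f + 1):(bi * f), drop = FALSE]
    # scatter pooled gradients back to the argmax windows
    r <- (rep(seq_len(n), times = f) - 1) * br$nw + as.vector(br$J)
    cidx <- rep(seq_len(f), each = n)
    Zmax <- br$Z[cbind(r, cidx)]
    dA <- matrix(0, nrow = n * br$nw, ncol = f)
    dA[cbind(r, cidx)] <- as.vector(dP) * (Zmax > 0)
    grads_conv[[bi]] <- list(W = crossprod(br$M, dA), b = colSums(dA))
  }
  list(conv = grads_conv, W2 = dW2, b2 = db2)
}

adam_state <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0),
         how = "list", classes = "ANY")
}

# Flattened walk over the nested parameter list.
adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, s) {
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
  }
  walk <- function(p, g, s) {
    if (is.list(p) && !is.numeric(p)) {
      out_p <- p; out_s <- s
      for (nm in seq_along(p)) {
        r <- walk(p[[nm]], g[[nm]], s[[nm]])
        out_p[[nm]] <- r$p; out_s[[nm]] <- r$s
      }
      list(p = out_p, s = out_s)
    } else {
      upd(p, g, s)
    }
  }
  walk(params, grads, state)
}

cross_entropy <- function(logits, y01) {
  pr <- softmax_rows(logits)
  eps <- 1e-12
  -mean(log(pmax(pr[cbind(seq_len(nrow(pr)), y01 + 1L)], eps)))
}

net_forward_logits <- function(arch, params, x, cols_cache = NULL) {
  if (arch$type == "fcnn") {
    fcnn_forward(params, x, train = FALSE)$logits
  } else {
    cnn_forward(params, arch, x, train = FALSE, cols_cache = cols_cache)$logits
  }
}

train_network <- function(arch, x, y01, x_val = NULL, y_val = NULL,
                          batch_size = 32, epochs = 10, lr = 1e-4, seed = 1) {
  n <- nrow(x)
  if (n == 0) abort_neorank("empty training partition", "neorank_data_error")
  dropout_p <- arch$dropout
  cache_val <- NULL
  if (arch$type == "cnn" && !is.null(x_val)) {
    cache_val <- lapply(seq_along(arch$kernel_widths), function(bi) {
      im2col(x_val, arch$kernel_widths[bi], arch$embed_dim, arch$t_max)
    })
  }
  with_seed(seed, {
    params <- init_params(arch)
    state <- adam_state(params)
    t_step <- 0
    history <- vector("list", epochs)
    full_cache <- NULL
    if (arch$type == "cnn") {
      full_cache <- lapply(seq_along(arch$kernel_widths), function(bi) {
        im2col(x, arch$kernel_widths[bi], arch$embed_dim, arch$t_max)
      })
    }
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      batch_losses <- c()
      for (b0 in seq(1, n, by = batch_size)) {
        bidx <- idx[b0:min(b0 + batch_size - 1, n)]
        xb <- x[bidx, , drop = FALSE]
        yb <- y01[bidx]
        Y <- matrix(0, length(bidx), 2)
        Y[cbind(seq_along(bidx), yb + 1L)] <- 1
        if (arch$type == "fcnn") {
          fwd <- fcnn_forward(params, xb, dropout_p, train = TRUE)
          loss <- cross_entropy(fwd$logits, yb)
          dlogits <- (softmax_rows(fwd$logits) - Y) / length(bidx)
          grads <- fcnn_backward(params, xb, fwd, dlogits)
        } else {
          bcache <- lapply(seq_along(full_cache), function(bi) {
            nw <- arch$t_max - arch$kernel_widths[bi] + 1
            rows <- as.vector(t(outer(bidx - 1, seq_len(nw), function(i, j) i * nw + j)))
            full_cache[[bi]][rows, , drop = FALSE]
          })
          fwd <- cnn_forward(params, arch, xb, dropout_p, train = TRUE,
                             cols_cache = bcache)
          loss <- cross_entropy(fwd$logits, yb)
          dlogits <- (softmax_rows(fwd$logits) - Y) / length(bidx)
          grads <- cnn_backward(params, arch, fwd, dlogits)
        }
        if (!is.finite(loss)) {
          abort_neorank(sprintf("training diverged (non-finite loss) at epoch %d", ep),
                        "neorank_divergence_error")
        }
        t_step <- t_step + 1
        r <- adam_update(params, grads, state, lr, t_step)
        params <- r$p
        state <- r$s
        batch_losses <- c(batch_losses, loss)
      }
      val_loss <- NA_real_
      if (!is.null(x_val) && nrow(x_val) > 0) {
        vl <- net_forward_logits(arch, params, x_val, cols_cache = cache_val)
        val_loss <- cross_entropy(vl, y_val)
      }
      history[[ep]] <- tibble::tibble(
        epoch = ep, train_loss = mean(batch_losses), val_loss = val_loss
      )
    }
    list(params = params, history = dplyr::bind_rows(history))
  })
}
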