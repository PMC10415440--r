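# Minimal convolutional-network engine on dense BLAS matrix algebra.
#
# Feature maps are stored channels-first as C x (H*W*N) matrices: columns
# enumerate spatial positions with the row index fastest (h, then w, then
# sample n), rows are channels. This makes im2col gathers and the
# transposed-conv/pooling scatters cheap column operations and lets
# per-channel scaling ride on R's vector recycling. Convolutions are one
# matrix product per layer; gradients are computed by explicit
# reverse-mode propagation through a static graph built once per
# architecture. Everything is double precision and deterministic given
# the init seed.

nn_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g$params <- list()
  g$grads <- list()
  g$state <- list()      # non-trainable state (batch-norm running moments)
  g$idx <- new.env(parent = emptyenv())  # gather/scatter index cache
  g
}

nn_add_node <- function(g, node) {
  node$id <- length(g$nodes) + 1L
  g$nodes[[node$id]] <- node
  node$id
}

nn_param <- function(g, name, value) {
  g$params[[name]] <- value
  name
}

# He-uniform initialization
he_uniform <- function(n_row, n_col, fan_in, extra = NULL) {
  lim <- sqrt(6 / fan_in)
  dims <- c(n_row, n_col, extra)
  array(stats::runif(prod(dims), -lim, lim), dims)
}

## ---- index caches ------------------------------------------------------

idx_key <- function(...) paste(..., sep = "_")

# (H*W*N) x 9 neighbour indices for a same-padded 3x3 window. Neighbours
# falling outside the image point at column H*W*N + 1, a shared zero "dump"
# column appended to the feature matrix (zero for reads, discarded for
# scatter-adds).
conv3_idx <- function(g, H, W, N) {
  key <- idx_key("c3", H, W, N)
  if (!is.null(g$idx[[key]])) return(g$idx[[key]])
  hh <- rep(seq_len(H), times = W * N)
  ww <- rep(rep(seq_len(W), each = H), times = N)
  nn <- rep(seq_len(N), each = H * W)
  dump <- H * W * N + 1L
  m <- matrix(dump, H * W * N, 9L)
  o <- 0L
  for (dw in -1:1) for (dh in -1:1) {
    o <- o + 1L
    h2 <- hh + dh
    w2 <- ww + dw
    ok <- h2 >= 1L & h2 <= H & w2 >= 1L & w2 <= W
    m[ok, o] <- h2[ok] + (w2[ok] - 1L) * H + (nn[ok] - 1L) * H * W
  }
  g$idx[[key]] <- m
  m
}

# 4 disjoint index columns pairing a (H x W) grid with its 2x2 blocks;
# used both by max pooling (gather) and transposed conv (scatter).
block2_idx <- function(g, H, W, N) {
  key <- idx_key("b2", H, W, N)
  if (!is.null(g$idx[[key]])) return(g$idx[[key]])
  Ho <- H %/% 2L; Wo <- W %/% 2L
  base <- as.vector(outer(outer(2L * (1:Ho) - 1L, (2L * (1:Wo) - 2L) * H, "+"),
                          (seq_len(N) - 1L) * H * W, "+"))
  m <- matrix(0L, length(base), 4L)
  k <- 0L
  for (dj in 0:1) for (di in 0:1) {
    k <- k + 1L
    m[, k] <- base + di + dj * H
  }
  g$idx[[key]] <- m
  m
}

## ---- graph construction ------------------------------------------------

nn_input <- function(g, channels) {
  nn_add_node(g, list(op = "input", inputs = integer(0), ch = channels))
}

nn_conv <- function(g, input, out_ch, kernel = 3L) {
  in_ch <- g$nodes[[input]]$ch
  id <- length(g$nodes) + 1L
  if (kernel == 3L) {
    # one (out_ch x in_ch) weight slab per 3x3 offset
    w <- nn_param(g, paste0("n", id, "_W"),
                  he_uniform(out_ch, in_ch, fan_in = 9L * in_ch, extra = 9L))
  } else {
    w <- nn_param(g, paste0("n", id, "_W"),
                  he_uniform(out_ch, in_ch, fan_in = in_ch))
  }
  b <- nn_param(g, paste0("n", id, "_b"), numeric(out_ch))
  nn_add_node(g, list(op = "conv", inputs = input, ch = out_ch,
                      kernel = as.integer(kernel), W = w, b = b))
}

nn_relu <- function(g, input) {
  nn_add_node(g, list(op = "relu", inputs = input, ch = g$nodes[[input]]$ch))
}

nn_bn <- function(g, input) {
  ch <- g$nodes[[input]]$ch
  id <- length(g$nodes) + 1L
  gmm <- nn_param(g, paste0("n", id, "_g"), rep(1, ch))
  bta <- nn_param(g, paste0("n", id, "_b"), numeric(ch))
  g$state[[paste0("n", id, "_rm")]] <- numeric(ch)
  g$state[[paste0("n", id, "_rv")]] <- rep(1, ch)
  nn_add_node(g, list(op = "bn", inputs = input, ch = ch,
                      gamma = gmm, beta = bta, eps = 1e-5, momentum = 0.9))
}

nn_pool <- function(g, input) {
  nn_add_node(g, list(op = "pool", inputs = input, ch = g$nodes[[input]]$ch))
}

nn_convT <- function(g, input, out_ch) {
  in_ch <- g$nodes[[input]]$ch
  id <- length(g$nodes) + 1L
  w <- nn_param(g, paste0("n", id, "_W"),
                he_uniform(out_ch, in_ch, fan_in = 4L * in_ch, extra = 4L))
  b <- nn_param(g, paste0("n", id, "_b"), numeric(out_ch))
  nn_add_node(g, list(op = "convT", inputs = input, ch = out_ch, W = w, b = b))
}

nn_concat <- function(g, a, b) {
  nn_add_node(g, list(op = "concat", inputs = c(a, b),
                      ch = g$nodes[[a]]$ch + g$nodes[[b]]$ch))
}

nn_attention <- function(g, input) {
  ch <- g$nodes[[input]]$ch
  chk <- max(1L, ch %/% 8L)
  id <- length(g$nodes) + 1L
  p <- list(
    Wq = nn_param(g, paste0("n", id, "_Wq"), he_uniform(chk, ch, ch)),
    bq = nn_param(g, paste0("n", id, "_bq"), numeric(chk)),
    Wk = nn_param(g, paste0("n", id, "_Wk"), he_uniform(chk, ch, ch)),
    bk = nn_param(g, paste0("n", id, "_bk"), numeric(chk)),
    Wv = nn_param(g, paste0("n", id, "_Wv"), he_uniform(ch, ch, ch)),
    bv = nn_param(g, paste0("n", id, "_bv"), numeric(ch)),
    gamma = nn_param(g, paste0("n", id, "_gamma"), 0))
  nn_add_node(g, list(op = "attn", inputs = input, ch = ch, chk = chk, p = p))
}

# per-channel output activation: "softplus", "relu", "sigmoid" or "linear"
nn_chanact <- function(g, input, spec) {
  stopifnot(length(spec) == g$nodes[[input]]$ch,
            all(spec %in% c("softplus", "relu", "sigmoid", "linear")))
  nn_add_node(g, list(op = "chanact", inputs = input,
                      ch = g$nodes[[input]]$ch, spec = spec))
}

## ---- forward -----------------------------------------------------------

# same-padded 3x3 convolution: sum over 9 shifted matrix products,
# fused with the neighbour gather in compiled code
conv3_forward <- function(g, X, W9, b, H, W, N) {
  conv3_fwd_cpp(X, conv3_idx(g, H, W, N), W9, b)
}

# numerically stable log(1 + exp(x))
softplus <- function(x) {
  out <- x
  lo <- x < 30
  out[lo] <- log1p(exp(x[lo]))
  out
}

softmax_rows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

# X: C x (S*N), per-sample blocks of S contiguous columns
attn_forward <- function(X, S, N, Wq, bq, Wk, bk, Wv, bv, gamma, scale) {
  Q <- (Wq %*% X) + bq
  K <- (Wk %*% X) + bk
  V <- (Wv %*% X) + bv
  O <- matrix(0, nrow(V), ncol(X))
  Bs <- vector("list", N)
  for (n in seq_len(N)) {
    cols <- ((n - 1L) * S + 1L):(n * S)
    B <- softmax_rows(crossprod(Q[, cols, drop = FALSE],
                                K[, cols, drop = FALSE]) * scale)
    O[, cols] <- tcrossprod(V[, cols, drop = FALSE], B)
    Bs[[n]] <- B
  }
  list(Y = X + gamma * O, Q = Q, K = K, V = V, O = O, B = Bs)
}

# forward pass: x is (2E) x (H*W*N) with columns ordered (h, w, n).
# Returns list(values, shapes, caches); shapes[[id]] = c(H, W).
nn_forward <- function(g, x, H, W, N, training = TRUE) {
  nn <- length(g$nodes)
  vals <- vector("list", nn)
  shp <- vector("list", nn)
  cache <- vector("list", nn)
  for (id in seq_len(nn)) {
    nd <- g$nodes[[id]]
    switch(nd$op,
      input = {
        stopifnot(nrow(x) == nd$ch, ncol(x) == H * W * N)
        vals[[id]] <- x
        shp[[id]] <- c(H, W)
      },
      conv = {
        X <- vals[[nd$inputs]]; s <- shp[[nd$inputs]]
        if (nd$kernel == 3L) {
          vals[[id]] <- conv3_forward(g, X, g$params[[nd$W]], g$params[[nd$b]],
                                      s[1], s[2], N)
        } else {
          vals[[id]] <- (g$params[[nd$W]] %*% X) + g$params[[nd$b]]
        }
        shp[[id]] <- s
      },
      relu = {
        vals[[id]] <- pmax(vals[[nd$inputs]], 0)
        shp[[id]] <- shp[[nd$inputs]]
      },
      bn = {
        X <- vals[[nd$inputs]]
        if (training) {
          mu <- rowMeans(X)
          xc <- X - mu
          v <- rowMeans(xc * xc)
          g$state[[paste0("n", id, "_rm")]] <-
            nd$momentum * g$state[[paste0("n", id, "_rm")]] + (1 - nd$momentum) * mu
          g$state[[paste0("n", id, "_rv")]] <-
            nd$momentum * g$state[[paste0("n", id, "_rv")]] + (1 - nd$momentum) * v
        } else {
          mu <- g$state[[paste0("n", id, "_rm")]]
          v <- g$state[[paste0("n", id, "_rv")]]
          xc <- X - mu
        }
        istd <- 1 / sqrt(v + nd$eps)
        xh <- xc * istd
        vals[[id]] <- xh * g$params[[nd$gamma]] + g$params[[nd$beta]]
        cache[[id]] <- list(xh = xh, istd = istd)
        shp[[id]] <- shp[[nd$inputs]]
      },
      pool = {
        X <- vals[[nd$inputs]]; s <- shp[[nd$inputs]]
        pidx <- block2_idx(g, s[1], s[2], N)
        a1 <- X[, pidx[, 1], drop = FALSE]; a2 <- X[, pidx[, 2], drop = FALSE]
        a3 <- X[, pidx[, 3], drop = FALSE]; a4 <- X[, pidx[, 4], drop = FALSE]
        M <- pmax(pmax(a1, a2), pmax(a3, a4))
        m1 <- a1 == M; m2 <- (a2 == M) & !m1
        m3 <- (a3 == M) & !(m1 | m2); m4 <- !(m1 | m2 | m3)
        vals[[id]] <- M
        cache[[id]] <- list(masks = list(m1, m2, m3, m4), pidx = pidx, s = s)
        shp[[id]] <- s %/% 2L
      },
      convT = {
        X <- vals[[nd$inputs]]; s <- shp[[nd$inputs]]
        so <- s * 2L
        sidx <- block2_idx(g, so[1], so[2], N)
        Wp <- g$params[[nd$W]]
        Y <- matrix(0, nd$ch, so[1] * so[2] * N)
        for (o in 1:4) Y[, sidx[, o]] <- Wp[, , o] %*% X
        vals[[id]] <- Y + g$params[[nd$b]]
        cache[[id]] <- list(sidx = sidx)
        shp[[id]] <- so
      },
      concat = {
        vals[[id]] <- rbind(vals[[nd$inputs[1]]], vals[[nd$inputs[2]]])
        shp[[id]] <- shp[[nd$inputs[1]]]
      },
      attn = {
        X <- vals[[nd$inputs]]; s <- shp[[nd$inputs]]
        S <- s[1] * s[2]
        p <- nd$p
        a <- attn_forward(X, S, N,
                          g$params[[p$Wq]], g$params[[p$bq]],
                          g$params[[p$Wk]], g$params[[p$bk]],
                          g$params[[p$Wv]], g$params[[p$bv]],
                          g$params[[p$gamma]], 1 / sqrt(nd$chk))
        vals[[id]] <- a$Y
        cache[[id]] <- c(a, list(S = S))
        shp[[id]] <- s
      },
      chanact = {
        X <- vals[[nd$inputs]]
        Y <- X
        for (cc in seq_along(nd$spec)) {
          Y[cc, ] <- switch(nd$spec[cc],
                            softplus = softplus(X[cc, ]),
                            relu = pmax(X[cc, ], 0),
                            sigmoid = 1 / (1 + exp(-X[cc, ])),
                            linear = X[cc, ])
        }
        vals[[id]] <- Y
        shp[[id]] <- shp[[nd$inputs]]
      },
      stop("unknown op: ", nd$op))
  }
  list(values = vals, shapes = shp, cache = cache, N = N)
}

## ---- backward ----------------------------------------------------------

# douts: named list, names are node ids (as character), values gradients.
# Accumulates parameter gradients into g$grads.
nn_backward <- function(g, fw, douts) {
  nn <- length(g$nodes)
  dvals <- vector("list", nn)
  for (nm in names(douts)) dvals[[as.integer(nm)]] <- douts[[nm]]
  g$grads <- list()
  addp <- function(name, val) {
    if (is.null(g$grads[[name]])) g$grads[[name]] <- val
    else g$grads[[name]] <- g$grads[[name]] + val
  }
  addv <- function(id, val) {
    if (is.null(dvals[[id]])) dvals[[id]] <<- val
    else dvals[[id]] <<- dvals[[id]] + val
  }
  N <- fw$N
  for (id in rev(seq_len(nn))) {
    dY <- dvals[[id]]
    if (is.null(dY)) next
    nd <- g$nodes[[id]]
    switch(nd$op,
      input = {},
      conv = {
        s <- fw$shapes[[nd$inputs]]
        X <- fw$values[[nd$inputs]]
        if (nd$kernel == 3L) {
          bk <- conv3_bwd_cpp(X, dY, conv3_idx(g, s[1], s[2], N),
                              g$params[[nd$W]])
          addp(nd$W, bk$dW)
          addp(nd$b, rowSums(dY))
          addv(nd$inputs, bk$dX)
        } else {
          addp(nd$W, tcrossprod(dY, X))
          addp(nd$b, rowSums(dY))
          addv(nd$inputs, crossprod(g$params[[nd$W]], dY))
        }
      },
      relu = {
        addv(nd$inputs, dY * (fw$values[[nd$inputs]] > 0))
      },
      bn = {
        ca <- fw$cache[[id]]
        xh <- ca$xh
        addp(nd$gamma, rowSums(dY * xh))
        addp(nd$beta, rowSums(dY))
        gam <- g$params[[nd$gamma]]
        dX <- (dY - rowMeans(dY) - xh * rowMeans(dY * xh)) * (gam * ca$istd)
        addv(nd$inputs, dX)
      },
      pool = {
        ca <- fw$cache[[id]]
        s <- ca$s
        dX <- matrix(0, nd$ch, s[1] * s[2] * N)
        for (o in 1:4) dX[, ca$pidx[, o]] <- dY * ca$masks[[o]]
        addv(nd$inputs, dX)
      },
      convT = {
        X <- fw$values[[nd$inputs]]
        sidx <- fw$cache[[id]]$sidx
        Wp <- g$params[[nd$W]]
        dW <- array(0, dim(Wp))
        dX <- matrix(0, nrow(X), ncol(X))
        for (o in 1:4) {
          dYo <- dY[, sidx[, o], drop = FALSE]
          dW[, , o] <- tcrossprod(dYo, X)
          dX <- dX + crossprod(Wp[, , o], dYo)
        }
        addp(nd$W, dW)
        addp(nd$b, rowSums(dY))
        addv(nd$inputs, dX)
      },
      concat = {
        c1 <- g$nodes[[nd$inputs[1]]]$ch
        addv(nd$inputs[1], dY[seq_len(c1), , drop = FALSE])
        addv(nd$inputs[2], dY[(c1 + 1L):nd$ch, , drop = FALSE])
      },
      attn = {
        ca <- fw$cache[[id]]
        X <- fw$values[[nd$inputs]]
        p <- nd$p
        gam <- g$params[[p$gamma]]
        scale <- 1 / sqrt(nd$chk)
        addp(p$gamma, sum(dY * ca$O))
        dO <- gam * dY
        dQ <- matrix(0, nd$chk, ncol(X))
        dK <- matrix(0, nd$chk, ncol(X))
        dV <- matrix(0, nd$ch, ncol(X))
        S <- ca$S
        for (n in seq_len(N)) {
          cols <- ((n - 1L) * S + 1L):(n * S)
          B <- ca$B[[n]]
          dOn <- dO[, cols, drop = FALSE]
          dB <- crossprod(dOn, ca$V[, cols, drop = FALSE])
          dV[, cols] <- dOn %*% B
          dL <- B * (dB - rowSums(dB * B))
          dQ[, cols] <- tcrossprod(ca$K[, cols, drop = FALSE], dL) * scale
          dK[, cols] <- (ca$Q[, cols, drop = FALSE] %*% dL) * scale
        }
        addp(p$Wq, tcrossprod(dQ, X)); addp(p$bq, rowSums(dQ))
        addp(p$Wk, tcrossprod(dK, X)); addp(p$bk, rowSums(dK))
        addp(p$Wv, tcrossprod(dV, X)); addp(p$bv, rowSums(dV))
        dX <- dY + crossprod(g$params[[p$Wq]], dQ) +
          crossprod(g$params[[p$Wk]], dK) + crossprod(g$params[[p$Wv]], dV)
        addv(nd$inputs, dX)
      },
      chanact = {
        X <- fw$values[[nd$inputs]]
        Y <- fw$values[[id]]
        dX <- dY
        for (cc in seq_along(nd$spec)) {
          dX[cc, ] <- switch(nd$spec[cc],
                             softplus = dY[cc, ] / (1 + exp(-X[cc, ])),
                             relu = dY[cc, ] * (X[cc, ] > 0),
                             sigmoid = dY[cc, ] * Y[cc, ] * (1 - Y[cc, ]),
                             linear = dY[cc, ])
        }
        addv(nd$inputs, dX)
      },
      stop("unknown op: ", nd$op))
  }
  invisible(g$grads)
}

## ---- optimizer ---------------------------------------------------------

adam_state <- function(g) {
  list(m = lapply(g$params, function(p) p * 0),
       v = lapply(g$params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(g$grads)) {
    gr <- g$grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * gr
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * gr * gr
    mhat <- st$m[[nm]] / bc1
    vhat <- st$v[[nm]] / bc2
    g$params[[nm]] <- g$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  st
}

nn_param_count <- function(g) sum(vapply(g$params, length, numeric(1)))
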