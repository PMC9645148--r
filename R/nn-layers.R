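# Differentiable layer primitives for the segmentation network.
#
# Tensors are base-R arrays in (H, W, C) layout; convolutions are im2col
# matrix products so the heavy lifting lands in BLAS. Each *Fwd returns the
# output plus whatever the matching *Bwd needs.

.padZero3 <- function(x, k = 1L) {
  d <- dim(x)
  out <- array(0, c(d[1L] + 2L * k, d[2L] + 2L * k, d[3L]))
  out[k + seq_len(d[1L]), k + seq_len(d[2L]), ] <- x
  out
}

# im2col for a 3x3 kernel with zero 'same' padding:
# rows index pixels (column-major over H, W), columns index (offset, channel)
# with offset ordered dr in -1:1 within dc in -1:1.
.im2col3 <- function(x) {
  d <- dim(x)
  h <- d[1L]; w <- d[2L]; cin <- d[3L]
  xp <- .padZero3(x, 1L)
  cols <- matrix(0, h * w, 9L * cin)
  k <- 0L
  for (dc in 0:2) for (dr in 0:2) {
    blk <- xp[dr + seq_len(h), dc + seq_len(w), , drop = FALSE]
    cols[, k * cin + seq_len(cin)] <- matrix(blk, h * w, cin)
    k <- k + 1L
  }
  cols
}

.col2im3 <- function(dcols, h, w, cin) {
  dxp <- array(0, c(h + 2L, w + 2L, cin))
  k <- 0L
  for (dc in 0:2) for (dr in 0:2) {
    blk <- array(dcols[, k * cin + seq_len(cin)], c(h, w, cin))
    dxp[dr + seq_len(h), dc + seq_len(w), ] <-
      dxp[dr + seq_len(h), dc + seq_len(w), , drop = FALSE] + blk
    k <- k + 1L
  }
  dxp[1L + seq_len(h), 1L + seq_len(w), , drop = FALSE]
}

# 3x3 convolution, zero-padded 'same'. W is (9*cin) x cout, b length cout.
.conv3Fwd <- function(x, W, b) {
  d <- dim(x)
  cols <- .im2col3(x)
  y <- cols %*% W
  y <- sweep(y, 2L, b, `+`)
  list(y = array(y, c(d[1L], d[2L], ncol(W))), cols = cols, dim = d)
}

.conv3Bwd <- function(dy, cache, W) {
  d <- cache$dim
  dym <- matrix(dy, d[1L] * d[2L], length(dy) / (d[1L] * d[2L]))
  dW <- crossprod(cache$cols, dym)
  db <- colSums(dym)
  dcols <- dym %*% t(W)
  dx <- .col2im3(dcols, d[1L], d[2L], d[3L])
  list(dx = dx, dW = dW, db = db)
}

# 1x1 convolution (pointwise linear map). W is cin x cout.
.conv1Fwd <- function(x, W, b) {
  d <- dim(x)
  xm <- matrix(x, d[1L] * d[2L], d[3L])
  y <- sweep(xm %*% W, 2L, b, `+`)
  list(y = array(y, c(d[1L], d[2L], ncol(W))), xm = xm, dim = d)
}

.conv1Bwd <- function(dy, cache, W) {
  d <- cache$dim
  dym <- matrix(dy, d[1L] * d[2L], length(dy) / (d[1L] * d[2L]))
  list(dx = array(dym %*% t(W), d),
       dW = crossprod(cache$xm, dym), db = colSums(dym))
}

.reluFwd <- function(x) {
  y <- x
  y[y < 0] <- 0
  list(y = y, mask = x > 0)
}

.reluBwd <- function(dy, cache) dy * cache$mask

# 2x2 max pooling, stride 2. Ties route the gradient to the first maximal
# corner in (top-left, bottom-left, top-right, bottom-right) order.
.pool2Fwd <- function(x) {
  d <- dim(x)
  h <- d[1L]; w <- d[2L]
  stopifnot(h %% 2L == 0L, w %% 2L == 0L)
  ro <- seq(1L, h, 2L); re <- seq(2L, h, 2L)
  co <- seq(1L, w, 2L); ce <- seq(2L, w, 2L)
  x11 <- x[ro, co, , drop = FALSE]; x21 <- x[re, co, , drop = FALSE]
  x12 <- x[ro, ce, , drop = FALSE]; x22 <- x[re, ce, , drop = FALSE]
  y <- pmax(x11, x21, x12, x22)
  list(y = y, corners = list(x11, x21, x12, x22), dim = d)
}

.pool2Bwd <- function(dy, cache) {
  d <- cache$dim
  dx <- array(0, d)
  y <- pmax(cache$corners[[1L]], cache$corners[[2L]],
            cache$corners[[3L]], cache$corners[[4L]])
  taken <- array(FALSE, dim(y))
  ro <- seq(1L, d[1L], 2L); re <- seq(2L, d[1L], 2L)
  co <- seq(1L, d[2L], 2L); ce <- seq(2L, d[2L], 2L)
  rows <- list(ro, re, ro, re)
  colsl <- list(co, co, ce, ce)
  for (k in 1:4) {
    m <- (cache$corners[[k]] == y) & !taken
    taken <- taken | m
    g <- dy
    g[!m] <- 0
    dx[rows[[k]], colsl[[k]], ] <- g
  }
  dx
}

# 2x2 transposed convolution, stride 2 (Up-Conv). W is a (2,2,cin,cout)
# array; each input pixel paints a 2x2 output block.
.upconv2Fwd <- function(x, W, b) {
  d <- dim(x)
  h <- d[1L]; w <- d[2L]; cin <- d[3L]; cout <- dim(W)[4L]
  xm <- matrix(x, h * w, cin)
  y <- array(0, c(2L * h, 2L * w, cout))
  for (a in 1:2) for (bb in 1:2) {
    yk <- xm %*% matrix(W[a, bb, , ], cin, cout)
    y[seq(a, 2L * h, 2L), seq(bb, 2L * w, 2L), ] <- array(yk, c(h, w, cout))
  }
  y <- sweep(y, 3L, b, `+`)
  list(y = y, xm = xm, dim = d, cout = cout)
}

.upconv2Bwd <- function(dy, cache, W) {
  d <- cache$dim
  h <- d[1L]; w <- d[2L]; cin <- d[3L]; cout <- cache$cout
  dW <- array(0, dim(W))
  dxm <- matrix(0, h * w, cin)
  for (a in 1:2) for (bb in 1:2) {
    dyk <- matrix(dy[seq(a, 2L * h, 2L), seq(bb, 2L * w, 2L), , drop = FALSE],
                  h * w, cout)
    dW[a, bb, , ] <- crossprod(cache$xm, dyk)
    dxm <- dxm + dyk %*% t(matrix(W[a, bb, , ], cin, cout))
  }
  db <- colSums(matrix(dy, 4L * h * w, cout))
  list(dx = array(dxm, d), dW = dW, db = db)
}

# Per-pixel softmax over the channel (class) axis.
.softmaxPix <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, d[1L] * d[2L], d[3L])
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  array(e / rowSums(e), d)
}
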