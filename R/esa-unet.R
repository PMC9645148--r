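#' @include nn-layers.R
NULL

#' LRSAR block configuration
#'
#' Settings of the low-rank self-attention reconstruction block: the number
#' of rank-one attention maps \code{s} (default 4, balancing model capacity
#' against computation), how the weighted maps recombine, and the softmax
#' normalization axis of each spatial attention map.
#'
#' \code{mode = "residual"} computes \code{Y = X + sum_i lambda_i attn_i},
#' adding the input once so that all-zero lambdas leave the features
#' untouched; \code{mode = "literal"} computes
#' \code{Y = sum_i lambda_i (X + attn_i)}, which scales \code{X} by
#' \code{sum(lambda)}. \code{softmaxAxis = "global"} normalizes each
#' attention map over all H x W entries (the map sums to 1);
#' \code{"row"} normalizes each row independently.
#'
#' @param s Number of rank-one attention maps, >= 1.
#' @param mode Recombination rule, see Details.
#' @param softmaxAxis Attention normalization axis, see Details.
#' @return Named list of settings.
#' @export
lrsarConfig <- function(s = 4L, mode = c("residual", "literal"),
                        softmaxAxis = c("global", "row")) {
  if (s < 1L) stop("s must be >= 1")
  list(s = as.integer(s), mode = match.arg(mode),
       softmaxAxis = match.arg(softmaxAxis))
}

#' Construct the ESA-UNet segmentation network
#'
#' A five-level residual encoder-decoder with skip connections and a
#' low-rank tensor self-attention reconstruction (LRSAR) block at the
#' bottleneck. Each encoder level applies two 3 x 3 convolutions with ReLU
#' and an additive residual shortcut (1 x 1 projection where channel counts
#' differ), followed by 2 x 2 max pooling (omitted after the deepest
#' level); channel widths double per level. The decoder mirrors this with
#' 2 x 2 transposed-convolution upsampling, skip concatenation and a 3 x 3
#' convolution + ReLU per stage, ending in a 1 x 1 convolution to the class
#' logits and a per-pixel softmax.
#'
#' Because the LRSAR block carries fully connected layers sized by the
#' bottleneck, the network is built for a fixed input side
#' (\code{inputSide}, divisible by 16).
#'
#' @param inputSide Input image side in pixels (square inputs), divisible
#'   by 16.
#' @param inChannels Input channels (1 for grayscale MRI).
#' @param numClasses Number of segmentation classes (4).
#' @param baseChannels Channels of the first level; widths double per
#'   level (64 gives the classic 64..1024 ladder).
#' @param lrsar An \code{\link{lrsarConfig}} list.
#' @param useLRSAR Set \code{FALSE} for the plain U-Net ablation.
#' @param seed RNG seed for He-style weight initialization.
#' @return An object of class \code{ESAUNet}: a list with \code{config} and
#'   the named parameter list \code{params} (weights, biases and the
#'   learnable attention weights \code{lambda}, initialized to 1/s).
#' @export
#' @examples
#' net <- esaUNet(inputSide = 32, baseChannels = 4, seed = 1)
#' net
esaUNet <- function(inputSide, inChannels = 1L, numClasses = 4L,
                    baseChannels = 64L, lrsar = lrsarConfig(),
                    useLRSAR = TRUE, seed = 1L) {
  if (inputSide %% 16L != 0L)
    stop("inputSide must be divisible by 16 (five levels of 2x pooling); got ",
         inputSide)
  depth <- 5L
  widths <- as.integer(baseChannels * 2^(0:(depth - 1L)))
  bH <- as.integer(inputSide) %/% 16L
  bC <- widths[depth]
  cfg <- list(inputSide = as.integer(inputSide),
              inChannels = as.integer(inChannels),
              numClasses = as.integer(numClasses),
              baseChannels = as.integer(baseChannels),
              depth = depth, widths = widths,
              bottleneck = c(H = bH, W = bH, C = bC),
              lrsar = lrsar, useLRSAR = isTRUE(useLRSAR),
              seed = as.integer(seed))
  params <- .withSeed(seed, .initESAUNetParams(cfg))
  structure(list(config = cfg, params = params), class = "ESAUNet")
}

.he <- function(dims, fanIn) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fanIn)), dims)
}

.initESAUNetParams <- function(cfg) {
  p <- list()
  cin <- cfg$inChannels
  for (l in seq_len(cfg$depth)) {
    cl <- cfg$widths[l]
    p[[sprintf("enc%d.conv1.W", l)]] <- .he(c(9L * cin, cl), 9L * cin)
    p[[sprintf("enc%d.conv1.b", l)]] <- numeric(cl)
    p[[sprintf("enc%d.conv2.W", l)]] <- .he(c(9L * cl, cl), 9L * cl)
    p[[sprintf("enc%d.conv2.b", l)]] <- numeric(cl)
    p[[sprintf("enc%d.proj.W", l)]] <- .he(c(cin, cl), cin)
    p[[sprintf("enc%d.proj.b", l)]] <- numeric(cl)
    cin <- cl
  }
  if (cfg$useLRSAR) {
    bh <- cfg$bottleneck[["H"]]; bw <- cfg$bottleneck[["W"]]
    bc <- cfg$bottleneck[["C"]]
    for (i in seq_len(cfg$lrsar$s)) {
      p[[sprintf("lrsar%d.fcq.W", i)]] <- .he(c(bh, bh), bh)
      p[[sprintf("lrsar%d.fcq.b", i)]] <- numeric(bh)
      p[[sprintf("lrsar%d.fck.W", i)]] <- .he(c(bw, bw), bw)
      p[[sprintf("lrsar%d.fck.b", i)]] <- numeric(bw)
      p[[sprintf("lrsar%d.fcv.W", i)]] <- .he(c(bc, bc), bc)
      p[[sprintf("lrsar%d.fcv.b", i)]] <- numeric(bc)
      p[[sprintf("lrsar%d.out.W", i)]] <- .he(c(bc, bc), bc)
      p[[sprintf("lrsar%d.out.b", i)]] <- numeric(bc)
    }
    p[["lrsar.lambda"]] <- rep(1 / cfg$lrsar$s, cfg$lrsar$s)
  }
  for (l in (cfg$depth - 1L):1L) {
    cu <- cfg$widths[l + 1L]; cl <- cfg$widths[l]
    p[[sprintf("dec%d.up.W", l)]] <- .he(c(2L, 2L, cu, cl), 4L * cu)
    p[[sprintf("dec%d.up.b", l)]] <- numeric(cl)
    p[[sprintf("dec%d.conv.W", l)]] <- .he(c(9L * 2L * cl, cl), 9L * 2L * cl)
    p[[sprintf("dec%d.conv.b", l)]] <- numeric(cl)
  }
  p[["final.W"]] <- .he(c(cfg$widths[1L], cfg$numClasses), cfg$widths[1L])
  p[["final.b"]] <- numeric(cfg$numClasses)
  p
}

#' @export
print.ESAUNet <- function(x, ...) {
  cfg <- x$config
  npar <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("ESAUNet: %dx%d input, %d classes, widths %s%s\n",
              cfg$inputSide, cfg$inputSide, cfg$numClasses,
              paste(cfg$widths, collapse = "-"),
              if (cfg$useLRSAR)
                sprintf(", LRSAR (s = %d, %s)", cfg$lrsar$s, cfg$lrsar$mode)
              else ", no attention (plain U-Net)"))
  cat(sprintf("  %s parameters\n", format(npar, big.mark = ",")))
  invisible(x)
}

# ---- encoder ---------------------------------------------------------------

#' Encoder forward pass
#'
#' Runs the five residual downsampling levels. Level l produces a feature
#' map of spatial size inputSide / 2^(l-1) with baseChannels * 2^(l-1)
#' channels; 2 x 2 max pooling sits between consecutive levels.
#'
#' @param model An \code{\link{esaUNet}}.
#' @param x Numeric H x W matrix or H x W x C array with H = W =
#'   \code{inputSide}.
#' @return List of the five per-level feature arrays (the fifth is the
#'   bottleneck).
#' @export
encoderForward <- function(model, x) {
  .encoderFwd(model, .asInputArray(model, x))$features
}

.asInputArray <- function(model, x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  if (d[1L] %% 16L != 0L || d[2L] %% 16L != 0L)
    stop("input spatial size ", d[1L], " x ", d[2L],
         " must be divisible by 16 (five pooling levels)")
  if (d[1L] != model$config$inputSide || d[2L] != model$config$inputSide)
    stop("input is ", d[1L], " x ", d[2L], " but the network was built for ",
         model$config$inputSide, " x ", model$config$inputSide)
  if (d[3L] != model$config$inChannels)
    stop("input has ", d[3L], " channels, expected ",
         model$config$inChannels)
  x
}

.encoderFwd <- function(model, x) {
  p <- model$params
  features <- vector("list", model$config$depth)
  caches <- vector("list", model$config$depth)
  a <- x
  for (l in seq_len(model$config$depth)) {
    c1 <- .conv3Fwd(a, p[[sprintf("enc%d.conv1.W", l)]],
                    p[[sprintf("enc%d.conv1.b", l)]])
    r1 <- .reluFwd(c1$y)
    c2 <- .conv3Fwd(r1$y, p[[sprintf("enc%d.conv2.W", l)]],
                    p[[sprintf("enc%d.conv2.b", l)]])
    pj <- .conv1Fwd(a, p[[sprintf("enc%d.proj.W", l)]],
                    p[[sprintf("enc%d.proj.b", l)]])
    r2 <- .reluFwd(c2$y + pj$y)
    features[[l]] <- r2$y
    lc <- list(c1 = c1, r1 = r1, c2 = c2, pj = pj, r2 = r2)
    if (l < model$config$depth) {
      pl <- .pool2Fwd(r2$y)
      a <- pl$y
      lc$pool <- pl
    }
    caches[[l]] <- lc
  }
  list(features = features, caches = caches)
}

.encoderBwd <- function(model, caches, dfeatures) {
  p <- model$params
  grads <- list()
  dnext <- NULL  # gradient flowing into the pooled output of level l
  for (l in model$config$depth:1L) {
    lc <- caches[[l]]
    dr2 <- dfeatures[[l]]
    if (!is.null(dnext)) dr2 <- dr2 + .pool2Bwd(dnext, lc$pool)
    dsum <- .reluBwd(dr2, lc$r2)
    g2 <- .conv3Bwd(dsum, lc$c2, p[[sprintf("enc%d.conv2.W", l)]])
    gp <- .conv1Bwd(dsum, lc$pj, p[[sprintf("enc%d.proj.W", l)]])
    dr1 <- .reluBwd(g2$dx, lc$r1)
    g1 <- .conv3Bwd(dr1, lc$c1, p[[sprintf("enc%d.conv1.W", l)]])
    grads[[sprintf("enc%d.conv1.W", l)]] <- g1$dW
    grads[[sprintf("enc%d.conv1.b", l)]] <- g1$db
    grads[[sprintf("enc%d.conv2.W", l)]] <- g2$dW
    grads[[sprintf("enc%d.conv2.b", l)]] <- g2$db
    grads[[sprintf("enc%d.proj.W", l)]] <- gp$dW
    grads[[sprintf("enc%d.proj.b", l)]] <- gp$db
    dnext <- g1$dx + gp$dx
  }
  grads
}

# ---- LRSAR -----------------------------------------------------------------

#' Generate the rank-one factor triple (Q_i, K_i, V_i)
#'
#' Decomposes the bottleneck tensor along its height, width and channel
#' axes: global average pooling over the complementary axes gives three
#' 1-d profiles, each passed through its own fully connected layer and a
#' sigmoid, so every factor entry lies in (0, 1). The s triples share the
#' (parameter-free) pooling but use independent FC parameters.
#'
#' @param model An \code{\link{esaUNet}} with the LRSAR block enabled.
#' @param x Bottleneck array H x W x C.
#' @param i Factor index in 1..s.
#' @return List with vectors \code{Q} (length H), \code{K} (length W),
#'   \code{V} (length C).
#' @export
lowRankGenerate <- function(model, x, i) {
  .lrFactorsFwd(model$params, x, i)$factors
}

.lrFactorsFwd <- function(p, x, i) {
  d <- dim(x)
  h <- d[1L]; w <- d[2L]; cc <- d[3L]
  gq <- rowMeans(matrix(x, h, w * cc))
  gk <- rowMeans(matrix(colMeans(matrix(x, h, w * cc)), w, cc))
  gv <- colMeans(matrix(x, h * w, cc))
  zq <- as.vector(p[[sprintf("lrsar%d.fcq.W", i)]] %*% gq) +
    p[[sprintf("lrsar%d.fcq.b", i)]]
  zk <- as.vector(p[[sprintf("lrsar%d.fck.W", i)]] %*% gk) +
    p[[sprintf("lrsar%d.fck.b", i)]]
  zv <- as.vector(p[[sprintf("lrsar%d.fcv.W", i)]] %*% gv) +
    p[[sprintf("lrsar%d.fcv.b", i)]]
  Q <- .sigmoid(zq); K <- .sigmoid(zk); V <- .sigmoid(zv)
  list(factors = list(Q = Q, K = K, V = V),
       cache = list(gq = gq, gk = gk, gv = gv, Q = Q, K = K, V = V,
                    dim = d))
}

#' Rank-one spatial attention map
#'
#' The outer product of the height factor Q_i and width factor K_i,
#' normalized by softmax: globally over all H x W entries by default (the
#' map then sums to 1), or row-wise when the block was configured with
#' \code{softmaxAxis = "row"}.
#'
#' @param factors A factor triple from \code{\link{lowRankGenerate}}.
#' @param softmaxAxis \code{"global"} or \code{"row"}.
#' @return H x W attention matrix with nonnegative entries.
#' @export
attentionMap <- function(factors, softmaxAxis = "global") {
  P <- outer(factors$Q, factors$K)
  if (softmaxAxis == "global") {
    .softmaxAll(P)
  } else {
    t(apply(P, 1L, function(r) .softmaxAll(r)))
  }
}

#' Apply one rank-one attention term to the bottleneck
#'
#' Builds the attention map A_i from the factors, reconstructs the rank-one
#' H x W x C attention tensor A_i (outer) V_i, projects it with a 1 x 1
#' convolution, and adds the result to the input (residual). With the
#' projection weights zeroed this is exactly the identity. The operation
#' count is linear in H * W * C.
#'
#' @param model An \code{\link{esaUNet}} with the LRSAR block enabled.
#' @param x Bottleneck array H x W x C.
#' @param factors Factor triple from \code{\link{lowRankGenerate}}.
#' @param i Index of the 1 x 1 projection to use.
#' @return Array of the same shape as \code{x}.
#' @export
lowRankAttention <- function(model, x, factors, i = 1L) {
  x + .lrAttnTermFwd(model$params, x, factors, i,
                     model$config$lrsar$softmaxAxis)$attn
}

.lrAttnTermFwd <- function(p, x, factors, i, softmaxAxis) {
  d <- dim(x)
  A <- attentionMap(factors, softmaxAxis)
  Tm <- as.vector(A) %o% factors$V           # (H*W) x C rank-one tensor
  W <- p[[sprintf("lrsar%d.out.W", i)]]
  attn <- sweep(Tm %*% W, 2L, p[[sprintf("lrsar%d.out.b", i)]], `+`)
  list(attn = array(attn, d), cache = list(A = A, Tm = Tm, dim = d))
}

#' LRSAR block forward pass
#'
#' Combines the s rank-one attention terms with the learnable weights
#' lambda into the high-rank attention tensor:
#' \code{Y = X + sum_i lambda_i attn_i} in the default residual mode (so
#' all-zero lambdas give the identity), or
#' \code{Y = sum_i lambda_i (X + attn_i)} in literal mode.
#'
#' @param model An \code{\link{esaUNet}} with the LRSAR block enabled.
#' @param x Bottleneck array H x W x C.
#' @return Array of the same shape.
#' @export
lrsarForward <- function(model, x) {
  .lrsarFwd(model, x)$y
}

.lrsarFwd <- function(model, x) {
  p <- model$params
  s <- model$config$lrsar$s
  lam <- p[["lrsar.lambda"]]
  axis <- model$config$lrsar$softmaxAxis
  terms <- vector("list", s)
  acc <- array(0, dim(x))
  for (i in seq_len(s)) {
    f <- .lrFactorsFwd(p, x, i)
    a <- .lrAttnTermFwd(p, x, f$factors, i, axis)
    terms[[i]] <- list(f = f, a = a)
    acc <- acc + lam[i] * a$attn
  }
  y <- if (model$config$lrsar$mode == "literal") sum(lam) * x + acc
       else x + acc
  list(y = y, terms = terms)
}

.lrsarBwd <- function(model, x, fwd, dy) {
  p <- model$params
  s <- model$config$lrsar$s
  lam <- p[["lrsar.lambda"]]
  axis <- model$config$lrsar$softmaxAxis
  d <- dim(x)
  h <- d[1L]; w <- d[2L]; cc <- d[3L]
  dx <- if (model$config$lrsar$mode == "literal") sum(lam) * dy else dy
  grads <- list()
  dlam <- numeric(s)
  xsum <- if (model$config$lrsar$mode == "literal") sum(dy * x) else 0
  for (i in seq_len(s)) {
    tr <- fwd$terms[[i]]
    attn <- tr$a$attn
    dlam[i] <- sum(dy * attn) + xsum
    dattn <- matrix(lam[i] * dy, h * w, cc)
    W <- p[[sprintf("lrsar%d.out.W", i)]]
    grads[[sprintf("lrsar%d.out.W", i)]] <- crossprod(tr$a$cache$Tm, dattn)
    grads[[sprintf("lrsar%d.out.b", i)]] <- colSums(dattn)
    dTm <- dattn %*% t(W)
    A <- tr$a$cache$A
    V <- tr$f$cache$V
    dA <- matrix(dTm %*% V, h, w)
    dV <- as.vector(crossprod(dTm, as.vector(A)))
    if (axis == "global") {
      dP <- A * (dA - sum(dA * A))
    } else {
      dP <- A * (dA - rowSums(dA * A))
    }
    Q <- tr$f$cache$Q; K <- tr$f$cache$K
    dQ <- as.vector(dP %*% K)
    dK <- as.vector(crossprod(dP, Q))
    # back through sigmoid + FC + GAP for each factor
    for (nm in c("q", "k", "v")) {
      dz <- switch(nm, q = dQ * Q * (1 - Q), k = dK * K * (1 - K),
                   v = dV * V * (1 - V))
      g <- switch(nm, q = tr$f$cache$gq, k = tr$f$cache$gk,
                  v = tr$f$cache$gv)
      Wf <- p[[sprintf("lrsar%d.fc%s.W", i, nm)]]
      grads[[sprintf("lrsar%d.fc%s.W", i, nm)]] <- dz %o% g
      grads[[sprintf("lrsar%d.fc%s.b", i, nm)]] <- dz
      dg <- as.vector(crossprod(Wf, dz))
      dx <- dx + switch(nm,
        q = array(matrix(dg / (w * cc), h, w * cc), d),
        k = array(rep(dg / (h * cc), each = h), d),
        v = array(rep(dg / (h * w), each = h * w), d))
    }
  }
  grads[["lrsar.lambda"]] <- dlam
  list(dx = dx, grads = grads)
}

# ---- decoder ---------------------------------------------------------------

#' Decoder forward pass
#'
#' Four upsampling stages, each a 2 x 2 transposed convolution, skip
#' concatenation with the matching encoder feature, and a 3 x 3
#' convolution + ReLU; a final 1 x 1 convolution produces class logits and
#' a per-pixel softmax the probability map. Output spatial size equals the
#' network input size.
#'
#' @param model An \code{\link{esaUNet}}.
#' @param features List of five encoder feature maps
#'   (from \code{\link{encoderForward}}).
#' @param bottleneck The (possibly LRSAR-transformed) deepest feature map;
#'   defaults to \code{features[[5]]}.
#' @return H x W x numClasses array of per-pixel class probabilities.
#' @export
decoderForward <- function(model, features, bottleneck = NULL) {
  if (is.null(bottleneck)) bottleneck <- features[[model$config$depth]]
  .softmaxPix(.decoderFwd(model, features, bottleneck)$logits)
}

.decoderFwd <- function(model, features, bottleneck) {
  p <- model$params
  d <- bottleneck
  caches <- vector("list", model$config$depth - 1L)
  for (l in (model$config$depth - 1L):1L) {
    up <- .upconv2Fwd(d, p[[sprintf("dec%d.up.W", l)]],
                      p[[sprintf("dec%d.up.b", l)]])
    skip <- features[[l]]
    if (!identical(dim(up$y)[1:2], dim(skip)[1:2]))
      stop("skip feature at level ", l, " has spatial size ",
           paste(dim(skip)[1:2], collapse = "x"),
           " but the upsampled map is ",
           paste(dim(up$y)[1:2], collapse = "x"))
    cat3 <- .bindChannels(up$y, skip)
    cv <- .conv3Fwd(cat3, p[[sprintf("dec%d.conv.W", l)]],
                    p[[sprintf("dec%d.conv.b", l)]])
    rl <- .reluFwd(cv$y)
    caches[[l]] <- list(up = up, cv = cv, rl = rl,
                        nUp = dim(up$y)[3L])
    d <- rl$y
  }
  fin <- .conv1Fwd(d, p[["final.W"]], p[["final.b"]])
  list(logits = fin$y, caches = caches, fin = fin)
}

.bindChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1L], da[2L], da[3L] + db[3L]))
  out[, , seq_len(da[3L])] <- a
  out[, , da[3L] + seq_len(db[3L])] <- b
  out
}

.decoderBwd <- function(model, dec, dlogits) {
  p <- model$params
  gf <- .conv1Bwd(dlogits, dec$fin, p[["final.W"]])
  grads <- list(`final.W` = gf$dW, `final.b` = gf$db)
  dd <- gf$dx
  dskips <- vector("list", model$config$depth)
  for (l in seq_len(model$config$depth - 1L)) {
    lc <- dec$caches[[l]]
    drl <- .reluBwd(dd, lc$rl)
    gc <- .conv3Bwd(drl, lc$cv, p[[sprintf("dec%d.conv.W", l)]])
    grads[[sprintf("dec%d.conv.W", l)]] <- gc$dW
    grads[[sprintf("dec%d.conv.b", l)]] <- gc$db
    nUp <- lc$nUp
    dcat <- gc$dx
    dup <- dcat[, , seq_len(nUp), drop = FALSE]
    dskips[[l]] <- dcat[, , nUp + seq_len(dim(dcat)[3L] - nUp),
                        drop = FALSE]
    gu <- .upconv2Bwd(dup, lc$up, p[[sprintf("dec%d.up.W", l)]])
    grads[[sprintf("dec%d.up.W", l)]] <- gu$dW
    grads[[sprintf("dec%d.up.b", l)]] <- gu$db
    dd <- gu$dx
  }
  list(grads = grads, dBottleneck = dd, dSkips = dskips)
}

# ---- full network ----------------------------------------------------------

# Forward pass with caches kept for backprop.
.netFwd <- function(model, x) {
  x <- .asInputArray(model, x)
  enc <- .encoderFwd(model, x)
  bt <- enc$features[[model$config$depth]]
  lr <- NULL
  y <- bt
  if (model$config$useLRSAR) {
    lr <- .lrsarFwd(model, bt)
    y <- lr$y
  }
  dec <- .decoderFwd(model, enc$features, y)
  probs <- .softmaxPix(dec$logits)
  list(probs = probs, logits = dec$logits, enc = enc, lr = lr, dec = dec,
       bottleneck = bt)
}

# Backward pass from a gradient w.r.t. the logits.
.netBwd <- function(model, fwd, dlogits) {
  db <- .decoderBwd(model, fwd$dec, dlogits)
  grads <- db$grads
  dBottleneck <- db$dBottleneck
  if (model$config$useLRSAR) {
    lb <- .lrsarBwd(model, fwd$bottleneck, fwd$lr, dBottleneck)
    grads <- c(grads, lb$grads)
    dBottleneck <- lb$dx
  }
  dfeat <- db$dSkips
  dfeat[[model$config$depth]] <- dBottleneck
  for (l in seq_len(model$config$depth - 1L))
    if (is.null(dfeat[[l]]))
      dfeat[[l]] <- array(0, dim(fwd$enc$features[[l]]))
  grads <- c(grads, .encoderBwd(model, fwd$enc$caches, dfeat))
  grads
}

#' Segment one image with the network
#'
#' @param model An \code{\link{esaUNet}}.
#' @param img Numeric H x W matrix (or H x W x C array) matching the
#'   network's input side.
#' @return H x W x numClasses array of per-pixel class probabilities
#'   (each pixel's probabilities sum to 1).
#' @export
predictProbs <- function(model, img) {
  .netFwd(model, img)$probs
}

#' Convert a probability map to a label mask
#'
#' Per-pixel argmax over the class axis, returning labels 0..K-1. Ties
#' resolve to the lowest class index.
#'
#' @param probs H x W x K probability array.
#' @return Integer H x W label matrix.
#' @export
probsToMask <- function(probs) {
  d <- dim(probs)
  m <- matrix(probs, d[1L] * d[2L], d[3L])
  matrix(max.col(m, ties.method = "first") - 1L, d[1L], d[2L])
}

# ---- complexity accounting -------------------------------------------------

#' Analytic multiply-add counts of the attention computations
#'
#' Counts construction and application of the attention tensors only: the
#' shared linear embeddings (GAP/FC factor generation here, the theta, phi,
#' g and output 1 x 1 projections in a dense non-local block) are excluded
#' from both counts, as both designs carry them. For LRSAR this is, per
#' rank-one term, the Q (outer) K product (H*W), the softmax (2*H*W), the
#' A (outer) V reconstruction (H*W*C) and the weighted accumulation into Y
#' (H*W*C): Theta(s * H * W * C) overall. A dense non-local block computes
#' pairwise similarities ((H*W)^2 * C), their softmax (2*(H*W)^2) and the
#' value aggregation ((H*W)^2 * C): Theta((H*W)^2 * C). Their ratio grows
#' linearly with H * W.
#'
#' @param H,W,C Feature-map height, width and channels.
#' @param s Number of rank-one terms.
#' @return Multiply-add count (numeric).
#' @export
#' @examples
#' denseAttentionMacs(32, 32, 64) / lrsarMacs(32, 32, 64, s = 4)
lrsarMacs <- function(H, W, C, s = 4) {
  s * (H * W + 2 * H * W + H * W * C + H * W * C)
}

#' @rdname lrsarMacs
#' @export
denseAttentionMacs <- function(H, W, C) {
  (H * W)^2 * C + 2 * (H * W)^2 + (H * W)^2 * C
}
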