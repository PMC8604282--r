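# Reverse-mode automatic differentiation on a flat tape.
#
# No deep-learning framework ships with this R stack, so the detection
# network runs on this small tape engine: every operation appends a node
# (value + backward closure) to the tape; ag_backward() walks the tape in
# reverse, accumulating gradients into parent nodes. Feature maps are plain
# numeric arrays (H, W, C); dense layers use matrices. All heavy lifting is
# BLAS matrix multiplication via im2col.

.ws_cache <- new.env(parent = emptyenv())

new_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

add_node <- function(tape, value, parents = list(), bw = NULL, param = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value; nd$grad <- NULL
  nd$parents <- parents; nd$bw <- bw; nd$param <- param
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- nd
  nd
}

ag_leaf <- function(tape, value) add_node(tape, value)

# wrap a parameter store (env with $value, $v, $id) as a tape leaf
ag_param <- function(tape, p) add_node(tape, p$value, param = p)

acc_grad <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
}

ag_backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$bw)) next
    gs <- nd$bw(nd$grad)
    for (j in seq_along(nd$parents)) {
      if (!is.null(gs[[j]])) acc_grad(nd$parents[[j]], gs[[j]])
    }
  }
  invisible(NULL)
}

# gradients accumulated per parameter id across the tape (weight sharing
# wraps one param env several times; contributions sum)
collect_param_grads <- function(tape) {
  out <- list()
  for (i in seq_len(tape$n)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$param) && !is.null(nd$grad)) {
      id <- nd$param$id
      out[[id]] <- if (is.null(out[[id]])) nd$grad else out[[id]] + nd$grad
    }
  }
  out
}

# ---- cached index builders -------------------------------------------------

im2col_idx <- function(H, W, C, k, pad) {
  key <- paste("i2c", H, W, C, k, pad, sep = "_")
  if (!is.null(.ws_cache[[key]])) return(.ws_cache[[key]])
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- Hp - k + 1L; Wo <- Wp - k + 1L
  oy <- rep(0:(Ho - 1L), Wo); ox <- rep(0:(Wo - 1L), each = Ho)
  cols <- vector("list", k * k * C)
  j <- 0L
  for (c in 0:(C - 1L)) for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
    j <- j + 1L
    cols[[j]] <- (oy + dy) + (ox + dx) * Hp + c * (Hp * Wp) + 1L
  }
  idx <- matrix(unlist(cols), Ho * Wo, k * k * C)
  out <- list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp)
  .ws_cache[[key]] <- out
  out
}

# scatter-add of the im2col gradient back to the padded input, looping over
# kernel offsets with precomputed flat indices (duplicates only across
# offsets, so each offset is a plain vectorised add)
col2im_add <- function(dcol, ci, k, C) {
  dxp <- numeric(ci$Hp * ci$Wp * C)
  for (j in seq_len(k * k * C)) {
    ix <- ci$idx[, j]
    dxp[ix] <- dxp[ix] + dcol[, j]
  }
  array(dxp, c(ci$Hp, ci$Wp, C))
}

pool_idx <- function(H, W, C, k) {
  key <- paste("pool", H, W, C, k, sep = "_")
  if (!is.null(.ws_cache[[key]])) return(.ws_cache[[key]])
  stopifnot(H %% k == 0L, W %% k == 0L)
  Ho <- H %/% k; Wo <- W %/% k
  oy <- rep(0:(Ho - 1L), Wo * C)
  ox <- rep(rep(0:(Wo - 1L), each = Ho), C)
  oc <- rep(0:(C - 1L), each = Ho * Wo)
  cols <- vector("list", k * k)
  j <- 0L
  for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
    j <- j + 1L
    cols[[j]] <- (oy * k + dy) + (ox * k + dx) * H + oc * (H * W) + 1L
  }
  idx <- matrix(unlist(cols), Ho * Wo * C, k * k)
  out <- list(idx = idx, Ho = Ho, Wo = Wo)
  .ws_cache[[key]] <- out
  out
}

deconv_idx <- function(h, w, Cout, k) {
  key <- paste("dc", h, w, Cout, k, sep = "_")
  if (!is.null(.ws_cache[[key]])) return(.ws_cache[[key]])
  H <- h * k; W <- w * k
  oy <- rep(0:(h - 1L), w); ox <- rep(0:(w - 1L), each = h)
  cols <- vector("list", k * k * Cout)
  j <- 0L
  for (c in 0:(Cout - 1L)) for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L)) {
    j <- j + 1L
    cols[[j]] <- (oy * k + dy) + (ox * k + dx) * H + c * (H * W) + 1L
  }
  idx <- as.vector(matrix(unlist(cols), h * w, k * k * Cout))
  out <- list(idx = idx, H = H, W = W)
  .ws_cache[[key]] <- out
  out
}

# ---- operations ------------------------------------------------------------

# 2-D convolution, stride 1. wN: param node, value array (k, k, Cin, Cout);
# bN: param node, value length Cout.
ag_conv2d <- function(tape, xN, wN, bN, pad = 1L) {
  x <- xN$value
  dims <- dim(wN$value)
  k <- dims[1]; Cin <- dims[3]; Cout <- dims[4]
  H <- dim(x)[1]; W <- dim(x)[2]
  ci <- im2col_idx(H, W, Cin, k, pad)
  if (pad > 0L) {
    xp <- array(0, c(ci$Hp, ci$Wp, Cin))
    xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  } else xp <- x
  col <- matrix(xp[ci$idx], ci$Ho * ci$Wo, k * k * Cin)
  Wm <- matrix(wN$value, k * k * Cin, Cout)
  y <- col %*% Wm
  y <- sweep(y, 2, bN$value, `+`)
  dim(y) <- c(ci$Ho, ci$Wo, Cout)
  add_node(tape, y, parents = list(xN, wN, bN), bw = function(g) {
    gm <- matrix(g, ci$Ho * ci$Wo, Cout)
    dW <- crossprod(col, gm); dim(dW) <- dims
    db <- colSums(gm)
    dcol <- tcrossprod(gm, Wm)
    dxp <- col2im_add(dcol, ci, k, Cin)
    dx <- if (pad > 0L) dxp[pad + seq_len(H), pad + seq_len(W), , drop = FALSE] else dxp
    list(dx, dW, db)
  })
}

ag_relu <- function(tape, xN) {
  m <- xN$value > 0
  add_node(tape, xN$value * m, parents = list(xN),
           bw = function(g) list(g * m))
}

ag_maxpool <- function(tape, xN, k = 2L) {
  x <- xN$value
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  pi <- pool_idx(H, W, C, k)
  cand <- matrix(x[pi$idx], nrow(pi$idx), k * k)
  am <- max.col(cand, ties.method = "first")
  sel <- cbind(seq_len(nrow(cand)), am)
  y <- cand[sel]
  dim(y) <- c(pi$Ho, pi$Wo, C)
  src <- pi$idx[sel]
  add_node(tape, y, parents = list(xN), bw = function(g) {
    dx <- array(0, d)
    dx[src] <- as.vector(g)   # pool windows are disjoint: no duplicates
    list(dx)
  })
}

# learned transposed convolution, kernel k, stride k (non-overlapping);
# wN value: matrix (Cin, k*k*Cout); bN: length Cout
ag_deconv <- function(tape, xN, wN, bN, k = 4L, Cout) {
  x <- xN$value
  d <- dim(x); h <- d[1]; w <- d[2]; Cin <- d[3]
  di <- deconv_idx(h, w, Cout, k)
  Xm <- matrix(x, h * w, Cin)
  y <- Xm %*% wN$value                     # (hw, k2*Cout)
  out <- array(0, c(di$H, di$W, Cout))
  out[di$idx] <- as.vector(y)
  bfull <- rep(bN$value, each = di$H * di$W)
  out <- out + array(bfull, c(di$H, di$W, Cout))
  add_node(tape, out, parents = list(xN, wN, bN), bw = function(g) {
    gy <- matrix(g[di$idx], h * w, k * k * Cout)
    dW <- crossprod(Xm, gy)
    dX <- tcrossprod(gy, wN$value)
    dim(dX) <- d
    db <- vapply(seq_len(Cout), function(c) sum(g[, , c]), numeric(1))
    list(dX, dW, db)
  })
}

ag_concat3 <- function(tape, xNs) {
  vals <- lapply(xNs, function(n) n$value)
  Cs <- vapply(vals, function(v) dim(v)[3], numeric(1))
  y <- array(0, c(dim(vals[[1]])[1:2], sum(Cs)))
  at <- 0L
  for (v in vals) { y[, , at + seq_len(dim(v)[3])] <- v; at <- at + dim(v)[3] }
  add_node(tape, y, parents = xNs, bw = function(g) {
    out <- vector("list", length(xNs)); at <- 0L
    for (i in seq_along(xNs)) {
      out[[i]] <- g[, , at + seq_len(Cs[i]), drop = FALSE]
      at <- at + Cs[i]
    }
    out
  })
}

# per-channel RMS response normalisation: y_c = x_c / rms(x_c)
ag_rmsnorm <- function(tape, xN, eps = 1e-6) {
  x <- xN$value
  d <- dim(x); n <- d[1] * d[2]
  r <- sqrt(apply(x, 3, function(m) mean(m^2)) + eps)
  y <- sweep(x, 3, r, `/`)
  add_node(tape, y, parents = list(xN), bw = function(g) {
    dx <- array(0, d)
    for (c in seq_len(d[3])) {
      gc <- g[, , c]; yc <- y[, , c]
      dx[, , c] <- (gc - yc * mean(gc * yc)) / r[c]
    }
    list(dx)
  })
}

ag_hadamard <- function(tape, aN, bN) {
  if (!identical(dim(aN$value), dim(bN$value))) {
    stop("hadamard: shape mismatch (", paste(dim(aN$value), collapse = "x"),
         " vs ", paste(dim(bN$value), collapse = "x"), ")")
  }
  add_node(tape, aN$value * bN$value, parents = list(aN, bN),
           bw = function(g) list(g * bN$value, g * aN$value))
}

ag_linear <- function(tape, xN, wN, bN) {
  y <- xN$value %*% wN$value
  y <- sweep(y, 2, bN$value, `+`)
  add_node(tape, y, parents = list(xN, wN, bN), bw = function(g) {
    list(tcrossprod(g, wN$value), crossprod(xN$value, g), colSums(g))
  })
}

# max-pooled region-of-interest features: boxes in input-pixel coordinates,
# feature map at the given stride; returns (n_roi, bins*bins*C) matrix
ag_roipool <- function(tape, xN, boxes, stride, bins = 7L) {
  x <- xN$value
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  n <- nrow(boxes)
  val <- matrix(0, n, bins * bins * C)
  src <- matrix(1L, n, bins * bins * C)
  bgrid <- expand.grid(by = seq_len(bins), bx = seq_len(bins))
  cseq <- 0:(C - 1L)
  for (i in seq_len(n)) {
    fx1 <- boxes[i, 1] / stride; fy1 <- boxes[i, 2] / stride
    fx2 <- boxes[i, 3] / stride; fy2 <- boxes[i, 4] / stride
    fh <- max(fy2 - fy1, 1e-3); fw <- max(fx2 - fx1, 1e-3)
    r1 <- pmin(pmax(floor(fy1 + (bgrid$by - 1) * fh / bins) + 1, 1), H)
    r2 <- pmin(pmax(ceiling(fy1 + bgrid$by * fh / bins), r1), H)
    c1 <- pmin(pmax(floor(fx1 + (bgrid$bx - 1) * fw / bins) + 1, 1), W)
    c2 <- pmin(pmax(ceiling(fx1 + bgrid$bx * fw / bins), c1), W)
    # on coarse maps many bins share one region: compute each region once
    rkey <- ((r1 * (H + 1L) + r2) * (W + 1L) + c1) * (W + 1L) + c2
    first <- match(rkey, rkey)
    for (u in unique(first)) {
      nr <- r2[u] - r1[u] + 1L; nc <- c2[u] - c1[u] + 1L
      sm <- matrix(x[r1[u]:r2[u], c1[u]:c2[u], , drop = FALSE], nr * nc, C)
      wm <- max.col(t(sm), ties.method = "first")  # argmax per channel
      mv <- sm[cbind(wm, seq_len(C))]
      lr <- (wm - 1L) %% nr; lc <- (wm - 1L) %/% nr
      gl <- (r1[u] - 1L + lr) + (c1[u] - 1L + lc) * H + cseq * (H * W) + 1L
      for (b in which(first == u)) {
        cols <- (b - 1L) + bins * bins * cseq + 1L
        val[i, cols] <- mv
        src[i, cols] <- gl
      }
    }
  }
  add_node(tape, val, parents = list(xN), bw = function(g) {
    agg <- rowsum(as.vector(g), group = as.vector(src))
    dx <- array(0, d)
    ix <- as.integer(rownames(agg))
    dx[ix] <- agg[, 1]
    list(dx)
  })
}

# scaled binary cross-entropy with logits over selected entries of a node
ag_bce_logits <- function(tape, xN, idx, targets, scale) {
  z <- xN$value[idx]
  loss <- scale * sum(pmax(z, 0) - z * targets + log1p(exp(-abs(z))))
  add_node(tape, loss, parents = list(xN), bw = function(g) {
    dz <- g * scale * (stats::plogis(z) - targets)
    dx <- array(0, dim(xN$value)); dx[idx] <- dz
    list(dx)
  })
}

# scaled smooth-L1 over selected entries
ag_smooth_l1_sel <- function(tape, xN, idx, targets, scale) {
  z <- xN$value[idx] - targets
  loss <- scale * sum(smooth_l1(z))
  add_node(tape, loss, parents = list(xN), bw = function(g) {
    dx <- array(0, dim(xN$value))
    dx[idx] <- g * scale * smooth_l1_grad(z)
    list(dx)
  })
}

# mean softmax cross-entropy over rows of a logits matrix
ag_softmax_ce <- function(tape, xN, labels) {
  z <- xN$value
  zs <- z - apply(z, 1, max)
  ez <- exp(zs)
  p <- ez / rowSums(ez)
  n <- nrow(z)
  sel <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(p[sel], 1e-12)))
  add_node(tape, loss, parents = list(xN), bw = function(g) {
    dp <- p
    dp[sel] <- dp[sel] - 1
    list(g * dp / n)
  })
}

ag_add_scalars <- function(tape, xNs, coefs = rep(1, length(xNs))) {
  v <- sum(vapply(seq_along(xNs), function(i) coefs[i] * xNs[[i]]$value, numeric(1)))
  add_node(tape, v, parents = xNs, bw = function(g) {
    lapply(coefs, function(cf) g * cf)
  })
}

# ---- parameters and optimiser ---------------------------------------------

new_param <- function(value, id) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$v <- array(0, dim(value) %||% length(value))
  p$id <- id
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# SGD with momentum and decoupled-from-nothing classic L2 weight decay:
# v <- mu v - lr (g + wd w); w <- w + v
sgd_update <- function(params_flat, grads, lr, momentum, weight_decay) {
  for (p in params_flat) {
    g <- grads[[p$id]]
    if (is.null(g)) next
    g <- g + weight_decay * p$value
    p$v <- momentum * p$v - lr * g
    p$value <- p$value + p$v
  }
  invisible(NULL)
}

flatten_params <- function(x) {
  if (is.environment(x)) return(list(x))
  unlist(lapply(x, flatten_params), recursive = FALSE, use.names = FALSE)
}
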