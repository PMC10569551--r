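#' Shallow two-level 3D U-Net configuration
#'
#' The network is fully convolutional with a fixed topology: an encoder level
#' of two 3x3x3 convolutions (stride 1, same padding, each followed by batch
#' normalisation and ReLU), a 2x2x2 max-pool, a bottleneck level of two such
#' convolutions at half resolution, an upsampling step back to full
#' resolution, concatenation with the encoder features (skip connection), a
#' decoder level of two such convolutions, and a final convolution to one
#' channel with a sigmoid, producing a voxelwise vessel probability. Only the
#' per-convolution widths, the upsampling operator and the final kernel are
#' configurable; kernel 3x3x3 and stride 1 are fixed.
#'
#' Convolutions carry no bias (the batch-norm shift immediately follows); the
#' final convolution keeps its bias. See [unet_reference_config()] for the
#' width assignment fixed against the published parameter budget.
#'
#' @param filters integer vector of length 6: output channels of the two
#'   encoder, two bottleneck and two decoder convolutions.
#' @param upsample `"nearest"` (parameter-free) or `"transposed"`
#'   (learned 2x2x2 stride-2 transposed convolution keeping channels).
#' @param final_kernel 1 or 3, edge length of the final convolution kernel.
#' @param conv_bias logical; bias on the hidden convolutions (default FALSE).
#' @return a `vs_unet_config`.
#' @export
unet_config <- function(filters = c(32L, 80L, 80L, 80L, 80L, 32L),
                        upsample = c("nearest", "transposed"),
                        final_kernel = 1L, conv_bias = FALSE) {
  upsample <- match.arg(upsample)
  stopifnot(length(filters) == 6L, all(filters >= 1), final_kernel %in% c(1L, 3L))
  structure(list(filters = as.integer(filters), upsample = upsample,
                 final_kernel = as.integer(final_kernel),
                 conv_bias = isTRUE(conv_bias),
                 kernel = 3L, stride = 1L, levels = 2L),
            class = "vs_unet_config")
}

#' Reference configuration
#'
#' Width assignment `(32, 80 | 80, 80 | 80, 32)` with nearest upsampling,
#' bias-free hidden convolutions and a 1x1x1 sigmoid head: the unique
#' palindromic configuration in the documented search space whose trainable
#' parameter count equals the published budget of 831,105 (see
#' [enumerate_configs_matching()] and the methods vignette).
#'
#' @return a `vs_unet_config`.
#' @export
unet_reference_config <- function() {
  unet_config(filters = c(32L, 80L, 80L, 80L, 80L, 32L),
              upsample = "nearest", final_kernel = 1L, conv_bias = FALSE)
}

# closed-form trainable parameter count for a config (BN = 2/channel)
unet_param_count <- function(config) {
  f <- config$filters
  cin <- c(1L, f[1:5])
  bias <- if (config$conv_bias) f else 0L * f
  n <- sum(27 * cin * f) + sum(bias) + sum(2L * f)   # convs + bias + BN
  if (config$upsample == "transposed") n <- n + 8 * f[4] * f[4] + f[4]
  dec_in <- f[4] + f[2]                               # skip concat
  n <- n - 27 * f[4] * f[5] + 27 * dec_in * f[5]      # widen first decoder conv
  n + config$final_kernel^3 * f[6] + 1                # sigmoid head + bias
}

#' Build the network
#'
#' Allocates weights (He-normal initialisation for convolutions, unit
#' gamma/zero beta batch norm, zero biases) and the running batch-norm
#' statistics.
#'
#' @param config a [unet_config()].
#' @param seed RNG seed for the weight initialisation.
#' @return a `vs_unet` model handle.
#' @export
build_unet <- function(config = unet_reference_config(), seed = 1L) {
  f <- config$filters
  cin <- c(1L, f[1:5])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  params <- list()
  for (i in 1:6) {
    ci <- if (i == 5L) f[4] + f[2] else cin[i]   # skip concat widens conv5
    w <- matrix(rnorm(27 * ci * f[i], sd = sqrt(2 / (27 * ci))), 27 * ci, f[i])
    params[[paste0("conv", i)]] <- list(
      w = w, b = if (config$conv_bias) numeric(f[i]) else NULL,
      k = 3L, cin = ci, cout = f[i])
    params[[paste0("bn", i)]] <- list(gamma = rep(1, f[i]), beta = numeric(f[i]))
  }
  if (config$upsample == "transposed")
    params$up <- list(w = array(rnorm(8 * f[4] * f[4], sd = sqrt(2 / f[4])),
                                c(8, f[4], f[4])),
                      b = numeric(f[4]))
  kf <- config$final_kernel
  params$final <- list(
    w = matrix(rnorm(kf^3 * f[6], sd = sqrt(2 / (kf^3 * f[6]))), kf^3 * f[6], 1),
    b = 0, k = kf, cin = f[6], cout = 1L)
  bn_state <- stats::setNames(
    lapply(1:6, function(i) list(mean = numeric(f[i]), var = rep(1, f[i]))),
    paste0("bn", 1:6))
  structure(list(config = config, params = params, bn_state = bn_state,
                 history = NULL),
            class = "vs_unet")
}

#' Count trainable parameters
#'
#' Convolution weights and biases plus batch-norm scale/shift; running
#' batch-norm statistics are not trainable and are excluded.
#'
#' @param model a `vs_unet` or a `vs_unet_config`.
#' @return integer parameter count.
#' @examples
#' count_parameters(unet_reference_config())
#' @export
count_parameters <- function(model) {
  config <- if (inherits(model, "vs_unet")) model$config else model
  n <- unet_param_count(config)
  if (inherits(model, "vs_unet")) {   # cross-check against allocated arrays
    alloc <- sum(vapply(model$params, function(p)
      sum(lengths(p[intersect(names(p), c("w", "b", "gamma", "beta"))])),
      numeric(1)))
    stopifnot(alloc == n)
  }
  as.integer(n)
}

#' Enumerate configurations matching a parameter budget
#'
#' The published architecture fixes kernel, stride, depth, normalisation and
#' activations but not the layer widths; the only printed architectural
#' constraint is the total trainable-parameter count. This operation searches
#' a documented space -- the strict channel-doubling family
#' `(F, F | 2F, 2F | F, F)` and the palindromic family `(a, b | b, b | b, a)`
#' -- over upsampling operator, final kernel and convolution-bias convention,
#' and returns every configuration whose count equals the target.
#'
#' @param target_count target trainable-parameter count.
#' @param base_filters candidate values for `F` / `a`.
#' @param second_filters candidate values for `b` (palindromic family).
#' @param upsample,final_kernel,conv_bias flag ranges to search.
#' @return a [tibble::tibble] of matches (possibly empty) with list-column
#'   `config`; if empty, the attribute `"nearest"` holds the five closest
#'   configurations with their counts.
#' @export
enumerate_configs_matching <- function(target_count,
                                       base_filters = 1:128,
                                       second_filters = 1:256,
                                       upsample = c("nearest", "transposed"),
                                       final_kernel = c(1L, 3L),
                                       conv_bias = c(FALSE, TRUE)) {
  # candidate width vectors: strict doubling (F,F,2F,2F,F,F) and
  # palindromic (a,b,b,b,b,a)
  cand <- rbind(
    cbind(family = "doubling", f1 = base_filters, f2 = base_filters,
          f3 = 2L * base_filters, f4 = 2L * base_filters,
          f5 = base_filters, f6 = base_filters),
    do.call(rbind, lapply(base_filters, function(a)
      cbind(family = "palindrome", f1 = a, f2 = second_filters,
            f3 = second_filters, f4 = second_filters, f5 = second_filters,
            f6 = a))))
  f <- apply(cand[, -1, drop = FALSE], 2, as.integer)
  flags <- expand.grid(upsample = upsample, final_kernel = final_kernel,
                       conv_bias = conv_bias, stringsAsFactors = FALSE)
  rows <- list(); best <- NULL
  for (i in seq_len(nrow(flags))) {
    up <- flags$upsample[i]; fk <- flags$final_kernel[i]
    cb <- flags$conv_bias[i]
    cin <- cbind(1L, f[, 1:5, drop = FALSE])
    n <- rowSums(27 * cin * f) + 2 * rowSums(f) +
      (if (cb) rowSums(f) else 0)
    if (up == "transposed") n <- n + 8 * f[, 4]^2 + f[, 4]
    n <- n - 27 * f[, 4] * f[, 5] + 27 * (f[, 4] + f[, 2]) * f[, 5]
    n <- n + fk^3 * f[, 6] + 1
    hit <- which(n == target_count)
    for (j in hit)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        family = cand[j, "family"], widths = paste(f[j, ], collapse = ","),
        upsample = up, final_kernel = as.integer(fk), conv_bias = cb,
        count = n[j],
        config = list(unet_config(f[j, ], up, as.integer(fk), cb)))
    ord <- order(abs(n - target_count))[1:5]
    nb <- tibble::tibble(family = cand[ord, "family"],
                         widths = apply(f[ord, , drop = FALSE], 1, paste,
                                        collapse = ","),
                         upsample = up, final_kernel = as.integer(fk),
                         conv_bias = cb, count = n[ord])
    best <- if (is.null(best)) nb else rbind(best, nb)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    tibble::tibble(family = character(), widths = character(),
                   upsample = character(), final_kernel = integer(),
                   conv_bias = logical(), count = numeric(), config = list())
  if (!nrow(out)) {
    best <- best[order(abs(best$count - target_count)), ]
    attr(out, "nearest") <- utils::head(best, 5L)
  }
  out
}

## ---- forward / backward -------------------------------------------------
## activations are (V, C, N) arrays; V = D*H*W voxels in (z,y,x) order

pool_maps <- function(d) {
  D <- d[1]; H <- d[2]; W <- d[3]
  Dc <- D %/% 2L; Hc <- H %/% 2L; Wc <- W %/% 2L
  Vc <- Dc * Hc * Wc
  zc <- rep_len(0:(Dc - 1L), Vc)
  yc <- rep(rep(0:(Hc - 1L), each = Dc), times = Wc)
  xc <- rep(0:(Wc - 1L), each = Dc * Hc)
  child <- matrix(0L, Vc, 8L)
  o <- 0L
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    o <- o + 1L
    child[, o] <- (2L * zc + dz) + D * ((2L * yc + dy) + H * (2L * xc + dx)) + 1L
  }
  parent <- integer(D * H * W)
  for (o in 1:8) parent[child[, o]] <- seq_len(Vc)
  list(child = child, parent = parent, coarse = c(Dc, Hc, Wc))
}

maxpool_forward <- function(x, maps) {
  C <- dim(x)[2]; N <- dim(x)[3]
  Vc <- nrow(maps$child)
  best <- x[maps$child[, 1], , , drop = FALSE]
  arg <- array(1L, c(Vc, C, N))
  for (o in 2:8) {
    cur <- x[maps$child[, o], , , drop = FALSE]
    upd <- cur > best
    best[upd] <- cur[upd]
    arg[upd] <- o
  }
  list(y = best, arg = arg)
}

maxpool_backward <- function(dy, arg, maps, V) {
  C <- dim(dy)[2]; N <- dim(dy)[3]
  Vc <- dim(dy)[1]
  dx <- array(0, c(V, C, N))
  for (o in 1:8) {
    sel <- which(arg == o)
    if (!length(sel)) next
    r <- (sel - 1L) %% Vc + 1L
    rest <- (sel - 1L) %/% Vc
    dx[maps$child[r, o] + rest * V] <- dx[maps$child[r, o] + rest * V] + dy[sel]
  }
  dx
}

upsample_forward <- function(x, maps) x[maps$parent, , , drop = FALSE]

upsample_backward <- function(dy, maps) {
  C <- dim(dy)[2]; N <- dim(dy)[3]
  V <- dim(dy)[1]
  m <- rowsum(matrix(dy, V, C * N), maps$parent)
  array(m, c(nrow(m), C, N))
}

# per-channel stats/normalisation; channel loop avoids sweep/aperm copies
bn_forward <- function(x, bn, state, training, momentum = 0.9, eps = 1e-5) {
  C <- dim(x)[2]
  xhat <- x
  y <- x
  inv <- numeric(C)
  mu_all <- numeric(C); vr_all <- numeric(C)
  for (c in seq_len(C)) {
    xc <- x[, c, ]
    if (training) {
      mu <- mean(xc)
      vr <- mean(xc * xc) - mu * mu
    } else {
      mu <- state$mean[c]; vr <- state$var[c]
    }
    mu_all[c] <- mu; vr_all[c] <- vr
    inv[c] <- 1 / sqrt(vr + eps)
    xh <- (xc - mu) * inv[c]
    xhat[, c, ] <- xh
    y[, c, ] <- bn$gamma[c] * xh + bn$beta[c]
  }
  if (training) {
    state$mean <- momentum * state$mean + (1 - momentum) * mu_all
    state$var <- momentum * state$var + (1 - momentum) * vr_all
  }
  list(y = y, xhat = xhat, inv = inv, state = state)
}

bn_backward <- function(dy, cache, bn) {
  m <- dim(dy)[1] * dim(dy)[3]                  # voxels x batch per channel
  C <- dim(dy)[2]
  dgamma <- numeric(C); dbeta <- numeric(C)
  dx <- dy
  # dxhat = dy * gamma; dx = inv * (dxhat - mean(dxhat) - xhat * mean(dxhat*xhat))
  for (c in seq_len(C)) {
    dyc <- dy[, c, ]
    xh <- cache$xhat[, c, ]
    dgamma[c] <- sum(dyc * xh)
    dbeta[c] <- sum(dyc)
    dxhat <- bn$gamma[c] * dyc
    s1 <- sum(dxhat)
    dx[, c, ] <- cache$inv[c] * (dxhat - s1 / m - xh * (dgamma[c] * bn$gamma[c] / m))
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

transposed_up_forward <- function(x, w, b, maps_fine) {
  # 2x2x2 stride-2 transposed conv: 8 independent channel mixes scattered
  Vc <- dim(x)[1]; C <- dim(x)[2]; N <- dim(x)[3]
  Cout <- dim(w)[3]
  V <- Vc * 8L
  y <- array(0, c(V, Cout, N))
  for (n in seq_len(N)) {
    Xn <- matrix(x[, , n], Vc, C)
    for (o in 1:8) {
      Yo <- Xn %*% w[o, , ]                   # Vc x Cout
      y[maps_fine$child[, o], , n] <- y[maps_fine$child[, o], , n] + Yo
    }
  }
  sweep(y, 2, b, "+")
}

transposed_up_backward <- function(x, w, dy, maps_fine) {
  Vc <- dim(x)[1]; C <- dim(x)[2]; N <- dim(x)[3]
  Cout <- dim(w)[3]
  dx <- array(0, dim(x))
  dw <- array(0, dim(w))
  for (n in seq_len(N)) {
    Xn <- matrix(x[, , n], Vc, C)
    for (o in 1:8) {
      dYo <- matrix(dy[maps_fine$child[, o], , n], Vc, Cout)
      dw[o, , ] <- dw[o, , ] + crossprod(Xn, dYo)
      dx[, , n] <- dx[, , n] + dYo %*% t(w[o, , ])
    }
  }
  db <- apply(dy, 2, sum)
  list(dx = dx, dw = dw, db = db)
}

unet_forward <- function(model, x, d, training = FALSE, keep_cache = FALSE) {
  p <- model$params
  cfg <- model$config
  maps <- pool_maps(d)
  dc <- maps$coarse
  cache <- list(d = d, maps = maps)
  run_block <- function(x, dims, i) {
    cv <- p[[paste0("conv", i)]]
    z <- conv3d_forward_cpp(x, dims, cv$w, cv$b %||% numeric(0), cv$k)
    bnc <- bn_forward(z, p[[paste0("bn", i)]], model$bn_state[[paste0("bn", i)]],
                      training)
    if (training) model$bn_state[[paste0("bn", i)]] <<- bnc$state
    a <- bnc$y * (bnc$y > 0)
    if (keep_cache) cache[[paste0("l", i)]] <<-
      list(x = x, z = z, bn = bnc[c("xhat", "inv")], a_pos = bnc$y > 0)
    a
  }
  e1 <- run_block(x, d, 1L)
  e2 <- run_block(e1, d, 2L)
  pool <- maxpool_forward(e2, maps)
  if (keep_cache) cache$pool_arg <- pool$arg
  b1 <- run_block(pool$y, dc, 3L)
  b2 <- run_block(b1, dc, 4L)
  if (cfg$upsample == "transposed") {
    up <- transposed_up_forward(b2, p$up$w, p$up$b, maps)
    if (keep_cache) cache$up_in <- b2
  } else {
    up <- upsample_forward(b2, maps)
  }
  cat5 <- abind3(up, e2)
  d1 <- run_block(cat5, d, 5L)
  d2 <- run_block(d1, d, 6L)
  zf <- conv3d_forward_cpp(d2, d, p$final$w, p$final$b, p$final$k)
  prob <- 1 / (1 + exp(-zf))
  if (keep_cache) {
    cache$d2 <- d2
    cache$prob <- prob
    cache$n_up <- dim(up)[2]
  }
  list(prob = prob, cache = if (keep_cache) cache else NULL,
       bn_state = model$bn_state)
}

abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2] + db[2], da[3]))
  out[, seq_len(da[2]), ] <- a
  out[, da[2] + seq_len(db[2]), ] <- b
  out
}

unet_backward <- function(model, cache, dprob) {
  p <- model$params
  cfg <- model$config
  d <- cache$d; maps <- cache$maps
  dc <- maps$coarse
  grads <- list()
  dz <- dprob * cache$prob * (1 - cache$prob)
  bw <- conv3d_backward_cpp(cache$d2, d, p$final$w, dz, p$final$k, TRUE)
  grads$final <- list(w = bw$dw, b = bw$db)
  da <- bw$dx
  back_block <- function(da, dims, i) {
    cc <- cache[[paste0("l", i)]]
    cv <- p[[paste0("conv", i)]]
    dbn_in <- da * cc$a_pos
    bnb <- bn_backward(dbn_in, cc$bn, p[[paste0("bn", i)]])
    cb <- conv3d_backward_cpp(cc$x, dims, cv$w, bnb$dx, cv$k, !is.null(cv$b))
    grads[[paste0("bn", i)]] <<- list(gamma = bnb$dgamma, beta = bnb$dbeta)
    grads[[paste0("conv", i)]] <<-
      c(list(w = cb$dw), if (!is.null(cv$b)) list(b = cb$db))
    cb$dx
  }
  da <- back_block(da, d, 6L)
  da <- back_block(da, d, 5L)
  n_up <- cache$n_up
  d_up <- da[, seq_len(n_up), , drop = FALSE]
  d_e2_skip <- da[, n_up + seq_len(dim(da)[2] - n_up), , drop = FALSE]
  if (cfg$upsample == "transposed") {
    tb <- transposed_up_backward(cache$up_in, p$up$w, d_up, maps)
    grads$up <- list(w = tb$dw, b = tb$db)
    d_b2 <- tb$dx
  } else {
    d_b2 <- upsample_backward(d_up, maps)
  }
  d_b2 <- back_block(d_b2, dc, 4L)
  d_pool <- back_block(d_b2, dc, 3L)
  d_e2 <- maxpool_backward(d_pool, cache$pool_arg, maps, prod(d))
  d_e2 <- d_e2 + d_e2_skip
  d_e1 <- back_block(d_e2, d, 2L)
  invisible(back_block(d_e1, d, 1L))
  grads
}

#' Predict vessel probabilities for a patch set
#'
#' Runs the network in evaluation mode (batch norm uses its running
#' statistics, so inference is deterministic) over every patch and returns a
#' patch set of voxelwise probabilities with identical ordering and geometry,
#' ready for [reassemble()].
#'
#' @param model a trained (or untrained) `vs_unet`.
#' @param patchset a `vs_patchset` of normalised `[0, 1]` patches.
#' @param batch_size patches per forward pass.
#' @return a `vs_patchset` of probability patches.
#' @export
predict_patches <- function(model, patchset, batch_size = 8L) {
  block <- patchset$block
  d <- rep(block, 3L)
  V <- prod(d)
  n <- length(patchset$patches)
  out <- vector("list", n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    x <- array(0, c(V, 1L, length(idx)))
    for (j in seq_along(idx)) {
      pj <- patchset$patches[[idx[j]]]
      if (!all(dim(pj) == block)) stop("patch shape does not match model block")
      x[, 1L, j] <- pj
    }
    fw <- unet_forward(model, x, d, training = FALSE)
    for (j in seq_along(idx))
      out[[idx[j]]] <- array(fw$prob[, 1L, j], d)
  }
  structure(list(patches = out, grid_shape = patchset$grid_shape,
                 block = block, geometry = patchset$geometry),
            class = "vs_patchset")
}

#' @export
print.vs_unet <- function(x, ...) {
  f <- x$config$filters
  cat(sprintf(paste0("<vs_unet> widths (%s), upsample %s, final %d^3, ",
                     "%s trainable parameters\n"),
              paste(f, collapse = ", "), x$config$upsample,
              x$config$final_kernel,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

## ---- model persistence --------------------------------------------------

#' Save / load a model
#'
#' Weights and batch-norm state are serialised with R's native format; the
#' architecture is additionally written to a JSON sidecar so a model can be
#' reconstructed and inspected without deserialising the weights.
#'
#' @param model a `vs_unet`.
#' @param path destination `.rds` path; the sidecar gets extension `.json`.
#' @return `load_model()` returns the `vs_unet`.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  cfg <- model$config
  jsonlite::write_json(
    list(filters = cfg$filters, upsample = cfg$upsample,
         final_kernel = cfg$final_kernel, conv_bias = cfg$conv_bias,
         parameters = count_parameters(model)),
    sub("\\.rds$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}
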