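# Shared fixtures, memoised so expensive objects are built once per run.
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# small default-style phantom used across modules
tiny_phantom <- function(seed = 11L) {
  memo(paste0("phantom", seed),
       generate_phantom(phantom_config(shape = c(48L, 48L, 48L),
                                       n_vessels = 4L,
                                       target_fg_fraction = 0.0013,
                                       seed = seed)))
}

# random probability volume with spatial correlation (so components exist)
random_prob_volume <- function(d = c(16L, 16L, 16L), smooth = 1) {
  v <- array(runif(prod(d)), d)
  if (smooth > 0)
    v <- unclass(gaussian_smooth(as_volume(v, "float"), smooth))
  v <- (v - min(v)) / (max(v) - min(v))
  bare_arr(v)
}

bare_arr <- function(x) { attributes(x) <- list(dim = dim(x)); x }

# independent region-growing oracle: label components of {p >= t} by
# synchronous dilation from the seed set {p >= s} (array-shift flood fill,
# no shared code with the BFS implementation)
grow_oracle <- function(p, s, t, connectivity = 6L) {
  fg <- p >= t
  cur <- (p >= s) & fg
  offs <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    if (connectivity == 6L && sum(abs(c(dz, dy, dx))) > 1) next
    offs[[length(offs) + 1L]] <- c(dz, dy, dx)
  }
  shift3 <- function(a, o) {
    d <- dim(a)
    out <- array(FALSE, d)
    src <- function(n, k) max(1, 1 - k):min(n, n - k)
    dst <- function(n, k) max(1, 1 + k):min(n, n + k)
    out[dst(d[1], o[1]), dst(d[2], o[2]), dst(d[3], o[3])] <-
      a[src(d[1], o[1]), src(d[2], o[2]), src(d[3], o[3])]
    out
  }
  repeat {
    grown <- cur
    for (o in offs) grown <- grown | shift3(cur, o)
    grown <- grown & fg
    if (identical(grown, cur)) break
    cur <- grown
  }
  cur * 1L
}

# labelled connected components via the oracle machinery (for phantom tests)
count_components <- function(mask, connectivity = 26L) {
  m <- mask == 1
  n <- 0L
  while (any(m)) {
    seed <- array(FALSE, dim(m))
    seed[which(m)[1]] <- TRUE
    p <- array(0, dim(m)); p[m] <- 0.6; p[seed & m] <- 1
    comp <- grow_oracle(p, 0.9, 0.5, connectivity) == 1L
    m <- m & !comp
    n <- n + 1L
  }
  n
}

ref_metrics <- function() {
  utils::read.csv(system.file("extdata", "reference_metrics.csv",
                              package = "murivess"))
}
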