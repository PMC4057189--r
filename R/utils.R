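# Internal helpers: rounding, seeded evaluation, 3-D binary morphology and
# connected components on voxel grids.

# round half away from zero; base round() is banker's rounding, but HU
# compartment bounds are printed as integers and ties must not alternate
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# shift a 3-D logical/numeric array by one voxel along `axis`, zero-filled
shift3 <- function(a, axis, by) {
  d <- dim(a)
  out <- array(vector(typeof(a), 1), d)
  src <- dst <- lapply(d, seq_len)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  if (by > 0) {
    dst[[axis]] <- (by + 1):n
    src[[axis]] <- 1:(n - by)
  } else if (by < 0) {
    dst[[axis]] <- 1:(n + by)
    src[[axis]] <- (1 - by):n
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# 6-neighbourhood dilation/erosion, `iter` rounds
dilate3 <- function(mask, iter = 1L) {
  for (i in seq_len(iter)) {
    out <- mask
    for (ax in 1:3) {
      out <- out | shift3(mask, ax, 1L) | shift3(mask, ax, -1L)
    }
    mask <- out
  }
  mask
}

erode3 <- function(mask, iter = 1L) {
  for (i in seq_len(iter)) {
    out <- mask
    for (ax in 1:3) {
      # zero-padding means border voxels erode against the outside
      out <- out & shift3(mask, ax, 1L) & shift3(mask, ax, -1L)
    }
    mask <- out
  }
  mask
}

closing3 <- function(mask, iter = 1L) {
  if (iter < 1L) return(mask)
  erode3(dilate3(mask, iter), iter)
}

# label 6-connected components of a 3-D logical array; returns an integer
# array (0 = background) plus per-component voxel counts and border flags
label_components <- function(mask) {
  d <- dim(mask)
  fg <- which(mask)
  lab <- array(0L, d)
  if (length(fg) == 0L) {
    return(list(labels = lab, sizes = integer(0), touches_border = logical(0)))
  }
  pos <- arrayInd(fg, d)
  vox_id <- integer(prod(d))
  vox_id[fg] <- seq_along(fg)
  edges <- integer(0)
  strides <- c(1L, d[1], d[1] * d[2])
  for (ax in 1:3) {
    ok <- pos[, ax] < d[ax]
    from <- fg[ok]
    to <- from + strides[ax]
    both <- mask[to]
    if (any(both)) {
      edges <- c(edges, rbind(vox_id[from[both]], vox_id[to[both]]))
    }
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  comp <- igraph::components(g)
  lab[fg] <- comp$membership
  border <- pos[, 1] == 1L | pos[, 1] == d[1] |
    pos[, 2] == 1L | pos[, 2] == d[2] |
    pos[, 3] == 1L | pos[, 3] == d[3]
  touches <- rep(FALSE, comp$no)
  if (any(border)) touches[unique(comp$membership[border])] <- TRUE
  list(labels = lab, sizes = as.integer(comp$csize), touches_border = touches)
}

# fill background cavities not connected to the array border
fill_holes3 <- function(mask) {
  cc <- label_components(!mask)
  if (length(cc$sizes) == 0L) return(mask)
  interior <- which(!cc$touches_border)
  if (length(interior)) mask[cc$labels %in% interior] <- TRUE
  mask
}

`%||%` <- function(a, b) if (is.null(a)) b else a
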