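# internal helpers shared across modules

# run `expr` under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# one step of 8-connected binary dilation on a logical matrix
dilate8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-nr, ]
  out[-nr, ] <- out[-nr, ] | m[-1, ]
  out[, -1] <- out[, -1] | out[, -nc]   # uses row-dilated result: full 3x3
  out[, -nc] <- out[, -nc] | out[, -1]
  out
}

# matrix row/col index grids (row-major semantics of our [row, col] images)
row_grid <- function(nr, nc) matrix(rep.int(seq_len(nr), nc), nr, nc)
col_grid <- function(nr, nc) matrix(rep(seq_len(nc), each = nr), nr, nc)

# logical disk mask of pixels within `radius` of (r0, c0) inside an nr x nc grid
disk_mask <- function(nr, nc, r0, c0, radius) {
  rr <- row_grid(nr, nc) - r0
  cc <- col_grid(nr, nc) - c0
  rr * rr + cc * cc <= radius * radius
}

# labels (from EBImage::bwlabel) of components touching the matrix border
border_labels <- function(lab) {
  edge <- c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)])
  setdiff(unique(edge), 0)
}

# md5 of an R object via its serialized bytes on disk
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
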