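# Independent oracles used across tests. The flood-fill labeller is written
# in plain R with an explicit stack, entirely independent of the package's
# C++ connected-component path.

flood_fill_count <- function(mask, connectivity = 26) {
  d <- dim(mask)
  if (length(d) == 2) d <- c(d, 1L)
  arr <- array(as.logical(mask), d)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  m <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- switch(as.character(connectivity),
                 "6" = offs[m <= 1, ], "18" = offs[m <= 2, ], offs)
  seen <- array(FALSE, d)
  count <- 0L
  labels <- array(0L, d)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (!arr[x, y, z] || seen[x, y, z]) next
    count <- count + 1L
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      labels[v[1], v[2], v[3]] <- count
      for (k in seq_len(nrow(offs))) {
        nx <- v[1] + offs$dx[k]; ny <- v[2] + offs$dy[k]; nz <- v[3] + offs$dz[k]
        if (nx < 1 || nx > d[1] || ny < 1 || ny > d[2] || nz < 1 || nz > d[3])
          next
        if (arr[nx, ny, nz] && !seen[nx, ny, nz]) {
          seen[nx, ny, nz] <- TRUE
          stack[[length(stack) + 1L]] <- c(nx, ny, nz)
        }
      }
    }
  }
  list(count = count, labels = labels)
}

# small noise-free stack fixture used by several tests
tiny_stack <- function(seed = 1, n_cells = 2, noise = TRUE) {
  gt <- plant_ground_truth(n_cells = n_cells, seed = seed)
  nz <- if (noise) list(photons = 150, read_sigma = 2, background = 10,
                        poisson = TRUE)
  else list(photons = 1, read_sigma = 0, background = 0, poisson = FALSE)
  list(gt = gt, stack = render_stack(gt, make_psf(), noise = nz,
                                     seed = seed + 500))
}
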