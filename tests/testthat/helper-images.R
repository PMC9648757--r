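# Small in-code rasters shared across tests.

grayToRgb <- function(gray) {
  array(rep(gray, 3), c(nrow(gray), ncol(gray), 3))
}

# uniform dark frame of the given thickness on a bright field
frameImage <- function(size, thickness, dark = 0L, bright = 200L) {
  g <- matrix(bright, size, size)
  g[seq_len(thickness), ] <- dark
  g[size - seq_len(thickness) + 1L, ] <- dark
  g[, seq_len(thickness)] <- dark
  g[, size - seq_len(thickness) + 1L] <- dark
  g
}

# brute-force oracle for the inner-corner diagonal walk (top-left
# orientation): scan every candidate d from the extent down and test the
# three-sub-threshold condition directly on the gray matrix
oracleInnerTL <- function(gray, threshold = 4L, extent = 20L) {
  for (d in seq(extent, 2L)) {
    v <- c(gray[d + 1L, d + 1L], gray[d, d], gray[d - 1L, d - 1L])
    if (all(v < threshold)) return(c(d, d))
  }
  NULL
}

# dark disk on a bright field with light noise; truth mask alongside
diskImage <- function(size = 80L, radius = 18L, fg = 60L, bg = 200L,
                      noise = 3L, seed = 1L) {
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  disk <- (rows - size / 2)^2 + (cols - size / 2)^2 <= radius^2
  img <- array(bg, c(size, size, 3))
  for (ch in 1:3) {
    p <- img[, , ch]
    p[disk] <- fg
    img[, , ch] <- p
  }
  set.seed(seed)
  img <- img + array(sample(seq(-noise, noise), size^2 * 3, TRUE),
                     c(size, size, 3))
  list(image = array(as.integer(pmin(pmax(img, 0), 255)), dim(img)),
       truth = matrix(ifelse(disk, 255L, 0L), size, size))
}
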