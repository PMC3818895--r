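# Independent oracles, deliberately naive implementations.

# breadth-first flood-fill connected-component labeling (2D/3D)
oracle_label <- function(mask, connectivity) {
  d <- dim(mask)
  if (length(d) == 2) d <- c(d, 1L)
  offs <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0 & offs$dz == 0), ]
  man <- abs(offs$dy) + abs(offs$dx) + abs(offs$dz)
  offs <- switch(as.character(connectivity),
                 "4" = offs[offs$dz == 0 & man == 1, ],
                 "8" = offs[offs$dz == 0, ],
                 "6" = offs[man == 1, ],
                 "26" = offs)
  arr <- array(mask, d)
  lab <- array(0L, d)
  nxt <- 0L
  for (seed in which(arr)) {
    if (lab[seed] != 0L) next
    nxt <- nxt + 1L
    queue <- seed
    lab[seed] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      z <- (v - 1) %/% (d[1] * d[2]) + 1
      rem <- (v - 1) %% (d[1] * d[2])
      x <- rem %/% d[1] + 1
      y <- rem %% d[1] + 1
      for (k in seq_len(nrow(offs))) {
        yy <- y + offs$dy[k]; xx <- x + offs$dx[k]; zz <- z + offs$dz[k]
        if (yy < 1 || yy > d[1] || xx < 1 || xx > d[2] || zz < 1 || zz > d[3])
          next
        w <- (zz - 1) * d[1] * d[2] + (xx - 1) * d[1] + yy
        if (arr[w] && lab[w] == 0L) {
          lab[w] <- nxt
          queue <- c(queue, w)
        }
      }
    }
  }
  attr(lab, "n_components") <- nxt
  lab
}

# brute-force Otsu: scan every midpoint between sorted unique values
oracle_otsu <- function(values) {
  u <- sort(unique(values))
  if (length(u) < 2) return(u[1])
  cands <- (u[-1] + u[-length(u)]) / 2
  bcv <- vapply(cands, function(t) {
    lo <- values[values <= t]; hi <- values[values > t]
    w <- length(lo) / length(values)
    w * (1 - w) * (mean(lo) - mean(hi))^2
  }, numeric(1))
  cands[which.max(bcv)]
}

# brute-force count of parenchyma-stroma voxel faces
oracle_border_area_um2 <- function(par, str, vd) {
  d <- dim(par)
  area <- 0
  for (z in seq_len(d[3])) for (x in seq_len(d[2])) for (y in seq_len(d[1])) {
    if (!par[y, x, z]) next
    for (o in list(c(1, 0, 0, vd[1] * vd[3]), c(-1, 0, 0, vd[1] * vd[3]),
                   c(0, 1, 0, vd[2] * vd[3]), c(0, -1, 0, vd[2] * vd[3]),
                   c(0, 0, 1, vd[1] * vd[2]), c(0, 0, -1, vd[1] * vd[2]))) {
      yy <- y + o[1]; xx <- x + o[2]; zz <- z + o[3]
      if (yy < 1 || yy > d[1] || xx < 1 || xx > d[2] || zz < 1 || zz > d[3])
        next
      if (str[yy, xx, zz]) area <- area + o[4]
    }
  }
  area
}
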