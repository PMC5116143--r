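# Independent brute-force flood fill used as the labeling oracle. Deliberately
# naive (queue of (row, col) pairs, explicit neighbour loop) and written
# without reference to the package's labeling code.
oracle_components <- function(mask, connectivity) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  offsets <- if (connectivity == 8) {
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
          c(1, -1), c(1, 0), c(1, 1))
  } else {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  nxt <- 0L
  for (cc in seq_len(W)) for (rr in seq_len(H)) {
    if (!mask[rr, cc] || lab[rr, cc] > 0L) next
    nxt <- nxt + 1L
    qr <- rr; qc <- cc
    lab[rr, cc] <- nxt
    head <- 1L
    while (head <= length(qr)) {
      pr <- qr[head]; pc <- qc[head]; head <- head + 1L
      for (k in seq_len(nrow(offsets))) {
        r2 <- pr + offsets[k, 1]; c2 <- pc + offsets[k, 2]
        if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W &&
            mask[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- nxt
          qr <- c(qr, r2); qc <- c(qc, c2)
        }
      }
    }
  }
  if (nxt == 0L) return(list())
  comps <- unname(split(which(lab > 0L), lab[lab > 0L]))
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, min, numeric(1)))]
}

# canonical form of the package's partition for comparison with the oracle
package_partition <- function(mask, connectivity) {
  comps <- label_components(mask, connectivity)$pixels
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, function(p) min(p), numeric(1)))]
}

# paint a filled dark rectangle (1-based inclusive rows/cols) on a light image
paint_block <- function(img, rows, cols, intensity = 20L) {
  img[rows, cols] <- intensity
  img
}

# blank light image as plain integer matrix
light_matrix <- function(h, w, intensity = 255L) matrix(intensity, h, w)
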