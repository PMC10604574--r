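# Connected-component labelling on binary matrices.
#
# EBImage::bwlabel is 4-connected; the geometry code needs 8-connectivity
# (diagonally touching plaque pixels are one plaque). We take the 4-connected
# labelling and merge labels that touch diagonally with a small union-find.

cc_label <- function(binary, connectivity = 8L) {
  stopifnot(is.matrix(binary))
  lab <- EBImage::bwlabel(binary != 0)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  nlab <- max(lab)
  if (connectivity == 4L || nlab <= 1L) return(lab)

  nr <- nrow(lab); nc <- ncol(lab)
  # label pairs adjacent along the two diagonal directions
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-1, -nc]),  as.vector(lab[-nr, -1])))
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                 pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  if (!nrow(pairs)) return(lab)

  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1L]); b <- find(pairs[k, 2L])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

# sizes of each positive label
cc_sizes <- function(lab) {
  if (max(lab) == 0L) return(integer(0))
  tabulate(lab[lab > 0L], nbins = max(lab))
}
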