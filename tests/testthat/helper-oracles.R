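# Independent brute-force oracles shared across test files. These stay
# deliberately naive (explicit loops, no reuse of package internals) so they
# check the vectorized implementations from a different direction.

# flood-fill connected components by breadth-first search
oracle_label_components <- function(mask, connectivity = 26) {
  dm <- dim(mask)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  ord <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 "6" = offs[ord == 1, , drop = FALSE],
                 "18" = offs[ord <= 2, , drop = FALSE],
                 "26" = offs)
  lab <- array(0L, dm)
  cur <- 0L
  for (lin in which(mask)) {
    if (lab[lin] != 0L) next
    cur <- cur + 1L
    queue <- lin
    lab[lin] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      ijk <- arrayInd(v, dm)
      for (o in seq_len(nrow(offs))) {
        n <- ijk + offs[o, ]
        if (any(n < 1) || any(n > dm)) next
        if (mask[n[1], n[2], n[3]] && lab[n[1], n[2], n[3]] == 0L) {
          lab[n[1], n[2], n[3]] <- cur
          queue <- c(queue, (n[3] - 1) * dm[1] * dm[2] + (n[2] - 1) * dm[1] + n[1])
        }
      }
    }
  }
  lab
}

# per-voxel minimum physical distance to any mask voxel
oracle_expand_roi <- function(mask, spacing, distance_mm) {
  dm <- dim(mask)
  src <- arrayInd(which(mask), dm)
  out <- array(FALSE, dm)
  for (lin in seq_len(prod(dm))) {
    v <- arrayInd(lin, dm)
    diff <- sweep(src, 2, as.vector(v), `-`)
    d2 <- (diff[, 1] * spacing[1])^2 + (diff[, 2] * spacing[2])^2 +
      (diff[, 3] * spacing[3])^2
    out[lin] <- min(d2) <= distance_mm^2 + 1e-9
  }
  out
}

# all-pairs longest diameter (cm)
oracle_longest_diameter <- function(mask, spacing) {
  ijk <- arrayInd(which(mask), dim(mask))
  n <- nrow(ijk)
  if (n <= 1) return(0)
  best <- 0
  for (a in seq_len(n - 1)) {
    for (b in seq(a + 1, n)) {
      d <- sqrt(sum(((ijk[a, ] - ijk[b, ]) * spacing)^2))
      if (d > best) best <- d
    }
  }
  best / 10
}

# all-pairs Mann-Whitney AUC with ties at 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (x in pos) for (y in neg)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(pos) * length(neg))
}

# exhaustive threshold scan over a fine sweep of cut points
oracle_best_accuracy <- function(scores, labels, direction = "higher") {
  s <- if (direction == "lower") -scores else scores
  y <- as.logical(labels)
  cands <- sort(unique(c(s - 1e-9, s + 1e-9, min(s) - 1, max(s) + 1)))
  best <- -1
  for (t in cands) {
    pred <- s > t
    acc <- mean(pred == y)
    if (acc > best) best <- acc
  }
  best
}

random_blob_mask <- function(dm, n_seeds = 3, p_fill = 0.4) {
  m <- array(stats::runif(prod(dm)) < p_fill, dim = dm)
  m
}
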