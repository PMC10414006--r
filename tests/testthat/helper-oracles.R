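# Independent brute-force oracles. These deliberately share no code with the
# package implementation: plain per-voxel loops and direct formula
# transcriptions, used to cross-check the vectorised/packaged routes.

oracle_offsets <- function(connectivity) {
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  g <- g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ]
  if (connectivity == 6) g <- g[abs(g$di) + abs(g$dj) + abs(g$dk) == 1, ]
  as.matrix(g)
}

# per-voxel neighbourhood-check erosion
oracle_erode <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- oracle_offsets(connectivity)
  out <- array(FALSE, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    ok <- TRUE
    for (r in seq_len(nrow(offs))) {
      ii <- i + offs[r, 1]; jj <- j + offs[r, 2]; kk <- k + offs[r, 3]
      if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3] ||
          !mask[ii, jj, kk]) { ok <- FALSE; break }
    }
    out[i, j, k] <- ok
  }
  out
}

# per-voxel dilation band (dilation minus mask)
oracle_band <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- oracle_offsets(connectivity)
  out <- array(FALSE, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k]) next
    for (r in seq_len(nrow(offs))) {
      ii <- i + offs[r, 1]; jj <- j + offs[r, 2]; kk <- k + offs[r, 3]
      if (ii >= 1 && jj >= 1 && kk >= 1 && ii <= d[1] && jj <= d[2] &&
          kk <= d[3] && mask[ii, jj, kk]) { out[i, j, k] <- TRUE; break }
    }
  }
  out
}

# stack-based flood fill, labels in raster-scan order of discovery
oracle_flood_fill <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- oracle_offsets(connectivity)
  out <- array(0L, dim = d)
  lab <- 0L
  for (start in which(mask)) {
    if (out[start] != 0L) next
    lab <- lab + 1L
    stack <- start
    out[start] <- lab
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      cc <- arrayInd(v, d)
      for (r in seq_len(nrow(offs))) {
        ii <- cc[1] + offs[r, 1]; jj <- cc[2] + offs[r, 2]; kk <- cc[3] + offs[r, 3]
        if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3]) next
        if (!mask[ii, jj, kk]) next
        w <- ii + (jj - 1L) * d[1] + (kk - 1L) * d[1] * d[2]
        if (out[w] == 0L) { out[w] <- lab; stack <- c(stack, w) }
      }
    }
  }
  out
}

# exact Fisher p for a 2x2 table by hypergeometric enumeration
oracle_fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# linearly weighted kappa written out from the defining sums
oracle_weighted_kappa <- function(tab) {
  k <- nrow(tab)
  o <- tab / sum(tab)
  pr <- rowSums(o); pc <- colSums(o)
  num <- 0; den <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    w <- abs(i - j) / (k - 1)
    num <- num + w * o[i, j]
    den <- den + w * pr[i] * pc[j]
  }
  1 - num / den
}

# small shared imaging fixture, built once per test run
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- generate_phantom(shape = c(40, 40, 40),
                             lesion_spec = lesion_spec(n_lacunes = 2,
                                                       n_wmh_blobs = 2,
                                                       n_cmb = 1),
                             seed = 42)
      tr <- generate_truth_maps(
        ph, focus_spec = focus_spec(at_lacune_rim = 2, random_wm = 4),
        seed = 43)
      vif <- generate_vif(times = seq(0, 600, by = 30))
      dce <- synthesize_dce(tr, vif, noise_sd = 0.002, seed = 44)
      cache <<- list(phantom = ph, truth = tr, vif = vif, dce = dce)
    }
    cache
  }
})
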