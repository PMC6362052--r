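# Independent brute-force TFCE oracle: explicit threshold sweep with
# flood-fill connected components, written without reference to the
# package's implementation.
tfce_oracle <- function(map, E = 0.5, H = 2, dh = NULL, connectivity = 26) {
  d <- dim(map)
  mx <- max(map)
  out <- array(0, dim = d)
  if (mx <= 0) return(out)
  if (is.null(dh)) dh <- mx / 100
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  if (connectivity == 6)
    offsets <- offsets[rowSums(abs(offsets)) == 1, ]
  hs <- dh * seq_len(floor(mx / dh + 1e-7))
  for (h in hs) {
    supra <- map >= h
    lab <- array(0L, dim = d)
    cur <- 0L
    idx <- which(supra, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      v <- idx[r, ]
      if (lab[v[1], v[2], v[3]] != 0L) next
      cur <- cur + 1L
      queue <- list(v)
      lab[v[1], v[2], v[3]] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(offsets))) {
          q <- p + offsets[k, ]
          if (any(q < 1) || any(q > d)) next
          if (supra[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
            lab[q[1], q[2], q[3]] <- cur
            queue[[length(queue) + 1]] <- q
          }
        }
      }
    }
    if (cur > 0L) {
      sizes <- tabulate(lab[lab > 0L], nbins = cur)
      contrib <- array(0, dim = d)
      contrib[lab > 0L] <- sizes[lab[lab > 0L]]^E * h^H * dh
      out <- out + contrib
    }
  }
  out
}

# Small phantom shared across tests (built once per test file)
tiny_phantom <- function(seed = 11) {
  make_phantom(c(24, 24, 8), n_cortical = 2, n_subcortical = 2, seed = seed)
}

# Deterministic 4D series from an array of per-voxel time courses
vol_from_matrix <- function(m, dims3, tr_vol_s = 1) {
  as_volume4d(array(t(m), dim = c(dims3, nrow(m))), tr_vol_s = tr_vol_s)
}
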