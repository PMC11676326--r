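# Build a fragment_model directly from coordinate matrices, bypassing file
# I/O. `cas` is a list of n x 3 CA matrices (one per chain); side-chain
# centers default to the CAs.
make_model <- function(cas, scs = cas, plddt = 90, pae = NULL) {
  chains <- lapply(seq_along(cas), function(k) {
    ca <- cas[[k]]; sc <- scs[[k]]
    n <- nrow(ca)
    data.frame(resno = seq_len(n), x = ca[, 1], y = ca[, 2], z = ca[, 3],
               sx = sc[, 1], sy = sc[, 2], sz = sc[, 3],
               plddt = rep_len(plddt, n))
  })
  names(chains) <- LETTERS[seq_along(cas)]
  structure(list(chains = chains, pae = pae, provenance = list()),
            class = "fragment_model")
}

# Straight helix-like CA trace along +z, offset in x.
straight_chain <- function(n, x_off = 0, rise = 1.5) {
  cbind(rep(x_off, n), numeric(n), rise * (seq_len(n) - 1))
}

# Independent windowing enumerator: walk the sequence start by start,
# replacing the overhanging final window by one ending at the C-terminus.
brute_windows <- function(len, L, O) {
  if (len < L) return(data.frame(start = 0L, end = len))
  starts <- integer()
  s <- 0L
  repeat {
    if (s + L >= len) {
      if (s + L > len) s <- len - L
      starts <- c(starts, s)
      break
    }
    starts <- c(starts, s)
    s <- s + (L - O)
  }
  data.frame(start = starts, end = starts + L)
}

# Brute-force orientation oracle for one chain pair: explicit loops over
# residues, no vectorized shortcuts shared with the implementation.
oracle_pair_parallel <- function(A, B) {
  n <- nrow(A)
  df <- 0; dr <- 0
  for (i in seq_len(n)) {
    df <- df + sqrt(sum((A[i, ] - B[i, ])^2))
    dr <- dr + sqrt(sum((A[i, ] - B[n + 1 - i, ])^2))
  }
  (dr / n) >= (df / n)
}

# Brute-force knob detection on a dimer: residue i of chain `which` is a
# knob iff >= 4 side-chain centers of the other chain fall within cutoff.
oracle_dimer_knobs <- function(model, cutoff = 7.0) {
  sc <- lapply(model$chains, function(ch) as.matrix(ch[, c("sx", "sy", "sz")]))
  n <- nrow(sc[[1]])
  out <- list()
  for (k in 1:2) {
    other <- sc[[3 - k]]
    knobs <- integer()
    for (i in seq_len(n)) {
      cnt <- 0L
      for (j in seq_len(n))
        if (sqrt(sum((sc[[k]][i, ] - other[j, ])^2)) <= cutoff)
          cnt <- cnt + 1L
      if (cnt >= 4L) knobs <- c(knobs, i)
    }
    out[[k]] <- knobs
  }
  out
}

expected_orientation_value <- function(orientation) {
  pr <- utils::combn(length(orientation), 2)
  same <- sum(orientation[pr[1, ]] == orientation[pr[2, ]])
  diff <- ncol(pr) - same
  if (same > diff) 1 else if (diff > same) 0 else 0.5
}
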