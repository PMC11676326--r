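test_that("per-residue pLDDT averages across chain copies", {
  m <- make_model(list(straight_chain(4), straight_chain(4, 10)))
  m$chains[[1]]$plddt <- c(80, 90, 70, 60)
  m$chains[[2]]$plddt <- c(60, 70, 90, 80)
  expect_equal(mean_plddt_per_residue(m), c(70, 80, 80, 70))

  mono <- make_model(list(straight_chain(4)), plddt = 77.7)
  expect_equal(mean_plddt_per_residue(mono), rep(77.7, 4))
})

test_that("per-residue PAE is the row-union-column mean over chain copies", {
  mono <- make_model(list(straight_chain(2)),
                     pae = matrix(c(0, 2, 4, 0), 2, 2))
  # row i and column i, diagonal included: (0 + 4 + 2 + 0) / 4
  expect_equal(mean_pae_per_residue(mono), c(1.5, 1.5))

  m <- make_model(list(straight_chain(3), straight_chain(3, 10)),
                  pae = matrix(5, 6, 6))
  expect_equal(mean_pae_per_residue(m), rep(5, 3))
  expect_null(mean_pae_per_residue(make_model(list(straight_chain(3)))))

  # brute-force cross-check on an asymmetric random matrix
  set.seed(3)
  pae <- matrix(runif(36, 0, 30), 6, 6)
  m2 <- make_model(list(straight_chain(3), straight_chain(3, 10)), pae = pae)
  got <- mean_pae_per_residue(m2)
  for (i in 1:3) {
    idx <- c(i, i + 3)
    vals <- c()
    for (r in idx) for (cc in 1:6) vals <- c(vals, pae[r, cc], pae[cc, r])
    expect_equal(got[i], mean(vals))
  }
})

test_that("orientation is called from forward vs reversed CA distances", {
  par <- crick_backbone(crick_params(2, 30))
  expect_equal(detect_orientation(par)$value, 1.0)

  # reversing one chain's stored residue order swaps d_fwd and d_rev exactly
  rev1 <- par
  rev1$chains[[2]][, c("x", "y", "z", "sx", "sy", "sz")] <-
    rev1$chains[[2]][30:1, c("x", "y", "z", "sx", "sy", "sz")]
  expect_equal(detect_orientation(rev1)$value, 0.0)
  p <- detect_orientation(par)$pairs; r <- detect_orientation(rev1)$pairs
  expect_equal(p$d_fwd, r$d_rev)
  expect_equal(p$d_rev, r$d_fwd)

  anti <- crick_backbone(crick_params(2, 30, orientation = c(1, -1)))
  expect_equal(detect_orientation(anti)$value, 0.0)

  # up-down-up-down tetramer: 4 of the 6 pairs are antiparallel
  tet <- crick_backbone(crick_params(4, 30, orientation = c(1, -1, 1, -1),
                                     R0 = 6.3))
  o <- detect_orientation(tet)
  expect_equal(o$value, 0.0)
  expect_equal(sum(!o$pairs$parallel), 4)

  expect_true(is.na(detect_orientation(
    make_model(list(straight_chain(5))))$value))
})

test_that("pairwise orientation calls match the brute-force distance oracle", {
  set.seed(11)
  for (rep in 1:20) {
    nc <- sample(2:4, 1)
    m <- crick_backbone(crick_params(nc, sample(21:40, 1),
                                     orientation = sample(c(-1, 1), nc,
                                                          replace = TRUE),
                                     R0 = runif(1, 4.5, 7.5)),
                        noise_sd = 0.3)
    calls <- detect_orientation(m)$pairs
    cas <- lapply(m$chains, function(ch) as.matrix(ch[, c("x", "y", "z")]))
    for (i in seq_len(nrow(calls))) {
      expect_equal(calls$parallel[i],
                   oracle_pair_parallel(cas[[calls$chain_a[i]]],
                                        cas[[calls$chain_b[i]]]))
    }
  }
})

test_that("knobs-into-holes detection finds packed cores and nothing else", {
  dimer <- crick_backbone(crick_params(2, 35))
  ann <- detect_kih(dimer)
  expect_true(any(ann$residues$is_knob))
  # every knob's hole is 4 residues on one single other chain
  knobs <- ann$residues[ann$residues$is_knob, ]
  for (i in seq_len(nrow(knobs))) {
    expect_false(knobs$partner_chain[i] == knobs$chain[i])
    expect_length(strsplit(knobs$hole_resnos[i], ",")[[1]], 4)
  }
  # hole members are flagged as participating
  expect_true(all(ann$residues$participates[ann$residues$in_hole]))

  # chains far apart: no packing at all
  apart <- make_model(list(straight_chain(20), straight_chain(20, 100)))
  expect_equal(sum(detect_kih(apart)$per_position), 0)

  # monomer: all-false annotation
  expect_equal(sum(detect_kih(make_model(list(straight_chain(8))))$per_position),
               0)

  # shrinking the cutoff never creates a knob
  for (cut in c(7.0, 6.5, 6.0, 5.5)) {
    k_lo <- which(detect_kih(dimer, cut - 0.5)$residues$is_knob)
    k_hi <- which(detect_kih(dimer, cut)$residues$is_knob)
    expect_true(all(k_lo %in% k_hi))
  }
})

test_that("features are invariant to rigid motion and chain relabeling", {
  m <- crick_backbone(crick_params(2, 28), plddt = 85)
  m$pae <- matrix(runif(56 * 56, 0, 15), 56, 56)
  feats <- function(x) list(p = mean_plddt_per_residue(x),
                            e = mean_pae_per_residue(x),
                            o = detect_orientation(x)$value,
                            k = detect_kih(x)$per_position)
  base <- feats(m)

  # global rotation + translation
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  shift <- c(12, -7, 30)
  rot <- m
  rot$chains <- lapply(rot$chains, function(ch) {
    ca <- t(R %*% t(as.matrix(ch[, c("x", "y", "z")]))) +
      rep(shift, each = nrow(ch))
    sc <- t(R %*% t(as.matrix(ch[, c("sx", "sy", "sz")]))) +
      rep(shift, each = nrow(ch))
    ch[, c("x", "y", "z")] <- ca
    ch[, c("sx", "sy", "sz")] <- sc
    ch
  })
  moved <- feats(rot)
  expect_equal(moved$p, base$p)
  expect_equal(moved$e, base$e)
  expect_equal(moved$o, base$o, tolerance = 1e-6)
  expect_equal(moved$k, base$k, tolerance = 1e-6)

  # swapping chain order changes no per-position feature value
  sw <- m
  sw$chains <- sw$chains[c(2, 1)]
  names(sw$chains) <- c("A", "B")
  perm <- c(29:56, 1:28)
  sw$pae <- m$pae[perm, perm]
  relab <- feats(sw)
  expect_equal(relab$p, base$p)
  expect_equal(relab$e, base$e)
  expect_equal(relab$o, base$o)
  expect_equal(relab$k, base$k)
})
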