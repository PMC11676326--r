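#' Per-residue mean pLDDT of a fragment model
#'
#' Averages pLDDT across the chain copies of each fragment position, so a
#' homo-dimer contributes one confidence value per position.
#'
#' @param model a `fragment_model`.
#' @return Numeric vector, one value per fragment position.
#' @export
mean_plddt_per_residue <- function(model) {
  stopifnot(inherits(model, "fragment_model"))
  rowMeans(vapply(model$chains, function(ch) ch$plddt,
                  numeric(chain_length(model))))
}

#' Per-residue mean PAE of a fragment model
#'
#' For fragment position i, averages every PAE entry lying in the rows or
#' the columns of all chain copies of residue i (the symmetrized
#' row-union-column slice, diagonal included). This summarizes how
#' confidently residue i is placed relative to the rest of the assembly,
#' which for oligomeric fragments is dominated by the inter-chain blocks.
#'
#' @param model a `fragment_model` with a PAE matrix.
#' @return Numeric vector (angstroms), one value per fragment position, or
#'   `NULL` when the model carries no PAE.
#' @export
mean_pae_per_residue <- function(model) {
  stopifnot(inherits(model, "fragment_model"))
  if (is.null(model$pae)) return(NULL)
  L <- chain_length(model)
  nc <- n_chains(model)
  vapply(seq_len(L), function(i) {
    idx <- i + (seq_len(nc) - 1L) * L
    mean(c(model$pae[idx, , drop = FALSE], model$pae[, idx, drop = FALSE]))
  }, 0)
}

#' Parallel/antiparallel orientation of a bundle
#'
#' For each unordered chain pair, compares the mean CA-CA distance between
#' equivalent residue indices (d_fwd) with the same mean computed after
#' reversing the residue index of the second chain (d_rev): if the reversal
#' reduces the mean distance, that pair is antiparallel. The model-level
#' call is the majority over all pairs, encoded 1 (parallel), 0
#' (antiparallel), or 0.5 when the pairs tie (possible only for >= 4
#' chains). A pair with d_rev == d_fwd exactly is called parallel; this
#' tie-break is deterministic and has measure zero on real coordinates.
#'
#' @param model a `fragment_model` with >= 2 chains.
#' @return List with `value` (1, 0, or 0.5) and `pairs` (data.frame of
#'   per-pair calls with the two mean distances). A monomer returns value
#'   `NA` (orientation is undefined).
#' @export
detect_orientation <- function(model) {
  stopifnot(inherits(model, "fragment_model"))
  nc <- n_chains(model)
  if (nc < 2L)
    return(list(value = NA_real_, pairs = NULL))
  L <- chain_length(model)
  cas <- lapply(model$chains, ca_xyz)
  pairs <- utils::combn(nc, 2L)
  calls <- apply(pairs, 2L, function(p) {
    A <- cas[[p[1L]]]; B <- cas[[p[2L]]]
    d_fwd <- mean(sqrt(rowSums((A - B)^2)))
    d_rev <- mean(sqrt(rowSums((A - B[L:1L, , drop = FALSE])^2)))
    c(parallel = as.numeric(d_rev >= d_fwd), d_fwd = d_fwd, d_rev = d_rev)
  })
  n_par <- sum(calls["parallel", ])
  n_anti <- ncol(pairs) - n_par
  value <- if (n_par > n_anti) 1 else if (n_anti > n_par) 0 else 0.5
  list(value = value,
       pairs = data.frame(chain_a = names(model$chains)[pairs[1L, ]],
                          chain_b = names(model$chains)[pairs[2L, ]],
                          parallel = calls["parallel", ] == 1,
                          d_fwd = calls["d_fwd", ], d_rev = calls["d_rev", ]))
}

#' Knobs-into-holes participation
#'
#' SOCKET-style packing detection on side-chain centers: residue r on chain
#' X is a knob when at least four side-chain centers of residues on one
#' single other chain Y lie within `contact_cutoff` of r's side-chain
#' center; the four nearest of those residues form the hole. The per-residue
#' annotation also marks hole membership, since a residue lining a hole
#' participates in the coiled-coil interface even if it is not itself a
#' knob.
#'
#' @param model a `fragment_model`.
#' @param contact_cutoff packing cutoff in angstroms (default 7.0, the
#'   SOCKET convention).
#' @return List with `residues` (data.frame: `chain`, `resno`,
#'   `position` (1-based fragment position), `is_knob`, `partner_chain`,
#'   `hole_resnos` (comma-joined), `in_hole`, `participates`) and
#'   `per_position` (numeric vector over fragment positions: 1 if the
#'   residue participates in a knobs-into-holes contact in any chain).
#' @export
detect_kih <- function(model, contact_cutoff = 7.0) {
  stopifnot(inherits(model, "fragment_model"))
  nc <- n_chains(model)
  L <- chain_length(model)
  scs <- lapply(model$chains, sc_xyz)
  res <- do.call(rbind, lapply(seq_len(nc), function(k)
    data.frame(chain = names(model$chains)[k],
               resno = model$chains[[k]]$resno,
               position = seq_len(L), is_knob = FALSE,
               partner_chain = NA_character_, hole_resnos = NA_character_,
               in_hole = FALSE, stringsAsFactors = FALSE)))
  if (nc >= 2L) {
    for (k in seq_len(nc)) {
      others <- setdiff(seq_len(nc), k)
      for (i in seq_len(L)) {
        best <- NULL
        for (j in others) {
          d <- sqrt(colSums((t(scs[[j]]) - scs[[k]][i, ])^2))
          hits <- which(d <= contact_cutoff)
          if (length(hits) >= 4L) {
            hole <- hits[order(d[hits])][1:4]
            if (is.null(best) || sum(d[hole]) < best$score)
              best <- list(chain = j, hole = hole, score = sum(d[hole]))
          }
        }
        if (!is.null(best)) {
          row <- (k - 1L) * L + i
          res$is_knob[row] <- TRUE
          res$partner_chain[row] <- names(model$chains)[best$chain]
          res$hole_resnos[row] <-
            paste(model$chains[[best$chain]]$resno[best$hole], collapse = ",")
          res$in_hole[(best$chain - 1L) * L + best$hole] <- TRUE
        }
      }
    }
  }
  res$participates <- res$is_knob | res$in_hole
  per_position <- vapply(seq_len(L), function(i)
    as.numeric(any(res$participates[res$position == i])), 0)
  list(residues = res, per_position = per_position)
}

#' All per-residue features of one fragment model
#'
#' @param model a `fragment_model`.
#' @param features character vector among `"plddt"`, `"pae"`,
#'   `"orientation"`, `"kih"`.
#' @param contact_cutoff knobs-into-holes packing cutoff (angstroms).
#' @return Named list of numeric vectors over fragment positions; a feature
#'   whose prerequisite is missing (PAE absent, monomer orientation) maps to
#'   `NULL`.
#' @export
fragment_features <- function(model,
                              features = c("plddt", "pae", "orientation",
                                           "kih"),
                              contact_cutoff = 7.0) {
  features <- match.arg(features, several.ok = TRUE)
  L <- chain_length(model)
  out <- list()
  if ("plddt" %in% features)
    out$plddt <- mean_plddt_per_residue(model)
  if ("pae" %in% features)
    out$pae <- mean_pae_per_residue(model)
  if ("orientation" %in% features) {
    ori <- detect_orientation(model)$value
    out$orientation <- if (is.na(ori)) NULL else rep(ori, L)
  }
  if ("kih" %in% features)
    out$kih <- detect_kih(model, contact_cutoff)$per_position
  out
}
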