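#' Read a predicted fragment model
#'
#' Parses a multi-chain PDB model of one fragment into the internal
#' representation used by all feature extractors: per chain, the CA trace,
#' a side-chain center per residue, and per-residue pLDDT taken from the
#' B-factor column of the CA atoms (the universal convention of structure
#' prediction outputs). The side-chain center is the centroid of the
#' non-backbone heavy atoms, falling back to CB and finally CA (glycine).
#' An optional PAE matrix is read from JSON; both the
#' `"predicted_aligned_error"` and the `"pae"` key dialects are accepted,
#' optionally wrapped in a one-element list.
#'
#' If the query carried a flanking adaptor, `flank_length` residues are
#' removed from both termini of every chain, and the corresponding rows and
#' columns of the PAE matrix, before anything else sees the model: flanks
#' never contribute to scores.
#'
#' @param pdb_path path to the model PDB file.
#' @param pae_path optional path to the PAE JSON file (`NULL` for none).
#' @param flank_length residues to strip from both ends of every chain.
#' @return A `fragment_model`: list with `chains` (named list, one element
#'   per chain: data.frame with `resno`, `x`, `y`, `z`, `sx`, `sy`, `sz`,
#'   `plddt`), `pae` (square matrix over all residues, chains concatenated
#'   in chain order, or `NULL`), and `provenance`.
#' @export
read_model <- function(pdb_path, pae_path = NULL, flank_length = 0L) {
  pdb <- bio3d::read.pdb(pdb_path, verbose = FALSE)
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(atoms)) stop("no ATOM records in ", pdb_path, call. = FALSE)
  atoms$chain[is.na(atoms$chain)] <- " "
  chain_ids <- unique(atoms$chain)

  backbone <- c("N", "CA", "C", "O", "OXT")
  chains <- lapply(chain_ids, function(ch) {
    a <- atoms[atoms$chain == ch, , drop = FALSE]
    a <- a[order(a$resno), , drop = FALSE]
    resnos <- unique(a$resno)
    ca <- a[a$elety == "CA", , drop = FALSE]
    if (nrow(ca) != length(resnos))
      stop("malformed model ", pdb_path, ": chain ", ch, " has ",
           length(resnos), " residues but ", nrow(ca), " CA atoms",
           call. = FALSE)
    sc <- t(vapply(resnos, function(r) {
      res <- a[a$resno == r, , drop = FALSE]
      side <- res[!(res$elety %in% backbone) &
                    !grepl("^H", res$elety), , drop = FALSE]
      if (nrow(side)) return(colMeans(side[, c("x", "y", "z")]))
      cb <- res[res$elety == "CB", , drop = FALSE]
      if (nrow(cb)) return(unlist(cb[1L, c("x", "y", "z")]))
      unlist(res[res$elety == "CA", c("x", "y", "z")][1L, ])
    }, numeric(3)))
    data.frame(resno = resnos, x = ca$x, y = ca$y, z = ca$z,
               sx = sc[, 1L], sy = sc[, 2L], sz = sc[, 3L],
               plddt = ca$b, row.names = NULL)
  })
  names(chains) <- chain_ids

  nres <- vapply(chains, nrow, 0L)
  if (length(unique(nres)) != 1L)
    stop("malformed model ", pdb_path,
         ": chains have unequal residue counts (",
         paste(nres, collapse = ", "),
         "); fragment models must be homo-oligomers", call. = FALSE)

  pae <- if (!is.null(pae_path)) read_pae(pae_path) else NULL
  if (!is.null(pae) && nrow(pae) != sum(nres))
    stop("PAE dimension ", nrow(pae), " does not match total residue count ",
         sum(nres), " of ", pdb_path, call. = FALSE)

  model <- structure(
    list(chains = chains, pae = pae,
         provenance = list(pdb = pdb_path, pae = pae_path)),
    class = "fragment_model")
  strip_flanks(model, flank_length)
}

#' Read a PAE matrix from JSON
#'
#' @param pae_path path to a JSON file holding the matrix under the key
#'   `"predicted_aligned_error"` or `"pae"`, optionally inside a one-element
#'   list (both dialects occur among prediction servers).
#' @return A square numeric matrix (angstroms).
#' @export
read_pae <- function(pae_path) {
  obj <- jsonlite::read_json(pae_path, simplifyVector = TRUE)
  if (is.list(obj) && is.null(names(obj)) && length(obj) == 1L)
    obj <- obj[[1L]]
  key <- intersect(c("predicted_aligned_error", "pae"), names(obj))
  if (!length(key))
    stop("unknown PAE JSON dialect in ", pae_path, ": found keys {",
         paste(names(obj), collapse = ", "),
         "}, expected 'predicted_aligned_error' or 'pae'", call. = FALSE)
  m <- obj[[key[1L]]]
  if (is.list(m)) m <- do.call(rbind, lapply(m, unlist))
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || any(m < 0))
    stop("PAE matrix in ", pae_path, " must be square and non-negative",
         call. = FALSE)
  unname(m)
}

strip_flanks <- function(model, flank_length) {
  flank_length <- as.integer(flank_length)
  if (flank_length == 0L) return(model)
  nres <- nrow(model$chains[[1L]])
  if (2L * flank_length >= nres)
    stop("flank_length ", flank_length, " leaves no core residues (chain ",
         "length ", nres, ")", call. = FALSE)
  keep <- (flank_length + 1L):(nres - flank_length)
  model$chains <- lapply(model$chains, function(ch) {
    out <- ch[keep, , drop = FALSE]
    row.names(out) <- NULL
    out
  })
  if (!is.null(model$pae)) {
    idx <- as.vector(outer(keep, (seq_along(model$chains) - 1L) * nres, "+"))
    model$pae <- model$pae[idx, idx, drop = FALSE]
  }
  model
}

n_chains <- function(model) length(model$chains)
chain_length <- function(model) nrow(model$chains[[1L]])
ca_xyz <- function(chain) as.matrix(chain[, c("x", "y", "z")])
sc_xyz <- function(chain) {
  m <- as.matrix(chain[, c("sx", "sy", "sz")])
  colnames(m) <- c("x", "y", "z")
  m
}

#' Write a fragment model as a PDB file
#'
#' Emits one CA atom per residue with pLDDT in the B-factor column, plus a
#' CB pseudo-atom at the side-chain center, so that [read_model()]
#' round-trips coordinates (to PDB fixed-width precision, 1e-3 A) and pLDDT
#' (1e-2).
#'
#' @param model a `fragment_model`.
#' @param pdb_path output path.
#' @export
write_model <- function(model, pdb_path) {
  stopifnot(inherits(model, "fragment_model"))
  if (!length(model$chains) || !nrow(model$chains[[1L]]))
    stop("cannot write an empty model", call. = FALSE)
  ids <- c(LETTERS, letters, as.character(0:9))
  if (length(model$chains) > length(ids))
    stop("more than ", length(ids), " chains are not representable in PDB",
         call. = FALSE)
  xyz <- c(); resno <- c(); chain <- c(); elety <- c(); b <- c()
  for (k in seq_along(model$chains)) {
    ch <- model$chains[[k]]
    for (i in seq_len(nrow(ch))) {
      xyz <- c(xyz, ch$x[i], ch$y[i], ch$z[i], ch$sx[i], ch$sy[i], ch$sz[i])
      resno <- c(resno, ch$resno[i], ch$resno[i])
      chain <- c(chain, ids[k], ids[k])
      elety <- c(elety, "CA", "CB")
      b <- c(b, ch$plddt[i], ch$plddt[i])
    }
  }
  n <- length(resno)
  bio3d::write.pdb(file = pdb_path, xyz = xyz, resno = resno, chain = chain,
                   elety = elety, resid = rep("ALA", n), b = b,
                   o = rep(1, n), eleno = seq_len(n))
  invisible(pdb_path)
}
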