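#' Write synthetic prediction artifacts for a model
#'
#' Emits exactly the pair of files the integrator consumes for one
#' fragment: a PDB with per-residue pLDDT in the CA B-factor column and a
#' PAE JSON matrix in one of the common prediction-server dialects.
#'
#' @param model a `fragment_model`.
#' @param plddt_profile numeric vector (length = residues per chain) of
#'   pLDDT values written onto every chain, or `NULL` to keep the model's.
#' @param pae_value constant expected positional error (A) used to fill the
#'   PAE matrix, or a full square matrix over all residues; `NULL` writes
#'   no PAE file.
#' @param pdb_path,pae_path output paths (`pae_path` ignored when
#'   `pae_value` is `NULL`).
#' @param pae_dialect JSON key to write the matrix under.
#' @return Invisibly, the model actually written (with profiles applied).
#' @export
synthesize_prediction <- function(model, plddt_profile = NULL,
                                  pae_value = NULL, pdb_path,
                                  pae_path = NULL,
                                  pae_dialect = c("predicted_aligned_error",
                                                  "pae")) {
  pae_dialect <- match.arg(pae_dialect)
  L <- chain_length(model)
  if (!is.null(plddt_profile)) {
    if (length(plddt_profile) == 1L) plddt_profile <- rep(plddt_profile, L)
    if (length(plddt_profile) != L)
      stop("plddt_profile length ", length(plddt_profile),
           " does not match chain length ", L, call. = FALSE)
    model$chains <- lapply(model$chains, function(ch) {
      ch$plddt <- plddt_profile
      ch
    })
  }
  write_model(model, pdb_path)
  if (!is.null(pae_value)) {
    n <- L * n_chains(model)
    pae <- if (is.matrix(pae_value)) pae_value else
      matrix(pae_value, n, n)
    if (nrow(pae) != n || ncol(pae) != n)
      stop("PAE matrix must be ", n, "x", n, call. = FALSE)
    obj <- list()
    obj[[pae_dialect]] <- pae
    jsonlite::write_json(obj, pae_path, digits = NA)
    model$pae <- pae
  }
  invisible(model)
}

#' Ground-truth region layout for a designed sequence
#'
#' @param labels character vector of region classes, each one of
#'   `"parallel"`, `"antiparallel"`, `"unstructured"`.
#' @param lengths integer vector of region lengths (residues).
#' @return A data.frame with `label`, `start`, `end` (0-based half-open)
#'   tiling `[0, sum(lengths))`.
#' @export
region_layout <- function(labels, lengths) {
  labels <- match.arg(labels, c("parallel", "antiparallel", "unstructured"),
                      several.ok = TRUE)
  if (length(labels) != length(lengths))
    stop("labels and lengths differ in length", call. = FALSE)
  ends <- cumsum(as.integer(lengths))
  data.frame(label = labels, start = c(0L, ends[-length(ends)]) , end = ends,
             stringsAsFactors = FALSE)
}

# Designed sequence for a layout: heptad-patterned residues in coiled-coil
# regions, glycine/serine-rich elsewhere. Content is cosmetic (synthetic
# models ignore sequence) but keeps queries realistic.
design_sequence <- function(layout) {
  heptad <- c("E", "I", "A", "A", "L", "E", "K")   # a-d core at 1 and 4
  loop <- c("G", "S", "G", "S", "P", "G", "S", "T")
  paste(unlist(lapply(seq_len(nrow(layout)), function(i) {
    n <- layout$end[i] - layout$start[i]
    src <- if (layout$label[i] == "unstructured") loop else heptad
    rep_len(src, n)
  })), collapse = "")
}

# Majority ground-truth label of a window [start, end) under a layout.
window_label <- function(layout, start, end) {
  cover <- pmax(0L, pmin(layout$end, end) - pmax(layout$start, start))
  layout$label[which.max(cover)]
}

#' Build a complete fake prediction run
#'
#' Stands in for the structure-prediction step at desk scale: designs a
#' sequence from a ground-truth region layout, divides it under the given
#' specifications, and synthesizes one model per fragment according to the
#' majority label of its window — a parallel Crick bundle, an antiparallel
#' bundle, or extended non-interacting chains. Confidence artifacts encode
#' region quality: coiled-coil regions get high pLDDT and low PAE,
#' unstructured regions low pLDDT and high PAE. Deterministic given `seed`.
#'
#' @param layout a [region_layout()] data.frame.
#' @param specs a `fragment_spec` or list of them.
#' @param outdir run directory; models are written under `outdir/models`.
#' @param seed integer seed driving all randomness (coordinate noise).
#' @param noise_sd coordinate noise (A) added to every synthetic model.
#' @param plddt_cc,plddt_loop pLDDT written in coiled-coil / unstructured
#'   regions.
#' @param pae_cc,pae_loop constant PAE (A) for the two region classes.
#' @return Invisibly, a list with the run `manifest`, the designed
#'   `sequence`, the `layout`, and `models_dir`.
#' @export
build_fake_run <- function(layout, specs, outdir, seed = 1L,
                           noise_sd = 0.2, plddt_cc = 90, plddt_loop = 40,
                           pae_cc = 3, pae_loop = 20) {
  if (inherits(specs, "fragment_spec")) specs <- list(specs)
  sequence <- design_sequence(layout)
  manifest <- divide_sequence(sequence, specs, outdir, seq_id = "design")
  models_dir <- file.path(outdir, "models")
  dir.create(models_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  by_label <- vapply(specs, function(s) s$label, "")
  for (i in seq_len(nrow(manifest))) {
    spec <- specs[[match(manifest$spec_label[i], by_label)]]
    lab <- window_label(layout, manifest$start[i], manifest$end[i])
    n_res <- manifest$core_length[i] + 2L * manifest$flank_length[i]
    model <- switch(lab,
      parallel = crick_backbone(
        crick_params(spec$n_copies, n_res, orientation = 1L,
                     R0 = if (spec$n_copies >= 4L) 6.3 else 4.9),
        noise_sd = noise_sd),
      antiparallel = crick_backbone(
        crick_params(spec$n_copies, n_res,
                     orientation = rep_len(c(1L, -1L), spec$n_copies),
                     R0 = if (spec$n_copies >= 4L) 6.3 else 4.9),
        noise_sd = noise_sd),
      unstructured = extended_chains(spec$n_copies, n_res,
                                     noise_sd = noise_sd))
    is_cc <- lab != "unstructured"
    stem <- sub("\\.fasta$", "", manifest$query_file[i])
    synthesize_prediction(
      model,
      plddt_profile = if (is_cc) plddt_cc else plddt_loop,
      pae_value = if (is_cc) pae_cc else pae_loop,
      pdb_path = file.path(models_dir, paste0(stem, ".pdb")),
      pae_path = file.path(models_dir, paste0(stem, ".pae.json")))
  }
  run_params <- jsonlite::read_json(file.path(outdir, "parameters.json"))
  run_params$seed <- seed
  run_params$layout <- layout
  jsonlite::write_json(run_params, file.path(outdir, "parameters.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, sequence = sequence, layout = layout,
                 models_dir = models_dir))
}
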