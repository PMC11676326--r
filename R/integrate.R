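reducer_fun <- function(reducer = c("mean", "min", "max", "median")) {
  reducer <- match.arg(reducer)
  switch(reducer,
         mean = function(x) mean(x),
         min = function(x) min(x),
         max = function(x) max(x),
         median = function(x) stats::median(x))
}

#' Flatten per-fragment feature vectors onto the full-length sequence
#'
#' Each fragment contributes its feature vector at the full-length
#' positions its window covers; where windows overlap, the contributions
#' are flattened with the reducer (default: arithmetic mean). For the
#' orientation feature (parallel = 1, antiparallel = 0) a flattened value
#' of 0.5 therefore means half of the covering models were parallel and
#' half antiparallel — the local sequence does not encode a topology. A
#' fragment with a missing feature (e.g. no PAE file) is excluded from that
#' feature's flattening but still counts toward `coverage` if its model
#' exists.
#'
#' @param manifest division manifest (data.frame from [divide_sequence()]
#'   or [read_manifest()]), possibly restricted to one spec.
#' @param fragment_values named list: for each feature name, a list of
#'   numeric vectors indexed like the manifest rows (NULL where missing);
#'   each vector must have length `end - start` of its fragment.
#' @param sequence_length full-length sequence length.
#' @param reducer flattening strategy: `"mean"` (default), `"min"`,
#'   `"max"`, or `"median"`.
#' @return A data.frame keyed by (`position` 1-based, `spec_label`) with
#'   one column per feature plus `coverage`, the number of fragment models
#'   covering the position.
#' @export
integrate_features <- function(manifest, fragment_values, sequence_length,
                               reducer = "mean") {
  red <- reducer_fun(reducer)
  specs <- unique(manifest$spec_label)
  features <- names(fragment_values)
  out <- list()
  for (sp in specs) {
    idx <- which(manifest$spec_label == sp)
    tbl <- data.frame(position = seq_len(sequence_length), spec_label = sp,
                      coverage = 0L, stringsAsFactors = FALSE)
    present <- rep(FALSE, length(idx))
    for (f in features)
      present <- present |
        !vapply(fragment_values[[f]][idx], is.null, TRUE)
    for (i in seq_along(idx)) {
      row <- idx[i]
      if (present[i]) {
        pos <- (manifest$start[row] + 1L):manifest$end[row]
        tbl$coverage[pos] <- tbl$coverage[pos] + 1L
      }
    }
    for (f in features) {
      acc <- vector("list", sequence_length)
      for (i in seq_along(idx)) {
        row <- idx[i]
        v <- fragment_values[[f]][[row]]
        if (is.null(v)) next
        span <- manifest$end[row] - manifest$start[row]
        if (length(v) != span)
          stop("feature '", f, "' of fragment ", manifest$fragment_index[row],
               " (spec ", sp, ") has length ", length(v),
               " but its window spans ", span, " residues", call. = FALSE)
        for (j in seq_len(span)) {
          p <- manifest$start[row] + j
          acc[[p]] <- c(acc[[p]], v[j])
        }
      }
      tbl[[f]] <- vapply(acc, function(x)
        if (is.null(x)) NA_real_ else red(x), 0)
    }
    out[[sp]] <- tbl
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  class(res) <- c("residue_feature_table", "data.frame")
  res
}

#' Run the full integration over a division run directory
#'
#' Reads `parameters.json` and `constructs.csv` from a run directory,
#' loads each fragment's model (`<query stem>.pdb`, with PAE from
#' `<query stem>.pae.json` when present) from the models directory, strips
#' flanks, computes the requested features, and flattens them into the
#' per-residue table. Fragments whose model file is absent are skipped with
#' a warning and simply reduce coverage.
#'
#' @param rundir division run directory.
#' @param models_dir directory of model files (default `rundir/models`).
#' @param features features to compute (see [fragment_features()]).
#' @param reducer flattening strategy, see [integrate_features()].
#' @param contact_cutoff knobs-into-holes packing cutoff (angstroms).
#' @return A `residue_feature_table` data.frame.
#' @export
integrate_run <- function(rundir, models_dir = file.path(rundir, "models"),
                          features = c("plddt", "pae", "orientation", "kih"),
                          reducer = "mean", contact_cutoff = 7.0) {
  run <- read_manifest(rundir)
  manifest <- run$manifest
  sequence_length <- nchar(run$params$sequence)
  vals <- stats::setNames(
    lapply(features, function(f) vector("list", nrow(manifest))), features)
  for (i in seq_len(nrow(manifest))) {
    stem <- sub("\\.fasta$", "", manifest$query_file[i])
    pdb <- file.path(models_dir, paste0(stem, ".pdb"))
    if (!file.exists(pdb)) {
      warning("model file missing for fragment ", manifest$fragment_index[i],
              " of spec ", manifest$spec_label[i], " (", pdb,
              "); coverage reduced", call. = FALSE)
      next
    }
    pae <- file.path(models_dir, paste0(stem, ".pae.json"))
    model <- read_model(pdb, pae_path = if (file.exists(pae)) pae else NULL,
                        flank_length = manifest$flank_length[i])
    fv <- fragment_features(model, features = features,
                            contact_cutoff = contact_cutoff)
    for (f in features) vals[[f]][[i]] <- fv[[f]]
  }
  integrate_features(manifest, vals, sequence_length, reducer = reducer)
}

#' Write a per-residue feature table as CSV
#'
#' @param table a `residue_feature_table`.
#' @param path output CSV path.
#' @export
write_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a per-residue feature table written by [write_table()]
#'
#' @param path CSV path.
#' @return A `residue_feature_table`.
#' @export
read_table <- function(path) {
  res <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(res) <- c("residue_feature_table", "data.frame")
  res
}

#' Graphical summary of an integrated feature table
#'
#' One stacked panel per feature, one trace per specification, over
#' full-length sequence position — the scanning view of where the sequence
#' supports confident, well-packed, consistently oriented coiled-coil
#' fragments.
#'
#' @param table a `residue_feature_table`.
#' @param path output image path (extension selects the device, e.g.
#'   `.png`, `.svg`, `.pdf`); `NULL` returns the plot object only.
#' @param width,height device size in inches.
#' @return The ggplot object, invisibly.
#' @export
plot_summary <- function(table, path = NULL, width = 9, height = 7) {
  stopifnot(nrow(table) > 0)
  feature_cols <- setdiff(names(table),
                          c("position", "spec_label", "coverage"))
  keep <- feature_cols[vapply(feature_cols, function(f)
    any(is.finite(table[[f]])), TRUE)]
  dropped <- setdiff(feature_cols, keep)
  if (length(dropped))
    message("omitting empty feature panel(s): ",
            paste(dropped, collapse = ", "))
  if (!length(keep)) stop("no non-empty feature columns", call. = FALSE)
  long <- do.call(rbind, lapply(keep, function(f)
    data.frame(position = table$position, spec_label = table$spec_label,
               feature = f, value = table[[f]])))
  gg <- ggplot2::ggplot(long,
          ggplot2::aes(x = position, y = value, colour = spec_label)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(feature),
                        scales = "free_y") +
    ggplot2::labs(x = "sequence position", y = NULL,
                  colour = "specification") +
    ggplot2::theme_minimal()
  if (!is.null(path))
    ggplot2::ggsave(path, gg, width = width, height = height)
  invisible(gg)
}
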