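#' Fragmentation specifications
#'
#' A fragmentation specification is the recipe "N_L_O": model each window of
#' `window_length` (L) residues as a homo-oligomer of `n_copies` (N) chains,
#' with consecutive windows sharing `overlap` (O) residues. An optional
#' flanking adaptor sequence is attached to both termini of every window to
#' promote folding of the isolated fragment; it is stripped again before
#' feature integration.
#'
#' @param n_copies integer, oligomeric state of each query (N >= 1).
#' @param window_length integer, residues per window (L >= 1).
#' @param overlap integer, residues shared by consecutive windows
#'   (0 <= O <= L - 1, so that the step L - O is at least 1).
#' @param flank amino-acid string attached N- and C-terminally to each
#'   window ("" for none).
#' @return An object of class `fragment_spec`.
#' @examples
#' fragment_spec(2, 30, 15)
#' parse_spec("2_30_15")
#' @export
fragment_spec <- function(n_copies, window_length, overlap, flank = "") {
  n_copies <- as.integer(n_copies)
  window_length <- as.integer(window_length)
  overlap <- as.integer(overlap)
  if (is.na(n_copies) || n_copies < 1L)
    stop("n_copies must be an integer >= 1, got ", n_copies, call. = FALSE)
  if (is.na(window_length) || window_length < 1L)
    stop("window_length must be an integer >= 1, got ", window_length,
         call. = FALSE)
  if (is.na(overlap) || overlap < 0L)
    stop("overlap must be a non-negative integer, got ", overlap,
         call. = FALSE)
  if (overlap > window_length - 1L)
    stop("overlap must be <= window_length - 1 (got O = ", overlap,
         ", L = ", window_length, "): the window step L - O must be >= 1",
         call. = FALSE)
  if (nchar(flank) > 0L) validate_aa(flank, what = "flank")
  structure(
    list(n_copies = n_copies, window_length = window_length,
         overlap = overlap, flank = flank,
         label = paste(n_copies, window_length, overlap, sep = "_")),
    class = "fragment_spec")
}

#' Parse an "N_L_O" specification label
#'
#' @param label string of the form `"N_L_O"`, e.g. `"2_30_15"`: 30-residue
#'   windows with 15-residue overlap, modeled as a dimer.
#' @param flank optional flanking adaptor sequence, see [fragment_spec()].
#' @return A `fragment_spec`.
#' @export
parse_spec <- function(label, flank = "") {
  if (length(label) != 1L || !is.character(label))
    stop("spec label must be a single string", call. = FALSE)
  parts <- strsplit(label, "_", fixed = TRUE)[[1L]]
  if (length(parts) != 3L || !all(grepl("^[0-9]+$", parts))) {
    bad <- if (length(parts)) parts[!grepl("^[0-9]+$", parts)] else label
    stop("malformed spec label '", label,
         "': expected N_L_O with integer fields; offending token(s): ",
         paste(sQuote(if (length(bad)) bad else label), collapse = ", "),
         call. = FALSE)
  }
  fragment_spec(as.integer(parts[1L]), as.integer(parts[2L]),
                as.integer(parts[3L]), flank = flank)
}

#' @export
format.fragment_spec <- function(x, ...) x$label

#' @export
print.fragment_spec <- function(x, ...) {
  cat(sprintf("fragment spec %s: %d-mer, %d-residue windows, %d overlap",
              x$label, x$n_copies, x$window_length, x$overlap))
  if (nchar(x$flank)) cat(sprintf(", flank '%s'", x$flank))
  cat("\n")
  invisible(x)
}

#' Window a sequence under a specification
#'
#' Windows start at 0, s, 2s, ... with step s = L - O. If the final regular
#' window would run past the end of the sequence, the window length is given
#' priority: that window is replaced by the single window ending exactly at
#' the C-terminus, so its overlap with the previous window grows beyond O.
#' If the sequence is shorter than L, a single full-sequence window is
#' returned with a warning.
#'
#' @param sequence_length integer length of the full sequence.
#' @param spec a `fragment_spec`.
#' @return A data.frame with 0-based half-open columns `start`, `end`, one
#'   row per window in N-to-C order.
#' @examples
#' make_windows(90, fragment_spec(2, 50, 25))
#' @export
make_windows <- function(sequence_length, spec) {
  stopifnot(inherits(spec, "fragment_spec"))
  sequence_length <- as.integer(sequence_length)
  if (is.na(sequence_length) || sequence_length < 1L)
    stop("sequence_length must be >= 1", call. = FALSE)
  L <- spec$window_length
  if (sequence_length < L) {
    warning("sequence length ", sequence_length, " < window length ", L,
            " for spec ", spec$label,
            ": emitting a single full-sequence window", call. = FALSE)
    return(data.frame(start = 0L, end = sequence_length))
  }
  step <- L - spec$overlap
  starts <- seq.int(0L, sequence_length - L, by = step)
  # C-terminal priority: keep L fixed, grow the last overlap instead
  if (starts[length(starts)] + L < sequence_length)
    starts <- c(starts, sequence_length - L)
  data.frame(start = as.integer(starts), end = as.integer(starts + L))
}

validate_aa <- function(sequence, what = "sequence") {
  if (!nzchar(sequence)) stop("empty ", what, call. = FALSE)
  chars <- strsplit(sequence, "")[[1L]]
  ok <- chars %in% strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1L]]
  if (!all(ok))
    stop("invalid amino-acid character(s) in ", what, " at position(s) ",
         paste(which(!ok), collapse = ", "), ": ",
         paste(sQuote(unique(chars[!ok])), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

query_file_name <- function(seq_id, label, fragment_index) {
  sprintf("%s__%s__f%04d.fasta", seq_id, label, fragment_index)
}

#' Divide a sequence and write the query bundle
#'
#' For every specification, windows the sequence, attaches the flank, and
#' writes one multimer FASTA query per fragment, plus a constructs table and
#' a parameters file. The written run directory is self-contained: the
#' integrator needs nothing else to map fragment models back to full-length
#' coordinates.
#'
#' @param sequence full-length amino-acid string (20 canonical letters + X).
#' @param specs a `fragment_spec` or list of them.
#' @param outdir run directory to create (holds `queries/`,
#'   `constructs.csv`, `parameters.json`).
#' @param seq_id identifier for the sequence, used in file names.
#' @param multimer_dialect `"colon"` writes one FASTA record per query with
#'   the chain repeated N times joined by ':' (the common prediction-server
#'   dialect); `"records"` writes one record per chain copy.
#' @return Invisibly, the division manifest: a data.frame with one row per
#'   fragment (columns `spec_label`, `fragment_index`, `start`, `end`,
#'   `core_length`, `flank_length`, `query_file`; coordinates 0-based
#'   half-open in memory, written 1-based inclusive to `constructs.csv`).
#' @export
divide_sequence <- function(sequence, specs, outdir, seq_id = "query",
                            multimer_dialect = c("colon", "records")) {
  multimer_dialect <- match.arg(multimer_dialect)
  validate_aa(sequence)
  if (inherits(specs, "fragment_spec")) specs <- list(specs)
  if (!length(specs) || !all(vapply(specs, inherits, TRUE, "fragment_spec")))
    stop("specs must be one or more fragment_spec objects", call. = FALSE)
  labels <- vapply(specs, function(s) s$label, "")
  if (anyDuplicated(labels))
    stop("duplicate spec labels: ",
         paste(labels[duplicated(labels)], collapse = ", "), call. = FALSE)

  dir.create(file.path(outdir, "queries"), recursive = TRUE,
             showWarnings = FALSE)
  rows <- list()
  for (spec in specs) {
    win <- make_windows(nchar(sequence), spec)
    for (i in seq_len(nrow(win))) {
      core <- substr(sequence, win$start[i] + 1L, win$end[i])
      query <- paste0(spec$flank, core, spec$flank)
      qfile <- query_file_name(seq_id, spec$label, i - 1L)
      write_query_fasta(
        file.path(outdir, "queries", qfile),
        id = sub("\\.fasta$", "", qfile),
        chain = query, n_copies = spec$n_copies, dialect = multimer_dialect)
      rows[[length(rows) + 1L]] <- data.frame(
        spec_label = spec$label, fragment_index = i - 1L,
        start = win$start[i], end = win$end[i],
        core_length = nchar(core), flank_length = nchar(spec$flank),
        query_file = qfile, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)

  constructs <- data.frame(
    spec_label = manifest$spec_label,
    fragment_index = manifest$fragment_index,
    start_1based = manifest$start + 1L,
    end_1based = manifest$end,
    core_length = manifest$core_length,
    flank_length = manifest$flank_length,
    query_file = manifest$query_file, stringsAsFactors = FALSE)
  utils::write.csv(constructs, file.path(outdir, "constructs.csv"),
                   row.names = FALSE, quote = FALSE)

  params <- list(
    seq_id = seq_id, sequence = sequence,
    specs = lapply(specs, function(s)
      list(label = s$label, n_copies = s$n_copies,
           window_length = s$window_length, overlap = s$overlap,
           flank = s$flank)),
    multimer_dialect = multimer_dialect,
    tool = "coilscan", version = as.character(utils::packageVersion("coilscan")))
  jsonlite::write_json(params, file.path(outdir, "parameters.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

write_query_fasta <- function(path, id, chain, n_copies, dialect) {
  seqs <- switch(dialect,
    colon = {
      x <- Biostrings::BStringSet(paste(rep(chain, n_copies), collapse = ":"))
      names(x) <- id
      x
    },
    records = {
      x <- Biostrings::BStringSet(rep(chain, n_copies))
      names(x) <- paste0(id, "_chain", seq_len(n_copies))
      x
    })
  Biostrings::writeXStringSet(seqs, path, width = 80L)
}

#' Read a division run directory back into a manifest
#'
#' @param rundir directory written by [divide_sequence()].
#' @return A list with elements `params` (the parameters file as a list) and
#'   `manifest` (data.frame in the in-memory 0-based convention).
#' @export
read_manifest <- function(rundir) {
  pfile <- file.path(rundir, "parameters.json")
  cfile <- file.path(rundir, "constructs.csv")
  if (!file.exists(pfile) || !file.exists(cfile))
    stop("not a division run directory (missing parameters.json or ",
         "constructs.csv): ", rundir, call. = FALSE)
  params <- jsonlite::read_json(pfile, simplifyVector = FALSE)
  con <- utils::read.csv(cfile, stringsAsFactors = FALSE)
  manifest <- data.frame(
    spec_label = con$spec_label, fragment_index = con$fragment_index,
    start = con$start_1based - 1L, end = con$end_1based,
    core_length = con$core_length, flank_length = con$flank_length,
    query_file = con$query_file, stringsAsFactors = FALSE)
  list(params = params, manifest = manifest)
}
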