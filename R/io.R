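#' Read subunit sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readAAStringSet()]; record ids (first
#' whitespace-delimited token of the header) become chain names.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta_chains <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  ss <- Biostrings::readAAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
  seqs
}

#' Read an observed MS peak list
#'
#' CSV with columns `mz` and `z`.
#'
#' @param path CSV path.
#' @export
read_peaks_csv <- function(path) {
  if (!file.exists(path)) stop("peak list not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("mz", "z") %in% names(df))) {
    stop("peak list must have columns mz, z", call. = FALSE)
  }
  df
}

#' Read a binary mask stored as a CSV matrix
#'
#' Comma-separated 0/1 matrix, no header; nonzero = foreground.
#'
#' @param path CSV path.
#' @export
read_mask_csv <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path, call. = FALSE)
  as.matrix(utils::read.csv(path, header = FALSE))
}

# TSV writer used by the CLI: '.' decimal separator, no quoting
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# run manifest written alongside every CLI output
write_manifest <- function(out_path, subcommand, params) {
  manifest <- list(
    tool = "sslock",
    version = as.character(utils::packageVersion("sslock")),
    subcommand = subcommand,
    params = params,
    timestamp = format(Sys.time(), tz = "UTC", "%Y-%m-%dT%H:%M:%SZ")
  )
  jsonlite::write_json(manifest, paste0(out_path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
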