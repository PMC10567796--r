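#' Read labeled sequences from FASTA
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped lines) and encodes
#' every record with [encode_sequence()]. Binary class labels are resolved
#' either from a sidecar TSV (`id<TAB>label`, no header; the preferred route)
#' or from a `|label` suffix on the FASTA header.
#'
#' @param path FASTA file.
#' @param alphabet A [make_alphabet()] object.
#' @param labels Either `NULL` (labels taken from header suffixes of the form
#'   `id|label`, or left `NA` if absent), the path to a two-column TSV, or a
#'   named vector/list keyed by sequence id.
#' @return A list of `encoded_seq` objects in file order.
#' @export
read_fasta <- function(path, alphabet, labels = NULL) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\|.*$", "", sub("\\s.*$", "", headers))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  label_map <- NULL
  if (is.character(labels) && length(labels) == 1L) {
    tab <- utils::read.table(labels, sep = "\t", header = FALSE,
                             colClasses = c("character", "integer"),
                             col.names = c("id", "label"))
    label_map <- stats::setNames(tab$label, tab$id)
  } else if (!is.null(labels)) {
    label_map <- unlist(labels)
  }
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    lab <- NA_integer_
    if (!is.null(label_map)) {
      if (!ids[i] %in% names(label_map)) {
        stop("no label found for sequence id '", ids[i], "'")
      }
      lab <- as.integer(label_map[[ids[i]]])
    } else {
      token <- sub("^[^|]*\\|?", "", sub("\\s.*$", "", headers[i]))
      if (nzchar(token)) {
        lab <- suppressWarnings(as.integer(token))
        if (is.na(lab)) stop("unresolvable label token '", token,
                             "' on header '", headers[i], "'")
      }
    }
    out[[i]] <- encode_sequence(as.character(set[[i]]), alphabet,
                                id = ids[i],
                                label = if (is.na(lab)) NULL else lab)
  }
  out
}

#' Write sequences and labels to FASTA plus sidecar TSV
#'
#' @param seqs Character vector of residue strings, named by id (unnamed
#'   sequences get ids `seq1, seq2, ...`).
#' @param labels Integer labels, same length as `seqs`, or `NULL`.
#' @param fasta Output FASTA path.
#' @param label_path Output TSV path (ignored when `labels` is `NULL`).
#' @return Invisibly, the FASTA path.
#' @export
write_fasta <- function(seqs, labels = NULL, fasta, label_path = NULL) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  con <- file(fasta, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", ids[i]), seqs[[i]]), con)
  }
  if (!is.null(labels) && !is.null(label_path)) {
    utils::write.table(data.frame(id = ids, label = as.integer(labels)),
                       label_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(fasta)
}

#' Extract labels from a list of encoded sequences
#' @param data List of `encoded_seq`.
#' @return Integer vector of labels.
#' @export
sequence_labels <- function(data) {
  vapply(data, function(s) {
    if (is.null(s$label)) NA_integer_ else as.integer(s$label)
  }, integer(1))
}
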