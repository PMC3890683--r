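# Labelled, aligned barcode data: construction, FASTA I/O, coding-frame QC,
# and tabular report export.

.IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "N", "-")

#' Construct a labelled barcode dataset
#'
#' A \code{barcode_dataset} holds an aligned, equal-length collection of
#' barcode sequences together with their specimen, species, genus and
#' (optional) population labels, plus the set of specimen ids that act as
#' outgroup. Every analysis in the package runs over this container.
#'
#' @param records a data.frame with columns \code{specimen_id},
#'   \code{species}, \code{genus}, \code{sequence} and optionally
#'   \code{population} (\code{NA} where absent). Sequences must be uppercase
#'   IUPAC nucleotide strings (gaps allowed as \code{-}) of equal length.
#' @param outgroup_ids character vector of specimen ids used to root trees;
#'   outgroup sequences are excluded from intra/interspecific pools and from
#'   leave-one-out queries.
#' @return an object of class \code{barcode_dataset}: a list with elements
#'   \code{records}, \code{alignment_length} and \code{outgroup_ids}.
#' @examples
#' rec <- data.frame(specimen_id = c("X1", "X2"),
#'                   species = "Urophora cardui", genus = "Urophora",
#'                   population = NA_character_,
#'                   sequence = c("ACGTACGT", "ACGTACGA"))
#' d <- barcode_dataset(rec)
#' @export
barcode_dataset <- function(records, outgroup_ids = character()) {
  stopifnot(is.data.frame(records))
  needed <- c("specimen_id", "species", "genus", "sequence")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("records is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!"population" %in% names(records)) records$population <- NA_character_
  records <- records[, c("specimen_id", "species", "genus", "population", "sequence")]
  for (col in names(records)) records[[col]] <- as.character(records[[col]])
  rownames(records) <- NULL

  if (nrow(records) == 0L) stop("dataset must contain at least one record")
  if (anyDuplicated(records$specimen_id)) {
    dup <- unique(records$specimen_id[duplicated(records$specimen_id)])
    stop("duplicate specimen_id(s): ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(records$specimen_id) | is.na(records$specimen_id)))
    stop("every record needs a non-empty specimen_id")
  if (any(!nzchar(records$species) | is.na(records$species)) ||
      any(!nzchar(records$genus) | is.na(records$genus)))
    stop("every record needs non-empty species and genus labels")
  if (any(!nzchar(records$sequence) | is.na(records$sequence)))
    stop("every record needs a non-empty sequence")

  records$sequence <- toupper(records$sequence)
  lens <- nchar(records$sequence)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1L])
    stop("sequences are not all the same length; deviant record(s): ",
         paste(sprintf("%s (#%d, %d bp vs %d bp)", records$specimen_id[bad],
                       bad, lens[bad], lens[1L]), collapse = ", "))
  }
  bad_chars <- vapply(strsplit(records$sequence, ""), function(s)
    any(!s %in% .IUPAC_CHARS), logical(1L))
  if (any(bad_chars))
    stop("non-IUPAC characters in sequence of record(s): ",
         paste(records$specimen_id[bad_chars], collapse = ", "))

  # one genus per species
  map <- unique(records[, c("species", "genus")])
  if (anyDuplicated(map$species)) {
    dup <- map$species[duplicated(map$species)]
    stop("species mapped to more than one genus: ", paste(dup, collapse = ", "))
  }
  outgroup_ids <- as.character(outgroup_ids)
  unknown <- setdiff(outgroup_ids, records$specimen_id)
  if (length(unknown))
    stop("outgroup_ids not present in records: ", paste(unknown, collapse = ", "))

  structure(list(records = records,
                 alignment_length = lens[1L],
                 outgroup_ids = outgroup_ids),
            class = "barcode_dataset")
}

#' @export
print.barcode_dataset <- function(x, ...) {
  ing <- ingroup_ids(x)
  sp <- unique(x$records$species[x$records$specimen_id %in% ing])
  ge <- unique(x$records$genus[x$records$specimen_id %in% ing])
  cat(sprintf("barcode_dataset: %d sequences (%d ingroup, %d outgroup)\n",
              nrow(x$records), length(ing), length(x$outgroup_ids)))
  cat(sprintf("  %d ingroup species in %d genera; alignment length %d bp\n",
              length(sp), length(ge), x$alignment_length))
  invisible(x)
}

#' Read a labelled barcode alignment from FASTA
#'
#' Headers carry delimiter-separated metadata fields in a configurable order,
#' by default \code{specimen_id|species|genus|population} with the population
#' field optional. Validation is total: malformed headers, duplicate ids and
#' unequal sequence lengths all raise diagnostics naming the offending
#' record, never a silently truncated dataset.
#'
#' @param path path to an aligned FASTA file.
#' @param header_schema character vector naming the header fields in order;
#'   must contain \code{specimen_id}, \code{species} and \code{genus};
#'   a trailing \code{population} field may be omitted per record.
#' @param delim single-character field delimiter in headers.
#' @param outgroup_ids specimen ids to mark as outgroup.
#' @return a \code{\link{barcode_dataset}} preserving input order.
#' @export
read_barcode_fasta <- function(path,
                               header_schema = c("specimen_id", "species",
                                                 "genus", "population"),
                               delim = "|",
                               outgroup_ids = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  required <- c("specimen_id", "species", "genus")
  if (!all(required %in% header_schema))
    stop("header_schema must contain specimen_id, species and genus")
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) stop("cannot parse FASTA '", path,
                                            "': ", conditionMessage(e)))
  if (length(seqs) == 0L) stop("'", path, "' contains no sequences")

  headers <- names(seqs)
  n_req <- max(match(required, header_schema))
  fields <- strsplit(headers, delim, fixed = TRUE)
  rec <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    f <- trimws(fields[[i]])
    if (length(f) < n_req || length(f) > length(header_schema))
      stop(sprintf("malformed header in record %d ('%s'): expected %d-%d '%s'-separated fields, got %d",
                   i, headers[i], n_req, length(header_schema), delim, length(f)))
    row <- as.list(rep(NA_character_, length(header_schema)))
    names(row) <- header_schema
    row[seq_along(f)] <- f
    rec[[i]] <- row
  }
  records <- do.call(rbind, lapply(rec, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  records$sequence <- as.character(seqs)
  barcode_dataset(records, outgroup_ids = outgroup_ids)
}

#' Write a barcode dataset to FASTA
#'
#' Inverse of \code{\link{read_barcode_fasta}}: headers are rebuilt from the
#' record labels (population omitted where \code{NA}), so a read/write
#' round-trip reproduces ids, labels and sequences exactly.
#'
#' @param dataset a \code{barcode_dataset}.
#' @param path output file path.
#' @param delim header field delimiter.
#' @return \code{path}, invisibly.
#' @export
write_barcode_fasta <- function(dataset, path, delim = "|") {
  stopifnot(inherits(dataset, "barcode_dataset"))
  r <- dataset$records
  hdr <- ifelse(is.na(r$population),
                paste(r$specimen_id, r$species, r$genus, sep = delim),
                paste(r$specimen_id, r$species, r$genus, r$population, sep = delim))
  x <- Biostrings::DNAStringSet(r$sequence)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Check a dataset for gaps and internal stop codons
#'
#' Barcode alignments of protein-coding COI should be free of indels and
#' internal stop codons; their presence usually indicates a pseudogene
#' (numt) or an alignment problem. This is a pure per-record QC report and
#' never mutates the data. Codons containing gaps or ambiguity codes cannot
#' be called and are skipped; the final complete codon is not counted as
#' internal.
#'
#' @param dataset a \code{barcode_dataset}.
#' @param genetic_code NCBI genetic-code id or name accepted by
#'   \code{Biostrings::getGeneticCode}; default \code{"5"}, the invertebrate
#'   mitochondrial code conventional for COI barcodes.
#' @param frame reading-frame offset, 0, 1 or 2.
#' @return data.frame with one row per record: \code{specimen_id},
#'   \code{n_internal_stops}, \code{has_stop}, \code{n_gaps},
#'   \code{has_gaps}.
#' @export
check_coding_frame <- function(dataset, genetic_code = "5", frame = 0) {
  stopifnot(inherits(dataset, "barcode_dataset"))
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2")
  code <- tryCatch(Biostrings::getGeneticCode(as.character(genetic_code)),
                   error = function(e) stop("unknown genetic code '",
                                            genetic_code, "'"))
  stop_codons <- names(code)[code == "*"]
  r <- dataset$records
  res <- lapply(seq_len(nrow(r)), function(i) {
    s <- r$sequence[i]
    n_gaps <- lengths(regmatches(s, gregexpr("-", s, fixed = TRUE)))
    body <- substring(s, frame + 1L)
    n_codons <- nchar(body) %/% 3L
    n_stop <- 0L
    if (n_codons > 1L) {
      starts <- seq.int(1L, by = 3L, length.out = n_codons - 1L)  # internal only
      codons <- substring(body, starts, starts + 2L)
      callable <- grepl("^[ACGT]{3}$", codons)
      n_stop <- sum(codons[callable] %in% stop_codons)
    }
    data.frame(specimen_id = r$specimen_id[i],
               n_internal_stops = n_stop, has_stop = n_stop > 0L,
               n_gaps = n_gaps, has_gaps = n_gaps > 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Write a tabular report to TSV or JSON
#'
#' Deterministic export used by every reporting surface of the package:
#' column order is preserved, floats are rendered at a fixed configured
#' precision, line endings are LF, and writing the same report twice yields
#' byte-identical files.
#'
#' @param report a data.frame (an empty one yields a header-only TSV).
#' @param path output file path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @param digits number of significant decimal places for numeric columns.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "json"), digits = 6) {
  if (is.null(report)) stop("report is NULL")
  format <- match.arg(format)
  report <- as.data.frame(report)
  if (format == "json") {
    jsonlite::write_json(report, path, dataframe = "rows", na = "null",
                         digits = digits, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(path))
  }
  out <- report
  for (col in names(out)) {
    if (is.double(out[[col]]))
      out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                           formatC(out[[col]], digits = digits, format = "f"))
  }
  con <- file(path, open = "wb")  # binary: force LF on every platform
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con, sep = "\n")
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con, sep = "\n")
  invisible(path)
}
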