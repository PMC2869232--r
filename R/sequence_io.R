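#' Read a FASTA file
#'
#' Reads all records, uppercases the sequences, and flags (but keeps)
#' characters outside the alphabet. Ambiguity codes, `X`, `*` and gap
#' characters are retained in place: the k-mer counting stage skips any
#' window overlapping them, so no artificial junction strings are created.
#'
#' @param path Path to a FASTA file (plain or gzipped).
#' @param alphabet A `dl_alphabet`, used only to flag non-alphabet characters.
#' @return A data.frame with columns `header`, `sequence` (uppercase) and
#'   `has_invalid` (logical), in file order.
#' @export
read_fasta <- function(path, alphabet = dna_alphabet()) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  headers <- names(set)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("FASTA record with empty sequence: ",
         paste(headers[empty], collapse = ", "))
  }
  ok <- paste(alphabet$letters, collapse = "")
  has_invalid <- grepl(sprintf("[^%s]", ok), seqs)
  data.frame(header = headers, sequence = unname(seqs),
             has_invalid = has_invalid, stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param records A data.frame with columns `header` and `sequence`, or a
#'   `genome_record` (headers are then `id|1`, `id|2`, ...).
#' @param path Output path.
#' @param width Line width for wrapping.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "genome_record")) {
    records <- data.frame(
      header = paste0(records$genome_id, "|", seq_along(records$sequences)),
      sequence = records$sequences, stringsAsFactors = FALSE)
  }
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$header
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Assemble a per-genome sequence collection
#'
#' A genome enters the analysis as an ordered set of sequences: a single
#' whole-genome sequence (or several replicons) in `WHOLE_DNA` mode, or one
#' sequence per protein-coding gene in `CDS_DNA` / `PROTEIN` mode. All
#' sequences of one genome are pooled by the counting stage with the
#' multi-gene frequency formula, each sequence contributing its own windows.
#'
#' @param genome_id Non-empty genome label.
#' @param records Data.frame from [read_fasta()], or a character vector of
#'   sequences.
#' @param mode `"WHOLE_DNA"`, `"CDS_DNA"` or `"PROTEIN"`.
#' @return A `genome_record` with fields `genome_id`, `mode`, `sequences`
#'   (order preserved; `m = length(sequences)`) and `alphabet`.
#' @export
assemble_genome <- function(genome_id, records, mode = "WHOLE_DNA") {
  mode <- match.arg(mode, c("WHOLE_DNA", "CDS_DNA", "PROTEIN"))
  if (!is.character(genome_id) || length(genome_id) != 1L || !nzchar(genome_id))
    stop("genome_id must be a non-empty label")
  seqs <- if (is.data.frame(records)) records$sequence else as.character(records)
  if (length(seqs) == 0L) stop("no sequence records for genome ", genome_id)
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs))) stop("empty sequence in genome ", genome_id)
  alphabet <- alphabet_for_mode(mode)
  ok <- paste(alphabet$letters, collapse = "")
  frac_bad <- vapply(seqs, function(s) {
    n <- nchar(s)
    (n - nchar(gsub(sprintf("[^%s]", ok), "", s))) / n
  }, numeric(1), USE.NAMES = FALSE)
  if (any(frac_bad > 0.5)) {
    stop("genome ", genome_id, ": a sequence has >50% characters outside the ",
         alphabet$name, " alphabet; wrong mode?")
  }
  structure(list(genome_id = genome_id, mode = mode, sequences = seqs,
                 alphabet = alphabet),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome %s: mode %s, %d sequence(s), total length %d>\n",
              x$genome_id, x$mode, length(x$sequences),
              sum(nchar(x$sequences))))
  invisible(x)
}

#' Read a dataset manifest
#'
#' A manifest maps genome ids to FASTA paths: a tab-separated file with
#' header line `genome_id<TAB>path`. Relative paths are resolved against the
#' manifest's directory.
#'
#' @param path Manifest path.
#' @return Data.frame with columns `genome_id` and `path`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("genome_id", "path") %in% names(m)))
    stop("manifest must have columns genome_id and path")
  if (nrow(m) == 0L) stop("empty manifest: ", path)
  if (anyDuplicated(m$genome_id))
    stop("duplicate genome_id in manifest")
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m[, c("genome_id", "path")]
}

#' Load all genomes listed in a manifest
#'
#' @param manifest Path to a manifest, or the data.frame from
#'   [read_manifest()].
#' @inheritParams assemble_genome
#' @return Named list of `genome_record`s, in manifest order.
#' @export
load_genomes <- function(manifest, mode = "WHOLE_DNA") {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  alphabet <- alphabet_for_mode(mode)
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    recs <- read_fasta(manifest$path[i], alphabet)
    assemble_genome(manifest$genome_id[i], recs, mode)
  })
  names(out) <- manifest$genome_id
  out
}
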