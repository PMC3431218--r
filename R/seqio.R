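#' Construct a genome sequence object
#'
#' A lightweight container for one nucleotide record: identifier, upper-cased
#' residue string (IUPAC codes tolerated), length and G+C fraction computed
#' over unambiguous bases only.
#'
#' @param residues character scalar of nucleotides (case-insensitive).
#' @param id non-empty record identifier.
#' @return An object of class `genome_sequence` with fields `id`, `residues`,
#'   `length` and `gc`.
#' @examples
#' s <- genome_sequence("aacg", "x")
#' s$length  # 4
#' s$gc      # 0.5
#' @export
genome_sequence <- function(residues, id = "seq") {
  stopifnot(is.character(residues), length(residues) == 1L)
  if (!nzchar(id)) stop("sequence id must be non-empty")
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (!nzchar(residues)) stop("sequence '", id, "' is empty")
  b <- charToRaw(residues)
  bad <- !(b %in% charToRaw("ACGTNRYSWKMBDHV-"))
  if (any(bad))
    stop("sequence '", id, "' contains non-nucleotide characters: ",
         paste(unique(rawToChar(b[bad], multiple = TRUE)), collapse = " "))
  structure(list(id = id, residues = residues, length = nchar(residues),
                 gc = .gc_from_raw(b)),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("<genome_sequence> %s: %s bp, G+C = %.3f\n",
              x$id, format(x$length, big.mark = ","), x$gc))
  invisible(x)
}

#' Coerce to a genome sequence
#'
#' Accepts a `genome_sequence`, a plain character string, or anything with an
#' `as.character` method yielding a nucleotide string (e.g. a
#' `Biostrings::DNAString`).
#'
#' @param x object to coerce.
#' @param id identifier to use when `x` carries none.
#' @return A `genome_sequence`.
#' @export
as_genome_sequence <- function(x, id = "seq") {
  if (inherits(x, "genome_sequence")) return(x)
  if (is.character(x) && length(x) == 1L) {
    nm <- names(x)
    return(genome_sequence(x, id = if (!is.null(nm) && nzchar(nm)) nm else id))
  }
  genome_sequence(as.character(x), id = id)
}

# gc over unambiguous bases, from a raw byte vector; NA if none
.gc_from_raw <- function(b) {
  gc <- sum(b == as.raw(71L)) + sum(b == as.raw(67L))   # G, C
  at <- sum(b == as.raw(65L)) + sum(b == as.raw(84L))   # A, T
  if (gc + at == 0L) return(NA_real_)
  gc / (gc + at)
}

#' G+C fraction of a sequence
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; ambiguity codes are excluded from both
#' numerator and denominator.
#'
#' @param seq a `genome_sequence` or character string.
#' @return Fraction in `[0, 1]`.
#' @examples
#' gc_content("ACGTN")  # 0.5, the N is ignored
#' @export
gc_content <- function(seq) {
  seq <- as_genome_sequence(seq)
  g <- .gc_from_raw(charToRaw(seq$residues))
  if (is.na(g))
    stop("sequence '", seq$id, "' has no unambiguous bases; ",
         "G+C content undefined")
  g
}

#' Read nucleotide sequences from a FASTA file
#'
#' Each record becomes one [genome_sequence()]; records are never
#' concatenated. Residues are upper-cased and whitespace-stripped; IUPAC
#' ambiguity codes are retained (they can never form part of an A-tract
#' match).
#'
#' @param path FASTA file, optionally multi-record.
#' @return A named list of `genome_sequence` objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e)
                    stop("failed to parse FASTA '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids)))
    stop("FASTA file '", path, "' has a record with an empty header")
  out <- lapply(seq_along(set), function(i)
    genome_sequence(as.character(set[[i]]), id = ids[i]))
  names(out) <- ids
  out
}

#' Write genome sequences to a FASTA file
#'
#' @param seqs a `genome_sequence` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "genome_sequence")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, `[[`, "", "residues"))
  names(set) <- vapply(seqs, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a prophage annotation table
#'
#' Tab-separated file with header columns `replicon_id`, `start`, `end`
#' (1-based inclusive coordinates, Prophinder/ACLAME style). A replicon may
#' appear any number of times; replicons absent from the table are
#' prophage-free.
#'
#' @param path TSV file.
#' @return A data frame with columns `replicon_id` (character), `start`,
#'   `end` (integer), one row per interval; zero rows for an empty table.
#' @export
read_prophage_table <- function(path) {
  if (!file.exists(path)) stop("prophage table not found: ", path)
  tbl <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    colClasses = "character", check.names = FALSE)
  need <- c("replicon_id", "start", "end")
  if (!all(need %in% names(tbl)))
    stop("prophage table must have columns: ", paste(need, collapse = ", "))
  if (nrow(tbl) == 0L)
    return(data.frame(replicon_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  start <- suppressWarnings(as.numeric(tbl$start))
  end <- suppressWarnings(as.numeric(tbl$end))
  for (i in seq_len(nrow(tbl))) {
    line <- i + 1L  # header is line 1
    if (is.na(start[i]) || is.na(end[i]) ||
        start[i] != round(start[i]) || end[i] != round(end[i]))
      stop("prophage table line ", line, ": non-integer coordinates")
    if (start[i] < 1) stop("prophage table line ", line, ": start < 1")
    if (start[i] > end[i]) stop("prophage table line ", line, ": start > end")
  }
  data.frame(replicon_id = tbl$replicon_id, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

#' Group prophage intervals by replicon
#'
#' @param tbl data frame from [read_prophage_table()].
#' @param replicon_ids optional character vector; replicons listed here but
#'   absent from the table get an empty interval set (prophage-free).
#' @return Named list mapping replicon id to a two-column matrix of
#'   `(start, end)` intervals (zero rows = no prophage).
#' @export
prophage_intervals <- function(tbl, replicon_ids = NULL) {
  ids <- union(replicon_ids, unique(tbl$replicon_id))
  out <- lapply(ids, function(id) {
    rows <- tbl[tbl$replicon_id == id, , drop = FALSE]
    cbind(start = rows$start, end = rows$end)
  })
  names(out) <- ids
  out
}

#' Read a replicon-to-organism table
#'
#' Tab-separated file with header columns `replicon_id` and `organism_name`.
#'
#' @param path TSV file.
#' @return Data frame with `replicon_id`, `organism_name` and the derived
#'   `species_key` (see [species_key()]).
#' @export
read_species_table <- function(path) {
  if (!file.exists(path)) stop("species table not found: ", path)
  tbl <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    colClasses = "character", check.names = FALSE)
  need <- c("replicon_id", "organism_name")
  if (!all(need %in% names(tbl)))
    stop("species table must have columns: ", paste(need, collapse = ", "))
  tbl$species_key <- species_key(tbl$organism_name)
  tbl[c("replicon_id", "organism_name", "species_key")]
}

#' Species key from an organism name
#'
#' Genus + species: the first two whitespace-separated tokens, lower-cased;
#' strain designations are ignored so that multiple strains of one species
#' share a key (used by the one-strain-per-species resampling).
#'
#' @param organism_name character vector of organism names.
#' @return Character vector of keys.
#' @examples
#' species_key("Mycoplasma hyopneumoniae J")  # "mycoplasma hyopneumoniae"
#' @export
species_key <- function(organism_name) {
  vapply(strsplit(tolower(trimws(organism_name)), "[[:space:]]+"),
         function(tok) paste(tok[seq_len(min(2L, length(tok)))],
                             collapse = " "),
         character(1))
}
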