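# Sequence and read-pool I/O.
#
# All sequences are held as uppercase character strings over {A,C,G,T,N};
# parsing maps U to T and collapses IUPAC ambiguity codes (other than N) to N
# with a warning, because the exact-k-mer baiting filter and the 100%-identity
# proofreading rule are defined over an unambiguous 4+N alphabet. Internal
# coordinates are 0-based half-open; printed reports are 1-based inclusive.

IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

# Structural pre-check of a (possibly gzipped) 4-line FASTQ file; the
# downstream parser does not reliably reject a quality line whose length
# disagrees with its sequence, so lengths are verified here with exact line
# numbers.
validate_fastq <- function(path, source) {
  lines <- readLines(if (grepl("\\.(gz|bgz)$", path)) gzfile(path) else path,
                     warn = FALSE)
  while (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (!length(lines)) return(invisible())
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("malformed fastq input '%s': %d lines is not a multiple of 4",
                 source, length(lines)), call. = FALSE)
  }
  n <- length(lines) %/% 4L
  for (i in seq_len(n)) {
    base <- 4L * (i - 1L)
    if (!startsWith(lines[base + 1L], "@") || !startsWith(lines[base + 3L], "+")) {
      stop(sprintf("malformed fastq record %d near line %d in '%s'",
                   i, base + 1L, source), call. = FALSE)
    }
    if (nchar(lines[base + 4L]) != nchar(lines[base + 2L])) {
      stop(sprintf(
        "malformed fastq record %d (line %d of '%s'): quality length %d != sequence length %d",
        i, base + 4L, source, nchar(lines[base + 4L]),
        nchar(lines[base + 2L])), call. = FALSE)
    }
  }
  invisible()
}

#' Parse FASTA or FASTQ sequences
#'
#' Reads a FASTA or FASTQ (Sanger-quality) file, possibly gzip-compressed, or
#' literal FASTA/FASTQ text, into a records table. Sequences are uppercased,
#' `U` is mapped to `T`, IUPAC ambiguity codes other than `N` are replaced by
#' `N` with a warning, and any other character is an error.
#'
#' @param source Path to a (optionally gzipped) FASTA/FASTQ file, or a string
#'   containing literal FASTA/FASTQ text.
#' @param format `"auto"` (guess from extension or leading character),
#'   `"fasta"` or `"fastq"`.
#' @return A `data.frame` with columns `id`, `seq` and `qual` (`NA` for
#'   FASTA). One row per record; an empty file gives zero rows.
#' @examples
#' parse_sequences(">r1\nacgt", format = "fasta")
#' @export
parse_sequences <- function(source, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  path <- source
  if (!file.exists(source) && (grepl("[\n>@]", source))) {
    path <- tempfile(fileext = ".txt")
    writeLines(source, path)
    on.exit(unlink(path), add = TRUE)
  }
  if (!file.exists(path)) stop("no such file: ", source)
  if (format == "auto") {
    base <- sub("\\.(gz|bgz)$", "", path)
    format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE)) {
      "fastq"
    } else if (grepl("\\.(fa|fasta|fna|ffn)$", base, ignore.case = TRUE)) {
      "fasta"
    } else {
      first <- substr(readLines(path, n = 1L), 1L, 1L)
      if (identical(first, "@")) "fastq" else "fasta"
    }
  }
  if (format == "fastq") validate_fastq(path, source)
  set <- tryCatch(
    if (format == "fastq") {
      Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
    } else {
      Biostrings::readBStringSet(path, format = "fasta")
    },
    error = function(e) {
      stop(sprintf("malformed %s input '%s': %s", format, source,
                   conditionMessage(e)), call. = FALSE)
    })
  if (length(set) == 0L) {
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  qual <- rep(NA_character_, length(set))
  if (format == "fastq") {
    qual <- as.character(S4Vectors::mcols(set)$qualities)
  }
  has_ambig <- grepl(paste0("[", paste(IUPAC_AMBIG, collapse = ""), "]"), seqs)
  if (any(has_ambig)) {
    warning(sprintf("%d record(s) contain IUPAC ambiguity codes; replaced by N",
                    sum(has_ambig)), call. = FALSE)
    seqs <- chartr(paste(IUPAC_AMBIG, collapse = ""),
                   strrep("N", length(IUPAC_AMBIG)), seqs)
  }
  bad <- !grepl("^[ACGTN]+$", seqs)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("record %d ('%s') contains non-nucleotide characters", i, ids[i]),
         call. = FALSE)
  }
  data.frame(id = unname(ids), seq = unname(seqs), qual = unname(qual),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write sequences as FASTA or FASTQ
#'
#' @param records A records `data.frame` (`id`, `seq`, optional `qual`), a
#'   [read_pool()], or a named character vector.
#' @param path Output file path; `.gz` suffix writes gzip-compressed.
#' @param format `"fasta"` or `"fastq"`. FASTQ records lacking qualities get a
#'   constant placeholder quality (`I`).
#' @return `path`, invisibly.
#' @export
write_sequences <- function(records, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  records <- as_records(records)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con), add = TRUE)
  if (format == "fasta") {
    lines <- rbind(paste0(">", records$id), records$seq)
  } else {
    qual <- records$qual
    if (is.null(qual)) qual <- rep(NA_character_, nrow(records))
    qual <- ifelse(is.na(qual), strrep("I", nchar(records$seq)), qual)
    lines <- rbind(paste0("@", records$id), records$seq, "+", qual)
  }
  writeLines(as.vector(lines), con)
  invisible(path)
}

#' Construct a read pool
#'
#' A read pool bundles a records table with optional pairing information and
#' optional per-read provenance labels (used by the simulator to track which
#' genome a read came from).
#'
#' @param records Records `data.frame` as returned by [parse_sequences()].
#' @param pairing Optional `data.frame` with columns `pair_id`, `fwd`, `rev`.
#' @param provenance Optional named character vector mapping read id to a
#'   source label.
#' @return An object of class `read_pool`.
#' @export
read_pool <- function(records, pairing = NULL, provenance = NULL) {
  records <- as_records(records)
  if (anyDuplicated(records$id)) {
    stop("duplicate read ids in pool: ",
         records$id[duplicated(records$id)][1])
  }
  if (any(grepl("\\s", records$id))) stop("read ids must not contain whitespace")
  assert_dna(records$seq, "read")
  if (!is.null(pairing)) {
    stopifnot(all(c("pair_id", "fwd", "rev") %in% names(pairing)))
    missing <- setdiff(c(pairing$fwd, pairing$rev), records$id)
    if (length(missing)) {
      stop("pairing references unknown read ids: ", missing[1])
    }
  }
  structure(list(records = records, pairing = pairing, provenance = provenance),
            class = "read_pool")
}

#' @export
print.read_pool <- function(x, ...) {
  cat(sprintf("<read_pool> %d reads, %s pairs%s\n",
              nrow(x$records),
              if (is.null(x$pairing)) "un-paired" else nrow(x$pairing),
              if (is.null(x$provenance)) "" else
                sprintf(", %d provenance labels",
                        length(unique(x$provenance)))))
  invisible(x)
}

#' Number of reads in a pool
#' @param pool A [read_pool()].
#' @export
n_reads <- function(pool) nrow(pool$records)

#' Pair reads in a pool
#'
#' Populates the pairing map of a pool, either from the `/1` `/2` id-suffix
#' convention or from interleaved order (forward then reverse). Reads whose
#' mate is missing are flagged unpaired with a warning.
#'
#' @param pool A [read_pool()].
#' @param convention `"suffix"` (ids `x/1` + `x/2`) or `"interleaved"`.
#' @return The pool with `pairing` populated and an `unpaired` id vector.
#' @export
pair_reads <- function(pool, convention = c("suffix", "interleaved")) {
  convention <- match.arg(convention)
  ids <- pool$records$id
  if (convention == "suffix") {
    has1 <- grepl("/1$", ids)
    has2 <- grepl("/2$", ids)
    base <- sub("/[12]$", "", ids)
    fwd <- setNames(ids[has1], base[has1])
    rev <- setNames(ids[has2], base[has2])
    shared <- intersect(names(fwd), names(rev))
    pairing <- data.frame(pair_id = shared, fwd = unname(fwd[shared]),
                          rev = unname(rev[shared]), stringsAsFactors = FALSE)
  } else {
    n <- length(ids)
    npair <- n %/% 2L
    take <- seq_len(npair * 2L)
    fwd <- ids[take[seq(1L, length(take), by = 2L)]]
    rev <- ids[take[seq(2L, length(take), by = 2L)]]
    pairing <- data.frame(pair_id = sub("/[12]$", "", fwd), fwd = fwd,
                          rev = rev, stringsAsFactors = FALSE)
  }
  paired_ids <- c(pairing$fwd, pairing$rev)
  unpaired <- setdiff(ids, paired_ids)
  if (length(unpaired)) {
    warning(length(unpaired), " read(s) lack a mate and are flagged unpaired",
            call. = FALSE)
  }
  pool$pairing <- pairing
  pool$unpaired <- unpaired
  pool
}

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`; alphabet restricted to `{A,C,G,T,N}` (`N` is its own
#' complement). Applying the function twice returns the input.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement(c("AAAC", "ANT"))
#' @export
reverse_complement <- function(x) {
  assert_dna(x)
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

# Keep only the given read ids (order of the original records preserved);
# pairing rows survive when both mates survive, provenance is subset.
subset_pool <- function(pool, ids) {
  keep <- pool$records$id %in% ids
  records <- pool$records[keep, , drop = FALSE]
  rownames(records) <- NULL
  pairing <- pool$pairing
  if (!is.null(pairing)) {
    pairing <- pairing[pairing$fwd %in% records$id & pairing$rev %in% records$id, ,
                       drop = FALSE]
    rownames(pairing) <- NULL
  }
  provenance <- pool$provenance
  if (!is.null(provenance)) provenance <- provenance[records$id]
  structure(list(records = records, pairing = pairing, provenance = provenance),
            class = "read_pool")
}
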